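# Exact rational arithmetic on (numerator, denominator) pairs stored as
# doubles.  All quantities handled here (measure weights, transport costs)
# have small integer numerators and denominators, so double arithmetic is
# exact as long as intermediates stay below 2^53; .rat_check guards that.

.MAX_EXACT <- 2^53

.gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) {
    r <- a %% b
    a <- b
    b <- r
  }
  a
}

.lcm2 <- function(a, b) (a / .gcd(a, b)) * b

.rat_check <- function(x) {
  if (abs(x) >= .MAX_EXACT) {
    stop("exact rational arithmetic overflow; value too large for exact mode",
         call. = FALSE)
  }
  x
}

# a rational is c(num, den) with den > 0, reduced
rat <- function(num, den = 1) {
  if (den == 0) stop("zero denominator", call. = FALSE)
  if (den < 0) {
    num <- -num
    den <- -den
  }
  g <- .gcd(num, den)
  if (g > 1) {
    num <- num / g
    den <- den / g
  }
  c(num, den)
}

rat_add <- function(a, b) {
  rat(.rat_check(a[1] * b[2] + b[1] * a[2]), .rat_check(a[2] * b[2]))
}

rat_sub <- function(a, b) rat_add(a, c(-b[1], b[2]))

rat_mul <- function(a, b) rat(.rat_check(a[1] * b[1]), .rat_check(a[2] * b[2]))

rat_eq <- function(a, b) a[1] == b[1] && a[2] == b[2]

rat_num <- function(a) a[1] / a[2]

rat_fmt <- function(a) {
  if (a[2] == 1) format(a[1]) else paste0(format(a[1]), "/", format(a[2]))
}

# sum of rationals given as parallel num/den vectors
rat_vsum <- function(num, den) {
  acc <- c(0, 1)
  for (i in seq_along(num)) acc <- rat_add(acc, c(num[i], den[i]))
  acc
}

# least common multiple of a vector of positive integers
lcm_all <- function(x) {
  acc <- 1
  for (v in x) acc <- .rat_check(.lcm2(acc, v))
  acc
}
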