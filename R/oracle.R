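# Independent brute-force 1-Wasserstein solver used to validate the
# transportation solver on small instances.  Both measures are expanded into
# D atoms of weight 1/D (D the least common multiple of all weight
# denominators); a transportation problem with rational marginals attains its
# optimum on the 1/D grid (the scaled transportation polytope is integral),
# so the minimum-cost atom assignment equals the LP optimum exactly.

.perm_cache <- new.env(parent = emptyenv())

.all_perms <- function(n) {
  key <- as.character(n)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  perms <- function(v) {
    if (length(v) <= 1) return(matrix(v, nrow = max(1, length(v))))
    out <- NULL
    for (i in seq_along(v)) {
      rest <- perms(v[-i])
      out <- rbind(out, cbind(v[i], rest))
    }
    out
  }
  p <- perms(seq_len(n))
  .perm_cache[[key]] <- p
  p
}

# exact min-cost perfect assignment (Hungarian algorithm, O(n^3)) on a
# square cost matrix; returns the optimal total cost
.hungarian_cost <- function(a) {
  n <- nrow(a)
  u <- numeric(n)
  v <- numeric(n + 1)          # column 1 is the virtual column
  p <- integer(n + 1)          # p[j]: row currently assigned to column j
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0L
      for (j in 2:(n + 1)) {
        if (!used[j]) {
          cur <- a[i0, j - 1] - u[i0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in seq_len(n + 1)) {
        if (used[j]) {
          if (p[j] > 0) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  assign_col <- integer(n)
  for (j in 2:(n + 1)) assign_col[p[j]] <- j - 1L
  sum(a[cbind(seq_len(n), assign_col)])
}

#' Brute-force 1-Wasserstein distance (test oracle)
#'
#' Expands both measures into D unit atoms of weight 1/D and minimises the
#' total distance over perfect atom assignments: exhaustive search over all
#' permutations for D <= 8, an exact Hungarian assignment solver otherwise.
#' The result is an exact rational equal to the transportation LP optimum.
#' Intended as an independent check of [wasserstein1()] on small instances;
#' it is deliberately slow and guards against D > 64.
#'
#' @param mu_a,mu_b `vertex_measure`s.
#' @param dist distance matrix as in [wasserstein1()] (entries need not be
#'   restricted to 0:3 here, only finite and non-negative).
#' @return list with `cost` (numeric) and `cost_rat` (numerator/denominator).
#' @export
brute_force_w1 <- function(mu_a, mu_b, dist) {
  stopifnot(inherits(mu_a, "vertex_measure"), inherits(mu_b, "vertex_measure"))
  D <- lcm_all(c(mu_a$den, mu_b$den))
  if (D > 64) {
    stop("common denominator ", D,
         " exceeds the oracle guard (64); use wasserstein1() instead")
  }
  atoms_a <- rep(mu_a$vertex, times = mu_a$num * (D / mu_a$den))
  atoms_b <- rep(mu_b$vertex, times = mu_b$num * (D / mu_b$den))
  stopifnot(length(atoms_a) == D, length(atoms_b) == D)
  C <- dist[atoms_a, atoms_b, drop = FALSE]
  if (any(!is.finite(C)) || any(C < 0)) {
    stop("distances must be finite and non-negative")
  }
  if (D == 1) {
    total <- C[1, 1]
  } else if (D <= 8) {
    P <- .all_perms(D)
    costs <- numeric(nrow(P))
    for (i in seq_len(D)) costs <- costs + C[i, P[, i]]
    total <- min(costs)
  } else {
    total <- .hungarian_cost(C)
  }
  list(cost = total / D, cost_rat = rat(total, D))
}
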