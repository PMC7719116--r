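#' Batch curvature computation
#'
#' Computes the selected edge measures for every edge or hyperedge of a
#' structure, in input order.  `"forman"` is the Forman-Ricci curvature,
#' `"daleth"` the degree difference, `"ollivier"` the Ollivier-Ricci
#' curvature together with the m-vector of one optimal transport plan.
#' Ollivier values are independent across edges, so any execution order
#' yields identical output.  A hyperedge with an empty tail or head has no
#' in- resp. out-measure; its Ollivier value is reported as `NA` with a
#' warning.
#'
#' @param structure an `undirected_graph`, `directed_graph` or
#'   `directed_hypergraph`.
#' @param measures character subset of `c("forman", "daleth", "ollivier")`.
#' @param progress_every log progress to stderr every this many edges
#'   (0 = never).
#' @return a `curvature_table` data frame with columns `edge_id`, `forman`,
#'   `degree_difference`, `ollivier`, `m0`..`m3` (unrequested measures are
#'   `NA`).
#' @examples
#' compute_curvatures(fixture("fig3"))
#' @export
compute_curvatures <- function(structure,
                               measures = c("forman", "daleth", "ollivier"),
                               progress_every = 1000) {
  measures <- match.arg(measures, several.ok = TRUE)
  hyper <- inherits(structure, "directed_hypergraph")
  edge_ids <- function(sep) {
    if (nrow(structure$edges) == 0) character(0)
    else paste0(structure$edges[, 1], sep, structure$edges[, 2])
  }
  if (hyper) {
    ids <- structure$ids
    edge_of <- function(i) structure$ids[i]
    olli_struct <- structure
  } else if (inherits(structure, "directed_graph")) {
    ids <- edge_ids("->")
    edge_of <- function(i) structure$edges[i, ]
    # convert once; per-edge conversion would redo the incidence index
    olli_struct <- if ("ollivier" %in% measures) {
      digraph_to_hypergraph(structure)
    }
  } else if (inherits(structure, "undirected_graph")) {
    ids <- edge_ids("--")
    edge_of <- function(i) structure$edges[i, ]
    olli_struct <- structure
  } else {
    stop("unsupported structure class")
  }
  n <- length(ids)
  res <- data.frame(edge_id = ids,
                    forman = rep(NA_integer_, n),
                    degree_difference = rep(NA_integer_, n),
                    ollivier = rep(NA_real_, n),
                    m0 = rep(NA_real_, n), m1 = rep(NA_real_, n),
                    m2 = rep(NA_real_, n), m3 = rep(NA_real_, n),
                    stringsAsFactors = FALSE)
  forman_fun <- if (hyper) forman_hypergraph
                else if (inherits(structure, "directed_graph")) forman_directed
                else forman_undirected
  empty_side <- FALSE
  for (i in seq_len(n)) {
    e <- edge_of(i)
    if ("forman" %in% measures) res$forman[i] <- forman_fun(structure, e)
    if ("daleth" %in% measures) {
      res$degree_difference[i] <- degree_difference(structure, e)
    }
    if ("ollivier" %in% measures) {
      key <- if (hyper) e else if (inherits(structure, "directed_graph")) {
        paste0(e[1], "->", e[2])
      } else e
      if (hyper && (length(structure$tail[[i]]) == 0 ||
                    length(structure$head[[i]]) == 0)) {
        empty_side <- TRUE
      } else {
        o <- ollivier(olli_struct, key)
        res$ollivier[i] <- o$value
        res[i, c("m0", "m1", "m2", "m3")] <- as.list(unname(o$m))
      }
    }
    if (progress_every > 0 && i %% progress_every == 0) {
      message("computed ", i, "/", n, " edges")
    }
  }
  if (empty_side) {
    warning("hyperedges with an empty tail or head have no Ollivier ",
            "curvature; reported as NA")
  }
  class(res) <- c("curvature_table", "data.frame")
  res
}

#' Summarise a curvature distribution
#'
#' Count, extremes, mean and median of one measure across a curvature table,
#' plus a histogram with contiguous bins of the given width anchored at the
#' integer floor of the minimum.  Default widths: 1 for the integer-valued
#' measures (`forman`, `degree_difference`), 0.05 for `ollivier`.
#'
#' @param records a `curvature_table` (or any data frame with the measure
#'   column).
#' @param measure column name to summarise.
#' @param bin_width histogram bin width.
#' @return an object of class `curvature_summary`: list with fields
#'   `measure`, `count`, `min`, `max`, `mean`, `median` and `histogram`
#'   (data frame with columns `lower`, `width`, `count`).
#' @export
summarize_curvatures <- function(records,
                                 measure = c("ollivier", "forman",
                                             "degree_difference"),
                                 bin_width = NULL) {
  measure <- match.arg(measure)
  x <- records[[measure]]
  x <- x[!is.na(x)]
  if (length(x) == 0) stop("no values for measure '", measure, "'")
  if (is.null(bin_width)) {
    bin_width <- if (measure == "ollivier") 0.05 else 1
  }
  lo <- floor(min(x))
  nb <- max(1L, ceiling((max(x) - lo) / bin_width + 1e-9))
  if (lo + nb * bin_width <= max(x)) nb <- nb + 1L
  breaks <- lo + bin_width * (0:nb)
  counts <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE,
                                  left.open = FALSE), nbins = nb)
  structure(list(measure = measure, count = length(x),
                 min = min(x), max = max(x), mean = mean(x),
                 median = stats::median(x),
                 histogram = data.frame(lower = breaks[-length(breaks)],
                                        width = bin_width, count = counts)),
            class = "curvature_summary")
}

#' @export
print.curvature_summary <- function(x, ...) {
  cat("summary of ", x$measure, ": n = ", x$count,
      ", min = ", format(x$min), ", max = ", format(x$max),
      ", mean = ", format(x$mean), ", median = ", format(x$median),
      "\n", sep = "")
  nonzero <- x$histogram[x$histogram$count > 0, ]
  for (i in seq_len(nrow(nonzero))) {
    cat(sprintf("  [%g, %g): %d\n", nonzero$lower[i],
                nonzero$lower[i] + nonzero$width[i], nonzero$count[i]))
  }
  invisible(x)
}

#' Degree assortativity of an undirected graph
#'
#' Pearson correlation of the remaining degrees at the two ends of an edge,
#' over the doubled edge list (the standard excess-degree formulation).
#' Negative values indicate that high-degree vertices preferentially attach
#' to low-degree ones.  Undefined (zero variance) for regular graphs.
#'
#' @param G an `undirected_graph` with at least 2 edges.
#' @return numeric in \[-1, 1\].
#' @export
degree_assortativity <- function(G) {
  stopifnot(inherits(G, "undirected_graph"))
  if (nrow(G$edges) < 2) stop("assortativity needs at least 2 edges")
  ig <- .as_igraph(G)
  degs <- igraph::degree(ig)
  if (length(unique(degs[degs > 0])) == 1 &&
      all(degs[as.vector(G$edges)] == degs[G$edges[1, 1]])) {
    stop("assortativity undefined for regular graphs")
  }
  r <- igraph::assortativity_degree(ig, directed = FALSE)
  if (!is.finite(r)) stop("assortativity undefined for regular graphs")
  r
}

#' Giant component of a graph
#'
#' Returns the subgraph induced by the largest connected component
#' (undirected sense for both graph classes), the standard restriction used
#' when analysing interaction networks that are globally disconnected.
#'
#' @param G an `undirected_graph` or `directed_graph`.
#' @return same class as `G`.
#' @export
giant_component <- function(G) {
  stopifnot(inherits(G, "undirected_graph") || inherits(G, "directed_graph"))
  if (length(G$vertices) == 0) return(G)
  und <- if (inherits(G, "undirected_graph")) G$edges else G$edges
  ig <- igraph::graph_from_data_frame(
    data.frame(from = und[, 1], to = und[, 2], stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = G$vertices, stringsAsFactors = FALSE))
  comp <- igraph::components(ig)
  keep <- names(comp$membership)[comp$membership == which.max(comp$csize)]
  edges <- G$edges[G$edges[, 1] %in% keep & G$edges[, 2] %in% keep, ,
                   drop = FALSE]
  if (inherits(G, "undirected_graph")) {
    undirected_graph(edges, vertices = keep)
  } else {
    directed_graph(edges, vertices = keep)
  }
}
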