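# Tab-delimited readers and writers.  All formats are UTF-8, tab-separated,
# with "#" comment lines.

.read_lines <- function(path) {
  raw <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*#", raw) & nzchar(trimws(raw))
  list(lines = raw[keep], lineno = which(keep))
}

# strsplit drops trailing empty fields; pad to a fixed column count
.split_tsv <- function(line, ncol) {
  f <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(f) < ncol) f <- c(f, rep("", ncol - length(f)))
  f
}

#' Read an edge list
#'
#' One edge per line: two vertex labels separated by whitespace (tab or
#' spaces).  Lines starting with `#` are ignored.  Self-loops are rejected
#' with the offending line number.  In undirected mode duplicate pairs
#' (in either order) collapse to a single edge with a warning; in directed
#' mode (a, b) and (b, a) are distinct edges.
#'
#' @param path file path.
#' @param directed logical; read as a directed graph?
#' @return an `undirected_graph` or `directed_graph`.
#' @export
read_edge_list <- function(path, directed = FALSE) {
  src <- .read_lines(path)
  n <- length(src$lines)
  edges <- matrix(character(0), ncol = 2)
  if (n > 0) {
    parts <- strsplit(trimws(src$lines), "[ \t]+")
    bad <- which(lengths(parts) != 2)
    if (length(bad)) {
      stop("malformed edge at line ", src$lineno[bad[1]],
           ": expected two vertex labels")
    }
    edges <- matrix(unlist(parts), ncol = 2, byrow = TRUE)
    loops <- which(edges[, 1] == edges[, 2])
    if (length(loops)) {
      stop("self-loop at line ", src$lineno[loops[1]],
           " (vertex '", edges[loops[1], 1], "')")
    }
    if (!directed) {
      canon <- t(apply(edges, 1, sort))
      key <- paste(canon[, 1], canon[, 2], sep = "\r")
      if (anyDuplicated(key)) {
        warning("collapsed ", sum(duplicated(key)),
                " duplicate undirected edge(s) in ", path)
        edges <- canon[!duplicated(key), , drop = FALSE]
      }
    }
  }
  if (directed) directed_graph(edges) else undirected_graph(edges)
}

#' Read a directed hypergraph
#'
#' One hyperedge per line: `id<TAB>tail<TAB>head`, where tail and head are
#' comma-separated vertex lists.  Either list may be empty, but not both.
#' Duplicate vertices within a list are deduplicated with a warning;
#' duplicate ids are an error.
#'
#' @param path file path.
#' @return a `directed_hypergraph`.
#' @export
read_hypergraph <- function(path) {
  src <- .read_lines(path)
  split_list <- function(s) {
    v <- trimws(strsplit(s, ",", fixed = TRUE)[[1]])
    v[nzchar(v)]
  }
  hes <- vector("list", length(src$lines))
  for (i in seq_along(src$lines)) {
    f <- .split_tsv(src$lines[i], 3)
    if (length(f) != 3 || !nzchar(trimws(f[1]))) {
      stop("malformed hyperedge record at line ", src$lineno[i])
    }
    tl <- split_list(f[2]); hd <- split_list(f[3])
    if (length(tl) == 0 && length(hd) == 0) {
      stop("line ", src$lineno[i], ": tail and head both empty")
    }
    if (anyDuplicated(tl) || anyDuplicated(hd)) {
      warning("line ", src$lineno[i], ": duplicate vertices deduplicated")
    }
    hes[[i]] <- list(id = trimws(f[1]), tail = unique(tl), head = unique(hd))
  }
  directed_hypergraph(hes)
}

#' Read a metabolic reaction table as a directed hypergraph
#'
#' TSV with four columns: reaction id, direction (`irrev` or `rev`),
#' comma-separated reactant list, comma-separated product list.  Species
#' tokens may carry a leading integer stoichiometric coefficient
#' (`"2 h"`); coefficients are dropped, since the hypergraph is set-valued
#' and unweighted (one warning per file).  Species are deduplicated within a
#' side; a species on both sides (a catalyst) is kept on both.  Each
#' irreversible reaction becomes one hyperedge (tail = reactants,
#' head = products); each reversible reaction is split into a forward
#' hyperedge `id_f` and a reverse hyperedge `id_r` with tail and head
#' swapped, so the hyperedge count is #irreversible + 2 * #reversible.
#'
#' @param path file path.
#' @return a `directed_hypergraph`.
#' @export
read_reaction_table <- function(path) {
  src <- .read_lines(path)
  coef_seen <- FALSE
  split_species <- function(s) {
    v <- trimws(strsplit(s, ",", fixed = TRUE)[[1]])
    v <- v[nzchar(v)]
    stripped <- sub("^[0-9]+\\s+", "", v)
    if (any(stripped != v)) coef_seen <<- TRUE
    unique(stripped)
  }
  hes <- list()
  for (i in seq_along(src$lines)) {
    f <- .split_tsv(src$lines[i], 4)
    id <- trimws(f[1]); dir <- trimws(f[2])
    if (!nzchar(id)) stop("missing reaction id at line ", src$lineno[i])
    if (!dir %in% c("irrev", "rev")) {
      stop("line ", src$lineno[i], ": unknown direction token '", dir,
           "' (expected 'irrev' or 'rev')")
    }
    reac <- split_species(f[3]); prod <- split_species(f[4])
    if (length(reac) == 0 && length(prod) == 0) {
      stop("line ", src$lineno[i], ": reactants and products both empty")
    }
    if (dir == "irrev") {
      hes[[length(hes) + 1L]] <- list(id = id, tail = reac, head = prod)
    } else {
      hes[[length(hes) + 1L]] <- list(id = paste0(id, "_f"),
                                      tail = reac, head = prod)
      hes[[length(hes) + 1L]] <- list(id = paste0(id, "_r"),
                                      tail = prod, head = reac)
    }
  }
  if (coef_seen) {
    warning("stoichiometric coefficients dropped (hypergraph is set-valued)")
  }
  directed_hypergraph(hes)
}

#' Write / read a curvature result table
#'
#' TSV with header `edge_id, forman, degree_difference, ollivier, m0, m1,
#' m2, m3`.  Values are rendered as decimals with 12 significant digits;
#' absent measures are written as `NA`.  `read_curvature_table` parses such a
#' file back into a data frame.
#'
#' @param path file path.
#' @param records a `curvature_table` data frame as produced by
#'   [compute_curvatures()].
#' @return `write_curvature_table` returns `path` invisibly.
#' @export
write_curvature_table <- function(path, records) {
  cols <- c("edge_id", "forman", "degree_difference", "ollivier",
            "m0", "m1", "m2", "m3")
  stopifnot(is.data.frame(records), all(cols %in% names(records)) ||
              nrow(records) == 0)
  fmt <- function(x) {
    ifelse(is.na(x), "NA", vapply(x, function(v) {
      if (is.na(v)) "NA" else format(signif(v, 12), scientific = FALSE)
    }, character(1)))
  }
  out <- c(paste(cols, collapse = "\t"))
  if (nrow(records) > 0) {
    body <- cbind(records$edge_id,
                  fmt(records$forman), fmt(records$degree_difference),
                  fmt(records$ollivier), fmt(records$m0), fmt(records$m1),
                  fmt(records$m2), fmt(records$m3))
    out <- c(out, apply(body, 1, paste, collapse = "\t"))
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}

#' @rdname write_curvature_table
#' @export
read_curvature_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = "NA", comment.char = "#")
  df$edge_id <- as.character(df$edge_id)
  class(df) <- c("curvature_table", "data.frame")
  df
}
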