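#' Format a reaction edge as a string
#'
#' A reaction (edge) is represented as `"node_0 -> node_1"`, meaning the
#' source metabolite is transformed into the target metabolite.
#'
#' @param source,target Non-empty node labels.
#' @return Character vector `source -> target` (vectorized).
#' @export
edge_string <- function(source, target) {
  stopifnot(all(nzchar(source)), all(nzchar(target)))
  paste(source, "->", target)
}

#' Parse a reaction edge string
#'
#' Inverse of [edge_string()]. Splits on the last occurrence of `" -> "` so
#' that a label containing that substring in source position is tolerated.
#'
#' @param x Character vector of `"node_0 -> node_1"` strings.
#' @return Two-column character matrix with columns `from`, `to`.
#' @export
parse_edge_string <- function(x) {
  from <- character(length(x)); to <- character(length(x))
  for (i in seq_along(x)) {
    hits <- gregexpr(" -> ", x[[i]], fixed = TRUE)[[1L]]
    if (hits[1L] < 0L) stop("not an edge string: ", x[[i]], call. = FALSE)
    p <- hits[length(hits)]
    from[i] <- substr(x[[i]], 1L, p - 1L)
    to[i] <- substr(x[[i]], p + 4L, nchar(x[[i]]))
  }
  cbind(from = from, to = to)
}

#' Differentiation by Pairs
#'
#' Compares two pathway graphs at the reaction (edge) level: lists the
#' reactions present in one pathway and absent from the other, in both
#' directions, and summarizes them as the numerical score
#' `(|unique to a| + |unique to b|) / (complexity(a) + complexity(b))`,
#' a difference fraction between 0 (identical edge sets) and 1 (disjoint
#' edge sets). An edge is identified purely by its (source, target) label
#' pair. Because the score is a difference, reports also carry the
#' complement `1 - numerical` as a similarity for plotting convenience.
#'
#' @param graph_a,graph_b Two [pathway_graph] objects; at least one edge
#'   between them.
#' @return An object of class `dbp_result`: `unique_to_a` and `unique_to_b`
#'   (sorted character vectors of `"node_0 -> node_1"` strings) and
#'   `numerical`.
#' @examples
#' a <- pathway_graph(list(A = "B", B = "C"))
#' b <- pathway_graph(list(A = "B", B = "D"))
#' differentiate_pairs(a, b)$numerical  # 0.5
#' @export
differentiate_pairs <- function(graph_a, graph_b) {
  stopifnot(inherits(graph_a, "pathway_graph"), inherits(graph_b, "pathway_graph"))
  ca <- pathway_complexity(graph_a)
  cb <- pathway_complexity(graph_b)
  if (ca + cb < 1L) {
    stop("numerical Differentiation by Pairs is undefined for two edgeless graphs",
         call. = FALSE)
  }
  ea <- pathway_edges(graph_a)
  eb <- pathway_edges(graph_b)
  sa <- if (nrow(ea)) edge_string(ea[, "from"], ea[, "to"]) else character()
  sb <- if (nrow(eb)) edge_string(eb[, "from"], eb[, "to"]) else character()
  structure(
    list(unique_to_a = sort(setdiff(sa, sb)),
         unique_to_b = sort(setdiff(sb, sa)),
         numerical = (length(setdiff(sa, sb)) + length(setdiff(sb, sa))) / (ca + cb)),
    class = "dbp_result"
  )
}

#' @export
print.dbp_result <- function(x, ...) {
  cat(sprintf("<dbp_result> numerical=%.4f (%d unique to a, %d unique to b)\n",
              x$numerical, length(x$unique_to_a), length(x$unique_to_b)))
  invisible(x)
}
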