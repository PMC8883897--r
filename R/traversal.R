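#' Breadth-first linearization of a pathway graph
#'
#' Visits the nodes reachable from `origin` level by level, which mirrors how
#' metabolite reactions proceed from an initial substrate towards products.
#' Within a level, children are enqueued in ascending label order so the
#' sequence is deterministic; a visited set makes the traversal cycle-safe.
#' Each reachable node appears exactly once.
#'
#' @param graph A [pathway_graph].
#' @param origin Node label to start from (must be a node of `graph`).
#' @return Character vector of labels in visit order, starting with `origin`.
#' @examples
#' g <- pathway_graph(list(A = c("B", "C"), B = "D", C = "D"))
#' bfs_sequence(g, "A")  # A B C D
#' dfs_sequence(g, "A")  # A B D C
#' @export
bfs_sequence <- function(graph, origin) {
  stopifnot(inherits(graph, "pathway_graph"))
  if (!origin %in% graph$nodes) {
    stop("origin \"", origin, "\" is not a node of graph ", graph$pathway_id,
         call. = FALSE)
  }
  visited <- structure(rep(FALSE, length(graph$nodes)), names = graph$nodes)
  queue <- origin
  visited[origin] <- TRUE
  sequence <- character()
  while (length(queue)) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    sequence <- c(sequence, v)
    for (w in graph$adjacency[[v]]) {  # stored sorted ascending
      if (!visited[[w]]) {
        visited[w] <- TRUE
        queue <- c(queue, w)
      }
    }
  }
  sequence
}

#' Depth-first linearization of a pathway graph
#'
#' Preorder depth-first traversal with children explored in ascending label
#' order and visited-set cycle protection. Provided for comparison with
#' [bfs_sequence()]: in a depth-first sequence the end product can surface in
#' the middle of the row, which makes the breadth-first order the default for
#' pathway comparison.
#'
#' @inheritParams bfs_sequence
#' @return Character vector of labels in preorder.
#' @export
dfs_sequence <- function(graph, origin) {
  stopifnot(inherits(graph, "pathway_graph"))
  if (!origin %in% graph$nodes) {
    stop("origin \"", origin, "\" is not a node of graph ", graph$pathway_id,
         call. = FALSE)
  }
  visited <- structure(rep(FALSE, length(graph$nodes)), names = graph$nodes)
  sequence <- character()
  stack <- origin
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (visited[[v]]) next
    visited[v] <- TRUE
    sequence <- c(sequence, v)
    kids <- graph$adjacency[[v]]
    if (length(kids)) stack <- c(stack, rev(kids))
  }
  sequence
}

#' Test the candidate-selection criteria for a traversal lecture
#'
#' A pair (origin, destiny) admits a valid traversal lecture when `origin`
#' is an origin node of the graph, `destiny` is a destiny node, and the
#' destiny is reachable from the origin. Some destinies are only reachable
#' from one of several origins, so reachability must be checked per pair.
#'
#' @param graph A [pathway_graph].
#' @param origin,destiny Node labels; both must exist in the graph.
#' @return `TRUE` or `FALSE`.
#' @export
is_valid_lecture <- function(graph, origin, destiny) {
  stopifnot(inherits(graph, "pathway_graph"))
  missing <- setdiff(c(origin, destiny), graph$nodes)
  if (length(missing)) {
    stop("label(s) not in graph ", graph$pathway_id, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  origin %in% origins(graph) &&
    destiny %in% destinies(graph) &&
    destiny %in% bfs_sequence(graph, origin)
}

#' Build a traversal lecture
#'
#' A traversal is the 1D label sequence read from a pathway graph: it starts
#' at the chosen origin and continues, breadth first, until every reachable
#' node has been visited — the destiny is a validity requirement, not a
#' stopping rule, and can be found anywhere in the sequence. The traversal
#' has full coverage when it visits every node of the graph.
#'
#' @inheritParams is_valid_lecture
#' @return An object of class `traversal`: `graph_id`, `origin`, `destiny`,
#'   `sequence` (character vector), `full_coverage` (logical).
#' @export
make_traversal <- function(graph, origin, destiny) {
  stopifnot(inherits(graph, "pathway_graph"))
  missing <- setdiff(c(origin, destiny), graph$nodes)
  if (length(missing)) {
    stop("label(s) not in graph ", graph$pathway_id, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!origin %in% origins(graph)) {
    stop("\"", origin, "\" is not an origin of graph ", graph$pathway_id,
         " (needs out-degree >= 1 and in-degree 0)", call. = FALSE)
  }
  if (!destiny %in% destinies(graph)) {
    stop("\"", destiny, "\" is not a destiny of graph ", graph$pathway_id,
         " (needs in-degree >= 1 and out-degree 0)", call. = FALSE)
  }
  sequence <- bfs_sequence(graph, origin)
  if (!destiny %in% sequence) {
    stop("destiny \"", destiny, "\" is not reachable from origin \"", origin,
         "\" in graph ", graph$pathway_id, call. = FALSE)
  }
  structure(
    list(graph_id = graph$pathway_id,
         origin = origin,
         destiny = destiny,
         sequence = sequence,
         full_coverage = length(sequence) == pathway_size(graph)),
    class = "traversal"
  )
}

#' @export
print.traversal <- function(x, ...) {
  cat(sprintf("<traversal> %s: %s => %s (%d nodes%s)\n  %s\n",
              x$graph_id, x$origin, x$destiny, length(x$sequence),
              if (x$full_coverage) ", full coverage" else "",
              paste(x$sequence, collapse = " -> ")))
  invisible(x)
}

valid_traversals <- function(graph) {
  out <- list()
  for (o in origins(graph)) {
    reach <- bfs_sequence(graph, o)
    for (d in intersect(destinies(graph), reach)) {
      out[[length(out) + 1L]] <- make_traversal(graph, o, d)
    }
  }
  out
}

#' Enumerate candidate traversal pairs for a pathway comparison
#'
#' Builds every valid traversal (one per valid origin-destiny pair) of each
#' graph and returns their cross product in deterministic sorted order. Each
#' candidate is annotated with whether the two origins carry the same label
#' and whether the two destinies do ("corresponding equivalent nodes");
#' label equality is annotated, not required. With
#' `require_full_coverage = TRUE`, only candidates where both traversals
#' cover their whole graph are kept (a "fair comparison").
#'
#' @param graph_a,graph_b Two [pathway_graph] objects.
#' @param require_full_coverage Keep only full-coverage pairs?
#' @return List of candidates, each a list with `traversal_a`,
#'   `traversal_b`, `origin_equivalent`, `destiny_equivalent`. Empty list
#'   when either graph has no valid lecture.
#' @export
enumerate_candidates <- function(graph_a, graph_b, require_full_coverage = FALSE) {
  ta <- valid_traversals(graph_a)
  tb <- valid_traversals(graph_b)
  if (require_full_coverage) {
    ta <- Filter(function(t) t$full_coverage, ta)
    tb <- Filter(function(t) t$full_coverage, tb)
  }
  out <- list()
  for (a in ta) {
    for (b in tb) {
      out[[length(out) + 1L]] <- list(
        traversal_a = a,
        traversal_b = b,
        origin_equivalent = identical(a$origin, b$origin),
        destiny_equivalent = identical(a$destiny, b$destiny)
      )
    }
  }
  if (length(out) > 1L) {
    keys <- vapply(out, function(cand) {
      paste(cand$traversal_a$origin, cand$traversal_a$destiny,
            cand$traversal_b$origin, cand$traversal_b$destiny, sep = "\r")
    }, character(1L))
    out <- out[order(keys)]
  }
  out
}
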