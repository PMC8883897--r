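#' Construct a pathway graph
#'
#' A pathway graph is a directed graph whose nodes are metabolite labels and
#' whose edges represent reactions transforming one metabolite into another.
#' Node labels are unique identifiers within a graph: two nodes cannot share
#' a label, and label comparison everywhere in the package is exact,
#' case-sensitive string equality.
#'
#' Labels that appear only as successors are materialized as nodes with an
#' empty successor list, duplicate edges are merged, and successor lists are
#' stored sorted ascending so that serialization and traversal are
#' deterministic.
#'
#' @param adjacency Named list mapping each node label to a character vector
#'   of successor labels (possibly empty). Labels occurring only inside
#'   successor vectors are added as keys automatically.
#' @param pathway_id Character scalar identifying the pathway.
#' @param families Character vector of family names the pathway belongs to
#'   (categories from a pathway-database hierarchy); may be empty.
#' @return An object of class `pathway_graph` with elements `pathway_id`,
#'   `nodes` (sorted character vector), `adjacency` (named list, one sorted
#'   character vector per node) and `families`.
#' @examples
#' g <- pathway_graph(list(A = c("B"), B = c("C")), pathway_id = "chain3")
#' pathway_size(g)        # 3
#' pathway_complexity(g)  # 2
#' origins(g)             # "A"
#' destinies(g)           # "C"
#' @export
pathway_graph <- function(adjacency, pathway_id = "pathway", families = character()) {
  if (length(adjacency) == 0L) {
    stop("a pathway graph must contain at least one node", call. = FALSE)
  }
  if (is.null(names(adjacency)) || any(!nzchar(names(adjacency)))) {
    stop("`adjacency` must be a fully named list of successor vectors", call. = FALSE)
  }
  if (anyDuplicated(names(adjacency))) {
    dup <- unique(names(adjacency)[duplicated(names(adjacency))])
    stop("duplicate node labels in adjacency: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  adjacency <- lapply(adjacency, function(s) {
    s <- as.character(s)
    sort(unique(s))
  })
  succ_only <- setdiff(unique(unlist(adjacency, use.names = FALSE)), names(adjacency))
  for (lab in succ_only) adjacency[[lab]] <- character()
  nodes <- sort(names(adjacency))
  adjacency <- adjacency[nodes]
  # labels embedding the reaction arrow would make edge strings ambiguous
  if (any(grepl(" -> ", nodes, fixed = TRUE))) {
    warning("node labels containing \" -> \" make Differentiation-by-Pairs ",
            "edge strings ambiguous when parsed back", call. = FALSE)
  }
  structure(
    list(pathway_id = as.character(pathway_id)[1L],
         nodes = nodes,
         adjacency = adjacency,
         families = sort(unique(as.character(families)))),
    class = "pathway_graph"
  )
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat(sprintf("<pathway_graph> %s: %d nodes, %d edges\n",
              x$pathway_id, pathway_size(x), pathway_complexity(x)))
  if (length(x$families)) {
    cat("  families:", paste(x$families, collapse = ", "), "\n")
  }
  o <- origins(x); d <- destinies(x)
  cat("  origins: ", if (length(o)) paste(o, collapse = ", ") else "(none)", "\n", sep = "")
  cat("  destinies: ", if (length(d)) paste(d, collapse = ", ") else "(none)", "\n", sep = "")
  invisible(x)
}

#' Number of nodes (size) and edges (complexity) of a pathway graph
#'
#' Size is the node count of the graph; complexity is its edge count,
#' i.e. the number of distinct reactions metabolite-to-metabolite.
#'
#' @param graph A `pathway_graph`.
#' @return Non-negative integer.
#' @export
pathway_size <- function(graph) {
  stopifnot(inherits(graph, "pathway_graph"))
  length(graph$nodes)
}

#' @rdname pathway_size
#' @export
pathway_complexity <- function(graph) {
  stopifnot(inherits(graph, "pathway_graph"))
  sum(lengths(graph$adjacency))
}

#' Edge list of a pathway graph
#'
#' @param graph A `pathway_graph`.
#' @return Two-column character matrix with columns `from` and `to`, sorted
#'   by (`from`, `to`); zero rows for an edgeless graph.
#' @export
pathway_edges <- function(graph) {
  stopifnot(inherits(graph, "pathway_graph"))
  from <- rep(names(graph$adjacency), lengths(graph$adjacency))
  to <- unlist(graph$adjacency, use.names = FALSE)
  if (is.null(to)) to <- character()
  m <- cbind(from = from, to = to)
  m[order(m[, "from"], m[, "to"]), , drop = FALSE]
}

in_degrees <- function(graph) {
  succ <- unlist(graph$adjacency, use.names = FALSE)
  tab <- table(factor(succ, levels = graph$nodes))
  as.integer(tab)
}

#' Origin and destiny nodes
#'
#' An origin is a node with out-degree at least one and in-degree zero:
#' it directs to other nodes but no node directs to it (the root of a
#' tree-shaped pathway, biologically an initial substrate). A destiny is the
#' converse: in-degree at least one, out-degree zero (a leaf, an end product
#' of interest). An isolated node (degree zero) is neither, and a node on a
#' self-loop is neither.
#'
#' @param graph A `pathway_graph`.
#' @return Sorted character vector of labels (possibly empty).
#' @export
origins <- function(graph) {
  stopifnot(inherits(graph, "pathway_graph"))
  out_deg <- lengths(graph$adjacency)
  graph$nodes[out_deg >= 1L & in_degrees(graph) == 0L]
}

#' @rdname origins
#' @export
destinies <- function(graph) {
  stopifnot(inherits(graph, "pathway_graph"))
  out_deg <- lengths(graph$adjacency)
  graph$nodes[out_deg == 0L & in_degrees(graph) >= 1L]
}

#' @export
`==.pathway_graph` <- function(e1, e2) {
  identical(e1$nodes, e2$nodes) && identical(e1$adjacency, e2$adjacency)
}

#' Read a pathway graph from a DPW (DictionaryPathWay) JSON file
#'
#' The DPW dialect stores a directed graph as a JSON object whose keys are
#' node labels and whose values are arrays with the labels each node directs
#' to. Duplicate successor entries are merged into a single edge (dictionary
#' semantics), and labels that appear only inside successor arrays become
#' nodes with no successors, so files that omit leaf keys load correctly.
#'
#' @param path Path to the JSON file.
#' @param pathway_id Identifier for the loaded pathway; defaults to the file
#'   name without its extension.
#' @param families Optional character vector of family names to attach.
#' @return A [pathway_graph].
#' @export
read_dpw <- function(path, pathway_id = NULL, families = character()) {
  if (!file.exists(path)) stop("DPW file not found: ", path, call. = FALSE)
  obj <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop("malformed JSON in DPW file ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (!is.list(obj) || (length(obj) > 0L && is.null(names(obj)))) {
    stop("DPW file ", path, " must be a JSON object of label -> successor arrays",
         call. = FALSE)
  }
  adjacency <- lapply(seq_along(obj), function(i) {
    v <- obj[[i]]
    if (!is.list(v) && !is.character(v)) {
      stop("DPW file ", path, ": value for key \"", names(obj)[i],
           "\" is not an array of strings", call. = FALSE)
    }
    v <- unlist(v, use.names = FALSE)
    if (length(v) && !is.character(v)) {
      stop("DPW file ", path, ": value for key \"", names(obj)[i],
           "\" is not an array of strings", call. = FALSE)
    }
    if (is.null(v)) character() else v
  })
  names(adjacency) <- names(obj)
  if (is.null(pathway_id)) {
    pathway_id <- sub("\\.[^.]*$", "", basename(path))
  }
  pathway_graph(adjacency, pathway_id = pathway_id, families = families)
}

#' Write a pathway graph to a DPW JSON file
#'
#' Canonical writer output: one key per node (successor-only nodes included,
#' with empty arrays), keys and successor arrays sorted ascending, so
#' `read_dpw(write_dpw(g))` reproduces `g` exactly.
#'
#' @param graph A [pathway_graph].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dpw <- function(graph, path) {
  stopifnot(inherits(graph, "pathway_graph"))
  json <- jsonlite::toJSON(graph$adjacency, auto_unbox = FALSE)
  ok <- tryCatch({ writeLines(json, path, useBytes = TRUE); TRUE },
                 error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write DPW file ", path, ": ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Read a reaction layout from an RNL (ReactionLayout) JSON file
#'
#' The RNL dialect stores a pathway as a JSON object whose keys are reaction
#' identifiers and whose values are two-element arrays: the first inner array
#' lists the substrate labels of the reaction, the second the product labels.
#'
#' @param path Path to the JSON file.
#' @param pathway_id Identifier; defaults to the file name without extension.
#' @return An object of class `reaction_layout` with elements `pathway_id`
#'   and `reactions` (named list of `list(substrates=, products=)`).
#' @export
read_rnl <- function(path, pathway_id = NULL) {
  if (!file.exists(path)) stop("RNL file not found: ", path, call. = FALSE)
  obj <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop("malformed JSON in RNL file ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (!is.list(obj) || length(obj) == 0L || is.null(names(obj))) {
    stop("RNL file ", path, " must be a non-empty JSON object of reactions",
         call. = FALSE)
  }
  if (anyDuplicated(names(obj))) {
    stop("RNL file ", path, ": duplicate reaction ids", call. = FALSE)
  }
  reactions <- lapply(seq_along(obj), function(i) {
    rid <- names(obj)[i]
    v <- obj[[i]]
    if (!is.list(v) || length(v) != 2L) {
      stop("RNL file ", path, ": reaction \"", rid,
           "\" must be a two-element array [substrates, products]",
           call. = FALSE)
    }
    subs <- as.character(unlist(v[[1L]], use.names = FALSE))
    prods <- as.character(unlist(v[[2L]], use.names = FALSE))
    if (length(subs) == 0L || length(prods) == 0L) {
      stop("RNL file ", path, ": reaction \"", rid,
           "\" must have at least one substrate and one product",
           call. = FALSE)
    }
    list(substrates = subs, products = prods)
  })
  names(reactions) <- names(obj)
  if (is.null(pathway_id)) pathway_id <- sub("\\.[^.]*$", "", basename(path))
  structure(list(pathway_id = as.character(pathway_id)[1L], reactions = reactions),
            class = "reaction_layout")
}

#' @export
print.reaction_layout <- function(x, ...) {
  cat(sprintf("<reaction_layout> %s: %d reactions\n",
              x$pathway_id, length(x$reactions)))
  invisible(x)
}

#' Convert a reaction layout to a pathway graph
#'
#' Every (substrate, product) pair of a reaction becomes one directed edge;
#' edges induced by several reactions are deduplicated. Reaction identifiers
#' are not carried over: the graph identifies a reaction purely by its
#' source and target metabolite labels.
#'
#' @param layout A `reaction_layout` from [read_rnl()].
#' @return A [pathway_graph].
#' @export
rnl_to_dpw <- function(layout) {
  stopifnot(inherits(layout, "reaction_layout"))
  adjacency <- list()
  for (rx in layout$reactions) {
    for (s in rx$substrates) {
      adjacency[[s]] <- c(adjacency[[s]], rx$products)
    }
  }
  pathway_graph(adjacency, pathway_id = layout$pathway_id)
}

#' Read a families sidecar file
#'
#' Family membership (database-hierarchy categories) is carried in a sidecar
#' JSON object mapping pathway id to an array of family-name strings.
#'
#' @param path Path to the JSON sidecar.
#' @return Named list of character vectors.
#' @export
read_families <- function(path) {
  if (!file.exists(path)) stop("families file not found: ", path, call. = FALSE)
  obj <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop("malformed JSON in families file ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  lapply(obj, function(v) sort(unique(as.character(unlist(v, use.names = FALSE)))))
}
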