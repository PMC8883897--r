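#' Default metabolite label pool
#'
#' Fixed readable labels (`"M001"`, `"M002"`, ...) so generated graphs and
#' their reports are diffable.
#'
#' @param n Number of labels.
#' @param prefix Label prefix.
#' @return Character vector of `n` labels.
#' @export
default_label_pool <- function(n, prefix = "M") {
  sprintf("%s%03d", prefix, seq_len(n))
}

#' Generate a random synthetic pathway graph
#'
#' Builds a directed acyclic graph emulating a curated metabolic pathway:
#' nodes are ordered along a topological backbone, the first `n_origins`
#' positions are origin nodes (in-degree 0, out-degree forced >= 1), and
#' every later node receives one backbone parent among its predecessors, so
#' every non-origin node is reachable from some origin. With a single
#' origin all nodes are reachable from it, guaranteeing a full-coverage
#' traversal. `extra_edges` additional forward edges are layered on without
#' creating cycles or new origins. At least one destiny always exists (the
#' last backbone node). Generation is a pure function of its arguments:
#' the same seed gives a bit-identical graph.
#'
#' @param size Number of nodes (>= 2).
#' @param extra_edges Forward edges beyond the spanning backbone.
#' @param n_origins Number of origin nodes (1 <= n_origins < size).
#' @param label_pool Labels to draw from (at least `size`).
#' @param seed Integer seed.
#' @param pathway_id Identifier for the generated pathway.
#' @param families Character vector of family names to attach.
#' @return A [pathway_graph].
#' @export
generate_pathway <- function(size, extra_edges = 0L, n_origins = 1L,
                             label_pool = default_label_pool(size),
                             seed = 1L, pathway_id = NULL,
                             families = character()) {
  stopifnot(size >= 2L, extra_edges >= 0L, n_origins >= 1L)
  if (n_origins >= size) {
    stop("`n_origins` must be smaller than `size`", call. = FALSE)
  }
  if (length(label_pool) < size) {
    stop("label pool smaller than requested size", call. = FALSE)
  }
  if (is.null(pathway_id)) pathway_id <- sprintf("synth_s%d_seed%d", size, seed)
  k <- as.integer(n_origins)
  with_seed(seed, {
    labels <- sample(label_pool, size)
    # adjacency over positions; edge u -> v always has u < v (keeps it a DAG)
    # and v > k (keeps origins at in-degree 0)
    parent_of <- integer(size)
    for (v in (k + 1L):size) {
      parent_of[v] <- if (v == k + 1L) sample.int(k, 1L) else sample.int(v - 1L, 1L)
    }
    edges <- cbind(parent_of[(k + 1L):size], (k + 1L):size)
    # force out-degree >= 1 for every origin
    for (o in seq_len(k)) {
      if (!any(edges[, 1L] == o)) {
        free <- setdiff((k + 1L):size, edges[edges[, 1L] == o, 2L])
        edges <- rbind(edges, c(o, if (length(free) == 1L) free else sample(free, 1L)))
      }
    }
    # extra forward edges among the unused (u < v, v > k) slots
    all_u <- rep(seq_len(size - 1L), times = pmax(size - pmax(seq_len(size - 1L), k), 0L))
    all_v <- unlist(lapply(seq_len(size - 1L), function(u) {
      lo <- max(u + 1L, k + 1L)
      if (lo > size) integer() else lo:size
    }))
    slot_key <- paste(all_u, all_v)
    used <- paste(edges[, 1L], edges[, 2L])
    free_idx <- which(!(slot_key %in% used))
    if (extra_edges > length(free_idx)) {
      stop("extra_edges = ", extra_edges, " exceeds remaining DAG capacity (",
           length(free_idx), ")", call. = FALSE)
    }
    if (extra_edges > 0L) {
      pick <- if (length(free_idx) == 1L) free_idx else sample(free_idx, extra_edges)
      edges <- rbind(edges, cbind(all_u[pick], all_v[pick]))
    }
  })
  adjacency <- lapply(seq_len(size), function(u) labels[edges[edges[, 1L] == u, 2L]])
  names(adjacency) <- labels
  pathway_graph(adjacency, pathway_id = pathway_id, families = families)
}

#' Generate a matched pair of synthetic pathways
#'
#' Produces two pathway graphs with a controlled number of shared node
#' labels — `round(overlap_fraction * max(size_a, size_b))` labels appear
#' in both graphs — and family sets intersecting in exactly
#' `common_families` names (each side also gets one private family when
#' annotated). With `ordered_overlap = TRUE` both graphs are simple chains
#' and the shared labels occur in the same relative order on both sides,
#' the construction behind the size-ratio bound on the relative global
#' score. The analytically expected pair features are returned for
#' assertion against [compute_features()].
#'
#' @param size_a,size_b Node counts (>= 2).
#' @param overlap_fraction Target shared-label fraction of the larger
#'   graph, in `[0, min(size)/max(size)]`.
#' @param extra_edges_a,extra_edges_b Extra forward edges per side.
#' @param n_origins_a,n_origins_b Origin counts per side.
#' @param common_families Number of shared family names.
#' @param seed Integer seed.
#' @param ordered_overlap Build chain graphs with shared labels in matching
#'   relative order.
#' @return List with `graph_a`, `graph_b` and `expected` (a
#'   [compute_features()]-style list of the analytically known features).
#' @export
generate_pair <- function(size_a, size_b, overlap_fraction = 0.5,
                          extra_edges_a = 0L, extra_edges_b = 0L,
                          n_origins_a = 1L, n_origins_b = 1L,
                          common_families = 0L, seed = 1L,
                          ordered_overlap = FALSE) {
  stopifnot(size_a >= 2L, size_b >= 2L,
            overlap_fraction >= 0, common_families >= 0L)
  n_shared <- round(overlap_fraction * max(size_a, size_b))
  if (n_shared > min(size_a, size_b)) {
    stop("infeasible overlap: ", n_shared, " shared labels exceed the ",
         "smaller graph's size ", min(size_a, size_b), call. = FALSE)
  }
  shared <- default_label_pool(n_shared, prefix = "C")
  pool_a <- c(shared, default_label_pool(size_a - n_shared, prefix = "A"))
  pool_b <- c(shared, default_label_pool(size_b - n_shared, prefix = "B"))
  fam_common <- if (common_families > 0L) sprintf("FAM-C%02d", seq_len(common_families)) else character()
  fam_a <- c(fam_common, "FAM-A")
  fam_b <- c(fam_common, "FAM-B")
  if (ordered_overlap) {
    ga <- chain_with_shared(pool_a, shared, seed, "pair_a", fam_a)
    gb <- chain_with_shared(pool_b, shared, seed + 1L, "pair_b", fam_b)
  } else {
    ga <- generate_pathway(size_a, extra_edges_a, n_origins_a, pool_a,
                           seed = seed, pathway_id = "pair_a", families = fam_a)
    gb <- generate_pathway(size_b, extra_edges_b, n_origins_b, pool_b,
                           seed = seed + 1L, pathway_id = "pair_b", families = fam_b)
  }
  sr <- min(size_a, size_b) / max(size_a, size_b)
  ca <- pathway_complexity(ga); cb <- pathway_complexity(gb)
  expected <- list(
    size_ratio = sr,
    complexity_ratio = if (ca == 0L && cb == 0L) 1
                       else if (min(ca, cb) == 0L) 0
                       else min(ca, cb) / max(ca, cb),
    equivalent_nodes_ratio = n_shared / max(size_a, size_b),
    common_families = as.integer(common_families),
    families_annotated = TRUE,
    size_ratio_level = size_ratio_level(sr),
    families_level = families_level(common_families)
  )
  list(graph_a = ga, graph_b = gb, expected = expected)
}

# a chain over a shuffled label pool in which the `shared` labels keep
# their relative order (shared[1] before shared[2], ...)
chain_with_shared <- function(pool, shared, seed, pathway_id, families) {
  n <- length(pool)
  with_seed(seed, {
    order_all <- sample(pool)
    pos_shared <- sort(which(order_all %in% shared))
    order_all[pos_shared] <- shared
  })
  adjacency <- c(lapply(seq_len(n - 1L), function(i) order_all[i + 1L]),
                 list(character()))
  names(adjacency) <- order_all
  pathway_graph(adjacency, pathway_id = pathway_id, families = families)
}

#' Canonical toy pathway fixtures
#'
#' Tiny named graphs used throughout documentation and tests:
#' `chain3` (A->B->C), `chain10` (a 10-node chain containing A, B, C in
#' order among seven other labels), `diamond` (A->B, A->C, B->D, C->D),
#' `cycle2` (A->B->A: no origins, no destinies), `disjoint_a`/`disjoint_b`
#' (two 3-chains over disjoint alphabets), `selfloop` (S->S, S->T) and
#' `twocomp` (A->B plus a disconnected C->D).
#'
#' @return Named list of [pathway_graph] objects.
#' @export
fixture_suite <- function() {
  chain <- function(labels, id) {
    adjacency <- c(lapply(seq_len(length(labels) - 1L), function(i) labels[i + 1L]),
                   list(character()))
    names(adjacency) <- labels
    pathway_graph(adjacency, pathway_id = id)
  }
  list(
    chain3 = chain(c("A", "B", "C"), "chain3"),
    chain10 = chain(c("N01", "A", "N02", "N03", "B", "N04", "N05", "N06", "C", "N07"),
                    "chain10"),
    diamond = pathway_graph(list(A = c("B", "C"), B = "D", C = "D"),
                            pathway_id = "diamond"),
    cycle2 = pathway_graph(list(A = "B", B = "A"), pathway_id = "cycle2"),
    disjoint_a = chain(c("A", "B", "C"), "disjoint_a"),
    disjoint_b = chain(c("X", "Y", "Z"), "disjoint_b"),
    selfloop = pathway_graph(list(S = c("S", "T")), pathway_id = "selfloop"),
    twocomp = pathway_graph(list(A = "B", C = "D"), pathway_id = "twocomp")
  )
}
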