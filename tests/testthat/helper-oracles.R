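# Independent reference implementations used to cross-check the package.

# reachable set by iterated edge relaxation (no traversal involved)
reach_oracle <- function(graph, origin) {
  reach <- origin
  repeat {
    nxt <- unique(c(reach, unlist(graph$adjacency[reach], use.names = FALSE)))
    if (length(nxt) == length(reach)) return(sort(reach))
    reach <- nxt
  }
}

graph_to_igraph <- function(graph) {
  ed <- pathway_edges(graph)
  igraph::graph_from_data_frame(
    as.data.frame(ed, stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = graph$nodes, stringsAsFactors = FALSE)
  )
}

# random label sequences with distinct labels (like traversals), sharing
# part of an alphabet so matches occur
random_sequence_pair <- function(seed, max_len = 8L, alphabet_size = 8L) {
  pool <- sprintf("L%02d", seq_len(alphabet_size))
  pathcomp:::with_seed(seed, {
    ns <- sample(1:max_len, 1L)
    nt <- sample(1:max_len, 1L)
    list(s = sample(pool, ns, replace = TRUE), t = sample(pool, nt, replace = TRUE))
  })
}

# cap extra edges so that any generated size can absorb them
cap_extra <- function(extra, size) if (size >= 6L) extra else 0L

# random generated pathway pair with arbitrary overlap, sizes 2..20
random_pathway_pair <- function(seed) {
  pathcomp:::with_seed(seed, {
    size_a <- sample(2:20, 1L)
    size_b <- sample(2:20, 1L)
    max_overlap <- min(size_a, size_b) / max(size_a, size_b)
    ov <- stats::runif(1L, 0, max_overlap)
    extra_a <- cap_extra(sample(0:2, 1L), size_a)
    extra_b <- cap_extra(sample(0:2, 1L), size_b)
    fams <- sample(0:5, 1L)
  })
  generate_pair(size_a, size_b, overlap_fraction = ov,
                extra_edges_a = extra_a, extra_edges_b = extra_b,
                common_families = fams, seed = seed + 1000L)
}
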