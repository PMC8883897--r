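test_that("breadth-first sequences visit by levels with lexicographic ties", {
  fx <- fixture_suite()
  expect_equal(bfs_sequence(fx$chain3, "A"), c("A", "B", "C"))
  expect_equal(bfs_sequence(fx$diamond, "A"), c("A", "B", "C", "D"))
  # only the component reachable from the origin is visited
  expect_equal(bfs_sequence(fx$twocomp, "A"), c("A", "B"))
  # cycle safety through the visited set
  expect_equal(bfs_sequence(fx$cycle2, "A"), c("A", "B"))
  expect_error(bfs_sequence(fx$chain3, "Z"), "not a node")
})

test_that("depth-first sequences are preorder with lexicographic ties", {
  fx <- fixture_suite()
  expect_equal(dfs_sequence(fx$chain3, "A"), c("A", "B", "C"))
  expect_equal(dfs_sequence(fx$diamond, "A"), c("A", "B", "D", "C"))
  expect_equal(dfs_sequence(fx$cycle2, "A"), c("A", "B"))
})

test_that("traversal sequences agree with independent reachability oracles", {
  skip_if_not_installed("igraph")
  for (seed in 1:30) {
    g <- generate_pathway(size = 2L + seed %% 7L,
                          extra_edges = cap_extra(seed %% 3L, 2L + seed %% 7L),
                          n_origins = min(1L + seed %% 2L, 1L + seed %% 7L),
                          label_pool = default_label_pool(20), seed = seed)
    for (o in origins(g)) {
      bfs <- bfs_sequence(g, o)
      dfs <- dfs_sequence(g, o)
      # same reachable set as iterated edge relaxation
      expect_equal(sort(bfs), reach_oracle(g, o))
      expect_setequal(bfs, dfs)
      expect_equal(bfs[1L], o)
      expect_false(anyDuplicated(bfs) > 0L)
      # BFS level monotonicity against shortest-path distances
      d <- igraph::distances(graph_to_igraph(g), v = o, mode = "out")
      expect_true(all(diff(d[1L, bfs]) >= 0))
      # determinism
      expect_identical(bfs, bfs_sequence(g, o))
    }
  }
})

test_that("lecture validity requires origin, destiny and reachability", {
  fx <- fixture_suite()
  expect_true(is_valid_lecture(fx$chain3, "A", "C"))
  expect_false(is_valid_lecture(fx$chain3, "C", "A"))
  expect_false(is_valid_lecture(fx$twocomp, "A", "D"))
  expect_true(is_valid_lecture(fx$twocomp, "A", "B"))
  expect_error(is_valid_lecture(fx$chain3, "A", "Z"), "not in graph")
})

test_that("traversals run past the destiny and record coverage", {
  fx <- fixture_suite()
  tr <- make_traversal(fx$chain3, "A", "C")
  expect_s3_class(tr, "traversal")
  expect_equal(tr$sequence, c("A", "B", "C"))
  expect_true(tr$full_coverage)

  # destiny is a validity requirement, not a stopping rule
  g <- pathway_graph(list(A = c("B", "C"), B = "D", C = character(), D = character()))
  tr2 <- make_traversal(g, "A", "C")
  expect_equal(tr2$sequence, c("A", "B", "C", "D"))

  expect_error(make_traversal(g, "A", "B"), "not a destiny")
  expect_error(make_traversal(fx$twocomp, "A", "D"), "not reachable")
  tr3 <- make_traversal(fx$twocomp, "A", "B")
  expect_false(tr3$full_coverage)
  expect_length(tr3$sequence, 2L)
})

test_that("candidate enumeration crosses valid lectures and annotates equivalence", {
  fx <- fixture_suite()
  other <- pathway_graph(list(A = "X", X = "C"), pathway_id = "chain3x")
  cands <- enumerate_candidates(fx$chain3, other)
  expect_length(cands, 1L)
  expect_true(cands[[1L]]$origin_equivalent)
  expect_true(cands[[1L]]$destiny_equivalent)

  expect_length(enumerate_candidates(fx$cycle2, fx$chain3), 0L)

  # two destinies on one side double the candidates
  two_dest <- pathway_graph(list(A = "B", B = c("D", "E")))
  cands2 <- enumerate_candidates(two_dest, fx$chain3)
  expect_length(cands2, 2L)
  expect_equal(vapply(cands2, function(cc) cc$traversal_a$destiny, character(1L)),
               c("D", "E"))

  # coverage filter drops partial traversals
  cands3 <- enumerate_candidates(fx$twocomp, fx$chain3)
  expect_length(cands3, 2L)
  expect_length(enumerate_candidates(fx$twocomp, fx$chain3,
                                     require_full_coverage = TRUE), 0L)
})

test_that("single-origin connected synthetic graphs always give full coverage", {
  for (seed in 1:15) {
    g <- generate_pathway(size = 2L + seed, extra_edges = seed %% 3L,
                          n_origins = 1L, label_pool = default_label_pool(25),
                          seed = seed)
    trs <- pathcomp:::valid_traversals(g)
    expect_gt(length(trs), 0L)
    expect_true(all(vapply(trs, function(t) t$full_coverage, logical(1L))))
  }
})
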