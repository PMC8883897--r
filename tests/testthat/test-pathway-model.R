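write_json_tmp <- function(text) {
  path <- withr::local_tempfile(fileext = ".dpw", .local_envir = parent.frame())
  writeLines(text, path)
  path
}

test_that("DPW reading applies dictionary semantics and the closure rule", {
  g <- read_dpw(write_json_tmp('{"A": ["B"], "B": ["C"], "C": []}'))
  expect_equal(g$nodes, c("A", "B", "C"))
  expect_equal(pathway_size(g), 3L)
  expect_equal(pathway_complexity(g), 2L)

  # duplicate successor entries merge into a single edge
  g2 <- read_dpw(write_json_tmp('{"A": ["B", "B"]}'))
  expect_equal(g2$adjacency$A, "B")
  expect_equal(pathway_complexity(g2), 1L)

  # labels appearing only as successors become nodes without successors
  g3 <- read_dpw(write_json_tmp('{"A": ["B"]}'))
  expect_setequal(g3$nodes, c("A", "B"))
  expect_equal(g3$adjacency$B, character())
})

test_that("DPW reading rejects malformed input with the file and key named", {
  bad <- write_json_tmp('{"A": ["B",}')
  expect_error(read_dpw(bad), "malformed JSON")
  expect_error(read_dpw(bad), basename(bad), fixed = TRUE)
  expect_error(read_dpw(write_json_tmp('{"A": [1, 2]}')), '"A"')
  expect_error(read_dpw(tempfile("nofile")), "not found")
})

test_that("DPW writing is canonical and round-trips exactly", {
  g <- pathway_graph(list(A = "B", B = "C"), pathway_id = "chain")
  path <- withr::local_tempfile(fileext = ".dpw")
  write_dpw(g, path)
  expect_equal(paste(readLines(path), collapse = ""),
               '{"A":["B"],"B":["C"],"C":[]}')
  singleton <- pathway_graph(list(X = character()))
  write_dpw(singleton, path)
  expect_equal(paste(readLines(path), collapse = ""), '{"X":[]}')

  for (seed in 1:20) {
    gg <- generate_pathway(size = 2L + seed %% 15L,
                           extra_edges = cap_extra(seed %% 3L, 2L + seed %% 15L),
                           n_origins = min(1L + seed %% 2L, 1L + seed %% 15L),
                           label_pool = default_label_pool(30), seed = seed)
    write_dpw(gg, path)
    back <- read_dpw(path, pathway_id = gg$pathway_id)
    expect_equal(back$nodes, gg$nodes)
    expect_equal(back$adjacency, gg$adjacency)
  }
})

test_that("RNL reading validates reaction structure", {
  rnl_tmp <- function(text) {
    p <- withr::local_tempfile(fileext = ".rnl", .local_envir = parent.frame())
    writeLines(text, p)
    p
  }
  layout <- read_rnl(rnl_tmp('{"R1": [["A","B"],["C"]]}'))
  expect_equal(layout$reactions$R1$substrates, c("A", "B"))
  expect_equal(layout$reactions$R1$products, "C")
  expect_length(read_rnl(rnl_tmp('{"R1": [["A"],["B"]], "R2": [["B"],["C"]]}'))$reactions, 2L)
  expect_error(read_rnl(rnl_tmp('{"R1": [["A"]]}')), "R1")
  expect_error(read_rnl(rnl_tmp('{"R1": [[],["B"]]}')), "at least one substrate")
})

test_that("RNL to DPW conversion takes the substrate-product cross product", {
  lay <- structure(list(pathway_id = "p",
                        reactions = list(R1 = list(substrates = c("A", "B"),
                                                   products = "C"))),
                   class = "reaction_layout")
  g <- rnl_to_dpw(lay)
  expect_setequal(g$nodes, c("A", "B", "C"))
  expect_equal(unname(pathway_edges(g)),
               unname(cbind(c("A", "B"), c("C", "C"))))

  # the same edge induced by two reactions is stored once
  lay2 <- structure(list(pathway_id = "p",
                         reactions = list(R1 = list(substrates = "A", products = "B"),
                                          R2 = list(substrates = "A", products = "B"))),
                    class = "reaction_layout")
  expect_equal(pathway_complexity(rnl_to_dpw(lay2)), 1L)

  # degenerate reaction producing its own substrate gives a self-loop
  lay3 <- structure(list(pathway_id = "p",
                         reactions = list(R1 = list(substrates = "A", products = "A"))),
                    class = "reaction_layout")
  g3 <- rnl_to_dpw(lay3)
  expect_equal(pathway_complexity(g3), 1L)
  expect_equal(g3$adjacency$A, "A")
})

test_that("origins and destinies follow the degree definitions", {
  fx <- fixture_suite()
  expect_equal(origins(fx$chain3), "A")
  expect_equal(destinies(fx$chain3), "C")
  expect_equal(origins(fx$diamond), "A")
  expect_equal(destinies(fx$diamond), "D")
  expect_length(origins(fx$cycle2), 0L)
  expect_length(destinies(fx$cycle2), 0L)

  # an isolated node is neither origin nor destiny
  iso <- pathway_graph(list(A = "B", X = character()))
  expect_equal(origins(iso), "A")
  expect_equal(destinies(iso), "B")

  # a self-loop makes its node neither origin nor destiny
  expect_false("S" %in% origins(fx$selfloop))
  expect_false("S" %in% destinies(fx$selfloop))
  expect_equal(destinies(fx$selfloop), "T")
})

test_that("origins and destinies are disjoint and complexity is well behaved", {
  for (seed in 1:25) {
    g <- generate_pathway(size = 3L + seed %% 12L,
                          extra_edges = cap_extra(seed %% 4L, 3L + seed %% 12L),
                          n_origins = min(1L + seed %% 3L, 2L + seed %% 12L),
                          label_pool = default_label_pool(30), seed = seed)
    expect_length(intersect(origins(g), destinies(g)), 0L)
    ed <- pathway_edges(g)
    expect_equal(nrow(ed), pathway_complexity(g))
    # dropping one edge reduces complexity by exactly 1, size unchanged
    drop <- ed[1L, ]
    adj <- g$adjacency
    adj[[drop[["from"]]]] <- setdiff(adj[[drop[["from"]]]], drop[["to"]])
    g2 <- pathway_graph(adj, pathway_id = g$pathway_id)
    expect_equal(pathway_complexity(g2), pathway_complexity(g) - 1L)
    expect_equal(pathway_size(g2), pathway_size(g))
  }
})

test_that("families sidecars load as sets", {
  p <- withr::local_tempfile(fileext = ".json")
  writeLines('{"pwA": ["F2", "F1", "F1"], "pwB": []}', p)
  fams <- read_families(p)
  expect_equal(fams$pwA, c("F1", "F2"))
  expect_length(fams$pwB, 0L)
})
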