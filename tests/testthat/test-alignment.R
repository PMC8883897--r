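test_that("scoring schemes enforce sign conventions", {
  expect_error(scoring_scheme(match = 0), "positive")
  expect_error(scoring_scheme(mismatch = 0.5), "non-positive")
  expect_error(scoring_scheme(gap = 1), "non-positive")
  sc <- scoring_scheme(1, -1, -2)
  expect_equal(sc$gap, -2)
})

test_that("global alignment reproduces the worked examples", {
  sc0 <- scoring_scheme(1, -1, 0)
  idn <- align_global(c("A", "B", "C", "D"), c("A", "B", "C", "D"), sc0)
  expect_equal(idn$x, 4L)
  expect_equal(idn$score, 4)
  expect_equal(idn$relative, 1)

  # single substitution between two length-6 sequences: 5/6 ~ 83%
  # (at gap 0 the optimum spells the substituted column as two free gaps)
  s <- sprintf("M%d", 1:6)
  t <- replace(s, 3L, "SUB")
  sub <- align_global(s, t, sc0)
  expect_equal(sub$x, 5L)
  expect_equal(sub$score, 5)
  expect_equal(sub$relative, 5 / 6)
  # at a negative gap value the substitution stays one mismatch column
  sub2 <- align_global(s, t, scoring_scheme(1, -1, -1))
  expect_equal(sub2$x, 5L)
  expect_equal(sub2$y, 1L)
  expect_equal(sub2$relative, 5 / 6)

  ins <- align_global(c("A", "B", "C"), c("A", "P", "B", "Q", "C"), sc0)
  expect_equal(ins$x, 3L)
  expect_equal(ins$y, 0L)
  expect_equal(ins$z, 2L)
  expect_equal(ins$score, 3)
  expect_equal(ins$relative, 0.6)

  expect_error(align_global(character(), "A", sc0), "non-empty")
})

test_that("local alignment finds the best contiguous segment pair", {
  sc <- scoring_scheme(1, -1, -2)
  loc <- align_local(c("Z", "A", "B", "Z"), c("Q", "A", "B", "Q"), sc)
  expect_equal(loc$score, 2)
  expect_equal(loc$x, 2L)
  expect_equal(loc$relative, 0.5)
  expect_equal(loc$row_s, c("A", "B"))

  disj <- align_local(c("A", "B"), c("X", "Y"), sc)
  expect_equal(disj$score, 0)
  expect_equal(disj$x, 0L)
  expect_equal(disj$relative, 0)
  expect_length(disj$row_s, 0L)

  idn <- align_local(c("A", "B", "C"), c("A", "B", "C"), sc)
  expect_equal(idn$score, 3)
  expect_equal(idn$relative, 1)
})

test_that("semi-global alignment gives free end gaps in both sequences", {
  sc <- scoring_scheme(1, -1, -2)
  ov <- align_semiglobal(c("A", "B", "C"), c("X", "A", "B", "C", "Y"), sc)
  expect_equal(ov$score, 3)
  expect_equal(ov$x, 3L)
  expect_equal(ov$z, 0L)          # end gaps are excluded from z
  expect_equal(ov$relative, 1)
  expect_length(ov$row_s, 5L)     # but still appear in the rows

  idn <- align_semiglobal(c("A", "B", "C"), c("A", "B", "C"), sc)
  expect_equal(idn$relative, 1)
  expect_equal(idn$z, 0L)

  disj <- align_semiglobal(c("A", "B", "C"), c("D", "E", "F"), sc)
  expect_equal(disj$x, 0L)
  expect_equal(disj$relative, 0)
})

test_that("alignment event counting decomposes columns", {
  expect_equal(count_alignment_events(c("A", "B", "C"), c("A", "B", "C")),
               c(x = 3L, y = 0L, z = 0L))
  expect_equal(count_alignment_events(c("A", "B", "-"), c("A", "X", "Y")),
               c(x = 1L, y = 1L, z = 1L))
  expect_error(count_alignment_events(c("A", "-"), c("B", "-")), "gap in both")
  expect_error(count_alignment_events("A", c("A", "B")), "equal length")
  # six columns, one interior gap in each row, five equal columns
  expect_equal(count_alignment_events(c("A", "B", "-", "C", "D", "E"),
                                      c("A", "-", "X", "C", "D", "E"))[["x"]], 4L)
  # semiglobal mode discounts leading/trailing same-row gap runs only
  ev <- count_alignment_events(c("-", "A", "B", "-", "C", "-"),
                               c("X", "A", "B", "Y", "C", "Z"),
                               mode = "semiglobal")
  expect_equal(ev, c(x = 3L, y = 0L, z = 1L))
})

test_that("absolute scores satisfy S = xm + yn + zg in all modes", {
  schemes <- list(scoring_scheme(1, -1, 0), scoring_scheme(1, -1, -1),
                  scoring_scheme(1, -1, -2), scoring_scheme(2, -3, -1))
  for (seed in 1:40) {
    p <- random_sequence_pair(seed)
    for (sc in schemes) {
      for (f in list(align_global, align_local, align_semiglobal)) {
        al <- f(p$s, p$t, sc)
        expect_equal(al$score,
                     al$x * sc$match + al$y * sc$mismatch + al$z * sc$gap)
        gaps <- sum(al$row_s == "-") + sum(al$row_t == "-")
        expect_equal(al$x + al$y + gaps, length(al$row_s))
        expect_false(any(al$row_s == "-" & al$row_t == "-"))
      }
    }
  }
})

test_that("scores are symmetric under operand swap", {
  for (seed in 1:40) {
    p <- random_sequence_pair(seed)
    for (sc in list(scoring_scheme(1, -1, 0), scoring_scheme(1, -1, -2))) {
      for (f in list(align_global, align_local, align_semiglobal)) {
        ab <- f(p$s, p$t, sc)
        ba <- f(p$t, p$s, sc)
        expect_equal(ab$score, ba$score)
        expect_equal(ab$x, ba$x)
        expect_equal(ab$y, ba$y)
        expect_equal(ab$z, ba$z)
        expect_equal(ab$relative, ba$relative)
      }
    }
  }
})

test_that("disjoint alphabets force zero matches and zero relative scores", {
  for (seed in 1:20) {
    p <- random_sequence_pair(seed)
    s <- paste0("S", p$s)
    t <- paste0("T", p$t)
    for (sc in list(scoring_scheme(1, -1, 0), scoring_scheme(1, -1, -2))) {
      for (f in list(align_global, align_local, align_semiglobal)) {
        al <- f(s, t, sc)
        expect_equal(al$x, 0L)
        expect_equal(al$relative, 0)
      }
    }
  }
})

test_that("relative global score never exceeds the length ratio", {
  for (seed in 1:40) {
    p <- random_sequence_pair(seed)
    bound <- min(length(p$s), length(p$t)) / max(length(p$s), length(p$t))
    for (g in c(-2, -1, 0)) {
      al <- align_global(p$s, p$t, scoring_scheme(1, -1, g))
      expect_lte(al$relative, bound)
    }
  }
})

test_that("with gap 0 a shared label guarantees a non-negative global score", {
  for (seed in 1:20) {
    p <- random_sequence_pair(seed)
    if (length(intersect(p$s, p$t)) == 0L) next
    al <- align_global(p$s, p$t, scoring_scheme(1, -1, 0))
    expect_gte(al$score, 0)
  }
})

test_that("appending a fresh shared label adds exactly one match at gap 0", {
  for (seed in 1:20) {
    p <- random_sequence_pair(seed)
    before <- align_global(p$s, p$t, scoring_scheme(1, -1, 0))
    after <- align_global(c(p$s, "FRESH"), c(p$t, "FRESH"), scoring_scheme(1, -1, 0))
    expect_equal(after$x, before$x + 1L)
  }
})

test_that("dynamic programming matches the exhaustive enumerator on random pairs", {
  for (seed in 1:60) {
    p <- random_sequence_pair(seed, max_len = 6L, alphabet_size = 4L)
    ref <- align_enumerate(p$s, p$t)
    for (g in c(-2, -1, 0)) {
      expect_equal(align_global(p$s, p$t, scoring_scheme(1, -1, g))$score,
                   ref$global[[as.character(g)]])
    }
    expect_equal(align_local(p$s, p$t, scoring_scheme(1, -1, -2))$score, ref$local)
    expect_equal(align_semiglobal(p$s, p$t, scoring_scheme(1, -1, -2))$score,
                 ref$semiglobal)
  }
})

test_that("reported matches equal the optimal-alignment maximum", {
  # several optimal global alignments can differ in match count; the DP
  # reports the maximal x among them, which the enumerator recomputes
  for (seed in 1:30) {
    p <- random_sequence_pair(seed, max_len = 6L, alphabet_size = 4L)
    for (g in c(-2, -1, 0)) {
      sc <- scoring_scheme(1, -1, g)
      fast <- align_global(p$s, p$t, sc)
      exact <- align_enumerate_global(p$s, p$t, sc)
      expect_equal(fast$score, exact$score)
      expect_equal(fast$x, exact$max_matches)
    }
  }
})
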