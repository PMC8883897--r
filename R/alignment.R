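#' Scoring scheme for traversal alignment
#'
#' Alignments are scored with the linear absolute-score formula
#' `S = x*m + y*n + z*g`, where `x`, `y`, `z` count matches, mismatches and
#' gaps and `m`, `n`, `g` are their per-event values. The base values used
#' for pathway comparison are match = 1 and mismatch = -1; the global
#' aligner is run at gap values -2, -1 and 0 (0 being the value selected for
#' the headline score, since a pathway lecture loses no information at a
#' gap, unlike sequencing reads), while local and semi-global alignment use
#' gap = -2.
#'
#' @param match Value of a match; must be positive.
#' @param mismatch Value of a mismatch; must be non-positive.
#' @param gap Value of a gap symbol; must be non-positive.
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 1, mismatch = -1, gap = 0) {
  stopifnot(is.numeric(match), is.numeric(mismatch), is.numeric(gap))
  if (match <= 0) stop("`match` must be positive", call. = FALSE)
  if (mismatch > 0) stop("`mismatch` must be non-positive", call. = FALSE)
  if (gap > 0) stop("`gap` must be non-positive", call. = FALSE)
  structure(list(match = as.numeric(match), mismatch = as.numeric(mismatch),
                 gap = as.numeric(gap)),
            class = "scoring_scheme")
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat(sprintf("<scoring_scheme> match=%g mismatch=%g gap=%g\n",
              x$match, x$mismatch, x$gap))
  invisible(x)
}

GAP <- "-"

check_alignment_input <- function(seq_s, seq_t, scheme) {
  if (length(seq_s) == 0L || length(seq_t) == 0L) {
    stop("alignment requires two non-empty sequences", call. = FALSE)
  }
  stopifnot(is.character(seq_s), is.character(seq_t),
            inherits(scheme, "scoring_scheme"))
}

# The dynamic programs below optimize the lexicographic objective
# (score, match count, -gap count): among score-optimal alignments the one
# with maximal x, and among those the one with minimal z, is reported.
# All three components are additive along an alignment and invariant under
# operand swap, so the reported counts are canonical and symmetric; they
# also coincide with the exhaustive enumerator's maximal match count.
# `lex_improves(a, b)` tests whether tuple a beats tuple b.
lex_improves <- function(s1, x1, z1, s2, x2, z2) {
  s1 > s2 || (s1 == s2 && (x1 > x2 || (x1 == x2 && z1 < z2)))
}

new_alignment <- function(mode, row_s, row_t, scheme, score, ns, nt) {
  ev <- count_alignment_events(row_s, row_t, mode = mode)
  denom <- if (mode == "global") max(ns, nt) else min(ns, nt)
  structure(
    list(mode = mode, row_s = row_s, row_t = row_t,
         x = ev[["x"]], y = ev[["y"]], z = ev[["z"]],
         score = score, relative = ev[["x"]] / denom,
         scheme = scheme),
    class = "pathway_alignment"
  )
}

#' @export
print.pathway_alignment <- function(x, ...) {
  cat(sprintf("<pathway_alignment> %s: score=%g relative=%.4f (x=%d y=%d z=%d)\n",
              x$mode, x$score, x$relative, x$x, x$y, x$z))
  if (length(x$row_s)) {
    cat("  S: ", paste(x$row_s, collapse = " "), "\n", sep = "")
    cat("  T: ", paste(x$row_t, collapse = " "), "\n", sep = "")
  }
  invisible(x)
}

# shared matrix fill; `edge_free` initializes the first row/column at zero
# cost (semi-global), `floor_empty` floors every cell at the empty local
# alignment. Returns the three DP matrices.
fill_matrices <- function(seq_s, seq_t, scheme, edge_free = FALSE,
                          floor_empty = FALSE) {
  m <- scheme$match; mis <- scheme$mismatch; g <- scheme$gap
  ns <- length(seq_s); nt <- length(seq_t)
  S <- matrix(0, ns + 1L, nt + 1L)
  X <- matrix(0L, ns + 1L, nt + 1L)
  Z <- matrix(0L, ns + 1L, nt + 1L)
  if (!edge_free && !floor_empty) {   # local and semi-global edges stay 0
    S[, 1L] <- g * (0:ns); Z[, 1L] <- 0:ns
    S[1L, ] <- g * (0:nt); Z[1L, ] <- 0:nt
  }
  for (i in seq_len(ns)) {
    si <- seq_s[[i]]
    for (j in seq_len(nt)) {
      eq <- si == seq_t[[j]]
      bs <- S[i, j] + (if (eq) m else mis)
      bx <- X[i, j] + (if (eq) 1L else 0L)
      bz <- Z[i, j]
      cs <- S[i, j + 1L] + g; cx <- X[i, j + 1L]; cz <- Z[i, j + 1L] + 1L
      if (lex_improves(cs, cx, cz, bs, bx, bz)) { bs <- cs; bx <- cx; bz <- cz }
      cs <- S[i + 1L, j] + g; cx <- X[i + 1L, j]; cz <- Z[i + 1L, j] + 1L
      if (lex_improves(cs, cx, cz, bs, bx, bz)) { bs <- cs; bx <- cx; bz <- cz }
      if (floor_empty && lex_improves(0, 0L, 0L, bs, bx, bz)) {
        bs <- 0; bx <- 0L; bz <- 0L
      }
      S[i + 1L, j + 1L] <- bs; X[i + 1L, j + 1L] <- bx; Z[i + 1L, j + 1L] <- bz
    }
  }
  list(S = S, X = X, Z = Z)
}

# traceback from (bi, bj); `edge_free` makes moves along the first row and
# column cost nothing (and not count as gaps); `stop_empty` stops at the
# first cell whose tuple is the empty alignment (local mode). Among moves
# achieving a cell's tuple, diagonal is preferred over consuming seq_s
# over consuming seq_t.
trace_alignment <- function(dp, seq_s, seq_t, scheme, bi, bj,
                            edge_free = FALSE, stop_empty = FALSE) {
  m <- scheme$match; mis <- scheme$mismatch; g <- scheme$gap
  S <- dp$S; X <- dp$X; Z <- dp$Z
  rs <- character(); rt <- character()
  i <- bi; j <- bj
  while (i > 1L || j > 1L) {
    if (stop_empty && S[i, j] == 0 && X[i, j] == 0L && Z[i, j] == 0L) break
    if (i > 1L && j > 1L) {
      eq <- seq_s[[i - 1L]] == seq_t[[j - 1L]]
      if (S[i, j] == S[i - 1L, j - 1L] + (if (eq) m else mis) &&
          X[i, j] == X[i - 1L, j - 1L] + (if (eq) 1L else 0L) &&
          Z[i, j] == Z[i - 1L, j - 1L]) {
        rs <- c(seq_s[[i - 1L]], rs); rt <- c(seq_t[[j - 1L]], rt)
        i <- i - 1L; j <- j - 1L
        next
      }
    }
    up_g <- if (edge_free && j == 1L) 0 else g
    up_z <- if (edge_free && j == 1L) 0L else 1L
    if (i > 1L && S[i, j] == S[i - 1L, j] + up_g &&
        X[i, j] == X[i - 1L, j] && Z[i, j] == Z[i - 1L, j] + up_z) {
      rs <- c(seq_s[[i - 1L]], rs); rt <- c(GAP, rt)
      i <- i - 1L
    } else {
      rs <- c(GAP, rs); rt <- c(seq_t[[j - 1L]], rt)
      j <- j - 1L
    }
  }
  list(row_s = rs, row_t = rt)
}

#' Global alignment of two traversal sequences
#'
#' Optimal Needleman-Wunsch-style global alignment of two node-label
#' sequences under a linear gap cost. Tokens are whole metabolite labels;
#' two tokens match iff their label strings are equal. The absolute score
#' is `S = x*m + y*n + z*g` maximized over all global alignments; the
#' relative global score is `x / max(|S|, |T|)`, the match count divided by
#' the longer sequence length, interpreted as the fraction of the smaller
#' traversal present in analogous order in the longer one. Among
#' score-optimal alignments the reported one maximizes the match count and
#' then minimizes the gap count, so the counts `x`, `y`, `z` are canonical
#' and invariant under operand swap.
#'
#' @param seq_s,seq_t Non-empty character vectors of node labels.
#' @param scheme A [scoring_scheme()].
#' @return An object of class `pathway_alignment` with fields `mode`,
#'   `row_s`/`row_t` (equal-length token rows, gaps as `"-"`), counts `x`,
#'   `y`, `z`, `score` and `relative`.
#' @examples
#' a <- align_global(c("A", "B", "C"), c("A", "P", "B", "Q", "C"),
#'                   scoring_scheme(1, -1, 0))
#' a$x         # 3
#' a$relative  # 0.6
#' @export
align_global <- function(seq_s, seq_t, scheme = scoring_scheme(1, -1, 0)) {
  check_alignment_input(seq_s, seq_t, scheme)
  ns <- length(seq_s); nt <- length(seq_t)
  dp <- fill_matrices(seq_s, seq_t, scheme)
  rows <- trace_alignment(dp, seq_s, seq_t, scheme, ns + 1L, nt + 1L)
  new_alignment("global", rows$row_s, rows$row_t, scheme,
                dp$S[ns + 1L, nt + 1L], ns, nt)
}

#' Local alignment of two traversal sequences
#'
#' Optimal Smith-Waterman-style local alignment: the best-scoring pair of
#' contiguous subsequences, with the dynamic-programming cells floored at
#' the empty alignment (score 0, `x = y = z = 0`). Among equal-scoring
#' cells the reported alignment maximizes the match count, then minimizes
#' the gap count, then takes the first cell in row-major order. The
#' relative local score is `x / min(|S|, |T|)`.
#'
#' @inheritParams align_global
#' @return A `pathway_alignment` (see [align_global()]); `row_s`/`row_t`
#'   strip to contiguous subsequences of the inputs.
#' @export
align_local <- function(seq_s, seq_t, scheme = scoring_scheme(1, -1, -2)) {
  check_alignment_input(seq_s, seq_t, scheme)
  ns <- length(seq_s); nt <- length(seq_t)
  dp <- fill_matrices(seq_s, seq_t, scheme, floor_empty = TRUE)
  bi <- 1L; bj <- 1L
  for (i in seq_len(ns + 1L)) {
    for (j in seq_len(nt + 1L)) {
      if (lex_improves(dp$S[i, j], dp$X[i, j], dp$Z[i, j],
                       dp$S[bi, bj], dp$X[bi, bj], dp$Z[bi, bj])) {
        bi <- i; bj <- j
      }
    }
  }
  rows <- trace_alignment(dp, seq_s, seq_t, scheme, bi, bj, stop_empty = TRUE)
  new_alignment("local", rows$row_s, rows$row_t, scheme, dp$S[bi, bj], ns, nt)
}

#' Semi-global (overlap) alignment of two traversal sequences
#'
#' Global alignment in which leading and trailing gap runs are penalty-free
#' in both sequences: the first dynamic-programming row and column are
#' initialized to zero and the score is the maximum over the last row and
#' column, with the remaining suffix consumed by free gaps. Free end gaps
#' appear in `row_s`/`row_t` but are excluded from the gap count `z`, so
#' the absolute-score identity `S = x*m + y*n + z*g` still holds. The
#' relative semi-global score is `x / min(|S|, |T|)`. Among equal-scoring
#' end cells the reported alignment maximizes the match count, then
#' minimizes the gap count, then prefers the last column top-to-bottom
#' before the last row left-to-right.
#'
#' @inheritParams align_global
#' @return A `pathway_alignment` (see [align_global()]).
#' @examples
#' a <- align_semiglobal(c("A", "B", "C"), c("X", "A", "B", "C", "Y"),
#'                       scoring_scheme(1, -1, -2))
#' a$score     # 3
#' a$relative  # 1
#' @export
align_semiglobal <- function(seq_s, seq_t, scheme = scoring_scheme(1, -1, -2)) {
  check_alignment_input(seq_s, seq_t, scheme)
  ns <- length(seq_s); nt <- length(seq_t)
  dp <- fill_matrices(seq_s, seq_t, scheme, edge_free = TRUE)
  bi <- 1L; bj <- nt + 1L
  for (i in seq_len(ns + 1L)) {           # last column, top to bottom
    if (lex_improves(dp$S[i, nt + 1L], dp$X[i, nt + 1L], dp$Z[i, nt + 1L],
                     dp$S[bi, bj], dp$X[bi, bj], dp$Z[bi, bj])) {
      bi <- i; bj <- nt + 1L
    }
  }
  for (j in seq_len(nt + 1L)) {           # then last row, left to right
    if (lex_improves(dp$S[ns + 1L, j], dp$X[ns + 1L, j], dp$Z[ns + 1L, j],
                     dp$S[bi, bj], dp$X[bi, bj], dp$Z[bi, bj])) {
      bi <- ns + 1L; bj <- j
    }
  }
  # trailing free gaps consume the unaligned suffix of one sequence
  if (bj == nt + 1L && bi <= ns) {
    rs <- seq_s[bi:ns]; rt <- rep(GAP, ns - bi + 1L)
  } else if (bi == ns + 1L && bj <= nt) {
    rs <- rep(GAP, nt - bj + 1L); rt <- seq_t[bj:nt]
  } else {
    rs <- character(); rt <- character()
  }
  rows <- trace_alignment(dp, seq_s, seq_t, scheme, bi, bj, edge_free = TRUE)
  new_alignment("semiglobal", c(rows$row_s, rs), c(rows$row_t, rt), scheme,
                dp$S[bi, bj], ns, nt)
}

#' Count matches, mismatches and gaps in an alignment
#'
#' Decomposes a pair of aligned token rows into the event counts entering
#' the absolute-score formula: `x` columns with equal labels, `y` columns
#' with two unequal labels, `z` columns with exactly one gap. For
#' semi-global alignments the leading and trailing runs of same-row gap
#' columns are the penalty-free end gaps and are excluded from `z`.
#'
#' @param row_s,row_t Equal-length character vectors with the gap token
#'   `"-"`; no column may have a gap in both rows.
#' @param mode `"global"`, `"local"` or `"semiglobal"` (controls only the
#'   end-gap exclusion).
#' @return Named integer vector with elements `x`, `y`, `z`.
#' @export
count_alignment_events <- function(row_s, row_t,
                                   mode = c("global", "local", "semiglobal")) {
  mode <- match.arg(mode)
  if (length(row_s) != length(row_t)) {
    stop("alignment rows must have equal length", call. = FALSE)
  }
  gs <- row_s == GAP
  gt <- row_t == GAP
  if (any(gs & gt)) {
    stop("invalid alignment: column with a gap in both rows", call. = FALSE)
  }
  x <- sum(!gs & !gt & row_s == row_t)
  y <- sum(!gs & !gt & row_s != row_t)
  z <- sum(gs | gt)
  if (mode == "semiglobal" && z > 0L) {
    n <- length(gs)
    run_len <- function(ind) {       # length of the initial TRUE run
      r <- 0L
      while (r < length(ind) && ind[r + 1L]) r <- r + 1L
      r
    }
    lead <- max(run_len(gs), run_len(gt))
    trail <- max(run_len(rev(gs)), run_len(rev(gt)))
    if (lead + trail > n) trail <- n - lead   # fully gapped alignment
    z <- z - lead - trail
  }
  c(x = as.integer(x), y = as.integer(y), z = as.integer(z))
}
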