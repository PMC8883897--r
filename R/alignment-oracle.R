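#' Exhaustive reference alignment scorer
#'
#' Computes optimal alignment scores by explicit enumeration of every
#' monotone alignment path between the two sequences, with no dynamic
#' programming: per path, the global score for each requested gap value is
#' the diagonal-column sum plus gap count times gap value; the semi-global
#' score discounts the free leading and trailing single-type gap runs; and
#' the local score is the best contiguous column window of the path
#' (every local alignment is such a window of some full path). Exponential
#' in the sequence lengths — use only for short sequences. This is the
#' independent reference against which the dynamic-programming aligners are
#' validated.
#'
#' @param seq_s,seq_t Non-empty character vectors of labels.
#' @param match,mismatch Match and mismatch values.
#' @param global_gaps Numeric vector of gap values for global scoring.
#' @param local_gap,semiglobal_gap Gap values for local / semi-global
#'   scoring.
#' @return List with `global` (named numeric vector, one score per gap
#'   value), `local` and `semiglobal` scores.
#' @export
align_enumerate <- function(seq_s, seq_t, match = 1, mismatch = -1,
                            global_gaps = c(-2, -1, 0),
                            local_gap = -2, semiglobal_gap = -2) {
  stopifnot(length(seq_s) >= 1L, length(seq_t) >= 1L)
  lev <- unique(c(seq_s, seq_t))
  s <- match(seq_s, lev)
  t <- match(seq_t, lev)
  v <- bf_all_scores_cpp(as.integer(s), as.integer(t),
                         match, mismatch, as.numeric(global_gaps),
                         local_gap, semiglobal_gap)
  ng <- length(global_gaps)
  list(global = structure(v[seq_len(ng)], names = as.character(global_gaps)),
       local = v[ng + 1L],
       semiglobal = v[ng + 2L])
}

#' Exhaustive global score with maximal match count
#'
#' Among all global alignments achieving the optimal score, reports the
#' maximal match count. The fast aligner's `x` is the match count of one
#' deterministic optimal traceback, which may be smaller when several
#' optimal alignments exist; this slower exact variant bounds it.
#'
#' @inheritParams align_enumerate
#' @param scheme A [scoring_scheme()].
#' @return List with `score` and `max_matches`.
#' @export
align_enumerate_global <- function(seq_s, seq_t, scheme = scoring_scheme(1, -1, 0)) {
  stopifnot(length(seq_s) >= 1L, length(seq_t) >= 1L,
            inherits(scheme, "scoring_scheme"))
  lev <- unique(c(seq_s, seq_t))
  s <- match(seq_s, lev)
  t <- match(seq_t, lev)
  v <- bf_global_best_cpp(as.integer(s), as.integer(t),
                          scheme$match, scheme$mismatch, scheme$gap)
  list(score = v[[1L]], max_matches = as.integer(v[[2L]]))
}
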