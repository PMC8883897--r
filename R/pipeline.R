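#' Options for pathway comparison runs
#'
#' Collects the tunable settings of the comparison pipeline. The scoring
#' base values follow the comparison protocol: match 1, mismatch -1; the
#' global aligner is always run at the three gap values (-2, -1, 0), with
#' gap 0 supplying the headline global score; local and semi-global
#' alignment use gap -2.
#'
#' @param match,mismatch Match / mismatch values.
#' @param gap_values Gap values for the global aligner (all are computed).
#' @param summary_gap Gap value whose global score fills the summary
#'   columns.
#' @param local_gap,semiglobal_gap Gap values for local and semi-global
#'   alignment.
#' @param skip_zero_overlap Short-circuit alignment when the two graphs
#'   share no node label (the scores are then known to be zero); the
#'   resulting report is identical either way, only faster.
#' @param require_full_coverage Keep only candidates whose traversals cover
#'   their whole graph.
#' @param best_per_pair In multi-candidate comparisons, keep only the
#'   candidate with maximal relative global score (ties broken by sorted
#'   origin/destiny labels).
#' @return A list of class `compare_options`.
#' @export
compare_options <- function(match = 1, mismatch = -1,
                            gap_values = c(-2, -1, 0), summary_gap = 0,
                            local_gap = -2, semiglobal_gap = -2,
                            skip_zero_overlap = FALSE,
                            require_full_coverage = FALSE,
                            best_per_pair = FALSE) {
  if (!summary_gap %in% gap_values) {
    stop("`summary_gap` must be one of `gap_values`", call. = FALSE)
  }
  structure(list(match = match, mismatch = mismatch,
                 gap_values = sort(gap_values), summary_gap = summary_gap,
                 local_gap = local_gap, semiglobal_gap = semiglobal_gap,
                 skip_zero_overlap = isTRUE(skip_zero_overlap),
                 require_full_coverage = isTRUE(require_full_coverage),
                 best_per_pair = isTRUE(best_per_pair)),
            class = "compare_options")
}

gap_tag <- function(g) {
  if (g < 0) paste0("gm", abs(g)) else paste0("g", g)
}

# closed-form optimal global score for two sequences sharing no label:
# alignments have x = 0, y mismatch columns (y <= min) and
# z = na + nb - 2y gap columns
zero_overlap_global_score <- function(na, nb, mismatch, gap) {
  y <- 0:min(na, nb)
  max(y * mismatch + (na + nb - 2 * y) * gap)
}

compare_from_traversals <- function(graph_a, graph_b, trav_a, trav_b,
                                    origin_equivalent, destiny_equivalent,
                                    options = compare_options()) {
  feats <- compute_features(graph_a, graph_b)
  dbp <- differentiate_pairs(graph_a, graph_b)
  sa <- trav_a$sequence; sb <- trav_b$sequence
  rep <- list(
    pathway_a = graph_a$pathway_id, pathway_b = graph_b$pathway_id,
    origin_a = trav_a$origin, destiny_a = trav_a$destiny,
    origin_b = trav_b$origin, destiny_b = trav_b$destiny,
    sequence_a = sa, sequence_b = sb,
    full_coverage_a = trav_a$full_coverage, full_coverage_b = trav_b$full_coverage,
    origin_equivalent = origin_equivalent, destiny_equivalent = destiny_equivalent
  )
  shortcut <- options$skip_zero_overlap && feats$equivalent_nodes_ratio == 0
  if (shortcut) {
    for (g in options$gap_values) {
      tag <- gap_tag(g)
      rep[[paste0("global_score_", tag)]] <-
        zero_overlap_global_score(length(sa), length(sb), options$mismatch, g)
      rep[[paste0("relative_global_", tag)]] <- 0
      rep[[paste0("matches_global_", tag)]] <- 0L
    }
    rep$local_score <- 0; rep$relative_local <- 0; rep$matches_local <- 0L
    rep$semiglobal_score <- 0; rep$relative_semiglobal <- 0
    rep$matches_semiglobal <- 0L
  } else {
    for (g in options$gap_values) {
      tag <- gap_tag(g)
      al <- align_global(sa, sb, scoring_scheme(options$match, options$mismatch, g))
      rep[[paste0("global_score_", tag)]] <- al$score
      rep[[paste0("relative_global_", tag)]] <- al$relative
      rep[[paste0("matches_global_", tag)]] <- al$x
    }
    loc <- align_local(sa, sb,
                       scoring_scheme(options$match, options$mismatch, options$local_gap))
    rep$local_score <- loc$score
    rep$relative_local <- loc$relative
    rep$matches_local <- loc$x
    sg <- align_semiglobal(sa, sb,
                           scoring_scheme(options$match, options$mismatch,
                                          options$semiglobal_gap))
    rep$semiglobal_score <- sg$score
    rep$relative_semiglobal <- sg$relative
    rep$matches_semiglobal <- sg$x
  }
  stag <- gap_tag(options$summary_gap)
  rep$global_score <- rep[[paste0("global_score_", stag)]]
  rep$relative_global <- rep[[paste0("relative_global_", stag)]]
  rep$dbp_unique_to_a <- dbp$unique_to_a
  rep$dbp_unique_to_b <- dbp$unique_to_b
  rep$dbp_numerical <- dbp$numerical
  rep$dbp_similarity <- 1 - dbp$numerical
  rep$size_ratio <- feats$size_ratio
  rep$complexity_ratio <- feats$complexity_ratio
  rep$equivalent_nodes_ratio <- feats$equivalent_nodes_ratio
  rep$common_families <- feats$common_families
  rep$families_annotated <- feats$families_annotated
  rep$size_ratio_level <- feats$size_ratio_level
  rep$families_level <- feats$families_level
  rep$zero_overlap_short_circuit <- shortcut
  structure(rep, class = "comparison_report")
}

#' Compare one pathway pair along chosen traversal lectures
#'
#' Runs the full pairwise comparison for a single candidate: both graphs
#' are traversed breadth-first from their chosen origins, the two label
#' sequences are aligned globally (at gap values -2, -1 and 0), locally and
#' semi-globally, the reaction-level Differentiation by Pairs is computed
#' on the graphs, and the structural pair features are annotated. When
#' `options$skip_zero_overlap` is set and the graphs share no label, the
#' alignment step is short-circuited to the closed-form zero-overlap scores
#' (all match counts and relative scores 0) and flagged.
#'
#' @param graph_a,graph_b Two [pathway_graph] objects.
#' @param origin_a,destiny_a,origin_b,destiny_b Origin and destiny labels
#'   per side; each pair must form a valid lecture.
#' @param options A [compare_options()] list.
#' @return An object of class `comparison_report` (flat named list): ids
#'   and lecture choices, traversal sequences, equivalence flags, global
#'   scores (absolute, relative and match count per gap value plus summary
#'   columns at the selected gap), local and semi-global scores,
#'   Differentiation-by-Pairs lists, its numerical score and complement,
#'   pair features with factor levels, and the short-circuit flag.
#' @export
compare_pair <- function(graph_a, graph_b, origin_a, destiny_a,
                         origin_b, destiny_b, options = compare_options()) {
  ta <- make_traversal(graph_a, origin_a, destiny_a)
  tb <- make_traversal(graph_b, origin_b, destiny_b)
  compare_from_traversals(graph_a, graph_b, ta, tb,
                          identical(origin_a, origin_b),
                          identical(destiny_a, destiny_b),
                          options)
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> %s (%s=>%s) vs %s (%s=>%s)%s\n",
              x$pathway_a, x$origin_a, x$destiny_a,
              x$pathway_b, x$origin_b, x$destiny_b,
              if (x$zero_overlap_short_circuit) " [zero-overlap short-circuit]" else ""))
  cat(sprintf("  relative global %.3f | local %.3f | semiglobal %.3f | numerical DbP %.3f\n",
              x$relative_global, x$relative_local, x$relative_semiglobal,
              x$dbp_numerical))
  cat(sprintf("  size ratio %.3f (%s), equivalent nodes %.3f, common families %d (%s)\n",
              x$size_ratio, x$size_ratio_level, x$equivalent_nodes_ratio,
              x$common_families, x$families_level))
  invisible(x)
}

#' Compare all candidate lectures of a pathway pair
#'
#' Enumerates every valid origin-destiny traversal pair of the two graphs
#' (see [enumerate_candidates()]) and produces one comparison report per
#' candidate, in deterministic sorted order. A pathway pair can therefore
#' yield several comparisons, one per lecture combination. With
#' `options$best_per_pair` only the report with maximal relative global
#' score is kept.
#'
#' @inheritParams compare_pair
#' @return List of `comparison_report` objects (empty when no candidate).
#' @export
compare_all_candidates <- function(graph_a, graph_b, options = compare_options()) {
  cands <- enumerate_candidates(graph_a, graph_b,
                                require_full_coverage = options$require_full_coverage)
  reports <- lapply(cands, function(cand) {
    compare_from_traversals(graph_a, graph_b,
                            cand$traversal_a, cand$traversal_b,
                            cand$origin_equivalent, cand$destiny_equivalent,
                            options)
  })
  if (options$best_per_pair && length(reports) > 1L) {
    rel <- vapply(reports, `[[`, numeric(1L), "relative_global")
    best <- which(rel == max(rel))
    if (length(best) > 1L) {
      keys <- vapply(reports[best], function(r) {
        paste(r$origin_a, r$destiny_a, r$origin_b, r$destiny_b, sep = "\r")
      }, character(1L))
      best <- best[order(keys)]
    }
    reports <- reports[best[1L]]
  }
  reports
}

report_columns <- function(gap_values = c(-2, -1, 0)) {
  gtags <- vapply(sort(gap_values), gap_tag, character(1L))
  c("pathway_a", "pathway_b", "origin_a", "destiny_a", "origin_b", "destiny_b",
    "sequence_a", "sequence_b", "full_coverage_a", "full_coverage_b",
    "origin_equivalent", "destiny_equivalent",
    as.vector(t(outer(c("global_score_", "relative_global_", "matches_global_"),
                      gtags, paste0))),
    "global_score", "relative_global",
    "local_score", "relative_local", "matches_local",
    "semiglobal_score", "relative_semiglobal", "matches_semiglobal",
    "dbp_unique_to_a", "dbp_unique_to_b", "dbp_numerical", "dbp_similarity",
    "size_ratio", "complexity_ratio", "equivalent_nodes_ratio",
    "common_families", "families_annotated", "size_ratio_level",
    "families_level", "zero_overlap_short_circuit")
}

flatten_report <- function(report) {
  out <- report
  out$sequence_a <- paste(report$sequence_a, collapse = "|")
  out$sequence_b <- paste(report$sequence_b, collapse = "|")
  out$dbp_unique_to_a <- paste(report$dbp_unique_to_a, collapse = "|")
  out$dbp_unique_to_b <- paste(report$dbp_unique_to_b, collapse = "|")
  as.data.frame(out[report_columns()], stringsAsFactors = FALSE)
}

#' Write comparison reports to CSV or JSON
#'
#' CSV output is a flat table with a fixed, documented column order (one
#' row per comparison; list-valued fields joined with `"|"`). JSON output
#' preserves nested lists: traversal sequences and
#' Differentiation-by-Pairs edge strings stay arrays. Both formats are
#' byte-deterministic for identical inputs.
#'
#' @param reports A single `comparison_report` or a list of them (possibly
#'   empty: CSV then contains only the header).
#' @param path Output file path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(reports, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (inherits(reports, "comparison_report")) reports <- list(reports)
  stopifnot(all(vapply(reports, inherits, logical(1L), "comparison_report")))
  if (format == "csv") {
    tab <- if (length(reports)) {
      do.call(rbind, lapply(reports, flatten_report))
    } else {
      empty <- lapply(report_columns(), function(x) character())
      names(empty) <- report_columns()
      as.data.frame(empty, stringsAsFactors = FALSE)
    }
    ok <- tryCatch({
      utils::write.csv(tab, path, row.names = FALSE, quote = TRUE,
                       fileEncoding = "UTF-8")
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok)) stop("cannot write report to ", path, ": ",
                          conditionMessage(ok), call. = FALSE)
  } else {
    stripped <- lapply(reports, function(r) {
      r <- unclass(r)
      r$sequence_a <- as.list(r$sequence_a)
      r$sequence_b <- as.list(r$sequence_b)
      r$dbp_unique_to_a <- as.list(r$dbp_unique_to_a)
      r$dbp_unique_to_b <- as.list(r$dbp_unique_to_b)
      r
    })
    ok <- tryCatch({
      jsonlite::write_json(stripped, path, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok)) stop("cannot write report to ", path, ": ",
                          conditionMessage(ok), call. = FALSE)
  }
  invisible(path)
}

#' Batch comparison over a directory of DPW files
#'
#' Loads every pathway in a dataset directory, applies the selection funnel
#' (size range, optional single-origin and full-coverage filters), takes a
#' seeded random sample proportional within each size stratum, compares all
#' remaining pathway pairs over all their candidate lectures, and writes
#' one CSV row per executed comparison. The run log records how many
#' pathways each criterion excluded. A fixed seed yields a byte-identical
#' output file.
#'
#' @param dataset_dir Directory containing `*.dpw` (or `*.json`) pathway
#'   files and an optional `families.json` sidecar.
#' @param output Optional CSV output path.
#' @param size_min,size_max Node-count range to keep (2-20 matches the
#'   curated-corpus selection).
#' @param single_origin_only Keep only pathways with exactly one origin
#'   (guarantees full-coverage traversals for connected graphs).
#' @param sample_fraction Fraction of pathways kept within each size
#'   stratum (seeded, without replacement); 0 keeps none.
#' @param seed Integer seed for the sampling.
#' @param options A [compare_options()] list (full-coverage filtering,
#'   zero-overlap short-circuit, best-per-pair, scoring values).
#' @return Invisibly, a list with `reports` (list of `comparison_report`),
#'   `table` (the flat data frame written to CSV) and `log` (character
#'   vector of funnel messages).
#' @export
batch_compare <- function(dataset_dir, output = NULL,
                          size_min = 2L, size_max = 20L,
                          single_origin_only = FALSE,
                          sample_fraction = 1, seed = 1L,
                          options = compare_options()) {
  stopifnot(dir.exists(dataset_dir), sample_fraction >= 0, sample_fraction <= 1)
  files <- sort(list.files(dataset_dir, pattern = "\\.dpw$", full.names = TRUE))
  if (!length(files)) {
    files <- sort(list.files(dataset_dir, pattern = "\\.json$", full.names = TRUE))
    files <- files[basename(files) != "families.json"]
  }
  if (!length(files)) stop("no DPW files found in ", dataset_dir, call. = FALSE)
  fam_path <- file.path(dataset_dir, "families.json")
  fams <- if (file.exists(fam_path)) read_families(fam_path) else list()
  log <- character()
  note <- function(...) {
    line <- sprintf(...)
    log <<- c(log, line)
    message(line)
  }
  graphs <- list()
  failed <- character()
  for (f in files) {
    g <- tryCatch(read_dpw(f), error = function(e) {
      note("skipping unreadable file %s: %s", basename(f), conditionMessage(e))
      NULL
    })
    if (is.null(g)) { failed <- c(failed, f); next }
    if (!is.null(fams[[g$pathway_id]])) g$families <- fams[[g$pathway_id]]
    graphs[[g$pathway_id]] <- g
  }
  if (!length(graphs)) stop("all input files failed to load", call. = FALSE)
  note("loaded %d of %d pathway files", length(graphs), length(files))
  sizes <- vapply(graphs, pathway_size, integer(1L))
  keep <- sizes >= size_min & sizes <= size_max
  note("size filter [%d, %d]: %d kept, %d excluded",
       size_min, size_max, sum(keep), sum(!keep))
  graphs <- graphs[keep]
  if (single_origin_only && length(graphs)) {
    one <- vapply(graphs, function(g) length(origins(g)) == 1L, logical(1L))
    note("single-origin filter: %d kept, %d excluded", sum(one), sum(!one))
    graphs <- graphs[one]
  }
  has_lecture <- vapply(graphs, function(g) length(valid_traversals(g)) > 0L,
                        logical(1L))
  note("valid-lecture filter: %d kept, %d excluded",
       sum(has_lecture), sum(!has_lecture))
  graphs <- graphs[has_lecture]
  if (sample_fraction < 1 && length(graphs)) {
    sizes <- vapply(graphs, pathway_size, integer(1L))
    keep_ids <- character()
    with_seed(seed, {
      for (s in sort(unique(sizes))) {
        ids <- sort(names(graphs)[sizes == s])
        n_keep <- round(sample_fraction * length(ids))
        if (n_keep > 0L) {
          keep_ids <- c(keep_ids,
                        if (length(ids) == 1L) ids else sample(ids, n_keep))
        }
      }
    })
    note("stratified sample (fraction %.2f, seed %d): %d of %d pathways kept",
         sample_fraction, seed, length(keep_ids), length(graphs))
    graphs <- graphs[sort(keep_ids)]
  }
  reports <- list()
  if (length(graphs) >= 2L) {
    ids <- sort(names(graphs))
    for (i in seq_len(length(ids) - 1L)) {
      for (j in (i + 1L):length(ids)) {
        reports <- c(reports,
                     compare_all_candidates(graphs[[ids[i]]], graphs[[ids[j]]],
                                            options))
      }
    }
  }
  note("%d comparisons executed over %d pathway pairs",
       length(reports), if (length(graphs) >= 2L) choose(length(graphs), 2L) else 0L)
  tab <- if (length(reports)) do.call(rbind, lapply(reports, flatten_report)) else NULL
  if (!is.null(output)) write_report(reports, output, format = "csv")
  invisible(list(reports = reports, table = tab, log = log))
}
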