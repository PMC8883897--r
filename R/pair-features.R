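#' Structural features of a pathway pair
#'
#' Three ratios characterize how comparable two pathway graphs are:
#' * size ratio — smaller node count over larger node count; how much of
#'   the bigger graph the smaller one could cover;
#' * complexity ratio — smaller edge count over larger edge count (defined
#'   as 1 when both graphs are edgeless and 0 when exactly one is);
#' * equivalent-nodes ratio — number of labels present in both graphs,
#'   divided by the larger graph's size.
#'
#' The pair is additionally characterized by the number of families the two
#' pathways have in common (set intersection; a pathway may belong to
#' several families) and by the factor levels of the size ratio and the
#' common-family count (see [size_ratio_level()] and [families_level()]).
#' `families_annotated` records whether both pathways carry at least one
#' family annotation, distinguishing "annotated and disjoint" from "not
#' annotated at all".
#'
#' @param graph_a,graph_b Two [pathway_graph] objects.
#' @return An object of class `pair_features` with fields `size_ratio`,
#'   `complexity_ratio`, `equivalent_nodes_ratio`, `common_families`,
#'   `families_annotated`, `size_ratio_level`, `families_level`.
#' @export
compute_features <- function(graph_a, graph_b) {
  stopifnot(inherits(graph_a, "pathway_graph"), inherits(graph_b, "pathway_graph"))
  sa <- pathway_size(graph_a); sb <- pathway_size(graph_b)
  ca <- pathway_complexity(graph_a); cb <- pathway_complexity(graph_b)
  complexity_ratio <- if (ca == 0L && cb == 0L) 1
                      else if (min(ca, cb) == 0L) 0
                      else min(ca, cb) / max(ca, cb)
  shared <- length(intersect(graph_a$nodes, graph_b$nodes))
  common <- length(intersect(graph_a$families, graph_b$families))
  size_ratio <- min(sa, sb) / max(sa, sb)
  structure(
    list(size_ratio = size_ratio,
         complexity_ratio = complexity_ratio,
         equivalent_nodes_ratio = shared / max(sa, sb),
         common_families = common,
         families_annotated = length(graph_a$families) > 0L &&
                              length(graph_b$families) > 0L,
         size_ratio_level = size_ratio_level(size_ratio),
         families_level = families_level(common)),
    class = "pair_features"
  )
}

#' @export
print.pair_features <- function(x, ...) {
  cat(sprintf(paste0("<pair_features> size_ratio=%.3f (%s), complexity_ratio=%.3f,\n",
                     "  equivalent_nodes_ratio=%.3f, common_families=%d (%s%s)\n"),
              x$size_ratio, x$size_ratio_level, x$complexity_ratio,
              x$equivalent_nodes_ratio, x$common_families, x$families_level,
              if (x$families_annotated) "" else ", unannotated"))
  invisible(x)
}

#' Factor level of a size ratio
#'
#' Buckets a size ratio into the three experimental levels:
#' `different` (much difference) for x < 0.4, `medium` (mean difference)
#' for 0.4 <= x < 0.7, `similar` (little difference) for x >= 0.7.
#'
#' @param x Size ratio in (0, 1].
#' @return `"different"`, `"medium"` or `"similar"`.
#' @export
size_ratio_level <- function(x) {
  stopifnot(is.numeric(x), length(x) == 1L)
  if (is.na(x) || x <= 0 || x > 1) {
    stop("size ratio must lie in (0, 1], got ", x, call. = FALSE)
  }
  if (x < 0.4) "different" else if (x < 0.7) "medium" else "similar"
}

#' Factor level of a common-family count
#'
#' Buckets the number of common families: `none` for 0, `few` for 1-3,
#' `several` for 4 or more.
#'
#' @param k Non-negative integer count.
#' @return `"none"`, `"few"` or `"several"`.
#' @export
families_level <- function(k) {
  stopifnot(is.numeric(k), length(k) == 1L)
  if (is.na(k) || k < 0 || k != trunc(k)) {
    stop("common-family count must be a non-negative integer, got ", k,
         call. = FALSE)
  }
  if (k == 0) "none" else if (k <= 3) "few" else "several"
}

#' Plan a two-factor designed experiment over candidate pairs
#'
#' Plans `n_levels1 * n_levels2 * replicas` comparison runs: for every cell
#' of the two-factor grid, `replicas` distinct pairs are drawn uniformly
#' without replacement from the candidate pool, so all planned comparisons
#' are unique. The canonical design is 3 size-ratio levels x 3
#' common-family levels x 50 replicas = 450 runs.
#'
#' @param n_levels1,n_levels2 Number of levels of each factor (>= 1). The
#'   levels used are the first `n_levels1` / `n_levels2` sorted distinct
#'   values of the pool's factor columns.
#' @param replicas Pairs to draw per cell (>= 1).
#' @param candidate_pool Data frame with columns `pair_id`, `factor1`,
#'   `factor2` listing the available pairs and their factor levels.
#' @param seed Integer seed; the same seed reproduces the identical plan.
#' @return An object of class `doe_plan`: `runs` (data frame with columns
#'   `factor1`, `factor2`, `replica`, `pair_id`), `n_runs`, `seed`.
#' @examples
#' pool <- expand.grid(f1 = c("different", "medium", "similar"),
#'                     f2 = c("none", "few", "several"),
#'                     i = 1:2, stringsAsFactors = FALSE)
#' pool <- data.frame(pair_id = paste0("p", seq_len(nrow(pool))),
#'                    factor1 = pool$f1, factor2 = pool$f2)
#' plan_doe(3, 3, 1, pool, seed = 1)$n_runs  # 9
#' @export
plan_doe <- function(n_levels1, n_levels2, replicas, candidate_pool, seed = 1L) {
  stopifnot(n_levels1 >= 1L, n_levels2 >= 1L, replicas >= 1L,
            is.data.frame(candidate_pool),
            all(c("pair_id", "factor1", "factor2") %in% names(candidate_pool)))
  pool <- candidate_pool[!duplicated(candidate_pool$pair_id), , drop = FALSE]
  lev1 <- sort(unique(as.character(pool$factor1)))
  lev2 <- sort(unique(as.character(pool$factor2)))
  if (length(lev1) < n_levels1 || length(lev2) < n_levels2) {
    stop("candidate pool has fewer factor levels than requested (",
         length(lev1), " x ", length(lev2), " available)", call. = FALSE)
  }
  lev1 <- lev1[seq_len(n_levels1)]
  lev2 <- lev2[seq_len(n_levels2)]
  runs <- vector("list", n_levels1 * n_levels2)
  k <- 0L
  with_seed(seed, {
    for (l1 in lev1) {
      for (l2 in lev2) {
        ids <- pool$pair_id[pool$factor1 == l1 & pool$factor2 == l2]
        if (length(ids) < replicas) {
          stop("cell (", l1, ", ", l2, ") has only ", length(ids),
               " candidate pairs, need ", replicas, call. = FALSE)
        }
        k <- k + 1L
        runs[[k]] <- data.frame(
          factor1 = l1, factor2 = l2, replica = seq_len(replicas),
          pair_id = sample(ids, replicas, replace = FALSE),
          stringsAsFactors = FALSE
        )
      }
    }
  })
  runs <- do.call(rbind, runs)
  rownames(runs) <- NULL
  structure(list(runs = runs, n_runs = nrow(runs), seed = as.integer(seed)),
            class = "doe_plan")
}

#' @export
print.doe_plan <- function(x, ...) {
  cat(sprintf("<doe_plan> %d runs (%d cells x %d replicas), seed %d\n",
              x$n_runs,
              length(unique(paste(x$runs$factor1, x$runs$factor2, sep = "/"))),
              max(x$runs$replica), x$seed))
  invisible(x)
}

# run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  eval.parent(substitute(expr))
}
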