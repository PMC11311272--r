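# The gut microbiome cancer index: per-sample log2 ratio of the detected
# fraction of control-associated marker species (H) to the detected
# fraction of case-associated marker species (C). Higher = healthier.

#' Parameters of the cancer index
#'
#' @param detection_threshold Relative abundance above which (`>=`) a
#'   marker species counts as detected in a sample; default `1e-5`,
#'   about one read at a 100,000-read depth.
#' @param epsilon Pseudo-fraction stabilising the ratio, default 0.01.
#' @param log_base Base of the logarithm, default 2.
#' @return List of class `index_params`.
#' @export
index_params <- function(detection_threshold = 1e-5, epsilon = 0.01,
                         log_base = 2) {
  stopifnot(detection_threshold >= 0, epsilon > 0, log_base > 1)
  structure(list(detection_threshold = detection_threshold,
                 epsilon = epsilon, log_base = log_base),
            class = "index_params")
}

#' Gut microbiome cancer index of one sample
#'
#' `f_H` is the fraction of control-associated markers H detected in the
#' sample (0 when H is empty), `f_C` likewise for case-associated markers
#' C; the index is `log2((f_H + eps) / (f_C + eps))`. A healthy profile
#' retains the control-associated species and lacks the case-associated
#' ones, giving a high index.
#'
#' @param abundances Named numeric vector of the sample's relative
#'   abundances (names are species).
#' @param markers A `marker_sets` object (or list with
#'   `control_associated` / `case_associated` character vectors); at
#'   least one of the two sets must be non-empty.
#' @param params An [index_params()] list.
#' @return A single finite number; positive when control-associated
#'   markers dominate.
#' @export
compute_index <- function(abundances, markers, params = index_params()) {
  H <- markers$control_associated
  C <- markers$case_associated
  if (length(H) == 0 && length(C) == 0) {
    stop("both marker sets are empty; the index is undefined")
  }
  detected <- function(set) {
    if (length(set) == 0) return(0)
    ab <- abundances[set]
    ab[is.na(ab)] <- 0
    sum(ab >= params$detection_threshold) / length(set)
  }
  f_H <- detected(H)
  f_C <- detected(C)
  # difference of logs (not log of ratio) so the H-C swap negates exactly
  log(f_H + params$epsilon, base = params$log_base) -
    log(f_C + params$epsilon, base = params$log_base)
}

#' Rank-based AUC (probability of correct ranking)
#'
#' Mann-Whitney `U / (n_pos * n_neg)`; tied pairs count one half.
#'
#' @param scores_pos,scores_neg Scores of the positive and negative
#'   class, both non-empty.
#' @return AUC in `[0, 1]`: the probability that a random positive
#'   outscores a random negative.
#' @export
auc_rank <- function(scores_pos, scores_neg) {
  if (length(scores_pos) == 0 || length(scores_neg) == 0) {
    stop("both score vectors must be non-empty")
  }
  n_pos <- length(scores_pos)
  r <- rank(c(scores_pos, scores_neg))
  U <- sum(r[seq_len(n_pos)]) - n_pos * (n_pos + 1) / 2
  U / (n_pos * length(scores_neg))
}

# Stratified fold assignment: each group is split as evenly as possible.
.stratified_folds <- function(ids_by_group, k, seed) {
  withr::with_seed(seed, {
    folds <- stats::setNames(integer(0), character(0))
    for (ids in ids_by_group) {
      if (length(ids) < k) {
        stop(sprintf("a class has %d samples, fewer than k = %d folds; use fewer folds",
                     length(ids), k))
      }
      f <- rep_len(seq_len(k), length(ids))[sample.int(length(ids))]
      folds <- c(folds, stats::setNames(f, ids))
    }
    folds
  })
}

#' Evaluate the cancer index on one cohort
#'
#' In the default cross-validated mode, marker sets are derived on
#' training folds only and each sample is scored by markers it did not
#' help select; this gives an honest estimate of separation. The
#' `"in_sample"` mode derives markers from all samples and scores the
#' same samples — the circular design whose optimism the CV mode exists
#' to expose — and is kept for comparability with single-cohort studies.
#'
#' Training folds in which no marker reaches significance yield a neutral
#' index of 0 for their held-out samples (both detected fractions are
#' treated as equal).
#'
#' @inheritParams filter_species
#' @param params An [index_params()] list.
#' @param k_folds Number of stratified folds, default 5.
#' @param seed Integer seed for the fold assignment.
#' @param mode `"cv"` (default) or `"in_sample"`.
#' @param alpha FDR threshold passed to [derive_marker_sets()].
#' @return Object of class `index_result`: `per_sample_index` (named
#'   vector), `group_summary` (medians, U, p), `auc` (probability a
#'   control outranks a case), `cv_scheme`.
#' @export
evaluate_index <- function(x, meta, cohort, params = index_params(),
                           k_folds = 5, seed = 1,
                           mode = c("cv", "in_sample"), alpha = 0.05,
                           min_mean_reads = 50, universe_fraction = 1e-4) {
  mode <- match.arg(mode)
  grp <- .cohort_samples(meta, cohort)
  ra <- relative_abundance(x)
  all_ids <- c(grp$cases, grp$controls)
  idx <- stats::setNames(numeric(length(all_ids)), all_ids)

  score_block <- function(markers, ids) {
    vapply(ids, function(s) {
      if (length(markers$control_associated) == 0 &&
          length(markers$case_associated) == 0) return(0)
      compute_index(ra[s, ], markers, params)
    }, numeric(1))
  }
  empty_markers <- list(control_associated = character(0),
                        case_associated = character(0))

  if (mode == "in_sample") {
    mk <- tryCatch(
      derive_marker_sets(x, meta, cohort, alpha, min_mean_reads, universe_fraction),
      error = function(e) empty_markers)
    idx[all_ids] <- score_block(mk, all_ids)
    scheme <- "in_sample (markers from all samples)"
  } else {
    folds <- .stratified_folds(list(grp$cases, grp$controls), k_folds, seed)
    for (f in seq_len(k_folds)) {
      test_ids <- names(folds)[folds == f]
      train_ids <- setdiff(all_ids, test_ids)
      meta_train <- meta[meta$sample_id %in% train_ids, , drop = FALSE]
      mk <- tryCatch(
        derive_marker_sets(subset_samples(x, train_ids),
                           sample_metadata(as.data.frame(meta_train)),
                           cohort, alpha, min_mean_reads, universe_fraction),
        error = function(e) empty_markers)
      idx[test_ids] <- score_block(mk, test_ids)
    }
    scheme <- sprintf("stratified %d-fold CV, seed %d", k_folds, seed)
  }

  i_case <- idx[grp$cases]
  i_ctrl <- idx[grp$controls]
  mw <- mann_whitney(i_case, i_ctrl)
  structure(list(
    cohort = cohort,
    per_sample_index = idx,
    group_summary = list(median_case = stats::median(i_case),
                         median_control = stats::median(i_ctrl),
                         U = mw$U, p = mw$p),
    auc = auc_rank(i_ctrl, i_case),
    cv_scheme = scheme
  ), class = "index_result")
}

#' @export
print.index_result <- function(x, ...) {
  cat(sprintf(
    "index_result [%s]: median case %.3f vs control %.3f; MW p = %.3g; AUC(control > case) = %.3f\n  %s\n",
    x$cohort, x$group_summary$median_case, x$group_summary$median_control,
    x$group_summary$p, x$auc, x$cv_scheme))
  invisible(x)
}
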