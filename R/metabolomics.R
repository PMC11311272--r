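# Fecal SCFA / amino-acid comparisons between case groups and the pooled
# healthy-control reference, in concentration and proportion-of-total modes.

#' Metabolite proportions of total
#'
#' Rescales one sample's 16 concentrations to percentages of their sum.
#'
#' @param row Numeric vector of concentrations; no missing values, at
#'   least one positive.
#' @return Vector of the same length summing to 100.
#' @export
to_proportions <- function(row) {
  if (anyNA(row)) stop("missing values: sample must be excluded from proportion mode")
  if (any(row < 0)) stop("concentrations must be >= 0")
  total <- sum(row)
  if (total == 0) stop("all-zero metabolite row has undefined proportions")
  row * 100 / total
}

#' Significance code for an adjusted p-value
#'
#' The four-level star scheme used in metabolite heatmaps:
#' 4 if `q < 1e-4`, 3 if `q < 1e-3`, 2 if `q < 0.01`, 1 if `q < 0.05`,
#' else 0.
#'
#' @param q Adjusted p-value(s) in `[0, 1]`.
#' @return Integer code(s) 0-4, monotone non-increasing in `q`.
#' @export
significance_code <- function(q) {
  if (anyNA(q) || any(q < 0 | q > 1)) stop("q must lie in [0, 1]")
  (q < 0.05) + (q < 1e-2) + (q < 1e-3) + (q < 1e-4)
}

#' Compare metabolite profiles between a case group and the HC pool
#'
#' Per metabolite, a two-sided Mann-Whitney U test between the cohort's
#' case samples and the whole healthy-control pool (controls are not
#' cohort-matched for metabolomics), with Benjamini-Hochberg adjustment
#' across the 16 metabolites within this cohort and mode. In
#' `"proportion"` mode each sample's panel is first rescaled to
#' percentages of its total; samples with any missing value are excluded
#' from that mode only. In `"concentration"` mode, missing values drop a
#' sample from the affected metabolite only.
#'
#' @param tbl A `metabolite_table`.
#' @param meta A `sample_metadata` data frame.
#' @param cohort Cohort identifier selecting the case samples.
#' @param mode `"concentration"` or `"proportion"`.
#' @return Object of class `metabolite_comparison`: data frame
#'   `per_metabolite` with medians, `direction`, `p`, `q` and `code`,
#'   plus `cohort` and `mode`.
#' @export
compare_metabolites <- function(tbl, meta, cohort,
                                mode = c("concentration", "proportion")) {
  mode <- match.arg(mode)
  stopifnot(inherits(tbl, "metabolite_table"), inherits(meta, "sample_metadata"))
  grp <- .cohort_samples(meta, cohort)
  case_ids <- intersect(grp$cases, tbl$sample_ids)
  hc_ids <- intersect(meta$sample_id[meta$group == "HC" & meta$timepoint == "pre"],
                      tbl$sample_ids)
  if (length(case_ids) == 0 || length(hc_ids) == 0) {
    stop("empty case or control group in the metabolite table")
  }
  m <- tbl$concentrations
  if (mode == "proportion") {
    complete <- rowSums(is.na(m)) == 0 & rowSums(m, na.rm = TRUE) > 0
    dropped <- c(case_ids, hc_ids)[!complete[c(case_ids, hc_ids)]]
    if (length(dropped)) {
      message(sprintf("proportion mode: excluded %d sample(s) with missing values",
                      length(dropped)))
    }
    case_ids <- case_ids[complete[case_ids]]
    hc_ids <- hc_ids[complete[hc_ids]]
    m <- t(apply(m[complete, , drop = FALSE], 1, to_proportions))
  }

  mets <- tbl$metabolite_names
  rows <- lapply(mets, function(met) {
    xc <- m[case_ids, met]
    xh <- m[hc_ids, met]
    xc <- xc[!is.na(xc)]
    xh <- xh[!is.na(xh)]
    if (length(xc) == 0 || length(xh) == 0) {
      return(data.frame(metabolite = met, median_case = NA_real_,
                        median_control = NA_real_, direction = "none",
                        p = NA_real_, stringsAsFactors = FALSE))
    }
    mw <- mann_whitney(xc, xh)
    d <- stats::median(xc) - stats::median(xh)
    data.frame(metabolite = met,
               median_case = stats::median(xc),
               median_control = stats::median(xh),
               direction = if (d > 0) "higher_in_cases"
                           else if (d < 0) "lower_in_cases" else "none",
               p = mw$p, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  ok <- !is.na(per$p)
  per$q <- NA_real_
  per$q[ok] <- bh_adjust(per$p[ok])
  per$code <- NA_integer_
  per$code[ok] <- significance_code(per$q[ok])
  structure(list(per_metabolite = per, cohort = cohort, mode = mode),
            class = "metabolite_comparison")
}

#' @export
print.metabolite_comparison <- function(x, ...) {
  sig <- x$per_metabolite[!is.na(x$per_metabolite$code) & x$per_metabolite$code > 0, ]
  cat(sprintf("metabolite_comparison [%s, %s mode]: %d of %d metabolites significant\n",
              x$cohort, x$mode, nrow(sig), nrow(x$per_metabolite)))
  if (nrow(sig)) {
    cat(paste(sprintf("  %s: code %d, %s", sig$metabolite, sig$code, sig$direction),
              collapse = "\n"), "\n")
  }
  invisible(x)
}
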