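# Marker-species selection: abundance filters, per-species Mann-Whitney on
# relative abundances, BH adjustment, direction assignment.

#' Two-sided Mann-Whitney U test
#'
#' Thin wrapper around [stats::wilcox.test()] fixing this package's policy:
#' exact enumeration when the pooled size is at most 12 and there are no
#' ties, otherwise the normal approximation with tie and continuity
#' correction.
#'
#' @param x,y Numeric vectors, each non-empty.
#' @return List with `U` (rank-sum statistic for `x`) and `p` (two-sided).
#' @export
mann_whitney <- function(x, y) {
  if (length(x) < 1 || length(y) < 1) stop("both groups must be non-empty")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && (length(x) + length(y)) <= 12
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = exact, correct = TRUE)
  )
  list(U = unname(ht$statistic), p = ht$p.value)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values in the input order (via [stats::p.adjust()]).
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Abundance filters ahead of differential testing
#'
#' Applies the study-universe filter first (species carrying more than
#' `universe_fraction` of all reads pooled over samples), then retains
#' species whose mean read count strictly exceeds `min_mean_reads` in the
#' case group OR in the matched control group.
#'
#' @param x A `count_table`.
#' @param meta A `sample_metadata` data frame.
#' @param cohort Cohort identifier resolving case and control samples.
#' @param min_mean_reads Per-group mean read threshold (strict `>`),
#'   default 50.
#' @param universe_fraction Overall read-fraction threshold (strict `>`),
#'   default `1e-4` (0.01% of reads).
#' @return Character vector of retained species names.
#' @export
filter_species <- function(x, meta, cohort, min_mean_reads = 50,
                           universe_fraction = 1e-4) {
  stopifnot(inherits(x, "count_table"))
  grp <- .cohort_samples(meta, cohort)
  in_universe <- colSums(x$counts) / sum(x$total_reads) > universe_fraction
  mean_case <- colMeans(x$counts[grp$cases, , drop = FALSE])
  mean_ctrl <- colMeans(x$counts[grp$controls, , drop = FALSE])
  keep <- in_universe & (mean_case > min_mean_reads | mean_ctrl > min_mean_reads)
  x$species_names[keep]
}

#' Select directed marker species for one cohort comparison
#'
#' For every species passing [filter_species()], tests case versus matched
#' control relative abundances with a two-sided Mann-Whitney U test,
#' adjusts p-values by Benjamini-Hochberg across the filtered species of
#' this cohort, and assigns significant species (`q < alpha`) to the
#' control-associated set `H` (mean relative abundance higher in controls,
#' i.e. under-represented in cases) or the case-associated set `C`.
#' A significant species with exactly equal group means is directionless
#' and dropped with a message.
#'
#' @inheritParams filter_species
#' @param alpha FDR threshold for membership, default 0.05.
#' @return Object of class `marker_sets`: list with `control_associated`,
#'   `case_associated`, `per_species_stats` (data frame), `alpha`, `cohort`.
#' @export
derive_marker_sets <- function(x, meta, cohort, alpha = 0.05,
                               min_mean_reads = 50, universe_fraction = 1e-4) {
  species <- filter_species(x, meta, cohort, min_mean_reads, universe_fraction)
  if (length(species) == 0) stop("no species pass the abundance filters")
  grp <- .cohort_samples(meta, cohort)
  ra <- relative_abundance(x)
  ra_case <- ra[grp$cases, species, drop = FALSE]
  ra_ctrl <- ra[grp$controls, species, drop = FALSE]

  U <- p <- numeric(length(species))
  for (i in seq_along(species)) {
    res <- mann_whitney(ra_case[, i], ra_ctrl[, i])
    U[i] <- res$U
    p[i] <- res$p
  }
  q <- bh_adjust(p)
  mean_case <- colMeans(ra_case)
  mean_ctrl <- colMeans(ra_ctrl)
  direction <- ifelse(mean_ctrl > mean_case, "control_associated",
                      ifelse(mean_case > mean_ctrl, "case_associated", "none"))
  sig <- q < alpha
  tied <- sig & direction == "none"
  if (any(tied)) {
    message(sprintf("dropped %d significant but directionless species (equal means)",
                    sum(tied)))
  }
  stats_df <- data.frame(
    species = species, U = U, p = p, q = q, direction = direction,
    mean_relabund_case = mean_case, mean_relabund_control = mean_ctrl,
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(
    control_associated = species[sig & direction == "control_associated"],
    case_associated = species[sig & direction == "case_associated"],
    per_species_stats = stats_df,
    alpha = alpha,
    cohort = cohort
  ), class = "marker_sets")
}

#' @export
print.marker_sets <- function(x, ...) {
  cat(sprintf(
    "marker_sets [%s]: %d control-associated (H), %d case-associated (C) of %d tested (q < %g)\n",
    x$cohort, length(x$control_associated), length(x$case_associated),
    nrow(x$per_species_stats), x$alpha))
  invisible(x)
}

#' Write marker statistics as TSV
#'
#' @param x A `marker_sets` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_marker_sets <- function(x, path) {
  stopifnot(inherits(x, "marker_sets"))
  df <- x$per_species_stats
  df$marker <- ifelse(df$species %in% x$control_associated, "H",
                      ifelse(df$species %in% x$case_associated, "C", ""))
  .write_tsv(df, path, sprintf("markers cohort=%s alpha=%g", x$cohort, x$alpha))
  invisible(path)
}
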