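# Taxa-metabolite Spearman correlation matrix over the pooled samples,
# with Ward clustering of taxa (and metabolites) into correlation modules.

#' Abundance/prevalence filter ahead of correlation analysis
#'
#' Retains taxa with a mean read count strictly above `min_mean_reads`
#' and detected (count > 0) in at least `min_prevalence` of samples.
#'
#' @param x A `count_table`.
#' @param min_mean_reads Mean read threshold (strict `>`), default 1000.
#' @param min_prevalence Detection-fraction threshold (`>=`), default 0.10.
#' @return Character vector of retained species names.
#' @export
filter_taxa_for_association <- function(x, min_mean_reads = 1000,
                                        min_prevalence = 0.10) {
  stopifnot(inherits(x, "count_table"))
  keep <- colMeans(x$counts) > min_mean_reads &
    colMeans(x$counts > 0) >= min_prevalence
  x$species_names[keep]
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks, computed by [stats::cor()]. A
#' zero-variance input has no defined rank correlation and errors; the
#' matrix-level wrapper flags and excludes such pairs instead.
#'
#' @param x,y Numeric vectors of equal length, at least 3.
#' @return Correlation in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("need vectors of equal length >= 3")
  }
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero-variance input: Spearman correlation undefined")
  }
  stats::cor(x, y, method = "spearman")
}

#' Taxa-metabolite Spearman correlation matrix
#'
#' Correlates relative abundances of filtered taxa with metabolite
#' concentrations over the samples shared by both tables (by design the
#' pooled healthy controls plus case-mixed patients). Pairs involving a
#' zero-variance vector are set to `NA` with a message.
#'
#' @param x A `count_table`.
#' @param tbl A `metabolite_table`.
#' @param min_mean_reads,min_prevalence Passed to
#'   [filter_taxa_for_association()].
#' @return Object of class `association_result`: `taxa_kept`, `corr`
#'   (taxa x metabolites Spearman matrix), and after clustering also
#'   module assignments (see [cluster_correlations()]).
#' @export
associate_taxa_metabolites <- function(x, tbl, min_mean_reads = 1000,
                                       min_prevalence = 0.10) {
  stopifnot(inherits(x, "count_table"), inherits(tbl, "metabolite_table"))
  ids <- intersect(x$sample_ids, tbl$sample_ids)
  if (length(ids) < 3) stop("fewer than 3 samples shared by the two tables")
  taxa <- filter_taxa_for_association(subset_samples(x, ids),
                                      min_mean_reads, min_prevalence)
  if (length(taxa) == 0) stop("no taxa pass the association filters")
  ra <- relative_abundance(subset_samples(x, ids))[, taxa, drop = FALSE]
  conc <- tbl$concentrations[ids, , drop = FALSE]
  corr <- matrix(NA_real_, length(taxa), ncol(conc),
                 dimnames = list(taxa, colnames(conc)))
  n_undef <- 0
  for (i in seq_along(taxa)) {
    xi <- ra[, i]
    for (j in seq_len(ncol(conc))) {
      yj <- conc[, j]
      ok <- !is.na(yj)
      if (sum(ok) < 3 || stats::sd(xi[ok]) == 0 || stats::sd(yj[ok]) == 0) {
        n_undef <- n_undef + 1
      } else {
        corr[i, j] <- stats::cor(xi[ok], yj[ok], method = "spearman")
      }
    }
  }
  if (n_undef > 0) {
    message(sprintf("%d correlation(s) undefined (zero variance) and set to NA", n_undef))
  }
  structure(list(taxa_kept = taxa, corr = corr, n_samples = length(ids)),
            class = "association_result")
}

#' Ward clustering of the correlation matrix into modules
#'
#' Taxa are clustered on the distance `1 - r` between their metabolite
#' correlation profiles (rows), metabolites on their taxa profiles
#' (columns), both with Ward linkage (`ward.D2`) cut at a fixed number
#' of clusters. Deterministic given the input.
#'
#' @param corr Finite taxa x metabolites correlation matrix (or an
#'   `association_result`).
#' @param k_taxa Number of taxa modules, default 5.
#' @param k_metab Number of metabolite clusters, default 2.
#' @return List with `taxa_modules` and `metabolite_clusters`, named
#'   integer cluster assignments.
#' @export
cluster_correlations <- function(corr, k_taxa = 5, k_metab = 2) {
  if (inherits(corr, "association_result")) corr <- corr$corr
  stopifnot(is.matrix(corr))
  if (anyNA(corr)) stop("correlation matrix must be finite (drop NA rows first)")
  if (k_taxa > nrow(corr)) stop("k_taxa exceeds the number of taxa")
  if (k_metab > ncol(corr)) stop("k_metab exceeds the number of metabolites")
  profile_dist <- function(m) {
    r <- suppressWarnings(stats::cor(t(m)))
    r[!is.finite(r)] <- 0
    diag(r) <- 1
    stats::as.dist(1 - r)
  }
  taxa_modules <- stats::cutree(
    stats::hclust(profile_dist(corr), method = "ward.D2"), k = k_taxa)
  metabolite_clusters <- stats::cutree(
    stats::hclust(profile_dist(t(corr)), method = "ward.D2"), k = k_metab)
  list(taxa_modules = taxa_modules, metabolite_clusters = metabolite_clusters)
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("association_result: %d taxa x %d metabolites over %d samples\n",
              nrow(x$corr), ncol(x$corr), x$n_samples))
  invisible(x)
}
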