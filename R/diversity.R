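# Alpha diversity (Shannon) and compositional beta diversity:
# CLR embedding, PCA, and PERMANOVA on Aitchison distances.

#' Shannon diversity of one sample
#'
#' `H = -sum p_i log p_i` in nats over species with positive counts,
#' where `p_i` is the count fraction. Invariant to rescaling of counts.
#'
#' @param counts Non-negative numeric vector with at least one positive
#'   entry.
#' @return Shannon index in nats, in `[0, log(n_species)]`.
#' @export
shannon_index <- function(counts) {
  if (anyNA(counts) || any(counts < 0)) stop("counts must be non-negative")
  total <- sum(counts)
  if (total == 0) stop("all-zero sample has undefined diversity")
  p <- counts[counts > 0] / total
  -sum(p * log(p))
}

#' Compare alpha diversity between a cohort's cases and controls
#'
#' Shannon indices are computed per sample and compared with a two-sided
#' Mann-Whitney U test ([mann_whitney()]).
#'
#' @inheritParams filter_species
#' @return List with per-sample Shannon values (`shannon_case`,
#'   `shannon_control`), `U`, `p`, and `direction` of the median
#'   difference (`"lower_in_cases"`, `"higher_in_cases"`, `"none"`).
#' @export
compare_alpha <- function(x, meta, cohort) {
  stopifnot(inherits(x, "count_table"))
  grp <- .cohort_samples(meta, cohort)
  if (length(grp$cases) < 2 || length(grp$controls) < 2) {
    stop("need at least 2 case and 2 control samples")
  }
  h_case <- apply(x$counts[grp$cases, , drop = FALSE], 1, shannon_index)
  h_ctrl <- apply(x$counts[grp$controls, , drop = FALSE], 1, shannon_index)
  res <- mann_whitney(h_case, h_ctrl)
  d <- stats::median(h_case) - stats::median(h_ctrl)
  list(shannon_case = h_case, shannon_control = h_ctrl,
       U = res$U, p = res$p,
       direction = if (d < 0) "lower_in_cases" else if (d > 0) "higher_in_cases" else "none")
}

#' Alpha-diversity tests across several cohorts with BH adjustment
#'
#' @param x A `count_table`.
#' @param meta A `sample_metadata` data frame.
#' @param cohorts Cohort identifiers; default all case cohorts in `meta`.
#' @return Data frame with one row per cohort: `cohort`, `U`, `p`, `q`,
#'   `direction`.
#' @export
compare_alpha_all <- function(x, meta,
                              cohorts = unique(meta$cohort[meta$group != "HC"])) {
  rows <- lapply(cohorts, function(ch) {
    r <- compare_alpha(x, meta, ch)
    data.frame(cohort = ch, U = r$U, p = r$p, direction = r$direction,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out[, c("cohort", "U", "p", "q", "direction")]
}

#' Centered log-ratio transform
#'
#' Per sample, `clr_i = log((x_i + pseudocount) / g)` with `g` the
#' geometric mean of the shifted entries; every output row sums to zero.
#' Accepts a `count_table` or a plain numeric matrix (e.g. proportions).
#'
#' @param x A `count_table` or samples x species numeric matrix.
#' @param pseudocount Positive shift applied before taking logs,
#'   default 0.5 (half a read).
#' @return Samples x species real matrix of CLR coordinates.
#' @export
clr_transform <- function(x, pseudocount = 0.5) {
  if (inherits(x, "count_table")) x <- x$counts
  stopifnot(is.matrix(x), pseudocount > 0)
  lx <- log(x + pseudocount)
  lx - rowMeans(lx)
}

#' PCA of a CLR matrix
#'
#' Centered principal component analysis; component signs are fixed by
#' making each component's largest-magnitude loading positive, so results
#' are fully deterministic.
#'
#' @param m Samples x species real matrix (typically CLR coordinates).
#' @param k Number of components to keep.
#' @return List with `scores` (samples x k), `variance_explained`
#'   (length-k fractions, non-increasing) and `loadings`.
#' @export
pca_beta <- function(m, k = 2) {
  stopifnot(is.matrix(m))
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  rank <- sum(pc$sdev > max(pc$sdev) * 1e-10)
  if (k > rank) stop(sprintf("k = %d exceeds matrix rank %d", k, rank))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  loadings <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    s <- sign(loadings[which.max(abs(loadings[, j])), j])
    if (s < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = scores, variance_explained = ve[seq_len(k)], loadings = loadings)
}

#' Aitchison distances between samples
#'
#' Euclidean distances on CLR coordinates.
#'
#' @inheritParams clr_transform
#' @return A `dist` object over samples.
#' @export
aitchison_dist <- function(x, pseudocount = 0.5) {
  stats::dist(clr_transform(x, pseudocount))
}

#' Two-group PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance via
#' [vegan::adonis2()], with a recorded seed so the permutation p-value
#' `p = (1 + #permuted F >= observed F) / (1 + n_perm)` is reproducible.
#'
#' @param d A `dist` or symmetric zero-diagonal distance matrix.
#' @param labels Group label per sample (at least two groups).
#' @param n_perm Number of permutations, default 999.
#' @param seed Integer RNG seed for the permutations.
#' @return List with `pseudo_F`, `p`, `n_permutations`, `seed`.
#' @export
permanova <- function(d, labels, n_perm = 999, seed = 1) {
  if (!inherits(d, "dist")) {
    d <- as.matrix(d)
    if (!isSymmetric(unname(d)) || any(abs(diag(d)) > 1e-12)) {
      stop("distance matrix must be symmetric with zero diagonal")
    }
    d <- stats::as.dist(d)
  }
  labels <- as.factor(labels)
  if (length(labels) != attr(d, "Size")) stop("labels must match distance size")
  if (nlevels(droplevels(labels)) < 2) stop("need at least two groups")
  fit <- withr::with_seed(seed,
    vegan::adonis2(d ~ labels, permutations = n_perm)
  )
  list(pseudo_F = fit$F[1], p = fit$`Pr(>F)`[1],
       n_permutations = n_perm, seed = seed)
}

#' Full diversity comparison for one cohort
#'
#' Bundles Shannon alpha diversity, CLR-PCA ordination and PERMANOVA on
#' Aitchison distances for a case/matched-control comparison.
#'
#' @inheritParams compare_alpha
#' @param k Number of PCA components.
#' @param n_perm,seed Passed to [permanova()].
#' @param pseudocount Passed to [clr_transform()].
#' @return Object of class `diversity_result`.
#' @export
diversity_analysis <- function(x, meta, cohort, k = 2, n_perm = 999,
                               seed = 1, pseudocount = 0.5) {
  grp <- .cohort_samples(meta, cohort)
  ids <- c(grp$cases, grp$controls)
  sub <- subset_samples(x, ids)
  labels <- ifelse(ids %in% grp$cases, "case", "control")
  alpha <- compare_alpha(x, meta, cohort)
  clr <- clr_transform(sub, pseudocount)
  pca <- pca_beta(clr, k = k)
  perm <- permanova(stats::dist(clr), labels, n_perm = n_perm, seed = seed)
  structure(list(
    cohort = cohort,
    per_sample_shannon = c(alpha$shannon_case, alpha$shannon_control),
    group_test = list(U = alpha$U, p = alpha$p, direction = alpha$direction),
    pca_scores = pca$scores,
    variance_explained = pca$variance_explained,
    permanova = perm
  ), class = "diversity_result")
}

#' @export
print.diversity_result <- function(x, ...) {
  cat(sprintf("diversity_result [%s]: Shannon MW p = %.3g (%s); PERMANOVA F = %.2f, p = %.3g\n",
              x$cohort, x$group_test$p, x$group_test$direction,
              x$permanova$pseudo_F, x$permanova$p))
  invisible(x)
}
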