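# Small in-code fixtures shared across test files.

# A deterministic little count table: n_case + n_ctrl samples x species.
make_cohort_fixture <- function(n_case = 4, n_ctrl = 4, counts_case, counts_ctrl,
                                species = NULL, cohort = "CRC") {
  if (is.null(species)) species <- sprintf("sp%02d", seq_len(ncol(counts_case)))
  ids <- c(sprintf("case%02d", seq_len(n_case)), sprintf("hc%02d", seq_len(n_ctrl)))
  m <- rbind(counts_case, counts_ctrl)
  dimnames(m) <- list(ids, species)
  meta <- sample_metadata(data.frame(
    sample_id = ids,
    group = c(rep(cohort, n_case), rep("HC", n_ctrl)),
    cohort = cohort,
    sex = rep(c("F", "M"), length.out = n_case + n_ctrl),
    age = 50 + seq_len(n_case + n_ctrl),
    stringsAsFactors = FALSE
  ))
  list(counts = count_table(m), meta = meta)
}

# Write a Bracken species report; rows is a data.frame(name, reads) plus
# optional taxonomy_lvl per row.
write_bracken_fixture <- function(path, name, reads, lvl = rep("S", length(name)),
                                  drop_col = NULL) {
  df <- data.frame(
    name = name, taxonomy_id = seq_along(name) + 1000, taxonomy_lvl = lvl,
    kraken_assigned_reads = reads, added_reads = 0L, new_est_reads = reads,
    fraction_total_reads = reads / sum(reads),
    stringsAsFactors = FALSE
  )
  if (!is.null(drop_col)) df[[drop_col]] <- NULL
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# A valid 16-column metabolite matrix with given sample ids.
make_metab_fixture <- function(ids, base = 100) {
  m <- matrix(base + seq_len(length(ids) * 16) %% 7, nrow = length(ids),
              dimnames = list(ids, metabolite_names()))
  m
}

# Exact two-sided Mann-Whitney p by exhaustive enumeration of rank splits
# (independent oracle; only the ranks matter for tie-free data).
enum_mw_p <- function(x, y) {
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  splits <- utils::combn(m + n, m)
  u_all <- colSums(matrix(seq_len(m + n)[splits], nrow = m)) - m * (m + 1) / 2
  p_low <- mean(u_all <= u_obs)
  p_high <- mean(u_all >= u_obs)
  min(1, 2 * min(p_low, p_high))
}

# Hand step-up BH (independent of stats::p.adjust).
step_up_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  q
}

# Pairwise-concordance AUC (independent oracle).
brute_auc <- function(pos, neg) {
  s <- 0
  for (p in pos) for (n in neg) s <- s + (p > n) + 0.5 * (p == n)
  s / (length(pos) * length(neg))
}
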