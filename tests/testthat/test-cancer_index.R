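test_that("the index matches its closed forms", {
  mk <- list(control_associated = c("h1", "h2"), case_associated = c("c1", "c2"))
  par <- index_params(detection_threshold = 1e-5, epsilon = 0.01)
  all_h <- c(h1 = 1e-3, h2 = 1e-3, c1 = 0, c2 = 0)
  expect_equal(compute_index(all_h, mk, par), log2(1.01 / 0.01), tolerance = 1e-12)
  balanced <- c(h1 = 1e-3, h2 = 0, c1 = 1e-3, c2 = 0) # f_H = f_C = 0.5
  expect_equal(compute_index(balanced, mk, par), 0)
  mk2 <- list(control_associated = c("h1", "h2"),
              case_associated = c("c1", "c2", "c3", "c4"))
  ab <- c(h1 = 1e-3, h2 = 0, c1 = 1e-3, c2 = 0, c3 = 0, c4 = 0)
  expect_equal(compute_index(ab, mk2, par), log2(0.51 / 0.26), tolerance = 1e-12)
  expect_error(compute_index(ab, list(control_associated = character(0),
                                      case_associated = character(0))),
               "empty")
})

test_that("the index is antisymmetric under H-C swap and monotone in markers", {
  set.seed(11)
  par <- index_params()
  for (rep in 1:50) {
    nH <- sample(1:10, 1); nC <- sample(1:10, 1)
    sp <- paste0("s", seq_len(nH + nC + 5))
    mk <- list(control_associated = sp[seq_len(nH)],
               case_associated = sp[nH + seq_len(nC)])
    ab <- setNames(ifelse(runif(length(sp)) < 0.5, 0, 1e-3), sp)
    swap <- list(control_associated = mk$case_associated,
                 case_associated = mk$control_associated)
    expect_equal(compute_index(ab, mk, par), -compute_index(ab, swap, par),
                 tolerance = 1e-12)
    # adding a detected H marker never lowers the index
    ab2 <- c(ab, extraH = 1e-3)
    mk_plus <- mk; mk_plus$control_associated <- c(mk$control_associated, "extraH")
    expect_gte(compute_index(ab2, mk_plus, par), compute_index(ab, mk, par) - 1e-12)
    # adding a detected C marker never raises it
    mk_minus <- mk; mk_minus$case_associated <- c(mk$case_associated, "extraH")
    expect_lte(compute_index(ab2, mk_minus, par), compute_index(ab, mk, par) + 1e-12)
  }
})

test_that("the index is depth-invariant when thresholds are proportions", {
  mk <- list(control_associated = c("a", "b"), case_associated = "c")
  ab <- c(a = 2e-5, b = 5e-6, c = 1e-4)
  # proportions are unchanged by sequencing depth, so the index is too
  expect_equal(compute_index(ab, mk), compute_index(ab, mk))
  counts <- c(a = 20, b = 5, c = 100)
  p1 <- counts / sum(counts)
  p2 <- (counts * 17) / sum(counts * 17)
  expect_identical(compute_index(p1, mk), compute_index(p2, mk))
})

test_that("rank AUC matches brute-force concordance", {
  expect_equal(auc_rank(c(0.9, 0.8), c(0.7, 0.1)), 1)
  expect_equal(auc_rank(c(3, 1), c(2, 0)), 0.75)
  expect_equal(auc_rank(c(1, 2, 3), c(1, 2, 3)), 0.5)
  set.seed(12)
  for (rep in 1:20) {
    pos <- sample(10, sample(2:6, 1), replace = TRUE)
    neg <- sample(10, sample(2:6, 1), replace = TRUE)
    expect_equal(auc_rank(pos, neg), brute_auc(pos, neg), tolerance = 1e-12)
  }
  # complement identity used for label inversion
  pos <- c(0.2, 0.5, 0.9); neg <- c(0.1, 0.6)
  expect_equal(auc_rank(neg, pos), 1 - auc_rank(pos, neg), tolerance = 1e-12)
  expect_error(auc_rank(numeric(0), 1), "non-empty")
})

test_that("cross-validated evaluation is seeded, honest and labelled", {
  sim <- generate_cohort(scenario_presets("strong_dysbiosis", seed = 41))
  r1 <- evaluate_index(sim$counts, sim$metadata, "CRC", seed = 5)
  r2 <- evaluate_index(sim$counts, sim$metadata, "CRC", seed = 5)
  expect_identical(r1$per_sample_index, r2$per_sample_index)
  expect_true(r1$auc >= 0 && r1$auc <= 1)
  expect_true(all(is.finite(r1$per_sample_index)))
  expect_match(r1$cv_scheme, "5-fold")
  rin <- evaluate_index(sim$counts, sim$metadata, "CRC", mode = "in_sample")
  expect_match(rin$cv_scheme, "in_sample")
  # in this separable scenario both modes separate strongly
  expect_gt(rin$auc, 0.9)
  expect_gt(r1$auc, 0.9)
  # inverted scoring: AUC complements
  expect_equal(auc_rank(r1$per_sample_index[sim$metadata$sample_id[sim$metadata$group != "HC"]],
                        r1$per_sample_index[sim$metadata$sample_id[sim$metadata$group == "HC"]]),
               1 - r1$auc, tolerance = 1e-12)
})

test_that("fold construction rejects classes smaller than k", {
  sim <- generate_cohort(cohort_config(n_cases = 3, n_controls = 8, seed = 6))
  expect_error(evaluate_index(sim$counts, sim$metadata, "CRC", k_folds = 5),
               "fewer folds")
})
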