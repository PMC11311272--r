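test_that("Shannon index matches closed forms and is scale-invariant", {
  expect_equal(shannon_index(c(10, 10, 10, 10)), log(4), tolerance = 1e-12)
  expect_equal(shannon_index(c(42, 0, 0)), 0)
  expect_equal(shannon_index(c(1, 2, 3)),
               -(1/6 * log(1/6) + 1/3 * log(1/3) + 1/2 * log(1/2)),
               tolerance = 1e-12)
  expect_equal(shannon_index(c(1, 2, 3)), shannon_index(c(10, 20, 30)))
  expect_error(shannon_index(c(0, 0)), "all-zero")
  # agrees with the community-standard implementation
  set.seed(1)
  x <- rpois(50, 20)
  expect_equal(shannon_index(x), unname(vegan::diversity(x, "shannon")),
               tolerance = 1e-12)
})

test_that("alpha comparison reports direction and needs non-degenerate groups", {
  set.seed(7)
  fx <- make_cohort_fixture(
    4, 4,
    counts_case = matrix(rpois(24, c(100, 5, 5, 1, 1, 1)), 4, 6, byrow = TRUE),
    counts_ctrl = matrix(rpois(24, 20), 4, 6)
  )
  r <- compare_alpha(fx$counts, fx$meta, "CRC")
  expect_true(r$p >= 0 && r$p <= 1)
  expect_true(r$direction %in% c("lower_in_cases", "higher_in_cases", "none"))
  meta1 <- fx$meta[-(1:3), , drop = FALSE]
  expect_error(compare_alpha(subset_samples(fx$counts, meta1$sample_id),
                             sample_metadata(as.data.frame(meta1)), "CRC"),
               "at least 2")
})

test_that("alpha tests across cohorts carry a BH-adjusted column", {
  sim <- generate_study(scenario_presets("null", seed = 13),
                        groups = c("CRC", "breast"))
  out <- compare_alpha_all(sim$counts, sim$metadata)
  expect_setequal(out$cohort, c("CRC", "breast"))
  expect_true(all(out$q >= out$p))
})

test_that("CLR rows sum to zero and match the closed form", {
  m <- matrix(c(5, 5, 5, 1, 2, 3), 2, 3, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("a", "b", "c")))
  clr <- clr_transform(m, pseudocount = 0.5)
  expect_equal(unname(clr[1, ]), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(unname(rowSums(clr)), c(0, 0), tolerance = 1e-9)
  # proportions (0.25, 0.75) in the vanishing-pseudocount limit
  p <- matrix(c(0.25, 0.75), 1, 2, dimnames = list("s", c("a", "b")))
  clr0 <- clr_transform(p, pseudocount = 1e-12)
  expect_equal(unname(clr0[1, ]), c(-0.5493061, 0.5493061), tolerance = 1e-4)
  expect_error(clr_transform(p, pseudocount = 0))
})

test_that("PCA is deterministic, ordered, and respects rank", {
  set.seed(42)
  m <- matrix(rnorm(60), 10, 6)
  r <- pca_beta(m, k = 3)
  expect_true(all(diff(r$variance_explained) <= 1e-12))
  expect_lte(sum(r$variance_explained), 1 + 1e-12)
  # duplicated sample set: pairs score identically
  r2 <- pca_beta(rbind(m, m), k = 2)
  expect_equal(unname(r2$scores[1:10, ]), unname(r2$scores[11:20, ]),
               tolerance = 1e-9)
  # two distinct samples span one dimension
  two <- matrix(c(1, 2, 3, 4, 6, 8), 2, 3, byrow = TRUE)
  r1 <- pca_beta(two, k = 1)
  expect_equal(r1$variance_explained[1], 1, tolerance = 1e-12)
  expect_error(pca_beta(two, k = 2), "rank")
  # sign convention: largest-magnitude loading positive
  expect_true(all(apply(r$loadings, 2, function(v) v[which.max(abs(v))] > 0)))
})

test_that("PERMANOVA behaves at the extremes and validates input", {
  set.seed(5)
  cloud1 <- matrix(rnorm(20, 0), 10, 2)
  cloud2 <- matrix(rnorm(20, 50), 10, 2)
  d <- dist(rbind(cloud1, cloud2))
  lab <- rep(c("a", "b"), each = 10)
  r <- permanova(d, lab, n_perm = 99, seed = 1)
  expect_equal(r$p, 1 / 100)
  expect_gte(r$p, 1 / (r$n_permutations + 1))
  expect_error(permanova(d, rep("a", 20), n_perm = 99), "two groups")
  bad <- matrix(1, 3, 3)
  expect_error(permanova(bad, c("a", "a", "b")), "zero diagonal")
  # seeded: reproducible p
  r2 <- permanova(d, lab, n_perm = 99, seed = 1)
  expect_identical(r$p, r2$p)
})

test_that("Aitchison distance is invariant to uniform depth rescaling of proportions", {
  set.seed(3)
  p <- matrix(rgamma(30, 2), 5, 6)
  p <- p / rowSums(p)
  d1 <- as.matrix(stats::dist(clr_transform(p, 1e-12)))
  d2 <- as.matrix(stats::dist(clr_transform(p * 1e6, 1e-12)))
  expect_equal(d1, d2, tolerance = 1e-6)
})

test_that("diversity_analysis bundles the cohort comparison", {
  sim <- generate_cohort(scenario_presets("strong_dysbiosis", seed = 21))
  r <- diversity_analysis(sim$counts, sim$metadata, "CRC", n_perm = 99, seed = 4)
  expect_s3_class(r, "diversity_result")
  expect_length(r$per_sample_shannon, 80)
  expect_true(all(r$per_sample_shannon >= 0 &
                    r$per_sample_shannon <= log(length(sim$counts$species_names))))
  expect_true(all(diff(r$variance_explained) <= 1e-12))
  expect_lt(r$permanova$p, 0.05) # strongly separated groups
})
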