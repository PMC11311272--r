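# Seeded synthetic case/control cohorts: Dirichlet-multinomial species
# counts with planted depleted/enriched marker species, matched metadata,
# and log-normal metabolite panels with planted case shifts.

#' Study design of the seven case-control comparisons
#'
#' Per-group case sample sizes, sex split and age ranges used as the
#' matched-cohort template by the simulators (controls mirror the case
#' structure).
#'
#' @return Data frame with one row per group and sex.
#' @export
study_design <- function() {
  data.frame(
    group = rep(c("CRC", "stomach", "breast", "lung", "melanoma",
                  "lymphoid", "AML"), times = c(2, 2, 1, 2, 2, 2, 2)),
    sex = c("F", "M", "F", "M", "F", "F", "M", "F", "M", "F", "M", "F", "M"),
    n = c(20, 20, 15, 30, 71, 17, 17, 23, 27, 35, 25, 26, 14),
    age_min = c(36, 35, 37, 40, 30, 54, 35, 48, 34, 22, 31, 20, 23),
    age_max = c(82, 82, 78, 87, 79, 81, 85, 84, 88, 78, 74, 68, 74),
    stringsAsFactors = FALSE
  )
}

# Default log-normal location (ug per g stool) per metabolite; SCFAs on
# the mg/g scale typical of stool, amino acids lower.
.metabolite_baseline <- function() {
  c(acetic = 3000, butanoic = 1000, formic = 60, hexanoic = 50,
    isobutyric = 150, pentanoic = 200, propanoic = 1200,
    Ala = 150, Gly = 120, Glu = 200, Ile = 60, Leu = 90, Met = 25,
    Phe = 60, Pro = 90, Val = 80)
}

#' Configuration of a synthetic cohort
#'
#' @param n_cases,n_controls Group sizes.
#' @param n_species Size of the species universe, default 260.
#' @param depth_mean Mean sequencing depth (reads per sample, Poisson),
#'   default 100,000 — a desk-scale stand-in for production depths.
#' @param n_depleted,n_enriched Numbers of planted control-associated
#'   (depleted in cases) and case-associated (enriched in cases) species.
#' @param effect_fold Multiplicative abundance shift applied to planted
#'   species in cases (must exceed 1).
#' @param base_concentration Dirichlet concentration mass controlling
#'   sample-to-sample overdispersion; default 50, in the range of
#'   Dirichlet-multinomial fits to stool metagenomes (lower = noisier).
#' @param formic_shift Multiplicative case shift of formic acid, default 1.
#' @param metabolite_sdlog Log-scale SD of metabolite concentrations,
#'   default 0.6.
#' @param baseline_sdlog Log-scale SD of the heavy-tailed baseline
#'   species profile, default 1.8, at which the ten most abundant of 260
#'   species carry close to half of all reads.
#' @param seed Integer RNG seed.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n_cases = 40, n_controls = 40, n_species = 260,
                          depth_mean = 1e5, n_depleted = 30, n_enriched = 8,
                          effect_fold = 4, base_concentration = 50,
                          formic_shift = 1, metabolite_sdlog = 0.6,
                          baseline_sdlog = 1.8, seed = 1) {
  cfg <- list(n_cases = n_cases, n_controls = n_controls,
              n_species = n_species, depth_mean = depth_mean,
              n_depleted = n_depleted, n_enriched = n_enriched,
              effect_fold = effect_fold,
              base_concentration = base_concentration,
              formic_shift = formic_shift,
              metabolite_sdlog = metabolite_sdlog,
              baseline_sdlog = baseline_sdlog, seed = seed)
  if (cfg$n_depleted + cfg$n_enriched > cfg$n_species) {
    stop("n_depleted + n_enriched exceeds n_species")
  }
  if (cfg$effect_fold <= 1) stop("effect_fold must exceed 1")
  if (cfg$depth_mean <= 0) stop("depth_mean must be positive")
  if (cfg$n_cases < 1 || cfg$n_controls < 1) stop("need at least one sample per group")
  structure(cfg, class = "cohort_config")
}

#' Named scenario presets
#'
#' `"null"`: no planted species effects, no metabolite shift (20/20
#' samples) — the error-control scenario. `"paper_like"`: planted
#' depleted and enriched species in the 179:24 ratio of the study-wide
#' marker split, scaled to the species universe by `n_species / 1030`
#' (1030 = the approximate number of species entering the per-cohort
#' tests study-wide), with a modest 2-fold effect. `"strong_dysbiosis"`:
#' 4-fold effects at 40/40 for power and ceiling tests.
#'
#' @param name One of `"null"`, `"paper_like"`, `"strong_dysbiosis"`.
#' @param n_species Species universe size, default 260.
#' @param seed Integer RNG seed stored in the config.
#' @return A [cohort_config()].
#' @export
scenario_presets <- function(name = c("null", "paper_like", "strong_dysbiosis"),
                             n_species = 260, seed = 1) {
  name <- match.arg(name)
  switch(name,
    null = cohort_config(n_cases = 20, n_controls = 20, n_species = n_species,
                         n_depleted = 0, n_enriched = 0, effect_fold = 2,
                         formic_shift = 1, seed = seed),
    paper_like = {
      scale <- n_species / 1030
      cohort_config(n_cases = 40, n_controls = 40, n_species = n_species,
                    n_depleted = round(179 * scale),
                    n_enriched = round(24 * scale),
                    effect_fold = 2, formic_shift = 2, seed = seed)
    },
    strong_dysbiosis = cohort_config(n_cases = 40, n_controls = 40,
                                     n_species = n_species,
                                     n_depleted = 30, n_enriched = 8,
                                     effect_fold = 4, formic_shift = 2,
                                     seed = seed)
  )
}

# One Dirichlet draw per row of alpha.
.rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha), nrow = n,
              byrow = TRUE)
  g / rowSums(g)
}

# Heavy-tailed baseline species profile, sorted so rank = abundance order.
.baseline_profile <- function(n_species, sdlog) {
  w <- sort(stats::rlnorm(n_species, meanlog = 0, sdlog = sdlog),
            decreasing = TRUE)
  w / sum(w)
}

# Sex/age structure for one group, matched between cases and controls.
.group_demographics <- function(group, n, prefix) {
  des <- study_design()
  des <- des[des$group == group, , drop = FALSE]
  if (nrow(des) == 0) { # fall back to a balanced template
    des <- data.frame(group = group, sex = c("F", "M"), n = c(1, 1),
                      age_min = c(30, 30), age_max = c(80, 80))
  }
  n_f <- round(n * des$n[des$sex == "F"][1] / sum(des$n))
  if (!"F" %in% des$sex) n_f <- 0
  if (!"M" %in% des$sex) n_f <- n
  sex <- c(rep("F", n_f), rep("M", n - n_f))
  age <- numeric(n)
  for (s in c("F", "M")) {
    i <- which(sex == s)
    if (!length(i)) next
    rng <- des[des$sex == s, , drop = FALSE]
    age[i] <- round(stats::runif(length(i), rng$age_min[1], rng$age_max[1]))
  }
  data.frame(sample_id = sprintf("%s%02d", prefix, seq_len(n)),
             sex = sex, age = age, stringsAsFactors = FALSE)
}

#' Generate one seeded synthetic case/control cohort
#'
#' Baseline species proportions are drawn once from a heavy-tailed
#' log-normal profile (a few species dominate); planted depleted species
#' have their proportions divided by `effect_fold` in cases, planted
#' enriched species multiplied, with renormalisation (so depleting many
#' species implicitly enriches the rest, as in real compositions).
#' Per-sample compositions are Dirichlet around the group profile, read
#' counts multinomial at a Poisson depth. Planted species are drawn from
#' the mid-abundance ranks (below the dominant top 10) so they are
#' detectable at the default depth. Metabolites are log-normal with the
#' case shift applied to formic acid. Sex and age are matched in
#' distribution between cases and controls. Identical config and seed
#' give bit-identical output.
#'
#' @param config A [cohort_config()].
#' @param group Case group label, default `"CRC"`.
#' @param cohort Cohort identifier, default the group label.
#' @return List with `counts` (`count_table`), `metadata`
#'   (`sample_metadata`), `metabolites` (`metabolite_table`) and `truth`
#'   (planted `depleted_species`, `enriched_species`,
#'   `metabolite_shifts`).
#' @export
generate_cohort <- function(config = cohort_config(), group = "CRC",
                            cohort = group) {
  stopifnot(inherits(config, "cohort_config"))
  withr::with_seed(config$seed, {
    .generate_cohort_impl(config, group, cohort)
  })
}

.generate_cohort_impl <- function(config, group, cohort,
                                  species_names = NULL, baseline = NULL,
                                  planted = NULL, id_prefix = "") {
  n_sp <- config$n_species
  if (is.null(species_names)) {
    species_names <- sprintf("Species_%03d", seq_len(n_sp))
  }
  if (is.null(baseline)) {
    baseline <- .baseline_profile(n_sp, config$baseline_sdlog)
  }
  if (is.null(planted)) {
    planted <- .plant_species(config, species_names, baseline)
  }
  dep_idx <- match(planted$depleted, species_names)
  enr_idx <- match(planted$enriched, species_names)

  prof_ctrl <- baseline
  prof_case <- baseline
  prof_case[dep_idx] <- prof_case[dep_idx] / config$effect_fold
  prof_case[enr_idx] <- prof_case[enr_idx] * config$effect_fold
  prof_case <- prof_case / sum(prof_case)

  demo_case <- .group_demographics(group, config$n_cases,
                                   paste0(id_prefix, group, "_case_"))
  demo_ctrl <- .group_demographics(group, config$n_controls,
                                   paste0(id_prefix, group, "_hc_"))
  ids <- c(demo_case$sample_id, demo_ctrl$sample_id)
  n_all <- length(ids)

  comp <- rbind(
    .rdirichlet(config$n_cases, config$base_concentration * prof_case),
    .rdirichlet(config$n_controls, config$base_concentration * prof_ctrl)
  )
  depth <- stats::rpois(n_all, config$depth_mean)
  depth[depth == 0] <- 1
  counts <- t(vapply(seq_len(n_all),
                     function(i) stats::rmultinom(1, depth[i], comp[i, ])[, 1],
                     integer(n_sp)))
  dimnames(counts) <- list(ids, species_names)
  # multinomial can empty a sample only at degenerate depth; guard anyway
  zero <- rowSums(counts) == 0
  if (any(zero)) counts[zero, 1] <- 1L

  meta <- sample_metadata(data.frame(
    sample_id = ids,
    group = c(rep(group, config$n_cases), rep("HC", config$n_controls)),
    cohort = cohort,
    sex = c(demo_case$sex, demo_ctrl$sex),
    age = c(demo_case$age, demo_ctrl$age),
    timepoint = "pre", stringsAsFactors = FALSE
  ))

  shifts <- if (config$formic_shift != 1) c(formic = config$formic_shift) else numeric(0)
  base_conc <- .metabolite_baseline()
  conc <- matrix(0, n_all, length(base_conc),
                 dimnames = list(ids, names(base_conc)))
  for (j in seq_along(base_conc)) {
    mu <- rep(log(base_conc[j]), n_all)
    if (names(base_conc)[j] %in% names(shifts)) {
      mu[seq_len(config$n_cases)] <- mu[seq_len(config$n_cases)] +
        log(shifts[[names(base_conc)[j]]])
    }
    conc[, j] <- stats::rlnorm(n_all, meanlog = mu, sdlog = config$metabolite_sdlog)
  }

  list(counts = count_table(counts),
       metadata = meta,
       metabolites = metabolite_table(conc),
       truth = list(depleted_species = planted$depleted,
                    enriched_species = planted$enriched,
                    metabolite_shifts = shifts))
}

# Planted species are mid-abundance taxa: below the dominant top 10 but
# with baseline expected reads at least twice the 50-read marker filter,
# so planted markers are detectable at the configured depth.
.plant_species <- function(config, species_names, baseline) {
  n_plant <- config$n_depleted + config$n_enriched
  if (n_plant == 0) {
    return(list(depleted = character(0), enriched = character(0)))
  }
  floor_prop <- 100 / config$depth_mean
  candidates <- which(seq_along(baseline) > 10 & baseline >= floor_prop)
  if (length(candidates) < n_plant) {
    candidates <- order(baseline, decreasing = TRUE)[-(1:10)][seq_len(n_plant)]
  }
  picked <- sample(candidates, n_plant)
  list(depleted = species_names[picked[seq_len(config$n_depleted)]],
       enriched = species_names[picked[config$n_depleted + seq_len(config$n_enriched)]])
}

#' Generate the full seven-cohort synthetic study
#'
#' One cohort per malignancy group with the sample sizes, sex split and
#' age ranges of [study_design()] (each cohort gets its own matched
#' healthy controls), sharing a single species universe, baseline
#' profile and planted marker sets across cohorts.
#'
#' @param config A [cohort_config()]; its `n_cases`/`n_controls` are
#'   overridden per group by the study design.
#' @param groups Case groups to simulate, default all seven.
#' @return As [generate_cohort()], with all cohorts stacked.
#' @export
generate_study <- function(config = scenario_presets("paper_like"),
                           groups = unique(study_design()$group)) {
  stopifnot(inherits(config, "cohort_config"))
  des <- study_design()
  withr::with_seed(config$seed, {
    species_names <- sprintf("Species_%03d", seq_len(config$n_species))
    baseline <- .baseline_profile(config$n_species, config$baseline_sdlog)
    planted <- .plant_species(config, species_names, baseline)
    parts <- lapply(groups, function(g) {
      n_g <- sum(des$n[des$group == g])
      cfg_g <- config
      cfg_g$n_cases <- n_g
      cfg_g$n_controls <- n_g
      .generate_cohort_impl(cfg_g, g, cohort = g,
                            species_names = species_names,
                            baseline = baseline, planted = planted)
    })
    counts <- do.call(rbind, lapply(parts, function(p) p$counts$counts))
    conc <- do.call(rbind, lapply(parts, function(p) p$metabolites$concentrations))
    meta <- do.call(rbind, lapply(parts, function(p) as.data.frame(p$metadata)))
    list(counts = count_table(counts),
         metadata = sample_metadata(meta),
         metabolites = metabolite_table(conc),
         truth = parts[[1]]$truth)
  })
}
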