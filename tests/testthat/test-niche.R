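make_elev_collection <- function(elev_mm, sites) {
  n <- length(elev_mm)
  am <- do.call(rbind, replicate(n, geno_row(rep("AB", 6)),
                                 simplify = FALSE))
  collection_from_matrix(am, site = sites, elev = elev_mm)
}

test_that("standardization centers every site at median zero", {
  col <- make_elev_collection(c(100L, 200L, 300L), rep("S1", 3))
  std <- standardize_elevations(col)
  expect_equal(std$std_elevation_cm, c(-10, 0, 10))
  # even-n site uses the midpoint median
  col2 <- make_elev_collection(c(100L, 200L, 300L, 400L), rep("S1", 4))
  expect_equal(standardize_elevations(col2)$std_elevation_cm,
               c(-15, -5, 5, 15))
  # single-ramet site
  col3 <- make_elev_collection(5L, "S1")
  expect_equal(standardize_elevations(col3)$std_elevation_cm, 0)
})

test_that("standardization is invariant to per-site translation", {
  set.seed(3)
  for (rep in 1:10) {
    sim <- simulate_community(sim_config(seed = rep, n_sites = 4,
                                         ramets_per_site = c(5L, 12L)))
    col <- sim$collection
    std <- standardize_elevations(col)
    med <- tapply(std$std_elevation_cm, std$site_id, median)
    expect_equal(max(abs(med)), 0)
    shifted <- col
    shift <- ifelse(col$records$site_id == col$records$site_id[1], 5000L, 0L)
    shifted$records$elevation_mm <- col$records$elevation_mm + shift
    expect_equal(standardize_elevations(shifted)$std_elevation_cm,
                 std$std_elevation_cm)
  }
})

test_that("KS statistic matches the exhaustive ECDF oracle and stats::ks.test", {
  expect_warning(same <- ks_compare(1:5, 1:5), "tie")
  expect_equal(same$D, 0)
  expect_equal(same$p_value, 1)
  expect_equal(ks_compare(1:3, 11:13)$D, 1)
  k <- suppressWarnings(ks_compare(c(1, 2, 3), c(2, 3, 4)))
  expect_equal(k$D, oracle_ks_D(c(1, 2, 3), c(2, 3, 4)))
  set.seed(17)
  for (rep in 1:60) {
    x <- round(rnorm(sample(2:12, 1)), 1)
    y <- round(rnorm(sample(2:12, 1), mean = runif(1, -1, 1)), 1)
    mine <- suppressWarnings(ks_compare(x, y))
    expect_equal(mine$D, oracle_ks_D(x, y))
    # symmetry
    expect_equal(suppressWarnings(ks_compare(y, x))$D, mine$D)
    # invariance under a common strictly monotone transform
    expect_equal(suppressWarnings(ks_compare(exp(x), exp(y)))$D, mine$D)
    ref <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
    expect_equal(mine$D, unname(ref$statistic))
    expect_lt(abs(mine$p_value - ref$p.value), 1e-4)
  }
  expect_warning(ks_compare(c(1, 2), c(2, 3)), "tie")
  expect_error(ks_compare(numeric(0), 1:3), "non-empty")
})

test_that("LMM with near-zero random variances matches ordinary least squares", {
  sim <- simulate_community(sim_config(seed = 9, n_sites = 6,
                                       ramets_per_site = 15,
                                       site_sd_cm = 0, genet_sd_cm = 0,
                                       clonality = 1,
                                       genotyping_error_rate = 0,
                                       species_offset_cm = c(PURE_A = -4,
                                                             PURE_B = 0,
                                                             F1 = 4,
                                                             LATER_GEN = 0)))
  cl <- classify_collection(sim$collection, sim$key)
  a <- assign_genets(cl, infer_genets(cl))
  fit <- suppressWarnings(fit_elevation_lmm(a, response = "raw"))
  dat <- data.frame(elev = a$records$elevation_mm / 10,
                    species = factor(a$records$species_call,
                                     levels = c("PURE_B", "PURE_A", "F1")),
                    height = a$records$height_cm)
  dat <- dat[!is.na(dat$species), ]
  ols <- lm(elev ~ species + height, data = dat)
  # species and height effects converge on OLS as the variances vanish
  mixed <- nlme::fixef(fit$model)
  expect_lt(max(abs(mixed[c("speciesPURE_A", "speciesF1")] -
                    coef(ols)[c("speciesPURE_A", "speciesF1")])), 0.5)
  expect_lt(abs(mixed[["height_cm"]] - coef(ols)[["height"]]), 0.05)
  expect_gt(fit$species$F, 0)
  expect_equal(fit$species$num_df, 2)
})

test_that("LMM recovers simulated lineage elevation offsets in adjusted means", {
  sim <- simulate_community(sim_config(seed = 19, n_sites = 10,
                                       ramets_per_site = 20,
                                       resid_sd_cm = 2, genet_sd_cm = 1,
                                       species_offset_cm = c(PURE_A = -6,
                                                             PURE_B = 0,
                                                             F1 = 6,
                                                             LATER_GEN = 0)))
  cl <- classify_collection(sim$collection, sim$key)
  a <- assign_genets(cl, infer_genets(cl))
  fit <- fit_elevation_lmm(a)
  m <- fit$adjusted_means_cm
  expect_lt(fit$species$p, 1e-6)
  expect_lt(m[["PURE_A"]], m[["PURE_B"]])
  expect_lt(m[["PURE_B"]], m[["F1"]])
  expect_equal(m[["F1"]] - m[["PURE_A"]], 12, tolerance = 0.25)
})

test_that("LMM drops lineages with fewer than two ramets and needs two classes", {
  am <- rbind(do.call(rbind, replicate(6, geno_row(rep("AA", 6)),
                                       simplify = FALSE)),
              do.call(rbind, replicate(6, geno_row(rep("BB", 6)),
                                       simplify = FALSE)),
              geno_row(rep("AB", 6)))
  set.seed(4)
  col <- collection_from_matrix(am, site = rep(c("S1", "S2"), length.out = 13),
                                elev = sample.int(500, 13))
  col$records$height_cm <- rnorm(13, 150, 5)
  cl <- classify_collection(col, fixture_key())
  a <- assign_genets(cl, infer_genets(cl))
  expect_warning(fit <- fit_elevation_lmm(a), "fewer than 2")
  expect_identical(fit$dropped, "F1")
  only_a <- study_collection(
    a$records[a$records$species_call == "PURE_A", , drop = FALSE], a$loci)
  expect_error(suppressWarnings(fit_elevation_lmm(only_a)), "2 lineages")
})

test_that("GLMM contrasts vanish under identical genet fractions", {
  tab <- expand.grid(species = c("PURE_A", "PURE_B", "F1"),
                     site = sprintf("S%02d", 1:8),
                     stringsAsFactors = FALSE)
  tab$n <- 10L
  tab$G <- 3L + match(tab$site, unique(tab$site)) %% 4L  # varies by site only
  fit <- fit_richness_glmm(tab)
  expect_true(all(abs(fit$contrasts$estimate) < 1e-4))
  expect_identical(fit$contrasts$level, c("PURE_A", "F1"))
  expect_match(fit$contrasts$contrast, "T. angustifolia vs", all = TRUE)
  # Wald Z is estimate/SE
  expect_equal(fit$contrasts$z,
               fit$contrasts$estimate / fit$contrasts$se)
})

test_that("single-site GLMM reduces to a plain binomial GLM", {
  tab <- data.frame(species = c("PURE_A", "PURE_B", "F1"),
                    site = "S01", n = c(12L, 10L, 20L), G = c(6L, 3L, 5L))
  fit <- fit_richness_glmm(tab)
  expect_true(fit$single_site)
  ref <- glm(cbind(G, n - G) ~ factor(species,
                                      levels = c("PURE_B", "PURE_A", "F1")),
             family = binomial, data = tab)
  expect_equal(unname(fit$contrasts$estimate), unname(coef(ref)[2:3]),
               tolerance = 1e-8)
})

test_that("GLMM recovers the direction of a simulated clonality difference", {
  sim <- simulate_community(sim_config(seed = 23, n_sites = 12,
                                       ramets_per_site = 16,
                                       clonality = c(PURE_A = 2, PURE_B = 6,
                                                     F1 = 6, LATER_GEN = 1),
                                       genotyping_error_rate = 0))
  cl <- classify_collection(sim$collection, sim$key)
  gen <- infer_genets(cl)
  fit <- fit_richness_glmm(richness_by_species_site(cl, gen))
  est <- fit$contrasts$estimate[fit$contrasts$level == "PURE_A"]
  expect_gt(est, 0)  # PURE_A is less clonal => higher genet fraction
})

test_that("analysis report carries all sections and renders to markdown", {
  sim <- simulate_community(sim_config(seed = 29, n_sites = 5,
                                       ramets_per_site = 14))
  fit <- hz_analyze(sim$collection, sim$key)
  rep_ <- build_report(fit, seed = 29)
  expect_named(rep_, c("seed", "n_ramets", "n_removed_incomplete",
                       "removed_ramets", "lineage_frequencies", "genets",
                       "richness", "elevation_summary_cm", "lmm", "glmm",
                       "ks", "ordination", "notes"))
  expect_identical(rep_$n_ramets, nrow(sim$collection$records))
  expect_false(is.null(rep_$lmm$species$p))
  expect_length(rep_$ks, 2)
  md <- render_report_md(rep_)
  expect_match(md, "Kolmogorov", all = FALSE)
  expect_match(md, "richness", all = FALSE, ignore.case = TRUE)
  # degenerate community: one lineage only -> tests skipped with notes
  am <- do.call(rbind, replicate(6, geno_row(rep("AA", 6)),
                                 simplify = FALSE))
  col <- collection_from_matrix(am)
  fit2 <- hz_analyze(col, fixture_key())
  expect_gt(length(fit2$notes), 0)
  expect_no_error(render_report_md(build_report(fit2)))
})
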