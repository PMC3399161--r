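test_that("score_locus follows the private-allele rule", {
  key <- fixture_key()
  expect_identical(score_locus(c(101L, 103L), key, "TA3"), "AA")
  expect_identical(score_locus(c(111L, 113L), key, "TA3"), "BB")
  expect_identical(score_locus(c(101L, 111L), key, "TA3"), "AB")
  expect_identical(score_locus(c(111L, 101L), key, "TA3"), "AB")
  expect_identical(score_locus(c(101L, 999L), key, "TA3"), "ambiguous")
  expect_identical(score_locus(c(999L, 997L), key, "TA3"), "ambiguous")
  expect_error(score_locus(c(101L, 103L), key, "XX1"), "not in the")
})

test_that("classification agrees with the rule-table oracle over all 4^6 evidence patterns", {
  key <- fixture_key()
  states <- c("AA", "BB", "AB", "XX")  # XX realises an off-key allele pair
  grid <- expand.grid(rep(list(states), 6), stringsAsFactors = FALSE)
  counts <- c(PURE_A = 0L, PURE_B = 0L, F1 = 0L, LATER_GEN = 0L,
              UNRESOLVED = 0L)
  for (i in seq_len(nrow(grid))) {
    pattern <- unlist(grid[i, ], use.names = FALSE)
    g <- as.list(as.data.frame(matrix(geno_row(pattern), nrow = 2)))
    names(g) <- hz_loci
    got <- classify_ramet(g, key)
    ev <- ifelse(pattern == "XX", "ambiguous", pattern)
    expect_identical(got$category, oracle_rule(ev))
    expect_identical(unname(got$evidence), ev)
    counts[got$category] <- counts[got$category] + 1L
  }
  # category cardinalities from direct enumeration: 1 each for the pure and
  # F1 corners, 4^6 - 3^6 patterns contain an ambiguous locus, rest mixed
  expect_identical(counts[["PURE_A"]], 1L)
  expect_identical(counts[["PURE_B"]], 1L)
  expect_identical(counts[["F1"]], 1L)
  expect_identical(counts[["UNRESOLVED"]], 4096L - 729L)
  expect_identical(counts[["LATER_GEN"]], 729L - 3L)
})

test_that("vectorised collection classification matches the per-ramet path", {
  key <- fixture_key()
  set.seed(99)
  states <- c("AA", "BB", "AB", "XX")
  am <- do.call(rbind, lapply(1:40, function(i)
    geno_row(sample(states, 6, replace = TRUE))))
  col <- collection_from_matrix(am)
  cl <- classify_collection(col, key)
  for (i in seq_len(40)) {
    g <- get_genotype(col, i)
    expect_identical(cl$records$species_call[i],
                     classify_ramet(g, key)$category)
  }
})

test_that("error-free simulated communities are recovered count-for-count", {
  cfg <- sim_config(seed = 5, n_sites = 6, ramets_per_site = 15,
                    genotyping_error_rate = 0)
  sim <- simulate_community(cfg)
  cl <- classify_collection(sim$collection, sim$key)
  truth_tab <- table(factor(sim$truth$true_lineage,
                            levels = names(lineage_frequencies(cl)$total)))
  expect_identical(lineage_frequencies(cl)$total,
                   setNames(as.integer(truth_tab), names(truth_tab)))
  # and per ramet, not just in aggregate
  expect_identical(cl$records$species_call, sim$truth$true_lineage)
})

test_that("lineage_frequencies totals are consistent and empty input gives zeros", {
  key <- fixture_key()
  am <- do.call(rbind, replicate(10, geno_row(rep("AA", 6)),
                                 simplify = FALSE))
  cl <- classify_collection(collection_from_matrix(am), key)
  f <- lineage_frequencies(cl)
  expect_identical(f$total[["PURE_A"]], 10L)
  expect_identical(sum(f$total), 10L)
  expect_identical(sum(f$by_site), 10L)
  empty <- classify_collection(
    collection_from_matrix(matrix(integer(0), 0, 12)), key)
  expect_identical(sum(lineage_frequencies(empty)$total), 0L)
  uncl <- collection_from_matrix(am)
  expect_error(lineage_frequencies(uncl), "unclassified")
})

test_that("genotypic distance matches the Smouse-Peakall rule table", {
  # single locus cases, checked against the published 0/1/2/3/4 values
  one <- function(a, b) {
    am <- rbind(c(a, rep(c(101L, 103L), 5)), c(b, rep(c(101L, 103L), 5)))
    genotypic_distance(collection_from_matrix(am))[1, 2]
  }
  expect_equal(one(c(101L, 101L), c(101L, 101L)), 0)
  expect_equal(one(c(101L, 101L), c(101L, 111L)), 1)
  expect_equal(one(c(101L, 111L), c(101L, 113L)), 1)
  expect_equal(one(c(101L, 111L), c(113L, 115L)), 2)
  expect_equal(one(c(101L, 101L), c(111L, 113L)), 3)
  expect_equal(one(c(101L, 101L), c(111L, 111L)), 4)
  # loci sum
  am <- rbind(geno_row(rep("AA", 6)), geno_row(rep("BB", 6)))
  expect_equal(genotypic_distance(collection_from_matrix(am))[1, 2],
               6 * 2)  # AA=(101,103) vs BB=(111,113): 2 per locus
})

test_that("ordination reproduces an independent double-centering eigen oracle", {
  am <- rbind(geno_row(rep("AA", 6)), geno_row(rep("BB", 6)),
              geno_row(rep("AB", 6)),
              geno_row(c("AA", "AA", "AA", "AB", "AB", "BB")))
  col <- collection_from_matrix(am)
  D2 <- genotypic_distance(col)
  n <- nrow(D2)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% D2 %*% J
  eg <- eigen(B, symmetric = TRUE)
  ord <- ordinate(col, k = n - 1)
  expect_equal(ord$eig[1:(n - 1)], eg$values[1:(n - 1)], tolerance = 1e-8)
  expect_true(all(diff(ord$eig) <= 1e-8))  # non-increasing
  # coordinates reproduce the distance matrix
  rec <- as.matrix(dist(ord$coords))^2
  expect_equal(max(abs(rec - D2)), 0, tolerance = 1e-8)
  # axis-1 coordinates match the oracle up to sign
  o1 <- eg$vectors[, 1] * sqrt(eg$values[1])
  expect_true(max(abs(ord$coords[, 1] - o1)) < 1e-8 ||
              max(abs(ord$coords[, 1] + o1)) < 1e-8)
  expect_true(ord$var_explained[1] >= ord$var_explained[2])
  expect_lte(sum(ord$var_explained), 1 + 1e-12)
})

test_that("two equal clusters sit symmetrically about zero on axis 1", {
  am <- rbind(do.call(rbind, replicate(3, geno_row(rep("AA", 6)),
                                       simplify = FALSE)),
              do.call(rbind, replicate(3, geno_row(rep("BB", 6)),
                                       simplify = FALSE)))
  ord <- ordinate(collection_from_matrix(am))
  m1 <- mean(ord$coords[1:3, 1]); m2 <- mean(ord$coords[4:6, 1])
  expect_equal(m1 + m2, 0, tolerance = 1e-10)
  expect_gt(abs(m1), 0.1)
  # degenerate case: identical genotypes
  same <- do.call(rbind, replicate(4, geno_row(rep("AB", 6)),
                                   simplify = FALSE))
  expect_error(ordinate(collection_from_matrix(same)), "degenerate")
})

test_that("F1 ramets fall between the parental clusters on axis 1", {
  sim <- simulate_community(sim_config(seed = 21, n_sites = 5,
                                       ramets_per_site = 15,
                                       genotyping_error_rate = 0))
  cl <- classify_collection(sim$collection, sim$key)
  ord <- ordinate(cl)
  calls <- cl$records$species_call
  conc <- corroborate(calls, ord, threshold = 0.4)
  mA <- mean(conc$axis1[calls == "PURE_A"])
  mB <- mean(conc$axis1[calls == "PURE_B"])
  mF <- mean(conc$axis1[calls == "F1"])
  expect_lt(mA, mF)
  expect_lt(mF, mB)
  expect_lt(mA, 0)  # orientation convention
})

test_that("corroborate handles thresholds and degenerate call sets", {
  am <- rbind(do.call(rbind, replicate(4, geno_row(rep("AA", 6)),
                                       simplify = FALSE)),
              do.call(rbind, replicate(4, geno_row(rep("BB", 6)),
                                       simplify = FALSE)),
              do.call(rbind, replicate(4, geno_row(rep("AB", 6)),
                                       simplify = FALSE)))
  col <- collection_from_matrix(am)
  cl <- classify_collection(col, fixture_key())
  ord <- ordinate(cl)
  conc <- corroborate(cl$records$species_call, ord, threshold = 0.4)
  expect_equal(unname(conc$concordance[c("PURE_A", "PURE_B")]), c(1, 1))
  expect_error(corroborate(cl$records$species_call, ord, threshold = 0),
               "positive")
  expect_warning(
    empty <- corroborate(rep("UNRESOLVED", 12), ord, threshold = 0.4),
    "concordance")
  expect_identical(empty$discordant, character(0))
})
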