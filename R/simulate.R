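#' Simulation configuration for a synthetic hybrid zone
#'
#' Bundles every generator knob: community scale, allele-pool structure,
#' lineage mixture, clonality, genotyping error, and the hierarchical
#' elevation model (site effect + lineage offset + genet effect + residual,
#' all in cm) with a linear shoot-height model.  Defaults describe a small
#' generic community; [paper_scale_preset()] gives the study-scale
#' configuration used throughout the package's validation.
#'
#' @param seed integer RNG seed; the whole simulation is a deterministic
#'   function of the configuration including this seed.
#' @param n_sites number of sites.
#' @param ramets_per_site single integer, or length-2 inclusive range from
#'   which each site's ramet count is drawn uniformly.
#' @param loci locus names.
#' @param alleles_per_species_per_locus private alleles per parental
#'   species at each locus (>= 1).
#' @param shared_fraction fraction of each locus's alleles private to
#'   neither species, in [0, 1).
#' @param mixture named lineage proportions (PURE_A, PURE_B, F1, LATER_GEN)
#'   summing to 1.
#' @param clonality mean ramets per genet (>= 1), recycled or named per
#'   lineage.
#' @param genotyping_error_rate per-allele-copy probability that a call is
#'   replaced by another allele from the same locus's pool, in [0, 1).
#' @param site_sd_cm,genet_sd_cm,resid_sd_cm standard deviations of the
#'   site, genet, and residual elevation components (cm).
#' @param species_offset_cm named per-lineage mean elevation offsets (cm).
#' @param height_intercept_cm,height_slope,height_sd_cm shoot-height model:
#'   height = intercept + slope * elevation_cm + noise.
#' @return A validated \code{sim_config} list.
#' @export
sim_config <- function(seed = 1L,
                       n_sites = 6L,
                       ramets_per_site = 10L,
                       loci = c("TA3", "TA5", "TA7", "TA8", "TA16", "TA20"),
                       alleles_per_species_per_locus = 4L,
                       shared_fraction = 0,
                       mixture = c(PURE_A = 0.3, PURE_B = 0.2,
                                   F1 = 0.465, LATER_GEN = 0.035),
                       clonality = c(PURE_A = 3, PURE_B = 3, F1 = 3,
                                     LATER_GEN = 1),
                       genotyping_error_rate = 0.005,
                       site_sd_cm = 25,
                       species_offset_cm = c(PURE_A = 0, PURE_B = 0,
                                             F1 = 0, LATER_GEN = 0),
                       genet_sd_cm = 6,
                       resid_sd_cm = 10,
                       height_intercept_cm = 150,
                       height_slope = 0,
                       height_sd_cm = 20) {
  lineages <- c("PURE_A", "PURE_B", "F1", "LATER_GEN")
  mixture <- expand_named(mixture, lineages, "mixture")
  clonality <- expand_named(clonality, lineages, "clonality")
  species_offset_cm <- expand_named(species_offset_cm, lineages,
                                    "species_offset_cm")
  stopifnot(n_sites >= 1,
            all(ramets_per_site >= 1),
            length(ramets_per_site) %in% c(1, 2),
            alleles_per_species_per_locus >= 1,
            shared_fraction >= 0, shared_fraction < 1,
            all(mixture >= 0),
            all(clonality >= 1),
            genotyping_error_rate >= 0, genotyping_error_rate < 1,
            site_sd_cm >= 0, genet_sd_cm >= 0, resid_sd_cm >= 0,
            height_sd_cm >= 0)
  if (abs(sum(mixture) - 1) > 1e-8)
    stop("mixture proportions must sum to 1")
  structure(list(
    seed = as.integer(seed), n_sites = as.integer(n_sites),
    ramets_per_site = as.integer(ramets_per_site), loci = loci,
    alleles_per_species_per_locus = as.integer(alleles_per_species_per_locus),
    shared_fraction = shared_fraction, mixture = mixture,
    clonality = clonality, genotyping_error_rate = genotyping_error_rate,
    site_sd_cm = site_sd_cm, species_offset_cm = species_offset_cm,
    genet_sd_cm = genet_sd_cm, resid_sd_cm = resid_sd_cm,
    height_intercept_cm = height_intercept_cm, height_slope = height_slope,
    height_sd_cm = height_sd_cm), class = "sim_config")
}

expand_named <- function(x, nm, what) {
  if (is.null(names(x))) {
    if (length(x) == 1) x <- rep(x, length(nm))
    if (length(x) != length(nm)) stop(what, " must be length 1 or named")
    names(x) <- nm
  } else {
    miss <- setdiff(nm, names(x))
    full <- stats::setNames(rep(if (what == "mixture") 0 else
                                if (what == "clonality") 1 else 0,
                                length(miss)), miss)
    x <- c(x[intersect(names(x), nm)], full)[nm]
  }
  x
}

#' Study-scale simulation preset
#'
#' The configuration the package uses to emulate the sampled community: 18
#' sites of 13-17 ramets (~265 total), a lineage mixture dominated by F1
#' hybrids with rare later-generation hybrids, six fully diagnostic loci,
#' clonal replication of about three ramets per genet (per-species
#' genotypic richness lands in roughly 0.1-0.3), occasional single-allele
#' genotyping errors, and a null elevation model (no lineage offsets, zero
#' height-elevation slope).
#'
#' @param seed integer RNG seed.
#' @param ... overrides passed on to [sim_config()].
#' @return A \code{sim_config}.
#' @export
paper_scale_preset <- function(seed = 1L, ...) {
  args <- list(seed = seed, n_sites = 18L, ramets_per_site = c(13L, 17L),
               alleles_per_species_per_locus = 4L, shared_fraction = 0,
               mixture = c(PURE_A = 0.30, PURE_B = 0.20, F1 = 0.465,
                           LATER_GEN = 0.035),
               clonality = c(PURE_A = 3, PURE_B = 3, F1 = 3, LATER_GEN = 1),
               genotyping_error_rate = 0.005,
               site_sd_cm = 25, genet_sd_cm = 6, resid_sd_cm = 10,
               height_intercept_cm = 150, height_slope = 0,
               height_sd_cm = 20)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation config: ", x$n_sites, " sites, ",
      paste(x$ramets_per_site, collapse = "-"), " ramets/site, ",
      length(x$loci), " loci, seed ", x$seed, "\n", sep = "")
  cat("  mixture:", paste(sprintf("%s=%.3f", names(x$mixture), x$mixture),
                          collapse = " "), "\n")
  cat(sprintf("  error rate %.4g, clonality %s\n", x$genotyping_error_rate,
              paste(sprintf("%s=%.3g", names(x$clonality), x$clonality),
                    collapse = " ")))
  invisible(x)
}

#' Write / read a simulation configuration as YAML
#' @param config a \code{sim_config}.
#' @param path YAML file path.
#' @return \code{write_sim_config} returns \code{path} invisibly;
#'   \code{read_sim_config} returns a \code{sim_config}.
#' @export
write_sim_config <- function(config, path) {
  yaml::write_yaml(lapply(unclass(config), function(v)
    if (!is.null(names(v))) as.list(v) else v), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (f in c("mixture", "clonality", "species_offset_cm"))
    if (!is.null(raw[[f]])) raw[[f]] <- unlist(raw[[f]])
  raw$loci <- as.character(raw$loci)
  do.call(sim_config, raw)
}

#' Simulate per-species allele pools and the matching diagnostic key
#'
#' Each locus gets disjoint sets of alleles private to species A and B
#' (plus optional shared alleles belonging to both pools, controlled by
#' \code{shared_fraction}); within-species allele frequencies are drawn from
#' a flat Dirichlet.  The emitted key lists exactly the private alleles, so
#' classification against it mirrors a fully resolved field key.
#'
#' @param config a \code{sim_config}.
#' @return List with \code{pools} (per locus: alleles and frequencies for A
#'   and B, plus the shared allele set) and \code{key} (a
#'   \code{diagnostic_key}).  Deterministic given \code{config$seed}.
#' @export
simulate_allele_pools <- function(config) {
  set.seed(config$seed)
  draw_pools(config)
}

draw_pools <- function(config) {
  k <- config$alleles_per_species_per_locus
  s <- config$shared_fraction
  n_shared <- round(2 * k * s / (1 - s))
  if (k < 1) stop("need at least one private allele per species per locus")
  pools <- list()
  key_rows <- list()
  for (i in seq_along(config$loci)) {
    loc <- config$loci[i]
    base <- 100L + (i - 1L) * 40L
    allA <- base + 2L * seq_len(k) - 2L
    allB <- base + 2L * (k + seq_len(k)) - 2L
    shared <- if (n_shared > 0) base + 2L * (2L * k + seq_len(n_shared)) - 2L
              else integer(0)
    fA <- stats::rgamma(k + n_shared, 1); fA <- fA / sum(fA)
    fB <- stats::rgamma(k + n_shared, 1); fB <- fB / sum(fB)
    pools[[loc]] <- list(
      A = list(alleles = c(allA, shared), freq = fA),
      B = list(alleles = c(allB, shared), freq = fB),
      shared = shared)
    key_rows[[loc]] <- data.frame(
      locus = loc, allele = c(allA, allB),
      species = rep(c("A", "B"), each = k), stringsAsFactors = FALSE)
  }
  list(pools = pools, key = diagnostic_key(do.call(rbind, key_rows)))
}

#' Simulate a hybrid-zone community with known truth
#'
#' Generates a full synthetic study: per site, genets are drawn from the
#' lineage mixture (pure parents sample both alleles from their own pool;
#' F1s take one allele from each pool at every locus; later-generation
#' hybrids are first-generation backcrosses — per locus a 50/50 choice of
#' heterospecific vs recurrent-parent pattern, constrained to show at least
#' one locus of each so the class is identifiable), replicated into ramets
#' according to the per-lineage clonality (genet size is 1 + Poisson(mean
#' clonality - 1)).  Each allele copy is then independently mis-called with
#' probability \code{genotyping_error_rate} (replaced by a different allele
#' from the locus's union pool).  Elevations (cm) are site effect + lineage
#' offset + genet effect + residual, stored as integer millimetres (rounded
#' half away from zero); heights follow the linear height model.
#'
#' @param config a \code{sim_config}.
#' @return Object of class \code{hz_simulation}: list with
#'   \code{collection} (a \code{study_collection}), \code{truth} (data
#'   frame of per-ramet true lineage, true genet, elevation components, and
#'   the count of injected allele errors), \code{key}, and \code{pools}.
#'   Bit-identical for identical configurations.
#' @export
simulate_community <- function(config) {
  set.seed(config$seed)
  ap <- draw_pools(config)
  pools <- ap$pools
  lineages <- names(config$mixture)
  draw1 <- function(pool) {
    if (length(pool$alleles) == 1) pool$alleles else
      sample(pool$alleles, 1, prob = pool$freq)
  }
  genet_genotype <- function(lineage) {
    g <- matrix(NA_integer_, nrow = 2, ncol = length(config$loci))
    if (lineage == "LATER_GEN") {
      recurrent <- sample(c("A", "B"), 1)
      repeat {
        het <- stats::runif(length(config$loci)) < 0.5
        if (any(het) && !all(het)) break
      }
    }
    for (j in seq_along(config$loci)) {
      p <- pools[[config$loci[j]]]
      g[, j] <- switch(lineage,
        PURE_A = c(draw1(p$A), draw1(p$A)),
        PURE_B = c(draw1(p$B), draw1(p$B)),
        F1 = c(draw1(p$A), draw1(p$B)),
        LATER_GEN = if (het[j]) c(draw1(p$A), draw1(p$B))
                    else { q <- p[[recurrent]]; c(draw1(q), draw1(q)) })
    }
    g
  }
  union_pools <- lapply(pools, function(p)
    sort(unique(c(p$A$alleles, p$B$alleles))))
  site_eff <- stats::rnorm(config$n_sites, 0, config$site_sd_cm)
  rec_rows <- list(); truth_rows <- list()
  ramet_no <- 0L
  for (i in seq_len(config$n_sites)) {
    site <- sprintf("S%02d", i)
    n_target <- if (length(config$ramets_per_site) == 2) {
      rng <- seq(config$ramets_per_site[1], config$ramets_per_site[2])
      rng[sample.int(length(rng), 1)]
    } else config$ramets_per_site
    filled <- 0L; genet_no <- 0L
    while (filled < n_target) {
      lineage <- sample(lineages, 1, prob = config$mixture)
      size <- min(1L + stats::rpois(1, config$clonality[[lineage]] - 1),
                  n_target - filled)
      genet_no <- genet_no + 1L
      true_genet <- sprintf("%s:T%03d", site, genet_no)
      g <- genet_genotype(lineage)
      genet_eff <- stats::rnorm(1, 0, config$genet_sd_cm)
      for (r in seq_len(size)) {
        ramet_no <- ramet_no + 1L
        rid <- sprintf("R%04d", ramet_no)
        obs <- g
        n_err <- 0L
        for (j in seq_along(config$loci)) for (cpy in 1:2) {
          if (stats::runif(1) < config$genotyping_error_rate) {
            others <- setdiff(union_pools[[j]], obs[cpy, j])
            if (length(others) > 0) {
              obs[cpy, j] <- if (length(others) == 1) others
                             else sample(others, 1)
              n_err <- n_err + 1L
            }
          }
        }
        resid <- stats::rnorm(1, 0, config$resid_sd_cm)
        elev_cm <- site_eff[i] + config$species_offset_cm[[lineage]] +
          genet_eff + resid
        elev_mm <- as.integer(sign(elev_cm) * floor(abs(elev_cm) * 10 + 0.5))
        height <- config$height_intercept_cm +
          config$height_slope * elev_cm +
          stats::rnorm(1, 0, config$height_sd_cm)
        row <- data.frame(ramet_id = rid, site_id = site,
                          elevation_mm = elev_mm, height_cm = height,
                          stringsAsFactors = FALSE)
        for (j in seq_along(config$loci)) {
          a <- sort(obs[, j])
          row[[paste0(config$loci[j], "_1")]] <- a[1]
          row[[paste0(config$loci[j], "_2")]] <- a[2]
        }
        rec_rows[[ramet_no]] <- row
        truth_rows[[ramet_no]] <- data.frame(
          ramet_id = rid, site_id = site, true_lineage = lineage,
          true_genet = true_genet, site_effect_cm = site_eff[i],
          species_offset_cm = config$species_offset_cm[[lineage]],
          genet_effect_cm = genet_eff, resid_cm = resid,
          n_allele_errors = n_err, stringsAsFactors = FALSE)
      }
      filled <- filled + size
    }
  }
  collection <- study_collection(do.call(rbind, rec_rows), config$loci)
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  structure(list(collection = collection, truth = truth, key = ap$key,
                 pools = pools, config = config),
            class = "hz_simulation")
}

#' @export
print.hz_simulation <- function(x, ...) {
  cat("Simulated hybrid zone (seed ", x$config$seed, "):\n", sep = "")
  print(x$collection)
  cat("  true lineages:",
      paste(sprintf("%s=%d", names(table(x$truth$true_lineage)),
                    table(x$truth$true_lineage)), collapse = " "), "\n")
  cat("  true genets:", length(unique(x$truth$true_genet)), "\n")
  invisible(x)
}
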