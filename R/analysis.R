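#' Full hybrid-zone niche-segregation analysis
#'
#' The package's one-stop fitting function.  Runs the whole pipeline on a
#' ramet-level genotype collection: (1) removes incompletely amplified
#' genotypes; (2) classifies each ramet as pure T. latifolia (PURE_A), pure
#' T. angustifolia (PURE_B), F1 T. x glauca, later-generation hybrid, or
#' unresolved, from private diagnostic alleles; (3) corroborates the calls
#' with a principal coordinates ordination of genotypic distances; (4)
#' partitions ramets into genets with the one-allele-mismatch rule and
#' computes genotypic richness R = (G-1)/(n-1) per species per site; (5)
#' standardizes elevations to the site median and tests for niche
#' segregation with the elevation LMM, the genotypic-diversity binomial
#' GLMM, and two-sample Kolmogorov-Smirnov comparisons of standardized
#' elevation distributions.
#'
#' @param collection a \code{study_collection} (see
#'   [read_genotype_table()] or [simulate_community()]).
#' @param key a \code{diagnostic_key}.
#' @param max_mismatch allele-mismatch tolerance for genet inference
#'   (default 1).
#' @param pc1_threshold axis-1 cutoff for the ordination concordance report
#'   (default 0.4).
#' @param ks_pairs list of 2-vectors of lineage categories to compare by KS
#'   test; default: T. latifolia vs T. angustifolia and T. latifolia vs
#'   T. x glauca.
#' @param lmm_response \code{"standardized"} or \code{"raw"} elevations.
#' @return Object of class \code{hz_analysis} with components
#'   \code{collection} (classified, genet-assigned), \code{removed},
#'   \code{frequencies}, \code{ordination}, \code{concordance},
#'   \code{genets}, \code{richness}, \code{std_elevations},
#'   \code{elevation_summary}, \code{lmm}, \code{glmm}, \code{ks}, and
#'   \code{notes} (stages skipped on degenerate input, with reasons).
#' @examples
#' sim <- simulate_community(sim_config(seed = 7, n_sites = 4,
#'                                      ramets_per_site = 12))
#' fit <- hz_analyze(sim$collection, sim$key)
#' fit
#' @export
hz_analyze <- function(collection, key, max_mismatch = 1,
                       pc1_threshold = 0.4,
                       ks_pairs = list(c("PURE_A", "PURE_B"),
                                       c("PURE_A", "F1")),
                       lmm_response = c("standardized", "raw")) {
  lmm_response <- match.arg(lmm_response)
  notes <- character(0)
  filtered <- drop_incomplete(collection)
  removed <- attr(filtered, "removed")
  classified <- classify_collection(filtered, key)
  freqs <- lineage_frequencies(classified)
  ord <- NULL; conc <- NULL
  ord_try <- tryCatch(ordinate(classified), error = function(e) e)
  if (inherits(ord_try, "error")) {
    notes <- c(notes, paste("ordination skipped:",
                            conditionMessage(ord_try)))
  } else {
    ord <- ord_try
    conc <- suppressWarnings(
      corroborate(classified$records$species_call, ord, pc1_threshold))
  }
  genets <- infer_genets(classified, max_mismatch = max_mismatch)
  analysed <- assign_genets(classified, genets)
  attr(analysed, "evidence") <- attr(classified, "evidence")
  richness <- richness_by_species_site(analysed, genets)
  std <- standardize_elevations(analysed)
  spp <- analysed$records$species_call
  elev_summary <- do.call(rbind, lapply(c("PURE_A", "PURE_B", "F1"),
    function(sp) {
      v <- std$std_elevation_cm[spp == sp]
      data.frame(species = sp, n = length(v),
                 mean_cm = if (length(v) > 0) mean(v) else NA_real_,
                 sd_cm = if (length(v) > 1) stats::sd(v) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  lmm <- tryCatch(fit_elevation_lmm(analysed, response = lmm_response),
                  error = function(e) e)
  if (inherits(lmm, "error")) {
    notes <- c(notes, paste("elevation LMM skipped:",
                            conditionMessage(lmm)))
    lmm <- NULL
  }
  glmm <- tryCatch(fit_richness_glmm(richness), error = function(e) e)
  if (inherits(glmm, "error")) {
    notes <- c(notes, paste("richness GLMM skipped:",
                            conditionMessage(glmm)))
    glmm <- NULL
  }
  ks <- list()
  for (pair in ks_pairs) {
    x <- std$std_elevation_cm[spp == pair[1]]
    y <- std$std_elevation_cm[spp == pair[2]]
    nm <- paste(pair, collapse = "_vs_")
    if (length(x) == 0 || length(y) == 0) {
      notes <- c(notes, paste0("KS ", nm,
                               " skipped: a lineage class is empty"))
    } else {
      ks[[nm]] <- suppressWarnings(ks_compare(x, y))
    }
  }
  structure(list(collection = analysed, removed = removed,
                 frequencies = freqs, ordination = ord, concordance = conc,
                 genets = genets, richness = richness,
                 std_elevations = std, elevation_summary = elev_summary,
                 lmm = lmm, glmm = glmm, ks = ks,
                 max_mismatch = max_mismatch,
                 pc1_threshold = pc1_threshold, notes = notes),
            class = "hz_analysis")
}

#' @export
print.hz_analysis <- function(x, ...) {
  cat("Hybrid-zone niche analysis\n")
  cat("  ramets analysed:", nrow(x$collection$records),
      sprintf("(%d removed for missing loci)\n", length(x$removed)))
  f <- x$frequencies$total
  cat("  lineages:", paste(sprintf("%s=%d", names(f), f), collapse = " "),
      "\n")
  cat("  genets:", length(unique(x$genets$genet_id)),
      sprintf("(max_mismatch = %d)\n", x$max_mismatch))
  if (!is.null(x$lmm))
    cat(sprintf("  elevation LMM species test: F_%d,%d = %.2f, P = %.3g\n",
                x$lmm$species$num_df, x$lmm$species$den_df,
                x$lmm$species$F, x$lmm$species$p))
  for (nm in names(x$ks))
    cat(sprintf("  KS %s: D = %.2f, P = %.3g\n", nm, x$ks[[nm]]$D,
                x$ks[[nm]]$p_value))
  if (length(x$notes) > 0)
    cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' @export
summary.hz_analysis <- function(object, ...) {
  x <- object
  print(x)
  cat("\nRichness per species (mean R +/- SE over sites):\n")
  s <- x$richness$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %s: R = %.2f +/- %.2f SE (%d sites)\n", s$species[i],
                s$mean_R[i], s$se_R[i], s$n_sites[i]))
  cat("\nStandardized elevations (cm):\n")
  e <- x$elevation_summary
  for (i in seq_len(nrow(e)))
    if (e$n[i] > 0)
      cat(sprintf("  %s: mean %.1f cm (sd %.1f, n = %d)\n", e$species[i],
                  e$mean_cm[i], e$sd_cm[i], e$n[i]))
  if (!is.null(x$glmm)) { cat("\n"); print(x$glmm) }
  if (!is.null(x$concordance))
    cat("\nOrdination concordance (threshold ", x$pc1_threshold, "): ",
        paste(sprintf("%s=%.2f", names(x$concordance$concordance),
                      x$concordance$concordance), collapse = " "),
        "; axis 1 explains ",
        sprintf("%.0f%%", 100 * x$ordination$var_explained[1]),
        "\n", sep = "")
  invisible(x)
}

#' Plot standardized-elevation distributions per lineage
#'
#' Base-graphics histograms of site-standardized shoot elevations for the
#' two parental species and the F1 hybrid, sharing common breaks.
#'
#' @param x an \code{hz_analysis}.
#' @param ... passed to [graphics::hist()].
#' @return Invisibly, \code{x}.
#' @export
plot.hz_analysis <- function(x, ...) {
  std <- x$std_elevations
  spp <- x$collection$records$species_call
  cats <- c(PURE_B = "T. angustifolia", F1 = "T. x glauca",
            PURE_A = "T. latifolia")
  present <- names(cats)[vapply(names(cats),
                                function(s) any(spp == s), logical(1))]
  if (length(present) == 0) {
    warning("no classified parental/F1 ramets to plot")
    return(invisible(x))
  }
  old <- graphics::par(mfrow = c(length(present), 1),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  brk <- pretty(std$std_elevation_cm, 20)
  for (s in present)
    graphics::hist(std$std_elevation_cm[spp == s], breaks = brk,
                   main = cats[[s]], xlab = "Standardized elevation (cm)",
                   col = "grey80", ...)
  invisible(x)
}

#' Assemble a machine-readable analysis report
#'
#' Collects every result of an [hz_analyze()] fit into a plain list ready
#' for JSON serialisation: lineage frequency tables, genet counts and
#' richness per species per site with means, the three inferential tests,
#' per-species standardized-elevation summaries, ordination variance and
#' concordance, and any skipped-stage notes.
#'
#' @param analysis an \code{hz_analysis}.
#' @param seed optional integer recorded in the report for provenance.
#' @return A nested list of plain vectors/lists.
#' @export
build_report <- function(analysis, seed = NULL) {
  x <- analysis
  rep_ <- list(
    seed = seed,
    n_ramets = nrow(x$collection$records),
    n_removed_incomplete = length(x$removed),
    removed_ramets = as.list(x$removed),
    lineage_frequencies = as.list(x$frequencies$total),
    genets = list(
      n_genets = length(unique(x$genets$genet_id)),
      max_mismatch = x$max_mismatch),
    richness = list(
      by_species_site = df_to_rows(x$richness$table),
      summary = df_to_rows(x$richness$summary)),
    elevation_summary_cm = df_to_rows(x$elevation_summary),
    lmm = if (!is.null(x$lmm)) list(
      response = x$lmm$response,
      species = x$lmm$species, height = x$lmm$height,
      adjusted_means_cm = as.list(x$lmm$adjusted_means_cm),
      singular = x$lmm$singular) else NULL,
    glmm = if (!is.null(x$glmm)) list(
      contrasts = df_to_rows(x$glmm$contrasts),
      singular = x$glmm$singular) else NULL,
    ks = lapply(x$ks, function(k)
      list(D = k$D, p_value = k$p_value, n_x = k$n_x, n_y = k$n_y,
           ties = k$ties)),
    ordination = if (!is.null(x$ordination)) list(
      var_explained = as.numeric(x$ordination$var_explained),
      concordance = as.list(x$concordance$concordance),
      n_discordant = length(x$concordance$discordant)) else NULL,
    notes = as.list(x$notes))
  rep_
}

df_to_rows <- function(df) {
  lapply(seq_len(nrow(df)), function(i) {
    row <- as.list(df[i, , drop = FALSE])
    lapply(row, function(v) if (is.factor(v)) as.character(v) else unname(v))
  })
}

#' Render an analysis report as Markdown
#'
#' @param report list from [build_report()].
#' @return Character vector of Markdown lines.
#' @export
render_report_md <- function(report) {
  f <- function(v) ifelse(is.na(v), "NA", sprintf("%.4g", v))
  out <- c("# Hybrid-zone niche analysis report", "",
           sprintf("- ramets analysed: %d (%d removed for missing loci)",
                   report$n_ramets, report$n_removed_incomplete),
           sprintf("- genets: %d (mismatch tolerance %d)",
                   report$genets$n_genets, report$genets$max_mismatch),
           "", "## Lineage frequencies", "")
  for (nm in names(report$lineage_frequencies))
    out <- c(out, sprintf("- %s: %d", nm, report$lineage_frequencies[[nm]]))
  out <- c(out, "", "## Genotypic richness (R, per species across sites)",
           "")
  for (row in report$richness$summary)
    out <- c(out, sprintf("- %s: mean R = %s +/- %s SE (%d sites)",
                          row$species, f(row$mean_R), f(row$se_R),
                          row$n_sites))
  out <- c(out, "", "## Standardized elevations (cm)", "")
  for (row in report$elevation_summary_cm)
    out <- c(out, sprintf("- %s: mean %s cm (sd %s, n = %d)", row$species,
                          f(row$mean_cm), f(row$sd_cm), row$n))
  if (!is.null(report$lmm))
    out <- c(out, "", "## Elevation linear mixed model", "",
             sprintf("- species: F_%d,%d = %s, P = %s",
                     report$lmm$species$num_df, report$lmm$species$den_df,
                     f(report$lmm$species$F), f(report$lmm$species$p)),
             sprintf("- height covariate: F_%d,%d = %s, P = %s",
                     report$lmm$height$num_df, report$lmm$height$den_df,
                     f(report$lmm$height$F), f(report$lmm$height$p)))
  if (!is.null(report$glmm)) {
    out <- c(out, "", "## Genotypic-diversity GLMM (binomial, logit)", "")
    for (row in report$glmm$contrasts)
      out <- c(out, sprintf(
        "- %s: estimate %s +/- %s SE, Wald Z = %s, P = %s", row$contrast,
        f(row$estimate), f(row$se), f(row$z), f(row$p)))
  }
  if (length(report$ks) > 0) {
    out <- c(out, "", "## Kolmogorov-Smirnov comparisons", "")
    for (nm in names(report$ks))
      out <- c(out, sprintf("- %s: D = %s, P = %s", nm,
                            f(report$ks[[nm]]$D),
                            f(report$ks[[nm]]$p_value)))
  }
  if (length(report$notes) > 0)
    out <- c(out, "", "## Notes", "",
             paste0("- ", unlist(report$notes)))
  out
}
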