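#' Standardize shoot elevations within sites
#'
#' Subtracts the per-site median shoot elevation from each measurement, so
#' that elevations are comparable across sites with different absolute
#' levels; the standardized value is a within-site proxy for relative water
#' depth.  Medians use the usual midpoint convention for even sample sizes.
#'
#' @param collection a \code{study_collection}.
#' @return Data frame with \code{ramet_id}, \code{site_id}, and
#'   \code{std_elevation_cm} (centimetres, site-median-centered; the
#'   per-site median of this column is 0).
#' @export
standardize_elevations <- function(collection) {
  rec <- collection$records
  med <- tapply(rec$elevation_mm, rec$site_id, stats::median)
  data.frame(ramet_id = rec$ramet_id, site_id = rec$site_id,
             std_elevation_cm =
               (rec$elevation_mm - as.numeric(med[rec$site_id])) / 10,
             stringsAsFactors = FALSE)
}

#' Linear mixed model for elevation differences between lineages
#'
#' Tests whether the parental species and F1 hybrids occupy different shoot
#' elevations.  The response is the site-standardized elevation (cm; or raw
#' elevation, see \code{response}), the fixed effects are lineage and shoot
#' height (covariate), and the random intercepts are site and genet nested
#' within site — genet absorbs the pseudo-replication of clonal shoots.
#' Fitted by REML via [nlme::lme()]; marginal (Type III) F tests use nlme's
#' containment denominator degrees of freedom.  Only PURE_A, PURE_B, and F1
#' ramets enter the model; later-generation and unresolved ramets are
#' excluded.
#'
#' @param collection a classified \code{study_collection} with genet IDs
#'   assigned (see [classify_collection()], [assign_genets()]).
#' @param response \code{"standardized"} (default) or \code{"raw"}
#'   elevations (cm).
#' @return Object of class \code{hz_lmm}: list with \code{species}
#'   (F, num/den df, p), \code{height} (same), \code{adjusted_means_cm}
#'   (per-lineage fixed-effect means at the average shoot height),
#'   \code{singular} (TRUE when a random-effect standard deviation collapsed
#'   to ~0), \code{dropped} (lineages removed for having < 2 ramets), and
#'   \code{model} (the underlying \code{lme} fit).
#' @export
fit_elevation_lmm <- function(collection,
                              response = c("standardized", "raw")) {
  response <- match.arg(response)
  rec <- collection$records
  if (anyNA(rec$species_call) || anyNA(rec$genet_id))
    stop("collection must be classified and genet-assigned first")
  std <- standardize_elevations(collection)
  dat <- data.frame(
    elev_cm = if (response == "standardized") std$std_elevation_cm
              else rec$elevation_mm / 10,
    species = rec$species_call,
    height_cm = rec$height_cm,
    site = rec$site_id,
    genet = rec$genet_id,
    stringsAsFactors = FALSE)
  dat <- dat[dat$species %in% c("PURE_A", "PURE_B", "F1"), ]
  counts <- table(dat$species)
  dropped <- names(counts)[counts < 2]
  if (length(dropped) > 0) {
    warning("dropping lineage(s) with fewer than 2 ramets: ",
            paste(dropped, collapse = ", "))
    dat <- dat[!dat$species %in% dropped, ]
  }
  if (length(unique(dat$species)) < 2)
    stop("need at least 2 lineages with >= 2 ramets each")
  dat$species <- factor(dat$species,
                        levels = intersect(c("PURE_B", "PURE_A", "F1"),
                                           unique(dat$species)))
  fit <- nlme::lme(elev_cm ~ species + height_cm,
                   random = ~ 1 | site / genet,
                   data = dat, method = "REML",
                   control = nlme::lmeControl(opt = "optim",
                                              maxIter = 200,
                                              msMaxIter = 200,
                                              returnObject = TRUE))
  an <- stats::anova(fit, type = "marginal")
  vc <- nlme::VarCorr(fit)
  sds <- suppressWarnings(as.numeric(vc[, "StdDev"]))
  sds <- sds[!is.na(sds)]
  singular <- any(utils::head(sds, -1) < 1e-6 * max(sds))
  fe <- nlme::fixef(fit)
  mean_h <- mean(dat$height_cm)
  lev <- levels(dat$species)
  adj <- vapply(lev, function(sp) {
    co <- if (sp == lev[1]) 0 else fe[[paste0("species", sp)]]
    unname(fe[["(Intercept)"]] + co + fe[["height_cm"]] * mean_h)
  }, numeric(1))
  structure(list(
    species = list(F = an["species", "F-value"],
                   num_df = an["species", "numDF"],
                   den_df = an["species", "denDF"],
                   p = an["species", "p-value"]),
    height = list(F = an["height_cm", "F-value"],
                  num_df = an["height_cm", "numDF"],
                  den_df = an["height_cm", "denDF"],
                  p = an["height_cm", "p-value"]),
    adjusted_means_cm = adj,
    singular = singular,
    dropped = dropped,
    response = response,
    n = nrow(dat),
    model = fit), class = "hz_lmm")
}

#' @export
print.hz_lmm <- function(x, ...) {
  cat("Elevation linear mixed model (", x$response, " response, n = ",
      x$n, ")\n", sep = "")
  cat(sprintf("  species: F_%d,%d = %.3f, P = %.4g\n",
              x$species$num_df, x$species$den_df, x$species$F, x$species$p))
  cat(sprintf("  height:  F_%d,%d = %.3f, P = %.4g\n",
              x$height$num_df, x$height$den_df, x$height$F, x$height$p))
  cat("  adjusted means (cm):",
      paste(sprintf("%s = %.2f", names(x$adjusted_means_cm),
                    x$adjusted_means_cm), collapse = ", "), "\n")
  if (x$singular)
    cat("  note: a random-effect variance collapsed to ~0 (singular fit)\n")
  invisible(x)
}

#' Binomial GLMM for genotypic-diversity differences between lineages
#'
#' Models the number of genets \code{G} out of \code{n} sampled ramets per
#' (lineage, site) cell as binomial with a logit link, lineage as the fixed
#' effect and site as a random intercept ([lme4::glmer()]).  The reference
#' level is PURE_B (T. angustifolia), so the reported Wald contrasts are
#' T. angustifolia vs. T. latifolia and T. angustifolia vs. T. x glauca.
#' With a single site the model reduces to a plain binomial GLM.
#'
#' @param richness the \code{table} element of
#'   [richness_by_species_site()] (columns species, site, G, n).
#' @return Object of class \code{hz_glmm}: list with \code{contrasts} (data
#'   frame: contrast, estimate, se, z, p), \code{singular}, and
#'   \code{model}.
#' @export
fit_richness_glmm <- function(richness) {
  tab <- if (is.list(richness) && !is.data.frame(richness)) richness$table
         else richness
  tab <- tab[tab$n > 0, ]
  if (length(unique(tab$species)) < 2)
    stop("need at least 2 lineages with data")
  tab$species <- factor(tab$species,
                        levels = intersect(c("PURE_B", "PURE_A", "F1"),
                                           unique(tab$species)))
  single_site <- length(unique(tab$site)) == 1
  singular <- FALSE
  if (single_site) {
    fit <- stats::glm(cbind(G, n - G) ~ species, family = stats::binomial,
                      data = tab)
    co <- summary(fit)$coefficients
  } else {
    fit <- lme4::glmer(cbind(G, n - G) ~ species + (1 | site),
                       family = stats::binomial, data = tab,
                       control = lme4::glmerControl(
                         check.conv.singular = "ignore"))
    singular <- lme4::isSingular(fit)
    co <- summary(fit)$coefficients
  }
  rows <- grep("^species", rownames(co), value = TRUE)
  label <- function(r) {
    sp <- sub("^species", "", r)
    pretty <- c(PURE_A = "T. latifolia", PURE_B = "T. angustifolia",
                F1 = "T. x glauca")
    paste0(pretty[[levels(tab$species)[1]]], " vs. ", pretty[[sp]])
  }
  contrasts <- data.frame(
    contrast = vapply(rows, label, character(1)),
    level = sub("^species", "", rows),
    estimate = co[rows, "Estimate"],
    se = co[rows, "Std. Error"],
    z = co[rows, grep("z value", colnames(co), value = TRUE)],
    p = co[rows, grep("^Pr", colnames(co), value = TRUE)],
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(contrasts = contrasts, singular = singular,
                 single_site = single_site, model = fit),
            class = "hz_glmm")
}

#' @export
print.hz_glmm <- function(x, ...) {
  cat("Genotypic-diversity binomial GLMM",
      if (x$single_site) "(single site: plain GLM)", "\n")
  for (i in seq_len(nrow(x$contrasts)))
    cat(sprintf("  %s: estimate = %.3f +/- %.3f SE, Wald Z = %.2f, P = %.3g\n",
                x$contrasts$contrast[i], x$contrasts$estimate[i],
                x$contrasts$se[i], x$contrasts$z[i], x$contrasts$p[i]))
  if (x$singular) cat("  note: site variance estimated at ~0\n")
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' \eqn{D} is the maximum absolute difference between the two empirical
#' cumulative distribution functions, evaluated over the pooled sample
#' points; the p-value uses the asymptotic Kolmogorov distribution with
#' effective sample size \eqn{mn/(m+n)}.  Ties between the samples are
#' reported with a warning (the asymptotic p-value is then conservative).
#'
#' @param x,y numeric samples (both non-empty).
#' @return Object of class \code{hz_ks}: list with \code{D}, \code{p_value},
#'   \code{n_x}, \code{n_y}, \code{ties}.
#' @export
ks_compare <- function(x, y) {
  if (length(x) == 0 || length(y) == 0)
    stop("both samples must be non-empty")
  if (anyNA(x) || anyNA(y)) stop("samples must not contain NA")
  ties <- length(intersect(x, y)) > 0
  if (ties) warning("samples share tied values; p-value is approximate")
  pts <- sort(unique(c(x, y)))
  Fx <- findInterval(pts, sort(x)) / length(x)
  Fy <- findInterval(pts, sort(y)) / length(y)
  D <- max(abs(Fx - Fy))
  n_eff <- length(x) * length(y) / (length(x) + length(y))
  t <- sqrt(n_eff) * D
  if (t == 0) {
    p <- 1
  } else {
    k <- 1:100
    p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))
    p <- min(1, max(0, p))
  }
  structure(list(D = D, p_value = p, n_x = length(x), n_y = length(y),
                 ties = ties), class = "hz_ks")
}

#' @export
print.hz_ks <- function(x, ...) {
  cat(sprintf("Two-sample KS: D = %.3f, P = %.3g (n = %d vs %d)%s\n",
              x$D, x$p_value, x$n_x, x$n_y,
              if (x$ties) " [ties present]" else ""))
  invisible(x)
}
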