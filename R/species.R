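#' Score one locus against the diagnostic key
#'
#' @param call integer vector of two allele sizes (a non-missing codominant
#'   call at one locus).
#' @param key a \code{diagnostic_key}.
#' @param locus locus name; must be present in the key.
#' @return One of \code{"AA"} (both alleles private to species A),
#'   \code{"BB"}, \code{"AB"} (one from each), or \code{"ambiguous"} (any
#'   allele absent from the key at that locus).
#' @export
score_locus <- function(call, key, locus) {
  if (!locus %in% names(key))
    stop("locus '", locus, "' is not in the diagnostic key")
  if (length(call) != 2 || anyNA(call))
    stop("call must be a non-missing pair of alleles")
  inA <- call %in% key[[locus]]$A
  inB <- call %in% key[[locus]]$B
  if (all(inA)) return("AA")
  if (all(inB)) return("BB")
  if (sum(inA) == 1 && sum(inB) == 1) return("AB")
  "ambiguous"
}

#' Classify per-locus evidence into a lineage category
#'
#' Deterministic rule over the six-locus evidence vector: \code{PURE_A} iff
#' every locus scores \code{AA}; \code{PURE_B} iff every locus scores
#' \code{BB}; \code{F1} iff every locus scores \code{AB} (one allele from
#' each parental species at all loci); \code{UNRESOLVED} iff any locus is
#' \code{ambiguous}; otherwise \code{LATER_GEN} (a backcross or advanced
#' intercross pattern).
#'
#' @param evidence character vector of per-locus scores
#'   (\code{"AA"}, \code{"BB"}, \code{"AB"}, \code{"ambiguous"}).
#' @return Category string.
#' @export
classify_evidence <- function(evidence) {
  stopifnot(all(evidence %in% c("AA", "BB", "AB", "ambiguous")))
  if (any(evidence == "ambiguous")) return("UNRESOLVED")
  if (all(evidence == "AA")) return("PURE_A")
  if (all(evidence == "BB")) return("PURE_B")
  if (all(evidence == "AB")) return("F1")
  "LATER_GEN"
}

#' Classify a single ramet from its multilocus genotype
#'
#' @param genotype named list mapping each locus to an allele pair (as
#'   returned by [get_genotype()]); must be complete (no missing loci) —
#'   run [drop_incomplete()] first.
#' @param key a \code{diagnostic_key} covering all loci of the genotype.
#' @return List with \code{category} (see [classify_evidence()]) and
#'   \code{evidence}, the named per-locus score vector.
#' @export
classify_ramet <- function(genotype, key) {
  if (any(vapply(genotype, function(g) length(g) < 2 || anyNA(g), logical(1))))
    stop("genotype has missing loci; run drop_incomplete() first")
  evidence <- vapply(names(genotype),
                     function(loc) score_locus(genotype[[loc]], key, loc),
                     character(1))
  list(category = classify_evidence(evidence), evidence = evidence)
}

#' Classify every ramet in a collection
#'
#' Vectorised application of the private-allele rule; fills the
#' \code{species_call} column and stores the per-locus evidence strings.
#'
#' @param collection a \code{study_collection} with complete genotypes.
#' @param key a \code{diagnostic_key}.
#' @return The collection with \code{species_call} set; attribute
#'   \code{"evidence"} holds a character matrix (ramet x locus) of per-locus
#'   scores.
#' @export
classify_collection <- function(collection, key) {
  loci <- collection$loci
  miss <- setdiff(loci, names(key))
  if (length(miss) > 0)
    stop("diagnostic key lacks locus/loci: ", paste(miss, collapse = ", "))
  rec <- collection$records
  n <- nrow(rec)
  ev <- matrix("ambiguous", n, length(loci), dimnames = list(rec$ramet_id, loci))
  for (k in seq_along(loci)) {
    loc <- loci[k]
    a1 <- rec[[paste0(loc, "_1")]]; a2 <- rec[[paste0(loc, "_2")]]
    if (anyNA(a1) || anyNA(a2))
      stop("genotypes have missing loci; run drop_incomplete() first")
    inA1 <- a1 %in% key[[loc]]$A; inA2 <- a2 %in% key[[loc]]$A
    inB1 <- a1 %in% key[[loc]]$B; inB2 <- a2 %in% key[[loc]]$B
    s <- rep("ambiguous", n)
    s[inA1 & inA2] <- "AA"
    s[inB1 & inB2] <- "BB"
    s[(inA1 & inB2) | (inB1 & inA2)] <- "AB"
    ev[, k] <- s
  }
  n_amb <- rowSums(ev == "ambiguous")
  n_aa <- rowSums(ev == "AA"); n_bb <- rowSums(ev == "BB")
  n_ab <- rowSums(ev == "AB")
  L <- length(loci)
  cat_ <- rep("LATER_GEN", n)
  cat_[n_amb > 0] <- "UNRESOLVED"
  cat_[n_aa == L] <- "PURE_A"
  cat_[n_bb == L] <- "PURE_B"
  cat_[n_ab == L] <- "F1"
  rec$species_call <- if (n > 0) cat_ else character(0)
  out <- study_collection(rec, loci)
  attr(out, "evidence") <- ev
  out
}

#' Lineage frequency table
#'
#' Counts of ramets per lineage category, overall and per site.  Later
#' generation hybrids (backcrosses and advanced intercrosses) are a single
#' pooled class.
#'
#' @param collection a classified \code{study_collection}.
#' @return List with \code{total} (named integer vector over all five
#'   categories) and \code{by_site} (site x category integer matrix).
#' @export
lineage_frequencies <- function(collection) {
  rec <- collection$records
  if (nrow(rec) > 0 && anyNA(rec$species_call))
    stop("collection contains unclassified records; ",
         "run classify_collection() first")
  cats <- factor(rec$species_call, levels = HZ_CATEGORIES)
  total <- table(cats)
  by_site <- table(factor(rec$site_id), cats)
  list(total = stats::setNames(as.integer(total), HZ_CATEGORIES),
       by_site = unclass(by_site))
}

#' Pairwise Smouse-Peakall squared genotypic distance
#'
#' Per-locus squared distance between two codominant diploid calls takes the
#' values 0 (identical genotypes), 1 (one shared allele: AA vs AB, or AB vs
#' AC), 2 (heterozygotes with no shared allele: AB vs CD), 3 (AA vs BC), or
#' 4 (opposite homozygotes: AA vs BB); loci are summed.  This is the squared
#' Euclidean distance between half-scaled allele-count vectors, so the
#' resulting matrix is embeddable and its principal-coordinates eigenvalues
#' are non-negative.
#'
#' @param collection a \code{study_collection} with complete genotypes.
#' @return A symmetric numeric matrix of summed squared distances with
#'   ramet_id dimnames.
#' @export
genotypic_distance <- function(collection) {
  rec <- collection$records
  n <- nrow(rec)
  D2 <- matrix(0, n, n, dimnames = list(rec$ramet_id, rec$ramet_id))
  for (loc in collection$loci) {
    a1 <- rec[[paste0(loc, "_1")]]; a2 <- rec[[paste0(loc, "_2")]]
    if (anyNA(a1) || anyNA(a2))
      stop("genotypes have missing loci; run drop_incomplete() first")
    alleles <- sort(unique(c(a1, a2)))
    # allele-count matrix (n x n_alleles), row sums are 2
    cnt <- matrix(0L, n, length(alleles))
    cnt[cbind(seq_len(n), match(a1, alleles))] <-
      cnt[cbind(seq_len(n), match(a1, alleles))] + 1L
    cnt[cbind(seq_len(n), match(a2, alleles))] <-
      cnt[cbind(seq_len(n), match(a2, alleles))] + 1L
    # squared Euclidean distance of count vectors, halved
    g <- tcrossprod(cnt)
    sq <- diag(g)
    D2 <- D2 + (outer(sq, sq, "+") - 2 * g) / 2
  }
  D2
}

#' Principal coordinates ordination of multilocus genotypes
#'
#' Eigen-decomposition (Gower double-centering, via [stats::cmdscale()]) of
#' the pairwise Smouse-Peakall squared genotypic distance matrix — the
#' standard codominant-genotype ordination.  Axis signs are arbitrary; use
#' [corroborate()] to fix the orientation against species calls.
#'
#' @param collection a \code{study_collection} with at least 3 complete
#'   genotypes.
#' @param k number of axes to return (default 2).
#' @return Object of class \code{hz_ordination}: list with \code{coords}
#'   (ramet x axis matrix, centered), \code{var_explained} (fraction of
#'   total positive eigenvalue per returned axis), and \code{eig} (all
#'   eigenvalues, non-increasing).
#' @export
ordinate <- function(collection, k = 2) {
  n <- nrow(collection$records)
  if (n < 3) stop("ordination needs at least 3 genotypes")
  D2 <- genotypic_distance(collection)
  if (all(D2 == 0))
    stop("degenerate ordination: all genotypes are identical")
  # cmdscale squares its input internally; feed the unsquared distance
  mds <- stats::cmdscale(sqrt(D2), k = min(k, n - 1), eig = TRUE)
  eig <- mds$eig
  pos <- sum(eig[eig > 0])
  coords <- mds$points
  colnames(coords) <- paste0("axis", seq_len(ncol(coords)))
  structure(list(coords = coords,
                 var_explained = pmax(eig[seq_len(ncol(coords))], 0) / pos,
                 eig = eig),
            class = "hz_ordination")
}

#' @export
print.hz_ordination <- function(x, ...) {
  cat("Genotypic PCoA:", nrow(x$coords), "ramets,",
      ncol(x$coords), "axes\n")
  cat("  variance explained:",
      paste(sprintf("%.1f%%", 100 * x$var_explained), collapse = ", "), "\n")
  invisible(x)
}

#' Corroborate species calls against the ordination
#'
#' Orients axis 1 so the PURE_A (T. latifolia) cluster has the lower mean,
#' then reports how well the private-allele calls separate along it: the
#' fraction of PURE_A ramets with score below \code{-threshold}, of PURE_B
#' above \code{+threshold}, and of F1 in between, together with the ramets
#' that fall on the wrong side (discordant).
#'
#' @param calls character vector of lineage categories, aligned with the
#'   ordination rows.
#' @param ordination an \code{hz_ordination}.
#' @param threshold positive axis-1 cutoff (the customary value is 0.4).
#' @return List with \code{axis1} (oriented scores), \code{concordance}
#'   (named fractions for PURE_A, PURE_B, F1; \code{NaN} when a class is
#'   absent), and \code{discordant} (ramet_ids outside their class band).
#' @export
corroborate <- function(calls, ordination, threshold = 0.4) {
  if (threshold <= 0) stop("threshold must be positive")
  ax1 <- ordination$coords[, 1]
  if (length(calls) != length(ax1))
    stop("calls and ordination rows are not aligned")
  informative <- calls %in% c("PURE_A", "PURE_B", "F1")
  if (!any(informative)) {
    warning("no PURE_A/PURE_B/F1 calls; concordance report is empty")
    return(list(axis1 = ax1,
                concordance = c(PURE_A = NaN, PURE_B = NaN, F1 = NaN),
                discordant = character(0)))
  }
  # sign convention: T. latifolia (PURE_A) on the negative side of axis 1
  if (any(calls == "PURE_A")) {
    if (mean(ax1[calls == "PURE_A"]) > 0) ax1 <- -ax1
  } else if (any(calls == "PURE_B")) {
    if (mean(ax1[calls == "PURE_B"]) < 0) ax1 <- -ax1
  }
  in_band <- function(cat_, ok) {
    idx <- calls == cat_
    if (!any(idx)) return(list(frac = NaN, bad = character(0)))
    good <- ok(ax1[idx])
    list(frac = mean(good), bad = names(ax1)[idx][!good])
  }
  a <- in_band("PURE_A", function(z) z < -threshold)
  b <- in_band("PURE_B", function(z) z > threshold)
  f <- in_band("F1", function(z) z >= -threshold & z <= threshold)
  list(axis1 = ax1,
       concordance = c(PURE_A = a$frac, PURE_B = b$frac, F1 = f$frac),
       discordant = c(a$bad, b$bad, f$bad))
}
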