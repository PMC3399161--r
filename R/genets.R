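#' Allele-copy mismatch distance between two multilocus genotypes
#'
#' Counts, summed over loci, the allele copies of one genotype that cannot
#' be matched to a copy of the other at the same locus (multiset
#' difference).  Symmetric; ranges 0-12 for six diploid loci.  A distance of
#' 1 is the classic "differing by only one allele" signature of a single
#' genotyping error between ramets of the same genet.
#'
#' @param g1,g2 named lists mapping each locus to a complete allele pair
#'   (see [get_genotype()]); the two genotypes must cover the same loci.
#' @return Non-negative integer.
#' @export
allele_mismatch_distance <- function(g1, g2) {
  if (!setequal(names(g1), names(g2)))
    stop("genotypes cover different locus sets")
  d <- 0L
  for (loc in names(g1)) {
    a <- g1[[loc]]; b <- g2[[loc]]
    if (anyNA(a) || anyNA(b)) stop("genotypes must be complete at all loci")
    d <- d + pair_mismatch(a, b)
  }
  d
}

# multiset difference size for two sorted allele pairs: 2 - |intersection|
pair_mismatch <- function(a, b) {
  if (a[1] == b[1] && a[2] == b[2]) return(0L)
  shared <- 0L
  bb <- b
  for (x in a) {
    j <- match(x, bb)
    if (!is.na(j)) { shared <- shared + 1L; bb <- bb[-j] }
  }
  2L - shared
}

# n x n integer matrix of allele-copy mismatches from an allele matrix
# (rows = ramets, 2 columns per locus, alleles sorted within locus)
mismatch_matrix <- function(am) {
  n <- nrow(am)
  L <- ncol(am) / 2
  D <- matrix(0L, n, n, dimnames = list(rownames(am), rownames(am)))
  for (k in seq_len(L)) {
    a1 <- am[, 2 * k - 1]; a2 <- am[, 2 * k]
    # shared copies between sorted pairs (x1,x2), (y1,y2):
    # both equal -> 2; else count one shared copy if any cross-match exists
    e11 <- outer(a1, a1, "=="); e22 <- outer(a2, a2, "==")
    e12 <- outer(a1, a2, "=="); e21 <- outer(a2, a1, "==")
    both <- e11 & e22
    any1 <- e11 | e22 | e12 | e21
    shared <- matrix(0L, n, n)
    shared[any1] <- 1L
    shared[both] <- 2L
    D <- D + (2L - shared)
  }
  D
}

#' Partition ramets into genets
#'
#' Within each site, ramets whose genotypes differ by at most
#' \code{max_mismatch} allele copies are linked, and genets are the
#' connected components of the resulting graph (single-linkage transitive
#' closure).  With \code{max_mismatch = 0} genets are exact-genotype
#' equivalence classes; the default of 1 absorbs single-allele genotyping
#' errors.  Genets never span sites.  Genet IDs are canonical — the
#' lexicographically smallest ramet_id in the component, prefixed by the
#' site — so the partition and its labels are invariant to record order.
#'
#' @param collection a \code{study_collection} with complete genotypes.
#' @param max_mismatch non-negative integer mismatch tolerance (default 1).
#' @return A \code{genet_assignment}: list with \code{genet_id} (named
#'   character vector, ramet_id -> genet ID) and \code{max_mismatch}.
#' @export
infer_genets <- function(collection, max_mismatch = 1) {
  stopifnot(max_mismatch >= 0)
  rec <- collection$records
  am <- allele_matrix(collection)
  if (nrow(am) > 0 && anyNA(am))
    stop("genotypes have missing loci; run drop_incomplete() first")
  out <- rep(NA_character_, nrow(rec))
  names(out) <- rec$ramet_id
  for (site in unique(rec$site_id)) {
    idx <- which(rec$site_id == site)
    ids <- rec$ramet_id[idx]
    if (length(idx) == 1) {
      out[idx] <- paste0(site, ":", ids)
      next
    }
    D <- mismatch_matrix(am[idx, , drop = FALSE])
    # connected components at threshold = single-linkage dendrogram cut
    hc <- stats::hclust(stats::as.dist(D), method = "single")
    comp <- stats::cutree(hc, h = max_mismatch + 0.5)
    labels <- vapply(split(ids, comp), min, character(1))
    out[idx] <- paste0(site, ":", labels[as.character(comp)])
  }
  structure(list(genet_id = out, max_mismatch = max_mismatch),
            class = "genet_assignment")
}

#' @export
print.genet_assignment <- function(x, ...) {
  cat("Genet assignment:", length(x$genet_id), "ramets in",
      length(unique(x$genet_id)), "genets",
      sprintf("(max_mismatch = %d)\n", x$max_mismatch))
  invisible(x)
}

#' Attach genet IDs to a study collection
#'
#' @param collection a \code{study_collection}.
#' @param genets a \code{genet_assignment} from [infer_genets()].
#' @return The collection with its \code{genet_id} column filled.
#' @export
assign_genets <- function(collection, genets) {
  rec <- collection$records
  rec$genet_id <- unname(genets$genet_id[rec$ramet_id])
  study_collection(rec, collection$loci)
}

#' Genotypic richness
#'
#' \eqn{R = (G - 1) / (n - 1)}: 0 when all \eqn{n} ramets in a sample belong
#' to one genet (monoclonal), 1 when every ramet is a distinct genet.
#'
#' @param G number of distinct genets detected (1 <= G <= n).
#' @param n number of ramets sampled.
#' @return Numeric in [0, 1]; \code{NA} for \code{n = 1}, where the index is
#'   undefined.
#' @export
genet_richness <- function(G, n) {
  if (any(G < 1) || any(G > n)) stop("G must satisfy 1 <= G <= n")
  ifelse(n == 1, NA_real_, (G - 1) / (n - 1))
}

#' Genotypic richness per species per site
#'
#' One record per (lineage, site) pair with at least one ramet: the number
#' of genets \code{G}, ramets \code{n}, and richness \code{R}
#' (see [genet_richness()]; \code{NA} for singleton samples).  Per-species
#' summaries are unweighted means across sites with defined \code{R}, with
#' the standard error \code{sd / sqrt(number of sites)}.
#'
#' @param collection a classified \code{study_collection}.
#' @param genets a \code{genet_assignment}.
#' @param categories lineage categories to tabulate (default: the three
#'   species classes PURE_A, PURE_B, F1).
#' @return List with \code{table} (data frame: species, site, G, n, R) and
#'   \code{summary} (data frame: species, mean_R, se_R, n_sites).
#' @export
richness_by_species_site <- function(collection, genets,
                                     categories = c("PURE_A", "PURE_B",
                                                    "F1")) {
  rec <- collection$records
  if (nrow(rec) > 0 && anyNA(rec$species_call))
    stop("collection contains unclassified records")
  gid <- genets$genet_id[rec$ramet_id]
  keep <- rec$species_call %in% categories
  rows <- list()
  for (sp in categories) {
    for (site in unique(rec$site_id[keep & rec$species_call == sp])) {
      idx <- keep & rec$species_call == sp & rec$site_id == site
      n <- sum(idx)
      G <- length(unique(gid[idx]))
      rows[[length(rows) + 1]] <-
        data.frame(species = sp, site = site, G = G, n = n,
                   R = genet_richness(G, n), stringsAsFactors = FALSE)
    }
  }
  tab <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(species = character(0), site = character(0), G = integer(0),
               n = integer(0), R = numeric(0))
  summ <- do.call(rbind, lapply(categories, function(sp) {
    r <- tab$R[tab$species == sp & !is.na(tab$R)]
    data.frame(species = sp,
               mean_R = if (length(r) > 0) mean(r) else NA_real_,
               se_R = if (length(r) > 1) stats::sd(r) / sqrt(length(r))
                      else NA_real_,
               n_sites = length(r), stringsAsFactors = FALSE)
  }))
  list(table = tab, summary = summ)
}
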