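# Shared fixture builders and independent oracles.

hz_loci <- c("TA3", "TA5", "TA7", "TA8", "TA16", "TA20")

# A fully diagnostic key: at every locus, alleles 101/103 private to A
# (T. latifolia), 111/113 private to B (T. angustifolia).
fixture_key <- function(loci = hz_loci) {
  diagnostic_key(do.call(rbind, lapply(loci, function(loc)
    data.frame(locus = loc, allele = c(101L, 103L, 111L, 113L),
               species = c("A", "A", "B", "B")))))
}

# Build a study_collection from an n x 2L allele matrix.
collection_from_matrix <- function(am, loci = hz_loci, site = "S1",
                                   elev = NULL, height = 150) {
  n <- nrow(am)
  rec <- data.frame(ramet_id = sprintf("R%03d", seq_len(n)),
                    site_id = rep_len(site, n),
                    elevation_mm = if (is.null(elev)) seq_len(n) * 10L
                                   else as.integer(elev),
                    height_cm = rep_len(height, n),
                    stringsAsFactors = FALSE)
  for (j in seq_along(loci)) {
    pair <- am[, c(2 * j - 1, 2 * j), drop = FALSE]
    rec[[paste0(loci[j], "_1")]] <- pmin(pair[, 1], pair[, 2])
    rec[[paste0(loci[j], "_2")]] <- pmax(pair[, 1], pair[, 2])
  }
  study_collection(rec, loci)
}

# Per-lineage genotype rows under fixture_key (one row = 12 alleles).
geno_row <- function(pattern, loci = hz_loci) {
  stopifnot(length(pattern) == length(loci))
  unlist(lapply(pattern, function(p) switch(p,
    AA = c(101L, 103L), BB = c(111L, 113L), AB = c(101L, 111L),
    XX = c(901L, 903L))))
}

# Independent mismatch-distance oracle: per locus, multiset difference size
# computed by exhaustive matching over allele tables.
oracle_mismatch <- function(r1, r2) {
  L <- length(r1) / 2
  d <- 0L
  for (j in seq_len(L)) {
    a <- r1[c(2 * j - 1, 2 * j)]; b <- r2[c(2 * j - 1, 2 * j)]
    ta <- table(a); tb <- table(b)
    shared <- 0L
    for (al in intersect(names(ta), names(tb)))
      shared <- shared + min(ta[[al]], tb[[al]])
    d <- d + 2L - shared
  }
  d
}

# Independent connected-components oracle: union-find over all pairs.
oracle_components <- function(am, max_mismatch) {
  n <- nrow(am)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (oracle_mismatch(am[i, ], am[j, ]) <= max_mismatch) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# Same partition up to relabelling?
same_partition <- function(a, b) {
  identical(as.integer(factor(a, levels = unique(a))),
            as.integer(factor(b, levels = unique(b))))
}

# Random small allele matrix drawing from a tight pool so that chains and
# near-duplicates actually occur.
random_small_matrix <- function(n, n_loci = 3, pool = c(101L, 103L, 105L)) {
  m <- matrix(sample(pool, n * 2 * n_loci, replace = TRUE), nrow = n)
  # sort allele pairs within each locus
  for (j in seq_len(n_loci)) {
    c1 <- 2 * j - 1; c2 <- 2 * j
    lo <- pmin(m[, c1], m[, c2]); hi <- pmax(m[, c1], m[, c2])
    m[, c1] <- lo; m[, c2] <- hi
  }
  m
}

# Exhaustive two-sample ECDF oracle for the KS statistic.
oracle_ks_D <- function(x, y) {
  pts <- c(x, y)
  max(vapply(pts, function(t) abs(mean(x <= t) - mean(y <= t)), numeric(1)))
}

# Evidence-level classification rule table, written out case by case.
oracle_rule <- function(ev) {
  n_aa <- sum(ev == "AA"); n_bb <- sum(ev == "BB")
  n_ab <- sum(ev == "AB"); n_amb <- sum(ev == "ambiguous")
  L <- length(ev)
  if (n_amb > 0) return("UNRESOLVED")
  if (n_aa == L) return("PURE_A")
  if (n_bb == L) return("PURE_B")
  if (n_ab == L) return("F1")
  "LATER_GEN"
}
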