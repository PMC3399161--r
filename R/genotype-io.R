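# Lineage categories used throughout.  PURE_A = T. latifolia,
# PURE_B = T. angustifolia, F1 = T. x glauca.
HZ_CATEGORIES <- c("PURE_A", "PURE_B", "F1", "LATER_GEN", "UNRESOLVED")

#' Construct a study collection of ramet records
#'
#' A study collection is the central container of the package: one row per
#' sampled ramet (shoot) holding its site, shoot elevation (integer
#' millimetres), shoot height (cm, length of the longest leaf), a six-locus
#' codominant microsatellite genotype (two integer allele sizes per locus,
#' stored sorted ascending; \code{NA} marks a locus that failed to amplify),
#' and two slots filled by downstream stages: \code{species_call} and
#' \code{genet_id}.
#'
#' @param records data frame with columns \code{ramet_id}, \code{site_id},
#'   \code{elevation_mm}, \code{height_cm}, two integer columns per locus
#'   named \code{<locus>_1}, \code{<locus>_2}, and optionally
#'   \code{species_call} and \code{genet_id}.
#' @param loci character vector of locus names, in display order.
#' @return An object of class \code{study_collection}: a list with elements
#'   \code{records} (the validated data frame) and \code{loci}.
#' @examples
#' rec <- data.frame(ramet_id = "R1", site_id = "S1", elevation_mm = 100L,
#'                   height_cm = 150, TA3_1 = 101L, TA3_2 = 105L)
#' study_collection(rec, loci = "TA3")
#' @export
study_collection <- function(records, loci) {
  stopifnot(is.data.frame(records), is.character(loci), length(loci) >= 1)
  base_cols <- c("ramet_id", "site_id", "elevation_mm", "height_cm")
  missing_cols <- setdiff(base_cols, names(records))
  if (length(missing_cols) > 0)
    stop("records is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  allele_cols <- allele_colnames(loci)
  missing_loci <- setdiff(allele_cols, names(records))
  if (length(missing_loci) > 0)
    stop("records is missing allele column(s): ",
         paste(missing_loci, collapse = ", "))
  records$ramet_id <- as.character(records$ramet_id)
  records$site_id <- as.character(records$site_id)
  if (anyDuplicated(records$ramet_id))
    stop("duplicate ramet_id: ",
         paste(unique(records$ramet_id[duplicated(records$ramet_id)]),
               collapse = ", "))
  if (any(!nzchar(records$site_id)) || anyNA(records$site_id))
    stop("site_id must be non-empty for every record")
  records$elevation_mm <- as.integer(records$elevation_mm)
  records$height_cm <- as.numeric(records$height_cm)
  if (nrow(records) > 0 &&
      (anyNA(records$elevation_mm) || any(!is.finite(records$height_cm))))
    stop("elevation_mm and height_cm must be finite for every record")
  if (is.null(records$species_call))
    records$species_call <- rep(NA_character_, nrow(records))
  if (is.null(records$genet_id))
    records$genet_id <- rep(NA_character_, nrow(records))
  for (loc in loci) {
    a1 <- paste0(loc, "_1"); a2 <- paste0(loc, "_2")
    v1 <- as.integer(records[[a1]]); v2 <- as.integer(records[[a2]])
    bad <- !is.na(v1) & v1 <= 0; v1[bad] <- NA_integer_
    bad <- !is.na(v2) & v2 <= 0; v2[bad] <- NA_integer_
    # a call is either complete (two alleles) or missing
    half <- xor(is.na(v1), is.na(v2))
    v1[half] <- NA_integer_; v2[half] <- NA_integer_
    # canonical order: sorted ascending
    swap <- !is.na(v1) & v1 > v2
    tmp <- v1[swap]; v1[swap] <- v2[swap]; v2[swap] <- tmp
    records[[a1]] <- v1; records[[a2]] <- v2
  }
  keep <- c(base_cols, "species_call", "genet_id", allele_cols)
  records <- records[, keep, drop = FALSE]
  rownames(records) <- NULL
  structure(list(records = records, loci = loci),
            class = "study_collection")
}

allele_colnames <- function(loci) {
  as.vector(rbind(paste0(loci, "_1"), paste0(loci, "_2")))
}

#' @export
print.study_collection <- function(x, ...) {
  cat("Study collection:", nrow(x$records), "ramets,",
      length(unique(x$records$site_id)), "sites,",
      length(x$loci), "loci (", paste(x$loci, collapse = ", "), ")\n")
  n_missing <- sum(!stats::complete.cases(
    x$records[, allele_colnames(x$loci), drop = FALSE]))
  if (n_missing > 0)
    cat(" ", n_missing, "ramet(s) with at least one missing locus\n")
  invisible(x)
}

#' Number of ramets in a study collection
#' @param x a \code{study_collection}.
#' @return Integer count of records.
#' @export
n_ramets <- function(x) nrow(x$records)

#' Extract one multilocus genotype
#'
#' @param x a \code{study_collection}.
#' @param i row index or ramet_id.
#' @return Named list mapping each locus to a sorted integer allele pair, or
#'   \code{NA} where the locus is missing.
#' @export
get_genotype <- function(x, i) {
  if (is.character(i)) i <- match(i, x$records$ramet_id)
  row <- x$records[i, , drop = FALSE]
  out <- lapply(x$loci, function(loc) {
    a <- c(row[[paste0(loc, "_1")]], row[[paste0(loc, "_2")]])
    if (anyNA(a)) NA else a
  })
  names(out) <- x$loci
  out
}

#' Allele matrix of a study collection
#'
#' @param x a \code{study_collection}.
#' @return Integer matrix, one row per ramet and two columns per locus
#'   (alleles sorted ascending within locus), rownames = ramet_id.
#' @export
allele_matrix <- function(x) {
  m <- as.matrix(x$records[, allele_colnames(x$loci), drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- x$records$ramet_id
  m
}

#' Read a ramet-level genotype table
#'
#' Two dialects are supported.  \code{"genalex"} is a codominant-genotype
#' layout with two columns per locus and \code{0} as the missing-allele
#' marker: line 1 carries three counts (loci, samples, sites), line 2 the
#' column header with each locus name over the first of its two allele
#' columns.  \code{"long"} is a plain CSV with one row per ramet x locus and
#' columns \code{ramet_id, site_id, elevation_mm, height_cm, locus, allele1,
#' allele2}.  Non-integer allele tokens are never coerced: they become
#' missing calls and are counted in the \code{"n_unparseable"} attribute of
#' the result.
#'
#' @param path CSV file path.
#' @param loci expected locus names; checked against the file header.
#'   \code{NULL} accepts the loci found in the file.
#' @param format \code{"genalex"} (default) or \code{"long"}.
#' @return A \code{study_collection}; attribute \code{"n_unparseable"} counts
#'   allele tokens that could not be parsed as positive integers.
#' @seealso [write_genotype_table()], [drop_incomplete()]
#' @export
read_genotype_table <- function(path, loci = NULL,
                                format = c("genalex", "long")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "genalex") read_genalex(path, loci) else read_long(path, loci)
}

parse_allele <- function(tok) {
  # strict: positive integer strings only; anything else is a missing call
  tok <- trimws(tok)
  ok <- grepl("^[0-9]+$", tok)
  v <- rep(NA_integer_, length(tok))
  v[ok] <- as.integer(tok[ok])
  v[!is.na(v) & v == 0] <- NA_integer_  # 0 is the GenAlEx missing marker
  v
}

read_genalex <- function(path, loci) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("malformed file: fewer than 2 header lines")
  split_row <- function(line, width = NULL) {
    # strsplit drops trailing empty fields; pad back to the comma count
    z <- strsplit(line, ",", fixed = TRUE)[[1]]
    w <- if (is.null(width)) nchar(gsub("[^,]", "", line)) + 1L else width
    c(z, rep("", max(0L, w - length(z))))
  }
  header <- split_row(lines[2])
  base_cols <- c("ramet_id", "site_id", "elevation_mm", "height_cm")
  for (col in base_cols)
    if (!col %in% header) stop("malformed header: missing column '", col, "'")
  n_base <- length(base_cols)
  rest <- header[-seq_len(n_base)]
  has_extra <- length(rest) >= 2 &&
    identical(utils::tail(rest, 2), c("species_call", "genet_id"))
  if (has_extra) rest <- rest[seq_len(length(rest) - 2)]
  file_loci <- rest[nzchar(rest)]
  if (length(rest) %% 2 != 0 ||
      !all(nzchar(rest[seq(1, length(rest), by = 2)])) ||
      any(nzchar(rest[seq(2, length(rest), by = 2)])))
    stop("malformed header: locus names must span two columns each")
  if (!is.null(loci)) {
    miss <- setdiff(loci, file_loci)
    if (length(miss) > 0)
      stop("malformed header: missing locus column '",
           paste(miss, collapse = "', '"), "'")
    file_loci <- loci
  }
  body <- if (length(lines) > 2) lines[-(1:2)] else character(0)
  body <- body[nzchar(body)]
  n_unparseable <- 0L
  if (length(body) == 0) {
    rec <- empty_records(file_loci)
  } else {
    width <- length(header)
    m <- do.call(rbind, lapply(body, split_row, width = width))
    rec <- data.frame(ramet_id = m[, 1], site_id = m[, 2],
                      elevation_mm = as.integer(m[, 3]),
                      height_cm = as.numeric(m[, 4]),
                      stringsAsFactors = FALSE)
    for (k in seq_along(file_loci)) {
      j <- n_base + 2 * (k - 1) + 1
      a1 <- parse_allele(m[, j]); a2 <- parse_allele(m[, j + 1])
      n_unparseable <- n_unparseable +
        sum(is.na(a1) & !(trimws(m[, j]) %in% c("0", ""))) +
        sum(is.na(a2) & !(trimws(m[, j + 1]) %in% c("0", "")))
      rec[[paste0(file_loci[k], "_1")]] <- a1
      rec[[paste0(file_loci[k], "_2")]] <- a2
    }
    if (has_extra) {
      sc <- m[, width - 1]; gi <- m[, width]
      sc[!nzchar(sc)] <- NA_character_; gi[!nzchar(gi)] <- NA_character_
      rec$species_call <- sc; rec$genet_id <- gi
    }
  }
  out <- study_collection(rec, file_loci)
  attr(out, "n_unparseable") <- n_unparseable
  out
}

read_long <- function(path, loci) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("ramet_id", "site_id", "elevation_mm", "height_cm",
            "locus", "allele1", "allele2")
  for (col in need)
    if (!col %in% names(df)) stop("malformed header: missing column '",
                                  col, "'")
  file_loci <- unique(df$locus)
  if (!is.null(loci)) {
    miss <- setdiff(loci, file_loci)
    if (length(miss) > 0 && nrow(df) > 0)
      stop("malformed header: missing locus column '",
           paste(miss, collapse = "', '"), "'")
    file_loci <- loci
  }
  ids <- unique(df$ramet_id)
  rec <- data.frame(ramet_id = ids, stringsAsFactors = FALSE)
  first <- df[match(ids, df$ramet_id), ]
  rec$site_id <- first$site_id
  rec$elevation_mm <- as.integer(first$elevation_mm)
  rec$height_cm <- as.numeric(first$height_cm)
  if ("species_call" %in% names(df)) {
    sc <- first$species_call; sc[!nzchar(sc)] <- NA_character_
    rec$species_call <- sc
  }
  if ("genet_id" %in% names(df)) {
    gi <- first$genet_id; gi[!nzchar(gi)] <- NA_character_
    rec$genet_id <- gi
  }
  n_unparseable <- 0L
  for (loc in file_loci) {
    sub <- df[df$locus == loc, ]
    idx <- match(ids, sub$ramet_id)
    a1 <- parse_allele(sub$allele1[idx]); a2 <- parse_allele(sub$allele2[idx])
    raw1 <- trimws(sub$allele1[idx]); raw2 <- trimws(sub$allele2[idx])
    n_unparseable <- n_unparseable +
      sum(is.na(a1) & !is.na(idx) & !(raw1 %in% c("0", ""))) +
      sum(is.na(a2) & !is.na(idx) & !(raw2 %in% c("0", "")))
    rec[[paste0(loc, "_1")]] <- a1
    rec[[paste0(loc, "_2")]] <- a2
  }
  if (length(ids) == 0) rec <- empty_records(file_loci)
  out <- study_collection(rec, file_loci)
  attr(out, "n_unparseable") <- n_unparseable
  out
}

empty_records <- function(loci) {
  rec <- data.frame(ramet_id = character(0), site_id = character(0),
                    elevation_mm = integer(0), height_cm = numeric(0),
                    stringsAsFactors = FALSE)
  for (col in allele_colnames(loci)) rec[[col]] <- integer(0)
  rec
}

#' Write a ramet-level genotype table
#'
#' Inverse of [read_genotype_table()]: a collection written and re-read is
#' reproduced field-for-field (missing calls serialised as \code{0};
#' downstream \code{species_call}/\code{genet_id} columns appended only when
#' at least one record carries them).
#'
#' @param collection a \code{study_collection}.
#' @param path output CSV path.
#' @param format \code{"genalex"} (default) or \code{"long"}.
#' @return Invisibly, \code{path}.
#' @export
write_genotype_table <- function(collection, path,
                                 format = c("genalex", "long")) {
  format <- match.arg(format)
  rec <- collection$records
  loci <- collection$loci
  has_extra <- any(!is.na(rec$species_call)) || any(!is.na(rec$genet_id))
  if (format == "genalex") {
    header1 <- c(length(loci), nrow(rec), length(unique(rec$site_id)))
    locus_hdr <- as.vector(rbind(loci, rep("", length(loci))))
    header2 <- c("ramet_id", "site_id", "elevation_mm", "height_cm",
                 locus_hdr, if (has_extra) c("species_call", "genet_id"))
    am <- rec[, allele_colnames(loci), drop = FALSE]
    am[is.na(am)] <- 0L
    body <- cbind(rec$ramet_id, rec$site_id, rec$elevation_mm,
                  format_num(rec$height_cm),
                  as.matrix(am),
                  if (has_extra) cbind(na_blank(rec$species_call),
                                       na_blank(rec$genet_id)))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(header1, collapse = ","), con)
    writeLines(paste(header2, collapse = ","), con)
    if (nrow(rec) > 0)
      writeLines(apply(body, 1, paste, collapse = ","), con)
  } else {
    rows <- lapply(loci, function(loc) {
      data.frame(ramet_id = rec$ramet_id, site_id = rec$site_id,
                 elevation_mm = rec$elevation_mm,
                 height_cm = format_num(rec$height_cm), locus = loc,
                 allele1 = ifelse(is.na(rec[[paste0(loc, "_1")]]), 0L,
                                  rec[[paste0(loc, "_1")]]),
                 allele2 = ifelse(is.na(rec[[paste0(loc, "_2")]]), 0L,
                                  rec[[paste0(loc, "_2")]]),
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    if (has_extra) {
      df$species_call <- na_blank(rec$species_call)[
        match(df$ramet_id, rec$ramet_id)]
      df$genet_id <- na_blank(rec$genet_id)[match(df$ramet_id, rec$ramet_id)]
    }
    df <- df[order(match(df$ramet_id, rec$ramet_id)), ]
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

# full-precision serialisation so a write/read cycle is value-exact
format_num <- function(x) sprintf("%.17g", x)
na_blank <- function(x) ifelse(is.na(x), "", x)

#' Remove ramets with incompletely amplified genotypes
#'
#' Ramets whose genotype is missing at any locus are removed, mirroring the
#' standard practice of excluding samples that did not amplify fully across
#' all loci before classification and clonal assignment.
#'
#' @param collection a \code{study_collection}.
#' @return The filtered collection; attribute \code{"removed"} holds the
#'   ramet_ids of dropped records (possibly empty).  Idempotent.
#' @export
drop_incomplete <- function(collection) {
  am <- allele_matrix(collection)
  complete <- if (nrow(am) == 0) logical(0) else
    stats::complete.cases(am)
  removed <- collection$records$ramet_id[!complete]
  out <- study_collection(collection$records[complete, , drop = FALSE],
                          collection$loci)
  if (length(removed) == nrow(collection$records) && length(removed) > 0)
    warning("all records had at least one missing locus; ",
            "returning an empty collection")
  attr(out, "removed") <- removed
  out
}

#' Read a diagnostic allele key
#'
#' The key lists, per locus, the microsatellite alleles private to each
#' parental species (species \code{A} = T. latifolia, \code{B} =
#' T. angustifolia).  File format: CSV with columns \code{locus},
#' \code{allele}, \code{species} (values \code{A} or \code{B}).
#'
#' @param path CSV file path.
#' @return A \code{diagnostic_key}: named list, one element per locus, each
#'   a list with integer vectors \code{A} and \code{B}.
#' @export
read_diagnostic_key <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("locus", "allele", "species"))
    if (!col %in% names(df)) stop("malformed key: missing column '", col, "'")
  diagnostic_key(df)
}

#' Construct a diagnostic key from a data frame
#'
#' @param df data frame with columns \code{locus}, \code{allele} (positive
#'   integer), \code{species} (\code{"A"} or \code{"B"}).
#' @return A \code{diagnostic_key} object.
#' @export
diagnostic_key <- function(df) {
  if (!all(df$species %in% c("A", "B")))
    stop("key species values must be 'A' or 'B'")
  df$allele <- as.integer(df$allele)
  if (anyNA(df$allele) || any(df$allele <= 0))
    stop("key alleles must be positive integers")
  loci <- unique(df$locus)
  key <- lapply(loci, function(loc) {
    sub <- df[df$locus == loc, ]
    a <- sort(unique(sub$allele[sub$species == "A"]))
    b <- sort(unique(sub$allele[sub$species == "B"]))
    if (length(intersect(a, b)) > 0)
      stop("key not diagnostic at locus ", loc,
           ": allele(s) listed as private to both species")
    list(A = a, B = b)
  })
  names(key) <- loci
  structure(key, class = "diagnostic_key")
}

#' Write a diagnostic key to CSV
#' @param key a \code{diagnostic_key}.
#' @param path output CSV path.
#' @return Invisibly, \code{path}.
#' @export
write_diagnostic_key <- function(key, path) {
  rows <- lapply(names(key), function(loc) {
    data.frame(locus = loc,
               allele = c(key[[loc]]$A, key[[loc]]$B),
               species = rep(c("A", "B"),
                             c(length(key[[loc]]$A), length(key[[loc]]$B))),
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @export
print.diagnostic_key <- function(x, ...) {
  cat("Diagnostic key:", length(x), "loci\n")
  for (loc in names(x))
    cat(sprintf("  %s: %d allele(s) private to A, %d to B\n", loc,
                length(x[[loc]]$A), length(x[[loc]]$B)))
  invisible(x)
}
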