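# hapmap dialect: tab-separated, header "rs# alleles chrom pos" then one
# column per accession; single-letter genotype codes, "N" or "-" = missing.

IUPAC_HET <- c("R", "Y", "S", "W", "K", "M")

#' Read a hapmap-format genotype table
#'
#' Parses the tab-separated hapmap dialect (`rs#`, `alleles`, `chrom`, `pos`,
#' then one single-letter genotype column per accession). Calls are mapped to
#' REF/ALT using the two-allele code in the `alleles` column (e.g. `"A/G"`);
#' `"N"` and `"-"` map to missing. Because the package models inbred lines,
#' IUPAC heterozygote codes are set to missing with a warning. Markers whose
#' observed calls include more than two alleles, or alleles absent from the
#' `alleles` field, are rejected (not fatal) and enumerated in the
#' `"rejected"` attribute of the result.
#'
#' @param path path to a hapmap text file.
#' @return a [geno_matrix()], markers sorted by (chrom, pos), with attribute
#'   `rejected`: data frame of dropped marker ids and reasons.
#' @export
read_hapmap <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(header) < 5L || header[1] != "rs#" || header[2] != "alleles" ||
      header[3] != "chrom" || header[4] != "pos")
    stop("malformed hapmap header at line 1: expected 'rs#\talleles\tchrom\tpos\t<accessions...>'")
  tab <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    colClasses = "character", comment.char = "",
                    quote = "")
  acc <- header[-(1:4)]
  m <- nrow(tab)
  if (m == 0L) stop("hapmap file contains no markers")
  al <- strsplit(tab[[2]], "/", fixed = TRUE)
  bad_alleles <- vapply(al, length, 1L) != 2L
  if (any(bad_alleles))
    stop("malformed alleles field at data line(s): ",
         paste(which(bad_alleles), collapse = ", "))
  ref <- vapply(al, `[`, "", 1L)
  alt <- vapply(al, `[`, "", 2L)
  raw <- as.matrix(tab[, -(1:4), drop = FALSE])
  n_het <- sum(raw %in% IUPAC_HET)
  if (n_het > 0L) {
    warning(n_het, " IUPAC heterozygote call(s) set to missing (inbred-panel model)")
    raw[raw %in% IUPAC_HET] <- "N"
  }
  calls <- matrix(NA_integer_, m, length(acc))
  miss <- raw == "N" | raw == "-"
  calls[raw == matrix(ref, m, length(acc))] <- 0L
  calls[raw == matrix(alt, m, length(acc))] <- 1L
  unresolved <- !miss & is.na(calls)
  reject <- rowSums(unresolved) > 0L
  rejected <- data.frame(marker_id = tab[[1]][reject],
                         reason = rep("more than two alleles observed", sum(reject)),
                         stringsAsFactors = FALSE)
  keep <- !reject
  if (!any(keep)) stop("no marker passed allele validation")
  g <- geno_matrix(calls[keep, , drop = FALSE], tab[[1]][keep],
                   as.integer(tab[[3]][keep]), as.integer(tab[[4]][keep]),
                   acc, ref[keep], alt[keep])
  attr(g, "rejected") <- rejected
  g
}

#' Write a genotype matrix in hapmap format
#'
#' Inverse of [read_hapmap()]: emits UTF-8, Unix-newline, tab-separated text
#' with missing calls coded `"N"`.
#'
#' @param g a [geno_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_hapmap <- function(g, path) {
  stopifnot(inherits(g, "geno_matrix"))
  m <- nrow(g$calls); n <- ncol(g$calls)
  let <- matrix("N", m, n)
  let[which(g$calls == 0L)] <- matrix(g$ref, m, n)[which(g$calls == 0L)]
  let[which(g$calls == 1L)] <- matrix(g$alt, m, n)[which(g$calls == 1L)]
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(paste(c("rs#", "alleles", "chrom", "pos", g$accession_ids),
                   collapse = "\t"), con, sep = "\n")
  body <- paste(g$marker_ids, paste0(g$ref, "/", g$alt), g$chrom, g$pos,
                apply(let, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con, sep = "\n")
  invisible(path)
}

#' Read a DArT presence/absence score table
#'
#' Expects a delimited table with a `clone_id` column followed by one column
#' per accession, cells in \{1, 0, -9\}; -9 maps to missing. Any other value
#' is a validation error naming the offending cell.
#'
#' @param path path to the CSV/TSV score table.
#' @param sep field separator (default `","`).
#' @return a [dart_matrix()].
#' @export
read_dart <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                    colClasses = "character")
  clone_ids <- tab[[1]]
  raw <- as.matrix(tab[, -1, drop = FALSE])
  ok <- raw %in% c("0", "1", "-9")
  if (!all(ok)) {
    bad <- which(!ok)[1]
    rr <- (bad - 1L) %% nrow(raw) + 1L
    cc <- (bad - 1L) %/% nrow(raw) + 1L
    stop(sprintf("invalid DArT score '%s' at marker %s, accession %s (allowed: 1, 0, -9)",
                 raw[bad], clone_ids[rr], colnames(raw)[cc]))
  }
  scores <- matrix(as.integer(raw), nrow(raw), ncol(raw))
  scores[scores == -9L] <- NA_integer_
  dart_matrix(scores, clone_ids, colnames(raw))
}

#' Write a DArT score table (missing coded -9)
#'
#' @param d a [dart_matrix()].
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_dart <- function(d, path, sep = ",") {
  stopifnot(inherits(d, "dart_matrix"))
  out <- d$scores
  out[is.na(out)] <- -9L
  df <- data.frame(clone_id = d$clone_ids, out, check.names = FALSE)
  colnames(df) <- c("clone_id", d$accession_ids)
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
              eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

ECOSYSTEM_LEVELS <- c("irrigated", "rainfed lowland", "upland", "mangrove",
                      "unknown")

#' Read passport or phenotype tables
#'
#' Passport tables carry `accession_id, region, ecosystem, varietal_type`;
#' phenotype tables carry `accession_id, days_to_flowering, grain_length_mm,
#' grain_width_mm, endosperm`. Empty or unrecognized categorical levels are
#' preserved as `"unknown"`; numeric cells that fail coercion are reported
#' per row (warning) and stored as `NA`. Duplicate accession ids are an
#' error.
#'
#' @param path CSV file path.
#' @param kind `"passport"` or `"phenotype"`.
#' @return a data frame keyed by unique `accession_id`.
#' @export
read_tables <- function(path, kind = c("passport", "phenotype")) {
  kind <- match.arg(kind)
  tab <- read.table(path, sep = ",", header = TRUE, check.names = TRUE,
                    colClasses = "character", na.strings = c("NA", ""))
  if (!"accession_id" %in% names(tab))
    stop("missing required column 'accession_id'")
  dup <- unique(tab$accession_id[duplicated(tab$accession_id)])
  if (length(dup))
    stop("duplicated accession_id: ", paste(dup, collapse = ", "))
  fix_cat <- function(x, levels = NULL) {
    x[is.na(x) | x == ""] <- "unknown"
    if (!is.null(levels)) x[!x %in% levels] <- "unknown"
    x
  }
  fix_num <- function(x, name, positive = TRUE) {
    y <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(y))
    if (length(bad))
      warning(sprintf("column %s: non-numeric value in row(s) %s set to NA",
                      name, paste(bad, collapse = ", ")))
    if (positive) {
      neg <- which(!is.na(y) & y <= 0)
      if (length(neg))
        stop(sprintf("column %s must be positive; offending row(s): %s",
                     name, paste(neg, collapse = ", ")))
    }
    y
  }
  if (kind == "passport") {
    for (col in c("region", "ecosystem", "varietal_type"))
      if (!col %in% names(tab)) tab[[col]] <- NA_character_
    data.frame(accession_id = tab$accession_id,
               region = fix_cat(tab$region),
               ecosystem = fix_cat(tab$ecosystem, ECOSYSTEM_LEVELS),
               varietal_type = fix_cat(tab$varietal_type),
               stringsAsFactors = FALSE)
  } else {
    for (col in c("days_to_flowering", "grain_length_mm", "grain_width_mm"))
      if (!col %in% names(tab)) tab[[col]] <- NA_character_
    if (!"endosperm" %in% names(tab)) tab$endosperm <- NA_character_
    data.frame(accession_id = tab$accession_id,
               days_to_flowering = fix_num(tab$days_to_flowering, "days_to_flowering"),
               grain_length_mm = fix_num(tab$grain_length_mm, "grain_length_mm"),
               grain_width_mm = fix_num(tab$grain_width_mm, "grain_width_mm"),
               endosperm = fix_cat(tab$endosperm,
                                   c("dark-blue", "brown", "G", "NG")),
               stringsAsFactors = FALSE)
  }
}
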