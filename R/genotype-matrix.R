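#' Genotype matrix for haploid-coded inbred accessions
#'
#' Container for biallelic SNP calls on inbred (effectively haploid) lines.
#' Calls are stored as an integer matrix (markers x accessions) with values
#' 0 (reference allele), 1 (alternate allele) and `NA` (missing).
#'
#' @param calls integer matrix, markers x accessions, values in \{0, 1, NA\}.
#' @param marker_ids character vector of unique marker identifiers.
#' @param chrom integer vector of chromosome numbers per marker.
#' @param pos integer vector of 1-based physical positions (bp) per marker.
#' @param accession_ids character vector of accession identifiers.
#' @param ref,alt single-letter allele codes per marker (used when writing
#'   hapmap files); defaults `"A"`/`"G"`.
#'
#' @return An object of class `geno_matrix`: a list with elements `calls`,
#'   `marker_ids`, `chrom`, `pos`, `accession_ids`, `ref`, `alt`. Markers are
#'   sorted by (chromosome, position).
#' @export
geno_matrix <- function(calls, marker_ids, chrom, pos, accession_ids,
                        ref = NULL, alt = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  m <- nrow(calls)
  n <- ncol(calls)
  if (m == 0L || n == 0L)
    stop("geno_matrix needs at least one marker and one accession")
  if (anyDuplicated(marker_ids))
    stop("marker_ids must be unique")
  if (anyDuplicated(accession_ids))
    stop("accession_ids must be unique")
  stopifnot(length(marker_ids) == m, length(chrom) == m, length(pos) == m,
            length(accession_ids) == n)
  bad <- calls[!is.na(calls)]
  if (length(bad) && !all(bad %in% c(0L, 1L)))
    stop("calls must be 0 (REF), 1 (ALT) or NA (missing)")
  if (is.null(ref)) ref <- rep("A", m)
  if (is.null(alt)) alt <- rep("G", m)
  ord <- order(chrom, pos)
  x <- structure(list(
    calls = calls[ord, , drop = FALSE],
    marker_ids = as.character(marker_ids)[ord],
    chrom = as.integer(chrom)[ord],
    pos = as.integer(pos)[ord],
    accession_ids = as.character(accession_ids),
    ref = as.character(ref)[ord],
    alt = as.character(alt)[ord]
  ), class = "geno_matrix")
  dimnames(x$calls) <- list(x$marker_ids, x$accession_ids)
  x
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d markers x %d accessions, %d chromosome(s), %.1f%% missing\n",
              nrow(x$calls), ncol(x$calls), length(unique(x$chrom)),
              100 * mean(is.na(x$calls))))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$calls)

#' Subset a genotype matrix by markers and/or accessions
#'
#' @param g a [geno_matrix()].
#' @param markers logical/integer/character index over markers (optional).
#' @param accessions logical/integer/character index over accessions
#'   (optional).
#' @return a `geno_matrix` restricted to the selection.
#' @export
subset_geno <- function(g, markers = NULL, accessions = NULL) {
  stopifnot(inherits(g, "geno_matrix"))
  mi <- if (is.null(markers)) seq_along(g$marker_ids) else markers
  if (is.character(mi)) mi <- match(mi, g$marker_ids)
  if (is.logical(mi)) mi <- which(mi)
  ai <- if (is.null(accessions)) seq_along(g$accession_ids) else accessions
  if (is.character(ai)) ai <- match(ai, g$accession_ids)
  if (is.logical(ai)) ai <- which(ai)
  geno_matrix(g$calls[mi, ai, drop = FALSE], g$marker_ids[mi], g$chrom[mi],
              g$pos[mi], g$accession_ids[ai], g$ref[mi], g$alt[mi])
}

#' Per-marker alternate-allele frequency and minor allele frequency
#'
#' Frequencies are computed over non-missing calls only.
#'
#' @param g a [geno_matrix()].
#' @return `alt_freq`: numeric vector of ALT-allele frequencies (NaN for
#'   all-missing markers); `maf`: minor allele frequency, `pmin(p, 1 - p)`.
#' @export
alt_freq <- function(g) {
  stopifnot(inherits(g, "geno_matrix"))
  rowMeans(g$calls, na.rm = TRUE)
}

#' @rdname alt_freq
#' @export
maf <- function(g) {
  p <- alt_freq(g)
  pmin(p, 1 - p)
}

#' Presence/absence (DArT) marker matrix
#'
#' Container for dominant markers scored 1 (fragment present), 0 (absent) or
#' `NA` (missing; coded -9 on disk). Optionally carries per-marker
#' hybridization intensities and replicate-pair metadata used for the
#' reproducibility and cluster-variance quality statistics.
#'
#' @param scores integer matrix markers x accessions with values \{0, 1, NA\}.
#' @param clone_ids unique marker (clone) identifiers.
#' @param accession_ids accession identifiers.
#' @param intensities optional numeric matrix of hybridization intensities,
#'   same shape as `scores`.
#' @param replicate_pairs optional two-column data frame of accession-id
#'   pairs that are technical replicates.
#' @return an object of class `dart_matrix`.
#' @export
dart_matrix <- function(scores, clone_ids, accession_ids, intensities = NULL,
                        replicate_pairs = NULL) {
  scores <- as.matrix(scores)
  storage.mode(scores) <- "integer"
  if (nrow(scores) == 0L || ncol(scores) == 0L)
    stop("dart_matrix needs at least one marker and one accession")
  stopifnot(length(clone_ids) == nrow(scores),
            length(accession_ids) == ncol(scores))
  if (anyDuplicated(clone_ids)) stop("clone_ids must be unique")
  vals <- scores[!is.na(scores)]
  if (length(vals) && !all(vals %in% c(0L, 1L)))
    stop("scores must be 0, 1 or NA")
  if (!is.null(intensities)) {
    intensities <- as.matrix(intensities)
    stopifnot(all(dim(intensities) == dim(scores)))
  }
  if (!is.null(replicate_pairs)) {
    replicate_pairs <- as.data.frame(replicate_pairs)
    names(replicate_pairs) <- c("a", "b")
    ok <- replicate_pairs$a %in% accession_ids &
      replicate_pairs$b %in% accession_ids
    if (!all(ok))
      stop("replicate_pairs reference unknown accessions: ",
           paste(unlist(replicate_pairs[!ok, ]), collapse = ", "))
  }
  x <- structure(list(scores = scores,
                      clone_ids = as.character(clone_ids),
                      accession_ids = as.character(accession_ids),
                      intensities = intensities,
                      replicate_pairs = replicate_pairs),
                 class = "dart_matrix")
  dimnames(x$scores) <- list(x$clone_ids, x$accession_ids)
  x
}

#' @export
print.dart_matrix <- function(x, ...) {
  cat(sprintf("<dart_matrix> %d clones x %d accessions, %.1f%% missing\n",
              nrow(x$scores), ncol(x$scores), 100 * mean(is.na(x$scores))))
  invisible(x)
}
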