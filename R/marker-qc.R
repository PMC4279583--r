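# Per-marker statistics and the filtering cascades for DArT (dominant) and
# GBS (biallelic SNP) matrices.

calls_of <- function(x) {
  if (inherits(x, "geno_matrix")) x$calls
  else if (inherits(x, "dart_matrix")) x$scores
  else stop("expected a geno_matrix or dart_matrix")
}

#' Per-marker call rate, MAF, PIC and monomorphism flag
#'
#' MAF and PIC are computed on non-missing calls only. PIC is the expected
#' heterozygosity diversity index \eqn{1 - \sum_i p_i^2} (equal to `2pq` for
#' biallelic loci, maximum 0.5), so a locus at p = 0.5 attains PIC = 0.5.
#'
#' @param x a [geno_matrix()] or [dart_matrix()].
#' @param marker optional marker index or id; default all markers.
#' @return data frame with columns `marker_id`, `call_rate`, `maf`, `pic`,
#'   `monomorphic`.
#' @export
marker_stats <- function(x, marker = NULL) {
  calls <- calls_of(x)
  ids <- rownames(calls)
  if (!is.null(marker)) {
    if (is.character(marker)) marker <- match(marker, ids)
    calls <- calls[marker, , drop = FALSE]
    ids <- ids[marker]
  }
  n_called <- rowSums(!is.na(calls))
  if (any(n_called == 0L))
    stop("all-missing marker(s): stats undefined for ",
         paste(ids[n_called == 0L], collapse = ", "))
  p <- rowMeans(calls, na.rm = TRUE)
  maf <- pmin(p, 1 - p)
  pic <- 1 - (p^2 + (1 - p)^2)
  data.frame(marker_id = ids,
             call_rate = n_called / ncol(calls),
             maf = maf,
             pic = pic,
             monomorphic = maf == 0,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' DArT reproducibility from replicated samples
#'
#' For each marker, 1 - mismatches/comparisons over all replicate pairs in
#' which both calls are non-missing (missing data excluded from the
#' denominator). Markers with no valid comparison get `NA`.
#'
#' @param d a [dart_matrix()] with non-empty `replicate_pairs`.
#' @return named numeric vector of per-marker reproducibility fractions.
#' @export
dart_reproducibility <- function(d) {
  stopifnot(inherits(d, "dart_matrix"))
  rp <- d$replicate_pairs
  if (is.null(rp) || nrow(rp) == 0L)
    stop("no replicate pairs available")
  ia <- match(rp$a, d$accession_ids)
  ib <- match(rp$b, d$accession_ids)
  A <- d$scores[, ia, drop = FALSE]
  B <- d$scores[, ib, drop = FALSE]
  comparable <- !is.na(A) & !is.na(B)
  mism <- rowSums((A != B) & comparable, na.rm = TRUE)
  ncomp <- rowSums(comparable)
  out <- ifelse(ncomp > 0L, 1 - mism / ncomp, NA_real_)
  setNames(out, d$clone_ids)
}

#' DArT cluster-variance quality index (P)
#'
#' Ratio of the between-cluster variance of hybridization intensity (0- vs
#' 1-scored samples) to the total intensity variance — the between-group sum
#' of squares over the total sum of squares of a one-way layout. Lies in
#' \[0, 1\]; high values denote well-separated, reliable markers.
#'
#' @param intensities numeric vector of hybridization intensities for one
#'   marker.
#' @param scores matching integer vector of 0/1 scores (`NA` allowed; those
#'   samples are ignored).
#' @return the quality index, a scalar in \[0, 1\].
#' @export
dart_quality_p <- function(intensities, scores) {
  keep <- !is.na(scores) & !is.na(intensities)
  y <- intensities[keep]
  s <- scores[keep]
  if (length(unique(s)) < 2L)
    stop("quality index undefined: marker has a single score cluster")
  tot <- sum((y - mean(y))^2)
  if (tot == 0) return(0)
  means <- tapply(y, s, mean)
  ns <- tapply(y, s, length)
  between <- sum(ns * (means - mean(y))^2)
  between / tot
}

per_marker_quality <- function(d) {
  if (is.null(d$intensities)) return(rep(NA_real_, nrow(d$scores)))
  vapply(seq_len(nrow(d$scores)), function(i) {
    tryCatch(dart_quality_p(d$intensities[i, ], d$scores[i, ]),
             error = function(e) NA_real_)
  }, 0)
}

#' DArT marker filtering cascade
#'
#' Applies, in order: (1) drop monomorphic markers; (2) drop markers with
#' reproducibility below `reproducibility_min` or quality index P below
#' `p_min`; (3) drop markers with missing-data fraction above `max_missing`
#' (strictly more than 10% by default). The report counts survivors of each
#' step; each removal is attributed to the first step that rejects it.
#'
#' @param d a [dart_matrix()].
#' @param p_min minimum cluster-variance quality index (default 0.8).
#' @param max_missing maximum tolerated missing fraction (default 0.10).
#' @param reproducibility_min minimum replicate reproducibility (default
#'   0.99). Markers without replicate data or intensities pass the
#'   corresponding check (not assessable).
#' @return list with `matrix` (filtered [dart_matrix()]) and `report` (step
#'   survivor counts and a per-marker removal table).
#' @export
filter_dart <- function(d, p_min = 0.8, max_missing = 0.10,
                        reproducibility_min = 0.99) {
  stopifnot(inherits(d, "dart_matrix"))
  st <- marker_stats(d)
  rep_ok <- if (!is.null(d$replicate_pairs)) {
    r <- dart_reproducibility(d)
    is.na(r) | r >= reproducibility_min
  } else rep(TRUE, nrow(d$scores))
  q <- per_marker_quality(d)
  q_ok <- is.na(q) | q >= p_min
  miss_ok <- (1 - st$call_rate) <= max_missing

  removed <- rep(NA_character_, nrow(d$scores))
  alive <- !st$monomorphic
  removed[!alive] <- "monomorphic"
  n1 <- sum(alive)
  fail2 <- alive & !(rep_ok & q_ok)
  removed[fail2] <- "reproducibility/quality"
  alive <- alive & rep_ok & q_ok
  n2 <- sum(alive)
  fail3 <- alive & !miss_ok
  removed[fail3] <- "call rate"
  alive <- alive & miss_ok
  n3 <- sum(alive)

  keep <- which(alive)
  out <- if (length(keep))
    dart_matrix(d$scores[keep, , drop = FALSE], d$clone_ids[keep],
                d$accession_ids,
                if (!is.null(d$intensities)) d$intensities[keep, , drop = FALSE],
                d$replicate_pairs)
  else NULL
  list(matrix = out,
       report = list(
         n_input = nrow(d$scores),
         n_polymorphic = n1,
         n_quality = n2,
         n_call_rate = n3,
         removed = data.frame(clone_id = d$clone_ids[!alive],
                              cause = removed[!alive],
                              stringsAsFactors = FALSE)))
}

#' Collapse markers with identical call patterns
#'
#' Markers whose call vectors are exactly equal — including the missing
#' mask — are grouped; the first marker (input order) of each group is kept.
#' Set `ignore_missing = TRUE` to instead group markers that agree on all
#' shared non-missing calls.
#'
#' @param x a [dart_matrix()] or [geno_matrix()].
#' @param ignore_missing match on shared calls only (default `FALSE`:
#'   strict equality).
#' @return list with `matrix` (reduced object) and `groups` (list of marker
#'   id vectors, one per group of size >= 2).
#' @export
collapse_identical <- function(x, ignore_missing = FALSE) {
  calls <- calls_of(x)
  ids <- rownames(calls)
  if (!ignore_missing) {
    key <- apply(calls, 1L, function(r) paste(ifelse(is.na(r), "x", r),
                                              collapse = ""))
    grp <- match(key, key)          # index of first marker with same pattern
  } else {
    m <- nrow(calls)
    grp <- seq_len(m)
    for (i in seq_len(m)) {
      if (grp[i] != i) next
      if (i == m) break
      for (j in (i + 1L):m) {
        if (grp[j] != j) next
        shared <- !is.na(calls[i, ]) & !is.na(calls[j, ])
        if (any(shared) && all(calls[i, shared] == calls[j, shared]))
          grp[j] <- i
      }
    }
  }
  keep <- sort(unique(grp))
  groups <- split(ids, grp)
  groups <- unname(groups[vapply(groups, length, 1L) > 1L])
  out <- if (inherits(x, "dart_matrix"))
    dart_matrix(x$scores[keep, , drop = FALSE], x$clone_ids[keep],
                x$accession_ids,
                if (!is.null(x$intensities)) x$intensities[keep, , drop = FALSE],
                x$replicate_pairs)
  else subset_geno(x, markers = keep)
  list(matrix = out, groups = groups)
}

#' GBS marker filter: mapped position and missing-data ceiling
#'
#' Removes markers lacking a physical position and markers with strictly
#' more than `max_missing` missing data (a marker at exactly the threshold
#' is retained).
#'
#' @param g a [geno_matrix()]; unmapped markers are flagged with `NA`
#'   position.
#' @param max_missing maximum missing fraction (default 0.20).
#' @return list with `matrix` (filtered [geno_matrix()]) and `report`
#'   (counts per removal cause).
#' @export
filter_gbs <- function(g, max_missing = 0.20) {
  stopifnot(inherits(g, "geno_matrix"))
  no_pos <- is.na(g$pos) | is.na(g$chrom)
  miss <- rowMeans(is.na(g$calls))
  too_missing <- !no_pos & miss > max_missing
  keep <- !no_pos & !too_missing
  if (!any(keep)) stop("no marker survived the GBS filter")
  list(matrix = subset_geno(g, markers = which(keep)),
       report = list(n_input = nrow(g$calls),
                     n_no_position = sum(no_pos),
                     n_too_missing = sum(too_missing),
                     n_kept = sum(keep)))
}

#' Marker density and coverage-gap report
#'
#' Per-chromosome marker counts, the census of inter-marker gaps above the
#' given thresholds, mean inter-marker distance, and the Pearson correlation
#' of per-chromosome marker counts against chromosome length (the maximum
#' observed position unless reference lengths are supplied). Chromosomes
#' with fewer than two markers are excluded from gap statistics and noted.
#'
#' @param g a [geno_matrix()], markers sorted by position.
#' @param gap_thresholds two increasing gap sizes in bp; gaps are classed as
#'   between the two thresholds or above the larger (defaults 300 kb /
#'   500 kb).
#' @param chrom_lengths optional named vector of reference chromosome
#'   lengths in bp.
#' @return list with `per_chromosome` (counts, lengths), `gaps` (data frame
#'   chrom/start/end/size/class), `mean_gap_bp`, `count_length_cor`
#'   (estimate + p, or `NA` when undefined), and `skipped_chromosomes`.
#' @export
density_report <- function(g, gap_thresholds = c(3e5, 5e5),
                           chrom_lengths = NULL) {
  stopifnot(inherits(g, "geno_matrix"), length(gap_thresholds) == 2L)
  chrs <- sort(unique(g$chrom))
  counts <- vapply(chrs, function(cc) sum(g$chrom == cc), 0L)
  lens <- if (!is.null(chrom_lengths)) as.numeric(chrom_lengths[as.character(chrs)])
  else vapply(chrs, function(cc) max(as.numeric(g$pos[g$chrom == cc])), 0)
  skipped <- chrs[counts < 2L]
  gap_rows <- list()
  all_gaps <- numeric(0)
  for (cc in setdiff(chrs, skipped)) {
    p <- sort(g$pos[g$chrom == cc])
    d <- diff(p)
    all_gaps <- c(all_gaps, d)
    big <- which(d >= gap_thresholds[1])
    if (length(big))
      gap_rows[[length(gap_rows) + 1L]] <- data.frame(
        chrom = cc, start = p[big], end = p[big + 1L], size = d[big],
        class = ifelse(d[big] > gap_thresholds[2],
                       sprintf(">%.0fkb", gap_thresholds[2] / 1e3),
                       sprintf("%.0f-%.0fkb", gap_thresholds[1] / 1e3,
                               gap_thresholds[2] / 1e3)))
  }
  gaps <- if (length(gap_rows)) do.call(rbind, gap_rows)
  else data.frame(chrom = integer(0), start = integer(0), end = integer(0),
                  size = numeric(0), class = character(0))
  cl_cor <- list(estimate = NA_real_, p_value = NA_real_)
  if (length(chrs) >= 3L && sd(counts) > 0 && sd(lens) > 0) {
    ct <- stats::cor.test(counts, lens)
    cl_cor <- list(estimate = unname(ct$estimate), p_value = ct$p.value)
  }
  list(per_chromosome = data.frame(chrom = chrs, n_markers = counts,
                                   length_bp = lens),
       gaps = gaps,
       mean_gap_bp = if (length(all_gaps)) mean(all_gaps) else NA_real_,
       count_length_cor = cl_cor,
       skipped_chromosomes = skipped)
}
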