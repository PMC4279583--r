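# Linkage-disequilibrium decay: pairwise r2 within chromosomes, 25-kb
# distance-class binning, power-law fitting y = a * x^k and inversion to the
# distance at which r2 reaches a target value.

#' Pairwise r2 between markers on one chromosome
#'
#' For haploid-coded calls, r2 is the squared Pearson correlation of the 0/1
#' allele vectors over accessions non-missing at both markers (for inbred
#' lines this equals the haplotype r2). Markers with MAF at or below
#' `maf_min` are excluded (strictly above 10% by default), as are pairs
#' beyond `max_distance` and pairs with fewer than 2 shared non-missing
#' accessions (counted in the `"n_skipped"` attribute).
#'
#' @param g a [geno_matrix()].
#' @param chrom chromosome to analyze.
#' @param maf_min MAF exclusion threshold (default 0.10, strict).
#' @param max_distance maximum pair distance in bp (default unlimited).
#' @return data frame (`marker_a`, `marker_b`, `distance_bp`, `r2`), with
#'   attribute `n_skipped`.
#' @export
pairwise_r2 <- function(g, chrom, maf_min = 0.10, max_distance = Inf) {
  stopifnot(inherits(g, "geno_matrix"))
  sel <- which(g$chrom == chrom)
  if (!length(sel)) stop("no markers on chromosome ", chrom)
  p <- rowMeans(g$calls[sel, , drop = FALSE], na.rm = TRUE)
  sel <- sel[pmin(p, 1 - p) > maf_min]
  if (length(sel) < 2L)
    return(structure(data.frame(marker_a = character(0), marker_b = character(0),
                                distance_bp = numeric(0), r2 = numeric(0)),
                     n_skipped = 0L))
  X <- t(g$calls[sel, , drop = FALSE]) * 1.0
  ids <- g$marker_ids[sel]
  pos <- as.numeric(g$pos[sel])
  cc <- suppressWarnings(cor(X, use = "pairwise.complete.obs"))
  nobs <- crossprod(!is.na(X))
  ut <- which(upper.tri(cc), arr.ind = TRUE)
  d <- abs(pos[ut[, 2]] - pos[ut[, 1]])
  keep_d <- d <= max_distance
  ut <- ut[keep_d, , drop = FALSE]
  d <- d[keep_d]
  r2 <- cc[ut]^2
  n_pair <- nobs[ut]
  usable <- n_pair >= 2L & !is.na(r2)
  out <- data.frame(marker_a = ids[ut[, 1]][usable],
                    marker_b = ids[ut[, 2]][usable],
                    distance_bp = d[usable],
                    r2 = r2[usable],
                    stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- sum(!usable)
  out
}

#' Average r2 by physical-distance class
#'
#' Distance class c covers `[c*bin_width, (c+1)*bin_width)` (half-open, so a
#' pair at exactly 25,000 bp falls in class 1 under the default). Averaging
#' within classes damps the large sampling variance of individual pair r2
#' values. Empty classes are omitted.
#'
#' @param pairs data frame from [pairwise_r2()] (rows from several
#'   chromosomes may be concatenated).
#' @param bin_width class width in bp (default 25 kb).
#' @return data frame: `bin` (class index), `midpoint_bp`, `mean_r2`,
#'   `n_pairs`.
#' @export
bin_r2 <- function(pairs, bin_width = 25e3) {
  if (nrow(pairs) == 0L) stop("no marker pairs to bin")
  cls <- floor(pairs$distance_bp / bin_width)
  agg <- tapply(pairs$r2, cls, mean)
  cnt <- tapply(pairs$r2, cls, length)
  bin <- as.integer(names(agg))
  data.frame(bin = bin,
             midpoint_bp = (bin + 0.5) * bin_width,
             mean_r2 = as.numeric(agg),
             n_pairs = as.integer(cnt),
             row.names = NULL)
}

#' Fit a power law y = a * x^k to binned r2
#'
#' Ordinary least squares of `log(mean_r2)` on `log(midpoint_bp)`; `a` is
#' the exponentiated intercept and `k` the slope. Bins with zero (or
#' negative) mean r2 are excluded and listed in the `"excluded_bins"`
#' attribute. Optionally weight bins by their pair counts.
#'
#' @param bins data frame from [bin_r2()].
#' @param weighted weight the regression by `n_pairs` (default `FALSE`).
#' @return list of class `ld_fit`: `a`, `k`, `n_bins`, plus the fitted
#'   `bins`.
#' @export
fit_power_law <- function(bins, weighted = FALSE) {
  usable <- bins$mean_r2 > 0
  excluded <- bins$bin[!usable]
  bins <- bins[usable, , drop = FALSE]
  if (nrow(bins) < 2L)
    stop("need at least 2 bins with positive mean r2 to fit a power law")
  w <- if (weighted) bins$n_pairs else rep(1, nrow(bins))
  fit <- lm(log(mean_r2) ~ log(midpoint_bp), data = bins, weights = w)
  structure(list(a = exp(unname(coef(fit)[1])),
                 k = unname(coef(fit)[2]),
                 n_bins = nrow(bins), bins = bins),
            class = "ld_fit", excluded_bins = excluded)
}

#' Distance at which the fitted power law reaches a target r2
#'
#' Inverts y = a x^k: x = (y/a)^(1/k). Requires a decaying fit (k < 0).
#'
#' @param fit an `ld_fit` from [fit_power_law()] (or a list with `a`, `k`).
#' @param y target r2 value (e.g. 0.2 or 0.1).
#' @return distance in the fit's distance units (bp when fitted on bp).
#' @export
distance_at_r2 <- function(fit, y) {
  if (!is.finite(fit$k) || fit$k >= 0)
    stop("no decay: the fitted exponent k is not negative")
  if (y <= 0) stop("target r2 must be positive")
  (y / fit$a)^(1 / fit$k)
}

#' Per-chromosome and average LD-decay report
#'
#' For a panel (or a subpanel selected by `accessions`), computes pairwise
#' r2 per chromosome, 25-kb bin means, a power-law fit and its inversion at
#' the requested r2 targets (in kb). The `"Average"` row is reported both
#' ways the study average can be formed: the mean of the per-chromosome
#' inversions (`average_of_chromosomes`) and the inversion of a single fit
#' pooling all chromosomes' pairs (`pooled_fit`). Also reports the 0-25 kb
#' class mean r2 and the fractions of that class below 0.10 and above 0.8.
#' Chromosomes with too few pairs or without decay are marked `NA`.
#'
#' @param g a [geno_matrix()].
#' @param accessions optional accession subset (ids or index) defining the
#'   subpanel.
#' @param targets r2 values to invert (default `c(0.1, 0.2)`).
#' @param maf_min,bin_width,max_distance passed to [pairwise_r2()] /
#'   [bin_r2()].
#' @return list of class `ld_report`: `table` (per-chromosome + average rows
#'   of distances in kb), `short_range` (0-25 kb class diagnostics),
#'   `pooled_fit`, `per_chromosome_fits`.
#' @export
decay_report <- function(g, accessions = NULL, targets = c(0.1, 0.2),
                         maf_min = 0.10, bin_width = 25e3,
                         max_distance = Inf) {
  stopifnot(inherits(g, "geno_matrix"))
  if (!is.null(accessions)) g <- subset_geno(g, accessions = accessions)
  chrs <- sort(unique(g$chrom))
  all_pairs <- list()
  fits <- list()
  rows <- list()
  for (cc in chrs) {
    pr <- pairwise_r2(g, cc, maf_min = maf_min, max_distance = max_distance)
    all_pairs[[as.character(cc)]] <- pr
    inv <- setNames(rep(NA_real_, length(targets)),
                    sprintf("r2_%g", targets))
    fit <- NULL
    if (nrow(pr) >= 2L) {
      fit <- tryCatch({
        f <- fit_power_law(bin_r2(pr, bin_width))
        for (t in seq_along(targets))
          inv[t] <- distance_at_r2(f, targets[t]) / 1e3
        f
      }, error = function(e) NULL)
    }
    fits[[as.character(cc)]] <- fit
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = as.character(cc), n_pairs = nrow(pr), t(inv),
      check.names = FALSE)
  }
  tab <- do.call(rbind, rows)
  avg_chr <- colMeans(tab[, -(1:2), drop = FALSE], na.rm = TRUE)
  pooled <- do.call(rbind, all_pairs)
  pooled_fit <- NULL
  avg_pool <- setNames(rep(NA_real_, length(targets)), names(avg_chr))
  short <- list(mean_r2 = NA_real_, frac_below_0.10 = NA_real_,
                frac_above_0.8 = NA_real_, n_pairs = 0L)
  if (!is.null(pooled) && nrow(pooled) >= 2L) {
    pooled_fit <- tryCatch(fit_power_law(bin_r2(pooled, bin_width)),
                           error = function(e) NULL)
    if (!is.null(pooled_fit) && pooled_fit$k < 0)
      for (t in seq_along(targets))
        avg_pool[t] <- distance_at_r2(pooled_fit, targets[t]) / 1e3
    first <- pooled[pooled$distance_bp < bin_width, , drop = FALSE]
    if (nrow(first))
      short <- list(mean_r2 = mean(first$r2),
                    frac_below_0.10 = mean(first$r2 < 0.10),
                    frac_above_0.8 = mean(first$r2 > 0.8),
                    n_pairs = nrow(first))
  }
  tab <- rbind(tab,
               data.frame(chrom = "average_of_chromosomes",
                          n_pairs = sum(tab$n_pairs), t(avg_chr),
                          check.names = FALSE),
               data.frame(chrom = "pooled_fit",
                          n_pairs = if (is.null(pooled)) 0L else nrow(pooled),
                          t(avg_pool), check.names = FALSE))
  structure(list(table = tab, short_range = short, pooled_fit = pooled_fit,
                 per_chromosome_fits = fits),
            class = "ld_report")
}

#' @export
print.ld_report <- function(x, ...) {
  cat("<ld_report> distances at target r2, in kb\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}
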