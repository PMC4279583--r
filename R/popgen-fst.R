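# Pairwise genetic differentiation between assigned populations, with
# permutation significance tests.
#
# Estimator: Weir-Cockerham-style ratio-of-sums variance-component FST
# adapted to haploid data. For each locus, with r populations of (non-
# missing) sample sizes n_i and ALT frequencies p_i:
#   MSP = sum n_i (p_i - pbar)^2 / (r - 1)         (between populations)
#   MSG = sum n_i p_i (1 - p_i) / sum (n_i - 1)    (within populations)
#   n_c = (N - sum n_i^2 / N) / (r - 1)
#   a_l = (MSP - MSG) / n_c ,  b_l = MSG
# and theta = sum_l a_l / sum_l (a_l + b_l) over loci polymorphic in the
# pair. Small negative estimates are legitimate sampling outcomes and are
# not truncated (except for display).

fst_components <- function(calls, idx1, idx2) {
  n1 <- rowSums(!is.na(calls[, idx1, drop = FALSE]))
  n2 <- rowSums(!is.na(calls[, idx2, drop = FALSE]))
  p1 <- rowMeans(calls[, idx1, drop = FALSE], na.rm = TRUE)
  p2 <- rowMeans(calls[, idx2, drop = FALSE], na.rm = TRUE)
  ok <- n1 >= 2L & n2 >= 2L
  N <- n1 + n2
  pbar <- (n1 * p1 + n2 * p2) / N
  poly <- ok & pbar > 0 & pbar < 1
  if (!any(poly)) return(c(a = 0, ab = 0))
  n1 <- n1[poly]; n2 <- n2[poly]; N <- N[poly]
  p1 <- p1[poly]; p2 <- p2[poly]; pbar <- pbar[poly]
  r <- 2L
  msp <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / (r - 1)
  msg <- (n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)) / ((n1 - 1) + (n2 - 1))
  nc <- (N - (n1^2 + n2^2) / N) / (r - 1)
  a <- (msp - msg) / nc
  c(a = sum(a), ab = sum(a + msg))
}

fst_pair <- function(calls, idx1, idx2) {
  cmp <- fst_components(calls, idx1, idx2)
  if (cmp[["ab"]] == 0) return(NA_real_)
  cmp[["a"]] / cmp[["ab"]]
}

#' Pairwise FST between assigned populations
#'
#' Multi-locus Weir-Cockerham-style ratio-of-sums estimator for haploid
#' data, computed independently for every pair of populations; markers
#' monomorphic within a pair are excluded from that pair's sums.
#'
#' @param g a [geno_matrix()].
#' @param labels per-accession population labels (named or in accession
#'   order); accessions labeled `"admixed"` or `NA` are ignored.
#' @return symmetric matrix of pairwise FST estimates (diagonal 0).
#' @export
pairwise_fst <- function(g, labels) {
  stopifnot(inherits(g, "geno_matrix"))
  labels <- resolve_labels(g, labels)
  keep <- !is.na(labels) & labels != "admixed"
  labs <- labels[keep]
  calls <- g$calls[, keep, drop = FALSE]
  pops <- sort(unique(labs))
  if (length(pops) < 2L) stop("need at least two populations")
  sizes <- table(labs)
  small <- names(sizes)[sizes < 2L]
  if (length(small))
    stop("population(s) with fewer than 2 members: ",
         paste(small, collapse = ", "))
  out <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)[-length(pops)]) {
    for (j in (i + 1L):length(pops)) {
      v <- fst_pair(calls, which(labs == pops[i]), which(labs == pops[j]))
      out[i, j] <- out[j, i] <- v
    }
  }
  out
}

resolve_labels <- function(g, labels) {
  if (!is.null(names(labels))) {
    out <- unname(labels[g$accession_ids])
  } else {
    stopifnot(length(labels) == length(g$accession_ids))
    out <- unname(labels)
  }
  as.character(out)
}

#' Permutation test for pairwise FST
#'
#' For each population pair, accessions are permuted between the two
#' populations (sizes preserved; each pair permuted independently) and the
#' one-sided p-value is `(1 + #\{FST_perm >= FST_obs\}) / (n_perm + 1)`, so
#' the smallest attainable p at 1000 permutations is 1/1001 (the 0.001
#' floor). Deterministic given `seed`.
#'
#' @param g a [geno_matrix()].
#' @param labels per-accession population labels (admixed/NA ignored).
#' @param n_perm number of permutations (default 1000).
#' @param seed RNG seed.
#' @return list of class `fst_result`: `fst` (matrix), `p_value` (matrix),
#'   `n_permutations`.
#' @export
fst_permutation_test <- function(g, labels, n_perm = 1000L, seed = 1L) {
  stopifnot(inherits(g, "geno_matrix"))
  labels <- resolve_labels(g, labels)
  keep <- !is.na(labels) & labels != "admixed"
  labs <- labels[keep]
  calls <- g$calls[, keep, drop = FALSE]
  pops <- sort(unique(labs))
  fst <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  pmat <- matrix(NA_real_, length(pops), length(pops),
                 dimnames = list(pops, pops))
  with_seed(seed, {
    for (i in seq_along(pops)[-length(pops)]) {
      for (j in (i + 1L):length(pops)) {
        ii <- which(labs == pops[i]); jj <- which(labs == pops[j])
        obs <- fst_pair(calls, ii, jj)
        both <- c(ii, jj)
        hits <- 0L
        for (b in seq_len(n_perm)) {
          sh <- sample(both)
          v <- fst_pair(calls, sh[seq_along(ii)], sh[-seq_along(ii)])
          if (!is.na(v) && v >= obs) hits <- hits + 1L
        }
        fst[i, j] <- fst[j, i] <- obs
        pmat[i, j] <- pmat[j, i] <- (1 + hits) / (n_perm + 1)
      }
    }
  })
  structure(list(fst = fst, p_value = pmat, n_permutations = as.integer(n_perm)),
            class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf("<fst_result> %d populations, %d permutations\n",
              nrow(x$fst), x$n_permutations))
  lower <- x$fst; lower[upper.tri(lower, diag = TRUE)] <- NA
  print(round(pmax(x$fst, 0), 3))
  invisible(x)
}

#' Write an FST/p-value table (FST below, p above the diagonal)
#'
#' @param x an `fst_result`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_fst_table <- function(x, path) {
  stopifnot(inherits(x, "fst_result"))
  out <- matrix("", nrow(x$fst), ncol(x$fst),
                dimnames = dimnames(x$fst))
  out[lower.tri(out)] <- sprintf("%.3f", x$fst[lower.tri(x$fst)])
  out[upper.tri(out)] <- sprintf("%.3f", x$p_value[upper.tri(x$p_value)])
  df <- data.frame(population = rownames(out), out, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              eol = "\n")
  invisible(path)
}
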