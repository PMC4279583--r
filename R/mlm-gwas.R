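# GWAS-matrix preparation and Q+K mixed-model association.
#
# The mixed model is y = X beta + Z u + e with var(u) = sigma_g^2 K and
# var(e) = sigma_e^2 I. It is solved by spectral decomposition of K: with
# K = U D U', the rotated model has diagonal covariance sigma_g^2 (D + delta I)
# where delta = sigma_e^2 / sigma_g^2, and REML profiles over delta alone.
# Markers are tested by generalized least squares with the null-model delta
# reused for every marker (single-variance-ratio approximation); exact
# per-marker REML is available behind a flag.

#' MAF filter for association matrices
#'
#' Removes markers with minor allele frequency strictly below `maf_min`
#' (a marker at exactly 5% is retained under the default). Monomorphic
#' markers have MAF 0 and are therefore removed whenever `maf_min > 0`,
#' which is how subpanel matrices drop markers that became monomorphic
#' within the subpanel.
#'
#' @param g a [geno_matrix()].
#' @param maf_min threshold (default 0.05).
#' @return the filtered [geno_matrix()] with attribute `n_removed`.
#' @export
maf_filter <- function(g, maf_min = 0.05) {
  stopifnot(inherits(g, "geno_matrix"))
  keep <- maf(g) >= maf_min
  if (!any(keep)) stop("no marker passes the MAF filter")
  out <- subset_geno(g, markers = which(keep))
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Nearest-haplotype imputation of missing calls
#'
#' Fills each missing call from the accessions whose observed calls agree
#' most with the target accession over a window of markers around the
#' missing site (same chromosome), restricted to accessions observed at the
#' site itself. A donor whose window matches the target perfectly is
#' decisive: its allele is copied (majority vote if several donors match
#' perfectly). Otherwise the `n_donors` best-agreeing donors vote. Exact
#' vote ties, and sites with no informative neighbor, are resolved by
#' drawing from the marker's allele frequency. Observed calls are never
#' altered. This is a deliberately simple, auditable local
#' haplotype-matching imputer; its accuracy on a given panel is measurable
#' by masking known calls (see [impute_accuracy()]).
#'
#' @param g a [geno_matrix()].
#' @param window number of flanking markers on each side used for matching
#'   (default 20, so the window spans roughly the within-population LD decay
#'   scale at the package's default marker density).
#' @param n_donors number of best-agreeing donors that vote when no donor
#'   matches the window perfectly (default 3).
#' @param seed RNG seed for tie-breaking draws.
#' @param max_missing per-marker missing-rate ceiling; markers above it are
#'   an error (impute after QC filtering).
#' @return list: `genotypes` (complete [geno_matrix()]), `imputed_mask`
#'   (logical matrix marking filled cells), `n_fallback` (cells filled by
#'   frequency draw).
#' @export
impute_missing <- function(g, window = 20L, n_donors = 3L, seed = 1L,
                           max_missing = 0.5) {
  stopifnot(inherits(g, "geno_matrix"))
  calls <- g$calls
  miss_rate <- rowMeans(is.na(calls))
  if (any(miss_rate > max_missing))
    stop("marker(s) exceed the missing-rate ceiling: ",
         paste(head(g$marker_ids[miss_rate > max_missing], 5), collapse = ", "))
  m <- nrow(calls); n <- ncol(calls)
  out <- calls
  mask <- matrix(FALSE, m, n, dimnames = dimnames(calls))
  n_fallback <- 0L
  p_all <- rowMeans(calls, na.rm = TRUE)
  with_seed(seed, {
    for (l in which(miss_rate > 0)) {
      same_chr <- which(g$chrom == g$chrom[l])
      ord <- same_chr[order(abs(g$pos[same_chr] - g$pos[l]))]
      win <- setdiff(head(ord, 2L * window + 1L), l)
      targets <- which(is.na(calls[l, ]))
      donors_obs <- which(!is.na(calls[l, ]))
      p_l <- p_all[l]
      if (is.nan(p_l)) p_l <- 0.5
      if (!length(donors_obs) || !length(win)) {
        out[l, targets] <- as.integer(runif(length(targets)) < p_l)
        n_fallback <- n_fallback + length(targets)
        mask[l, targets] <- TRUE
        next
      }
      W <- calls[win, , drop = FALSE]
      W0 <- (!is.na(W)) & W == 0L
      W1 <- (!is.na(W)) & W == 1L
      # agreement fraction between each target and each donor over the window
      agree <- crossprod(W0[, targets, drop = FALSE], W0[, donors_obs, drop = FALSE]) +
        crossprod(W1[, targets, drop = FALSE], W1[, donors_obs, drop = FALSE])
      comp <- crossprod((!is.na(W))[, targets, drop = FALSE] * 1,
                        (!is.na(W))[, donors_obs, drop = FALSE] * 1)
      frac <- ifelse(comp > 0, agree / comp, -1)
      for (t in seq_along(targets)) {
        f <- frac[t, ]
        if (max(f) < 0) {                     # no comparable donor
          out[l, targets[t]] <- as.integer(runif(1) < p_l)
          n_fallback <- n_fallback + 1L
        } else {
          best <- max(f)
          top <- if (best >= 1 - 1e-12)       # perfect match is decisive
            donors_obs[f >= 1 - 1e-12]
          else donors_obs[order(-f)[seq_len(min(n_donors, sum(f >= 0)))]]
          mv <- mean(calls[l, top])           # majority vote
          if (mv > 0.5) out[l, targets[t]] <- 1L
          else if (mv < 0.5) out[l, targets[t]] <- 0L
          else {                              # exact vote tie
            out[l, targets[t]] <- as.integer(runif(1) < p_l)
            n_fallback <- n_fallback + 1L
          }
        }
        mask[l, targets[t]] <- TRUE
      }
    }
  })
  gg <- geno_matrix(out, g$marker_ids, g$chrom, g$pos, g$accession_ids,
                    g$ref, g$alt)
  list(genotypes = gg, imputed_mask = mask, n_fallback = n_fallback)
}

#' Masking experiment: imputation accuracy
#'
#' Masks a fraction of the observed calls completely at random, imputes, and
#' reports the fraction of masked calls recovered exactly.
#'
#' @param g a [geno_matrix()].
#' @param mask_rate fraction of observed calls to hide (default 0.05).
#' @param seed RNG seed (controls both the mask and the imputer).
#' @param ... passed to [impute_missing()].
#' @return list: `accuracy`, `n_masked`.
#' @export
impute_accuracy <- function(g, mask_rate = 0.05, seed = 1L, ...) {
  stopifnot(inherits(g, "geno_matrix"))
  obs <- which(!is.na(g$calls))
  with_seed(substream_seed(seed, "mask"), {
    hide <- sample(obs, round(mask_rate * length(obs)))
    calls <- g$calls
    truth <- calls[hide]
    calls[hide] <- NA_integer_
    gm <- geno_matrix(calls, g$marker_ids, g$chrom, g$pos, g$accession_ids,
                      g$ref, g$alt)
    imp <- impute_missing(gm, seed = substream_seed(seed, "impute"), ...)
    list(accuracy = mean(imp$genotypes$calls[hide] == truth),
         n_masked = length(hide))
  })
}

#' Kinship matrix by the centered, standardized cross-product
#'
#' Marker columns are centered at their ALT frequency p and scaled by
#' sqrt(p(1-p)); K = G G' / m over m markers. If the smallest eigenvalue is
#' negative, the matrix is bent by adding `|lambda_min| + 1e-8` to the
#' diagonal (recorded in attribute `"bending"`).
#'
#' @param g a complete (imputed) [geno_matrix()].
#' @param method `"standardized"` (default) or `"ibs"` (identity-by-state
#'   similarity).
#' @return symmetric positive semi-definite kinship matrix (accessions x
#'   accessions).
#' @export
kinship <- function(g, method = c("standardized", "ibs")) {
  method <- match.arg(method)
  stopifnot(inherits(g, "geno_matrix"))
  if (anyNA(g$calls)) stop("kinship requires a complete matrix; impute first")
  p <- rowMeans(g$calls)
  if (any(p == 0 | p == 1))
    stop("monomorphic marker(s) present; apply maf_filter first")
  if (method == "standardized") {
    Z <- (t(g$calls) - rep(p, each = ncol(g$calls))) /
      rep(sqrt(p * (1 - p)), each = ncol(g$calls))
    K <- tcrossprod(Z) / nrow(g$calls)
  } else {
    X <- t(g$calls)
    K <- (tcrossprod(X) + tcrossprod(1 - X)) / nrow(g$calls)
  }
  dimnames(K) <- list(g$accession_ids, g$accession_ids)
  ev_min <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  bend <- 0
  if (ev_min < 0) {
    bend <- -ev_min + 1e-8
    K <- K + diag(bend, nrow(K))
  }
  attr(K, "bending") <- bend
  K
}

# REML profile log-likelihood in the rotated model, as a function of
# log(delta); `d` are the eigenvalues of K, Uy/UX the rotated data.
reml_loglik <- function(log_delta, d, Uy, UX) {
  delta <- exp(log_delta)
  w <- 1 / (d + delta)
  Xw <- UX * w
  XtX <- crossprod(UX, Xw)
  Xty <- crossprod(Xw, Uy)
  beta <- solve(XtX, Xty)
  r <- Uy - UX %*% beta
  n <- length(Uy); p <- ncol(UX)
  rss <- sum(r^2 * w)
  sigma2 <- rss / (n - p)
  -0.5 * ((n - p) * log(2 * pi * sigma2) + sum(log(d + delta)) +
            determinant(XtX, logarithm = TRUE)$modulus[1] + (n - p))
}

#' Q+K mixed-model association scan
#'
#' Fits the null mixed model y = X beta + u + e (X = intercept + structure
#' covariates) with var(u) = sigma_g^2 K by spectral REML, then tests each
#' marker by a generalized least squares Wald t-test in the rotated model,
#' reusing the null variance ratio for every marker (set
#' `exact_reml = TRUE` to re-profile the ratio per marker). With K = 0
#' (or identity-scaled) covariance the test reduces exactly to ordinary
#' least squares.
#'
#' @param y named numeric vector of trait values.
#' @param g a complete [geno_matrix()] of the same accessions.
#' @param Q optional structure covariates (accessions x K admixture matrix;
#'   one column is dropped internally to avoid collinearity with the
#'   intercept).
#' @param K kinship matrix from [kinship()]; identity if `NULL`.
#' @param exact_reml re-estimate the variance ratio for every marker.
#' @return an `mlm_result`: data frame `results` (marker, chrom, pos,
#'   effect, stat, p_value, maf), `vc` (variance components of the null
#'   model), `h2` (pseudo-heritability), `covariates` (design description).
#' @export
mlm_assoc <- function(y, g, Q = NULL, K = NULL, exact_reml = FALSE) {
  stopifnot(inherits(g, "geno_matrix"))
  acc <- g$accession_ids
  if (!is.null(names(y))) y <- y[acc]
  if (anyNA(y)) {
    keep <- !is.na(y)
    g <- subset_geno(g, accessions = which(keep))
    y <- y[keep]
    if (!is.null(Q)) Q <- Q[keep, , drop = FALSE]
    if (!is.null(K)) K <- K[keep, keep]
    acc <- g$accession_ids
  }
  n <- length(y)
  if (sd(y) == 0) stop("constant trait: nothing to test")
  X <- matrix(1, n, 1)
  covdesc <- "intercept"
  if (!is.null(Q)) {
    Q <- as.matrix(Q)
    if (ncol(Q) > 1L) Q <- Q[, -ncol(Q), drop = FALSE]  # drop one column
    X <- cbind(X, Q)
    covdesc <- sprintf("intercept + %d structure covariate(s)", ncol(Q))
  }
  if (is.null(K)) K <- diag(n)
  eg <- eigen((K + t(K)) / 2, symmetric = TRUE)
  if (min(eg$values) < -1e-6)
    stop("kinship matrix is not positive semi-definite after bending")
  d <- pmax(eg$values, 0)
  U <- eg$vectors
  Uy <- drop(crossprod(U, y))
  UX <- crossprod(U, X)

  opt <- optimize(reml_loglik, interval = log(c(1e-5, 1e5)), d = d, Uy = Uy,
                  UX = UX, maximum = TRUE)
  delta <- exp(opt$maximum)
  w0 <- 1 / (d + delta)
  beta0 <- solve(crossprod(UX, UX * w0), crossprod(UX * w0, Uy))
  rss0 <- sum((Uy - UX %*% beta0)^2 * w0)
  sigma_g2 <- rss0 / (n - ncol(X))
  vc <- c(genetic = sigma_g2, residual = sigma_g2 * delta)
  h2 <- sigma_g2 / (sigma_g2 + sigma_g2 * delta)

  Ug <- crossprod(U, t(g$calls))         # n x m rotated marker matrix
  m <- nrow(g$calls)
  eff <- stat <- pv <- rep(NA_real_, m)
  p_marker <- rowMeans(g$calls)
  sw <- sqrt(w0)
  yw <- Uy * sw
  Xw <- UX * sw
  qrX <- qr(Xw)
  ry <- qr.resid(qrX, yw)
  df <- n - ncol(X) - 1L
  if (!exact_reml) {
    Gw <- Ug * sw
    RG <- qr.resid(qrX, Gw)
    gg <- colSums(RG^2)
    gy <- colSums(RG * ry)
    ok <- gg > 1e-12
    b <- ifelse(ok, gy / gg, NA_real_)
    rss <- pmax(sum(ry^2) - ifelse(ok, gy^2 / gg, 0), 0)
    se <- sqrt(rss / df / gg)
    tt <- b / se
    eff <- b
    stat <- tt
    pv <- 2 * pt(-abs(tt), df)
    pv[!ok] <- NA_real_
  } else {
    for (j in seq_len(m)) {
      Xj <- cbind(UX, Ug[, j])
      oj <- optimize(reml_loglik, interval = log(c(1e-5, 1e5)), d = d,
                     Uy = Uy, UX = Xj, maximum = TRUE)
      wj <- 1 / (d + exp(oj$maximum))
      XtX <- crossprod(Xj, Xj * wj)
      if (rcond(XtX) < 1e-12) next
      bj <- solve(XtX, crossprod(Xj * wj, Uy))
      rj <- sum((Uy - Xj %*% bj)^2 * wj)
      s2 <- rj / df
      seb <- sqrt(s2 * solve(XtX)[ncol(Xj), ncol(Xj)])
      eff[j] <- bj[ncol(Xj)]
      stat[j] <- eff[j] / seb
      pv[j] <- 2 * pt(-abs(stat[j]), df)
    }
  }
  res <- data.frame(marker = g$marker_ids, chrom = g$chrom, pos = g$pos,
                    effect = eff, stat = stat, p_value = pv,
                    maf = pmin(p_marker, 1 - p_marker),
                    stringsAsFactors = FALSE)
  structure(list(results = res, vc = vc, h2 = unname(h2), delta = delta,
                 covariates = covdesc, n = n),
            class = "mlm_result")
}

#' @export
print.mlm_result <- function(x, ...) {
  cat(sprintf("<mlm_result> %d markers, n=%d, %s, pseudo-h2 %.2f\n",
              nrow(x$results), x$n, x$covariates, x$h2))
  print(head(x$results[order(x$results$p_value), ], 5), row.names = FALSE)
  invisible(x)
}

#' Significant associations at a fixed threshold
#'
#' Markers with p strictly below `alpha` (p = alpha exactly is excluded),
#' sorted by chromosome and position. When results from several panels are
#' supplied as a named list, markers significant in more than one panel are
#' flagged in `in_multiple_panels`.
#'
#' @param result an `mlm_result`, or a named list of them (one per panel).
#' @param alpha significance threshold (default 5e-4).
#' @return data frame: `panel`, `marker`, `chrom`, `pos`, `effect`,
#'   `p_value`, `in_multiple_panels`.
#' @export
significant_hits <- function(result, alpha = 5e-4) {
  if (inherits(result, "mlm_result")) result <- list(panel = result)
  rows <- lapply(names(result), function(nm) {
    r <- result[[nm]]$results
    r <- r[!is.na(r$p_value) & r$p_value < alpha, , drop = FALSE]
    if (nrow(r) == 0L) return(NULL)
    data.frame(panel = nm, r[, c("marker", "chrom", "pos", "effect", "p_value")],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(panel = character(0), marker = character(0),
                      chrom = integer(0), pos = integer(0),
                      effect = numeric(0), p_value = numeric(0),
                      in_multiple_panels = logical(0)))
  counts <- table(out$marker)
  out$in_multiple_panels <- counts[out$marker] > 1L
  out[order(out$panel, out$chrom, out$pos), , drop = FALSE]
}

#' Quantile-quantile data for association p-values
#'
#' Observed sorted -log10 p against the expected uniform quantiles
#' -log10((i - 0.5) / m).
#'
#' @param result an `mlm_result` or a numeric vector of p-values.
#' @return data frame with `expected` and `observed` (-log10 scale), plus
#'   the genomic-inflation proxy `lambda_gc` (median chi-square ratio) as an
#'   attribute.
#' @export
qq_data <- function(result) {
  p <- if (inherits(result, "mlm_result")) result$results$p_value else result
  p <- p[!is.na(p)]
  if (!length(p)) stop("no p-values")
  m <- length(p)
  obs <- sort(p)
  out <- data.frame(expected = -log10((seq_len(m) - 0.5) / m),
                    observed = -log10(obs))
  chi <- qchisq(1 - p, df = 1)
  attr(out, "lambda_gc") <- stats::median(chi) / qchisq(0.5, df = 1)
  out
}
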