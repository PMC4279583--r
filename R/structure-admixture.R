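# Model-based population structure on haploid-coded genotypes.
#
# The admixture model: accession i carries ALT at locus l with probability
# sum_k q_ik * f_kl. Q and F are estimated by maximum-likelihood EM
# (deterministic given the restart seed); replicate "runs" are random
# restarts, which preserves the Evanno delta-K workflow built on replicate
# log-likelihoods.

#' Subset markers for structure analysis
#'
#' Random selection among markers with missing-data rate below `max_missing`
#' such that all retained markers on a chromosome are at least `min_spacing`
#' bp apart. Eligible markers are visited in random order (deterministic
#' given `seed`) and greedily accepted if they respect the spacing against
#' all previously accepted markers.
#'
#' @param g a [geno_matrix()].
#' @param max_missing maximum per-marker missing fraction (default 0.025,
#'   strict: a marker at 3% missing is never retained).
#' @param min_spacing minimum distance in bp to the nearest retained marker
#'   on the same chromosome (default 1e5).
#' @param seed RNG seed.
#' @param max_markers optional cap on the subset size.
#' @return integer vector of retained marker indices (sorted).
#' @export
subset_markers <- function(g, max_missing = 0.025, min_spacing = 1e5,
                           seed = 1L, max_markers = Inf) {
  stopifnot(inherits(g, "geno_matrix"))
  miss <- rowMeans(is.na(g$calls))
  eligible <- which(miss < max_missing)
  if (!length(eligible)) stop("no marker satisfies the missing-data rule")
  with_seed(seed, {
    order_visit <- sample(eligible)
    kept <- integer(0)
    for (i in order_visit) {
      same <- kept[g$chrom[kept] == g$chrom[i]]
      if (!length(same) || all(abs(g$pos[same] - g$pos[i]) >= min_spacing)) {
        kept <- c(kept, i)
        if (length(kept) >= max_markers) break
      }
    }
    sort(kept)
  })
}

#' Fit the admixture model by maximum-likelihood EM
#'
#' Maximizes \eqn{\sum_{il} \log(\sum_k q_{ik} f_{kl}^{x_{il}}
#' (1-f_{kl})^{1-x_{il}})} over admixture proportions Q (rows sum to 1) and
#' population ALT-allele frequencies F, with missing genotypes marginalized
#' by omission. The EM log-likelihood is non-decreasing at every iteration;
#' frequencies are clamped to `[1e-6, 1 - 1e-6]` to keep the likelihood
#' finite.
#'
#' @param g a [geno_matrix()].
#' @param K number of model populations (>= 1).
#' @param seed seed for the random initialization (restart).
#' @param max_iter maximum EM iterations.
#' @param tol convergence threshold on the log-likelihood gain.
#' @return an `admixture_fit`: list with `Q` (accessions x K), `F` (K x
#'   markers), `loglik`, `loglik_trace`, `n_iter`, `converged`, `K`.
#' @export
fit_admixture <- function(g, K, seed = 1L, max_iter = 2000L, tol = 1e-3) {
  stopifnot(inherits(g, "geno_matrix"), K >= 1L)
  X <- t(g$calls)                        # accessions x markers
  n <- nrow(X); m <- ncol(X)
  if (K > n) stop("K cannot exceed the number of accessions")
  eps <- 1e-6
  obs <- !is.na(X)
  m_i <- rowSums(obs)
  if (any(m_i == 0L)) stop("accession with no observed call")

  if (K == 1L) {
    f <- pmin(pmax(colMeans(X, na.rm = TRUE), eps), 1 - eps)
    ll <- sum(X * log(matrix(f, n, m, byrow = TRUE)) +
                (1 - X) * log(matrix(1 - f, n, m, byrow = TRUE)), na.rm = TRUE)
    return(structure(list(
      Q = matrix(1, n, 1, dimnames = list(g$accession_ids, "P1")),
      F = matrix(f, 1, m, dimnames = list("P1", g$marker_ids)),
      loglik = ll, loglik_trace = ll, n_iter = 0L, converged = TRUE, K = 1L),
      class = "admixture_fit"))
  }

  with_seed(seed, {
    pbar <- colMeans(X, na.rm = TRUE)
    Fmat <- matrix(pmin(pmax(rep(pbar, each = K) +
                               runif(K * m, -0.2, 0.2), eps), 1 - eps), K, m)
    Q <- matrix(rgamma(n * K, 1), n, K)
    Q <- Q / rowSums(Q)

    X0 <- X; X0[!obs] <- 0L              # zero-filled copies for crossprods
    trace <- numeric(0)
    ll_old <- -Inf
    converged <- FALSE
    it <- 0L
    W <- vector("list", K)
    while (it < max_iter) {
      it <- it + 1L
      # E step: responsibilities r_ilk; accumulate normalizer S
      S <- matrix(0, n, m)
      for (k in seq_len(K)) {
        B <- matrix(Fmat[k, ], n, m, byrow = TRUE)
        B <- B * X0 + (1 - B) * (1 - X0)  # f^x (1-f)^(1-x) on observed cells
        W[[k]] <- Q[, k] * B
        S <- S + W[[k]]
      }
      ll <- sum(log(S[obs]))
      trace <- c(trace, ll)
      # M step
      for (k in seq_len(K)) {
        R <- W[[k]] / S
        R[!obs] <- 0
        Q[, k] <- rowSums(R) / m_i
        num <- colSums(R * X0)
        den <- colSums(R)
        Fmat[k, ] <- pmin(pmax(ifelse(den > 0, num / den, pbar), eps), 1 - eps)
      }
      Q <- Q / rowSums(Q)
      if (ll - ll_old < tol && it > 1L) {
        converged <- TRUE
        break
      }
      ll_old <- ll
    }
    dimnames(Q) <- list(g$accession_ids, paste0("P", seq_len(K)))
    dimnames(Fmat) <- list(paste0("P", seq_len(K)), g$marker_ids)
    structure(list(Q = Q, F = Fmat, loglik = trace[length(trace)],
                   loglik_trace = trace, n_iter = it, converged = converged,
                   K = as.integer(K)),
              class = "admixture_fit")
  })
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat(sprintf("<admixture_fit> K=%d, %d accessions, loglik %.2f, %s in %d iter\n",
              x$K, nrow(x$Q), x$loglik,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' Replicate-run grid over K
#'
#' Fits the admixture model for K = 1..`K_max` with `replicates` random
#' restarts per K, recording the log-likelihood of each run. Non-converged
#' runs are flagged and excluded from downstream statistics such as
#' [evanno_delta_k()].
#'
#' @param g a [geno_matrix()].
#' @param K_max largest K (default 10).
#' @param replicates restarts per K (default 10).
#' @param seed master seed; run seeds are derived per (K, replicate).
#' @param max_iter,tol passed to [fit_admixture()].
#' @param keep_fits keep the fitted objects (default `TRUE`).
#' @return a `structure_runs` object: `runs` data frame (K, replicate,
#'   loglik, converged, n_iter), `fits` (list keyed "K/replicate" or NULL),
#'   `K_range`.
#' @export
run_grid <- function(g, K_max = 10L, replicates = 10L, seed = 1L,
                     max_iter = 2000L, tol = 1e-3, keep_fits = TRUE) {
  rows <- list()
  fits <- if (keep_fits) list() else NULL
  for (K in seq_len(K_max)) {
    for (r in seq_len(replicates)) {
      s <- substream_seed(seed, sprintf("structure-K%d-r%d", K, r))
      fit <- fit_admixture(g, K, seed = s, max_iter = max_iter, tol = tol)
      rows[[length(rows) + 1L]] <- data.frame(
        K = K, replicate = r, loglik = fit$loglik,
        converged = fit$converged, n_iter = fit$n_iter)
      if (keep_fits) fits[[sprintf("%d/%d", K, r)]] <- fit
    }
  }
  structure(list(runs = do.call(rbind, rows), fits = fits,
                 K_range = seq_len(K_max), replicates = replicates),
            class = "structure_runs")
}

#' Evanno delta-K from replicate log-likelihoods
#'
#' For interior K, \eqn{\Delta K = |L(K+1) - 2 L(K) + L(K-1)| / sd(L(K))}
#' where \eqn{L(K)} is the mean log-likelihood over converged replicates and
#' the denominator is the replicate standard deviation at K. Undefined when
#' the standard deviation is zero (reported as `NA`).
#'
#' @param runs a `structure_runs`, or a data frame with columns `K`,
#'   `loglik` and optionally `converged`.
#' @return data frame with `K`, `mean_loglik`, `sd_loglik`, `delta_k` (NA at
#'   the boundary K values and where undefined), plus the best-supported K
#'   in attribute `"best_K"`.
#' @export
evanno_delta_k <- function(runs) {
  df <- if (inherits(runs, "structure_runs")) runs$runs else as.data.frame(runs)
  if (!is.null(df$converged)) df <- df[df$converged, ]
  ks <- sort(unique(df$K))
  mu <- vapply(ks, function(k) mean(df$loglik[df$K == k]), 0)
  sdv <- vapply(ks, function(k) {
    x <- df$loglik[df$K == k]
    if (length(x) < 2L) NA_real_ else sd(x)
  }, 0)
  dk <- rep(NA_real_, length(ks))
  for (j in seq_along(ks)) {
    k <- ks[j]
    if (!(k - 1) %in% ks || !(k + 1) %in% ks) next
    if (is.na(sdv[j]) || sdv[j] == 0) next
    second <- mu[match(k + 1, ks)] - 2 * mu[j] + mu[match(k - 1, ks)]
    dk[j] <- abs(second) / sdv[j]
  }
  out <- data.frame(K = ks, mean_loglik = mu, sd_loglik = sdv, delta_k = dk)
  attr(out, "best_K") <- if (all(is.na(dk))) NA_integer_
  else ks[which.max(dk)]
  out
}

#' Threshold assignment of accessions to populations
#'
#' An accession is assigned to the population contributing strictly more
#' than `threshold` of its genome; otherwise it is labeled `"admixed"`
#' (so q = 0.75 exactly is admixed under the default).
#'
#' @param Q accessions x K matrix of admixture proportions (or an
#'   `admixture_fit`).
#' @param threshold membership threshold (default 0.75).
#' @return character vector of population labels (column names of Q, or
#'   `"admixed"`), named by accession.
#' @export
assign_populations <- function(Q, threshold = 0.75) {
  if (inherits(Q, "admixture_fit")) Q <- Q$Q
  stopifnot(is.matrix(Q))
  if (is.null(colnames(Q))) colnames(Q) <- paste0("P", seq_len(ncol(Q)))
  top <- max.col(Q, ties.method = "first")
  lab <- ifelse(Q[cbind(seq_len(nrow(Q)), top)] > threshold,
                colnames(Q)[top], "admixed")
  setNames(lab, rownames(Q))
}

#' Discriminant analysis of principal components (DAPC)
#'
#' Centers and scales the accession x marker allele matrix (missing calls
#' replaced by the marker mean), retains `n_pcs` principal components, finds
#' `n_clusters` groups by k-means (multiple starts, deterministic given
#' `seed`), then describes the clusters by linear discriminant analysis on
#' the retained PCs. PCs with (near-)zero within-group variance are dropped
#' before the LDA, with a note in the result, to keep the within-group
#' covariance non-singular.
#'
#' @param g a [geno_matrix()].
#' @param n_pcs number of principal components to retain (< n accessions).
#' @param n_clusters number of k-means clusters; if a vector, the value
#'   minimizing the k-means BIC is used.
#' @param seed RNG seed.
#' @return list with `assignments` (named cluster labels), `coords`
#'   (discriminant coordinates, NULL when `n_clusters = 1`), `posterior`,
#'   `n_clusters`, `pca_scores`, `dropped_pcs`.
#' @export
dapc <- function(g, n_pcs = 10L, n_clusters = 2L, seed = 1L) {
  stopifnot(inherits(g, "geno_matrix"))
  X <- t(g$calls) * 1.0
  n <- nrow(X)
  if (n_pcs >= n) stop("n_pcs must be below the number of accessions")
  cm <- colMeans(X, na.rm = TRUE)
  idx <- which(is.na(X))
  if (length(idx)) X[idx] <- cm[(idx - 1L) %/% n + 1L]
  keep <- apply(X, 2L, sd) > 0
  Xs <- scale(X[, keep, drop = FALSE])
  pc <- stats::prcomp(Xs, center = FALSE, scale. = FALSE)
  n_pcs <- min(n_pcs, ncol(pc$x))
  scores <- pc$x[, seq_len(n_pcs), drop = FALSE]

  with_seed(seed, {
    pick_k <- function(k) kmeans(scores, centers = k, nstart = 20L,
                                 iter.max = 100L)
    if (length(n_clusters) > 1L) {
      bic <- vapply(n_clusters, function(k) {
        km <- pick_k(k)
        n * log(km$tot.withinss / n) + log(n) * k * ncol(scores)
      }, 0)
      n_clusters <- n_clusters[which.min(bic)]
    }
    if (n_clusters == 1L) {
      list(assignments = setNames(rep("C1", n), g$accession_ids),
           coords = NULL, posterior = NULL, n_clusters = 1L,
           pca_scores = scores, dropped_pcs = character(0))
    } else {
      km <- pick_k(n_clusters)
      grp <- factor(km$cluster)
      # guard singular within-group covariance
      wvar <- vapply(seq_len(ncol(scores)), function(j)
        mean(tapply(scores[, j], grp, var), na.rm = TRUE), 0)
      ok <- which(wvar > 1e-10)
      dropped <- colnames(scores)[setdiff(seq_len(ncol(scores)), ok)]
      ld <- MASS::lda(scores[, ok, drop = FALSE], grouping = grp)
      pr <- stats::predict(ld)
      list(assignments = setNames(paste0("C", pr$class), g$accession_ids),
           coords = pr$x, posterior = pr$posterior,
           n_clusters = as.integer(n_clusters), pca_scores = scores,
           dropped_pcs = dropped)
    }
  })
}

#' RMSE between estimated and true admixture proportions
#'
#' Estimated Q columns are only identified up to permutation
#' (label switching); the RMSE is minimized over all column permutations
#' (exhaustive for the small K used here).
#'
#' @param Q estimated accessions x K matrix.
#' @param true_Q ground-truth matrix of the same shape.
#' @return list with `rmse` and the optimal `permutation`.
#' @export
q_rmse <- function(Q, true_Q) {
  stopifnot(all(dim(Q) == dim(true_Q)))
  K <- ncol(Q)
  if (K > 7L) stop("exhaustive permutation search limited to K <= 7")
  perms <- permutations_of(K)
  best <- Inf; best_p <- NULL
  for (p in perms) {
    r <- sqrt(mean((Q[, p, drop = FALSE] - true_Q)^2))
    if (r < best) { best <- r; best_p <- p }
  }
  list(rmse = best, permutation = best_p)
}

permutations_of <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  for (p in permutations_of(k - 1L)) {
    for (pos in seq_len(k)) {
      out[[length(out) + 1L]] <- append(p, k, after = pos - 1L)
    }
  }
  out
}
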