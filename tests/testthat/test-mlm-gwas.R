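test_that("the MAF filter is strict below 5% and catches subpanel monomorphism", {
  calls <- rbind(c(1L, rep(0L, 19)),           # MAF 0.05 exactly: retained
                 rep(0L, 20),                  # monomorphic: removed
                 c(rep(1L, 10), rep(0L, 10)),  # monomorphic within each half
                 rep(c(0L, 1L), 10))           # polymorphic everywhere
  g <- geno_matrix(calls, c("edge", "mono", "half", "ok"), rep(1L, 4), 1:4,
                   sprintf("a%d", 1:20))
  out <- maf_filter(g)
  expect_setequal(out$marker_ids, c("edge", "half", "ok"))
  expect_equal(attr(out, "n_removed"), 1L)

  # marker polymorphic overall but monomorphic within a subpanel is dropped
  # from that subpanel's matrix by the same rule
  sub <- maf_filter(subset_geno(out, accessions = 11:20))
  expect_false("half" %in% sub$marker_ids)
  expect_true("ok" %in% sub$marker_ids)

  # survivor count equals the brute-force predicate on a random spectrum
  set.seed(31)
  cc <- matrix(rbinom(100 * 40, 1L, runif(100, 0, 0.5)), 100, 40)
  gg <- geno_matrix(cc, sprintf("m%d", 1:100), rep(1L, 100), 1:100,
                    sprintf("a%d", 1:40))
  p <- rowMeans(cc)
  expect_equal(nrow(maf_filter(gg)$calls), sum(pmin(p, 1 - p) >= 0.05))
})

test_that("imputation honors observed calls and the unique-neighbor contract", {
  sim <- simulate_genotypes(sim_config(seed = 5L))
  g <- filter_gbs(sim$genotypes)$matrix

  # no missing: identity
  complete <- impute_missing(maf_filter(g), seed = 1L)
  again <- impute_missing(complete$genotypes, seed = 2L)
  expect_identical(again$genotypes$calls, complete$genotypes$calls)
  expect_equal(sum(again$imputed_mask), 0)

  # observed calls never altered
  obs <- !is.na(g$calls)
  imp <- impute_missing(g, seed = 3L)
  expect_identical(imp$genotypes$calls[obs], g$calls[obs])
  expect_false(anyNA(imp$genotypes$calls))
  expect_identical(which(imp$imputed_mask), which(!obs))

  # a window identical to exactly one other accession: copied from it
  calls <- cbind(t1 = c(1L, 0L, NA, 1L, 0L),
                 donor = c(1L, 0L, 1L, 1L, 0L),
                 other = c(0L, 1L, 0L, 0L, 1L))
  gt <- geno_matrix(calls, sprintf("m%d", 1:5), rep(1L, 5),
                    seq(1e3, 5e3, 1e3), colnames(calls))
  got <- impute_missing(gt, window = 2L, seed = 1L)
  expect_equal(got$genotypes$calls["m3", "t1"], 1L)
})

test_that("masked-call recovery exceeds 90% on the default panel", {
  g <- filter_gbs(simulate_genotypes(sim_config(seed = 5L))$genotypes)$matrix
  acc <- impute_accuracy(g, mask_rate = 0.05, seed = 17L)
  expect_gte(acc$accuracy, 0.90)
  expect_gt(acc$n_masked, 5000)
})

test_that("kinship equals the direct cross-product and flags duplicates", {
  set.seed(41)
  calls <- matrix(rbinom(60 * 10, 1L, runif(60, 0.2, 0.8)), 60, 10)
  calls[, 10] <- calls[, 9]                     # duplicated accession
  p <- rowMeans(calls)
  keep <- p > 0 & p < 1
  g <- geno_matrix(calls[keep, ], sprintf("m%d", seq_len(sum(keep))),
                   rep(1L, sum(keep)), seq_len(sum(keep)),
                   sprintf("a%d", 1:10))
  K <- kinship(g)
  # direct oracle
  pp <- rowMeans(g$calls)
  Z <- (t(g$calls) - rep(pp, each = 10)) / rep(sqrt(pp * (1 - pp)), each = 10)
  K0 <- tcrossprod(Z) / sum(keep)
  expect_lt(max(abs(K - diag(attr(K, "bending"), 10) - K0)), 1e-9)
  expect_equal(K["a9", "a10"], K["a10", "a10"] - attr(K, "bending"),
               tolerance = 1e-9)
  expect_true(isSymmetric(K))

  gm <- geno_matrix(rbind(calls[keep, ], 1L), c(sprintf("m%d", seq_len(sum(keep))), "mono"),
                    rep(1L, sum(keep) + 1), seq_len(sum(keep) + 1),
                    sprintf("a%d", 1:10))
  expect_error(kinship(gm), "monomorphic")
})

test_that("unrelated panmictic accessions have near-zero mean kinship", {
  sim <- two_pop_panel(f = 0, n_per_pop = 40L, n_markers = 800L, seed = 51L)
  K <- kinship(maf_filter(sim$genotypes, 0.05))
  off <- K[upper.tri(K)]
  expect_lt(abs(mean(off)), 0.02)
})

test_that("with identity kinship and no covariates the MLM reduces to OLS", {
  sim <- two_pop_panel(f = 0, n_per_pop = 30L, n_markers = 150L, seed = 61L)
  g <- maf_filter(sim$genotypes, 0.05)
  set.seed(2)
  y <- setNames(rnorm(ncol(g$calls)), g$accession_ids)
  res <- mlm_assoc(y, g)
  pv_ols <- apply(g$calls, 1L, function(x)
    summary(lm(y ~ x))$coefficients[2, 4])
  expect_lt(max(abs(res$results$p_value - pv_ols)), 1e-6)
  # exact per-marker REML agrees in this degenerate case
  res_x <- mlm_assoc(y, subset_geno(g, markers = 1:20), exact_reml = TRUE)
  expect_lt(max(abs(res_x$results$p_value[1:20] -
                      res$results$p_value[1:20])), 1e-4)
  expect_error(mlm_assoc(rep(1, ncol(g$calls)), g), "constant")
})

test_that("null p-values are calibrated over 5000 marker tests", {
  sim <- two_pop_panel(f = 0.2, n_per_pop = 60L, n_markers = 5000L,
                       seed = 71L)
  g <- maf_filter(sim$genotypes, 0.05)
  set.seed(9)
  y <- setNames(rnorm(ncol(g$calls)), g$accession_ids)   # trait independent of genotype
  K <- kinship(g)
  res <- mlm_assoc(y, g, K = K)
  frac <- mean(res$results$p_value < 0.01)
  m <- nrow(res$results)
  ci <- 0.01 + c(-3, 3) * sqrt(0.01 * 0.99 / m)
  expect_gte(frac, ci[1])
  expect_lte(frac, ci[2])
})

test_that("REML optimum beats a 21-point grid and effects flip sign with alleles", {
  sim <- simulate_phenotype(
    simulate_genotypes(three_pop_panel(seed = 81L)), qtl_variance = 0.25,
    pop_effect_sd = 4)
  g <- impute_missing(maf_filter(filter_gbs(sim$genotypes)$matrix, 0.05),
                      seed = 1L)$genotypes
  y <- setNames(sim$phenotype$days_to_flowering, sim$phenotype$accession_id)
  K <- kinship(g)
  res <- mlm_assoc(y, g, K = K)
  # optimizer sanity on the profile REML
  eg <- eigen(K, symmetric = TRUE)
  Uy <- drop(crossprod(eg$vectors, y[g$accession_ids]))
  UX <- crossprod(eg$vectors, matrix(1, length(y), 1))
  ll_opt <- panelforge:::reml_loglik(log(res$delta), pmax(eg$values, 0), Uy, UX)
  grid <- seq(log(1e-5), log(1e5), length.out = 21)
  expect_true(all(ll_opt >= vapply(
    grid, panelforge:::reml_loglik, 0, d = pmax(eg$values, 0),
    Uy = Uy, UX = UX) - 1e-6))

  # allele relabeling flips the effect sign, p-value unchanged
  flip <- g
  flip$calls[1, ] <- 1L - flip$calls[1, ]
  res_f <- mlm_assoc(y, flip, K = K)
  expect_equal(res_f$results$effect[1], -res$results$effect[1],
               tolerance = 1e-8)
  expect_equal(res_f$results$p_value[1], res$results$p_value[1],
               tolerance = 1e-8)
})

test_that("hit tables are strict at the threshold and flag cross-panel hits", {
  fake <- function(p, marker = sprintf("m%d", seq_along(p))) {
    structure(list(results = data.frame(
      marker = marker, chrom = 1L, pos = seq_along(p), effect = 1,
      stat = 1, p_value = p, maf = 0.3)), class = "mlm_result")
  }
  hits <- significant_hits(fake(c(5e-4, 4.99e-4, 0.2)))
  expect_identical(hits$marker, "m2")            # p = alpha exactly excluded
  empty <- significant_hits(fake(c(0.5, 0.9)))
  expect_equal(nrow(empty), 0L)

  two <- significant_hits(list(full = fake(c(1e-5, 1e-5, 0.5)),
                               sub = fake(c(1e-5, 0.5, 0.5))))
  expect_true(all(two$in_multiple_panels[two$marker == "m1"]))
  expect_false(any(two$in_multiple_panels[two$marker == "m2"]))
})

test_that("QQ data follows the plotting-position formula", {
  qq1 <- qq_data(0.1)
  expect_equal(qq1$expected, -log10(0.5))
  expect_equal(qq1$observed, 1)

  set.seed(3)
  p <- runif(2000)
  qq <- qq_data(p)
  fit <- coef(lm(observed ~ 0 + expected, data = qq))[[1]]
  expect_lt(abs(fit - 1), 0.1)
  expect_lt(abs(attr(qq, "lambda_gc") - 1), 0.1)
})

test_that("structure covariates deflate confounded inflation", {
  # strongly structured panel, trait driven by population membership only
  sim <- simulate_genotypes(three_pop_panel(seed = 91L, f = 0.4))
  simp <- simulate_phenotype(sim, qtl_variance = 0, pop_effect_sd = 8)
  g <- impute_missing(maf_filter(filter_gbs(simp$genotypes)$matrix, 0.05),
                      seed = 4L)$genotypes
  y <- setNames(simp$phenotype$days_to_flowering, simp$phenotype$accession_id)
  naive <- mlm_assoc(y, g)
  K <- kinship(g)
  Q <- fit_admixture(g, 3L, seed = 7L)$Q
  corrected <- mlm_assoc(y, g, Q = Q, K = K)
  l_naive <- attr(qq_data(naive), "lambda_gc")
  l_corr <- attr(qq_data(corrected), "lambda_gc")
  expect_lt(abs(l_corr - 1), abs(l_naive - 1))
})
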