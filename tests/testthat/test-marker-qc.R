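test_that("marker stats: call rate, MAF and PIC from direct counts", {
  # 10 accessions, 2 missing, 3 ALT among the 8 called
  calls <- matrix(c(1L, 1L, 1L, 0L, 0L, 0L, 0L, 0L, NA, NA), 1)
  g <- geno_matrix(calls, "m", 1L, 1L, sprintf("a%d", 1:10))
  st <- marker_stats(g)
  expect_equal(st$call_rate, 0.8)
  expect_equal(st$maf, 0.375)
  expect_equal(st$pic, 1 - (0.375^2 + 0.625^2))

  # p = 0.5 attains the PIC maximum of 0.5
  g2 <- geno_matrix(matrix(c(0L, 1L, 0L, 1L), 1), "m", 1L, 1L,
                    sprintf("a%d", 1:4))
  expect_equal(marker_stats(g2)$pic, 0.5)

  # monomorphic: pic = 0, maf = 0
  g3 <- geno_matrix(matrix(rep(1L, 4), 1), "m", 1L, 1L, sprintf("a%d", 1:4))
  st3 <- marker_stats(g3)
  expect_equal(st3$pic, 0)
  expect_equal(st3$maf, 0)
  expect_true(st3$monomorphic)

  g4 <- geno_matrix(matrix(c(NA_integer_, 0L, NA_integer_, 1L), 2),
                    c("x", "y"), c(1L, 1L), c(1L, 2L), c("a", "b"))
  expect_error(marker_stats(g4), "all-missing")
})

test_that("PIC stays within [0, 0.5] on random markers", {
  set.seed(1)
  calls <- matrix(rbinom(5000, 1, runif(100)), 100, 50)
  g <- geno_matrix(calls, sprintf("m%d", 1:100), rep(1L, 100), 1:100,
                   sprintf("a%d", 1:50))
  st <- marker_stats(g)
  expect_true(all(st$pic >= 0 & st$pic <= 0.5))
  expect_true(all(st$maf <= 0.5))
  expect_identical(st$pic == 0, st$monomorphic)
})

make_dart <- function(scores, intensities = NULL, pairs = NULL) {
  dart_matrix(scores, sprintf("c%d", seq_len(nrow(scores))),
              sprintf("s%d", seq_len(ncol(scores))),
              intensities = intensities, replicate_pairs = pairs)
}

test_that("reproducibility counts mismatches over comparable replicate calls", {
  scores <- rbind(rep(c(1L, 1L), 5),                  # identical replicates
                  c(1L, 0L, rep(c(0L, 0L), 4), 1L, 1L)[1:10],
                  c(1L, NA, rep(c(0L, 0L), 4))[1:10])
  pairs <- data.frame(a = paste0("s", c(1, 3, 5, 7, 9)),
                      b = paste0("s", c(2, 4, 6, 8, 10)))
  d <- make_dart(scores, pairs = pairs)
  r <- dart_reproducibility(d)
  expect_equal(unname(r["c1"]), 1.0)
  expect_equal(unname(r["c2"]), 1 - 1 / 5)    # one mismatch in 5 comparisons
  expect_equal(unname(r["c3"]), 1.0)          # missing pair excluded: 4 of 4
})

test_that("cluster-variance quality index equals the ANOVA SS ratio", {
  # perfectly separated constant clusters
  expect_equal(dart_quality_p(c(1, 1, 5, 5), c(0L, 0L, 1L, 1L)), 1.0)
  # equal cluster means
  expect_equal(dart_quality_p(c(1, 3, 1, 3), c(0L, 0L, 1L, 1L)), 0.0)
  expect_error(dart_quality_p(c(1, 2, 3), c(1L, 1L, 1L)), "single score cluster")

  set.seed(8)
  y <- rnorm(40); s <- rep(c(0L, 1L), 20)
  # brute-force sums of squares
  ssb <- sum(tapply(y, s, length) * (tapply(y, s, mean) - mean(y))^2)
  sst <- sum((y - mean(y))^2)
  expect_equal(dart_quality_p(y, s), ssb / sst, tolerance = 1e-12)
  p <- dart_quality_p(y, s)
  expect_true(p >= 0 && p <= 1)
})

test_that("DArT filter cascade matches the brute-force predicates and is idempotent", {
  set.seed(3)
  m <- 20; n <- 20
  scores <- matrix(rbinom(m * n, 1L, 0.5), m, n)
  scores[1, ] <- 1L                              # monomorphic
  scores[2, sample(n, 5)] <- NA                  # 25% missing
  inten <- matrix(rnorm(m * n), m, n) + scores * 4
  inten[3, ] <- rnorm(n)                         # low quality marker
  pairs <- data.frame(a = paste0("s", 1:3), b = paste0("s", 4:6))
  scores[4, 1:3] <- 1L; scores[4, 4:6] <- 0L     # irreproducible
  d <- make_dart(scores, intensities = inten, pairs = pairs)

  res <- filter_dart(d)
  st <- marker_stats(d)
  q <- vapply(1:m, function(i) tryCatch(
    dart_quality_p(inten[i, ], scores[i, ]), error = function(e) NA_real_), 0)
  r <- dart_reproducibility(d)
  expected <- !st$monomorphic & (is.na(r) | r >= 0.99) & (is.na(q) | q >= 0.8) &
    (1 - st$call_rate) <= 0.10
  expect_identical(res$matrix$clone_ids, d$clone_ids[expected])
  expect_false("c1" %in% res$matrix$clone_ids)
  expect_equal(res$report$n_input, m)
  # survivor counts non-increasing along the cascade
  expect_true(res$report$n_polymorphic >= res$report$n_quality)
  expect_true(res$report$n_quality >= res$report$n_call_rate)
  # each removal attributed to exactly one cause
  expect_equal(nrow(res$report$removed) + res$report$n_call_rate, m)
  # idempotent
  res2 <- filter_dart(res$matrix)
  expect_identical(res2$matrix$clone_ids, res$matrix$clone_ids)
})

test_that("a marker just over 10% missing is removed; at 20% the GBS rule keeps it", {
  scores <- matrix(rbinom(18 * 2, 1L, 0.5), 2, 18)
  scores[1, 1:2] <- NA                           # 2/18 = 11.1% missing
  scores[2, 1] <- 1L; scores[2, 2] <- 0L
  d <- make_dart(scores)
  res <- filter_dart(d)
  expect_false("c1" %in% res$matrix$clone_ids)

  calls <- matrix(rbinom(3 * 10, 1L, 0.5), 3, 10)
  calls[1, 1:2] <- NA                            # exactly 20%: retained
  calls[2, 1:3] <- NA                            # 30%: removed
  calls[1, 3] <- 1L; calls[2, 4] <- 1L; calls[3, 1] <- 1L
  g <- geno_matrix(calls, c("k1", "k2", "k3"), rep(1L, 3), 1:3,
                   sprintf("a%d", 1:10))
  g$pos[3] <- NA                                 # unmapped
  res_g <- filter_gbs(g)
  expect_identical(res_g$matrix$marker_ids, "k1")
  expect_equal(res_g$report$n_no_position, 1L)
  expect_equal(res_g$report$n_too_missing, 1L)
})

test_that("identical-pattern collapse is strict about the missing mask", {
  calls <- rbind(c(1L, 0L, NA, 1L),
                 c(1L, 0L, NA, 1L),     # exact duplicate of row 1
                 c(1L, 0L, 0L, 1L),     # differs only where row 1 is missing
                 c(0L, 1L, 1L, 0L))
  d <- make_dart(calls)
  res <- collapse_identical(d)
  expect_identical(res$matrix$clone_ids, c("c1", "c3", "c4"))
  expect_equal(res$groups, list(c("c1", "c2")))

  # planted duplicate triplet in a random matrix found as one group of 3
  set.seed(9)
  calls2 <- matrix(rbinom(30 * 8, 1L, 0.5), 30, 8)
  calls2[12, ] <- calls2[25, ] <- calls2[4, ]
  res2 <- collapse_identical(make_dart(calls2))
  grp <- res2$groups[vapply(res2$groups, function(g) "c4" %in% g, NA)]
  expect_equal(grp, list(c("c4", "c12", "c25")))
})

test_that("density report finds the planted gap census", {
  g <- geno_matrix(matrix(rep(c(0L, 1L), 4), 4), c("a", "b", "c", "d"),
                   rep(1L, 4), c(1L, 400001L, 400100L, 1000200L),
                   c("x", "y"))
  rep <- density_report(g)
  expect_equal(nrow(rep$gaps), 2)
  expect_identical(sort(rep$gaps$class),
                   sort(c("300-500kb", ">500kb")))

  # gap census equals a brute-force scan on a random layout
  set.seed(10)
  pos <- sort(sample.int(5e6, 60))
  g2 <- geno_matrix(matrix(rbinom(120, 1L, 0.5), 60), sprintf("m%d", 1:60),
                    rep(1L, 60), pos, c("x", "y"))
  rep2 <- density_report(g2)
  brute <- diff(pos)[diff(pos) >= 3e5]
  expect_equal(sort(rep2$gaps$size), sort(brute))
  expect_equal(rep2$mean_gap_bp, mean(diff(pos)))

  # equal counts on equal-length chromosomes: correlation undefined
  g3 <- geno_matrix(matrix(rbinom(12, 1L, 0.5), 6), sprintf("m%d", 1:6),
                    rep(1:3, each = 2), rep(c(1L, 1000L), 3), c("x", "y"))
  expect_true(is.na(density_report(g3)$count_length_cor$estimate))
})
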