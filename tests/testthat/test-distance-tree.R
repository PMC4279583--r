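test_that("Sokal-Michener distance follows u/(m+u) over comparable loci", {
  scores <- rbind(c(1L, 1L), c(0L, 0L), c(1L, 1L), c(0L, 1L))
  d <- dart_matrix(scores, sprintf("c%d", 1:4), c("a", "b"))
  dm <- sokal_michener(d)
  expect_equal(dm$d["a", "b"], 1 / 4)            # u = 1, m = 3
  expect_equal(dm$pairwise_support["a", "b"], 4)
  expect_equal(dm$d["a", "a"], 0)

  # identical and fully complementary vectors hit the bounds
  sc2 <- cbind(a = c(1L, 0L, 1L), b = c(1L, 0L, 1L), c = c(0L, 1L, 0L))
  dm2 <- sokal_michener(dart_matrix(sc2, sprintf("c%d", 1:3), colnames(sc2)))
  expect_equal(dm2$d["a", "b"], 0)
  expect_equal(dm2$d["a", "c"], 1)
})

test_that("shared-allele distance equals the brute-force mismatch fraction", {
  set.seed(4)
  calls <- matrix(sample(c(0L, 1L, NA), 200, TRUE, c(.45, .45, .1)), 50, 4)
  g <- geno_matrix(calls, sprintf("m%d", 1:50), rep(1L, 50), 1:50,
                   c("w", "x", "y", "z"))
  dm <- shared_allele_distance(g)
  for (i in 1:3) for (j in (i + 1):4) {
    both <- !is.na(calls[, i]) & !is.na(calls[, j])
    expect_equal(dm$d[i, j], mean(calls[both, i] != calls[both, j]))
    expect_equal(dm$d[j, i], dm$d[i, j])
  }
  expect_true(all(dm$d >= 0 & dm$d <= 1))

  # a pair with no comparable locus is an error naming the pair
  calls2 <- cbind(a = c(1L, NA), b = c(NA, 0L))
  g2 <- geno_matrix(calls2, c("m1", "m2"), c(1L, 1L), 1:2, c("a", "b"))
  expect_error(shared_allele_distance(g2), "a/b")
})

test_that("NJ recovers additive distances exactly (50 random 8-leaf trees)", {
  for (s in 1:50) {
    ref <- random_additive_matrix(8, seed = s)
    tr <- nj_tree(as_dist_matrix(ref$d))
    d_hat <- ape::cophenetic.phylo(tr)[rownames(ref$d), colnames(ref$d)]
    expect_lt(max(abs(d_hat - ref$d)), 1e-9)
  }
})

test_that("three leaves solve the closed-form three-point formulas", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(as_dist_matrix(d))
  pl <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(pl["a"]), (3 + 4 - 5) / 2)
  expect_equal(unname(pl["b"]), (3 + 5 - 4) / 2)
  expect_equal(unname(pl["c"]), (4 + 5 - 3) / 2)
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2)), "symmetric|3")
})

test_that("NJ is deterministic under ties and clips negative branches", {
  d <- matrix(1, 4, 4) - diag(4)
  dimnames(d) <- list(letters[1:4], letters[1:4])
  t1 <- nj_tree(as_dist_matrix(d))
  t2 <- nj_tree(as_dist_matrix(d))
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_true(all(t1$edge.length >= 0))
})

test_that("max length subtree drops zero-distance duplicates first", {
  ref <- random_additive_matrix(6, seed = 99)
  d <- ref$d
  # plant an exact duplicate of the first accession
  d <- rbind(cbind(d, dup = d[, 1]), dup = c(d[1, ], 0))
  rownames(d)[7] <- colnames(d)[7] <- "dup"
  sel <- max_length_subtree(as_dist_matrix(d), n_keep = 6)
  expect_equal(sel$loss_trace[1], 0)
  expect_true(sel$removed[1] %in% c("t1", "dup") ||
                !all(c("t1", "dup") %in% sel$kept))
})

test_that("keeping everything changes nothing; selection is anti-monotone", {
  ref <- random_additive_matrix(7, seed = 5)
  dm <- as_dist_matrix(ref$d)
  all7 <- max_length_subtree(dm, n_keep = 7)
  expect_setequal(all7$kept, rownames(ref$d))

  lens <- vapply(7:4, function(k) {
    sel <- max_length_subtree(dm, n_keep = k)
    sum(sel$tree$edge.length)
  }, 0)
  expect_true(all(diff(lens) <= 1e-9))
  expect_error(max_length_subtree(dm, 2), "at least 3")
})

test_that("greedy selection stays within the exhaustive-subset optimum", {
  ref <- random_additive_matrix(6, seed = 17)
  dm <- as_dist_matrix(ref$d)
  for (mode in c("prune", "recompute")) {
    sel <- max_length_subtree(dm, n_keep = 4, mode = mode)
    best <- max(apply(combn(rownames(ref$d), 4), 2, function(keep) {
      sum(nj_tree(as_dist_matrix(ref$d[keep, keep]))$edge.length)
    }))
    expect_lte(sum(sel$tree$edge.length), best + 1e-9)
  }

  # under extreme redundancy (duplicated leaves) greedy attains the optimum
  base <- random_additive_matrix(4, seed = 3)$d
  dup <- base[c(1:4, 1, 2), c(1:4, 1, 2)]
  rownames(dup)[5:6] <- colnames(dup)[5:6] <- c("d1", "d2")
  sel <- max_length_subtree(as_dist_matrix(dup), n_keep = 4)
  opt <- max(apply(combn(rownames(dup), 4), 2, function(keep) {
    sum(nj_tree(as_dist_matrix(dup[keep, keep]))$edge.length)
  }))
  expect_equal(sum(sel$tree$edge.length), opt, tolerance = 1e-9)
})

test_that("tree annotation tags leaves and survives a comment-stripping round trip", {
  ref <- random_additive_matrix(5, seed = 21)
  tr <- nj_tree(as_dist_matrix(ref$d))
  labmap <- data.frame(accession_id = rownames(ref$d)[1:3],
                       population = c("I1", "I2", "J1"),
                       ecosystem = c("upland", NA, "irrigated"))
  ann <- annotate_tree(tr, labmap)
  expect_equal(sum(gregexpr("[&", ann$newick, fixed = TRUE)[[1]] > 0), 5)
  got <- setNames(ann$table$population, ann$table$accession_id)
  expect_identical(unname(got[labmap$accession_id]), labmap$population)
  expect_true(all(got[setdiff(tr$tip.label, labmap$accession_id)] == "unknown"))
  expect_identical(ann$table$ecosystem[match(labmap$accession_id[2],
                                             ann$table$accession_id)],
                   "unknown")
  tr2 <- ape::read.tree(text = strip_newick_comments(ann$newick))
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), ape::unroot(tr2))), 0)
})
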