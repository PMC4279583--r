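# Dissimilarity matrices, unweighted neighbor-joining trees and
# core-collection selection by maximum length subtree pruning.

dist_matrix <- function(d, support, labels) {
  dimnames(d) <- list(labels, labels)
  dimnames(support) <- list(labels, labels)
  structure(list(labels = labels, d = d, pairwise_support = support),
            class = "dist_matrix")
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("<dist_matrix> %d accessions, range [%.3f, %.3f]\n",
              length(x$labels), min(x$d), max(x$d[upper.tri(x$d)])))
  invisible(x)
}

# mismatch proportion over pairwise-complete loci, shared across both indices
mismatch_dist <- function(calls, what) {
  n <- ncol(calls)
  X0 <- (!is.na(calls)) & calls == 0L
  X1 <- (!is.na(calls)) & calls == 1L
  match00 <- crossprod(X0)
  match11 <- crossprod(X1)
  obs <- crossprod(!is.na(calls))
  m <- match00 + match11
  u <- obs - m
  if (any(obs[upper.tri(obs)] == 0)) {
    bad <- which(obs == 0 & upper.tri(obs), arr.ind = TRUE)
    stop(what, ": no comparable marker for pair(s) ",
         paste(apply(bad, 1L, function(r)
           paste(colnames(calls)[r], collapse = "/")), collapse = ", "))
  }
  d <- u / obs
  diag(d) <- 0
  dist_matrix(d, obs, colnames(calls))
}

#' Sokal-Michener dissimilarity for dominant (DArT) markers
#'
#' \eqn{d_{ij} = u / (m + u)} where `u` is the number of non-matching and `m`
#' the number of matching scores between accessions i and j, counted over
#' markers where both calls are non-missing.
#'
#' @param d a [dart_matrix()].
#' @return a `dist_matrix` (symmetric, zero diagonal, values in \[0,1\],
#'   with per-pair comparable-locus counts in `pairwise_support`).
#' @export
sokal_michener <- function(d) {
  stopifnot(inherits(d, "dart_matrix"))
  mismatch_dist(d$scores, "sokal_michener")
}

#' Shared-allele dissimilarity for haploid-coded SNPs
#'
#' For inbred (haploid-coded) lines this is the proportion of comparable
#' loci at which the two accessions carry different alleles.
#'
#' @param g a [geno_matrix()].
#' @return a `dist_matrix`.
#' @export
shared_allele_distance <- function(g) {
  stopifnot(inherits(g, "geno_matrix"))
  mismatch_dist(g$calls, "shared_allele_distance")
}

#' Unweighted neighbor-joining tree
#'
#' Classical Saitou-Nei neighbor joining on a dissimilarity matrix. Negative
#' branch lengths are clipped to zero; the total clipped length is recorded
#' in the `"clipped_length"` attribute.
#'
#' @param dm a `dist_matrix` (or a plain symmetric matrix with dimnames).
#' @return an unrooted `phylo` tree (see \pkg{ape}) over the input labels.
#' @export
nj_tree <- function(dm) {
  d <- if (inherits(dm, "dist_matrix")) dm$d else as.matrix(dm)
  if (!isSymmetric(unname(d), tol = 1e-12))
    stop("distance matrix must be symmetric")
  if (nrow(d) < 3L) stop("neighbor joining needs at least 3 accessions")
  tr <- ape::nj(as.dist(d))
  deficit <- -sum(tr$edge.length[tr$edge.length < 0])
  tr$edge.length[tr$edge.length < 0] <- 0
  attr(tr, "clipped_length") <- deficit
  tr
}

tree_length <- function(tr) sum(tr$edge.length)

pendant_lengths <- function(tr) {
  ntip <- length(tr$tip.label)
  idx <- match(seq_len(ntip), tr$edge[, 2])
  setNames(tr$edge.length[idx], tr$tip.label)
}

#' Core-collection selection by maximum length subtree pruning
#'
#' Greedy backward elimination of the most redundant accessions: at each
#' step the leaf whose removal loses the least total tree length is dropped,
#' until `n_keep` accessions remain. Two modes: `"prune"` (default) drops
#' the tip with the shortest pendant branch from the current tree;
#' `"recompute"` rebuilds the NJ tree from the distance submatrix for every
#' candidate removal and keeps the subset of maximal total length. Ties are
#' broken by label order.
#'
#' @param dm a `dist_matrix`.
#' @param n_keep number of accessions to retain (>= 3).
#' @param mode `"prune"` or `"recompute"`.
#' @return list with `kept` (accession ids), `removed` (in removal order),
#'   `loss_trace` (length lost at each step) and `tree` (NJ tree of the kept
#'   set).
#' @export
max_length_subtree <- function(dm, n_keep, mode = c("prune", "recompute")) {
  mode <- match.arg(mode)
  stopifnot(inherits(dm, "dist_matrix"))
  labels <- dm$labels
  if (n_keep < 3L) stop("n_keep must be at least 3")
  if (n_keep > length(labels)) stop("n_keep exceeds the number of accessions")
  removed <- character(0)
  loss <- numeric(0)
  current <- labels
  tr <- nj_tree(dm)
  while (length(current) > n_keep) {
    if (mode == "prune") {
      pl <- pendant_lengths(tr)
      pl <- pl[order(pl, names(pl))]       # deterministic tie-break
      victim <- names(pl)[1]
      step_loss <- unname(pl[1])
      tr <- ape::drop.tip(tr, victim)
    } else {
      before <- tree_length(tr)
      best <- NULL
      best_len <- -Inf
      for (cand in sort(current)) {
        rest <- setdiff(current, cand)
        sub <- dist_matrix(dm$d[rest, rest, drop = FALSE],
                           dm$pairwise_support[rest, rest, drop = FALSE], rest)
        len <- tree_length(nj_tree(sub))
        if (len > best_len + 1e-12) {
          best_len <- len
          best <- cand
        }
      }
      victim <- best
      step_loss <- before - best_len
      current2 <- setdiff(current, victim)
      tr <- nj_tree(dist_matrix(dm$d[current2, current2, drop = FALSE],
                                dm$pairwise_support[current2, current2, drop = FALSE],
                                current2))
    }
    current <- setdiff(current, victim)
    removed <- c(removed, victim)
    loss <- c(loss, step_loss)
  }
  list(kept = current, removed = removed, loss_trace = loss, tree = tr)
}

#' Annotate tree leaves and serialize to newick with comment tags
#'
#' Projects per-accession annotations (population assignment, ecosystem,
#' maturity class, ...) onto the tree as bracketed newick comments appended
#' to each leaf. Missing annotations are rendered `"unknown"`.
#'
#' @param tree a `phylo` tree.
#' @param labels_map data frame keyed by `accession_id`, remaining columns
#'   are annotations; or a named list of named vectors.
#' @return list with `newick` (annotated string), `table` (leaf annotation
#'   data frame). Stripping `[...]` comments from `newick` restores a
#'   parseable newick string with the original topology.
#' @export
annotate_tree <- function(tree, labels_map) {
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  if (is.data.frame(labels_map)) {
    if (!"accession_id" %in% names(labels_map))
      stop("labels_map needs an accession_id column")
    ann <- labels_map[match(tips, labels_map$accession_id), -1, drop = FALSE]
  } else {
    ann <- as.data.frame(lapply(labels_map, function(v) unname(v[tips])),
                         stringsAsFactors = FALSE)
  }
  ann[] <- lapply(ann, function(v) {
    v <- as.character(v)
    v[is.na(v) | v == ""] <- "unknown"
    v
  })
  tab <- data.frame(accession_id = tips, ann, row.names = NULL,
                    stringsAsFactors = FALSE)
  nwk <- ape::write.tree(tree)
  for (i in seq_along(tips)) {
    tag <- paste0("[&", paste(names(ann), unlist(ann[i, ]), sep = "=",
                              collapse = ","), "]")
    # tip labels in newick are followed by ':' (branch length) or ,/)
    nwk <- sub(paste0("([(,])", tips[i], "([:,)])"),
               paste0("\\1", tips[i], tag, "\\2"), nwk)
  }
  list(newick = nwk, table = tab)
}

#' Strip newick comment tags
#'
#' @param newick an annotated newick string from [annotate_tree()].
#' @return the plain newick string.
#' @export
strip_newick_comments <- function(newick) gsub("\\[[^]]*\\]", "", newick)
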