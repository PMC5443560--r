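#' Cluster voxels by their largest factorization weight
#'
#' Assigns every voxel (column of `H`) to the basis vector with the
#' largest weight — the clustering rule that exploits the categorical,
#' one-dominant-weight structure of NMF voxel representations. Exact ties
#' are broken toward the lowest row index and flagged; all-zero weight
#' columns are assigned cluster 1 and flagged empty.
#'
#' @param H Non-negative s-by-n weight matrix (or an `nmf_fit`).
#' @return An object of class `cluster_assignment`: list with integer
#'   vector `cluster` (one entry per voxel, values in `1..s`), logical
#'   vectors `tie` and `empty`, and `s`.
#' @export
assign_clusters <- function(H) {
  if (inherits(H, "nmf_fit")) H <- H$H
  if (any(H < 0)) stop("`H` must be non-negative", call. = FALSE)
  n <- ncol(H)
  cluster <- max.col(t(H), ties.method = "first")
  peak <- H[cbind(cluster, seq_len(n))]
  tie <- colSums(H == rep(peak, each = nrow(H))) > 1L
  empty <- colSums(H) == 0
  tie[empty] <- FALSE
  structure(list(cluster = as.integer(cluster), tie = tie, empty = empty,
                 s = nrow(H)),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> %d voxels in %d clusters (%d ties, %d empty)\n",
              length(x$cluster), x$s, sum(x$tie), sum(x$empty)))
  print(table(cluster = x$cluster))
  invisible(x)
}

#' Sort weight-matrix columns by peak row to expose block structure
#'
#' Reorders the columns of `H` so that voxels are grouped by the basis
#' vector on which they peak (groups in ascending row order) and, within a
#' group, ordered by descending peak value. Row contents and values are
#' untouched; only the column order changes. Plotted as a heatmap, the
#' result reveals the block-diagonal structure of an NMF parcellation.
#'
#' @param H Non-negative s-by-n weight matrix (or an `nmf_fit`).
#' @return A list with `order` (the column permutation), `H_sorted`
#'   (`H[, order]`) and `assignment` (the [assign_clusters()] result on
#'   the original `H`).
#' @export
sort_weights_by_peak <- function(H) {
  if (inherits(H, "nmf_fit")) H <- H$H
  asg <- assign_clusters(H)
  peak <- H[cbind(asg$cluster, seq_len(ncol(H)))]
  ord <- order(asg$cluster, -peak)
  list(order = ord, H_sorted = H[, ord, drop = FALSE], assignment = asg)
}

#' Average weight vector of each cluster block
#'
#' For each requested cluster, the arithmetic mean of the weight columns of
#' its member voxels — the length-s profile summarising how exclusively
#' that block loads on its own basis dimension (conventionally drawn as a
#' polar plot per block).
#'
#' @param H Non-negative s-by-n weight matrix (or an `nmf_fit`).
#' @param assignment A [cluster_assignment()] for the columns of `H`; if
#'   missing, computed from `H`.
#' @param clusters Integer vector of cluster indices to summarise
#'   (default: all of `1..s`).
#' @return An s-by-length(clusters) matrix; column `k` is cluster `k`'s
#'   mean weight vector.
#' @export
block_profiles <- function(H, assignment = NULL, clusters = NULL) {
  if (inherits(H, "nmf_fit")) H <- H$H
  if (is.null(assignment)) assignment <- assign_clusters(H)
  s <- nrow(H)
  if (is.null(clusters)) clusters <- seq_len(s)
  out <- vapply(clusters, function(k) {
    member <- assignment$cluster == k
    if (!any(member)) {
      stop(sprintf("cluster %d has no member voxels", k), call. = FALSE)
    }
    rowMeans(H[, member, drop = FALSE])
  }, numeric(s))
  colnames(out) <- sprintf("cluster_%d", clusters)
  out
}

#' Hierarchical clustering of the NMF basis vectors
#'
#' Computes pairwise Euclidean distances between the columns of the basis
#' matrix `W` (the signature expression profiles) and builds an
#' agglomerative dendrogram, summarising how similar the discovered
#' genomic territories are to one another.
#'
#' @param W m-by-s basis matrix (or an `nmf_fit`), `s >= 2`.
#' @param method Linkage passed to [stats::hclust()]; `"complete"` by
#'   default.
#' @return An [stats::hclust] tree over the s basis vectors.
#' @export
basis_dendrogram <- function(W, method = "complete") {
  if (inherits(W, "nmf_fit")) W <- W$W
  if (ncol(W) < 2L) stop("need at least 2 basis vectors for a dendrogram", call. = FALSE)
  stats::hclust(stats::dist(t(W), method = "euclidean"), method = method)
}

# all permutations of 1..n (n <= 8), in lexicographic order
permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(first) {
    rest <- seq_len(n)[-first]
    cbind(first, matrix(rest[sub], nrow(sub)))
  }))
}

#' Classification accuracy under the best label permutation
#'
#' Cluster labels are arbitrary, so a clustering is compared against
#' reference labels after relabelling the clusters by the
#' accuracy-maximising permutation (exact exhaustive search; intended for
#' the small-s regime, s <= 8). Both labelings must use values in `1..s`.
#'
#' @param cluster Integer vector of predicted cluster indices (or a
#'   [cluster_assignment()]).
#' @param truth Integer vector of reference labels, same length.
#' @param s Number of classes; default `max(cluster, truth)`.
#' @return A list with `accuracy` (fraction of voxels correct under the
#'   best permutation), `permutation` (`permutation[k]` is the truth label
#'   assigned to cluster `k`) and `correct` (per-voxel logical under that
#'   permutation).
#' @export
classification_accuracy <- function(cluster, truth, s = NULL) {
  if (inherits(cluster, "cluster_assignment")) cluster <- cluster$cluster
  stopifnot(length(cluster) == length(truth))
  if (is.null(s)) s <- max(cluster, truth)
  if (s > 8L) stop("exhaustive permutation matching supports at most 8 classes", call. = FALSE)
  conf <- matrix(0L, s, s)
  tab <- table(factor(cluster, levels = seq_len(s)), factor(truth, levels = seq_len(s)))
  conf[] <- tab
  perms <- permutations(s)
  scores <- vapply(seq_len(nrow(perms)), function(i) {
    sum(conf[cbind(seq_len(s), perms[i, ])])
  }, 0)
  best <- perms[which.max(scores), ]
  mapped <- best[cluster]
  list(accuracy = max(scores) / length(cluster),
       permutation = as.integer(best),
       correct = mapped == truth)
}

#' Classification accuracy as a function of gene count
#'
#' Quantifies how many genes the factorization needs to recover a known
#' parcellation: for each gene count `g` and each of `reps` repetitions,
#' `g` genes are sampled uniformly without replacement, the sampled
#' submatrix is factorized at rank `s`, voxels are clustered by largest
#' weight, and the clustering is scored against `truth_labels` under the
#' best label permutation. Reported per gene count are the mean accuracy
#' over repetitions and the fraction of voxels classified correctly in
#' every repetition ("perfectly classified voxels"); the full per-rep
#' accuracy matrix is kept so alternative summaries can be recomputed.
#'
#' @param atlas An [expression_atlas()].
#' @param truth_labels Integer vector (one per voxel) with values in
#'   `1..s`.
#' @param gene_counts Increasing integer vector of gene subset sizes, each
#'   `<= nrow(atlas)`.
#' @param reps Repetitions (independent gene samples) per count.
#' @param s Subspace size; must equal the number of truth classes.
#' @param seed Master seed; gene sampling and factorizations for each
#'   (count, rep) pair are seeded deterministically from it.
#' @param nmf_args List of extra arguments passed on to [als_nmf()]
#'   (e.g. `max_iter`, `tol`, `restarts`).
#' @return An object of class `accuracy_curve`: data frame with columns
#'   `gene_count`, `mean_accuracy`, `perfect_fraction`, with attributes
#'   `rep_accuracy` (counts x reps matrix), `reps` and `seed`.
#' @export
accuracy_vs_gene_count <- function(atlas, truth_labels, gene_counts, reps, s,
                                   seed = 1L, nmf_args = list()) {
  stopifnot(inherits(atlas, "expression_atlas"))
  m <- nrow(atlas$matrix)
  n <- ncol(atlas$matrix)
  if (length(truth_labels) != n) stop("one truth label per voxel required", call. = FALSE)
  if (length(unique(truth_labels)) != s) {
    stop("truth_labels must contain exactly s classes", call. = FALSE)
  }
  if (any(gene_counts > m)) stop("gene count exceeds number of genes", call. = FALSE)
  if (reps < 1L) stop("reps must be >= 1", call. = FALSE)

  n_seeds <- length(gene_counts) * reps
  sub_seeds <- matrix(withr::with_seed(seed, sample.int(2147483646L, 2L * n_seeds)),
                      nrow = 2L)
  rep_acc <- matrix(NA_real_, length(gene_counts), reps)
  perfect <- numeric(length(gene_counts))
  idx <- 0L
  for (ci in seq_along(gene_counts)) {
    g <- gene_counts[ci]
    correct_all <- rep(TRUE, n)
    for (ri in seq_len(reps)) {
      idx <- idx + 1L
      rows <- withr::with_seed(sub_seeds[1L, idx], sample.int(m, g))
      A_sub <- atlas$matrix[rows, , drop = FALSE]
      fit <- do.call(als_nmf, c(list(A = A_sub, s = s, seed = sub_seeds[2L, idx]),
                                nmf_args))
      res <- classification_accuracy(assign_clusters(fit), truth_labels, s = s)
      rep_acc[ci, ri] <- res$accuracy
      correct_all <- correct_all & res$correct
    }
    perfect[ci] <- mean(correct_all)
  }
  out <- data.frame(gene_count = gene_counts,
                    mean_accuracy = rowMeans(rep_acc),
                    perfect_fraction = perfect)
  structure(out, rep_accuracy = rep_acc, reps = as.integer(reps),
            seed = as.integer(seed),
            class = c("accuracy_curve", "data.frame"))
}
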