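#' Per-gene mean expression over two voxel sets
#'
#' Computes, for every gene, the arithmetic mean expression over each of
#' two disjoint voxel sets — e.g. the anterior and posterior halves of a
#' structure whose molecular asymmetry is being screened.
#'
#' @param atlas An [expression_atlas()].
#' @param voxels_a,voxels_b Disjoint, non-empty voxel selections: character
#'   vectors of voxel IDs or integer column indices.
#' @return A data frame with columns `gene_id`, `mean_a`, `mean_b`.
#' @export
region_means <- function(atlas, voxels_a, voxels_b) {
  stopifnot(inherits(atlas, "expression_atlas"))
  resolve <- function(v) {
    if (is.character(v)) {
      idx <- match(v, atlas$lookup$voxel_id)
      if (anyNA(idx)) stop("unknown voxel ID(s): ",
                           paste(v[is.na(idx)], collapse = ", "), call. = FALSE)
      idx
    } else as.integer(v)
  }
  ia <- resolve(voxels_a)
  ib <- resolve(voxels_b)
  if (length(ia) == 0L || length(ib) == 0L) {
    stop("both voxel sets must be non-empty", call. = FALSE)
  }
  if (length(intersect(ia, ib)) > 0L) {
    stop("voxel sets must be disjoint", call. = FALSE)
  }
  data.frame(
    gene_id = atlas$genes$gene_id,
    mean_a = unname(rowMeans(atlas$matrix[, ia, drop = FALSE])),
    mean_b = unname(rowMeans(atlas$matrix[, ib, drop = FALSE])),
    stringsAsFactors = FALSE
  )
}

#' Split a region's voxels into two halves along a grid axis
#'
#' Convenience for anterior/posterior style contrasts: the voxels of
#' `region` are bisected at the median of their coordinates along `axis`;
#' voxels strictly below the median form set A, the rest set B.
#'
#' @param atlas An [expression_atlas()].
#' @param region Region label whose voxels are split.
#' @param axis One of `"x"`, `"y"`, `"z"`.
#' @return A list with character vectors `a` and `b` of voxel IDs.
#' @export
split_region <- function(atlas, region, axis = c("x", "y", "z")) {
  axis <- match.arg(axis)
  sub <- select_regions(atlas, region)
  coord <- sub$lookup[[axis]]
  cut <- stats::median(coord)
  a <- sub$lookup$voxel_id[coord < cut]
  b <- sub$lookup$voxel_id[coord >= cut]
  if (length(a) == 0L || length(b) == 0L) {
    stop(sprintf("median split along %s leaves an empty half", axis), call. = FALSE)
  }
  list(a = a, b = b)
}

#' Differential enrichment scores with SD-threshold flagging
#'
#' Converts per-gene region means into a differential enrichment screen.
#' The primary score is the normalized contrast
#' `(mean_a - mean_b) / (mean_a + mean_b + eps)` — bounded in \[-1, 1\],
#' invariant to global rescaling of the expression matrix, positive when a
#' gene is enriched in region A. The raw difference `mean_a - mean_b` is
#' also reported so either convention can be screened. Scores are
#' standardised against the empirical distribution of the chosen score
#' across genes, and genes whose standardised score exceeds `k_sd`
#' standard deviations in magnitude are flagged as asymmetric.
#'
#' @param means Data frame from [region_means()] (columns `gene_id`,
#'   `mean_a`, `mean_b`), computed for at least 4 genes.
#' @param k_sd Flagging threshold in standard deviations (default 4).
#' @param type Which score the z-standardisation and flags use:
#'   `"normalized"` (default) or `"raw"`.
#' @param eps Stabiliser in the normalized contrast's denominator.
#' @return An object of class `enrichment_table`: data frame with columns
#'   `gene_id`, `mean_a`, `mean_b`, `score_norm`, `score_raw`, `z`,
#'   `flagged`; attributes `k_sd` and `score_type`.
#' @export
enrichment_scores <- function(means, k_sd = 4, type = c("normalized", "raw"),
                              eps = .Machine$double.eps) {
  type <- match.arg(type)
  stopifnot(all(c("gene_id", "mean_a", "mean_b") %in% names(means)))
  if (nrow(means) < 4L) {
    stop("need at least 4 genes to standardise enrichment scores", call. = FALSE)
  }
  score_norm <- (means$mean_a - means$mean_b) / (means$mean_a + means$mean_b + eps)
  score_raw <- means$mean_a - means$mean_b
  score <- if (type == "normalized") score_norm else score_raw
  sd_s <- stats::sd(score)
  if (sd_s == 0) stop("all enrichment scores identical; SD is zero", call. = FALSE)
  z <- (score - mean(score)) / sd_s
  out <- data.frame(gene_id = means$gene_id,
                    mean_a = means$mean_a, mean_b = means$mean_b,
                    score_norm = score_norm, score_raw = score_raw,
                    z = z, flagged = abs(z) > k_sd,
                    stringsAsFactors = FALSE)
  structure(out, k_sd = k_sd, score_type = type,
            class = c("enrichment_table", "data.frame"))
}

#' @export
print.enrichment_table <- function(x, ...) {
  cat(sprintf("<enrichment_table> %d genes, %d flagged (|z| > %g, %s score)\n",
              nrow(x), sum(x$flagged), attr(x, "k_sd"), attr(x, "score_type")))
  NextMethod()
}

#' Histogram of enrichment scores
#'
#' Bins enrichment scores into fixed-width bins over their range. For
#' symmetric expression the distribution is sharply peaked at 0, with
#' asymmetric genes visible in the tails — most clearly on a log count
#' axis, which the `log_counts` flag records as plotting metadata.
#'
#' @param scores Numeric scores, or an [enrichment_scores()] table (its
#'   flagged score column is used).
#' @param breaks Number of bins (or a breaks vector, as in
#'   [graphics::hist()]).
#' @param log_counts Logical; recorded in the result to request a
#'   log-scaled count axis when plotted.
#' @return A list with `breaks`, `counts`, `mids` and `log_counts`;
#'   `sum(counts)` always equals the number of scores.
#' @export
score_histogram <- function(scores, breaks = 30, log_counts = FALSE) {
  if (inherits(scores, "enrichment_table")) {
    scores <- if (attr(scores, "score_type") == "raw") scores$score_raw else scores$score_norm
  }
  if (length(scores) < 1L) stop("need at least one score", call. = FALSE)
  if (length(unique(scores)) == 1L) {
    h <- list(breaks = c(scores[1L] - 0.5, scores[1L] + 0.5),
              counts = length(scores), mids = scores[1L])
  } else {
    h <- graphics::hist(scores, breaks = breaks, plot = FALSE)
  }
  list(breaks = h$breaks, counts = h$counts, mids = h$mids,
       log_counts = isTRUE(log_counts))
}
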