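#' Per-gene cross-replicate Pearson correlations
#'
#' For each gene, computes the Pearson correlation of its expression
#' profile across matched voxels of two replicate atlases (e.g. atlases
#' built from independent sagittal and coronal image series). Genes whose
#' expression is constant in either replicate have no defined correlation
#' and are returned as `NA` with a reason, never silently dropped.
#'
#' @param atlas_a,atlas_b Two [expression_atlas()]s with identical gene
#'   lists and voxel sets.
#' @return A data frame with columns `gene_id`, `r` (`NA` where undefined)
#'   and `reason` (`"ok"` or `"zero_variance"`).
#' @export
replicate_correlations <- function(atlas_a, atlas_b) {
  stopifnot(inherits(atlas_a, "expression_atlas"),
            inherits(atlas_b, "expression_atlas"))
  if (!identical(atlas_a$genes$gene_id, atlas_b$genes$gene_id)) {
    stop("replicate atlases must share the same gene list", call. = FALSE)
  }
  if (!identical(atlas_a$lookup$voxel_id, atlas_b$lookup$voxel_id)) {
    stop("replicate atlases must share the same voxel set", call. = FALSE)
  }
  a <- atlas_a$matrix
  b <- atlas_b$matrix
  ctr_a <- a - rowMeans(a)
  ctr_b <- b - rowMeans(b)
  ss_a <- rowSums(ctr_a^2)
  ss_b <- rowSums(ctr_b^2)
  r <- rowSums(ctr_a * ctr_b) / sqrt(ss_a * ss_b)
  degenerate <- ss_a == 0 | ss_b == 0
  r[degenerate] <- NA_real_
  data.frame(
    gene_id = atlas_a$genes$gene_id,
    r = unname(r),
    reason = ifelse(degenerate, "zero_variance", "ok"),
    stringsAsFactors = FALSE
  )
}

#' Lowest-quartile reproducibility filter
#'
#' Applies the gene quality-control rule used to curate voxel-level
#' expression atlases: genes in the lowest quartile of the cross-replicate
#' correlation distribution are discarded and the remaining ~75% retained.
#' The cutoff is the empirical 25th percentile of the scorable correlations
#' (linear interpolation, [stats::quantile()] type 7); genes strictly below
#' the cutoff are discarded, ties at the cutoff are retained. Genes with
#' undefined correlation (constant expression) are discarded and reported
#' separately.
#'
#' @param r Numeric vector of per-gene correlations (possibly `NA`), or the
#'   data frame returned by [replicate_correlations()].
#' @return An object of class `qc_report`: a data frame with columns
#'   `gene_id`, `r`, `retained`, `reason`, plus attributes
#'   `quartile_cutoff`, `n_scorable` and `n_retained`.
#' @export
quartile_filter <- function(r) {
  if (is.data.frame(r)) {
    gene_id <- r$gene_id
    r <- r$r
  } else {
    gene_id <- if (is.null(names(r))) sprintf("g%04d", seq_along(r)) else names(r)
    r <- unname(r)
  }
  scorable <- !is.na(r)
  if (sum(scorable) < 4L) {
    stop("need at least 4 scorable genes to locate the lowest quartile", call. = FALSE)
  }
  cutoff <- unname(stats::quantile(r[scorable], probs = 0.25, type = 7))
  retained <- scorable & r >= cutoff
  reason <- rep("retained", length(r))
  reason[scorable & !retained] <- "lowest_quartile"
  reason[!scorable] <- "unscorable"
  out <- data.frame(gene_id = gene_id, r = r, retained = retained,
                    reason = reason, stringsAsFactors = FALSE)
  structure(out,
            quartile_cutoff = cutoff,
            n_scorable = sum(scorable),
            n_retained = sum(retained),
            class = c("qc_report", "data.frame"))
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(
    "<qc_report> %d genes: %d scorable, %d retained (cutoff r >= %.4f), %d unscorable\n",
    nrow(x), attr(x, "n_scorable"), attr(x, "n_retained"),
    attr(x, "quartile_cutoff"), sum(x$reason == "unscorable")
  ))
  NextMethod()
}
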