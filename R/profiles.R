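#' Rank genes within a basis vector
#'
#' Orders all genes by descending coefficient in one column of the basis
#' matrix `W` — the signature expression profile of one genomic territory.
#' The head of the ranking names the genes that define the territory.
#' Ties are broken by lexicographic gene ID so the ranking is total and
#' reproducible.
#'
#' @param W m-by-s basis matrix (or an `nmf_fit`); row names are used as
#'   gene IDs when `gene_ids` is not given.
#' @param cluster_index Column of `W` to rank, in `1..s`.
#' @param gene_ids Optional character vector of gene IDs (one per row).
#' @return An object of class `gene_ranking`: data frame with columns
#'   `rank`, `gene_id`, `coefficient` (non-increasing), plus attribute
#'   `cluster_index`.
#' @export
rank_genes <- function(W, cluster_index, gene_ids = NULL) {
  if (inherits(W, "nmf_fit")) W <- W$W
  if (cluster_index < 1L || cluster_index > ncol(W)) {
    stop(sprintf("cluster_index %d out of range [1, %d]", cluster_index, ncol(W)),
         call. = FALSE)
  }
  if (is.null(gene_ids)) gene_ids <- rownames(W)
  if (is.null(gene_ids)) gene_ids <- sprintf("g%04d", seq_len(nrow(W)))
  stopifnot(length(gene_ids) == nrow(W))
  w <- W[, cluster_index]
  ord <- order(-w, gene_ids, method = "radix")
  out <- data.frame(rank = seq_len(nrow(W)),
                    gene_id = gene_ids[ord],
                    coefficient = unname(w[ord]),
                    stringsAsFactors = FALSE)
  structure(out, cluster_index = as.integer(cluster_index),
            class = c("gene_ranking", "data.frame"))
}

#' Hoyer sparseness of a non-negative vector
#'
#' The standard scalar sparseness measure for NMF factors:
#' `(sqrt(m) - l1/l2) / (sqrt(m) - 1)` where `l1` and `l2` are the vector's
#' 1- and 2-norms and `m` its length. Equals 1 for a one-hot vector, 0 for
#' a constant vector, and is invariant to positive rescaling. Used to
#' quantify the observation that signature expression profiles have strong
#' "hits" for only a small subset of genes.
#'
#' @param w Non-negative, non-zero numeric vector of length >= 2.
#' @return A scalar in \[0, 1\].
#' @examples
#' sparseness(c(1, 0, 0, 0))  # 1
#' sparseness(c(1, 1, 1, 1))  # 0
#' @export
sparseness <- function(w) {
  if (any(w < 0)) stop("`w` must be non-negative", call. = FALSE)
  m <- length(w)
  if (m < 2L) stop("sparseness needs a vector of length >= 2", call. = FALSE)
  l2 <- sqrt(sum(w^2))
  if (l2 == 0) stop("sparseness of the zero vector is undefined", call. = FALSE)
  (sqrt(m) - sum(w) / l2) / (sqrt(m) - 1)
}

#' Histogram of basis-vector coefficients
#'
#' Bins the coefficients of a signature expression profile, either on a
#' linear scale or on a log10 scale. Under log binning, exact zeros cannot
#' be placed on the axis and are pooled into a dedicated zero bin; the
#' remaining counts cover the positive values. Total counts always sum to
#' the vector length. On planted data the log-scale histogram is bimodal:
#' background mass near zero plus a separated tail of signature-gene hits.
#'
#' @param w Non-negative numeric vector.
#' @param log_x Logical; bin `log10(w)` of the positive entries if `TRUE`.
#' @param breaks Number of bins (or breaks vector).
#' @return A list with `breaks`, `counts`, `mids`, `zero_count` (0 unless
#'   `log_x`) and `log_x`.
#' @export
profile_histogram <- function(w, log_x = FALSE, breaks = 30) {
  if (any(w < 0)) stop("`w` must be non-negative", call. = FALSE)
  if (log_x) {
    pos <- w[w > 0]
    zero_count <- sum(w == 0)
    if (length(pos) == 0L) {
      return(list(breaks = numeric(0), counts = integer(0), mids = numeric(0),
                  zero_count = zero_count, log_x = TRUE))
    }
    x <- log10(pos)
    if (length(unique(x)) == 1L) {
      h <- list(breaks = c(x[1L] - 0.5, x[1L] + 0.5), counts = length(x), mids = x[1L])
    } else {
      h <- graphics::hist(x, breaks = breaks, plot = FALSE)
    }
    list(breaks = h$breaks, counts = h$counts, mids = h$mids,
         zero_count = zero_count, log_x = TRUE)
  } else {
    if (length(unique(w)) == 1L) {
      h <- list(breaks = c(w[1L] - 0.5, w[1L] + 0.5), counts = length(w), mids = w[1L])
    } else {
      h <- graphics::hist(w, breaks = breaks, plot = FALSE)
    }
    list(breaks = h$breaks, counts = h$counts, mids = h$mids,
         zero_count = 0L, log_x = FALSE)
  }
}

#' Export per-cluster rank-ordered gene lists
#'
#' Writes one CSV per basis vector (columns `rank`, `gene_id`,
#' `coefficient`) plus a combined file with an extra `cluster` column —
#' the tabular companion to a parcellation, listing the genes that define
#' each genomic territory.
#'
#' @param W m-by-s basis matrix (or an `nmf_fit`).
#' @param dir Output directory (created if needed).
#' @param gene_ids Optional gene IDs (default: rownames of `W`).
#' @return Invisibly, the paths written.
#' @export
write_gene_rankings <- function(W, dir, gene_ids = NULL) {
  if (inherits(W, "nmf_fit")) W <- W$W
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  s <- ncol(W)
  paths <- character(0)
  combined <- list()
  for (k in seq_len(s)) {
    rk <- rank_genes(W, k, gene_ids = gene_ids)
    p <- file.path(dir, sprintf("cluster_%02d_gene_ranking.csv", k))
    utils::write.csv(as.data.frame(rk), p, row.names = FALSE, quote = FALSE)
    combined[[k]] <- cbind(cluster = k, as.data.frame(rk))
    paths <- c(paths, p)
  }
  p_all <- file.path(dir, "gene_rankings_all_clusters.csv")
  utils::write.csv(do.call(rbind, combined), p_all, row.names = FALSE, quote = FALSE)
  invisible(c(paths, p_all))
}
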