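#' Parameters for the synthetic atlas generator
#'
#' Bundles and validates the knobs of the synthetic expression-atlas
#' generator. The generator emulates the structure of a registered
#' voxel-level expression-energy atlas: a 3D grid partitioned into
#' spatially contiguous expression domains, each marked by a small set of
#' signature genes elevated inside the domain, on top of a large background
#' of near-ubiquitously expressed genes, with non-negative noise.
#'
#' The defaults describe the generator's reference condition: a 20x20x10
#' grid split into 4 block domains, 20 signature genes per domain at mean
#' 10 against a background mean of 1 (a 10:1 contrast), 200 background
#' genes, and gamma noise with dispersion 1 (variance equal to the mean).
#'
#' @param grid_shape Integer triple: voxels per axis; each dimension >= 2.
#' @param n_regions Number of planted spatial domains (>= 1).
#' @param n_signature_genes_per_region Signature genes per domain (>= 1).
#' @param n_background_genes Ubiquitous background genes (>= 1).
#' @param signature_mean Expected expression of a signature gene inside its
#'   domain (>= 0).
#' @param background_mean Expected expression everywhere else (>= 0).
#' @param noise_model One of `"gamma"` (default), `"lognormal"`,
#'   `"truncated-normal"`. Gamma and lognormal are parameterised to have
#'   mean equal to the planted mean and variance `mean * noise_dispersion`;
#'   the truncated normal clamps `N(mean, sqrt(mean * dispersion))` at 0,
#'   which slightly inflates the realised mean when the mean/sd ratio is
#'   small.
#' @param noise_dispersion Non-negative dispersion; 0 gives noiseless data
#'   exactly equal to the planted means.
#' @param replicate_corr_range Ordered pair in \[-1, 1\]: per-gene target
#'   cross-replicate correlations are drawn uniformly from this range by
#'   [generate_replicate_pair()].
#' @param domain_geometry `"blocks"` (axis-aligned partition, default) or
#'   `"voronoi"` (random seed voxels, nearest-centre assignment, re-drawn
#'   until every domain is 6-connected).
#' @param seed Integer RNG seed; all randomness flows from it.
#' @return A validated list of class `synthetic_atlas_params`.
#' @export
synthetic_atlas_params <- function(grid_shape = c(20L, 20L, 10L),
                                   n_regions = 4L,
                                   n_signature_genes_per_region = 20L,
                                   n_background_genes = 200L,
                                   signature_mean = 10,
                                   background_mean = 1,
                                   noise_model = c("gamma", "lognormal", "truncated-normal"),
                                   noise_dispersion = 1,
                                   replicate_corr_range = c(0, 1),
                                   domain_geometry = c("blocks", "voronoi"),
                                   seed = 1L) {
  noise_model <- match.arg(noise_model)
  domain_geometry <- match.arg(domain_geometry)
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L)
  if (any(grid_shape < 1L) || prod(grid_shape) < 2L) {
    stop("grid_shape must have positive dimensions and at least 2 voxels", call. = FALSE)
  }
  counts <- c(n_regions, n_signature_genes_per_region, n_background_genes)
  if (any(counts < 1L)) stop("all counts must be >= 1", call. = FALSE)
  if (signature_mean < 0 || background_mean < 0) stop("means must be >= 0", call. = FALSE)
  if (noise_dispersion < 0) stop("noise_dispersion must be >= 0", call. = FALSE)
  if (length(replicate_corr_range) != 2L ||
      replicate_corr_range[1L] > replicate_corr_range[2L] ||
      any(abs(replicate_corr_range) > 1)) {
    stop("replicate_corr_range must be an ordered pair within [-1, 1]", call. = FALSE)
  }
  structure(list(
    grid_shape = grid_shape,
    n_regions = as.integer(n_regions),
    n_signature_genes_per_region = as.integer(n_signature_genes_per_region),
    n_background_genes = as.integer(n_background_genes),
    signature_mean = signature_mean,
    background_mean = background_mean,
    noise_model = noise_model,
    noise_dispersion = noise_dispersion,
    replicate_corr_range = as.numeric(replicate_corr_range),
    domain_geometry = domain_geometry,
    seed = as.integer(seed)
  ), class = "synthetic_atlas_params")
}

# recursively bisect the grid into n axis-aligned blocks, splitting the
# longest axis proportionally; guarantees contiguity by construction
block_ranges <- function(lo, hi, n) {
  if (n == 1L) return(list(rbind(lo = lo, hi = hi)))
  ext <- hi - lo + 1L
  if (prod(ext) < n) {
    stop("grid too small to host the requested number of connected domains",
         call. = FALSE)
  }
  ax <- which.max(ext)
  if (ext[ax] < 2L) {
    stop("grid too small to host the requested number of connected domains",
         call. = FALSE)
  }
  n1 <- n %/% 2L
  n2 <- n - n1
  len1 <- round(ext[ax] * n1 / n)
  len1 <- max(1L, min(as.integer(len1), ext[ax] - 1L))
  hi1 <- hi; hi1[ax] <- lo[ax] + len1 - 1L
  lo2 <- lo; lo2[ax] <- lo[ax] + len1
  c(block_ranges(lo, hi1, n1), block_ranges(lo2, hi, n2))
}

# 6-connectivity check of a logical 3D mask by flood fill
is_connected6 <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) <= 1L) return(nrow(idx) == 1L)
  dims <- dim(mask)
  lin <- which(mask)
  visited <- logical(length(mask))
  queue <- lin[1L]
  visited[queue] <- TRUE
  offs <- rbind(c(1L, 0L, 0L), c(-1L, 0L, 0L), c(0L, 1L, 0L),
                c(0L, -1L, 0L), c(0L, 0L, 1L), c(0L, 0L, -1L))
  while (length(queue)) {
    cur <- queue[1L]; queue <- queue[-1L]
    co <- arrayInd(cur, dims)
    for (k in seq_len(6L)) {
      nb <- co + offs[k, ]
      if (any(nb < 1L) || any(nb > dims)) next
      nl <- nb[1L] + (nb[2L] - 1L) * dims[1L] + (nb[3L] - 1L) * dims[1L] * dims[2L]
      if (mask[nl] && !visited[nl]) {
        visited[nl] <- TRUE
        queue <- c(queue, nl)
      }
    }
  }
  all(visited[lin])
}

plant_domains <- function(params) {
  gs <- params$grid_shape
  n <- params$n_regions
  labels <- array(0L, dim = gs)
  if (params$domain_geometry == "blocks") {
    rng <- block_ranges(c(0L, 0L, 0L), gs - 1L, n)
    for (r in seq_along(rng)) {
      b <- rng[[r]]
      labels[(b["lo", 1L]:b["hi", 1L]) + 1L,
             (b["lo", 2L]:b["hi", 2L]) + 1L,
             (b["lo", 3L]:b["hi", 3L]) + 1L] <- r
    }
  } else {
    if (prod(gs) < n) {
      stop("grid too small to host the requested number of connected domains",
           call. = FALSE)
    }
    coords <- as.matrix(expand.grid(x = seq_len(gs[1L]) - 1L,
                                    y = seq_len(gs[2L]) - 1L,
                                    z = seq_len(gs[3L]) - 1L))
    for (attempt in seq_len(25L)) {
      centers <- coords[sample.int(nrow(coords), n), , drop = FALSE]
      d2 <- outer(rowSums(coords^2), rowSums(centers^2), `+`) -
        2 * coords %*% t(centers)
      lab <- max.col(-d2, ties.method = "first")
      labels[coords + 1L] <- lab
      ok <- all(vapply(seq_len(n), function(r) is_connected6(labels == r), TRUE))
      if (ok) break
      if (attempt == 25L) {
        stop("could not place connected voronoi domains on this grid", call. = FALSE)
      }
    }
  }
  labels
}

# elementwise non-negative noise around a matrix of planted means
sample_noise <- function(mean_mat, model, dispersion) {
  if (dispersion == 0) return(mean_mat)
  out <- numeric(length(mean_mat))
  pos <- mean_mat > 0
  mu <- mean_mat[pos]
  out[pos] <- switch(
    model,
    gamma = stats::rgamma(length(mu), shape = mu / dispersion, scale = dispersion),
    lognormal = {
      s2 <- log1p(dispersion / mu)
      stats::rlnorm(length(mu), meanlog = log(mu) - s2 / 2, sdlog = sqrt(s2))
    },
    `truncated-normal` = pmax(0, stats::rnorm(length(mu), mu, sqrt(mu * dispersion)))
  )
  dim(out) <- dim(mean_mat)
  out
}

# shared scaffolding: planted labels, lookup, gene table, mean matrix
synthetic_scaffold <- function(params) {
  labels <- plant_domains(params)
  gs <- params$grid_shape
  coords <- expand.grid(x = seq_len(gs[1L]) - 1L,
                        y = seq_len(gs[2L]) - 1L,
                        z = seq_len(gs[3L]) - 1L)
  voxel_labels <- labels[as.matrix(coords) + 1L]
  lookup <- data.frame(
    voxel_id = sprintf("v%05d", seq_len(nrow(coords))),
    coords,
    region_label = sprintf("domain_%d", voxel_labels),
    stringsAsFactors = FALSE
  )
  nr <- params$n_regions
  nsig <- params$n_signature_genes_per_region
  sig_ids <- unlist(lapply(seq_len(nr), function(r) {
    sprintf("sig_r%02d_g%03d", r, seq_len(nsig))
  }))
  bg_ids <- sprintf("bg_g%04d", seq_len(params$n_background_genes))
  genes <- data.frame(gene_id = c(sig_ids, bg_ids),
                      symbol = c(sig_ids, bg_ids),
                      gene_class = NA_character_,
                      stringsAsFactors = FALSE)
  m <- length(sig_ids) + length(bg_ids)
  n <- nrow(lookup)
  mean_mat <- matrix(params$background_mean, m, n)
  for (r in seq_len(nr)) {
    rows <- (r - 1L) * nsig + seq_len(nsig)
    mean_mat[rows, voxel_labels == r] <- params$signature_mean
  }
  sig_map <- stats::setNames(
    lapply(seq_len(nr), function(r) sig_ids[(r - 1L) * nsig + seq_len(nsig)]),
    sprintf("domain_%d", seq_len(nr))
  )
  list(labels = labels, lookup = lookup, genes = genes, mean_mat = mean_mat,
       voxel_labels = voxel_labels, signature_gene_map = sig_map)
}

#' Generate a synthetic expression atlas with planted domains
#'
#' Builds an [expression_atlas()] whose voxel grid is partitioned into
#' `n_regions` spatially contiguous domains, each carrying its own disjoint
#' set of signature genes with elevated mean expression inside the domain;
#' background genes are expressed at the background mean everywhere.
#' The planted ground truth is returned alongside so that cluster recovery,
#' signature-gene ranking and enrichment screens can be scored exactly.
#'
#' The same parameters and seed always yield bit-identical output.
#'
#' @param params A [synthetic_atlas_params()] object.
#' @return A list with elements `atlas` (the [expression_atlas()]) and
#'   `truth` (class `synthetic_truth`: `voxel_domain_labels` — integer per
#'   atlas column, `label_volume` — the 3D domain array,
#'   `signature_gene_map` — region name to gene IDs, and `params`).
#' @examples
#' p <- synthetic_atlas_params(grid_shape = c(6, 6, 2), n_regions = 2,
#'                             n_signature_genes_per_region = 5,
#'                             n_background_genes = 20, seed = 7)
#' sim <- generate_atlas(p)
#' table(sim$truth$voxel_domain_labels)
#' @export
generate_atlas <- function(params) {
  stopifnot(inherits(params, "synthetic_atlas_params"))
  withr::with_seed(params$seed, {
    sc <- synthetic_scaffold(params)
    values <- sample_noise(sc$mean_mat, params$noise_model, params$noise_dispersion)
    dimnames(values) <- list(sc$genes$gene_id, sc$lookup$voxel_id)
    atlas <- expression_atlas(values, sc$lookup, genes = sc$genes,
                              grid_shape = params$grid_shape)
    truth <- structure(list(
      voxel_domain_labels = sc$voxel_labels,
      label_volume = sc$labels,
      signature_gene_map = sc$signature_gene_map,
      params = params
    ), class = "synthetic_truth")
    list(atlas = atlas, truth = truth)
  })
}

#' Generate a pair of replicate atlases with controlled per-gene correlation
#'
#' Emulates the paired "sagittal"/"coronal" image series that underlie the
#' replicate-correlation quality-control filter: two atlases over the same
#' voxel grid and planted domain structure, where each gene's target
#' cross-replicate Pearson correlation is drawn uniformly from
#' `replicate_corr_range`. The correlation is induced by mixing a shared
#' latent Gaussian field with independent noise (mixing weight
#' `sqrt(|rho|)`, sign applied to the shared part), around the planted
#' means with sd `sqrt(mean * dispersion)`; values are clamped at 0, which
#' can mildly attenuate mid-range correlations when the mean/sd ratio is
#' small. With `noise_dispersion = 0` both replicates equal the planted
#' means exactly.
#'
#' @param params A [synthetic_atlas_params()] object.
#' @return A list with elements `a` and `b` (two [expression_atlas()]s),
#'   `true_correlation` (named per-gene target correlations) and `truth`
#'   (as in [generate_atlas()]).
#' @export
generate_replicate_pair <- function(params) {
  stopifnot(inherits(params, "synthetic_atlas_params"))
  withr::with_seed(params$seed, {
    sc <- synthetic_scaffold(params)
    m <- nrow(sc$mean_mat)
    n <- ncol(sc$mean_mat)
    rho <- stats::runif(m, params$replicate_corr_range[1L], params$replicate_corr_range[2L])
    names(rho) <- sc$genes$gene_id
    if (params$noise_dispersion == 0) {
      a_vals <- b_vals <- sc$mean_mat
    } else {
      sd_mat <- sqrt(sc$mean_mat * params$noise_dispersion)
      z <- matrix(stats::rnorm(m * n), m, n)
      e1 <- matrix(stats::rnorm(m * n), m, n)
      e2 <- matrix(stats::rnorm(m * n), m, n)
      a_w <- sqrt(abs(rho))
      b_w <- sqrt(1 - abs(rho))
      a_vals <- pmax(sc$mean_mat + sd_mat * (a_w * z + b_w * e1), 0)
      b_vals <- pmax(sc$mean_mat + sd_mat * (sign(rho) * a_w * z + b_w * e2), 0)
    }
    dimnames(a_vals) <- dimnames(b_vals) <- list(sc$genes$gene_id, sc$lookup$voxel_id)
    truth <- structure(list(
      voxel_domain_labels = sc$voxel_labels,
      label_volume = sc$labels,
      signature_gene_map = sc$signature_gene_map,
      params = params
    ), class = "synthetic_truth")
    list(
      a = expression_atlas(a_vals, sc$lookup, genes = sc$genes,
                           grid_shape = params$grid_shape),
      b = expression_atlas(b_vals, sc$lookup, genes = sc$genes,
                           grid_shape = params$grid_shape),
      true_correlation = rho,
      truth = truth
    )
  })
}
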