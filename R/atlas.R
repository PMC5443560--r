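#' Construct an expression atlas
#'
#' An expression atlas bundles a non-negative genes-by-voxels matrix of
#' expression energy with per-gene annotations and a voxel lookup table that
#' ties each matrix column to an integer 3D grid coordinate and a region
#' label. All downstream operations (factorization, clustering, enrichment)
#' work on this container; spatial information lives exclusively in the
#' lookup table, so matrix operations are blind to voxel positions.
#'
#' Grid coordinates are 0-based integer indices into a regular voxel grid.
#' The physical voxel size (200 micrometres per side in the Allen Brain
#' Atlas convention) is metadata only and plays no computational role.
#'
#' @param matrix Numeric matrix, genes in rows, voxels in columns. All
#'   entries must be finite and non-negative.
#' @param lookup Data frame with one row per matrix column and columns
#'   `voxel_id` (unique strings), `x`, `y`, `z` (non-negative integer grid
#'   coordinates) and `region_label` (strings, matched exactly and
#'   case-sensitively by [select_regions()]).
#' @param genes Data frame with one row per matrix row and columns
#'   `gene_id` (unique strings), `symbol` and optionally `gene_class`
#'   (e.g. `"ion_channel"`, `"gpcr"`, `"other"`). If `NULL`, built from the
#'   matrix rownames.
#' @param grid_shape Integer vector of length 3: the number of voxels per
#'   axis of the enclosing grid. If `NULL`, inferred as `max(coord) + 1`
#'   per axis.
#'
#' @return An object of class `expression_atlas`: a list with elements
#'   `matrix`, `genes`, `lookup` and `grid_shape`.
#' @examples
#' m <- matrix(runif(12), 3, 4, dimnames = list(paste0("g", 1:3), paste0("v", 1:4)))
#' lk <- data.frame(voxel_id = paste0("v", 1:4), x = 0:3, y = 0L, z = 0L,
#'                  region_label = c("OB", "OB", "CTX", "CTX"))
#' atlas <- expression_atlas(m, lk)
#' dim(atlas)
#' @export
expression_atlas <- function(matrix, lookup, genes = NULL, grid_shape = NULL) {
  if (!is.matrix(matrix) || !is.numeric(matrix)) {
    stop("`matrix` must be a numeric matrix (genes x voxels)", call. = FALSE)
  }
  if (is.null(genes)) {
    ids <- rownames(matrix)
    if (is.null(ids)) ids <- sprintf("g%04d", seq_len(nrow(matrix)))
    genes <- data.frame(gene_id = ids, symbol = ids, gene_class = NA_character_,
                        stringsAsFactors = FALSE)
  }
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  lookup <- as.data.frame(lookup, stringsAsFactors = FALSE)
  if (!"symbol" %in% names(genes)) genes$symbol <- genes$gene_id
  if (!"gene_class" %in% names(genes)) genes$gene_class <- NA_character_

  obj <- structure(
    list(matrix = matrix, genes = genes, lookup = lookup,
         grid_shape = if (is.null(grid_shape)) NULL else as.integer(grid_shape)),
    class = "expression_atlas"
  )
  if (is.null(grid_shape)) {
    obj$grid_shape <- as.integer(c(max(lookup$x), max(lookup$y), max(lookup$z)) + 1L)
  }
  if (nrow(obj$matrix) == nrow(genes)) rownames(obj$matrix) <- genes$gene_id
  if (ncol(obj$matrix) == nrow(lookup)) colnames(obj$matrix) <- lookup$voxel_id
  validate_atlas(obj)
  obj
}

validate_atlas <- function(atlas) {
  m <- atlas$matrix
  if (anyNA(m) || any(!is.finite(m))) {
    stop("expression matrix contains missing or non-finite values", call. = FALSE)
  }
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "expression energy must be non-negative; first offending entry: gene '%s', voxel '%s' (value %g)",
      atlas$genes$gene_id[bad[1L]], atlas$lookup$voxel_id[bad[2L]], m[bad[1L], bad[2L]]
    ), call. = FALSE)
  }
  if (nrow(m) != nrow(atlas$genes)) {
    stop(sprintf("dimension mismatch: matrix has %d rows but %d gene annotations",
                 nrow(m), nrow(atlas$genes)), call. = FALSE)
  }
  if (ncol(m) != nrow(atlas$lookup)) {
    stop(sprintf("dimension mismatch: matrix has %d columns but %d lookup rows",
                 ncol(m), nrow(atlas$lookup)), call. = FALSE)
  }
  req <- c("voxel_id", "x", "y", "z", "region_label")
  if (!all(req %in% names(atlas$lookup))) {
    stop("lookup table must have columns voxel_id, x, y, z, region_label", call. = FALSE)
  }
  if (anyDuplicated(atlas$lookup$voxel_id)) {
    stop("duplicate voxel IDs in lookup table", call. = FALSE)
  }
  if (anyDuplicated(atlas$genes$gene_id)) {
    stop("duplicate gene IDs in gene annotations", call. = FALSE)
  }
  coords <- as.matrix(atlas$lookup[, c("x", "y", "z")])
  if (any(coords < 0) || any(coords != round(coords))) {
    stop("voxel coordinates must be non-negative integers", call. = FALSE)
  }
  gs <- atlas$grid_shape
  if (length(gs) != 3L || any(gs < 1L)) {
    stop("grid_shape must be three positive integers", call. = FALSE)
  }
  if (any(t(coords) >= gs)) {
    stop("voxel coordinates fall outside the declared grid_shape", call. = FALSE)
  }
  invisible(atlas)
}

#' @export
dim.expression_atlas <- function(x) dim(x$matrix)

#' @export
print.expression_atlas <- function(x, ...) {
  cat(sprintf("<expression_atlas> %d genes x %d voxels on a %s grid\n",
              nrow(x$matrix), ncol(x$matrix),
              paste(x$grid_shape, collapse = "x")))
  tab <- sort(table(x$lookup$region_label), decreasing = TRUE)
  show <- utils::head(tab, 8L)
  cat("regions:", paste(sprintf("%s (%d)", names(show), show), collapse = ", "))
  if (length(tab) > length(show)) cat(", ...")
  cat("\n")
  invisible(x)
}

# column subset preserving order; internal
subset_voxels <- function(atlas, keep) {
  out <- atlas
  out$matrix <- atlas$matrix[, keep, drop = FALSE]
  out$lookup <- atlas$lookup[keep, , drop = FALSE]
  rownames(out$lookup) <- NULL
  out
}

#' Select voxels belonging to named regions
#'
#' Extracts the sub-atlas whose columns carry one of the requested region
#' labels, preserving the original column order. Labels are matched exactly
#' (case-sensitive). This is the "extract the columns of known olfactory
#' areas" step that precedes factorization.
#'
#' @param atlas An [expression_atlas()].
#' @param region_labels Character vector of region labels to keep.
#' @return An `expression_atlas` restricted to the matching voxels.
#' @export
select_regions <- function(atlas, region_labels) {
  stopifnot(inherits(atlas, "expression_atlas"))
  keep <- which(atlas$lookup$region_label %in% region_labels)
  if (length(keep) == 0L) {
    stop(sprintf("no voxels match region label(s): %s",
                 paste(region_labels, collapse = ", ")), call. = FALSE)
  }
  subset_voxels(atlas, keep)
}

#' Select a single planar slice of voxels
#'
#' Restricts the atlas to the voxels whose grid coordinate along `axis`
#' equals `index` — e.g. a single coronal section when `axis` is the
#' rostro-caudal axis of the grid. Which anatomical plane an axis
#' corresponds to is a property of the atlas's declared orientation, not of
#' this function.
#'
#' @param atlas An [expression_atlas()].
#' @param axis One of `"x"`, `"y"`, `"z"`.
#' @param index 0-based slice index along `axis`.
#' @return An `expression_atlas` containing the voxels of that slice.
#' @export
select_slice <- function(atlas, axis = c("x", "y", "z"), index) {
  stopifnot(inherits(atlas, "expression_atlas"))
  axis <- match.arg(axis)
  ax <- match(axis, c("x", "y", "z"))
  if (length(index) != 1L || index < 0 || index >= atlas$grid_shape[ax]) {
    stop(sprintf("slice index %s out of range [0, %d] on axis %s",
                 toString(index), atlas$grid_shape[ax] - 1L, axis), call. = FALSE)
  }
  keep <- which(atlas$lookup[[axis]] == index)
  if (length(keep) == 0L) {
    stop(sprintf("no voxels on slice %s = %d", axis, index), call. = FALSE)
  }
  subset_voxels(atlas, keep)
}

#' Select genes by a predicate on the gene annotations
#'
#' Row-subsets the atlas to the genes for which `predicate` returns `TRUE`,
#' preserving order. Used e.g. to restrict a factorization to the
#' physiological genes (ion channels and GPCRs) of a curated list.
#'
#' @param atlas An [expression_atlas()].
#' @param predicate Either a function taking the gene annotation data frame
#'   and returning a logical vector (one per gene), or a logical/character
#'   vector selecting genes directly (character values are matched against
#'   `gene_id`).
#' @return An `expression_atlas` restricted to the matching genes.
#' @export
select_genes <- function(atlas, predicate) {
  stopifnot(inherits(atlas, "expression_atlas"))
  keep <- if (is.function(predicate)) {
    pv <- predicate(atlas$genes)
    if (!is.logical(pv) || length(pv) != nrow(atlas$genes)) {
      stop("gene predicate must return one logical per gene", call. = FALSE)
    }
    which(pv %in% TRUE)
  } else if (is.logical(predicate)) {
    stopifnot(length(predicate) == nrow(atlas$genes))
    which(predicate)
  } else {
    which(atlas$genes$gene_id %in% predicate)
  }
  if (length(keep) == 0L) stop("gene selection is empty", call. = FALSE)
  out <- atlas
  out$matrix <- atlas$matrix[keep, , drop = FALSE]
  out$genes <- atlas$genes[keep, , drop = FALSE]
  rownames(out$genes) <- NULL
  out
}

#' Register a voxel clustering back to the 3D grid
#'
#' Places per-voxel cluster indices into an integer volume of the atlas's
#' grid shape, so that a clustering computed purely in gene space can be
#' visualised in its correct spatial context. Grid cells not covered by the
#' atlas receive the reserved background value 0; cluster `k` maps to
#' value `k`.
#'
#' @param assignment A [cluster_assignment()] (or bare integer vector) with
#'   one cluster index per atlas voxel.
#' @param atlas The [expression_atlas()] whose lookup table supplies voxel
#'   coordinates.
#' @return A 3D integer array of dimension `atlas$grid_shape`.
#' @export
register_labels <- function(assignment, atlas) {
  stopifnot(inherits(atlas, "expression_atlas"))
  cl <- if (inherits(assignment, "cluster_assignment")) assignment$cluster else assignment
  if (length(cl) != ncol(atlas$matrix)) {
    stop(sprintf("assignment covers %d voxels but atlas has %d columns",
                 length(cl), ncol(atlas$matrix)), call. = FALSE)
  }
  vol <- array(0L, dim = atlas$grid_shape)
  idx <- cbind(atlas$lookup$x, atlas$lookup$y, atlas$lookup$z) + 1L
  vol[idx] <- as.integer(cl)
  vol
}
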