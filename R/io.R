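#' Read an expression atlas from delimited text files
#'
#' Loads the three-file on-disk representation written by [write_atlas()]:
#' a matrix file (first column `gene_id`, remaining columns one per voxel,
#' header row of voxel IDs), a lookup table and, optionally, a gene
#' annotation table. The three files are cross-validated: counts and IDs
#' must agree, and any negative matrix entry is a hard error.
#'
#' @param matrix_path Path to the matrix CSV/TSV.
#' @param lookup_path Path to the lookup CSV (`voxel_id,x,y,z,region_label`).
#' @param gene_path Optional path to the gene annotation CSV
#'   (`gene_id,symbol,gene_class`); if `NULL`, annotations are built from
#'   the matrix gene IDs.
#' @param sep Field separator, `,` by default.
#' @return An [expression_atlas()].
#' @export
read_atlas <- function(matrix_path, lookup_path, gene_path = NULL, sep = ",") {
  raw <- utils::read.table(matrix_path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (names(raw)[1L] != "gene_id") {
    stop("matrix file must have 'gene_id' as its first column", call. = FALSE)
  }
  m <- as.matrix(raw[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("malformed matrix file: non-numeric expression values", call. = FALSE)
  rownames(m) <- raw$gene_id
  lookup <- utils::read.table(lookup_path, header = TRUE, sep = sep,
                              stringsAsFactors = FALSE,
                              colClasses = c(voxel_id = "character",
                                             region_label = "character"))
  if (!identical(colnames(m), lookup$voxel_id)) {
    if (ncol(m) != nrow(lookup)) {
      stop(sprintf("dimension mismatch: matrix has %d voxel columns but lookup has %d rows",
                   ncol(m), nrow(lookup)), call. = FALSE)
    }
    stop("voxel IDs in matrix header and lookup table disagree", call. = FALSE)
  }
  genes <- NULL
  if (!is.null(gene_path)) {
    genes <- utils::read.table(gene_path, header = TRUE, sep = sep,
                               stringsAsFactors = FALSE)
    if (!identical(genes$gene_id, rownames(m))) {
      stop("gene IDs in matrix and gene annotation file disagree", call. = FALSE)
    }
  }
  expression_atlas(m, lookup, genes = genes)
}

#' Write an expression atlas to delimited text files
#'
#' Writes `matrix.csv`, `lookup.csv` and `genes.csv` under `dir`. Numeric
#' values are formatted with `digits` significant digits; the default of 17
#' makes the write/read round-trip exact for double precision. Pass a
#' smaller value (e.g. 6) for compact, human-oriented output.
#'
#' @param atlas An [expression_atlas()].
#' @param dir Output directory (created if needed).
#' @param digits Significant digits for expression values.
#' @param sep Field separator.
#' @return Invisibly, the paths of the three files written.
#' @export
write_atlas <- function(atlas, dir, digits = 17L, sep = ",") {
  stopifnot(inherits(atlas, "expression_atlas"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("matrix.csv", "lookup.csv", "genes.csv"))

  fmt <- formatC(atlas$matrix, format = "g", digits = digits)
  df <- data.frame(gene_id = atlas$genes$gene_id, fmt,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene_id", atlas$lookup$voxel_id)
  utils::write.table(df, paths[1L], sep = sep, row.names = FALSE, quote = FALSE)
  utils::write.table(atlas$lookup, paths[2L], sep = sep, row.names = FALSE, quote = FALSE)
  utils::write.table(atlas$genes, paths[3L], sep = sep, row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' Write a 3D label volume as NRRD
#'
#' Writes an integer label volume (as produced by [register_labels()]) in
#' NRRD format with ascii encoding, axis order fastest-first (x, y, z),
#' matching R's column-major array layout.
#'
#' @param volume 3D integer array.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_nrrd <- function(volume, path) {
  stopifnot(is.array(volume), length(dim(volume)) == 3L)
  con <- file(path, "wb")
  on.exit(close(con))
  header <- c(
    "NRRD0004",
    "# label volume",
    "type: int",
    "dimension: 3",
    sprintf("sizes: %s", paste(dim(volume), collapse = " ")),
    "encoding: ascii",
    ""
  )
  writeLines(header, con)
  writeLines(paste(as.integer(volume), collapse = " "), con)
  invisible(path)
}

#' Read a 3D label volume from NRRD
#'
#' Reads NRRD files with `ascii`/`text` encoding as written by
#' [write_nrrd()]. Only the minimal header fields (`sizes`, `encoding`,
#' `dimension`) are interpreted.
#'
#' @param path NRRD file path.
#' @return A 3D integer array.
#' @export
read_nrrd <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!startsWith(lines[1L], "NRRD")) stop("not an NRRD file: ", path, call. = FALSE)
  blank <- which(lines == "")[1L]
  if (is.na(blank)) stop("malformed NRRD: no header-terminating blank line", call. = FALSE)
  header <- lines[2:(blank - 1L)]
  header <- header[!startsWith(header, "#")]
  fields <- strsplit(header, ": ", fixed = TRUE)
  keys <- vapply(fields, `[`, "", 1L)
  vals <- vapply(fields, function(f) paste(f[-1L], collapse = ": "), "")
  enc <- vals[match("encoding", keys)]
  if (!enc %in% c("ascii", "txt", "text")) {
    stop("unsupported NRRD encoding: ", enc, call. = FALSE)
  }
  sizes <- as.integer(strsplit(vals[match("sizes", keys)], " ")[[1L]])
  data <- scan(text = paste(lines[(blank + 1L):length(lines)], collapse = " "),
               what = integer(), quiet = TRUE)
  if (length(data) != prod(sizes)) {
    stop(sprintf("NRRD payload has %d values, expected %d", length(data), prod(sizes)),
         call. = FALSE)
  }
  array(data, dim = sizes)
}
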