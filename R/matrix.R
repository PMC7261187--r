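# The repair count matrix is a plain Matrix::dgCMatrix with cells as rows and
# "substrate:position" feature identifiers as columns, serialized in the
# 10x-style triplet layout (matrix.mtx is features x cells, plus
# barcodes.tsv and features.tsv).

feature_id <- function(substrate, position) {
  if (!length(substrate)) return(character(0))
  paste0(substrate, ":", position)
}

#' Split "substrate:position" feature identifiers
#'
#' The position is the text after the last `":"`, so substrate names must not
#' contain `":"` (enforced by [substrate_set()]).
#'
#' @param ids Character vector of feature identifiers.
#' @return Data frame with columns `feature`, `substrate`, `position`.
#' @export
parse_features <- function(ids) {
  pos <- sub("^.*:", "", ids)
  data.frame(
    feature = ids,
    substrate = sub(":[^:]*$", "", ids),
    position = as.integer(pos),
    stringsAsFactors = FALSE
  )
}

#' Assemble the cells x features repair count matrix
#'
#' Rows are restricted to the supplied cell-associated barcodes (mirroring
#' filtering against an external mRNA pipeline's cell list); listed cells
#' without signal keep an all-zero row. Features are the (substrate,
#' position) keys observed among retained cells, sorted by substrate then
#' position.
#'
#' @param counts Data frame from [count_positions()].
#' @param cells Character vector of unique cell barcodes to retain.
#' @return A sparse `dgCMatrix` (cells x features) with barcode rownames and
#'   `"substrate:position"` colnames.
#' @export
build_matrix <- function(counts, cells) {
  if (!length(cells)) stop("empty cell list")
  if (anyDuplicated(cells)) stop("duplicate cell barcodes")
  keep <- counts[counts$cell_barcode %in% cells, , drop = FALSE]
  feats <- unique(keep[, c("substrate", "position")])
  feats <- feats[order(feats$substrate, feats$position), , drop = FALSE]
  fid <- feature_id(feats$substrate, feats$position)
  m <- Matrix::sparseMatrix(
    i = match(keep$cell_barcode, cells),
    j = match(feature_id(keep$substrate, keep$position), fid),
    x = as.numeric(keep$count),
    dims = c(length(cells), length(fid)),
    dimnames = list(cells, fid)
  )
  methods::as(m, "CsparseMatrix")
}

#' Write / read a repair matrix in MatrixMarket triplet layout
#'
#' `write_mtx()` emits `matrix.mtx` (features x cells, 10x-style),
#' `barcodes.tsv` and `features.tsv` (feature id, substrate, position) into
#' `dir`. `read_mtx()` reverses it and errors on dimension or label
#' mismatches; round-trips are exact.
#'
#' @param m Matrix from [build_matrix()] (cells x features).
#' @param dir Directory to write into / read from (created if needed).
#' @return `write_mtx()` returns `dir` invisibly; `read_mtx()` the matrix.
#' @export
write_mtx <- function(m, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(Matrix::t(m), "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(m), file.path(dir, "barcodes.tsv"))
  fi <- parse_features(colnames(m))
  write.table(fi, file.path(dir, "features.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' @rdname write_mtx
#' @export
read_mtx <- function(dir) {
  mm <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  fpath <- file.path(dir, "features.tsv")
  fi <- if (file.size(fpath) == 0L) {
    data.frame(V1 = character(), V2 = character(), V3 = integer())
  } else {
    read.delim(fpath, header = FALSE, stringsAsFactors = FALSE)
  }
  if (nrow(fi) != nrow(mm) || length(barcodes) != ncol(mm))
    stop("matrix dimensions do not match barcodes/features files")
  if (anyDuplicated(fi[[1L]])) stop("duplicate feature identifier")
  if (anyDuplicated(barcodes)) stop("duplicate barcode")
  m <- Matrix::t(mm)
  dimnames(m) <- list(barcodes, fi[[1L]])
  methods::as(m, "CsparseMatrix")
}

#' Fallback cell caller: top barcodes by total UMI count
#'
#' Plumbing for purely synthetic runs without an external cell list: ranks
#' barcodes by total molecule count (descending, ties lexicographic) and
#' returns the top `n`.
#'
#' @param counts Data frame from [count_positions()].
#' @param n Number of barcodes to return.
#' @return Character vector of barcodes.
#' @export
top_n_by_umi <- function(counts, n) {
  tot <- tapply(counts$count, counts$cell_barcode, sum)
  ord <- order(-tot, names(tot))
  head(names(tot)[ord], n)
}

#' Mean empty-droplet background profile per hairpin position
#'
#' Barcodes not in the cell list are ranked by total UMI count (descending,
#' ties lexicographic) and the top `n_keep` (default: as many as there are
#' cell-associated barcodes) are retained as empty drops. For every substrate
#' the mean count at each observed position across the retained drops is
#' reported, counting absent entries as zero.
#'
#' @param counts Data frame from [count_positions()] including non-cell
#'   barcodes.
#' @param cells Cell-associated barcodes to exclude.
#' @param n_keep Number of empty drops to keep, or `"match_cells"`.
#' @return Data frame with columns `substrate`, `position`, `mean_count`,
#'   `n_drops`.
#' @export
empty_drop_profile <- function(counts, cells, n_keep = "match_cells") {
  bg <- counts[!counts$cell_barcode %in% cells, , drop = FALSE]
  if (nrow(bg) == 0L) stop("no non-cell barcodes in counts")
  if (identical(n_keep, "match_cells")) n_keep <- length(cells)
  drops <- top_n_by_umi(bg, n_keep)
  bg <- bg[bg$cell_barcode %in% drops, , drop = FALSE]
  agg <- stats::aggregate(count ~ substrate + position, data = bg, FUN = sum)
  out <- data.frame(
    substrate = agg$substrate,
    position = as.integer(agg$position),
    mean_count = agg$count / length(drops),
    n_drops = length(drops),
    stringsAsFactors = FALSE
  )
  out[order(out$substrate, out$position), , drop = FALSE]
}
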