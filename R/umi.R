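# UMI deduplication. The directional method is the umi_tools criterion:
# a directed edge a -> b exists when Hamming(a, b) == 1 and
# count(a) >= 2 * count(b) - 1; clusters grow from unvisited highest-count
# roots (ties broken lexicographically), which makes the result independent
# of input order.

#' Group UMIs within one stratum
#'
#' @param umis Named integer vector: UMI sequence -> read count.
#' @param method `"directional"` (default; umi_tools adjacency criterion) or
#'   `"unique"` (every distinct UMI is its own molecule).
#' @return List of clusters; each cluster is a list with `representative`
#'   (highest-count member, ties lexicographic) and `members`.
#' @export
group_umis <- function(umis, method = c("directional", "unique")) {
  method <- match.arg(method)
  if (!length(umis)) stop("empty UMI set")
  u <- names(umis)
  if (is.null(u)) stop("umis must be a named vector (umi -> read count)")
  if (length(unique(nchar(u))) != 1L) stop("mixed UMI lengths")
  cnt <- as.integer(umis)
  if (any(cnt < 1L)) stop("read counts must be >= 1")
  if (method == "unique") {
    reps <- seq_along(u)
  } else {
    reps <- umi_cluster_cpp(rep(1L, length(u)), u, cnt)
  }
  lapply(unique(reps), function(r) {
    list(representative = u[r], members = u[reps == r])
  })
}

#' Count molecules per (cell, substrate, position)
#'
#' Reads are stratified by (cell barcode, substrate, position); within each
#' stratum UMIs are deduplicated with `method` and the molecule count is the
#' number of UMI clusters. Strata are independent: the same UMI at two
#' positions of one substrate yields two molecules (no cross-position
#' merging), since the incision position is the signal.
#'
#' @param events Data frame of aligned reads with columns `cell_barcode`,
#'   `substrate`, `position`, `umi` (one row per read, corrected barcodes
#'   only).
#' @param method Passed to the UMI grouping (`"directional"` or `"unique"`).
#' @return Data frame (`position_counts`) with columns `cell_barcode`,
#'   `substrate`, `position`, `count`, sorted by those keys.
#' @export
count_positions <- function(events, method = c("directional", "unique")) {
  method <- match.arg(method)
  need <- c("cell_barcode", "substrate", "position", "umi")
  miss <- setdiff(need, names(events))
  if (length(miss)) stop("events missing column(s): ",
                         paste(miss, collapse = ", "))
  dt <- data.table::as.data.table(events[, need])
  if (nrow(dt) == 0L) {
    out <- data.frame(cell_barcode = character(), substrate = character(),
                      position = integer(), count = integer(),
                      stringsAsFactors = FALSE)
    return(out)
  }
  if (length(unique(nchar(dt$umi))) != 1L) stop("mixed UMI lengths")
  # reads per (stratum, umi)
  byu <- dt[, list(reads = .N),
            by = c("cell_barcode", "substrate", "position", "umi")]
  data.table::setorder(byu, cell_barcode, substrate, position, umi)
  byu[, GRP := .GRP, by = c("cell_barcode", "substrate", "position")]
  if (method == "unique") {
    out <- byu[, list(count = .N),
               by = c("cell_barcode", "substrate", "position")]
  } else {
    byu$cluster <- umi_cluster_cpp(byu$GRP, byu$umi, byu$reads)
    out <- byu[, list(count = length(unique(cluster))),
               by = c("cell_barcode", "substrate", "position")]
  }
  data.table::setorder(out, cell_barcode, substrate, position)
  out <- as.data.frame(out)
  out$position <- as.integer(out$position)
  out$count <- as.integer(out$count)
  out
}
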