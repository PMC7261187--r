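# Genotype calling for knockout cell-mixing experiments and classification
# evaluation. The genotype rule works on raw counts at the scored repair
# sites (position 44 for the ribonucleotide substrate, position 45 for the
# uracil substrate): an activity is "high" when its site count is strictly
# greater than 5% of the maximum of that activity over all cells, "low" when
# not (equality falls to low; the two strict inequalities of the published
# rule leave it unassigned). Thresholding on raw counts relative to the
# per-activity maximum makes the labels invariant to rescaling both count
# vectors by a common factor.

#' Call genotypes from uracil and ribonucleotide site counts
#'
#' A cell with high uracil incision and low ribonucleotide incision lacks
#' RNASEH2 activity (`RNASEH2C_KO`); the converse lacks UNG (`UNG_KO`); both
#' high is a `doublet`; both low is `unclassified` (low signal).
#'
#' @param uracil_counts,ribo_counts Named integer vectors (cell barcode ->
#'   raw count at the scored site), same cell universe.
#' @param threshold Fraction of the per-activity maximum separating high from
#'   low (default 0.05).
#' @return Data frame with columns `cell_barcode`, `label`,
#'   `uracil_site_count`, `ribo_site_count`, `uracil_fraction_of_max`,
#'   `ribo_fraction_of_max`.
#' @export
call_genotypes <- function(uracil_counts, ribo_counts, threshold = 0.05) {
  cells <- names(uracil_counts)
  if (is.null(cells) || is.null(names(ribo_counts)))
    stop("count vectors must be named by cell barcode")
  if (!setequal(cells, names(ribo_counts)))
    stop("uracil and ribo counts cover different cells")
  ribo_counts <- ribo_counts[cells]
  max_u <- max(uracil_counts)
  max_r <- max(ribo_counts)
  if (max_u <= 0 || max_r <= 0)
    stop("zero maximum count for an activity: degenerate experiment")
  u_hi <- uracil_counts > threshold * max_u
  r_hi <- ribo_counts > threshold * max_r
  label <- ifelse(u_hi & r_hi, "doublet",
           ifelse(u_hi, "RNASEH2C_KO",
           ifelse(r_hi, "UNG_KO", "unclassified")))
  data.frame(
    cell_barcode = cells,
    label = label,
    uracil_site_count = as.integer(uracil_counts),
    ribo_site_count = as.integer(ribo_counts),
    uracil_fraction_of_max = as.numeric(uracil_counts) / max_u,
    ribo_fraction_of_max = as.numeric(ribo_counts) / max_r,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Site counts for genotype calling from a repair matrix
#'
#' Convenience extractor: raw counts at one feature per cell (0 when the
#' feature is absent from the matrix).
#'
#' @param m Sparse cells x features count matrix.
#' @param feature Feature identifier, e.g. `"uracilA:45"`.
#' @return Named numeric vector (cell -> count).
#' @export
site_counts <- function(m, feature) {
  if (feature %in% colnames(m)) setNames(as.numeric(m[, feature]), rownames(m))
  else setNames(numeric(nrow(m)), rownames(m))
}

#' One-vs-rest confusion statistics per class
#'
#' For every true class, cells predicted as that class are positives and all
#' other predictions (including `doublet` and `unclassified`) are negatives.
#' `TPR = TP / (TP + FN)`, `FPR = FP / (FP + TN)`; `0/0` is reported as `NA`.
#'
#' @param pred,truth Named character vectors (cell -> label), same cell
#'   universe.
#' @return Data frame with columns `class`, `TP`, `FP`, `TN`, `FN`, `TPR`,
#'   `FPR`.
#' @export
confusion <- function(pred, truth) {
  if (!setequal(names(pred), names(truth)))
    stop("pred and truth cover different cells")
  pred <- pred[names(truth)]
  classes <- sort(unique(truth))
  out <- do.call(rbind, lapply(classes, function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    tn <- sum(pred != cl & truth != cl)
    data.frame(class = cl, TP = tp, FP = fp, TN = tn, FN = fn,
               TPR = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               FPR = if (fp + tn > 0) fp / (fp + tn) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Random-reassignment classification baseline
#'
#' Uniformly permutes the existing label multiset across cells (seeded), the
#' chance baseline against which repair-based classification is compared.
#'
#' @param truth Named character vector (cell -> label).
#' @param seed Integer seed.
#' @return Named character vector of permuted labels.
#' @export
random_baseline <- function(truth, seed) {
  if (!length(truth)) stop("empty truth labels")
  set.seed(seed)
  setNames(sample(unname(truth)), names(truth))
}

#' Nearest-centroid classification on normalized profiles
#'
#' Per-class mean feature vectors are computed on the training matrix; each
#' test cell is assigned the class of the nearest centroid by Euclidean
#' distance (ties broken lexicographically by class name). Classes without
#' training cells are excluded. Stands in for reference-based label
#' transfer.
#'
#' @param train_m,test_m Normalized matrices sharing the same feature space.
#' @param train_labels Named character vector for the training cells.
#' @return Named character vector: test cell -> predicted class.
#' @export
centroid_classify <- function(train_m, train_labels, test_m) {
  if (!identical(colnames(train_m), colnames(test_m)))
    stop("train and test matrices must share the same feature space")
  lab <- train_labels[rownames(train_m)]
  if (anyNA(lab)) stop("unlabeled training cells")
  classes <- sort(unique(lab))
  centroids <- t(vapply(classes, function(cl) {
    Matrix::colMeans(train_m[lab == cl, , drop = FALSE])
  }, numeric(ncol(train_m))))
  x <- as.matrix(test_m)
  # squared Euclidean distance via the expansion ||x||^2 - 2 x.c + ||c||^2
  d2 <- outer(rowSums(x^2), rep(1, nrow(centroids))) -
    2 * x %*% t(centroids) +
    outer(rep(1, nrow(x)), rowSums(centroids^2))
  best <- apply(d2, 1L, function(v) which(v <= min(v) + 1e-12)[1L])
  setNames(classes[best], rownames(test_m))
}

#' Read-downsampling sensitivity of genotype classification
#'
#' For each target depth, aligned reads are sampled without replacement per
#' cell (cells with fewer reads keep all of them) *before* UMI
#' deduplication, counts are rebuilt with [count_positions()], genotypes are
#' recalled with [call_genotypes()], and the fraction of cells assigned
#' their true label is reported. A target at or above the deepest cell
#' reproduces the full-depth result exactly. Deterministic given `seed`.
#'
#' @param events Read-level data frame (columns `cell_barcode`, `substrate`,
#'   `position`, `umi`; one row per aligned read).
#' @param truth Named character vector (cell -> true label); defines the
#'   cell universe evaluated.
#' @param targets Integer vector of reads-per-cell targets (must be
#'   positive).
#' @param seed Integer seed.
#' @param uracil_feature,ribo_feature Scored-site feature identifiers, e.g.
#'   `"uracilA:45"` and `"riboG:44"`.
#' @param method UMI deduplication method.
#' @param threshold Genotype-calling threshold.
#' @return Data frame with columns `target`, `n_cells`, `n_correct`,
#'   `fraction_correct`.
#' @export
downsample_and_classify <- function(events, truth, targets, seed,
                                    uracil_feature, ribo_feature,
                                    method = "directional",
                                    threshold = 0.05) {
  if (any(targets <= 0)) stop("downsampling targets must be positive")
  cells <- names(truth)
  set.seed(seed)
  ev <- data.table::as.data.table(events)
  ev <- ev[ev$cell_barcode %in% cells, ]
  out <- lapply(targets, function(tg) {
    idx <- ev[, if (.N <= tg) list(row = .I) else
                list(row = .I[sample.int(.N, tg)]), by = "cell_barcode"]
    sub <- as.data.frame(ev[idx$row, ])
    cnt <- count_positions(sub, method = method)
    m <- build_matrix(cnt, cells)
    calls <- call_genotypes(site_counts(m, uracil_feature),
                            site_counts(m, ribo_feature),
                            threshold = threshold)
    pred <- setNames(calls$label, calls$cell_barcode)[cells]
    n_ok <- sum(pred == truth)
    data.frame(target = tg, n_cells = length(cells), n_correct = n_ok,
               fraction_correct = n_ok / length(cells))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
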