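# Repair-activity scoring. Counts are normalized per cell exactly as
# LogNormalize: each feature count is divided by the cell's total count
# across all repair features, multiplied by a scaling factor (1e4 by
# default) and natural-log transformed with a pseudocount of 1 (log1p), so a
# zero count maps to a zero score. The denominator is the repair fraction
# only; the matrix is normalized standalone.

#' Log-normalize a repair count matrix
#'
#' `out[c, f] = ln(1 + count[c, f] / total[c] * scale)` with `total[c]` the
#' cell's total count over all features. Cells with zero total keep an
#' all-zero row. Scores are invariant to multiplying a cell's counts by a
#' common factor and monotone in the raw count at fixed total.
#'
#' @param m Sparse cells x features count matrix from [build_matrix()].
#' @param scale Scaling factor (default `1e4`).
#' @return Sparse matrix of the same shape with normalized values.
#' @export
log_normalize <- function(m, scale = 1e4) {
  if (scale <= 0) stop("scale must be positive")
  tot <- Matrix::rowSums(m)
  inv <- ifelse(tot > 0, 1 / tot, 0)
  out <- methods::as(Matrix::Diagonal(x = inv * scale) %*% m,
                     "CsparseMatrix")
  out@x <- log1p(out@x)
  dimnames(out) <- dimnames(m)
  Matrix::drop0(out)
}

#' Per-cell repair-activity scores at the scored incision sites
#'
#' For every cell and every scored site of every substrate, the raw count at
#' the `"substrate:position"` feature (0 when the feature was never
#' observed) and its log-normalized score (computed with the cell's total
#' over the full matrix).
#'
#' @param m Sparse cells x features count matrix.
#' @param substrates A [substrate_set()] defining the scored sites.
#' @param scale Scaling factor for the normalization.
#' @return Data frame with columns `cell_barcode`, `activity`, `substrate`,
#'   `position`, `raw_count`, `score`.
#' @export
activity_scores <- function(m, substrates, scale = 1e4) {
  acts <- scored_activities(substrates)
  norm <- log_normalize(m, scale)
  cells <- rownames(m)
  out <- do.call(rbind, lapply(seq_len(nrow(acts)), function(i) {
    f <- acts$activity[i]
    raw <- if (f %in% colnames(m)) as.numeric(m[, f]) else numeric(length(cells))
    sc <- if (f %in% colnames(m)) as.numeric(norm[, f]) else numeric(length(cells))
    data.frame(cell_barcode = cells, activity = f,
               substrate = acts$substrate[i], position = acts$position[i],
               raw_count = raw, score = sc, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Mean incision-position profile per cell group
#'
#' Mean raw count per (substrate, position) within each group, zeros
#' included, mirroring the per-cell-type position profiles plotted against
#' hairpin coordinates. Empty groups (labels without cells in the matrix) are
#' dropped with a warning. `mean_count * n_cells` summed over a group's
#' features equals that group's share of the matrix total.
#'
#' @param m Sparse cells x features count matrix.
#' @param labels Named character vector: cell barcode -> group label; every
#'   cell in `m` must be labeled.
#' @return Data frame with columns `group`, `substrate`, `position`,
#'   `mean_count`, `n_cells`.
#' @export
position_profile <- function(m, labels) {
  cells <- rownames(m)
  if (!all(cells %in% names(labels)))
    stop("every cell in the matrix must be labeled")
  lab <- labels[cells]
  groups <- unique(labels)
  empty <- setdiff(groups, lab)
  if (length(empty))
    warning("excluding empty group(s): ", paste(empty, collapse = ", "))
  fi <- parse_features(colnames(m))
  out <- do.call(rbind, lapply(sort(intersect(groups, lab)), function(g) {
    sub <- m[lab == g, , drop = FALSE]
    data.frame(group = g, substrate = fi$substrate, position = fi$position,
               mean_count = as.numeric(Matrix::colMeans(sub)),
               n_cells = nrow(sub), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Pairwise rank tests of activity scores between groups
#'
#' For every activity and every unordered pair of groups, a two-sided
#' Wilcoxon rank-sum (Mann-Whitney) test of the per-cell scores: exact for
#' small untied samples, otherwise the normal approximation with tie
#' correction (no continuity correction). `log_fold_change` is the
#' difference of group mean scores (a vs b; scores are already on the
#' natural-log scale). P-values are corrected across all reported tests.
#' Pairs in which either group has fewer than two cells are skipped with a
#' warning.
#'
#' @param scores Data frame from [activity_scores()].
#' @param labels Named character vector: cell barcode -> group label.
#' @param correction `"bonferroni"` (default) or `"bh"`.
#' @return Data frame with columns `activity`, `group_a`, `group_b`,
#'   `statistic` (Mann-Whitney U of a vs b), `p_value`, `adjusted_p`,
#'   `log_fold_change`.
#' @export
pairwise_rank_test <- function(scores, labels,
                               correction = c("bonferroni", "bh")) {
  correction <- match.arg(correction)
  scores$group <- labels[scores$cell_barcode]
  if (anyNA(scores$group)) stop("unlabeled cells in scores")
  groups <- sort(unique(scores$group))
  if (length(groups) < 2L) stop("need at least two groups")
  pairs <- utils::combn(groups, 2L)
  rows <- list()
  for (act in unique(scores$activity)) {
    sa <- scores[scores$activity == act, , drop = FALSE]
    for (k in seq_len(ncol(pairs))) {
      ga <- pairs[1L, k]; gb <- pairs[2L, k]
      xa <- sa$score[sa$group == ga]
      xb <- sa$score[sa$group == gb]
      if (length(xa) < 2L || length(xb) < 2L) {
        warning(sprintf("skipping %s %s vs %s: fewer than 2 cells",
                        act, ga, gb))
        next
      }
      wt <- suppressWarnings(wilcox.test(xa, xb, correct = FALSE))
      rows[[length(rows) + 1L]] <- data.frame(
        activity = act, group_a = ga, group_b = gb,
        statistic = unname(wt$statistic), p_value = wt$p.value,
        log_fold_change = mean(xa) - mean(xb), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("no testable group pairs")
  out <- do.call(rbind, rows)
  out$adjusted_p <- p.adjust(out$p_value,
                             method = if (correction == "bh") "BH"
                                      else "bonferroni")
  out[, c("activity", "group_a", "group_b", "statistic", "p_value",
          "adjusted_p", "log_fold_change")]
}
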