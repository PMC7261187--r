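test_that("genotype calls follow the >5%-of-maximum rule", {
  u <- c(A = 100L, B = 0L, C = 100L, D = 2L, E = 5L)
  r <- c(A = 0L, B = 100L, C = 100L, D = 2L, E = 40L)
  calls <- call_genotypes(u, r)
  lab <- setNames(calls$label, calls$cell_barcode)
  expect_equal(lab[["A"]], "RNASEH2C_KO")  # uracil high only
  expect_equal(lab[["B"]], "UNG_KO")       # ribo high only
  expect_equal(lab[["C"]], "doublet")      # both high
  expect_equal(lab[["D"]], "unclassified") # both below 5% of max
  # boundary: exactly 5% of max is not ">5%", so it falls to the low side
  expect_equal(lab[["E"]], "UNG_KO")
  expect_true(all(calls$uracil_fraction_of_max >= 0 &
                  calls$uracil_fraction_of_max <= 1))
  expect_error(call_genotypes(c(A = 0L), c(A = 1L)), "zero maximum")
})

test_that("genotype labels partition cells and survive count rescaling", {
  set.seed(43)
  n <- 300
  cells <- paste0("C", 1:n)
  u <- setNames(rpois(n, 30), cells)
  r <- setNames(rpois(n, 30), cells)
  u[1] <- 200L  # ensure nonzero maxima
  calls <- call_genotypes(u, r)
  expect_setequal(calls$cell_barcode, cells)
  expect_equal(nrow(calls), n)  # exactly one label per cell
  expect_true(all(calls$label %in%
                  c("UNG_KO", "RNASEH2C_KO", "doublet", "unclassified")))
  scaled <- call_genotypes(u * 7L, r * 7L)
  expect_identical(scaled$label, calls$label)
})

test_that("genotype calls recover simulated knockouts at molecule depth", {
  # two knockout genotypes, incision probability 0.6 at the scored site,
  # 2000 molecules per cell, no background
  set.seed(47)
  n <- 400
  umis <- 2000
  cells <- paste0("C", 1:(2 * n + 40))
  truth <- rep(c("RNASEH2C_KO", "UNG_KO", "doublet"), c(n, n, 40))
  active_u <- truth %in% c("RNASEH2C_KO", "doublet")
  active_r <- truth %in% c("UNG_KO", "doublet")
  u <- setNames(ifelse(active_u, rbinom(length(cells), umis, 0.6), 0L), cells)
  r <- setNames(ifelse(active_r, rbinom(length(cells), umis, 0.6), 0L), cells)
  calls <- call_genotypes(u, r)
  pred <- setNames(calls$label, calls$cell_barcode)[cells]
  singlet <- truth != "doublet"
  expect_gte(mean(pred[singlet] == truth[singlet]), 0.99)
  expect_gte(mean(pred[!singlet] == "doublet"), 0.90)
})

test_that("one-vs-rest confusion matches a brute-force per-cell tally", {
  cells <- paste0("C", 1:10)
  truth <- setNames(rep(c("a", "b"), each = 5), cells)
  perfect <- confusion(truth, truth)
  expect_equal(perfect$TPR, c(1, 1))
  expect_equal(perfect$FPR, c(0, 0))

  pred <- truth
  pred["C1"] <- "b"  # class a: TP 4, FN 1
  cm <- confusion(pred, truth)
  expect_equal(cm$TPR[cm$class == "a"], 0.8)

  set.seed(53)
  for (i in 1:5) {
    p <- setNames(sample(c("a", "b", "doublet", "unclassified"), 10, TRUE),
                  cells)
    cm <- confusion(p, truth)
    for (cl in cm$class) {
      tp <- sum(p == cl & truth == cl)
      fp <- sum(p == cl & truth != cl)
      fn <- sum(p != cl & truth == cl)
      tn <- sum(p != cl & truth != cl)
      row <- cm[cm$class == cl, ]
      expect_equal(unlist(row[, c("TP", "FP", "TN", "FN")]),
                   c(TP = tp, FP = fp, TN = tn, FN = fn))
      expect_equal(row$TP + row$FP + row$TN + row$FN, 10L)
      expect_equal(row$TP + row$FN, sum(truth == cl))
    }
  }
})

test_that("random baseline permutes labels and attains chance-level TPR", {
  truth <- setNames(rep(c("a", "b", "c"), c(20, 10, 10)), paste0("C", 1:40))
  b1 <- random_baseline(truth, seed = 9)
  expect_identical(sort(unname(b1)), sort(unname(truth)))  # same multiset
  expect_identical(b1, random_baseline(truth, seed = 9))
  expect_false(identical(b1, random_baseline(truth, seed = 10)))

  # expected TPR of a permutation baseline equals the class frequency
  tprs <- vapply(1:500, function(s) {
    cm <- confusion(random_baseline(truth, seed = s), truth)
    cm$TPR[cm$class == "a"]
  }, 0)
  expect_equal(mean(tprs), 0.5, tolerance = 0.03)  # freq(a) = 20/40
})

test_that("nearest-centroid classification behaves at and between centroids", {
  train <- Matrix::Matrix(rbind(
    c(1, 0), c(1.2, 0), c(0, 1), c(0, 0.8)), sparse = TRUE,
    dimnames = list(paste0("T", 1:4), c("f1", "f2")))
  labels <- setNames(c("x", "x", "y", "y"), paste0("T", 1:4))
  test <- Matrix::Matrix(rbind(
    c(1.1, 0),        # exactly centroid x
    c(0.55, 0.45)), sparse = TRUE,
    dimnames = list(c("q1", "q2"), c("f1", "f2")))
  pred <- centroid_classify(train, labels, test)
  expect_equal(unname(pred["q1"]), "x")

  # perfectly equidistant point falls to the lexicographically first class
  eq <- Matrix::Matrix(rbind(c(0.5, 0), c(0, 0.5)), sparse = TRUE,
                       dimnames = list(c("cx", "cy"), c("f1", "f2")))
  elab <- setNames(c("x", "y"), c("cx", "cy"))
  mid <- Matrix::Matrix(rbind(c(0.25, 0.25)), sparse = TRUE,
                        dimnames = list("m", c("f1", "f2")))
  expect_equal(unname(centroid_classify(eq, elab, mid)), "x")

  # separable synthetic two-class data classifies accurately
  set.seed(59)
  n <- 100
  tr <- rbind(matrix(rnorm(2 * n, c(3, 0), 0.7), n, 2, byrow = TRUE),
              matrix(rnorm(2 * n, c(0, 3), 0.7), n, 2, byrow = TRUE))
  rownames(tr) <- paste0("T", 1:(2 * n)); colnames(tr) <- c("f1", "f2")
  te <- rbind(matrix(rnorm(2 * n, c(3, 0), 0.7), n, 2, byrow = TRUE),
              matrix(rnorm(2 * n, c(0, 3), 0.7), n, 2, byrow = TRUE))
  rownames(te) <- paste0("Q", 1:(2 * n)); colnames(te) <- c("f1", "f2")
  lab <- setNames(rep(c("x", "y"), each = n), rownames(tr))
  pred <- centroid_classify(Matrix::Matrix(tr, sparse = TRUE), lab,
                            Matrix::Matrix(te, sparse = TRUE))
  expect_gt(mean(pred == rep(c("x", "y"), each = n)), 0.9)
})

test_that("downsampling at full depth is a no-op and is seed-reproducible", {
  set.seed(61)
  cells <- paste0("C", 1:30)
  truth <- setNames(rep(c("UNG_KO", "RNASEH2C_KO"), each = 15), cells)
  ev <- do.call(rbind, lapply(cells, function(cb) {
    act <- if (truth[[cb]] == "UNG_KO") "riboG" else "uracilA"
    pos <- if (act == "riboG") 44L else 45L
    n <- sample(30:60, 1)
    data.frame(cell_barcode = cb, substrate = act, position = pos,
               umi = random_dna(n, 6), stringsAsFactors = FALSE)
  }))
  full_cnt <- count_positions(ev)
  m <- build_matrix(full_cnt, cells)
  full_calls <- call_genotypes(site_counts(m, "uracilA:45"),
                               site_counts(m, "riboG:44"))
  full_frac <- mean(setNames(full_calls$label,
                             full_calls$cell_barcode)[cells] == truth)

  tab <- downsample_and_classify(ev, truth, targets = c(10L, 1000L),
                                 seed = 3, uracil_feature = "uracilA:45",
                                 ribo_feature = "riboG:44")
  expect_equal(tab$fraction_correct[tab$target == 1000L], full_frac)
  expect_identical(tab, downsample_and_classify(
    ev, truth, targets = c(10L, 1000L), seed = 3,
    uracil_feature = "uracilA:45", ribo_feature = "riboG:44"))
  expect_error(downsample_and_classify(
    ev, truth, targets = 0L, seed = 1, uracil_feature = "u",
    ribo_feature = "r"), "positive")
})
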