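test_that("reads place at their true 5' position on the hairpin", {
  s <- tiny_substrates()
  refs <- setNames(s$sequence, s$name)

  # incised fragment: suffix starting at position 45
  a <- align_read(substr(refs[["subA"]], 45, 60), s)
  expect_equal(a$status, "aligned")
  expect_equal(a$substrate, "subA")
  expect_equal(a$position, 45L)
  expect_equal(a$mismatches, 0L)

  # intact substrate: full-length read starts at position 1
  a <- align_read(refs[["subB"]], s)
  expect_equal(unlist(a[, c("substrate", "position")]),
               c(substrate = "subB", position = "1"), ignore_attr = TRUE)

  # identical fragment present in two substrates: ambiguous, never guessed
  shared <- substr(refs[["subA"]], 10, 39)
  s2 <- substrate_set(
    name = c("x", "y"),
    sequence = c(refs[["subA"]], paste0(shared, substr(refs[["subB"]], 1, 30))),
    lesion_position = c(5L, 5L), lesion_type = "other",
    scored_sites = list(6L, 6L), polya_length = 0L)
  a <- align_read(shared, s2)
  expect_equal(a$status, "ambiguous")
  expect_true(is.na(a$position))

  expect_error(align_reads("ACGT", s[0, ]), "empty")
})

test_that("alignment matches the exhaustive placement oracle on random instances", {
  set.seed(23)
  n_checked <- 0L
  for (trial in 1:60) {
    nref <- sample(1:3, 1)
    refs <- setNames(random_dna(nref, sample(40:100, 1)), paste0("r", 1:nref))
    subs <- substrate_set(names(refs), unname(refs),
                          lesion_position = 10L, lesion_type = "other",
                          scored_sites = as.list(rep(11L, nref)),
                          polya_length = 0L)
    reads <- character(5)
    for (i in 1:5) {
      kind <- sample(c("exact", "mut", "random"), 1)
      src <- sample(names(refs), 1)
      len <- sample(15:35, 1)
      maxs <- nchar(refs[[src]]) - len + 1L
      start <- sample(maxs, 1)
      rd <- substr(refs[[src]], start, start + len - 1L)
      if (kind == "mut") {
        p <- sample(len, sample(1:3, 1))
        v <- strsplit(rd, "")[[1]]
        v[p] <- sample(c("A", "C", "G", "T"), length(p), TRUE)
        rd <- paste(v, collapse = "")
      } else if (kind == "random") {
        rd <- random_dna(1, len)
      }
      reads[i] <- rd
    }
    got <- align_reads(reads, subs, max_mismatches = 2L)
    for (i in 1:5) {
      want <- oracle_align(reads[i], refs, 2L)
      expect_identical(got$status[i], want$status)
      if (want$status == "aligned") {
        expect_identical(got$substrate[i], want$ref)
        expect_identical(got$position[i], as.integer(want$pos))
        expect_identical(got$mismatches[i], as.integer(want$mm))
      }
      n_checked <- n_checked + 1L
    }
  }
  expect_gte(n_checked, 300L)
})

test_that("reverse-complement reads never align", {
  set.seed(31)
  s <- tiny_substrates(len = 80)
  refs <- setNames(s$sequence, s$name)
  rc <- function(x) as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(x)))
  for (i in 1:20) {
    src <- sample(names(refs), 1)
    start <- sample(1:50, 1)
    frag <- substr(refs[[src]], start, start + 29)
    fwd <- align_read(frag, s)
    rev <- align_read(rc(frag), s)
    expect_equal(fwd$status, "aligned")
    # forward-only placement: the reverse complement must not be reported
    # at the incision position (it is unaligned unless a coincidental
    # forward match exists, which the oracle rules out here)
    expect_identical(rev$status,
                     oracle_align(rc(frag), refs, 2L)$status)
    expect_false(identical(rev$position, fwd$position) &&
                 identical(rev$substrate, fwd$substrate))
  }
})

test_that("raising the mismatch cap never loses aligned reads", {
  set.seed(41)
  s <- tiny_substrates(len = 70)
  reads <- character(80)
  for (i in seq_along(reads)) {
    rd <- substr(s$sequence[sample(2, 1)], sample(30, 1), 70)
    v <- strsplit(rd, "")[[1]]
    p <- sample(length(v), sample(0:4, 1))
    v[p] <- sample(c("A", "C", "G", "T"), length(p), TRUE)
    reads[i] <- paste(v, collapse = "")
  }
  n_aligned <- vapply(0:4, function(mm) {
    sum(align_reads(reads, s, max_mismatches = mm)$status == "aligned")
  }, 0)
  expect_true(all(diff(n_aligned) >= 0))
})

test_that("tagged SAM round-trips substrate, position, barcode and UMI", {
  s <- tiny_substrates()
  aln <- align_reads(c(substr(s$sequence[1], 45, 60),
                       substr(s$sequence[2], 44, 60),
                       s$sequence[1]), s)
  aln$barcode <- c("AACC", "GGTT", "AACC")
  aln$umi <- c("ACGTACGTAC", "TTTTACGTAC", "ACACACACAC")
  aln$sequence <- c(substr(s$sequence[1], 45, 60),
                    substr(s$sequence[2], 44, 60), s$sequence[1])
  sam <- tempfile(fileext = ".sam")
  write_tagged_sam(aln, s, sam)

  bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  rec <- Rsamtools::scanBam(
    bam, param = Rsamtools::ScanBamParam(
      what = c("rname", "pos"), tag = c("XT", "CB", "UB")))[[1]]
  expect_equal(as.character(rec$rname), aln$substrate)
  expect_equal(rec$pos, aln$position)
  expect_equal(rec$tag$XT, paste0(aln$substrate, ":", aln$position))
  expect_equal(rec$tag$CB, aln$barcode)
  expect_equal(rec$tag$UB, aln$umi)

  # header-only file for zero aligned reads
  sam0 <- tempfile(fileext = ".sam")
  write_tagged_sam(aln[0, ], s, sam0)
  expect_true(all(grepl("^@", readLines(sam0))))
  expect_error(write_tagged_sam(
    data.frame(status = "unaligned"), s, tempfile()), "aligned")
})
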