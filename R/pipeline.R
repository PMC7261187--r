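# End-to-end single-cell processing: extract -> correct -> trim -> align ->
# deduplicate -> matrix. Every input read pair lands in exactly one QC
# category, so the tallies partition the input count; the run itself uses no
# randomness and is idempotent given identical inputs.

read_fastq_seqs <- function(x) {
  if (length(x) == 1L && file.exists(x)) {
    s <- Biostrings::readDNAStringSet(x, format = "fastq")
    setNames(as.character(s), sub("\\s.*$", "", names(s)))
  } else {
    as.character(x)
  }
}

read_lines_or_vector <- function(x) {
  if (length(x) == 1L && file.exists(x)) readLines(x) else as.character(x)
}

#' Run the Haircut counting pipeline
#'
#' Extracts barcodes/UMIs from R1, corrects barcodes against the whitelist,
#' trims the template-switch prefix and polyA tail from R2, aligns to the
#' hairpin references (forward-only, ungapped), deduplicates UMIs per (cell,
#' substrate, position) and assembles the sparse repair count matrix
#' restricted to the cell-associated barcodes. QC tallies
#' (`counted`, `excluded_short_r1`, `umi_with_n`, `unmatched_barcode`,
#' `discarded_short_r2`, `unaligned`, `ambiguous`) sum to the number of
#' input read pairs.
#'
#' @param r1,r2 FASTQ paths (plain or gzipped) or character vectors of
#'   sequences, pairwise matched.
#' @param substrates A [substrate_set()] or path to a substrate table TSV.
#' @param whitelist Barcode whitelist: path (one barcode per line) or
#'   character vector.
#' @param cells Cell-associated barcodes: path or character vector; or
#'   `NULL` to call the top `n_top_cells` barcodes by total UMI count
#'   (synthetic-run plumbing, not the assay's cell calling).
#' @param outdir Optional output directory: writes `matrix/` (MatrixMarket
#'   triplet), `qc.json`, `manifest.json`, and `alignments.sam` when
#'   `write_sam = TRUE`.
#' @param n_top_cells Number of cells for the fallback caller when
#'   `cells = NULL`.
#' @param tso,min_polya_run,polya_max_nona,min_len Trimming parameters, see
#'   [trim_read2()].
#' @param max_mismatches Alignment mismatch cap, see [align_reads()].
#' @param umi_method UMI deduplication method, see [count_positions()].
#' @param write_sam Also emit the tagged SAM of aligned reads.
#' @return List with `matrix` (cells x features), `counts` (all barcodes,
#'   from [count_positions()]), `events` (read-level aligned records for
#'   downsampling), `qc` (named integer tallies) and `params`.
#' @export
run_count <- function(r1, r2, substrates, whitelist, cells = NULL,
                      outdir = NULL, n_top_cells = NULL,
                      tso = tso_default(), min_polya_run = 6L,
                      polya_max_nona = 0.1, min_len = 20L,
                      max_mismatches = 2L,
                      umi_method = c("directional", "unique"),
                      write_sam = FALSE) {
  umi_method <- match.arg(umi_method)
  if (is.character(substrates) && length(substrates) == 1L)
    substrates <- load_substrate_table(substrates)
  validate_substrate_set(substrates)
  wl <- read_lines_or_vector(whitelist)
  r1s <- read_fastq_seqs(r1)
  r2s <- read_fastq_seqs(r2)
  if (length(r1s) != length(r2s)) stop("R1 and R2 read counts differ")
  n_input <- length(r1s)
  if (is.null(names(r1s)))
    names(r1s) <- sprintf("read%08d", seq_along(r1s))
  qc <- c(counted = 0L, excluded_short_r1 = 0L, umi_with_n = 0L,
          unmatched_barcode = 0L, discarded_short_r2 = 0L,
          unaligned = 0L, ambiguous = 0L)

  bu <- extract_barcode_umi(r1s)
  qc["excluded_short_r1"] <- sum(!bu$ok)
  live <- which(bu$ok)

  bad_umi <- grepl("[^ACGT]", bu$umi[live])
  qc["umi_with_n"] <- sum(bad_umi)
  live <- live[!bad_umi]

  bc <- correct_barcode(bu$barcode[live], wl)
  qc["unmatched_barcode"] <- sum(bc$status == "unmatched")
  keep <- bc$status != "unmatched"
  barcodes <- bc$corrected_barcode[keep]
  live <- live[keep]

  tr <- trim_read2(r2s[live], tso = tso, min_polya_run = min_polya_run,
                   polya_max_nona = polya_max_nona, min_len = min_len)
  qc["discarded_short_r2"] <- sum(!tr$keep)
  barcodes <- barcodes[tr$keep]
  live <- live[tr$keep]
  trimmed <- tr$sequence[tr$keep]

  aln <- align_reads(trimmed, substrates, max_mismatches = max_mismatches)
  qc["unaligned"] <- sum(aln$status == "unaligned")
  qc["ambiguous"] <- sum(aln$status == "ambiguous")
  ok <- aln$status == "aligned"
  qc["counted"] <- sum(ok)
  stopifnot(sum(qc) == n_input)

  events <- data.frame(
    read_id = names(r1s)[live][ok],
    cell_barcode = barcodes[ok],
    substrate = aln$substrate[ok],
    position = aln$position[ok],
    umi = bu$umi[live][ok],
    mismatches = aln$mismatches[ok],
    sequence = trimmed[ok],
    aligned_length = aln$aligned_length[ok],
    stringsAsFactors = FALSE
  )

  counts <- count_positions(events, method = umi_method)
  if (is.null(cells)) {
    if (is.null(n_top_cells))
      stop("supply either `cells` or `n_top_cells`")
    cells <- top_n_by_umi(counts, n_top_cells)
  } else {
    cells <- read_lines_or_vector(cells)
  }
  m <- build_matrix(counts, cells)

  params <- list(tso = tso, min_polya_run = min_polya_run,
                 polya_max_nona = polya_max_nona, min_len = min_len,
                 max_mismatches = max_mismatches, umi_method = umi_method,
                 n_cells = length(cells), n_input_reads = n_input)

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_mtx(m, file.path(outdir, "matrix"))
    jsonlite::write_json(as.list(qc), file.path(outdir, "qc.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    manifest <- list(
      package = "haircutr",
      version = as.character(utils::packageVersion("haircutr")),
      substrates = substrates$name,
      inputs = list(
        r1 = if (is.character(r1) && length(r1) == 1L) r1 else "in-memory",
        r2 = if (is.character(r2) && length(r2) == 1L) r2 else "in-memory"),
      params = params, qc = as.list(qc))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    if (write_sam) {
      sam <- cbind(events[, c("cell_barcode", "substrate", "position",
                              "umi", "mismatches", "sequence",
                              "aligned_length")],
                   status = "aligned", stringsAsFactors = FALSE)
      names(sam)[names(sam) == "cell_barcode"] <- "barcode"
      sam$qname <- events$read_id
      write_tagged_sam(sam, substrates, file.path(outdir, "alignments.sam"))
    }
  }
  list(matrix = m, counts = counts, events = events, qc = qc,
       params = params, cells = cells)
}
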