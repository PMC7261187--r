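# Hairpin references are ~50-100 nt synthetic sequences, so reads are placed
# by an exhaustive ungapped scan over every offset of every reference rather
# than a seeded aligner. Forward orientation only: the assay reads the sense
# strand of the hairpin, and a reverse-complement placement would fabricate
# an incision position. The 1-based 5' start of the read on the reference is
# the incision readout.

#' Align trimmed reads to the hairpin references
#'
#' Every read is placed, forward orientation only and without gaps, at every
#' offset of every reference at which it is fully contained (no 3' overhang;
#' overhanging A's indicate untrimmed polyA and are handled upstream). The
#' unique placement with the fewest mismatches wins if it has at most
#' `max_mismatches`; a tie across (substrate, offset) placements is reported
#' `"ambiguous"`, no qualifying placement `"unaligned"`.
#'
#' @param reads Character vector of trimmed R2 sequences.
#' @param substrates A [substrate_set()].
#' @param max_mismatches Maximum mismatches for a reported alignment
#'   (default 2).
#' @return Data frame with columns `substrate`, `position` (1-based 5'
#'   start), `mismatches`, `aligned_length`, `status`
#'   (`aligned`/`unaligned`/`ambiguous`); non-aligned rows carry `NA`s.
#' @export
align_reads <- function(reads, substrates, max_mismatches = 2L) {
  validate_substrate_set(substrates)
  # errors concentrate on few sequences, so align unique sequences once
  useq <- unique(reads)
  res <- align_reads_cpp(useq, substrates$sequence, as.integer(max_mismatches))
  idx <- match(reads, useq)
  data.frame(
    substrate = substrates$name[res$ref_idx][idx],
    position = res$position[idx],
    mismatches = res$mismatches[idx],
    aligned_length = ifelse(res$status[idx] == 0L, nchar(reads), NA_integer_),
    status = c("aligned", "unaligned", "ambiguous")[res$status[idx] + 1L],
    stringsAsFactors = FALSE
  )
}

#' @rdname align_reads
#' @param read A single read sequence.
#' @export
align_read <- function(read, substrates, max_mismatches = 2L) {
  align_reads(read, substrates, max_mismatches)
}

#' Write aligned reads as a tagged SAM file
#'
#' One record per aligned read, mapped to its substrate at its 1-based start
#' position with a fully-matching CIGAR. Custom tags follow the assay's
#' convention: `XT` holds `"substrate:position"` (the incision feature), `CB`
#' the corrected cell barcode and `UB` the UMI; `NM` carries the mismatch
#' count. Unaligned or ambiguous rows must be removed (and tallied) by the
#' caller.
#'
#' @param alignments Data frame from [align_reads()] (aligned rows only) with
#'   additional columns `barcode` and `umi`; optional columns `qname`,
#'   `sequence`, `qualities`.
#' @param substrates A [substrate_set()] (provides the SAM header).
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
write_tagged_sam <- function(alignments, substrates, path) {
  validate_substrate_set(substrates)
  if (nrow(alignments) && any(alignments$status != "aligned"))
    stop("write_tagged_sam expects aligned records only")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", substrates$name,
                     nchar(substrates$sequence)), con)
  if (nrow(alignments)) {
    qname <- if (!is.null(alignments$qname)) alignments$qname else
      sprintf("read%07d", seq_len(nrow(alignments)))
    seqs <- if (!is.null(alignments$sequence)) alignments$sequence else "*"
    quals <- if (!is.null(alignments$qualities)) alignments$qualities else "*"
    cigar <- paste0(alignments$aligned_length, "M")
    writeLines(paste(qname, 0L, alignments$substrate, alignments$position,
                     255L, cigar, "*", 0L, 0L, seqs, quals,
                     sprintf("NM:i:%d", alignments$mismatches),
                     sprintf("XT:Z:%s:%d", alignments$substrate,
                             alignments$position),
                     sprintf("CB:Z:%s", alignments$barcode),
                     sprintf("UB:Z:%s", alignments$umi),
                     sep = "\t"), con)
  }
  invisible(path)
}
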