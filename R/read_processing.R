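# R1 carries the 16 nt cell barcode followed by the 10 nt UMI (10x 3' v2
# layout); R2 is the hairpin-derived cDNA flanked by the template-switch
# sequence at the 5' end and the polyA tail at the 3' end.

#' Default template-switch oligo prefix
#'
#' The 13-mer prefix of the 10x template-switch oligo, removed (allowing one
#' mismatch) from the 5' end of R2. Overridable in [trim_read2()] and
#' [sim_config()].
#' @export
tso_default <- function() "AAGCAGTGGTATC"

#' Extract cell barcode and UMI from R1
#'
#' Positional slicing: the barcode is the first `barcode_len` bases, the UMI
#' the next `umi_len`; trailing bases are ignored. Reads shorter than
#' `barcode_len + umi_len` are flagged (`ok = FALSE`) and should be excluded
#' and tallied by the caller.
#'
#' @param r1 Character vector of R1 sequences.
#' @param barcode_len,umi_len Barcode and UMI lengths (default 16 + 10).
#' @return Data frame with columns `barcode`, `umi`, `ok`.
#' @export
extract_barcode_umi <- function(r1, barcode_len = 16L, umi_len = 10L) {
  len <- nchar(r1)
  ok <- len >= barcode_len + umi_len
  data.frame(
    barcode = ifelse(ok, substr(r1, 1L, barcode_len), NA_character_),
    umi = ifelse(ok, substr(r1, barcode_len + 1L, barcode_len + umi_len),
                 NA_character_),
    ok = ok,
    stringsAsFactors = FALSE
  )
}

hamming1_neighbors <- function(bc) {
  len <- nchar(bc[1L])
  bases <- c("A", "C", "G", "T")
  out <- vector("list", len * 4L)
  k <- 0L
  for (p in seq_len(len)) {
    pre <- substr(bc, 1L, p - 1L)
    suf <- substr(bc, p + 1L, len)
    for (b in bases) {
      k <- k + 1L
      out[[k]] <- paste0(pre, b, suf)
    }
  }
  out
}

#' Correct cell barcodes against a whitelist
#'
#' An exact whitelist hit keeps the barcode (`status = "exact"`); otherwise a
#' barcode matching exactly one whitelist entry at Hamming distance 1 is
#' corrected to that entry (`"corrected"`); anything else, including ties
#' between two whitelist entries, is `"unmatched"`. A single N counts as one
#' mismatch, so a barcode with one N can still be rescued.
#'
#' @param raw Character vector of raw barcodes, all the same length.
#' @param whitelist Character vector of valid barcodes (same length as `raw`
#'   entries).
#' @return Data frame with columns `raw_barcode`, `corrected_barcode`
#'   (`NA` when unmatched), `status`.
#' @export
correct_barcode <- function(raw, whitelist) {
  if (!length(whitelist)) stop("whitelist is empty")
  wlen <- unique(nchar(whitelist))
  if (length(wlen) != 1L) stop("whitelist entries differ in length")
  if (any(nchar(raw) != wlen))
    stop("barcode length differs from whitelist length")

  uraw <- unique(raw)
  exact <- uraw %in% whitelist
  corrected <- uraw
  status <- ifelse(exact, "exact", "unmatched")

  todo <- which(!exact)
  if (length(todo)) {
    cand <- uraw[todo]
    nb <- hamming1_neighbors(cand)  # list of length 4*wlen, each len(cand)
    hitmat <- vapply(nb, function(v) v %in% whitelist, logical(length(cand)))
    hitmat <- matrix(hitmat, nrow = length(cand))
    # neighbor sets include the original base at each position, i.e. the raw
    # barcode itself; it is not in the whitelist here, so no self-hit arises
    nhit <- rowSums(hitmat)
    one <- which(nhit == 1L)
    if (length(one)) {
      col1 <- apply(hitmat[one, , drop = FALSE], 1L, which.max)
      corr <- vapply(seq_along(one), function(i) nb[[col1[i]]][one[i]], "")
      corrected[todo[one]] <- corr
      status[todo[one]] <- "corrected"
    }
  }
  corrected[status == "unmatched"] <- NA_character_

  idx <- match(raw, uraw)
  data.frame(
    raw_barcode = raw,
    corrected_barcode = corrected[idx],
    status = status[idx],
    stringsAsFactors = FALSE
  )
}

#' Trim template-switch sequence and polyA tail from R2
#'
#' If the first `nchar(tso)` bases match `tso` with at most one mismatch, the
#' prefix is removed. Then the maximal 3' suffix that starts with an A, has
#' non-A content at most `polya_max_nona`, and is at least `min_polya_run`
#' long is removed. Reads shorter than `min_len` after trimming are flagged
#' `keep = FALSE` (tallied, not errored). Trimming never lengthens a read:
#' `tso_trimmed + polya_trimmed + nchar(sequence)` equals the input length.
#'
#' @param seq Character vector of R2 sequences.
#' @param qual Optional quality strings (same lengths); trimmed in step.
#' @param tso Template-switch prefix to remove (see [tso_default()]).
#' @param min_polya_run Minimum qualifying polyA suffix length (default 6).
#' @param polya_max_nona Maximum non-A fraction within the trimmed suffix
#'   (default 0.1, i.e. >= 90 percent A).
#' @param min_len Minimum post-trim length to keep a read (default 20).
#' @return Data frame with columns `sequence`, `qualities` (if `qual` given),
#'   `tso_trimmed`, `polya_trimmed`, `keep`.
#' @export
trim_read2 <- function(seq, qual = NULL, tso = tso_default(),
                       min_polya_run = 6L, polya_max_nona = 0.1,
                       min_len = 20L) {
  n <- length(seq)
  tso_trim <- integer(n)
  if (nzchar(tso)) {
    mm <- prefix_mismatch_cpp(seq, tso)
    hit <- !is.na(mm) & mm <= 1L
    tso_trim[hit] <- nchar(tso)
  }
  body <- substr(seq, tso_trim + 1L, nchar(seq))
  polya_trim <- polya_suffix_cpp(body, as.integer(min_polya_run),
                                 polya_max_nona)
  out_seq <- substr(body, 1L, nchar(body) - polya_trim)
  res <- data.frame(
    sequence = out_seq,
    tso_trimmed = tso_trim,
    polya_trimmed = polya_trim,
    keep = nchar(out_seq) >= min_len,
    stringsAsFactors = FALSE
  )
  if (!is.null(qual)) {
    if (any(nchar(qual) != nchar(seq)))
      stop("quality strings differ in length from sequences")
    res$qualities <- substr(qual, tso_trim + 1L,
                            tso_trim + nchar(out_seq))
    res <- res[, c("sequence", "qualities", "tso_trimmed", "polya_trimmed",
                   "keep")]
  }
  res
}
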