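#' Hairpin substrate sets
#'
#' A substrate set describes the hairpin DNA repair substrates used in an
#' experiment: the single-stranded reference sequence as sequenced (polyA tail
#' excluded), the 1-based position of the synthetic lesion, the lesion type,
#' and the scored incision site(s) whose counts define named repair
#' activities (e.g. uracil incision is scored at lesion position + 1 because
#' UNG removes the uracil and AP endonuclease cleaves the abasic site,
#' placing the new 5' end one base downstream; ribonucleotide incision is
#' scored at the lesion itself because RNASEH2 cleaves 5' of the
#' ribonucleotide).
#'
#' @param name Character vector of unique substrate identifiers (must not
#'   contain `":"`, which separates substrate and position in feature ids).
#' @param sequence Uppercase ACGT reference sequences, polyA tail excluded.
#' @param lesion_position 1-based integer position of the lesion.
#' @param lesion_type One of `"unmodified"`, `"U_A"`, `"U_G"`, `"riboG_C"`,
#'   `"abasic_G"`, `"other"`.
#' @param scored_sites List of integer vectors of 1-based scored positions
#'   (one vector per substrate).
#' @param polya_length Non-negative integer tail length on the physical oligo.
#'
#' @return A `substrate_set`: a data frame with one row per substrate and a
#'   `scored_sites` list column.
#' @export
substrate_set <- function(name, sequence, lesion_position, lesion_type,
                          scored_sites, polya_length) {
  s <- data.frame(
    name = as.character(name),
    sequence = toupper(as.character(sequence)),
    lesion_position = as.integer(lesion_position),
    lesion_type = as.character(lesion_type),
    polya_length = as.integer(polya_length),
    stringsAsFactors = FALSE
  )
  if (!is.list(scored_sites)) scored_sites <- list(scored_sites)
  s$scored_sites <- lapply(scored_sites, as.integer)
  class(s) <- c("substrate_set", "data.frame")
  validate_substrate_set(s)
  s
}

LESION_TYPES <- c("unmodified", "U_A", "U_G", "riboG_C", "abasic_G", "other")

validate_substrate_set <- function(s, rows = seq_len(nrow(s))) {
  if (nrow(s) == 0L) stop("substrate set is empty")
  fail <- function(i, msg) stop(sprintf("substrate row %d: %s", rows[i], msg))
  if (anyDuplicated(s$name)) {
    i <- which(duplicated(s$name))[1L]
    fail(i, sprintf("duplicate substrate name '%s'", s$name[i]))
  }
  for (i in seq_len(nrow(s))) {
    if (is.na(s$name[i]) || !nzchar(s$name[i])) fail(i, "empty name")
    if (grepl(":", s$name[i], fixed = TRUE)) fail(i, "name contains ':'")
    if (!nzchar(s$sequence[i])) fail(i, "empty sequence")
    if (grepl("[^ACGT]", s$sequence[i]))
      fail(i, "sequence contains non-ACGT characters")
    len <- nchar(s$sequence[i])
    if (is.na(s$lesion_position[i]) || s$lesion_position[i] < 1L ||
        s$lesion_position[i] > len)
      fail(i, sprintf("lesion_position %s outside [1, %d]",
                      s$lesion_position[i], len))
    if (!s$lesion_type[i] %in% LESION_TYPES)
      fail(i, sprintf("unknown lesion_type '%s'", s$lesion_type[i]))
    sites <- s$scored_sites[[i]]
    if (length(sites) && (any(is.na(sites)) || any(sites < 1L | sites > len)))
      fail(i, "scored site outside [1, reference length]")
    if (is.na(s$polya_length[i]) || s$polya_length[i] < 0L)
      fail(i, "negative polya_length")
  }
  invisible(s)
}

#' Read a substrate metadata table
#'
#' Expects a TSV with columns `name`, `sequence`, `lesion_position`,
#' `lesion_type`, `scored_sites` (comma-separated 1-based positions) and
#' `polya_length`. Rows failing validation are reported with their row number.
#'
#' @param path Path to the TSV file.
#' @return A [substrate_set()].
#' @export
load_substrate_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("name", "sequence", "lesion_position", "lesion_type",
            "scored_sites", "polya_length")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("substrate table is missing column(s): ", paste(miss, collapse = ", "))
  sites <- lapply(strsplit(tab$scored_sites, ","), function(x) {
    x <- trimws(x[nzchar(trimws(x))])
    v <- suppressWarnings(as.integer(x))
    if (length(v) && any(is.na(v))) stop("non-integer scored site")
    v
  })
  substrate_set(
    name = tab$name,
    sequence = tab$sequence,
    lesion_position = suppressWarnings(as.integer(tab$lesion_position)),
    lesion_type = tab$lesion_type,
    scored_sites = sites,
    polya_length = suppressWarnings(as.integer(tab$polya_length))
  )
}

#' Example hairpin substrates
#'
#' Five example 80-nt substrates (unmodified and with U:A, U:G, riboG:C and
#' abasic:G lesions), each with the lesion at position 44. Uracil substrates
#' are scored at position 45 (lesion + 1), the ribonucleotide substrate at
#' position 44, and the abasic substrate at 45 (short patch) and 46 (long
#' patch).
#'
#' @return A [substrate_set()].
#' @export
example_substrates <- function() {
  load_substrate_table(system.file("extdata", "substrates.tsv",
                                   package = "haircutr", mustWork = TRUE))
}

#' Write / read the hairpin reference FASTA
#'
#' One record per substrate; header is the substrate name, sequence excludes
#' the polyA tail. `read_reference_fasta()` returns a named character vector.
#'
#' @param substrates A [substrate_set()].
#' @param path Output FASTA path.
#' @return `write_reference_fasta()` returns `path` invisibly.
#' @export
write_reference_fasta <- function(substrates, path) {
  validate_substrate_set(substrates)
  seqs <- Biostrings::DNAStringSet(setNames(substrates$sequence,
                                            substrates$name))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' @rdname write_reference_fasta
#' @export
read_reference_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  setNames(as.character(seqs), names(seqs))
}

#' Scored activities of a substrate set
#'
#' One row per (substrate, scored site); `activity` is the feature-style
#' identifier `"substrate:position"`.
#'
#' @param substrates A [substrate_set()].
#' @return Data frame with columns `activity`, `substrate`, `position`.
#' @export
scored_activities <- function(substrates) {
  n <- vapply(substrates$scored_sites, length, 1L)
  out <- data.frame(
    substrate = rep(substrates$name, n),
    position = unlist(substrates$scored_sites, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  out$activity <- paste0(out$substrate, ":", out$position)
  out[, c("activity", "substrate", "position")]
}
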