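# Seeded generator of synthetic Haircut experiments: paired FASTQ reads plus
# complete ground truth. Emulates cells whose genotype determines the
# incision-position distribution on each hairpin, intact (uncleaved)
# substrate molecules starting at position 1 (the C3-spacer-blocked oligo
# yields full-length cDNA), empty-droplet ambient background, UMI
# duplication with geometric read multiplicity, and uniform per-base
# substitution error. All draws come from one RNG stream seeded from the
# config, in a fixed documented order, so outputs are byte-identical across
# reruns.

DNA_BASES <- c("A", "C", "G", "T")

random_seqs <- function(n, len) {
  if (n == 0L) return(character())
  m <- matrix(sample(DNA_BASES, n * len, replace = TRUE), nrow = n)
  apply(m, 1L, paste, collapse = "")
}

# substitute k[i] random positions of seqs[i] with a different base
add_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  k <- rbinom(length(seqs), nchar(seqs), rate)
  for (i in which(k > 0L)) {
    s <- strsplit(seqs[i], "")[[1L]]
    pos <- sample.int(length(s), k[i])
    for (p in pos) s[p] <- sample(setdiff(DNA_BASES, s[p]), 1L)
    seqs[i] <- paste(s, collapse = "")
  }
  seqs
}

#' Cell profile for the simulator
#'
#' @param label Genotype or cell-type label.
#' @param incision Named list: substrate name -> named probability vector
#'   over 1-based hairpin positions (names are positions; include mass at
#'   `"1"` for intact molecules). Each vector must sum to 1.
#' @param umis_per_substrate Mean molecules per cell per substrate (Poisson).
#' @param n_cells Number of singlet cells with this profile.
#' @return A `cell_profile` list.
#' @export
cell_profile <- function(label, incision, umis_per_substrate, n_cells) {
  stopifnot(umis_per_substrate >= 0, n_cells >= 0)
  for (s in names(incision)) {
    p <- incision[[s]]
    if (is.null(names(p)) || abs(sum(p) - 1) > 1e-8 || any(p < 0))
      stop(sprintf("incision distribution for '%s' must be a named probability vector summing to 1", s),
           call. = FALSE)
  }
  structure(list(label = label, incision = incision,
                 umis_per_substrate = umis_per_substrate, n_cells = n_cells),
            class = "cell_profile")
}

#' Simulation configuration
#'
#' @param substrates A [substrate_set()].
#' @param profiles List of [cell_profile()]s (labels must be unique).
#' @param n_empty_drops Number of cell-free droplets emitting ambient
#'   background.
#' @param doublet_rate Fraction (of total singlets) of additional droplets
#'   containing two cells; each doublet merges the molecule draws of two
#'   *distinct* profiles (same-profile doublets are invisible to the assay
#'   and are not simulated).
#' @param background_per_substrate Mean ambient molecules per empty drop per
#'   substrate (Poisson).
#' @param background_profile Named probability vector over positions for
#'   ambient molecules (default: all mass at position 1, i.e. intact).
#' @param reads_per_umi Mean reads per molecule (geometric, minimum 1).
#' @param error_rate Per-base substitution probability (in [0, 0.1]).
#' @param umi_len,barcode_len UMI and barcode lengths (10x 3' v2: 10 + 16).
#' @param whitelist_size Size of the generated barcode whitelist.
#' @param tso Template-switch prefix prepended to R2 (`""` for none).
#' @param seed Integer seed (mandatory).
#' @return A `sim_config` list.
#' @export
sim_config <- function(substrates, profiles, n_empty_drops = 0L,
                       doublet_rate = 0, background_per_substrate = 0,
                       background_profile = c("1" = 1), reads_per_umi = 2,
                       error_rate = 0.001, umi_len = 10L, barcode_len = 16L,
                       whitelist_size = 5000L, tso = tso_default(),
                       seed) {
  validate_substrate_set(substrates)
  if (missing(seed)) stop("seed is mandatory")
  if (doublet_rate < 0 || doublet_rate > 1) stop("doublet_rate not in [0, 1]")
  if (error_rate < 0 || error_rate > 0.1) stop("error_rate not in [0, 0.1]")
  if (reads_per_umi < 1) stop("reads_per_umi must be >= 1")
  labels <- vapply(profiles, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("profile labels must be unique")
  structure(list(substrates = substrates, profiles = profiles,
                 n_empty_drops = as.integer(n_empty_drops),
                 doublet_rate = doublet_rate,
                 background_per_substrate = background_per_substrate,
                 background_profile = background_profile,
                 reads_per_umi = reads_per_umi, error_rate = error_rate,
                 umi_len = as.integer(umi_len),
                 barcode_len = as.integer(barcode_len),
                 whitelist_size = as.integer(whitelist_size),
                 tso = tso, seed = as.integer(seed)),
            class = "sim_config")
}

# draw molecules for one (droplet set, profile, substrate) combination
draw_molecules <- function(barcodes, dist, mean_mol) {
  n_mol <- rpois(length(barcodes), mean_mol)
  tot <- sum(n_mol)
  if (tot == 0L) return(NULL)
  pos <- as.integer(sample(names(dist), tot, replace = TRUE, prob = dist))
  data.frame(barcode = rep(barcodes, n_mol), position = pos,
             stringsAsFactors = FALSE)
}

#' Simulate a Haircut experiment
#'
#' Draw order, given the seed: (1) whitelist barcodes; (2) droplet barcodes
#' (sampled from the whitelist without replacement: singlets, then doublets,
#' then empty drops); (3) doublet profile pairs; (4) per-droplet molecule
#' counts and positions, looping profiles then substrates; (5) UMIs;
#' (6) read multiplicities; (7) R1 sequencing errors; (8) R2 sequencing
#' errors.
#'
#' @param cfg A [sim_config()].
#' @param outdir Optional directory; when given, writes `R1.fastq`,
#'   `R2.fastq`, `whitelist.txt`, `cells.txt`, `truth_cells.tsv`,
#'   `truth_molecules.tsv` and `truth_reads.tsv`.
#' @return List with `r1`, `r2` (character vectors of read sequences, named
#'   by read id), `whitelist`, `cells` (cell-associated barcodes), and
#'   `truth` (list of data frames `cells`, `molecules`, `reads`).
#' @export
simulate_experiment <- function(cfg, outdir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  subs <- cfg$substrates

  # (1) whitelist
  whitelist <- unique(random_seqs(cfg$whitelist_size, cfg$barcode_len))

  # (2) droplet barcodes
  n_singlet <- sum(vapply(cfg$profiles, `[[`, 0, "n_cells"))
  n_doublet <- if (length(cfg$profiles) >= 2L)
    as.integer(round(cfg$doublet_rate * n_singlet)) else 0L
  n_drops <- n_singlet + n_doublet + cfg$n_empty_drops
  if (n_drops > length(whitelist))
    stop("droplet count exceeds whitelist size")
  bcs <- sample(whitelist, n_drops)

  prof_labels <- vapply(cfg$profiles, `[[`, "", "label")
  cells <- data.frame(
    barcode = bcs[seq_len(n_singlet + n_doublet)],
    label = c(rep(prof_labels,
                  vapply(cfg$profiles, `[[`, 0, "n_cells")),
              rep("doublet", n_doublet)),
    stringsAsFactors = FALSE
  )
  cells$profile_a <- c(rep(seq_along(cfg$profiles),
                           vapply(cfg$profiles, `[[`, 0, "n_cells")),
                       integer(n_doublet))
  cells$profile_b <- NA_integer_
  empty_bcs <- bcs[seq_len(cfg$n_empty_drops) + n_singlet + n_doublet]

  # (3) doublet composition: two distinct profiles per doublet
  if (n_doublet > 0L) {
    pair_pool <- utils::combn(seq_along(cfg$profiles), 2L)
    pick <- sample.int(ncol(pair_pool), n_doublet, replace = TRUE)
    di <- which(cells$label == "doublet")
    cells$profile_a[di] <- pair_pool[1L, pick]
    cells$profile_b[di] <- pair_pool[2L, pick]
  }

  # (4) molecules: loop profiles then substrates, vectorized within
  mols <- list()
  for (pi in seq_along(cfg$profiles)) {
    prof <- cfg$profiles[[pi]]
    carrier <- cells$barcode[cells$profile_a == pi |
                             (!is.na(cells$profile_b) &
                              cells$profile_b == pi)]
    if (!length(carrier)) next
    for (s in subs$name) {
      dist <- prof$incision[[s]]
      if (is.null(dist)) next
      d <- draw_molecules(carrier, dist, prof$umis_per_substrate)
      if (!is.null(d)) {
        d$substrate <- s
        mols[[length(mols) + 1L]] <- d
      }
    }
  }
  if (cfg$n_empty_drops > 0L && cfg$background_per_substrate > 0) {
    for (s in subs$name) {
      d <- draw_molecules(empty_bcs, cfg$background_profile,
                          cfg$background_per_substrate)
      if (!is.null(d)) {
        d$substrate <- s
        mols[[length(mols) + 1L]] <- d
      }
    }
  }
  mols <- if (length(mols)) do.call(rbind, mols) else
    data.frame(barcode = character(), position = integer(),
               substrate = character(), stringsAsFactors = FALSE)

  # (5) UMIs, (6) read multiplicity
  n_mol <- nrow(mols)
  mols$umi <- random_seqs(n_mol, cfg$umi_len)
  mult <- 1L + rgeom(n_mol, prob = 1 / cfg$reads_per_umi)

  ridx <- rep(seq_len(n_mol), mult)
  reads <- data.frame(
    read_id = sprintf("read%08d", seq_along(ridx)),
    barcode = mols$barcode[ridx],
    umi = mols$umi[ridx],
    substrate = mols$substrate[ridx],
    position = mols$position[ridx],
    stringsAsFactors = FALSE
  )

  # (7) R1 = barcode + UMI with errors
  r1 <- add_errors(paste0(reads$barcode, reads$umi), cfg$error_rate)
  # (8) R2 = TSO + reference[pos..end] + polyA with errors
  si <- match(reads$substrate, subs$name)
  frag <- substr(subs$sequence[si], reads$position, nchar(subs$sequence[si]))
  r2 <- add_errors(paste0(cfg$tso, frag,
                          strrep("A", subs$polya_length[si])),
                   cfg$error_rate)
  names(r1) <- names(r2) <- reads$read_id

  mol_truth <- count_truth(mols)
  truth <- list(cells = cells[, c("barcode", "label")],
                molecules = mol_truth, reads = reads)
  out <- list(r1 = r1, r2 = r2, whitelist = whitelist,
              cells = cells$barcode, truth = truth)

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_fastq(r1, file.path(outdir, "R1.fastq"))
    write_fastq(r2, file.path(outdir, "R2.fastq"))
    writeLines(whitelist, file.path(outdir, "whitelist.txt"))
    writeLines(cells$barcode, file.path(outdir, "cells.txt"))
    wt <- function(d, f) write.table(d, file.path(outdir, f), sep = "\t",
                                     quote = FALSE, row.names = FALSE)
    wt(truth$cells, "truth_cells.tsv")
    wt(truth$molecules, "truth_molecules.tsv")
    wt(truth$reads, "truth_reads.tsv")
    out$outdir <- outdir
  }
  out
}

# aggregate per-molecule rows into per-cell true counts
count_truth <- function(mols) {
  if (!nrow(mols)) {
    return(data.frame(barcode = character(), substrate = character(),
                      position = integer(), n_molecules = integer(),
                      stringsAsFactors = FALSE))
  }
  dt <- data.table::as.data.table(mols)
  out <- dt[, list(n_molecules = .N),
            by = c("barcode", "substrate", "position")]
  data.table::setorder(out, barcode, substrate, position)
  as.data.frame(out)
}

write_fastq <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(strrep("I", nchar(seqs))))
  invisible(path)
}

#' Mixing-experiment simulation config
#'
#' Two mirrored knockout profiles: `UNG_KO` cells incise the ribonucleotide
#' substrate (scored site 44) but leave the uracil substrate intact;
#' `RNASEH2C_KO` cells do the converse (uracil incision scored at 45).
#' Incision mass is 0.6 at the scored site with additional downstream
#' processing mass and 0.25 intact; empty drops emit intact-only ambient
#' background.
#'
#' @param n_per_genotype Singlet cells per genotype (default 500).
#' @param umis_per_substrate Mean molecules per cell per substrate
#'   (default 100).
#' @param doublet_rate Fraction of additional cross-genotype doublet
#'   droplets (default 0.05).
#' @param n_empty_drops Empty droplets (default 500).
#' @param seed Integer seed (mandatory).
#' @param ... Further arguments passed to [sim_config()].
#' @return A [sim_config()].
#' @export
make_mixing_config <- function(n_per_genotype = 500L,
                               umis_per_substrate = 100,
                               doublet_rate = 0.05, n_empty_drops = 500L,
                               seed, ...) {
  subs <- example_substrates()
  subs <- subs[subs$name %in% c("uracilA", "riboG"), , drop = FALSE]
  ung_ko <- cell_profile(
    label = "UNG_KO",
    incision = list(
      uracilA = c("1" = 1),
      riboG = c("44" = 0.6, "1" = 0.25, "45" = 0.1, "46" = 0.05)
    ),
    umis_per_substrate = umis_per_substrate, n_cells = n_per_genotype)
  rnh_ko <- cell_profile(
    label = "RNASEH2C_KO",
    incision = list(
      uracilA = c("45" = 0.6, "1" = 0.25, "46" = 0.1, "47" = 0.05),
      riboG = c("1" = 1)
    ),
    umis_per_substrate = umis_per_substrate, n_cells = n_per_genotype)
  sim_config(substrates = subs, profiles = list(ung_ko, rnh_ko),
             n_empty_drops = n_empty_drops, doublet_rate = doublet_rate,
             background_per_substrate = 2, seed = seed, ...)
}
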