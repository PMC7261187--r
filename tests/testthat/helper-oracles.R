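# Independent brute-force oracles, deliberately naive and kept in plain R so
# they share no code with the implementation they check.

hamming_str <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# exhaustive all-offsets, all-references placement scan
oracle_align <- function(read, refs, max_mm = 2L) {
  L <- nchar(read)
  hits <- list()
  for (nm in names(refs)) {
    ref <- refs[[nm]]
    if (L > nchar(ref)) next
    for (o in seq_len(nchar(ref) - L + 1L)) {
      mm <- hamming_str(read, substr(ref, o, o + L - 1L))
      hits[[length(hits) + 1L]] <- list(ref = nm, pos = o, mm = mm)
    }
  }
  mms <- vapply(hits, `[[`, 0, "mm")
  if (!length(mms) || min(mms) > max_mm) return(list(status = "unaligned"))
  b <- which(mms == min(mms))
  if (length(b) > 1L) return(list(status = "ambiguous"))
  c(hits[[b]], list(status = "aligned"))
}

# exhaustive Hamming-1 correction scan over the whole whitelist
oracle_correct <- function(raw, whitelist) {
  if (raw %in% whitelist) return(list(barcode = raw, status = "exact"))
  d1 <- whitelist[vapply(whitelist, function(w) hamming_str(raw, w) == 1L,
                         TRUE)]
  if (length(d1) == 1L) return(list(barcode = d1, status = "corrected"))
  list(barcode = NA_character_, status = "unmatched")
}

# explicit adjacency-graph construction for directional UMI clustering:
# returns the partition as a sorted list of sorted member vectors
oracle_directional <- function(counts) {
  u <- names(counts)
  k <- length(u)
  chars <- matrix(unlist(strsplit(u, "")), nrow = k, byrow = TRUE)
  adj <- matrix(FALSE, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i != j) {
        adj[i, j] <- sum(chars[i, ] != chars[j, ]) == 1L &&
          counts[[i]] >= 2L * counts[[j]] - 1L
      }
    }
  }
  ord <- order(-unlist(counts), u)
  assigned <- rep(NA_integer_, k)
  for (r in ord) {
    if (!is.na(assigned[r])) next
    queue <- r
    assigned[r] <- r
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      nxt <- which(adj[v, ] & is.na(assigned))
      assigned[nxt] <- r
      queue <- c(queue, nxt)
    }
  }
  parts <- lapply(unique(assigned), function(r) sort(u[assigned == r]))
  parts[order(vapply(parts, `[[`, "", 1L))]
}

# two-sided exact Mann-Whitney p by enumerating every group assignment
oracle_exact_wilcox_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  ustat <- function(a, b) {
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  mid <- n1 * length(y) / 2
  obs <- abs(ustat(x, y) - mid)
  picks <- utils::combn(length(pooled), n1)
  us <- apply(picks, 2L, function(ix) ustat(pooled[ix], pooled[-ix]))
  mean(abs(us - mid) >= obs - 1e-12)
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, "")
}

# minimal two-substrate set for unit tests
tiny_substrates <- function(len = 60L, seed = 1L) {
  set.seed(seed)
  substrate_set(
    name = c("subA", "subB"),
    sequence = random_dna(2L, len),
    lesion_position = c(44L, 44L),
    lesion_type = c("U_A", "riboG_C"),
    scored_sites = list(45L, 44L),
    polya_length = c(30L, 30L)
  )
}

# partition of group_umis() output in the oracle's canonical form
partition_of <- function(clusters) {
  parts <- lapply(clusters, function(cl) sort(cl$members))
  parts[order(vapply(parts, `[[`, "", 1L))]
}
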