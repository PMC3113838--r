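# Independent brute-force oracles used across test files. These deliberately
# avoid the package's own algorithmic paths: structures are enumerated
# recursively, matches are found by substring comparison, correlations by
# direct cor() over hand-built overlaps.

# All nested secondary structures of a sequence (dot-bracket strings),
# respecting the minimum hairpin loop, by exhaustive recursion.
enumerate_structures <- function(seq, min_loop = 3) {
  seq <- chartr("Tt", "Uu", toupper(seq))
  n <- nchar(seq)
  chars <- strsplit(seq, "")[[1]]
  pairable <- function(i, j) {
    paste0(chars[i], chars[j]) %in% c("AU", "UA", "CG", "GC", "GU", "UG") &&
      j - i > min_loop
  }
  rec <- function(i, j) {
    if (j < i) return(list(integer(0)))
    if (j - i < min_loop + 1) return(list(integer(0)))
    out <- rec(i + 1, j)                       # i unpaired
    for (k in seq.int(i + min_loop + 1, j)) {
      if (!pairable(i, k)) next
      inner <- rec(i + 1, k - 1)
      rest <- if (k < j) rec(k + 1, j) else list(integer(0))
      for (si in inner) for (sr in rest) {
        out[[length(out) + 1]] <- c(i, k, si, sr)
      }
    }
    out
  }
  vapply(rec(1, n), function(pairs) {
    db <- rep(".", n)
    if (length(pairs) > 0) {
      idx <- matrix(pairs, ncol = 2, byrow = TRUE)
      db[idx[, 1]] <- "("
      db[idx[, 2]] <- ")"
    }
    paste(db, collapse = "")
  }, character(1))
}

# Minimum energy over all enumerated structures (independent of the DP).
enumeration_min_energy <- function(seq, min_loop = 3) {
  structs <- enumerate_structures(seq, min_loop)
  min(vapply(structs, function(s) structure_energy(seq, s, min_loop),
             numeric(1)))
}

# Brute-force seed-site scan: compare every k-window (with circular wrap) on
# both strands against the target site by plain string equality.
brute_seed_scan <- function(mirna, genome_seq, circular = TRUE, k = 7,
                            seed_start = 1) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  revcomp <- function(s) paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  seed_dna <- chartr("U", "T", toupper(substr(mirna, seed_start,
                                              seed_start + k - 1)))
  L <- nchar(genome_seq)
  ext <- if (circular) paste0(genome_seq, substr(genome_seq, 1, k - 1)) else genome_seq
  max_start <- if (circular) L else L - k + 1
  hits <- list()
  for (p in seq_len(max_start)) {
    win <- substr(ext, p, p + k - 1)
    if (win == revcomp(seed_dna))
      hits[[length(hits) + 1]] <- data.frame(start = p, end = p + k - 1, strand = "+")
    if (win == seed_dna)
      hits[[length(hits) + 1]] <- data.frame(start = p, end = p + k - 1, strand = "-")
  }
  if (length(hits) == 0)
    return(data.frame(start = integer(), end = integer(), strand = character()))
  out <- do.call(rbind, hits)
  out[order(out$start, out$strand), , drop = FALSE]
}

# Straight-line recomputation of the whole enrichment chain for one scan
# (no shared code with normalize_scan beyond base R).
brute_normalize_scan <- function(scan) {
  n5 <- scan$hy5_signal - scan$hy5_background
  n3 <- scan$hy3_signal - scan$hy3_background
  t5 <- median(scan$hy5_background)
  t3 <- median(scan$hy3_background)
  kept <- n5 >= t5 & n3 >= t3 & n3 > 0
  ratio <- n5 / n3
  cal <- ratio[kept & scan$is_calibrator]
  norm <- ratio / exp(median(log(cal)))
  sapply(unique(scan$probe_id), function(p) {
    r <- norm[kept & scan$probe_id == p]
    if (length(r) == 0) NA_real_ else mean(r)
  })
}
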