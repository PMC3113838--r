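# Seed-site scanning of a (circular) mitochondrial genome with a Poisson
# random-match statistic, exact mapping of full-length mature miRNAs, and
# annotation overlap.
#
# Conventions:
#  - coordinates are 1-based inclusive on the forward strand; a hit on the
#    minus strand at (start, end) means the reverse complement of the
#    forward-strand span carries the matched sequence;
#  - circular genomes are scanned across the origin with a (k-1)-nt wrap
#    window; an origin-spanning hit is reported with end = start + k - 1,
#    which may exceed the genome length (interpret modulo L);
#  - a target site is the reverse complement of the miRNA seed, so a
#    plus-strand site corresponds to the forward strand containing
#    revcomp(seed) and a minus-strand site to the forward strand containing
#    the seed itself (DNA alphabet).

#' Construct a genome sequence object
#'
#' @param seq character scalar over A/C/G/T (U accepted and converted);
#'   ambiguity codes are rejected.
#' @param accession label for the sequence (default "synthetic").
#' @param circular logical; scan across the origin when TRUE.
#' @return object of class `genome_sequence` with fields `seq`, `accession`,
#'   `circular`, `length`.
#' @export
genome_sequence <- function(seq, accession = "synthetic", circular = TRUE) {
  seq <- as_dna(seq)
  if (nchar(seq) == 0) stop("empty genome sequence", call. = FALSE)
  validate_dna(seq, what = paste0("genome ", accession))
  structure(list(seq = seq, accession = accession, circular = circular,
                 length = nchar(seq)),
            class = "genome_sequence")
}

#' @export
print.genome_sequence <- function(x, ...) {
  cat(sprintf("genome_sequence %s: %d bp, %s\n", x$accession, x$length,
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

#' Read the first record of a FASTA file as a genome
#'
#' @param path FASTA file.
#' @inheritParams genome_sequence
#' @export
read_genome_fasta <- function(path, circular = TRUE) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0) stop("no sequence in ", path, call. = FALSE)
  genome_sequence(as.character(ss[[1]]), accession = names(ss)[1],
                  circular = circular)
}

#' Read mature miRNA sequences from FASTA
#'
#' @param path FASTA file of mature miRNAs (RNA or DNA alphabet).
#' @return named character vector of RNA sequences.
#' @export
read_mirna_fasta <- function(path) {
  ss <- Biostrings::readRNAStringSet(path)
  stats::setNames(as_rna(as.character(ss)), names(ss))
}

# Match a DNA pattern against the genome, honouring circularity.
# Returns forward-strand start positions (1..L).
match_positions <- function(pattern, genome) {
  k <- nchar(pattern)
  ext <- genome$seq
  if (genome$circular && k > 1)
    ext <- paste0(ext, substr(genome$seq, 1, k - 1))
  hits <- Biostrings::matchPattern(Biostrings::DNAString(pattern),
                                   Biostrings::DNAString(ext))
  starts <- Biostrings::start(hits)
  sort(unique(starts[starts <= genome$length]))
}

#' Find seed target sites on a genome
#'
#' Extracts the seed (by default the 5'-proximal heptamer, nucleotides
#' `seed_start .. seed_start + k - 1`) of a mature miRNA and reports every
#' genome position whose strand sequence equals the reverse complement of
#' the seed, i.e. every perfect seed target site.
#'
#' @param mirna mature miRNA sequence (5'->3', RNA or DNA alphabet),
#'   optionally named.
#' @param genome a [genome_sequence()].
#' @param k seed length (>= 4; default 7).
#' @param seed_start 1-based offset of the seed within the miRNA (default 1;
#'   use 2 for the canonical nucleotide 2-8 seed).
#' @param strands `"both"` (default), `"+"`, or `"-"`.
#' @return data frame with `start`, `end`, `strand`, `site` (forward-strand
#'   sequence of the span); `end` may exceed the genome length for
#'   origin-spanning hits on a circular genome.
#' @export
seed_sites <- function(mirna, genome, k = 7, seed_start = 1,
                       strands = c("both", "+", "-")) {
  strands <- match.arg(strands)
  stopifnot(inherits(genome, "genome_sequence"))
  if (k < 4) stop("seed length k must be >= 4", call. = FALSE)
  mirna <- validate_rna(as_rna(mirna), "miRNA")
  if (seed_start + k - 1 > nchar(mirna))
    stop("seed extends past the miRNA 3' end", call. = FALSE)
  seed_dna <- as_dna(substr(mirna, seed_start, seed_start + k - 1))

  res <- list()
  if (strands %in% c("both", "+")) {
    p <- match_positions(revcomp_dna(seed_dna), genome)
    if (length(p) > 0)
      res[["+"]] <- data.frame(start = p, end = p + k - 1, strand = "+")
  }
  if (strands %in% c("both", "-")) {
    p <- match_positions(seed_dna, genome)
    if (length(p) > 0)
      res[["-"]] <- data.frame(start = p, end = p + k - 1, strand = "-")
  }
  out <- if (length(res) > 0) do.call(rbind, res) else
    data.frame(start = integer(), end = integer(), strand = character())
  rownames(out) <- NULL
  ext <- paste0(genome$seq, substr(genome$seq, 1, max(0, k - 1)))
  out$site <- if (nrow(out) > 0) substring(ext, out$start, out$end) else character(0)
  out[order(out$start, out$strand), , drop = FALSE]
}

#' Poisson significance of an observed seed-match count
#'
#' Under the null, random matches of a k-mer in the genome follow a Poisson
#' law with mean `lambda = n_positions x per-position match probability`,
#' where `n_positions` is `L` per scanned strand for a circular genome and
#' `L - k + 1` for a linear one, and the match probability is the product
#' of the background frequencies of the required site bases
#' (`composition = "genome"`, mononucleotide frequencies of the forward
#' strand) or `4^-k` (`composition = "uniform"`). The p-value is the upper
#' tail `P(X >= n_obs)`, equal to 1 when `n_obs = 0`: a low probability
#' implies a significant hit.
#'
#' @param n_obs observed hit count (>= 0).
#' @param genome a [genome_sequence()].
#' @param seed seed sequence (RNA or DNA; its reverse complement is the
#'   plus-strand site).
#' @param composition `"genome"` (default) or `"uniform"`.
#' @param strands strands that were scanned.
#' @return list with `lambda` and `p_value`.
#' @export
poisson_match_pvalue <- function(n_obs, genome, seed,
                                 composition = c("genome", "uniform"),
                                 strands = c("both", "+", "-")) {
  composition <- match.arg(composition)
  strands <- match.arg(strands)
  stopifnot(inherits(genome, "genome_sequence"), n_obs >= 0)
  seed_dna <- as_dna(seed)
  k <- nchar(seed_dna)
  L <- genome$length
  n_pos <- if (genome$circular) L else max(0L, L - k + 1L)
  if (n_pos == 0) stop("genome shorter than the seed", call. = FALSE)

  site_prob <- function(pattern) {
    if (composition == "uniform") return(4^-nchar(pattern))
    f <- Biostrings::letterFrequency(Biostrings::DNAString(genome$seq),
                                     DNA_BASES, as.prob = TRUE)
    prod(f[strsplit(pattern, "")[[1]]])
  }
  lambda <- 0
  if (strands %in% c("both", "+")) lambda <- lambda + n_pos * site_prob(revcomp_dna(seed_dna))
  if (strands %in% c("both", "-")) lambda <- lambda + n_pos * site_prob(seed_dna)
  p <- if (n_obs == 0) 1 else stats::ppois(n_obs - 1, lambda, lower.tail = FALSE)
  list(lambda = lambda, p_value = p)
}

#' Exact full-length occurrences of a mature miRNA on a genome
#'
#' Every zero-mismatch occurrence of the miRNA (U -> T) on either strand,
#' in 1-based inclusive forward-strand coordinates; a plus-strand hit means
#' the forward strand carries the miRNA sequence itself, a minus-strand hit
#' that the reverse complement of the span does. Circular wrap included.
#'
#' @inheritParams seed_sites
#' @return data frame with `start`, `end`, `strand`.
#' @export
exact_mature_match <- function(mirna, genome) {
  stopifnot(inherits(genome, "genome_sequence"))
  mir_dna <- as_dna(validate_rna(as_rna(mirna), "miRNA"))
  k <- nchar(mir_dna)
  res <- list()
  p <- match_positions(mir_dna, genome)
  if (length(p) > 0) res[["+"]] <- data.frame(start = p, end = p + k - 1, strand = "+")
  p <- match_positions(revcomp_dna(mir_dna), genome)
  if (length(p) > 0) res[["-"]] <- data.frame(start = p, end = p + k - 1, strand = "-")
  out <- if (length(res) > 0) do.call(rbind, res) else
    data.frame(start = integer(), end = integer(), strand = character())
  rownames(out) <- NULL
  out[order(out$start, out$strand), , drop = FALSE]
}

#' Label hits with overlapping genome features
#'
#' Any-overlap rule; feature strand is ignored for labeling because the
#' mitochondrial genome is transcribed polycistronically from both strands,
#' so the gene hosting a site need not be the regulated one. Hits without
#' any overlapping feature are labeled "intergenic". Origin-spanning hits
#' (end > genome length) are split across the origin before the overlap
#' test.
#'
#' @param hits data frame with `start`, `end` (from [seed_sites()] or
#'   [exact_mature_match()]).
#' @param annotation data frame of features with columns `gene`, `type`,
#'   `start`, `end`, `strand` (origin-spanning features represented split).
#' @param genome_length genome length, used to wrap origin-spanning hits
#'   (optional; taken as `max(annotation$end)` when absent).
#' @return `hits` with a `genes` character column (comma-separated labels).
#' @export
annotate_hits <- function(hits, annotation, genome_length = NULL) {
  if (nrow(hits) == 0) {
    hits$genes <- character(0)
    return(hits)
  }
  if (is.null(annotation) || nrow(annotation) == 0) {
    hits$genes <- "unannotated"
    return(hits)
  }
  L <- genome_length %||% max(annotation$end)
  feat <- GenomicRanges::GRanges("chr",
                                 IRanges::IRanges(annotation$start, annotation$end))
  labels <- vapply(seq_len(nrow(hits)), function(i) {
    s <- hits$start[i]; e <- hits$end[i]
    spans <- if (e > L) list(c(s, L), c(1, e - L)) else list(c(s, e))
    q <- GenomicRanges::GRanges("chr", IRanges::IRanges(
      vapply(spans, `[`, numeric(1), 1), vapply(spans, `[`, numeric(1), 2)))
    ov <- GenomicRanges::findOverlaps(q, feat)
    g <- unique(annotation$gene[S4Vectors::subjectHits(ov)])
    if (length(g) == 0) "intergenic" else paste(g, collapse = ",")
  }, character(1))
  hits$genes <- labels
  hits
}

#' Scan a panel of miRNAs against an annotated genome
#'
#' Runs [seed_sites()], [poisson_match_pvalue()] and [annotate_hits()] for
#' each miRNA and assembles a merged report.
#'
#' @param mirnas named character vector of mature miRNA sequences.
#' @inheritParams seed_sites
#' @param annotation optional feature data frame (see [annotate_hits()]);
#'   when missing, hits are labeled "unannotated" with a warning.
#' @param composition null composition mode for the Poisson statistic.
#' @param alpha significance level for the report flag (default 0.05).
#' @return list with `reports` (per-miRNA list of `seed_scan_report`s) and
#'   `table` (one row per miRNA: id, seed, n_hits, lambda, p_value,
#'   significant, genes).
#' @export
scan_panel <- function(mirnas, genome, annotation = NULL, k = 7,
                       seed_start = 1, strands = "both",
                       composition = "genome", alpha = 0.05) {
  stopifnot(length(mirnas) >= 1)
  if (is.null(names(mirnas)))
    names(mirnas) <- sprintf("mirna_%02d", seq_along(mirnas))
  if (is.null(annotation))
    warning("no annotation provided; hits labeled 'unannotated'")
  reports <- lapply(names(mirnas), function(id) {
    seq <- as_rna(mirnas[[id]])
    seed <- substr(seq, seed_start, seed_start + k - 1)
    hits <- seed_sites(seq, genome, k = k, seed_start = seed_start,
                       strands = strands)
    hits <- suppressWarnings(
      annotate_hits(hits, annotation, genome_length = genome$length))
    pv <- poisson_match_pvalue(nrow(hits), genome, seed,
                               composition = composition, strands = strands)
    structure(list(mirna_id = id, seed = seed, k = k, seed_start = seed_start,
                   hits = hits, lambda = pv$lambda, p_value = pv$p_value),
              class = "seed_scan_report")
  })
  names(reports) <- names(mirnas)
  tab <- do.call(rbind, lapply(reports, function(r) {
    data.frame(mirna_id = r$mirna_id, seed = r$seed, n_hits = nrow(r$hits),
               lambda = r$lambda, p_value = r$p_value,
               significant = r$p_value < alpha,
               genes = paste(unique(unlist(strsplit(r$hits$genes, ","))),
                             collapse = ","),
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  list(reports = reports, table = tab)
}

#' @export
print.seed_scan_report <- function(x, ...) {
  cat(sprintf("seed_scan_report %s: seed %s (k=%d, start %d), %d hit(s), lambda = %.4g, p = %.4g\n",
              x$mirna_id, x$seed, x$k, x$seed_start, nrow(x$hits),
              x$lambda, x$p_value))
  invisible(x)
}
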