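# Synthetic genomes with planted miRNA seed sites, synthetic hairpins, and
# plain-text writers (FASTA / GFF3 / CSV truth tables).

#' Generate a genome with planted seed target sites
#'
#' Writes the reverse complement of each planted seed at the requested
#' forward-strand position (for `strand == "+"`), or the seed itself (for
#' `strand == "-"`), over a random background, so that [seed_sites()] run
#' with the same seed sequence recovers exactly the planted coordinates
#' (plus any chance background matches). Planted sites may span the origin
#' of a circular genome.
#'
#' @param length genome length in nucleotides.
#' @param planted data frame with columns `seed` (RNA or DNA k-mer),
#'   `position` (1-based forward-strand start), `strand` (`"+"`/`"-"`).
#' @param circular logical (default TRUE).
#' @param background either `"uniform"` or a length-4 probability vector for
#'   A,C,G,T; `"A"` gives an all-A background (no spurious matches for seeds
#'   containing C).
#' @param features optional integer: generate this many evenly spaced,
#'   evenly sized gene features named `GENE01..` as an annotation.
#' @param seed RNG seed.
#' @return list with `genome` (a [genome_sequence()]), `truth` (the planted
#'   table with an `end` column added), and `annotation` (data frame or
#'   NULL).
#' @export
gen_genome_with_sites <- function(length, planted = NULL, circular = TRUE,
                                  background = "uniform", features = NULL,
                                  seed = NULL) {
  stopifnot(length >= 1)
  with_seed_if(seed, {
    if (identical(background, "uniform")) {
      chars <- sample(DNA_BASES, length, replace = TRUE)
    } else if (identical(background, "A")) {
      chars <- rep("A", length)
    } else {
      stopifnot(length(background) == 4)
      chars <- sample(DNA_BASES, length, replace = TRUE,
                      prob = background / sum(background))
    }
    truth <- NULL
    if (!is.null(planted) && nrow(planted) > 0) {
      if (any(planted$position < 1 | planted$position > length))
        stop("planted positions must lie within [1, length]", call. = FALSE)
      occupied <- integer(0)
      for (i in seq_len(nrow(planted))) {
        sd <- as_dna(planted$seed[i])
        k <- nchar(sd)
        site <- if (planted$strand[i] == "+") revcomp_dna(sd) else sd
        pos <- planted$position[i]
        idx <- ((pos - 1 + seq_len(k) - 1) %% length) + 1
        if (!circular && pos + k - 1 > length)
          stop("planted site extends past the end of a linear genome", call. = FALSE)
        if (any(idx %in% occupied))
          warning("planted sites overlap; truth table remains exact")
        occupied <- c(occupied, idx)
        chars[idx] <- strsplit(site, "")[[1]]
      }
      truth <- planted
      truth$end <- planted$position + nchar(as_dna(planted$seed)) - 1
    }
    ann <- NULL
    if (!is.null(features) && features > 0) {
      n <- as.integer(features)
      bounds <- floor(seq(1, length + 1, length.out = n + 1))
      ann <- data.frame(gene = sprintf("GENE%02d", seq_len(n)),
                        type = "gene",
                        start = bounds[-(n + 1)],
                        end = bounds[-1] - 1,
                        strand = rep(c("+", "-"), length.out = n),
                        stringsAsFactors = FALSE)
    }
    list(genome = genome_sequence(paste(chars, collapse = ""),
                                  accession = "synthetic",
                                  circular = circular),
         truth = truth, annotation = ann)
  })
}

#' Generate a hairpin-forming RNA sequence
#'
#' Returns a sequence of length `2 * stem_len + loop_len` whose optimal
#' nested pairing under the package's folding model is a single stem of
#' `stem_len` base pairs closing an unpaired loop. Stem base pairs are G-C
#' with probability `gc_fraction` and A-U otherwise; the loop is all A
#' (non-pairing against a G/C stem).
#'
#' @param stem_len number of stem base pairs (>= 0).
#' @param loop_len loop length (>= 3, the minimum hairpin loop).
#' @param gc_fraction fraction of G-C stem pairs (default 1).
#' @param seed RNG seed.
#' @return RNA sequence string.
#' @export
gen_hairpin <- function(stem_len, loop_len = 4, gc_fraction = 1, seed = NULL) {
  if (loop_len < 3) stop("loop_len must be >= 3 (minimum hairpin loop)", call. = FALSE)
  if (stem_len < 0) stop("stem_len must be >= 0", call. = FALSE)
  with_seed_if(seed, {
    if (stem_len == 0) return(paste(rep("A", loop_len), collapse = ""))
    is_gc <- stats::runif(stem_len) < gc_fraction
    left <- ifelse(is_gc, sample(c("G", "C"), stem_len, replace = TRUE), "A")
    comp <- c(A = "U", C = "G", G = "C", U = "A")
    right <- rev(unname(comp[left]))
    paste0(paste(left, collapse = ""),
           paste(rep("A", loop_len), collapse = ""),
           paste(right, collapse = ""))
  })
}

#' Write named sequences to FASTA
#'
#' @param seqs named character vector (RNA or DNA).
#' @param path file path.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Write an annotation data frame as GFF3
#'
#' @param annotation data frame with `gene`, `type`, `start`, `end`,
#'   `strand`.
#' @param path file path.
#' @param seqid sequence name used in column 1 (default "chrM").
#' @export
write_annotation_gff3 <- function(annotation, path, seqid = "chrM") {
  lines <- c("##gff-version 3",
             sprintf("%s\tmitomir\t%s\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
                     seqid, annotation$type, annotation$start, annotation$end,
                     annotation$strand, annotation$gene, annotation$gene))
  writeLines(lines, path)
  invisible(path)
}

#' Read a GFF3 annotation into the feature table used by [annotate_hits()]
#'
#' Uses rtracklayer when available, otherwise a minimal tab-split of the
#' nine GFF3 columns.
#'
#' @param path GFF3 file.
#' @return data frame with `gene`, `type`, `start`, `end`, `strand`.
#' @export
read_annotation_gff3 <- function(path) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    g <- rtracklayer::import(path, format = "gff3")
    name <- if (!is.null(g$Name)) as.character(g$Name) else
      if (!is.null(g$ID)) as.character(g$ID) else as.character(seq_along(g))
    return(data.frame(gene = name,
                      type = as.character(g$type),
                      start = GenomicRanges::start(g),
                      end = GenomicRanges::end(g),
                      strand = as.character(GenomicRanges::strand(g)),
                      stringsAsFactors = FALSE))
  }
  x <- utils::read.table(path, sep = "\t", comment.char = "#",
                         stringsAsFactors = FALSE)
  attr_field <- function(a, key) {
    m <- regmatches(a, regexpr(paste0(key, "=[^;]+"), a))
    ifelse(lengths(regmatches(a, gregexpr(paste0(key, "="), a))) > 0,
           sub(paste0(key, "="), "", m), NA_character_)
  }
  data.frame(gene = attr_field(x$V9, "Name"), type = x$V3,
             start = x$V4, end = x$V5, strand = x$V7,
             stringsAsFactors = FALSE)
}
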