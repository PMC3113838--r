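# Shared sequence helpers and validators.

RNA_BASES <- c("A", "C", "G", "U")
DNA_BASES <- c("A", "C", "G", "T")

#' Convert a sequence to RNA (U) or DNA (T) alphabet
#'
#' U and T are treated interchangeably on input throughout the package.
#'
#' @param x character vector of sequences.
#' @return character vector in the requested alphabet, uppercased.
#' @keywords internal
as_rna <- function(x) chartr("Tt", "Uu", toupper(x))

#' @rdname as_rna
#' @keywords internal
as_dna <- function(x) chartr("Uu", "Tt", toupper(x))

#' Reverse complement of a DNA string
#' @param x character scalar over A/C/G/T.
#' @return character scalar.
#' @keywords internal
revcomp_dna <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

validate_rna <- function(x, what = "sequence") {
  chars <- strsplit(as_rna(x), "")[[1]]
  bad <- which(!chars %in% RNA_BASES)
  if (length(bad) > 0) {
    stop(sprintf("invalid character '%s' at position %d of %s",
                 chars[bad[1]], bad[1], what), call. = FALSE)
  }
  invisible(paste(chars, collapse = ""))
}

validate_dna <- function(x, what = "sequence") {
  chars <- strsplit(toupper(x), "")[[1]]
  bad <- which(!chars %in% DNA_BASES)
  if (length(bad) > 0) {
    stop(sprintf("invalid character '%s' at position %d of %s (ambiguity codes are rejected)",
                 chars[bad[1]], bad[1], what), call. = FALSE)
  }
  invisible(paste(chars, collapse = ""))
}

# Run `expr` under a fixed RNG state without touching the caller's stream;
# seed = NULL leaves the current stream in use.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
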