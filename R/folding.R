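# RNA secondary-structure minimum free energy by dynamic programming under
# a reduced nearest-neighbor model, plus the derived thermodynamic features
# AMFE and MFEI.
#
# Model: Watson-Crick and G.U wobble pairs; hairpin loops of at least 3
# unpaired bases; no pseudoknots. The energy of a structure is the sum of
# the stacking energies of adjacent base pairs (kcal/mol, all negative), so
# the open chain scores 0 and MFE <= 0 always. Loop-size penalties beyond
# the minimum-hairpin constraint are deliberately omitted; the full Turner
# parameterization lives in dedicated folding software whose energies can
# be ingested through `feature_table(mfe_file = ...)` for exact parity.

.PAIR_TYPES <- c("AU", "CG", "GC", "UA", "GU", "UG")

# Build the 6x6 stacking-energy table (outer pair x inner pair) from a set
# of canonical doublets, mirroring each entry to its symmetry-equivalent
# stack read from the opposite strand: E[XY, WZ] = E[ZW, YX].
.build_stack_table <- function() {
  raw <- c(
    "AU AU -0.93", "AU CG -2.24", "AU GC -2.08", "AU UA -1.10",
    "AU GU -1.36", "AU UG -0.55",
    "CG AU -2.11", "CG CG -3.26", "CG GC -2.36",
    "CG GU -2.11", "CG UG -1.41",
    "GC CG -3.42", "GC GU -2.51", "GC UG -1.53",
    "UA AU -1.33", "UA CG -2.35", "UA GU -1.00", "UA UG -1.27",
    "GU GU -0.50", "GU UG -0.30", "UG GU -0.30")
  E <- matrix(NA_real_, 6, 6, dimnames = list(.PAIR_TYPES, .PAIR_TYPES))
  rev2 <- function(p) paste0(substr(p, 2, 2), substr(p, 1, 1))
  for (entry in raw) {
    f <- strsplit(entry, " +")[[1]]
    p <- f[1]; q <- f[2]; v <- as.numeric(f[3])
    E[p, q] <- v
    E[rev2(q), rev2(p)] <- v
  }
  stopifnot(!anyNA(E))
  E
}

.STACK_ENERGY <- .build_stack_table()

# pair type index ("" when the bases cannot pair)
.pair_type <- function(x, y) {
  p <- paste0(x, y)
  if (p %in% .PAIR_TYPES) p else ""
}

#' Energy of a given secondary structure
#'
#' Sums the stacking energies of adjacent base pairs under the package's
#' reduced nearest-neighbor model; validates that the structure is nested,
#' that every pair is Watson-Crick or G.U, and that hairpin loops have at
#' least `min_loop` unpaired bases.
#'
#' @param sequence RNA sequence (U/T interchangeable).
#' @param structure dot-bracket string of the same length.
#' @param min_loop minimum hairpin loop size (default 3).
#' @return energy in kcal/mol (0 for the open chain).
#' @export
structure_energy <- function(sequence, structure, min_loop = 3) {
  seq <- validate_rna(as_rna(sequence))
  n <- nchar(seq)
  if (nchar(structure) != n)
    stop("structure length differs from sequence length", call. = FALSE)
  chars <- strsplit(seq, "")[[1]]
  db <- strsplit(structure, "")[[1]]
  stack_idx <- integer(0)
  partner <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    if (db[i] == "(") stack_idx <- c(stack_idx, i)
    else if (db[i] == ")") {
      if (length(stack_idx) == 0) stop("unbalanced structure", call. = FALSE)
      j <- stack_idx[length(stack_idx)]
      stack_idx <- stack_idx[-length(stack_idx)]
      partner[j] <- i; partner[i] <- j
      if (.pair_type(chars[j], chars[i]) == "")
        stop(sprintf("bases %d and %d cannot pair", j, i), call. = FALSE)
      if (i - j - 1 < min_loop && !any(!is.na(partner[(j + 1):(i - 1)])))
        stop(sprintf("hairpin loop closed by (%d,%d) is shorter than %d",
                     j, i, min_loop), call. = FALSE)
    } else if (db[i] != ".") stop("invalid structure character", call. = FALSE)
  }
  if (length(stack_idx) > 0) stop("unbalanced structure", call. = FALSE)
  e <- 0
  for (i in seq_len(n)) {
    j <- partner[i]
    if (!is.na(j) && j > i && !is.na(partner[i + 1]) && partner[i + 1] == j - 1) {
      e <- e + .STACK_ENERGY[.pair_type(chars[i], chars[j]),
                             .pair_type(chars[i + 1], chars[j - 1])]
    }
  }
  e
}

#' Minimum free energy fold of an RNA sequence
#'
#' Dynamic programming over all nested secondary structures under the
#' reduced nearest-neighbor stacking model (see [structure_energy()]).
#' Co-optimal structures are resolved by a deterministic traceback that
#' prefers pairing the leftmost base, with the smallest partner index, and
#' a continued stack over a branch; pairs that contribute no stabilizing
#' energy (isolated pairs) are left unpaired.
#'
#' @param sequence RNA sequence (U/T interchangeable); invalid characters
#'   raise an error naming the offending position.
#' @param min_loop minimum hairpin loop size (default 3).
#' @return object of class `fold_result`: list with `sequence`, `structure`
#'   (dot-bracket), `mfe` (kcal/mol, <= 0), `model`.
#' @export
fold_mfe <- function(sequence, min_loop = 3) {
  seq <- validate_rna(as_rna(sequence))
  n <- nchar(seq)
  chars <- strsplit(seq, "")[[1]]
  result <- function(db, mfe) structure(
    list(sequence = seq, structure = paste(db, collapse = ""),
         mfe = mfe, model = "reduced-stacking-v1"),
    class = "fold_result")
  if (n < min_loop + 2) return(result(rep(".", n), 0))

  type <- matrix("", n, n)
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n))
    type[i, j] <- .pair_type(chars[i], chars[j])
  can_pair <- function(i, j) j - i > min_loop && type[i, j] != ""

  V <- matrix(Inf, n, n)   # min energy with (i,j) paired
  W <- matrix(0, n, n)     # min energy of subsequence i..j
  for (l in seq.int(min_loop + 1, n - 1)) {
    for (i in seq_len(n - l)) {
      j <- i + l
      if (can_pair(i, j)) {
        v <- if (j - 1 >= i + 1) W[i + 1, j - 1] else 0
        if (can_pair(i + 1, j - 1)) {
          v <- min(v, .STACK_ENERGY[type[i, j], type[i + 1, j - 1]] +
                     V[i + 1, j - 1])
        }
        V[i, j] <- v
      }
      w <- W[i + 1, j]  # i unpaired
      ks <- seq.int(i + min_loop + 1, j)
      for (k in ks) {
        if (is.finite(V[i, k])) {
          cand <- V[i, k] + if (k < j) W[k + 1, j] else 0
          if (cand < w) w <- cand
        }
      }
      W[i, j] <- w
    }
  }

  eps <- 1e-9
  db <- rep(".", n)
  trace_V <- function(i, j) {
    db[i] <<- "("; db[j] <<- ")"
    target <- V[i, j]
    if (can_pair(i + 1, j - 1) &&
        abs(.STACK_ENERGY[type[i, j], type[i + 1, j - 1]] + V[i + 1, j - 1] -
              target) < eps) {
      trace_V(i + 1, j - 1)
      return(invisible())
    }
    if (j - 1 >= i + 1) trace_W(i + 1, j - 1)
  }
  trace_W <- function(i, j) {
    if (j - i < min_loop + 1) return(invisible())
    target <- W[i, j]
    # zero-energy region: the open chain is co-optimal; report it rather
    # than decorating the structure with non-stabilizing lone pairs
    if (target > -eps) return(invisible())
    for (k in seq.int(i + min_loop + 1, j)) {
      if (is.finite(V[i, k])) {
        rest <- if (k < j) W[k + 1, j] else 0
        if (abs(V[i, k] + rest - target) < eps && V[i, k] < -eps) {
          trace_V(i, k)
          if (k < j) trace_W(k + 1, j)
          return(invisible())
        }
      }
    }
    trace_W(i + 1, j)
  }
  trace_W(1, n)
  res <- result(db, W[1, n])
  # the traceback must reproduce the DP energy exactly
  stopifnot(abs(structure_energy(seq, res$structure, min_loop) - res$mfe) < 1e-6)
  res
}

#' @export
print.fold_result <- function(x, ...) {
  cat(x$sequence, "\n", x$structure,
      sprintf("  (MFE %.2f kcal/mol, %s)\n", x$mfe, x$model), sep = "")
  invisible(x)
}

#' Adjusted minimum free energy
#'
#' Length-normalized MFE: `AMFE = (-MFE / length) * 100`, i.e. the folding
#' energy per 100 nucleotides with the sign flipped (stable structures give
#' large positive AMFE).
#'
#' @param mfe minimum free energy (kcal/mol, <= 0).
#' @param length sequence length in nucleotides (> 0).
#' @return AMFE (unitless, per-100-nt normalized).
#' @export
amfe <- function(mfe, length) {
  if (any(length <= 0)) stop("length must be > 0", call. = FALSE)
  (-mfe / length) * 100
}

#' Minimum free energy index
#'
#' `MFEI = AMFE / (G+C)%`.
#'
#' @param amfe_value AMFE value(s) (see [amfe()]).
#' @param gc_pct (G+C) percentage in \[0, 100\]; must be > 0.
#' @return MFEI (unitless).
#' @export
mfei <- function(amfe_value, gc_pct) {
  if (any(gc_pct <= 0)) stop("undefined index: GC percentage is 0", call. = FALSE)
  amfe_value / gc_pct
}

#' (G+C) percentage of a sequence
#'
#' @param sequence RNA or DNA sequence(s).
#' @return percentage(s) in \[0, 100\].
#' @export
gc_content <- function(sequence) {
  vapply(sequence, function(s) {
    s <- toupper(s)
    if (nchar(s) == 0) stop("empty sequence", call. = FALSE)
    chars <- strsplit(s, "")[[1]]
    100 * sum(chars %in% c("G", "C")) / length(chars)
  }, numeric(1), USE.NAMES = !is.null(names(sequence)))
}

#' Per-miRNA structural and thermodynamic feature table
#'
#' Computes length, GC%, MFE (internal folding engine or externally supplied
#' energies), AMFE and MFEI for each miRNA.
#'
#' @param mature named character vector of mature sequences.
#' @param precursor named character vector of pre-miRNA sequences (names
#'   must cover those of `mature`); folding features are computed on the
#'   precursor.
#' @param mfe_file optional path to a TSV with columns `id` and `mfe`
#'   holding externally computed energies (e.g. from a Turner-model folder);
#'   these override the internal engine and are flagged in `mfe_source`.
#' @param groups optional named character vector of group labels (e.g.
#'   `"mitomiR"` / `"control"`).
#' @return data frame: `mirna_id`, `mature_len`, `pre_len`, `gc_pct`,
#'   `mfe`, `amfe`, `mfei`, `mfe_source`, `group`. The identities
#'   `amfe == (-mfe/pre_len)*100` and `mfei == amfe/gc_pct` hold exactly for
#'   every row.
#' @export
feature_table <- function(mature, precursor, mfe_file = NULL, groups = NULL) {
  ids <- names(mature)
  stopifnot(!is.null(ids), all(ids %in% names(precursor)))
  external <- NULL
  if (!is.null(mfe_file)) {
    external <- utils::read.table(mfe_file, sep = "\t", header = TRUE,
                                  stringsAsFactors = FALSE)
    missing <- setdiff(ids, external$id)
    if (length(missing) > 0)
      stop("external MFE file lacks ids: ", paste(missing, collapse = ", "),
           call. = FALSE)
  }
  rows <- lapply(ids, function(id) {
    pre <- as_rna(precursor[[id]])
    gc <- gc_content(pre)
    if (!is.null(external)) {
      m <- external$mfe[match(id, external$id)]
      src <- "external"
    } else {
      m <- fold_mfe(pre)$mfe
      src <- "internal"
    }
    a <- amfe(m, nchar(pre))
    data.frame(mirna_id = id,
               mature_len = nchar(mature[[id]]),
               pre_len = nchar(pre),
               gc_pct = gc,
               mfe = m,
               amfe = a,
               mfei = if (gc > 0) mfei(a, gc) else NA_real_,
               mfe_source = src,
               group = if (!is.null(groups)) groups[[id]] else NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
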