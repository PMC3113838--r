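# Synthetic two-channel microarray data with known ground truth.
#
# The generator emulates the structure of a dual-color miRNA array:
# 1460 miRNA probes plus 97 control probes spotted in quadruplicate
# (6228 spots), 18 of the controls being spike-in calibrators present at
# equal abundance in both samples. Spot foregrounds are log-normal around
# (abundance x planted fold x dye bias) with an additive per-spot
# background, so ratio-scale behavior mimics a real two-color scan without
# claiming the scanner's physics.

#' Describe a two-channel array layout
#'
#' @param n_mirna number of miRNA probes (default 1460).
#' @param n_controls number of control probes (default 97).
#' @param n_replicate_spots spots per probe (default 4, i.e. quadruplicates).
#' @param n_calibrators number of control probes used as spike-in calibrators
#'   (default 18); calibrators are the first `n_calibrators` control probes.
#' @return an object of class `array_design` with fields `probe_ids`,
#'   `n_replicate_spots`, `calibrator_ids`.
#' @export
#' @examples
#' d <- array_design()
#' length(d$probe_ids) * d$n_replicate_spots  # 6228 spots per scan
array_design <- function(n_mirna = 1460, n_controls = 97,
                         n_replicate_spots = 4, n_calibrators = 18) {
  stopifnot(n_mirna >= 1, n_controls >= 0, n_replicate_spots >= 1,
            n_calibrators >= 0, n_calibrators <= n_controls)
  mirna_ids <- sprintf("miR-%04d", seq_len(n_mirna))
  ctrl_ids <- if (n_controls > 0) sprintf("ctrl-%03d", seq_len(n_controls)) else character()
  structure(
    list(probe_ids = c(mirna_ids, ctrl_ids),
         mirna_ids = mirna_ids,
         control_ids = ctrl_ids,
         n_replicate_spots = as.integer(n_replicate_spots),
         calibrator_ids = ctrl_ids[seq_len(n_calibrators)]),
    class = "array_design")
}

#' @export
print.array_design <- function(x, ...) {
  cat(sprintf("array_design: %d probes (%d miRNA + %d control, %d calibrators), %d spots each (%d spots total)\n",
              length(x$probe_ids), length(x$mirna_ids), length(x$control_ids),
              length(x$calibrator_ids), x$n_replicate_spots,
              length(x$probe_ids) * x$n_replicate_spots))
  invisible(x)
}

#' Planted ground truth for synthetic scans
#'
#' Defines the true mitochondrial/cytosolic abundance ratio of every probe
#' together with the nuisance parameters of the intensity model. By default
#' `n_mito` probes are planted as mitochondria-enriched with folds drawn
#' log-uniformly on `mito_fold_range` (the 1.5- to 56-fold range observed for
#' mitochondrially enriched miRNAs) and `n_cyto` probes as cytosol-enriched
#' with the reciprocal folds; all other probes (and always all calibrators)
#' have fold 1.
#'
#' @param design an [array_design()].
#' @param n_mito,n_cyto number of planted mitochondria-/cytosol-enriched
#'   probes (defaults 13 and 44).
#' @param mito_fold_range range of planted enrichment folds (default
#'   `c(1.5, 56)`).
#' @param dye_bias length-2 numeric, multiplicative labeling bias of the
#'   `c(hy5, hy3)` channels (default `c(1.3, 1)`).
#' @param background_mean,background_sd additive per-spot background level
#'   and spread (arbitrary units).
#' @param abundance_meanlog,abundance_sdlog log-normal parameters of the
#'   per-probe base abundance.
#' @param noise_cv multiplicative measurement noise, as coefficient of
#'   variation per spot per channel (default 0.1).
#' @param seed RNG seed for the fold/abundance draws.
#' @return an object of class `planted_truth`; `$fold` is a named vector of
#'   true Hy5/Hy3 folds per probe.
#' @export
planted_truth <- function(design,
                          n_mito = 13, n_cyto = 44,
                          mito_fold_range = c(1.5, 56),
                          dye_bias = c(hy5 = 1.3, hy3 = 1),
                          background_mean = 50, background_sd = 10,
                          abundance_meanlog = log(500), abundance_sdlog = 0.5,
                          noise_cv = 0.1,
                          seed = NULL) {
  stopifnot(inherits(design, "array_design"))
  if (noise_cv < 0) stop("noise scale must be >= 0", call. = FALSE)
  if (any(mito_fold_range <= 0)) stop("planted folds must be > 0", call. = FALSE)
  if (n_mito + n_cyto > length(design$mirna_ids))
    stop("more planted probes than miRNA probes in the design", call. = FALSE)

  with_seed_if(seed, {
    fold <- stats::setNames(rep(1, length(design$probe_ids)), design$probe_ids)
    planted_ids <- sample(design$mirna_ids, n_mito + n_cyto)
    mito_ids <- planted_ids[seq_len(n_mito)]
    cyto_ids <- setdiff(planted_ids, mito_ids)
    lo <- log(mito_fold_range[1]); hi <- log(mito_fold_range[2])
    if (n_mito > 0) fold[mito_ids] <- exp(stats::runif(n_mito, lo, hi))
    if (n_cyto > 0) fold[cyto_ids] <- 1 / exp(stats::runif(n_cyto, lo, hi))
    abundance <- stats::setNames(
      stats::rlnorm(length(design$probe_ids), abundance_meanlog, abundance_sdlog),
      design$probe_ids)
    # calibrators are spiked equally into both samples
    fold[design$calibrator_ids] <- 1
    structure(
      list(fold = fold, abundance = abundance,
           mito_ids = sort(mito_ids), cyto_ids = sort(cyto_ids),
           dye_bias = dye_bias,
           background_mean = background_mean, background_sd = background_sd,
           noise_cv = noise_cv),
      class = "planted_truth")
  })
}

#' Generate spot-level scans for one or more hybridizations
#'
#' Each scan has `design$n_replicate_spots` rows per probe with columns
#' `probe_id, spot_index, hy5_signal, hy5_background, hy3_signal,
#' hy3_background, is_calibrator`. The foreground is
#' `background + abundance x fold x dye_bias x exp(noise)` so that with zero
#' noise the calibrator-normalized mean ratio equals the planted fold exactly.
#'
#' @param design an [array_design()].
#' @param truth a [planted_truth()].
#' @param n_arrays number of independent scans (default 3).
#' @param seed RNG seed; each array uses an offset sub-stream so scans are
#'   independent but jointly reproducible.
#' @return a list of `array_scan` objects (data frames with attributes
#'   `array_id` and `design`).
#' @export
gen_array_scans <- function(design, truth, n_arrays = 3, seed = NULL) {
  stopifnot(inherits(design, "array_design"), inherits(truth, "planted_truth"))
  if (n_arrays < 1) stop("n_arrays must be >= 1", call. = FALSE)
  if (any(truth$fold <= 0)) stop("planted folds must be > 0", call. = FALSE)
  if (truth$noise_cv < 0) stop("noise scale must be >= 0", call. = FALSE)

  with_seed_if(seed, {
    lapply(seq_len(n_arrays), function(a) {
      n_spot <- design$n_replicate_spots
      ids <- rep(design$probe_ids, each = n_spot)
      n <- length(ids)
      sdlog <- sqrt(log(1 + truth$noise_cv^2))
      noise5 <- if (sdlog > 0) stats::rlnorm(n, -sdlog^2 / 2, sdlog) else rep(1, n)
      noise3 <- if (sdlog > 0) stats::rlnorm(n, -sdlog^2 / 2, sdlog) else rep(1, n)
      bg5 <- pmax(0, stats::rnorm(n, truth$background_mean, truth$background_sd))
      bg3 <- pmax(0, stats::rnorm(n, truth$background_mean, truth$background_sd))
      ab <- truth$abundance[ids]
      fold <- truth$fold[ids]
      scan <- data.frame(
        probe_id = ids,
        spot_index = rep(seq_len(n_spot), times = length(design$probe_ids)),
        hy5_signal = bg5 + ab * fold * truth$dye_bias[[1]] * noise5,
        hy5_background = bg5,
        hy3_signal = bg3 + ab * truth$dye_bias[[2]] * noise3,
        hy3_background = bg3,
        is_calibrator = ids %in% design$calibrator_ids,
        stringsAsFactors = FALSE)
      attr(scan, "array_id") <- sprintf("array_%d", a)
      attr(scan, "design") <- design
      class(scan) <- c("array_scan", "data.frame")
      scan
    })
  })
}

#' Write / read a spot table as tab-separated text
#'
#' @param scan an `array_scan` data frame.
#' @param path file path.
#' @return `read_spot_table` returns an `array_scan` data frame.
#' @export
write_spot_table <- function(scan, path) {
  utils::write.table(as.data.frame(scan), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spot_table
#' @param array_id identifier attached to the scan (defaults to the file name).
#' @param columns optional named character vector mapping the canonical column
#'   names (`probe_id`, `spot_index`, `hy5_signal`, `hy5_background`,
#'   `hy3_signal`, `hy3_background`, `is_calibrator`) to the names used in the
#'   file, for tables produced by other software.
#' @export
read_spot_table <- function(path, array_id = basename(path), columns = NULL) {
  x <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  if (!is.null(columns)) {
    for (canon in names(columns)) {
      names(x)[names(x) == columns[[canon]]] <- canon
    }
  }
  need <- c("probe_id", "spot_index", "hy5_signal", "hy5_background",
            "hy3_signal", "hy3_background", "is_calibrator")
  missing <- setdiff(need, names(x))
  if (length(missing) > 0)
    stop("spot table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  x$is_calibrator <- as.logical(x$is_calibrator)
  attr(x, "array_id") <- array_id
  class(x) <- c("array_scan", "data.frame")
  x
}
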