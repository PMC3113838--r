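# Two-channel normalization and mitochondrial-enrichment classification.
#
# Processing chain per scan:
#   net intensity   = spot signal - local background (per channel)
#   filter          = keep spots with net >= 50th-percentile background
#                     threshold in BOTH channels
#   spot ratio      = Hy5 net / Hy3 net
#   normalization   = divide by the median spot ratio of the spike-in
#                     calibrators (dye-bias correction)
#   probe ratio     = mean of the kept replicate-spot ratios
# Across scans, a probe is called mitochondria-enriched when its normalized
# ratio is >= the fold cutoff in every passing array, cytosol-enriched when
# the reciprocal is, and unchanged otherwise.

#' Net signal intensity of a spot
#'
#' @param spot a one-row data frame (or list) with `*_signal` and
#'   `*_background` columns.
#' @param channel `"hy5"` or `"hy3"`.
#' @return signal minus background; may be negative (negative nets always
#'   fail the background filter downstream).
#' @export
net_intensity <- function(spot, channel = c("hy5", "hy3")) {
  channel <- match.arg(tolower(channel), c("hy5", "hy3"))
  spot[[paste0(channel, "_signal")]] - spot[[paste0(channel, "_background")]]
}

#' Background filter threshold for one channel of a scan
#'
#' The 50th percentile (median, mean-of-middle-two for even counts) of the
#' channel's background intensities over all spots. With
#' `adjust = "calibrator"` the threshold is additionally scaled by the ratio
#' of the channel's median calibrator net intensity to the geometric mean of
#' the two channels' median calibrator nets, so that a channel with brighter
#' calibrators is filtered proportionally harder.
#'
#' @param scan an `array_scan` data frame.
#' @param channel `"hy5"` or `"hy3"`.
#' @param adjust `"none"` (default) or `"calibrator"`.
#' @return scalar intensity threshold.
#' @export
background_threshold <- function(scan, channel = c("hy5", "hy3"),
                                 adjust = c("none", "calibrator")) {
  channel <- match.arg(tolower(channel), c("hy5", "hy3"))
  adjust <- match.arg(adjust)
  if (nrow(scan) == 0) stop("empty scan", call. = FALSE)
  thr <- stats::median(scan[[paste0(channel, "_background")]])
  if (adjust == "calibrator") {
    cal <- scan[scan$is_calibrator, , drop = FALSE]
    if (nrow(cal) == 0) stop("no calibrator spots for threshold adjustment", call. = FALSE)
    m5 <- stats::median(net_intensity(cal, "hy5"))
    m3 <- stats::median(net_intensity(cal, "hy3"))
    if (m5 <= 0 || m3 <= 0)
      stop("non-positive calibrator net intensities; cannot adjust threshold", call. = FALSE)
    m <- if (channel == "hy5") m5 else m3
    thr <- thr * m / sqrt(m5 * m3)
  }
  thr
}

#' Apply the background filter to a scan
#'
#' Keeps spots whose net intensity is at or above the channel threshold in
#' both channels.
#'
#' @inheritParams background_threshold
#' @return the scan with a logical `kept` column added.
#' @export
filter_spots <- function(scan, adjust = c("none", "calibrator")) {
  adjust <- match.arg(adjust)
  t5 <- background_threshold(scan, "hy5", adjust)
  t3 <- background_threshold(scan, "hy3", adjust)
  net5 <- net_intensity(scan, "hy5")
  net3 <- net_intensity(scan, "hy3")
  scan$kept <- net5 >= t5 & net3 >= t3
  if ("excluded" %in% names(scan)) scan$kept <- scan$kept & !scan$excluded
  scan
}

#' Hy5/Hy3 ratio of net intensities
#'
#' @param spot spot record(s) with the four intensity columns.
#' @return numeric ratio(s); `NA` where the Hy3 net is not positive (such
#'   spots are excluded from probe means with a warning).
#' @export
spot_ratio <- function(spot) {
  net3 <- net_intensity(spot, "hy3")
  r <- net_intensity(spot, "hy5") / net3
  r[net3 <= 0] <- NA_real_
  r
}

#' Normalize spot ratios by the spike-in calibrators
#'
#' Divides every ratio by the median of the calibrator spot ratios. The
#' median is computed on the log scale (geometric mean of the middle two for
#' even counts) so that swapping the channels maps the normalizer to its
#' exact reciprocal.
#'
#' @param ratios numeric vector of spot ratios.
#' @param calibrator_ratios ratios of calibrator spots that passed the filter.
#' @return normalized ratios; after normalization the calibrator median is 1.
#' @export
calibrator_normalize <- function(ratios, calibrator_ratios) {
  calibrator_ratios <- calibrator_ratios[is.finite(calibrator_ratios) &
                                           calibrator_ratios > 0]
  if (length(calibrator_ratios) == 0)
    stop("no calibrator spots passed the filter; rerun with raw ratios",
         call. = FALSE)
  ratios / exp(stats::median(log(calibrator_ratios)))
}

#' Mean normalized ratio of one probe's kept spots
#'
#' @param ratios kept, normalized spot ratios for one probe.
#' @param mean_type `"arithmetic"` (the conventional mean of replicate-spot
#'   ratios) or `"geometric"` (exactly antisymmetric under channel swap).
#' @return scalar mean, or `NA` when no spot was kept (probe filtered for
#'   that array).
#' @export
probe_mean_ratio <- function(ratios, mean_type = c("arithmetic", "geometric")) {
  mean_type <- match.arg(mean_type)
  ratios <- ratios[is.finite(ratios)]
  if (length(ratios) == 0) return(NA_real_)
  if (mean_type == "arithmetic") mean(ratios) else exp(mean(log(ratios)))
}

#' Normalize one scan to per-probe mean ratios
#'
#' Runs the whole per-array chain: net intensities, background filter,
#' spot ratios, calibrator normalization, probe means.
#'
#' @param scan an `array_scan`.
#' @param threshold_adjust passed to [background_threshold()].
#' @param mean_type passed to [probe_mean_ratio()].
#' @return data frame with `probe_id`, `n_spots`, `n_kept`, `mean_ratio`
#'   (NA when the probe is filtered), `is_calibrator`.
#' @export
normalize_scan <- function(scan, threshold_adjust = c("none", "calibrator"),
                           mean_type = c("arithmetic", "geometric")) {
  threshold_adjust <- match.arg(threshold_adjust)
  mean_type <- match.arg(mean_type)
  scan <- filter_spots(scan, adjust = threshold_adjust)
  r <- spot_ratio(scan)
  bad <- scan$kept & is.na(r)
  if (any(bad))
    warning(sum(bad), " kept spot(s) had non-positive Hy3 net intensity and were excluded")
  keep <- scan$kept & !is.na(r)
  rnorm_ <- rep(NA_real_, nrow(scan))
  rnorm_[keep] <- calibrator_normalize(r[keep], r[keep & scan$is_calibrator])
  probes <- unique(scan$probe_id)
  f <- factor(scan$probe_id, levels = probes)
  kept_by <- tapply(keep, f, sum)
  mean_by <- tapply(rnorm_, f, probe_mean_ratio, mean_type = mean_type)
  out <- data.frame(
    probe_id = probes,
    n_spots = as.integer(table(f)),
    n_kept = as.integer(kept_by),
    mean_ratio = as.numeric(mean_by),
    is_calibrator = probes %in% scan$probe_id[scan$is_calibrator],
    stringsAsFactors = FALSE)
  attr(out, "array_id") <- attr(scan, "array_id")
  out
}

#' Classify probes as mitochondria- or cytosol-enriched across arrays
#'
#' @param ratio_matrix numeric probe x array matrix of per-array normalized
#'   mean ratios (`NA` = probe filtered in that array), as built by
#'   [enrich_scans()].
#' @param cutoff fold-of-enrichment cutoff (> 1; default 1.5).
#' @param min_arrays minimum number of arrays in which a probe must pass the
#'   filters to be classifiable; default `NULL` means all provided arrays
#'   (the reproducibility rule).
#' @param mode `"per_array"` (default; the cutoff must hold in every passing
#'   array) or `"mean"` (the cutoff is applied to the cross-array mean only).
#' @param mean_type cross-array averaging convention, `"arithmetic"`
#'   (default) or `"geometric"`.
#' @return data frame with one row per probe: `probe_id`, `n_arrays_pass`,
#'   `mean_ratio` (cross-array mean of the per-array ratios), `log2_ratio`,
#'   `class` in mito/cyto/unchanged/filtered, and `fold` =
#'   `max(mean_ratio, 1/mean_ratio)`.
#' @export
classify_enrichment <- function(ratio_matrix, cutoff = 1.5, min_arrays = NULL,
                                mode = c("per_array", "mean"),
                                mean_type = c("arithmetic", "geometric")) {
  mode <- match.arg(mode)
  mean_type <- match.arg(mean_type)
  if (cutoff <= 1) stop("cutoff fold of enrichment must be > 1", call. = FALSE)
  ratio_matrix <- as.matrix(ratio_matrix)
  n_arrays <- ncol(ratio_matrix)
  if (is.null(min_arrays)) min_arrays <- n_arrays
  n_pass <- rowSums(!is.na(ratio_matrix))
  mean_ratio <- if (mean_type == "arithmetic") {
    rowMeans(ratio_matrix, na.rm = TRUE)
  } else {
    exp(rowMeans(log(ratio_matrix), na.rm = TRUE))
  }
  mean_ratio[n_pass == 0] <- NA_real_

  if (mode == "per_array") {
    all_hi <- apply(ratio_matrix, 1, function(r) all(r[!is.na(r)] >= cutoff))
    all_lo <- apply(ratio_matrix, 1, function(r) all(1 / r[!is.na(r)] >= cutoff))
  } else {
    all_hi <- !is.na(mean_ratio) & mean_ratio >= cutoff
    all_lo <- !is.na(mean_ratio) & 1 / mean_ratio >= cutoff
  }
  cls <- rep("unchanged", nrow(ratio_matrix))
  cls[all_hi & n_pass >= min_arrays & n_pass > 0] <- "mito"
  cls[all_lo & n_pass >= min_arrays & n_pass > 0] <- "cyto"
  cls[n_pass < min_arrays] <- "filtered"

  data.frame(
    probe_id = rownames(ratio_matrix) %||% as.character(seq_len(nrow(ratio_matrix))),
    n_arrays_pass = as.integer(n_pass),
    mean_ratio = mean_ratio,
    log2_ratio = log2(mean_ratio),
    class = cls,
    fold = pmax(mean_ratio, 1 / mean_ratio),
    stringsAsFactors = FALSE)
}

#' Full enrichment analysis over replicate scans
#'
#' @param scans list of `array_scan` data frames (see [gen_array_scans()] or
#'   [read_spot_table()]).
#' @inheritParams classify_enrichment
#' @inheritParams normalize_scan
#' @param drop_calibrators drop calibrator probes from the result
#'   (default TRUE; they are fold-1 by construction).
#' @return an `enrichment_result` data frame (see [classify_enrichment()])
#'   with the per-array ratio matrix in `attr(, "ratio_matrix")`.
#' @export
enrich_scans <- function(scans, cutoff = 1.5, min_arrays = NULL,
                         mode = c("per_array", "mean"),
                         threshold_adjust = c("none", "calibrator"),
                         mean_type = c("arithmetic", "geometric"),
                         drop_calibrators = TRUE) {
  stopifnot(length(scans) >= 1)
  per_array <- lapply(scans, normalize_scan,
                      threshold_adjust = match.arg(threshold_adjust),
                      mean_type = match.arg(mean_type))
  probes <- per_array[[1]]$probe_id
  mat <- vapply(per_array, function(x) x$mean_ratio[match(probes, x$probe_id)],
                numeric(length(probes)))
  mat <- matrix(mat, nrow = length(probes),
                dimnames = list(probes, vapply(seq_along(per_array), function(i) {
                  attr(per_array[[i]], "array_id") %||% sprintf("array_%d", i)
                }, character(1))))
  if (drop_calibrators) {
    cal <- per_array[[1]]$is_calibrator
    mat <- mat[!cal, , drop = FALSE]
  }
  res <- classify_enrichment(mat, cutoff = cutoff, min_arrays = min_arrays,
                             mode = match.arg(mode),
                             mean_type = match.arg(mean_type))
  attr(res, "ratio_matrix") <- mat
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Log2-ratio matrix of the differentially enriched probes
#'
#' Restricts the per-array log2 normalized ratios to probes classified
#' mito or cyto, ordered by class (mito first) then decreasing fold —
#' the layout of a green-to-red two-color heatmap.
#'
#' @param result an `enrichment_result` from [enrich_scans()].
#' @param file optional CSV path to write the matrix (with class and fold
#'   columns appended).
#' @param plot_file optional PNG path; drawn with pheatmap (green-to-red
#'   gradient) when that package is available.
#' @return numeric matrix of log2 ratios with attributes `class` and `fold`.
#' @export
heatmap_table <- function(result, file = NULL, plot_file = NULL) {
  mat <- attr(result, "ratio_matrix")
  if (is.null(mat)) stop("result carries no per-array ratio matrix", call. = FALSE)
  sel <- result$class %in% c("mito", "cyto")
  if (!any(sel)) stop("no differentially enriched probe to tabulate", call. = FALSE)
  sub <- result[sel, , drop = FALSE]
  ord <- order(match(sub$class, c("mito", "cyto")), -sub$fold)
  sub <- sub[ord, , drop = FALSE]
  lmat <- log2(mat[sub$probe_id, , drop = FALSE])
  attr(lmat, "class_label") <- sub$class
  attr(lmat, "fold") <- sub$fold
  if (!is.null(file)) {
    out <- data.frame(probe_id = rownames(lmat), lmat,
                      class = sub$class, fold = sub$fold, check.names = FALSE)
    utils::write.csv(out, file, row.names = FALSE)
  }
  if (!is.null(plot_file) && requireNamespace("pheatmap", quietly = TRUE)) {
    grDevices::png(plot_file, width = 600, height = 200 + 12 * nrow(lmat))
    pheatmap::pheatmap(lmat, cluster_rows = FALSE, cluster_cols = FALSE,
                       color = grDevices::colorRampPalette(c("green", "black", "red"))(50))
    grDevices::dev.off()
  }
  lmat
}
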