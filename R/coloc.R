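# Pixel-wise dual-channel co-localization statistics: Pearson coefficient
# and the Van Steensel cross-correlation function (CCF), with a bell /
# hollow / flat classification of the CCF curve.

check_channel_pair <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b)))
    stop("channel images must have identical dimensions", call. = FALSE)
  if (length(a) < 2) stop("need at least 2 pixels", call. = FALSE)
  list(a = a, b = b)
}

#' Pearson correlation of two channel images
#'
#' The correlation of paired pixel intensities between the green and red
#' channels; lies in \[-1, +1\], with 1 indicating complete co-localization.
#' Invariant under positive affine transforms of either channel's
#' intensities.
#'
#' @param a,b numeric matrices of identical dimensions (one per channel).
#' @return scalar Pearson coefficient.
#' @export
pearson_coloc <- function(a, b) {
  p <- check_channel_pair(a, b)
  if (stats::sd(p$a) == 0 || stats::sd(p$b) == 0)
    stop("undefined correlation: zero variance in a channel", call. = FALSE)
  stats::cor(as.vector(p$a), as.vector(p$b))
}

#' Van Steensel cross-correlation function
#'
#' Computes the Pearson coefficient while translating image `b` horizontally
#' by dx pixels relative to `a`, for dx in `-max_dx .. +max_dx`, using only
#' the overlapping region (no wrap, no zero padding). `ccf[dx = 0]` equals
#' the plain Pearson coefficient. A curve peaked around dx = 0 (bell)
#' indicates co-localization; a dip at dx = 0 (hollow) indicates mutual
#' exclusion.
#'
#' @inheritParams pearson_coloc
#' @param max_dx maximum shift in pixels (must leave an overlap of at least
#'   2 columns).
#' @param window,edge_frac,margin passed to [classify_ccf()].
#' @return object of class `coloc_result`: list with `rp` (unshifted
#'   coefficient), `dx`, `ccf`, `dx_peak`, `ccf_max`, `shape`.
#' @export
cross_correlation_function <- function(a, b, max_dx = 20,
                                       window = NULL, edge_frac = 0.1,
                                       margin = 0.1) {
  p <- check_channel_pair(a, b)
  w <- ncol(p$a)
  if (max_dx >= w - 1)
    stop("max_dx leaves an overlap of fewer than 2 columns", call. = FALSE)
  dx <- seq.int(-max_dx, max_dx)
  ccf <- vapply(dx, function(d) {
    # CCF(d) correlates a[, i] with b[, i + d] over the valid overlap
    ia <- if (d >= 0) seq_len(w - d) else seq.int(1 - d, w)
    ib <- ia + d
    va <- as.vector(p$a[, ia]); vb <- as.vector(p$b[, ib])
    if (stats::sd(va) == 0 || stats::sd(vb) == 0) return(NA_real_)
    stats::cor(va, vb)
  }, numeric(1))
  names(ccf) <- dx
  dx_peak <- dx[which.max(ccf)]
  res <- structure(
    list(rp = ccf[[as.character(0)]], dx = dx, ccf = ccf,
         dx_peak = dx_peak, ccf_max = max(ccf, na.rm = TRUE),
         max_dx = max_dx),
    class = "coloc_result")
  res$shape <- classify_ccf(res, window = window, edge_frac = edge_frac,
                            margin = margin)
  res
}

#' Classify a CCF curve as bell, hollow, or flat
#'
#' Bell: the curve's maximum lies within `window` pixels of dx = 0 and
#' exceeds the edge mean (mean CCF over the outermost `edge_frac` of shifts
#' on each side) by at least `margin`. Hollow: the minimum lies within the
#' window and falls below the edge mean by the margin. Otherwise flat.
#'
#' @param result a `coloc_result` from [cross_correlation_function()].
#' @param window half-width (pixels) of the central tolerance window;
#'   default `max(1, round(0.1 * max_dx))`.
#' @param edge_frac fraction of shifts per side treated as the curve's edge
#'   (default 0.1).
#' @param margin required excursion from the edge mean, in correlation units
#'   (default 0.1).
#' @return `"bell"`, `"hollow"`, or `"flat"`.
#' @export
classify_ccf <- function(result, window = NULL, edge_frac = 0.1, margin = 0.1) {
  dx <- result$dx; ccf <- result$ccf
  window <- window %||% max(1, round(0.1 * result$max_dx))
  n_edge <- max(1, ceiling(edge_frac * length(dx) / 2))
  edge_mean <- mean(c(utils::head(ccf, n_edge), utils::tail(ccf, n_edge)),
                    na.rm = TRUE)
  i_max <- which.max(ccf); i_min <- which.min(ccf)
  if (abs(dx[i_max]) <= window && ccf[i_max] >= edge_mean + margin) return("bell")
  if (abs(dx[i_min]) <= window && ccf[i_min] <= edge_mean - margin) return("hollow")
  "flat"
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("coloc_result: rp = %.3f, max CCF = %.3f at dx = %d px, shape = %s\n",
              x$rp, x$ccf_max, x$dx_peak, x$shape))
  invisible(x)
}

#' Generate a synthetic dual-channel image pair with known co-localization
#'
#' Spot objects are Gaussian blobs on a dark background, mimicking punctate
#' staining. A fraction `coloc_fraction` of the spots is placed at identical
#' coordinates in both channels; the remainder is placed independently (or,
#' with `exclusive = TRUE`, away from the first channel's spots). The second
#' channel can be translated horizontally by `shift` pixels (with
#' wrap-around), planting a known CCF peak position.
#'
#' @param shape `c(rows, cols)` image dimensions (default `c(128, 128)`).
#' @param n_spots number of blobs per channel.
#' @param coloc_fraction fraction in \[0, 1\] of co-localized spots.
#' @param shift horizontal translation of channel 2 (pixels; |shift| must be
#'   smaller than the image width).
#' @param spot_sigma Gaussian blob radius (pixels).
#' @param noise additive Gaussian noise sd (intensity units).
#' @param exclusive place non-shared channel-2 spots at least `4*spot_sigma`
#'   away from every channel-1 spot (mutually exclusive staining).
#' @param seed RNG seed.
#' @return list with matrices `green` and `red` (intensities in \[0, 1\]).
#' @export
gen_coloc_images <- function(shape = c(128, 128), n_spots = 40,
                             coloc_fraction = 1, shift = 0, spot_sigma = 2,
                             noise = 0, exclusive = FALSE, seed = NULL) {
  if (coloc_fraction < 0 || coloc_fraction > 1)
    stop("coloc_fraction must be in [0, 1]", call. = FALSE)
  if (abs(shift) >= shape[2])
    stop("shift larger than image width", call. = FALSE)
  with_seed_if(seed, {
    h <- shape[1]; w <- shape[2]
    ya <- stats::runif(n_spots, 1, h); xa <- stats::runif(n_spots, 1, w)
    n_shared <- round(coloc_fraction * n_spots)
    yb <- ya; xb <- xa
    if (n_shared < n_spots) {
      idx <- seq.int(n_shared + 1, n_spots)
      for (i in idx) {
        repeat {
          yy <- stats::runif(1, 1, h); xx <- stats::runif(1, 1, w)
          if (!exclusive ||
              min(sqrt((ya - yy)^2 + (xa - xx)^2)) > 4 * spot_sigma) break
        }
        yb[i] <- yy; xb[i] <- xx
      }
    }
    xb <- ((xb + shift - 1) %% w) + 1
    render <- function(ys, xs) {
      img <- matrix(0, h, w)
      half <- ceiling(4 * spot_sigma)
      for (i in seq_along(ys)) {
        r0 <- max(1, floor(ys[i]) - half); r1 <- min(h, floor(ys[i]) + half)
        c0 <- max(1, floor(xs[i]) - half); c1 <- min(w, floor(xs[i]) + half)
        rr <- r0:r1; cc <- c0:c1
        blob <- exp(-(outer((rr - ys[i])^2, (cc - xs[i])^2, "+")) /
                      (2 * spot_sigma^2))
        img[rr, cc] <- img[rr, cc] + blob
      }
      img
    }
    g <- render(ya, xa); r <- render(yb, xb)
    if (noise > 0) {
      g <- g + stats::rnorm(length(g), 0, noise)
      r <- r + stats::rnorm(length(r), 0, noise)
    }
    clip <- function(x) { x[x < 0] <- 0; x[x > 1] <- 1; x }
    list(green = clip(g), red = clip(r))
  })
}

#' Write / read a single-channel grayscale image
#'
#' Intensities are scaled to \[0, 1\]. TIFF files (`.tif`/`.tiff`) are
#' written as 16-bit grayscale; PNG files as 8-bit.
#'
#' @param img numeric matrix with values in \[0, 1\].
#' @param path file path; the extension selects the format.
#' @export
write_channel_image <- function(img, path) {
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::writeTIFF(as.matrix(img), path, bits.per.sample = 16)
  } else {
    png::writePNG(as.matrix(img), path)
  }
  invisible(path)
}

#' @rdname write_channel_image
#' @return `read_channel_image` returns a numeric matrix in \[0, 1\]; color
#'   images are collapsed to their first (grayscale) plane.
#' @export
read_channel_image <- function(path) {
  img <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}
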