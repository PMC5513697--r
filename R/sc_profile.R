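#' Medio-lateral tracer density profile of an SC section
#'
#' The retinorecipient SC outline is divided into medio-lateral bins of
#' `bin_um` micrometres (default 4), measured from the medial (left) edge
#' of the mask. Each bin's density is the percentage of its mask pixels
#' whose intensity exceeds the background-derived threshold:
#' `100 * CTB-positive pixels / mask pixels`. Bins containing no mask
#' pixels are reported as `NA`.
#'
#' @param image Intensity matrix (medial on the left).
#' @param sc_mask Logical matrix outlining the retinorecipient SC.
#' @param um_per_pixel Physical scale.
#' @param bin_um Bin width, um (default 4).
#' @param threshold Binarisation threshold, e.g. from
#'   [background_threshold()].
#' @return Data frame: `bin`, `x_start_um` (bin left edge, from the
#'   medial mask edge), `density_pct`, `n_pixels`.
#' @export
sc_profile <- function(image, sc_mask, um_per_pixel, bin_um = 4, threshold) {
  if (!any(sc_mask)) stop("sc_mask is empty")
  if (bin_um <= 0 || um_per_pixel <= 0) stop("scales must be > 0")
  cols_with_mask <- which(colSums(sc_mask) > 0)
  medial <- min(cols_with_mask)
  idx <- which(sc_mask)
  px_col <- (idx - 1L) %/% nrow(sc_mask) + 1L
  # pixel centre position from the medial mask edge
  x_um <- (px_col - medial + 0.5) * um_per_pixel
  bin <- floor(x_um / bin_um)
  on <- image[idx] > threshold
  bins <- 0:max(bin)
  n_px <- vapply(bins, function(b) sum(bin == b), integer(1))
  n_on <- vapply(bins, function(b) sum(on[bin == b]), integer(1))
  data.frame(bin = bins + 1L, x_start_um = bins * bin_um,
             density_pct = ifelse(n_px > 0, 100 * n_on / n_px, NA_real_),
             n_pixels = n_px)
}

#' Dorsal-view reconstruction of SC innervation density
#'
#' Stacks per-section medio-lateral profiles into a matrix (rows =
#' sections in rostro-caudal order, columns = medio-lateral bins) and
#' optionally writes a colorimetric thermal map with densities mapped
#' from 0% (blue) to 100% (red).
#'
#' @param profiles List of [sc_profile()] data frames, one per section.
#' @param png_file Optional path; when given and the \pkg{png} package is
#'   available, the thermal map is written there.
#' @return Invisibly, a list with `density` (sections x bins matrix,
#'   percent, `NA` padded) and, when written, `png_file`.
#' @export
sc_reconstruction <- function(profiles, png_file = NULL) {
  nb <- max(vapply(profiles, nrow, integer(1)))
  dens <- t(vapply(profiles, function(p) {
    v <- rep(NA_real_, nb); v[p$bin] <- p$density_pct; v
  }, numeric(nb)))
  out <- list(density = dens)
  if (!is.null(png_file)) {
    if (!requireNamespace("png", quietly = TRUE))
      stop("the png package is required to write thermal maps")
    pal <- grDevices::colorRamp(c("blue", "cyan", "green", "yellow", "red"))
    v <- pmin(pmax(dens / 100, 0), 1)
    rgb <- pal(as.vector(v))
    arr <- array(0, c(nrow(dens), ncol(dens), 3))
    for (ch in 1:3) arr[, , ch] <- matrix(rgb[, ch] / 255, nrow(dens))
    arr[is.na(array(v, dim(arr)))] <- 0
    png::writePNG(arr, png_file)
    out$png_file <- png_file
  }
  invisible(out)
}
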