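#' Construct a two-channel dLGN section image pair
#'
#' @param contra,ipsi Numeric intensity matrices of equal shape
#'   (contralateral- and ipsilateral-eye tracer channels).
#' @param dlgn_mask Logical matrix: the dLGN region of interest.
#' @param background_mask Logical matrix: a region guaranteed to contain
#'   no retinal innervation, disjoint from `dlgn_mask`; its maximum
#'   intensity defines each channel's binarisation threshold.
#' @param um_per_pixel Physical scale.
#' @param contra_ref_mask,ipsi_ref_mask Optional logical matrices marking
#'   regions maximally innervated by the contralateral / ipsilateral eye,
#'   used as reference ROIs for the R-distribution method.
#' @return A `section_image_pair` object.
#' @export
section_image_pair <- function(contra, ipsi, dlgn_mask, background_mask,
                               um_per_pixel = 1,
                               contra_ref_mask = NULL, ipsi_ref_mask = NULL) {
  stopifnot(is.matrix(contra), identical(dim(contra), dim(ipsi)),
            identical(dim(contra), dim(dlgn_mask)),
            identical(dim(contra), dim(background_mask)))
  if (any(dlgn_mask & background_mask))
    stop("dlgn_mask and background_mask must be disjoint")
  if (!any(background_mask)) stop("background_mask must be nonempty")
  structure(list(contra = contra, ipsi = ipsi, dlgn_mask = dlgn_mask,
                 background_mask = background_mask,
                 um_per_pixel = um_per_pixel,
                 contra_ref_mask = contra_ref_mask,
                 ipsi_ref_mask = ipsi_ref_mask),
            class = "section_image_pair")
}

ellipse_mask <- function(height, width, cy, cx, ry, rx) {
  y <- matrix(seq_len(height), height, width)
  x <- matrix(seq_len(width), height, width, byrow = TRUE)
  ((y - cy) / ry)^2 + ((x - cx) / rx)^2 <= 1
}

#' Simulate a stack of two-channel dLGN sections with programmed overlap
#'
#' Each section carries an elliptical dLGN mask filled with contralateral
#' tracer signal, an ipsilateral patch occupying `ipsi_area_fraction` of
#' the mask, and contralateral signal retained inside exactly
#' `programmed_overlap` of the mask's pixels (the core of the ipsi patch)
#' and suppressed in the rest of the patch — so in the noise-free limit
#' the downstream percent overlap equals the programmed value exactly, up
#' to rounding a fraction to a whole pixel count. A border strip free of
#' any signal provides the background region from which thresholds are
#' derived. Reference ROIs (maximally contra- and ipsi-innervated) are
#' emitted for the R-distribution method. A programmed fraction of mask
#' pixels (`mixing`) has both channels replaced by their mean, emulating
#' unsegregated binocular input at those pixels.
#'
#' @param params An [image_sim_params()] object.
#' @return A list: `sections` (list of [section_image_pair()]) and `truth`
#'   (data frame of realised per-section fractions: `n_mask_px`,
#'   `ipsi_fraction`, `overlap_fraction`).
#' @export
simulate_dlgn_sections <- function(params) {
  stopifnot(inherits(params, "image_sim_params"))
  p <- params
  set.seed(p$seed)
  H <- p$height; W <- p$width; m <- p$background_margin
  baseline <- 100; signal <- 10000

  border <- matrix(FALSE, H, W)
  border[seq_len(m), ] <- TRUE; border[(H - m + 1):H, ] <- TRUE
  border[, seq_len(m)] <- TRUE; border[, (W - m + 1):W] <- TRUE

  sections <- vector("list", p$n_sections)
  truth <- vector("list", p$n_sections)
  for (s in seq_len(p$n_sections)) {
    cy <- H / 2; cx <- W / 2
    ry <- H / 2 - 2 * m; rx <- W / 2 - 2 * m
    mask <- ellipse_mask(H, W, cy, cx, ry, rx)
    n_mask <- sum(mask)
    idx <- which(mask)
    iy <- (idx - 1L) %% H + 1L
    ix <- (idx - 1L) %/% H + 1L

    # ipsi patch: the k_ipsi mask pixels nearest a jittered dorsomedial
    # centre; its core (k_ov pixels) keeps contra signal -> exact overlap
    k_ipsi <- round(p$ipsi_area_fraction * n_mask)
    k_ov <- round(p$programmed_overlap * n_mask)
    by0 <- cy - ry * 0.35 + runif(1, -1, 1)
    bx0 <- cx + rx * 0.25 + runif(1, -1, 1)
    d2 <- (iy - by0)^2 + (ix - bx0)^2
    ord <- order(d2)
    ipsi_idx <- idx[ord[seq_len(k_ipsi)]]
    ov_idx <- idx[ord[seq_len(k_ov)]]
    ipsi_only <- setdiff(ipsi_idx, ov_idx)

    contra <- matrix(baseline, H, W)
    ipsi <- matrix(baseline, H, W)
    contra[mask] <- signal
    contra[ipsi_only] <- baseline
    ipsi[ipsi_idx] <- signal

    # reference ROIs: deep ipsi-only pixels and mask pixels far from the patch
    n_ref <- min(300L, max(20L, length(ipsi_only) %/% 4L))
    ipsi_ref <- matrix(FALSE, H, W)
    if (length(ipsi_only))
      ipsi_ref[ipsi_only[seq_len(min(n_ref, length(ipsi_only)))]] <- TRUE
    contra_ref <- matrix(FALSE, H, W)
    contra_ref[idx[rev(ord)[seq_len(n_ref)]]] <- TRUE

    # mixed pixels: nested across mixing levels for a fixed seed, so a
    # programmed series 0, 0.25, ... is monotone by construction
    perm <- sample(idx)
    k_mix <- round(p$mixing * n_mask)
    if (k_mix > 0L) {
      mixed <- perm[seq_len(k_mix)]
      mid <- (contra[mixed] + ipsi[mixed]) / 2
      contra[mixed] <- mid
      ipsi[mixed] <- mid
    }
    if (p$noise_sd > 0) {
      contra <- pmax(contra + rnorm(H * W, 0, p$noise_sd), 0)
      ipsi <- pmax(ipsi + rnorm(H * W, 0, p$noise_sd), 0)
    }

    sections[[s]] <- section_image_pair(contra, ipsi, mask, border,
                                        p$um_per_pixel, contra_ref, ipsi_ref)
    truth[[s]] <- data.frame(section = s, n_mask_px = n_mask,
                             ipsi_fraction = k_ipsi / n_mask,
                             overlap_fraction = k_ov / n_mask)
  }
  list(sections = sections, truth = do.call(rbind, truth))
}

#' Parameters for the synthetic SC section simulator
#'
#' @param height,width Image size in pixels.
#' @param um_per_pixel Physical scale (default 4, one pixel per density
#'   bin).
#' @param n_sections Number of coronal sections.
#' @param profile Function mapping normalised medio-lateral position
#'   `u` in `[0, 1]` (0 = medial edge) to programmed tracer density in
#'   percent; default a linear 0-100 ramp.
#' @param noise_sd Additive Gaussian noise SD.
#' @param margin Pixels of signal-free border used as the background
#'   region.
#' @param seed Integer seed.
#' @return An `sc_sim_params` list.
#' @export
sc_sim_params <- function(height = 80L, width = 220L, um_per_pixel = 4,
                          n_sections = 1L,
                          profile = function(u) 100 * u,
                          noise_sd = 0, margin = 10L, seed = 1L) {
  p <- list(height = as.integer(height), width = as.integer(width),
            um_per_pixel = um_per_pixel, n_sections = as.integer(n_sections),
            profile = profile, noise_sd = noise_sd,
            margin = as.integer(margin), seed = as.integer(seed))
  if (p$noise_sd < 0) stop("noise_sd must be >= 0")
  if (p$n_sections < 1L) stop("n_sections must be >= 1")
  if (p$height <= 2L * p$margin || p$width <= 2L * p$margin)
    stop("image too small for margin")
  class(p) <- "sc_sim_params"
  p
}

#' Simulate single-channel SC sections with a programmed density profile
#'
#' The retinorecipient SC is a rectangular band; within each image column
#' (one medio-lateral position) the programmed fraction of mask pixels is
#' set to full tracer intensity (topmost pixels, deterministically), the
#' rest stay at baseline, so the realised column density equals the
#' programmed profile up to rounding to whole pixels.
#'
#' @param params An [sc_sim_params()] object.
#' @return A list: `sections` (each a list with `image`, `sc_mask`,
#'   `background_mask`, `um_per_pixel`) and `truth` (per section, the
#'   realised density per mask column, percent).
#' @export
simulate_sc_sections <- function(params) {
  stopifnot(inherits(params, "sc_sim_params"))
  p <- params
  set.seed(p$seed)
  H <- p$height; W <- p$width; m <- p$margin
  baseline <- 50; signal <- 8000
  rows <- (m + 1L):(H - m); cols <- (m + 1L):(W - m)

  sections <- vector("list", p$n_sections)
  truth <- vector("list", p$n_sections)
  for (s in seq_len(p$n_sections)) {
    img <- matrix(baseline, H, W)
    mask <- matrix(FALSE, H, W)
    mask[rows, cols] <- TRUE
    bg <- matrix(FALSE, H, W)
    bg[seq_len(m), ] <- TRUE
    dens <- numeric(length(cols))
    for (k in seq_along(cols)) {
      u <- (k - 0.5) / length(cols)
      target <- min(max(p$profile(u), 0), 100)
      n_on <- round(target / 100 * length(rows))
      if (n_on > 0L) img[rows[seq_len(n_on)], cols[k]] <- signal
      dens[k] <- 100 * n_on / length(rows)
    }
    if (p$noise_sd > 0) img <- pmax(img + rnorm(H * W, 0, p$noise_sd), 0)
    sections[[s]] <- list(image = img, sc_mask = mask, background_mask = bg,
                          um_per_pixel = p$um_per_pixel)
    truth[[s]] <- data.frame(section = s, col = cols,
                             position_um = (seq_along(cols) - 0.5) * p$um_per_pixel,
                             density_pct = dens)
  }
  list(sections = sections, truth = do.call(rbind, truth))
}
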