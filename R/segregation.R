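#' Background-derived binarisation threshold
#'
#' The threshold for a channel is the maximum intensity over a region of
#' the section containing no retinal innervation; binarisation is then
#' strictly above threshold, so every background pixel is off.
#'
#' @param img Intensity matrix.
#' @param background_mask Logical matrix, nonempty.
#' @return The maximum background intensity.
#' @export
background_threshold <- function(img, background_mask) {
  if (!any(background_mask)) stop("background_mask is empty")
  max(img[background_mask])
}

#' Percent overlap, ipsi and contra coverage of a dLGN section
#'
#' Each channel is binarised at its own background-derived threshold
#' (strictly greater). Within the dLGN ROI, overlap pixels are on in both
#' channels; percentages are taken over \emph{all} ROI pixels:
#' `percent_overlap = 100 * overlap / n_roi`, and likewise for the ipsi
#' and contra coverages.
#'
#' @param pair A [section_image_pair()].
#' @return A `segregation_result` list: `percent_overlap`,
#'   `percent_ipsi`, `percent_contra`, `thresholds` (named, per channel),
#'   `n_roi_px`.
#' @export
overlap_fractions <- function(pair) {
  stopifnot(inherits(pair, "section_image_pair"))
  if (!any(pair$dlgn_mask)) stop("dlgn_mask is empty")
  th_c <- background_threshold(pair$contra, pair$background_mask)
  th_i <- background_threshold(pair$ipsi, pair$background_mask)
  roi <- pair$dlgn_mask
  on_c <- pair$contra[roi] > th_c
  on_i <- pair$ipsi[roi] > th_i
  n <- sum(roi)
  structure(list(
    percent_overlap = 100 * sum(on_c & on_i) / n,
    percent_ipsi = 100 * sum(on_i) / n,
    percent_contra = 100 * sum(on_c) / n,
    thresholds = c(contra = th_c, ipsi = th_i),
    n_roi_px = n
  ), class = "segregation_result")
}

#' Per-pixel R-values of a section
#'
#' The R-value of a pixel is the base-10 log of its ipsilateral-to-
#' contralateral intensity ratio, offset by `epsilon` to keep the ratio
#' defined at zero intensity:
#' \deqn{R = \log_{10}\frac{I_{ipsi} + \epsilon}{I_{contra} + \epsilon}.}
#' Ipsi-dominant pixels have positive R, contra-dominant negative;
#' swapping the channels negates R.
#'
#' @param pair A [section_image_pair()].
#' @param mask Logical matrix selecting the pixels (default the dLGN ROI).
#' @param epsilon Intensity offset (default 1 intensity unit).
#' @return Numeric vector of R-values at the mask pixels.
#' @export
r_map <- function(pair, mask = pair$dlgn_mask, epsilon = 1) {
  stopifnot(inherits(pair, "section_image_pair"))
  ii <- pair$ipsi[mask] + epsilon
  ic <- pair$contra[mask] + epsilon
  if (any(ii <= 0) || any(ic <= 0))
    stop("nonpositive intensity after epsilon offset")
  log10(ii / ic)
}

#' Unsegregated-pixel fraction and R-distribution variance
#'
#' Reference R-distributions from maximally contralaterally and maximally
#' ipsilaterally innervated ROIs, pooled across the section stack, define
#' two cutoffs: the value below which fraction `q` of the contra
#' reference lies (its `q` quantile) and the value above which fraction
#' `q` of the ipsi reference lies (its `1 - q` quantile). dLGN pixels
#' whose R falls strictly between the cutoffs are unsegregated — they
#' resemble neither pure-eye reference. The variance of the full dLGN
#' R-distribution is also reported: larger variance means more pixels at
#' the eye-specific extremes and fewer with balanced binocular input.
#'
#' @param r_dlgn R-values of all dLGN pixels (vector, or list of
#'   per-section vectors which are pooled).
#' @param r_contra_ref,r_ipsi_ref Reference R-values (vector or list),
#'   pooled across sections.
#' @param q Reference quantile (default 0.999).
#' @return An `r_distribution_result` list: `r_variance`,
#'   `unsegregated_fraction`, `cutoff_contra`, `cutoff_ipsi`, `n_pixels`,
#'   `degenerate` (TRUE when the cutoffs cross, in which case the
#'   fraction is reported as 1 with a warning).
#' @export
unsegregated_stats <- function(r_dlgn, r_contra_ref, r_ipsi_ref, q = 0.999) {
  pool <- function(x) if (is.list(x)) unlist(x, use.names = FALSE) else x
  r <- pool(r_dlgn); rc <- pool(r_contra_ref); ri <- pool(r_ipsi_ref)
  if (!length(rc) || !length(ri)) stop("reference ROIs must be nonempty")
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)")
  cutoff_contra <- unname(quantile(rc, q))
  cutoff_ipsi <- unname(quantile(ri, 1 - q))
  degenerate <- cutoff_contra >= cutoff_ipsi
  frac <- if (degenerate) {
    warning("reference cutoffs crossed; reporting unsegregated fraction 1")
    1
  } else {
    mean(r > cutoff_contra & r < cutoff_ipsi)
  }
  structure(list(r_variance = var(r), unsegregated_fraction = frac,
                 cutoff_contra = cutoff_contra, cutoff_ipsi = cutoff_ipsi,
                 n_pixels = length(r), degenerate = degenerate),
            class = "r_distribution_result")
}

#' Quantify a dLGN section stack by both segregation methods
#'
#' Runs [overlap_fractions()] on every section and pools R-values across
#' the stack for [unsegregated_stats()], using each section's reference
#' ROI masks.
#'
#' @param sections List of [section_image_pair()]s carrying
#'   `contra_ref_mask` and `ipsi_ref_mask`.
#' @param q Reference quantile for the unsegregated rule.
#' @param epsilon Intensity offset for [r_map()].
#' @return A list: `per_section` (data frame of overlap percentages) and
#'   `r_stats` (the pooled [unsegregated_stats()] result).
#' @export
segregation_stack <- function(sections, q = 0.999, epsilon = 1) {
  per <- lapply(seq_along(sections), function(s) {
    o <- overlap_fractions(sections[[s]])
    data.frame(section = s, percent_overlap = o$percent_overlap,
               percent_ipsi = o$percent_ipsi,
               percent_contra = o$percent_contra)
  })
  r_all <- lapply(sections, r_map, epsilon = epsilon)
  r_c <- lapply(sections, function(p) r_map(p, p$contra_ref_mask, epsilon))
  r_i <- lapply(sections, function(p) r_map(p, p$ipsi_ref_mask, epsilon))
  list(per_section = do.call(rbind, per),
       r_stats = unsegregated_stats(r_all, r_c, r_i, q))
}

#' @export
print.segregation_result <- function(x, ...) {
  cat(sprintf("<segregation_result> overlap %.2f%% | ipsi %.2f%% | contra %.2f%% (n = %d px)\n",
              x$percent_overlap, x$percent_ipsi, x$percent_contra, x$n_roi_px))
  invisible(x)
}
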