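#' Robust LOWESS smoothing of a displacement field
#'
#' Smooths each displacement component by locally weighted linear regression
#' over the `window_pixels` nearest masked pixels, with tricube distance
#' weights; with `robust = TRUE` (the default) the fit is iterated with
#' bisquare robustness weights computed from the residuals, making it
#' resistant to displacement outliers in the way a least-absolute-residual
#' fit is. The default window of 150 pixels is the value used for
#' displacement-encoded MRI regions of interest. Smoothing is mask-local:
#' pixels outside the mask never enter a window, and each connected mask
#' region is fitted from its own pixels only (window distances cannot jump
#' across unmasked space in a straight line, but windows are distance-based;
#' for strongly non-convex masks consider cropping first).
#'
#' @param field a [displacement_field()].
#' @param window_pixels number of nearest pixels in each local window
#'   (default 150; `>= 3`). Windows larger than a mask region shrink to the
#'   region with a warning.
#' @param robust logical; run 3 robustness reweighting iterations.
#' @return a smoothed [displacement_field()] with identical geometry, mask
#'   and weights.
#' @export
smooth_lowess <- function(field, window_pixels = 150L, robust = TRUE) {
  stopifnot(inherits(field, "displacement_field"))
  window_pixels <- as.integer(window_pixels)
  if (window_pixels < 3L) stop("`window_pixels` must be >= 3")
  nmasked <- sum(field$mask)
  if (window_pixels > nmasked) {
    warning("window (", window_pixels, " pixels) exceeds the masked region (",
            nmasked, " pixels); shrinking to the region size")
    window_pixels <- nmasked
  }
  iters <- if (isTRUE(robust)) 3L else 0L
  shp <- grid_dim(field$mask)
  comps <- lapply(field$components, function(cmp) {
    cmp[!field$mask] <- 0
    out <- .lowess_grid_cpp(cmp, field$mask, shp, field$spacing,
                            window_pixels, iters)
    out[!field$mask] <- 0
    out
  })
  displacement_field(comps, spacing = field$spacing, origin = field$origin,
                     mask = field$mask, weights = field$weights)
}

#' Mask-normalized Gaussian smoothing of a displacement field
#'
#' Convolves each component with an isotropic Gaussian kernel of standard
#' deviation `sigma_pixels` (in pixel units), renormalized inside the mask:
#' the smoothed value is `conv(field * mask) / conv(mask)`, so pixels outside
#' the mask are excluded from the kernel average rather than treated as
#' zeros. Even so, near a mask edge the kernel average is one-sided, which
#' flattens genuine gradients at thin-mask boundaries; this edge bias is the
#' reason robust LOWESS is preferred for displacement preprocessing.
#'
#' @param field a [displacement_field()].
#' @param sigma_pixels Gaussian standard deviation in pixels (`> 0`).
#' @return a smoothed [displacement_field()].
#' @export
smooth_gaussian <- function(field, sigma_pixels) {
  stopifnot(inherits(field, "displacement_field"))
  if (!is.finite(sigma_pixels) || sigma_pixels <= 0)
    stop("`sigma_pixels` must be positive")
  shp <- grid_dim(field$mask)
  nd <- length(shp)
  half <- max(1L, ceiling(3 * sigma_pixels))
  offs1d <- -half:half
  w1d <- exp(-offs1d^2 / (2 * sigma_pixels^2))
  offgrid <- as.matrix(expand.grid(rep(list(offs1d), nd)))
  wts <- apply(offgrid, 1L, function(o) prod(w1d[match(o, offs1d)]))
  m <- array(0, dim = shp)
  sums <- lapply(field$components, function(cmp) array(0, dim = shp))
  masknum <- field$mask * 1
  comps0 <- lapply(field$components, function(cmp) { cmp[!field$mask] <- 0; cmp })
  for (r in seq_len(nrow(offgrid))) {
    off <- offgrid[r, ]
    sm <- shift_array(masknum, off)
    sm[is.na(sm)] <- 0
    m <- m + wts[r] * sm
    for (a in seq_len(length(sums))) {
      sc <- shift_array(comps0[[a]], off)
      sc[is.na(sc)] <- 0
      sums[[a]] <- sums[[a]] + wts[r] * sc
    }
  }
  comps <- lapply(sums, function(s) {
    out <- array(0, dim = shp)
    out[field$mask] <- s[field$mask] / m[field$mask]
    out
  })
  displacement_field(comps, spacing = field$spacing, origin = field$origin,
                     mask = field$mask, weights = field$weights)
}

#' Down-weight pixels with outlying residuals
#'
#' Optional pre-pass for the inversion objective: compares a field to its
#' smoothed version and assigns weight `outlier_weight` to pixels whose
#' absolute residual exceeds `threshold` times the robust residual SD
#' (1.4826 * median absolute deviation); all other pixels keep weight 1.
#'
#' @param field a [displacement_field()] (raw).
#' @param smoothed its smoothed counterpart (defaults to [smooth_lowess()]
#'   of `field`).
#' @param threshold robust-SD multiple above which a pixel counts as an
#'   outlier (default 3).
#' @param outlier_weight weight given to flagged pixels (default 0.5).
#' @return `field` with updated `weights`.
#' @export
weight_outliers <- function(field, smoothed = NULL, threshold = 3,
                            outlier_weight = 0.5) {
  stopifnot(inherits(field, "displacement_field"))
  if (is.null(smoothed)) smoothed <- smooth_lowess(field)
  res2 <- array(0, dim = grid_dim(field$mask))
  for (a in seq_along(field$components))
    res2 <- res2 + (field$components[[a]] - smoothed$components[[a]])^2
  res <- sqrt(res2)
  rsd <- 1.4826 * stats::median(res[field$mask])
  w <- field$weights
  # a zero robust SD (majority of residuals exactly zero) makes any nonzero
  # residual an outlier
  flag <- if (rsd > 0) field$mask & (res > threshold * rsd) else
    field$mask & (res > 0)
  w[flag] <- outlier_weight
  displacement_field(field$components, spacing = field$spacing,
                     origin = field$origin, mask = field$mask, weights = w)
}
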