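#' Displacement fields on a regular imaging grid
#'
#' A `displacement_field` holds one scalar grid per spatial component of a
#' displacement vector field (units mm), together with the grid geometry
#' (pixel spacing and physical origin), a boolean mask of valid pixels, and
#' optional per-pixel weights used later to down-vote unreliable nodes in the
#' inversion objective.
#'
#' Conventions: pixel `(1,1[,1])` sits at the physical `origin`; physical
#' coordinate of pixel index `i` along axis `a` is
#' `origin[a] + (i - 1) * spacing[a]`. Axis order is `(x, y[, z])`, matching
#' the component order.
#'
#' @param components list of numeric arrays (one per axis), identical shape;
#'   values in mm.
#' @param spacing numeric vector of pixel spacings (mm), one per axis,
#'   strictly positive.
#' @param origin physical coordinate (mm) of the first pixel; defaults to 0.
#' @param mask logical array of the same shape; `TRUE` marks tissue pixels.
#'   Defaults to all `TRUE`.
#' @param weights optional non-negative numeric array of the same shape;
#'   defaults to 1 everywhere.
#' @return An object of class `displacement_field`.
#' @export
displacement_field <- function(components, spacing, origin = NULL, mask = NULL,
                               weights = NULL) {
  if (!is.list(components) || length(components) < 1L)
    stop("`components` must be a non-empty list of arrays, one per axis")
  components <- lapply(components, as_grid_array)
  shp <- grid_dim(components[[1L]])
  nd <- length(shp)
  for (cmp in components)
    if (!identical(grid_dim(cmp), shp))
      stop("all component grids must share one shape")
  if (length(spacing) == 1L) spacing <- rep(spacing, nd)
  if (length(spacing) != nd || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be strictly positive, one value per axis")
  if (is.null(origin)) origin <- rep(0, nd)
  if (length(origin) != nd) stop("`origin` must have one value per axis")
  if (is.null(mask)) mask <- array(TRUE, dim = shp)
  mask <- as_grid_array(mask)
  storage.mode(mask) <- "logical"
  if (!identical(grid_dim(mask), shp)) stop("`mask` shape must match components")
  if (is.null(weights)) weights <- array(1, dim = shp)
  weights <- as_grid_array(weights)
  if (!identical(grid_dim(weights), shp)) stop("`weights` shape must match components")
  if (any(weights[mask] < 0, na.rm = TRUE)) stop("`weights` must be non-negative")
  for (cmp in components)
    if (any(!is.finite(cmp[mask])))
      stop("components must be finite inside the mask")
  structure(
    list(components = components, spacing = as.numeric(spacing),
         origin = as.numeric(origin), mask = mask, weights = weights),
    class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  shp <- grid_dim(x$mask)
  cat("<displacement_field> ", length(x$components), "D, grid ",
      paste(shp, collapse = " x "), ", spacing ",
      paste(signif(x$spacing, 4), collapse = " x "), " mm, ",
      sum(x$mask), "/", length(x$mask), " masked pixels\n", sep = "")
  invisible(x)
}

#' Wrapped or unwrapped phase maps
#'
#' Scalar phase grid (radians) with the same geometry conventions as
#' [displacement_field()]. Raw displacement-encoded phase is wrapped to
#' `(-pi, pi]`; [unwrap_phase()] removes the wraps before conversion to
#' displacement with [decode_displacement()].
#'
#' @param phase numeric array of phase values (radians).
#' @inheritParams displacement_field
#' @return An object of class `phase_field`.
#' @export
phase_field <- function(phase, spacing, origin = NULL, mask = NULL) {
  phase <- as_grid_array(phase)
  shp <- grid_dim(phase)
  nd <- length(shp)
  if (length(spacing) == 1L) spacing <- rep(spacing, nd)
  if (length(spacing) != nd || any(spacing <= 0))
    stop("`spacing` must be strictly positive, one value per axis")
  if (is.null(origin)) origin <- rep(0, nd)
  if (is.null(mask)) mask <- array(TRUE, dim = shp)
  mask <- as_grid_array(mask)
  storage.mode(mask) <- "logical"
  if (!identical(grid_dim(mask), shp)) stop("`mask` shape must match phase")
  if (any(!is.finite(phase[mask]))) stop("phase must be finite inside the mask")
  structure(list(phase = phase, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), mask = mask),
            class = "phase_field")
}

#' Displacement-encoding parameters
#'
#' The phase accumulated by a displacement-encoded stimulated-echo sequence is
#' proportional to displacement: `dphi = gamma * t_enc * (G - Gref) * dx`,
#' where `gamma` is the gyromagnetic ratio, `t_enc` the encoding-gradient
#' duration, `G` the displacement-encoding gradient and `Gref` the gradient of
#' the reference acquisition that cancels shared phase contributions. All
#' parameters are accepted in SI units; decoded displacements are returned
#' in mm.
#'
#' @param gyromagnetic_ratio gyromagnetic ratio (rad s^-1 T^-1); default is
#'   the proton value 2.675e8.
#' @param encoding_duration encoding-gradient duration t_enc (s).
#' @param encoding_gradient per-axis encoding gradient magnitude (T/m).
#' @param reference_gradient per-axis reference gradient magnitude (T/m);
#'   default 0.
#' @return An object of class `phase_encoding_spec`.
#' @export
phase_encoding_spec <- function(gyromagnetic_ratio = 2.675e8,
                                encoding_duration,
                                encoding_gradient,
                                reference_gradient = 0) {
  if (gyromagnetic_ratio <= 0) stop("`gyromagnetic_ratio` must be positive")
  if (encoding_duration <= 0) stop("`encoding_duration` must be positive")
  n <- max(length(encoding_gradient), length(reference_gradient))
  encoding_gradient <- rep_len(as.numeric(encoding_gradient), n)
  reference_gradient <- rep_len(as.numeric(reference_gradient), n)
  structure(list(gyromagnetic_ratio = gyromagnetic_ratio,
                 encoding_duration = encoding_duration,
                 encoding_gradient = encoding_gradient,
                 reference_gradient = reference_gradient),
            class = "phase_encoding_spec")
}

#' Gaussian displacement-noise model
#'
#' Describes the zero-mean Gaussian perturbation added independently to every
#' displacement component at every masked pixel. The experimental noise level
#' of displacement-encoded MRI at typical averaging is about 0.1 mm standard
#' deviation, which is the default used throughout the validation phantoms.
#' Noise is applied at boundary pixels as well unless `apply_to_boundary` is
#' `FALSE`, since measured boundary values are as noisy as interior ones.
#'
#' @param sigma noise standard deviation (mm), `>= 0`.
#' @param seed integer seed making the draw reproducible.
#' @param apply_to_boundary logical; perturb mask-boundary pixels too
#'   (default `TRUE`).
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(sigma = 0.1, seed = 1L, apply_to_boundary = TRUE) {
  if (!is.finite(sigma) || sigma < 0) stop("`sigma` must be >= 0")
  structure(list(sigma = as.numeric(sigma), seed = as.integer(seed),
                 apply_to_boundary = isTRUE(apply_to_boundary)),
            class = "noise_spec")
}

# internal: coerce vectors/matrices to arrays with a dim attribute
as_grid_array <- function(x) {
  if (is.null(dim(x))) dim(x) <- length(x)
  x
}

grid_dim <- function(x) as.integer(dim(x))

# physical coordinates of every pixel (rows) for a grid geometry
grid_coordinates <- function(shp, spacing, origin) {
  axes <- lapply(seq_along(shp),
                 function(a) origin[a] + (seq_len(shp[a]) - 1) * spacing[a])
  as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
}

#' Decode displacement from unwrapped phase
#'
#' Converts an (already unwrapped) phase map into one displacement component:
#' `dx = dphi / (gamma * t_enc * (G - Gref))` on the requested axis. Encoding
#' parameters are in SI units (so the quotient is in metres) and the result is
#' converted to mm.
#'
#' @param phase a [phase_field()], unwrapped.
#' @param enc a [phase_encoding_spec()].
#' @param axis 1-based index of the encoded axis.
#' @return numeric array: the displacement component (mm), same shape as the
#'   phase grid.
#' @export
decode_displacement <- function(phase, enc, axis = 1L) {
  stopifnot(inherits(phase, "phase_field"), inherits(enc, "phase_encoding_spec"))
  axis <- as.integer(axis)
  if (axis < 1L || axis > length(enc$encoding_gradient))
    stop("`axis` out of range of the encoding specification")
  dg <- enc$encoding_gradient[axis] - enc$reference_gradient[axis]
  if (!is.finite(dg) || dg == 0)
    stop("invalid encoding: zero gradient difference on axis ", axis)
  scale_m <- 1 / (enc$gyromagnetic_ratio * enc$encoding_duration * dg)
  out <- phase$phase * scale_m * 1000  # m -> mm
  out[!phase$mask] <- NA_real_
  out
}

#' Synthesize encoded phase from a known displacement component
#'
#' Inverse of [decode_displacement()]; mainly used to round-trip test the
#' conversion and to build simulated raw-phase inputs. Optionally wraps the
#' result into `(-pi, pi]`.
#'
#' @param displacement_mm numeric array of displacements (mm).
#' @param enc a [phase_encoding_spec()].
#' @param axis encoded axis.
#' @param wrap logical; wrap the phase into `(-pi, pi]`.
#' @return numeric array of phase (radians).
#' @export
encode_phase <- function(displacement_mm, enc, axis = 1L, wrap = FALSE) {
  stopifnot(inherits(enc, "phase_encoding_spec"))
  dg <- enc$encoding_gradient[axis] - enc$reference_gradient[axis]
  if (dg == 0) stop("invalid encoding: zero gradient difference on axis ", axis)
  ph <- (displacement_mm / 1000) * enc$gyromagnetic_ratio *
    enc$encoding_duration * dg
  if (wrap) ph <- wrap_phase(ph)
  ph
}

# wrap angles into (-pi, pi]; NAs pass through
wrap_phase <- function(x) {
  w <- x - 2 * pi * round(x / (2 * pi))
  idx <- which(w <= -pi)
  w[idx] <- w[idx] + 2 * pi
  w
}

#' Unwrap a wrapped phase map
#'
#' Removes 2*pi wraps from a phase grid by quality-guided flood fill: starting
#' from the masked pixel with the locally smoothest phase, neighbours are
#' visited in order of a local-variance quality score and each pixel is offset
#' by the multiple of 2*pi that brings its difference to the already-unwrapped
#' neighbour into `(-pi, pi]`. Each connected mask component is unwrapped
#' independently (their mutual offsets are unidentifiable); a warning reports
#' when more than one component is present.
#'
#' @param phase a [phase_field()] with wrapped values.
#' @return a [phase_field()] whose masked pixel-to-pixel differences all lie
#'   in `(-pi, pi]`; equal to the input plus integer multiples of 2*pi.
#' @export
unwrap_phase <- function(phase) {
  stopifnot(inherits(phase, "phase_field"))
  shp <- grid_dim(phase$phase)
  comp <- label_components(phase$mask)
  ncomp <- max(comp)
  if (ncomp == 0L) stop("mask is empty")
  if (ncomp > 1L)
    warning("mask has ", ncomp, " disconnected regions; each is unwrapped ",
            "independently (relative 2*pi offsets are unidentifiable)")
  out <- phase$phase
  quality <- -local_phase_roughness(phase$phase, phase$mask)
  for (cc in seq_len(ncomp)) {
    idx <- which(comp == cc)
    seed <- idx[which.max(quality[idx])]
    out <- flood_unwrap(out, comp == cc, seed, quality, shp)
  }
  phase_field(out, spacing = phase$spacing, origin = phase$origin,
              mask = phase$mask)
}

# roughness = sum of squared wrapped differences to grid neighbours
local_phase_roughness <- function(ph, mask) {
  shp <- grid_dim(ph)
  rough <- array(0, dim = shp)
  for (off in axis_offsets(length(shp))) {
    nb <- shift_array(ph, off)
    ok <- shift_array(mask, off)
    ok[is.na(ok)] <- FALSE
    d <- wrap_phase(nb - ph)
    d[!ok | !mask] <- 0
    rough <- rough + d^2
  }
  rough
}

# unit offsets +/- along each axis
axis_offsets <- function(nd) {
  offs <- list()
  for (a in seq_len(nd)) for (s in c(-1L, 1L)) {
    o <- integer(nd); o[a] <- s
    offs[[length(offs) + 1L]] <- o
  }
  offs
}

# shift an array by an integer offset, padding with NA
shift_array <- function(x, off) {
  shp <- grid_dim(x)
  idx <- lapply(seq_along(shp), function(a) seq_len(shp[a]) + off[a])
  out <- array(NA, dim = shp)
  src <- lapply(seq_along(shp), function(a) idx[[a]][idx[[a]] >= 1 & idx[[a]] <= shp[a]])
  dst <- lapply(seq_along(shp), function(a) which(idx[[a]] >= 1 & idx[[a]] <= shp[a]))
  out_call <- do.call(`[<-`, c(list(out), dst, list(do.call(`[`, c(list(x), src)))))
  out_call
}

# priority flood fill from seed; quality decides the visiting order
flood_unwrap <- function(ph, mask, seed, quality, shp) {
  n <- length(ph)
  visited <- logical(n)
  visited[seed] <- TRUE
  nb_offsets <- neighbor_linear_offsets(shp)
  frontier_idx <- integer(0)
  frontier_q <- numeric(0)
  push_neighbors <- function(i) {
    for (k in seq_along(nb_offsets$off)) {
      j <- i + nb_offsets$off[k]
      if (j < 1L || j > n) next
      if (!nb_offsets$valid[[k]][i]) next
      if (!mask[j] || visited[j]) next
      frontier_idx[length(frontier_idx) + 1L] <<- j
      frontier_q[length(frontier_q) + 1L] <<- quality[j]
    }
  }
  push_neighbors(seed)
  while (length(frontier_idx) > 0L) {
    pick <- which.max(frontier_q)
    i <- frontier_idx[pick]
    frontier_idx <- frontier_idx[-pick]
    frontier_q <- frontier_q[-pick]
    if (visited[i]) next
    # unwrap against any visited neighbour
    ref <- NA_real_
    for (k in seq_along(nb_offsets$off)) {
      j <- i + nb_offsets$off[k]
      if (j < 1L || j > n) next
      if (!nb_offsets$valid[[k]][i]) next
      if (visited[j] && mask[j]) { ref <- ph[j]; break }
    }
    ph[i] <- ref + wrap_phase(ph[i] - ref)
    visited[i] <- TRUE
    push_neighbors(i)
  }
  ph
}

# linear-index offsets of grid neighbours plus validity masks guarding the
# array edges (so offsets do not wrap across rows)
neighbor_linear_offsets <- function(shp) {
  nd <- length(shp)
  strides <- cumprod(c(1L, shp[-nd]))
  n <- prod(shp)
  coord <- arrayInd(seq_len(n), .dim = shp)
  off <- integer(0); valid <- list()
  for (a in seq_len(nd)) for (s in c(-1L, 1L)) {
    off <- c(off, s * strides[a])
    v <- if (s < 0) coord[, a] > 1L else coord[, a] < shp[a]
    valid[[length(valid) + 1L]] <- v
  }
  list(off = off, valid = valid)
}

# connected-component labelling of a logical grid (4/6-connectivity)
label_components <- function(mask) {
  shp <- grid_dim(mask)
  n <- length(mask)
  labels <- integer(n)
  nb <- neighbor_linear_offsets(shp)
  cur <- 0L
  for (start in which(as.logical(mask))) {
    if (labels[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    labels[start] <- cur
    while (length(stack) > 0L) {
      i <- stack[length(stack)]
      stack <- stack[-length(stack)]
      for (k in seq_along(nb$off)) {
        j <- i + nb$off[k]
        if (j < 1L || j > n) next
        if (!nb$valid[[k]][i]) next
        if (mask[j] && labels[j] == 0L) {
          labels[j] <- cur
          stack[length(stack) + 1L] <- j
        }
      }
    }
  }
  array(labels, dim = shp)
}

#' Add Gaussian noise to a displacement field
#'
#' Perturbs every masked pixel of every component with independent zero-mean
#' Gaussian noise of standard deviation `noise$sigma` (mm). Boundary pixels of
#' the mask are perturbed too when `noise$apply_to_boundary` is `TRUE`,
#' matching the fact that measured boundary values carry the same noise as
#' interior ones. The draw is reproducible under the spec's seed and leaves
#' the caller's RNG state untouched.
#'
#' @param field a [displacement_field()].
#' @param noise a [noise_spec()].
#' @return a new [displacement_field()].
#' @export
add_noise <- function(field, noise) {
  stopifnot(inherits(field, "displacement_field"), inherits(noise, "noise_spec"))
  if (noise$sigma == 0) return(field)
  target <- field$mask
  if (!noise$apply_to_boundary) target <- target & !mask_boundary(field$mask)
  idx <- which(target)
  comps <- field$components
  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(noise$seed)
  for (a in seq_along(comps))
    comps[[a]][idx] <- comps[[a]][idx] + stats::rnorm(length(idx), 0, noise$sigma)
  displacement_field(comps, spacing = field$spacing, origin = field$origin,
                     mask = field$mask, weights = field$weights)
}

# pixels of the mask adjacent to (or at the grid edge of) unmasked space
mask_boundary <- function(mask) {
  shp <- grid_dim(mask)
  interior <- mask
  for (off in axis_offsets(length(shp))) {
    nb <- shift_array(mask, off)
    nb[is.na(nb)] <- FALSE
    interior <- interior & nb
  }
  mask & !interior
}
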