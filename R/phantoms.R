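#' Parametric ground-truth phantom specification
#'
#' Describes a synthetic validation specimen: its geometry (2D rectangle or
#' 3D cylinder), its ground-truth stiffness pattern, its indentation loading
#' and the imaging resolution. The phantom catalogue mirrors the standard
#' validation suite for displacement-based stiffness reconstruction: a 6 x 6
#' mm bilayer (1000 Pa over 500 Pa), stiff circular inclusions (1000 and
#' 1500 Pa on a 500 Pa background), a soft slender inclusion (200 Pa,
#' fissure-like) on a stiffness gradient rising to 1000 Pa, and a two-layer
#' 3D cylinder with a 2:1 top:bottom modulus ratio.
#'
#' @param geometry list: `list(type = "rectangle", width, height)` or
#'   `list(type = "cylinder", radius, height)` (mm).
#' @param pattern list with `type` one of `"bilayer"` (`top_fraction`,
#'   `E_top`, `E_bottom`), `"inclusions"` (`E_background`, `centers` matrix,
#'   `radii`, `moduli`), `"gradient_fissure"` (`E_from` at the bottom,
#'   `E_to` at the top, `E_inclusion`, `inclusion_center`,
#'   `inclusion_halfwidth` per axis) or `"homogeneous"` (`E`). Moduli in Pa.
#' @param indent_fraction indentation depth as a fraction of thickness
#'   (default 0.15).
#' @param spacing pixel spacing / element size (mm).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(geometry, pattern, indent_fraction = 0.15,
                         spacing = 0.15) {
  if (!geometry$type %in% c("rectangle", "cylinder"))
    stop("unknown geometry type: ", geometry$type)
  if (!pattern$type %in% c("bilayer", "inclusions", "gradient_fissure",
                           "homogeneous"))
    stop("unknown pattern type: ", pattern$type)
  moduli <- switch(pattern$type,
    bilayer = c(pattern$E_top, pattern$E_bottom),
    inclusions = c(pattern$E_background, pattern$moduli),
    gradient_fissure = c(pattern$E_from, pattern$E_to, pattern$E_inclusion),
    homogeneous = pattern$E)
  if (any(moduli <= 0)) stop("all moduli must be positive")
  if (pattern$type == "bilayer" &&
      (pattern$top_fraction <= 0 || pattern$top_fraction >= 1))
    stop("`top_fraction` must be in (0, 1)")
  structure(list(geometry = geometry, pattern = pattern,
                 indent_fraction = indent_fraction, spacing = spacing),
            class = "phantom_spec")
}

# pixel mask of the phantom geometry at its imaging resolution
phantom_mask <- function(spec) {
  h <- spec$spacing
  if (spec$geometry$type == "rectangle") {
    nx <- max(1L, round(spec$geometry$width / h))
    ny <- max(1L, round(spec$geometry$height / h))
    array(TRUE, dim = c(nx, ny))
  } else {
    r <- spec$geometry$radius
    nz <- max(1L, round(spec$geometry$height / h))
    nxy <- 2L * ceiling(r / h)
    ctr <- nxy * h / 2
    xc <- (seq_len(nxy) - 0.5) * h
    inside <- outer((xc - ctr)^2, (xc - ctr)^2, `+`) <= r^2
    array(inside, dim = c(nxy, nxy, nz))
  }
}

#' Mesh a phantom at its native resolution
#'
#' @param spec a [phantom_spec()].
#' @param family optional element family override.
#' @return an [fe_mesh()] with one element per phantom pixel/voxel.
#' @export
phantom_mesh <- function(spec, family = NULL) {
  mesh_from_mask(phantom_mask(spec), spacing = spec$spacing, family = family)
}

#' Rasterize the ground-truth stiffness pattern onto a mesh
#'
#' Assigns each element the true modulus of the region containing its
#' centroid, converts to relative densities `rho_true = E / max(E)` (so the
#' stiffest region is 1), and exports region labels for evaluation. The
#' loading (thickness) axis is the last coordinate; the bilayer's "top" is
#' the high end of that axis. Gradient backgrounds are labelled by thirds of
#' the thickness (`grad_low`/`grad_mid`/`grad_high`).
#'
#' @param spec a [phantom_spec()].
#' @param mesh an [fe_mesh()] of the phantom (default: [phantom_mesh()]).
#' @return list: `E` (Pa), `rho` (relative density), `labels` (character),
#'   one entry per element.
#' @export
rasterize_truth <- function(spec, mesh = NULL) {
  if (is.null(mesh)) mesh <- phantom_mesh(spec)
  cen <- element_centroids(mesh)
  ax <- mesh$dim  # loading/thickness axis
  zmin <- min(mesh$nodes[, ax]); zmax <- max(mesh$nodes[, ax])
  zfrac <- (cen[, ax] - zmin) / (zmax - zmin)
  pat <- spec$pattern
  ne <- nrow(cen)
  if (pat$type == "homogeneous") {
    E <- rep(pat$E, ne); labels <- rep("body", ne)
  } else if (pat$type == "bilayer") {
    top <- zfrac > (1 - pat$top_fraction)
    E <- ifelse(top, pat$E_top, pat$E_bottom)
    labels <- ifelse(top, "top", "bottom")
  } else if (pat$type == "inclusions") {
    E <- rep(pat$E_background, ne)
    labels <- rep("background", ne)
    centers <- as.matrix(pat$centers)
    for (k in seq_len(nrow(centers))) {
      if (pat$radii[k] <= 0) next  # degenerate: no centroid can fall inside
      lat <- seq_len(ncol(centers))
      d2 <- rowSums(sweep(cen[, lat, drop = FALSE], 2L, centers[k, ],
                          `-`)^2)
      inside <- d2 <= pat$radii[k]^2
      E[inside] <- pat$moduli[k]
      labels[inside] <- paste0("inclusion", k)
    }
  } else {  # gradient + slender soft inclusion
    E <- pat$E_from + (pat$E_to - pat$E_from) * zfrac
    labels <- cut(zfrac, breaks = c(-Inf, 1 / 3, 2 / 3, Inf),
                  labels = c("grad_low", "grad_mid", "grad_high"))
    labels <- as.character(labels)
    hw <- rep_len(pat$inclusion_halfwidth, mesh$dim)
    ctr <- rep_len(pat$inclusion_center, mesh$dim)
    inside <- rep(TRUE, ne)
    for (a in seq_len(mesh$dim))
      inside <- inside & abs(cen[, a] - ctr[a]) <= hw[a]
    E[inside] <- pat$E_inclusion
    labels[inside] <- "fissure"
  }
  list(E = E, rho = E / max(E), labels = labels)
}

#' Forward-simulate phantom displacements
#'
#' Solves the phantom's forward indentation problem (bottom fixed, top
#' displaced by the indentation fraction of the thickness, lateral surfaces
#' free) on its ground-truth stiffness map, samples the nodal solution onto
#' the imaging grid (grid points at element corners, the native lattice of
#' the phantom mesh), and optionally adds Gaussian measurement noise. The
#' generated field satisfies the prescribed boundary values exactly at
#' boundary pixels before noise; with `noise$apply_to_boundary = TRUE` (the
#' default model of real measurements) boundary pixels are perturbed too.
#'
#' @param spec a [phantom_spec()].
#' @param noise optional [noise_spec()]; `NULL` for noise-free output.
#' @param family optional element family override.
#' @return list: `field` (the [displacement_field()]), `mesh`, `truth`
#'   (from [rasterize_truth()]), `bc` (the loading [dirichlet_bc()]),
#'   `solution` (the [solve_forward()] result) and `spec`.
#' @export
generate_displacements <- function(spec, noise = NULL, family = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  mesh <- phantom_mesh(spec, family = family)
  truth <- rasterize_truth(spec, mesh)
  material <- material_field(rho = truth$rho)
  bc <- indentation_protocol(mesh, spec$indent_fraction)
  sol <- solve_forward(mesh, material, bc)
  cg <- attr(mesh, "cell_grid")
  # imaging grid = the node lattice of the mesh (pixel spacing = element size)
  gdim <- dim(cg$elem_of_cell) + 1L
  nd <- mesh$dim
  gi <- round(sweep(sweep(mesh$nodes, 2L, cg$origin, `-`), 2L, cg$cell_size,
                    `/`)) + 1L
  lin <- as.integer(1 + (gi - 1) %*% cumprod(c(1L, gdim[-nd])))
  mask <- array(FALSE, dim = gdim)
  mask[lin] <- TRUE
  comps <- lapply(seq_len(nd), function(a) {
    g <- array(0, dim = gdim)
    g[lin] <- sol$displacements[, a]
    g
  })
  field <- displacement_field(comps, spacing = cg$cell_size, origin = cg$origin,
                              mask = mask)
  if (!is.null(noise)) field <- add_noise(field, noise)
  list(field = field, mesh = mesh, truth = truth, bc = bc, solution = sol,
       spec = spec)
}

#' Packaged end-to-end validation cases
#'
#' Deterministic, seeded fixtures used throughout the tests and
#' documentation. Moduli, geometry and loading follow the validation suite:
#' `bilayer2d` is the 6 x 6 mm, 1000/500 Pa bilayer at 0.15 mm resolution
#' with 15% indentation; `inclusions2d` puts stiff 1000 and 1500 Pa circles
#' on a 500 Pa background; `gradient_fissure2d` puts a soft slender 200 Pa
#' inclusion on a 500-to-1000 Pa bottom-to-top gradient; `cylinder3d` is a
#' two-layer cylinder (radius 5 mm, height 6 mm, top third at 1000 Pa over
#' 500 Pa: a 2:1 top:bottom ratio) at the usual 0.6 mm mesh density;
#' `homogeneous` is a uniform 500 Pa square for null-case testing. Inclusion
#' positions/sizes and the 2D resolutions of the non-bilayer cases are
#' package defaults chosen to keep desk-scale runs light.
#'
#' @param name one of `"bilayer2d"`, `"inclusions2d"`,
#'   `"gradient_fissure2d"`, `"cylinder3d"`, `"homogeneous"`.
#' @param noise_sigma Gaussian displacement noise SD in mm (default 0:
#'   noise-free).
#' @param seed integer seed for the noise draw.
#' @param spacing optional resolution override (mm).
#' @return the bundle of [generate_displacements()].
#' @export
end_to_end_case <- function(name, noise_sigma = 0, seed = 1L,
                            spacing = NULL) {
  specs <- list(
    bilayer2d = phantom_spec(
      geometry = list(type = "rectangle", width = 6, height = 6),
      pattern = list(type = "bilayer", top_fraction = 0.5, E_top = 1000,
                     E_bottom = 500),
      spacing = 0.15),
    inclusions2d = phantom_spec(
      geometry = list(type = "rectangle", width = 6, height = 6),
      pattern = list(type = "inclusions", E_background = 500,
                     centers = rbind(c(1.8, 3.9), c(4.2, 2.0)),
                     radii = c(0.8, 0.9), moduli = c(1000, 1500)),
      spacing = 0.2),
    gradient_fissure2d = phantom_spec(
      geometry = list(type = "rectangle", width = 6, height = 6),
      pattern = list(type = "gradient_fissure", E_from = 500, E_to = 1000,
                     E_inclusion = 200, inclusion_center = c(3, 3.6),
                     inclusion_halfwidth = c(1.2, 0.2)),
      spacing = 0.2),
    cylinder3d = phantom_spec(
      geometry = list(type = "cylinder", radius = 5, height = 6),
      pattern = list(type = "bilayer", top_fraction = 1 / 3, E_top = 1000,
                     E_bottom = 500),
      spacing = 0.6),
    homogeneous = phantom_spec(
      geometry = list(type = "rectangle", width = 6, height = 6),
      pattern = list(type = "homogeneous", E = 500),
      spacing = 0.3))
  if (!name %in% names(specs)) stop("unknown case: ", name)
  spec <- specs[[name]]
  if (!is.null(spacing)) spec$spacing <- spacing
  noise <- if (noise_sigma > 0) noise_spec(sigma = noise_sigma, seed = seed)
  generate_displacements(spec, noise = noise)
}

#' Write a phantom bundle to disk
#'
#' Exports the displacement field (NIfTI for 3D, delimited text and NIfTI
#' for 2D), the ground truth as a VTK mesh with cell data, and the loading
#' boundary condition as JSON.
#'
#' @param bundle result of [generate_displacements()] /
#'   [end_to_end_case()].
#' @param dir output directory (created if missing).
#' @param prefix file name prefix (default `"phantom"`).
#' @return invisibly, the output directory.
#' @export
write_phantom_bundle <- function(bundle, dir, prefix = "phantom") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- file.path(dir, prefix)
  write_field_nifti(bundle$field, p)
  if (bundle$mesh$dim == 2L) write_field_text(bundle$field, paste0(p, "_txt"))
  write_mesh_vtk(bundle$mesh, paste0(p, "_truth.vtk"),
                 cell_data = list(relative_stiffness = bundle$truth$rho,
                                  modulus_Pa = bundle$truth$E))
  write_bc_json(bundle$bc, paste0(p, "_bc.json"))
  invisible(dir)
}
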