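#' Finite-element mesh container
#'
#' Nodes are physical coordinates in mm; elements are 1-based connectivity
#' rows in one of the supported families: `tri3` (3-node triangle), `quad4`
#' (4-node quadrilateral), `tet4` (4-node tetrahedron), `hex8` (8-node
#' hexahedron). Boundary nodes are the nodes lying on facets that belong to
#' exactly one element.
#'
#' @param nodes numeric matrix (n_nodes x dim), dim 2 or 3.
#' @param elements integer matrix (n_elements x nodes_per_element).
#' @param family element family string.
#' @param check validate element measures and connectivity (default `TRUE`).
#' @return An object of class `fe_mesh` with fields `nodes`, `elements`,
#'   `family`, `dim` and `boundary_nodes`.
#' @export
fe_mesh <- function(nodes, elements, family, check = TRUE) {
  nodes <- as.matrix(nodes)
  elements <- matrix(as.integer(as.matrix(elements)), nrow = NROW(elements))
  dim <- ncol(nodes)
  npe_expect <- c(tri3 = 3L, quad4 = 4L, tet4 = 4L, hex8 = 8L)[family]
  if (is.na(npe_expect)) stop("unknown element family: ", family)
  if (ncol(elements) != npe_expect)
    stop(family, " elements need ", npe_expect, " nodes per element")
  fam_dim <- if (family %in% c("tri3", "quad4")) 2L else 3L
  if (dim != fam_dim) stop(family, " requires ", fam_dim, "D nodes")
  if (check) {
    if (max(elements) > nrow(nodes) || min(elements) < 1L)
      stop("element connectivity indexes nonexistent nodes")
    meas <- element_measures(nodes, elements, family)
    bad <- which(meas <= 0)
    if (length(bad) > 0)
      stop("elements with non-positive measure: ",
           paste(utils::head(bad, 5), collapse = ", "))
  }
  mesh <- structure(list(nodes = nodes, elements = elements, family = family,
                         dim = dim, boundary_nodes = integer(0)),
                    class = "fe_mesh")
  mesh$boundary_nodes <- find_boundary_nodes(mesh)
  mesh
}

#' @export
print.fe_mesh <- function(x, ...) {
  cat("<fe_mesh> ", x$dim, "D, ", nrow(x$nodes), " nodes, ",
      nrow(x$elements), " ", x$family, " elements, ",
      length(x$boundary_nodes), " boundary nodes\n", sep = "")
  invisible(x)
}

# facet (edge/face) definitions per family, as local node indices
element_facets <- function(family) {
  switch(family,
    tri3 = list(c(1L, 2L), c(2L, 3L), c(3L, 1L)),
    quad4 = list(c(1L, 2L), c(2L, 3L), c(3L, 4L), c(4L, 1L)),
    tet4 = list(c(1L, 2L, 3L), c(1L, 2L, 4L), c(2L, 3L, 4L), c(1L, 3L, 4L)),
    hex8 = list(c(1L, 2L, 3L, 4L), c(5L, 6L, 7L, 8L), c(1L, 2L, 6L, 5L),
                c(2L, 3L, 7L, 6L), c(3L, 4L, 8L, 7L), c(4L, 1L, 5L, 8L)),
    stop("unknown element family: ", family))
}

# table of all facets with element counts; key = sorted node indices
facet_table <- function(mesh) {
  facets <- element_facets(mesh$family)
  keys <- character(0)
  for (f in facets) {
    sub <- mesh$elements[, f, drop = FALSE]
    sorted <- t(apply(sub, 1L, sort))
    keys <- c(keys, apply(sorted, 1L, paste, collapse = "-"))
  }
  table(keys)
}

find_boundary_nodes <- function(mesh) {
  tab <- facet_table(mesh)
  bkeys <- names(tab)[tab == 1L]
  if (length(bkeys) == 0) return(integer(0))
  ids <- unique(as.integer(unlist(strsplit(bkeys, "-"))))
  sort(ids)
}

# per-element area (2D) or volume (3D)
element_measures <- function(nodes, elements, family) {
  tri_area <- function(a, b, c)
    0.5 * ((b[, 1] - a[, 1]) * (c[, 2] - a[, 2]) -
           (c[, 1] - a[, 1]) * (b[, 2] - a[, 2]))
  tet_vol <- function(a, b, c, d) {
    u <- b - a; v <- c - a; w <- d - a
    (u[, 1] * (v[, 2] * w[, 3] - v[, 3] * w[, 2]) -
     u[, 2] * (v[, 1] * w[, 3] - v[, 3] * w[, 1]) +
     u[, 3] * (v[, 1] * w[, 2] - v[, 2] * w[, 1])) / 6
  }
  P <- function(k) nodes[elements[, k], , drop = FALSE]
  switch(family,
    tri3 = tri_area(P(1), P(2), P(3)),
    quad4 = tri_area(P(1), P(2), P(3)) + tri_area(P(1), P(3), P(4)),
    tet4 = tet_vol(P(1), P(2), P(3), P(4)),
    hex8 = {  # 5-tet decomposition of each hexahedron
      tet_vol(P(1), P(2), P(4), P(5)) + tet_vol(P(2), P(3), P(4), P(7)) +
      tet_vol(P(2), P(7), P(4), P(5)) + tet_vol(P(5), P(7), P(8), P(4)) +
      tet_vol(P(2), P(6), P(7), P(5))
    })
}

#' Element centroids
#' @param mesh an [fe_mesh()].
#' @return numeric matrix (n_elements x dim).
#' @export
element_centroids <- function(mesh) {
  npe <- ncol(mesh$elements)
  out <- matrix(0, nrow(mesh$elements), mesh$dim)
  for (k in seq_len(npe))
    out <- out + mesh$nodes[mesh$elements[, k], , drop = FALSE]
  out / npe
}

#' Build a finite-element mesh from a pixel/voxel mask
#'
#' Converts a binary imaging mask into a mesh whose nodes sit at pixel
#' corners. On the (possibly coarsened) cell grid, each masked cell becomes
#' one `quad4`/`hex8` element; the simplicial families `tri3`/`tet4` split
#' each cell along its diagonal(s), which is a Delaunay triangulation of the
#' regular corner lattice. Simplices with any edge shorter than the
#' minimum-feature threshold, or with non-positive measure, are culled; with
#' the default threshold (0.5 mm, capped at the element size so regular
#' elements survive) this only prunes degenerate slivers of irregular masks.
#' Boundary nodes are detected as nodes on facets shared by exactly one
#' element.
#'
#' @param mask logical 2D or 3D array (`TRUE` = tissue pixel).
#' @param spacing pixel size (mm), scalar or per-axis.
#' @param target_element_size desired element edge length (mm); defaults to
#'   the pixel spacing (one element per pixel). Coarser sizes merge blocks of
#'   pixels; a coarse cell is kept when at least half its pixels are masked.
#' @param family element family: `"quad4"` (2D default), `"tri3"`, `"hex8"`
#'   (3D default) or `"tet4"`.
#' @param min_feature_mm minimum simplex edge length (mm); default
#'   `min(0.5, element size)`.
#' @param origin physical coordinate of the corner of pixel (1,1[,1]);
#'   default 0.
#' @return an [fe_mesh()]; attribute `"cell_grid"` records the structured
#'   cell layout (element index array, cell size, origin) for fast
#'   pixel-to-element lookup.
#' @export
mesh_from_mask <- function(mask, spacing, target_element_size = NULL,
                           family = NULL, min_feature_mm = NULL,
                           origin = NULL) {
  mask <- as_grid_array(mask)
  storage.mode(mask) <- "logical"
  shp <- grid_dim(mask)
  nd <- length(shp)
  if (nd < 2L || nd > 3L) stop("mask must be 2D or 3D")
  if (length(spacing) == 1L) spacing <- rep(spacing, nd)
  if (is.null(origin)) origin <- rep(0, nd)
  if (sum(mask) == 0L) stop("mask is empty")
  comp <- label_components(mask)
  ncomp <- max(comp)
  if (ncomp > 1L) {
    sizes <- tabulate(comp[comp > 0L])
    stop("mask has ", ncomp, " disconnected components (sizes ",
         paste(sizes, collapse = ", "), "); mesh each separately")
  }
  if (is.null(family)) family <- if (nd == 2L) "quad4" else "hex8"
  if (is.null(target_element_size)) target_element_size <- max(spacing)
  if (target_element_size < max(spacing) - 1e-12)
    stop("`target_element_size` must be >= pixel spacing")
  f <- pmax(1L, as.integer(round(target_element_size / spacing)))
  cell_size <- spacing * f
  cdim <- pmax(1L, shp %/% f)
  # coarse cell kept when at least half of its pixels are masked
  cmask <- array(FALSE, dim = cdim)
  cidx <- arrayInd(seq_len(prod(cdim)), .dim = cdim)
  frac <- vapply(seq_len(prod(cdim)), function(ci) {
    lo <- (cidx[ci, ] - 1L) * f + 1L
    hi <- pmin(shp, cidx[ci, ] * f)
    sub <- do.call(`[`, c(list(mask), lapply(seq_len(nd),
                                             function(a) lo[a]:hi[a])))
    mean(sub)
  }, numeric(1))
  cmask[frac >= 0.5] <- TRUE
  if (sum(cmask) == 0L) stop("no cells survive coarsening; reduce element size")

  # node lattice at cell corners used by at least one kept cell
  ndim <- cdim + 1L
  node_used <- array(FALSE, dim = ndim)
  kept <- which(cmask)
  kc <- arrayInd(kept, .dim = cdim)
  corner_offsets <- as.matrix(expand.grid(rep(list(0L:1L), nd)))
  for (r in seq_len(nrow(corner_offsets))) {
    cc <- kc + matrix(corner_offsets[r, ], nrow(kc), nd, byrow = TRUE)
    node_used[cc] <- TRUE
  }
  node_id <- array(0L, dim = ndim)
  node_id[node_used] <- seq_len(sum(node_used))
  ni <- arrayInd(which(node_used), .dim = ndim)
  nodes <- sweep(sweep(ni - 1, 2L, cell_size, `*`), 2L, origin, `+`)

  corner_id <- function(off)  # node ids of one corner for all kept cells
    node_id[kc + matrix(off, nrow(kc), nd, byrow = TRUE)]
  if (nd == 2L) {
    conn <- cbind(corner_id(c(0L, 0L)), corner_id(c(1L, 0L)),
                  corner_id(c(1L, 1L)), corner_id(c(0L, 1L)))
  } else {
    conn <- cbind(corner_id(c(0L, 0L, 0L)), corner_id(c(1L, 0L, 0L)),
                  corner_id(c(1L, 1L, 0L)), corner_id(c(0L, 1L, 0L)),
                  corner_id(c(0L, 0L, 1L)), corner_id(c(1L, 0L, 1L)),
                  corner_id(c(1L, 1L, 1L)), corner_id(c(0L, 1L, 1L)))
  }
  cell_of_element <- kept
  if (family %in% c("tri3", "tet4")) {
    if (nd == 2L && family == "tri3") {
      conn2 <- rbind(conn[, c(1L, 2L, 3L), drop = FALSE],
                     conn[, c(1L, 3L, 4L), drop = FALSE])
    } else if (nd == 3L && family == "tet4") {
      conn2 <- rbind(conn[, c(1L, 2L, 4L, 5L), drop = FALSE],
                     conn[, c(2L, 3L, 4L, 7L), drop = FALSE],
                     conn[, c(2L, 7L, 4L, 5L), drop = FALSE],
                     conn[, c(5L, 7L, 8L, 4L), drop = FALSE],
                     conn[, c(2L, 6L, 7L, 5L), drop = FALSE])
    } else stop("family ", family, " incompatible with a ", nd, "D mask")
    nsplit <- nrow(conn2) / nrow(conn)
    cell_of_element <- rep(cell_of_element, times = nsplit)
    conn <- conn2
    # minimum-feature culling of slivers
    if (is.null(min_feature_mm)) min_feature_mm <- min(0.5, min(cell_size))
    edges <- element_facets(if (nd == 2L) "tri3" else "tet4")
    if (nd == 3L) edges <- utils::combn(4L, 2L, simplify = FALSE)
    keep <- rep(TRUE, nrow(conn))
    for (e in edges) {
      d <- sqrt(rowSums((nodes[conn[, e[1]], , drop = FALSE] -
                         nodes[conn[, e[2]], , drop = FALSE])^2))
      keep <- keep & d >= min_feature_mm - 1e-12
    }
    meas <- element_measures(nodes, conn, family)
    keep <- keep & meas > 0
    conn <- conn[keep, , drop = FALSE]
    cell_of_element <- cell_of_element[keep]
  }
  # drop nodes orphaned by culling
  used <- sort(unique(as.integer(conn)))
  remap <- integer(nrow(nodes)); remap[used] <- seq_along(used)
  nodes <- nodes[used, , drop = FALSE]
  conn <- matrix(remap[conn], nrow = nrow(conn))
  mesh <- fe_mesh(nodes = nodes, elements = conn, family = family)
  elem_of_cell <- array(NA_integer_, dim = cdim)
  first_of_cell <- !duplicated(cell_of_element)
  elem_of_cell[cell_of_element[first_of_cell]] <-
    which(first_of_cell)
  attr(mesh, "cell_grid") <- list(elem_of_cell = elem_of_cell,
                                  cell_size = cell_size, origin = origin,
                                  cell_of_element = cell_of_element)
  mesh
}

#' Interpolate a grid field onto mesh nodes
#'
#' Bilinear (2D) or trilinear (3D) interpolation of every displacement
#' component and of the pixel weights from the imaging grid to the mesh
#' nodes. Stencil pixels outside the mask are dropped and the remaining
#' weights renormalized; nodes whose whole stencil is unmasked take the value
#' of the nearest masked pixel and are flagged. A node farther than one
#' element size from any masked pixel raises an error.
#'
#' @param field a [displacement_field()].
#' @param mesh an [fe_mesh()].
#' @param element_size reach (mm) beyond which a node is considered outside
#'   the data; defaults to the largest element edge estimate.
#' @return list: `values` (n_nodes x dim matrix, mm), `weights` (length
#'   n_nodes), `flagged` (indices of nearest-pixel fallback nodes).
#' @export
interpolate_to_mesh <- function(field, mesh, element_size = NULL) {
  stopifnot(inherits(field, "displacement_field"), inherits(mesh, "fe_mesh"))
  shp <- grid_dim(field$mask)
  nd <- length(shp)
  if (nd != mesh$dim) stop("field and mesh dimensionality differ")
  if (is.null(element_size)) {
    e1 <- mesh$elements[1, ]
    element_size <- max(sqrt(rowSums(
      (mesh$nodes[e1, , drop = FALSE] -
         mesh$nodes[e1[c(2:length(e1), 1)], , drop = FALSE])^2)))
  }
  nn <- nrow(mesh$nodes)
  gpos <- sweep(sweep(mesh$nodes, 2L, field$origin, `-`), 2L, field$spacing,
                `/`) + 1  # continuous 1-based pixel index
  base <- pmin(pmax(floor(gpos), 1), matrix(shp - 1L, nn, nd, byrow = TRUE))
  frac <- gpos - base
  frac <- pmin(pmax(frac, 0), 1)
  corner_offsets <- as.matrix(expand.grid(rep(list(0L:1L), nd)))
  ncr <- nrow(corner_offsets)
  vals <- matrix(0, nn, length(field$components))
  wsum <- numeric(nn)
  wfield <- numeric(nn)
  strides <- cumprod(c(1L, shp[-nd]))
  for (r in seq_len(ncr)) {
    off <- corner_offsets[r, ]
    cidx <- sweep(base, 2L, off, `+`)
    lin <- as.integer(1 + (cidx - 1) %*% strides)
    w <- rep(1, nn)
    for (a in seq_len(nd))
      w <- w * if (off[a] == 1L) frac[, a] else 1 - frac[, a]
    ok <- field$mask[lin]
    w[!ok] <- 0
    wsum <- wsum + w
    for (a in seq_along(field$components))
      vals[, a] <- vals[, a] + w * field$components[[a]][lin]
    wfield <- wfield + w * field$weights[lin]
  }
  flagged <- which(wsum < 1e-12)
  good <- wsum >= 1e-12
  vals[good, ] <- vals[good, , drop = FALSE] / wsum[good]
  wfield[good] <- wfield[good] / wsum[good]
  if (length(flagged) > 0) {
    mcoord <- grid_coordinates(shp, field$spacing, field$origin)[field$mask, ,
                                                                 drop = FALSE]
    midx <- which(field$mask)
    for (i in flagged) {
      d2 <- rowSums(sweep(mcoord, 2L, mesh$nodes[i, ], `-`)^2)
      j <- which.min(d2)
      if (sqrt(d2[j]) > element_size + 1e-9)
        stop("node ", i, " is ", signif(sqrt(d2[j]), 3),
             " mm from the nearest masked pixel (> one element size)")
      for (a in seq_along(field$components))
        vals[i, a] <- field$components[[a]][midx[j]]
      wfield[i] <- field$weights[midx[j]]
    }
  }
  list(values = vals, weights = wfield, flagged = flagged)
}

#' Crop an artifact margin off a displacement field
#'
#' Removes a rim of pixels from the mask (morphological erosion repeated
#' `margin_pixels` times with the axis-neighbour structuring element). The
#' values of surviving pixels are untouched; cropped pixels are zeroed and
#' unmasked. After cropping, the new mask rim becomes the boundary on which
#' measured displacements are prescribed, which is the partial-model remedy
#' for edge artifacts in the raw data.
#'
#' @param field a [displacement_field()].
#' @param margin_pixels number of one-pixel erosion passes (`>= 0`).
#' @return a cropped [displacement_field()].
#' @export
crop_artifact_margin <- function(field, margin_pixels) {
  stopifnot(inherits(field, "displacement_field"))
  margin_pixels <- as.integer(margin_pixels)
  if (margin_pixels < 0L) stop("`margin_pixels` must be >= 0")
  if (margin_pixels == 0L) return(field)
  mask <- field$mask
  for (k in seq_len(margin_pixels)) {
    inner <- mask
    for (off in axis_offsets(length(grid_dim(mask)))) {
      nb <- shift_array(mask, off)
      nb[is.na(nb)] <- FALSE
      inner <- inner & nb
    }
    mask <- inner
  }
  if (sum(mask) == 0L)
    stop("cropping ", margin_pixels, " pixels empties the mask")
  comps <- lapply(field$components, function(cmp) { cmp[!mask] <- 0; cmp })
  displacement_field(comps, spacing = field$spacing, origin = field$origin,
                     mask = mask, weights = field$weights)
}
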