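#' Per-element material field (density-scaled linear elasticity)
#'
#' Element stiffness follows the density parameterization of topology
#' optimization: `E_k = rho_k^p * E0`, with densities bounded away from zero
#' by `rho_min` and bounded above by 1. With the exponent `p = 1` the modulus
#' is linearly related to the density, i.e. the parameterization is
#' un-penalized and the density map reads directly as a relative-stiffness
#' map. Under pure-displacement boundary data only relative stiffness is
#' identifiable, so `E0` is an arbitrary scale (default 500 Pa).
#'
#' @param rho numeric vector of per-element densities, in `(rho_min, 1]`.
#' @param E0 baseline Young's modulus (Pa), default 500.
#' @param nu Poisson's ratio, default 0.49 (nearly incompressible soft
#'   tissue on loading time scales too short for fluid flow).
#' @param penal density exponent `p >= 1`, default 1.
#' @param rho_min lower density bound (default 0.01).
#' @return An object of class `material_field`.
#' @export
material_field <- function(rho, E0 = 500, nu = 0.49, penal = 1,
                           rho_min = 0.01) {
  rho <- as.numeric(rho)
  if (!is.finite(E0) || E0 <= 0) stop("`E0` must be positive")
  if (nu < 0 || nu >= 0.5) stop("`nu` must be in [0, 0.5)")
  if (penal < 1) stop("`penal` must be >= 1")
  if (rho_min <= 0 || rho_min >= 1) stop("`rho_min` must be in (0, 1)")
  if (any(rho < rho_min - 1e-12) || any(rho > 1 + 1e-12))
    stop("densities must lie in [rho_min, 1]")
  structure(list(rho = pmin(pmax(rho, rho_min), 1), E0 = E0, nu = nu,
                 penal = penal, rho_min = rho_min),
            class = "material_field")
}

#' Dirichlet boundary data
#'
#' Prescribed displacement vectors (all components, mm) at a set of nodes.
#'
#' @param nodes integer node indices (no duplicates).
#' @param values numeric matrix `length(nodes) x dim` of prescribed
#'   displacements (mm).
#' @return An object of class `dirichlet_bc`.
#' @export
dirichlet_bc <- function(nodes, values) {
  nodes <- as.integer(nodes)
  values <- as.matrix(values)
  if (anyDuplicated(nodes)) stop("duplicate nodes in boundary data")
  if (nrow(values) != length(nodes))
    stop("`values` must have one row per node")
  if (any(!is.finite(values))) stop("boundary values must be finite")
  structure(list(nodes = nodes, values = unname(values)),
            class = "dirichlet_bc")
}

# isotropic constitutive matrix; 2D = plane stress
constitutive_matrix <- function(E, nu, dim) {
  if (dim == 2L) {
    E / (1 - nu^2) * matrix(c(1, nu, 0,
                              nu, 1, 0,
                              0, 0, (1 - nu) / 2), 3, 3, byrow = TRUE)
  } else {
    lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
    mu <- E / (2 * (1 + nu))
    D <- diag(c(rep(2 * mu, 3), rep(mu, 3)))
    D[1:3, 1:3] <- D[1:3, 1:3] + lam
    D
  }
}

# natural coordinates of the element nodes, matching connectivity order
natural_nodes <- function(family) {
  switch(family,
    quad4 = matrix(c(-1, -1, 1, -1, 1, 1, -1, 1), 4, 2, byrow = TRUE),
    hex8 = matrix(c(-1, -1, -1, 1, -1, -1, 1, 1, -1, -1, 1, -1,
                    -1, -1, 1, 1, -1, 1, 1, 1, 1, -1, 1, 1),
                  8, 3, byrow = TRUE),
    stop("no natural coordinates for family ", family))
}

# shape-function derivatives wrt natural coordinates at one point
shape_gradients <- function(family, xi) {
  nat <- natural_nodes(family)
  nd <- ncol(nat)
  npe <- nrow(nat)
  dN <- matrix(0, npe, nd)
  for (i in seq_len(npe)) {
    for (a in seq_len(nd)) {
      g <- nat[i, a] / 2
      for (b in seq_len(nd)[-a]) g <- g * (1 + nat[i, b] * xi[b]) / 2
      dN[i, a] <- g
    }
  }
  dN
}

gauss_points <- function(dim) {
  g <- 1 / sqrt(3)
  pts <- as.matrix(expand.grid(rep(list(c(-g, g)), dim)))
  list(points = pts, weights = rep(1, nrow(pts)))
}

# strain-displacement matrix from physical shape gradients (npe x dim)
b_matrix <- function(dNx, dim) {
  npe <- nrow(dNx)
  if (dim == 2L) {
    B <- matrix(0, 3, 2 * npe)
    B[1, seq(1, 2 * npe, 2)] <- dNx[, 1]
    B[2, seq(2, 2 * npe, 2)] <- dNx[, 2]
    B[3, seq(1, 2 * npe, 2)] <- dNx[, 2]
    B[3, seq(2, 2 * npe, 2)] <- dNx[, 1]
  } else {
    B <- matrix(0, 6, 3 * npe)
    ix <- seq(1, 3 * npe, 3); iy <- ix + 1; iz <- ix + 2
    B[1, ix] <- dNx[, 1]; B[2, iy] <- dNx[, 2]; B[3, iz] <- dNx[, 3]
    B[4, ix] <- dNx[, 2]; B[4, iy] <- dNx[, 1]
    B[5, iy] <- dNx[, 3]; B[5, iz] <- dNx[, 2]
    B[6, ix] <- dNx[, 3]; B[6, iz] <- dNx[, 1]
  }
  B
}

# stiffness of one element at E = 1 (isoparametric Gauss quadrature for
# quads/hexes; closed-form constant-strain for simplices)
element_stiffness_unit <- function(coords, family, nu) {
  dim <- ncol(coords)
  D <- constitutive_matrix(1, nu, dim)
  if (family %in% c("tri3", "tet4")) {
    npe <- nrow(coords)
    Xa <- cbind(1, coords)
    vol <- det(Xa) / if (dim == 2L) 2 else 6
    if (vol <= 0) stop("degenerate simplex element")
    grads <- solve(Xa)[-1, , drop = FALSE]  # dN_i/dx as columns
    B <- b_matrix(t(grads), dim)
    return(t(B) %*% D %*% B * vol)
  }
  gp <- gauss_points(dim)
  npe <- nrow(coords)
  Ke <- matrix(0, npe * dim, npe * dim)
  for (q in seq_len(nrow(gp$points))) {
    dN <- shape_gradients(family, gp$points[q, ])
    J <- t(dN) %*% coords  # dim x dim
    detJ <- det(J)
    if (detJ <= 0) stop("inverted element Jacobian (detJ <= 0)")
    dNx <- dN %*% t(solve(J))
    B <- b_matrix(dNx, dim)
    Ke <- Ke + t(B) %*% D %*% B * detJ * gp$weights[q]
  }
  Ke
}

#' Element stiffness matrix
#'
#' Returns the isotropic linear-elastic stiffness matrix of one element with
#' modulus `E_k = rho_k^p * E0` (plane stress in 2D, full isotropic law in
#' 3D; 2x2(x2) Gauss quadrature for quads/hexes, closed form for simplices).
#'
#' @param mesh an [fe_mesh()].
#' @param element element index.
#' @param material a [material_field()].
#' @return dense matrix `(nodes_per_element * dim)` square.
#' @export
element_stiffness <- function(mesh, element, material) {
  stopifnot(inherits(mesh, "fe_mesh"), inherits(material, "material_field"))
  coords <- mesh$nodes[mesh$elements[element, ], , drop = FALSE]
  Ek <- material$rho[element]^material$penal * material$E0
  Ke <- tryCatch(element_stiffness_unit(coords, mesh$family, material$nu),
                 error = function(e)
                   stop("element ", element, ": ", conditionMessage(e)))
  Ke * Ek
}

# Precomputed assembly context: per-element unit stiffness (one shared
# matrix when all elements are congruent), dof maps and triplet indices.
fem_context <- function(mesh, nu) {
  ne <- nrow(mesh$elements)
  npe <- ncol(mesh$elements)
  dim <- mesh$dim
  nde <- npe * dim
  edof <- matrix(0L, ne, nde)
  for (k in seq_len(npe)) for (a in seq_len(dim))
    edof[, (k - 1L) * dim + a] <- (mesh$elements[, k] - 1L) * dim + a
  # per element, triplets run column-major over its unit stiffness matrix
  II <- as.vector(apply(edof, 1L, function(d) rep(d, times = nde)))
  JJ <- as.vector(apply(edof, 1L, function(d) rep(d, each = nde)))
  # congruence: all elements identical up to translation?
  ref <- mesh$nodes[mesh$elements[1, ], , drop = FALSE]
  ref <- sweep(ref, 2L, ref[1, ], `-`)
  congruent <- TRUE
  probe <- unique(c(1L, ne, seq(1L, ne, length.out = min(ne, 25L))))
  for (e in as.integer(probe)) {
    ce <- mesh$nodes[mesh$elements[e, ], , drop = FALSE]
    ce <- sweep(ce, 2L, ce[1, ], `-`)
    if (max(abs(ce - ref)) > 1e-9) { congruent <- FALSE; break }
  }
  if (congruent) {
    Ke1 <- element_stiffness_unit(mesh$nodes[mesh$elements[1, ], ,
                                             drop = FALSE], mesh$family, nu)
    KeAll <- NULL
  } else {
    Ke1 <- NULL
    KeAll <- matrix(0, nde * nde, ne)
    for (e in seq_len(ne))
      KeAll[, e] <- as.vector(element_stiffness_unit(
        mesh$nodes[mesh$elements[e, ], , drop = FALSE], mesh$family, nu))
  }
  list(mesh = mesh, nu = nu, ne = ne, nde = nde, dim = dim, edof = edof,
       II = II, JJ = JJ, Ke1 = Ke1, KeAll = KeAll,
       ndof = nrow(mesh$nodes) * dim)
}

# assemble the global stiffness for moduli E (per element, Pa)
assemble_stiffness <- function(ctx, E) {
  nv <- ctx$nde * ctx$nde
  VV <- if (!is.null(ctx$Ke1)) rep(as.vector(ctx$Ke1), ctx$ne) *
    rep(E, each = nv) else as.vector(ctx$KeAll) * rep(E, each = nv)
  Matrix::sparseMatrix(i = ctx$II, j = ctx$JJ, x = VV,
                       dims = c(ctx$ndof, ctx$ndof))
}

# dof bookkeeping for Dirichlet data
bc_dofs <- function(bc, dim, ndof) {
  pdof <- rep((bc$nodes - 1L) * dim, each = dim) + seq_len(dim)
  pvals <- as.vector(t(bc$values))
  o <- order(pdof)
  list(prescribed = pdof[o], values = pvals[o],
       free = setdiff(seq_len(ndof), pdof))
}

#' Solve the forward elasticity problem
#'
#' Assembles the global stiffness for the given density field, condenses the
#' prescribed (Dirichlet) degrees of freedom, and solves the remaining
#' sparse symmetric positive-definite system with a direct Cholesky
#' factorization. Prescribed nodes reproduce their boundary values exactly.
#'
#' @param mesh an [fe_mesh()].
#' @param material a [material_field()] with one density per element.
#' @param bc a [dirichlet_bc()]; must cover at least enough nodes to remove
#'   rigid-body motion (the inversion presets cover all boundary nodes).
#' @param ctx optional precomputed context (internal reuse).
#' @return An object of class `forward_solution`: `displacements` (n_nodes x
#'   dim, mm) and `diagnostics` (free-equation residual norm, dof counts).
#' @export
solve_forward <- function(mesh, material, bc, ctx = NULL) {
  stopifnot(inherits(mesh, "fe_mesh"), inherits(material, "material_field"),
            inherits(bc, "dirichlet_bc"))
  if (length(material$rho) != nrow(mesh$elements))
    stop("material has ", length(material$rho), " densities for ",
         nrow(mesh$elements), " elements")
  if (is.null(ctx)) ctx <- fem_context(mesh, material$nu)
  E <- material$rho^material$penal * material$E0
  K <- assemble_stiffness(ctx, E)
  dofs <- bc_dofs(bc, ctx$dim, ctx$ndof)
  Kff <- K[dofs$free, dofs$free, drop = FALSE]
  Kfp <- K[dofs$free, dofs$prescribed, drop = FALSE]
  rhs <- -as.numeric(Kfp %*% dofs$values)
  uf <- tryCatch(
    as.numeric(Matrix::solve(Matrix::Cholesky(Matrix::forceSymmetric(Kff)),
                             rhs)),
    error = function(e)
      stop("singular condensed system (insufficient boundary support?): ",
           conditionMessage(e)))
  u <- numeric(ctx$ndof)
  u[dofs$free] <- uf
  u[dofs$prescribed] <- dofs$values
  res <- as.numeric(Kff %*% uf - rhs)
  structure(list(
    displacements = matrix(u, ncol = ctx$dim, byrow = TRUE),
    diagnostics = list(residual_norm = sqrt(sum(res^2)),
                       n_free = length(dofs$free),
                       n_prescribed = length(dofs$prescribed))),
    class = "forward_solution")
}

#' @export
print.forward_solution <- function(x, ...) {
  cat("<forward_solution> ", nrow(x$displacements), " nodes, residual ",
      format(x$diagnostics$residual_norm, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Indentation loading preset
#'
#' Builds the Dirichlet data of the validation loading protocol: the bottom
#' boundary (minimum coordinate along `axis`) is fully constrained and the
#' top boundary is displaced downward by `depth_fraction` of the specimen
#' thickness, with the lateral components of the indented nodes held at zero
#' (adhered platen). Lateral boundaries are left free — this is the
#' forward-generation protocol; the inversion instead prescribes measured
#' values on every boundary node.
#'
#' @param mesh an [fe_mesh()].
#' @param depth_fraction indentation depth as a fraction of thickness, in
#'   `(0, 0.5)`; 0 returns an all-zero constraint of top and bottom.
#' @param indenter_width width (mm) of a centred indenter contact patch;
#'   `NULL` (default) indents the full top surface.
#' @param axis loading axis (default: last coordinate).
#' @return a [dirichlet_bc()].
#' @export
indentation_protocol <- function(mesh, depth_fraction,
                                 indenter_width = NULL, axis = NULL) {
  stopifnot(inherits(mesh, "fe_mesh"))
  if (depth_fraction < 0 || depth_fraction >= 0.5)
    stop("`depth_fraction` must be in [0, 0.5)")
  if (is.null(axis)) axis <- mesh$dim
  z <- mesh$nodes[, axis]
  tol <- 1e-9 + 1e-9 * diff(range(z))
  thickness <- diff(range(z))
  bottom <- which(z <= min(z) + tol)
  top <- which(z >= max(z) - tol)
  if (!is.null(indenter_width)) {
    lat <- setdiff(seq_len(mesh$dim), axis)
    ctr <- colMeans(mesh$nodes[, lat, drop = FALSE])
    d <- sqrt(rowSums(sweep(mesh$nodes[top, lat, drop = FALSE], 2L, ctr,
                            `-`)^2))
    top <- top[d <= indenter_width / 2 + tol]
    if (length(top) == 0) stop("indenter contacts no top node")
  }
  nodes <- c(bottom, top)
  values <- matrix(0, length(nodes), mesh$dim)
  values[seq_along(top) + length(bottom), axis] <-
    -depth_fraction * thickness
  dirichlet_bc(nodes = nodes, values = values)
}
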