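test_that("element stiffness scales linearly in density (p = 1)", {
  mesh <- mesh_from_mask(array(TRUE, c(3L, 3L)), spacing = 0.5)
  ne <- nrow(mesh$elements)
  m1 <- material_field(rep(0.4, ne))
  m2 <- material_field(rep(0.8, ne))
  expect_equal(element_stiffness(mesh, 1L, m2),
               2 * element_stiffness(mesh, 1L, m1), tolerance = 1e-12)
  # rigid-body translations lie in the null space
  Ke <- element_stiffness(mesh, 1L, m1)
  expect_lt(max(abs(Ke %*% rep(c(1, 0), 4))), 1e-10)
  expect_lt(max(abs(Ke %*% rep(c(0, 1), 4))), 1e-10)
})

test_that("unit-square plane-stress stiffness matches the textbook closed form", {
  # classical closed form for the bilinear square element, E = 1, nu = 0.3
  nu <- 0.3
  k <- c(1 / 2 - nu / 6, 1 / 8 + nu / 8, -1 / 4 - nu / 12, -1 / 8 + 3 * nu / 8,
         -1 / 4 + nu / 12, -1 / 8 - nu / 8, nu / 6, 1 / 8 - 3 * nu / 8)
  idx <- rbind(c(1, 2, 3, 4, 5, 6, 7, 8),
               c(2, 1, 8, 7, 6, 5, 4, 3),
               c(3, 8, 1, 6, 7, 4, 5, 2),
               c(4, 7, 6, 1, 8, 3, 2, 5),
               c(5, 6, 7, 8, 1, 2, 3, 4),
               c(6, 5, 4, 3, 2, 1, 8, 7),
               c(7, 4, 5, 2, 3, 8, 1, 6),
               c(8, 3, 2, 5, 4, 7, 6, 1))
  KE <- matrix(k[idx], 8, 8) / (1 - nu^2)
  mesh <- fe_mesh(nodes = rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)),
                  elements = matrix(1:4, 1), family = "quad4")
  mat <- material_field(1, E0 = 1, nu = nu, rho_min = 0.5)
  expect_equal(element_stiffness(mesh, 1L, mat), KE, tolerance = 1e-12)
})

test_that("degenerate element geometry raises an error naming the element", {
  nodes <- rbind(c(0, 0), c(1, 0), c(1, 0), c(0, 0))  # zero area
  expect_error(fe_mesh(nodes, matrix(1:4, 1), "quad4"), "non-positive")
})

test_that("affine boundary data reproduces the affine field (patch test)", {
  for (spec3d in c(FALSE, TRUE)) {
    mask <- if (spec3d) array(TRUE, c(4L, 4L, 4L)) else array(TRUE, c(6L, 6L))
    mesh <- mesh_from_mask(mask, spacing = 0.5)
    nd <- mesh$dim
    set.seed(5 + nd)
    A <- matrix(rnorm(nd * nd, sd = 0.01), nd, nd)
    b0 <- rnorm(nd, sd = 0.1)
    uaff <- mesh$nodes %*% t(A) + matrix(b0, nrow(mesh$nodes), nd,
                                         byrow = TRUE)
    mat <- material_field(rep(0.6, nrow(mesh$elements)))
    bc <- dirichlet_bc(mesh$boundary_nodes,
                       uaff[mesh$boundary_nodes, , drop = FALSE])
    sol <- solve_forward(mesh, mat, bc)
    expect_lt(max(abs(sol$displacements - uaff)), 1e-9)
  }
})

test_that("zero boundary data gives the zero field", {
  mesh <- mesh_from_mask(array(TRUE, c(5L, 5L)), spacing = 1)
  mat <- material_field(rep(0.5, nrow(mesh$elements)))
  bc <- dirichlet_bc(mesh$boundary_nodes,
                     matrix(0, length(mesh$boundary_nodes), 2))
  sol <- solve_forward(mesh, mat, bc)
  expect_equal(max(abs(sol$displacements)), 0)
})

test_that("a two-layer column under uniform compression strains like series springs", {
  # nu = 0 decouples the axes so the closed-form 1D series solution is exact:
  # with E ratio 2:1 the layer-average axial strains are in ratio 1:2
  mask <- array(TRUE, c(4L, 16L))
  mesh <- mesh_from_mask(mask, spacing = 0.5)
  cen <- element_centroids(mesh)
  top <- cen[, 2] > 4
  mat <- material_field(ifelse(top, 1, 0.5), E0 = 1000, nu = 0)
  z <- mesh$nodes[, 2]
  bottom_n <- which(z < 1e-9); top_n <- which(z > 8 - 1e-9)
  bc <- dirichlet_bc(c(bottom_n, top_n),
                     rbind(matrix(0, length(bottom_n), 2),
                           cbind(0, rep(-0.8, length(top_n)))))
  sol <- solve_forward(mesh, mat, bc)
  uy <- sol$displacements[, 2]
  # interface displacement: strain_bottom/strain_top = E_top/E_bottom = 2
  mid <- which(abs(z - 4) < 1e-9)
  u_mid <- mean(uy[mid])
  strain_bottom <- u_mid / 4
  strain_top <- (-0.8 - u_mid) / 4
  expect_equal(strain_bottom / strain_top, 2, tolerance = 1e-6)
})

test_that("pure-Dirichlet solutions are invariant to the arbitrary modulus scale", {
  case <- coarse_bilayer()
  mesh <- case$mesh
  bc <- dirichlet_bc(mesh$boundary_nodes,
                     case$solution$displacements[mesh$boundary_nodes, ])
  s1 <- solve_forward(mesh, material_field(case$truth$rho, E0 = 500), bc)
  s2 <- solve_forward(mesh, material_field(case$truth$rho, E0 = 4937), bc)
  expect_equal(s1$displacements, s2$displacements, tolerance = 1e-10)
})

test_that("the assembled stiffness is symmetric", {
  mesh <- mesh_from_mask(array(TRUE, c(4L, 3L)), spacing = 0.3)
  mat <- material_field(runif(nrow(mesh$elements), 0.2, 1))
  ctx <- fdelast:::fem_context(mesh, mat$nu)
  K <- fdelast:::assemble_stiffness(ctx, mat$rho * mat$E0)
  expect_lt(max(abs(K - Matrix::t(K))) / max(abs(K)), 1e-12)
})

test_that("interior displacements converge at second order under refinement", {
  # divergence-free field with harmonic components solves the Navier
  # equations with no body force for any isotropic material; the
  # transcendental choice avoids superconvergent nodal exactness
  exact <- function(p) cbind(exp(p[, 1]) * cos(p[, 2]),
                             -exp(p[, 1]) * sin(p[, 2]))
  err_at <- function(n) {
    mesh <- mesh_from_mask(array(TRUE, c(n, n)), spacing = 2 / n)
    mat <- material_field(rep(1, nrow(mesh$elements)), E0 = 1, nu = 0.3,
                          rho_min = 0.5)
    ua <- exact(mesh$nodes)
    bc <- dirichlet_bc(mesh$boundary_nodes,
                       ua[mesh$boundary_nodes, , drop = FALSE])
    sol <- solve_forward(mesh, mat, bc)
    max(abs(sol$displacements - ua))
  }
  e1 <- err_at(8L); e2 <- err_at(16L)
  expect_gt(e1 / e2, 3)  # O(h^2) predicts a factor ~4
})

test_that("the indentation preset prescribes the documented displacements", {
  mesh <- mesh_from_mask(array(TRUE, c(10L, 10L)), spacing = 0.6)  # 6 x 6 mm
  bc0 <- indentation_protocol(mesh, 0)
  expect_equal(max(abs(bc0$values)), 0)
  bc <- indentation_protocol(mesh, 0.15)
  z <- mesh$nodes[bc$nodes, 2]
  expect_equal(unique(bc$values[z > 5.9, 2]), -0.9)   # 15% of 6 mm
  expect_equal(max(abs(bc$values[z < 0.1, ])), 0)
  expect_error(indentation_protocol(mesh, 0.7), "depth_fraction")

  # a narrow indenter only moves the contact patch
  bcn <- indentation_protocol(mesh, 0.15, indenter_width = 2)
  topn <- bcn$nodes[mesh$nodes[bcn$nodes, 2] > 5.9]
  expect_true(all(abs(mesh$nodes[topn, 1] - 3) <= 1 + 1e-9))
  expect_lt(length(topn), sum(mesh$nodes[, 2] > 5.9))
})
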