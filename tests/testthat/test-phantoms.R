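test_that("ground-truth rasterization assigns moduli by centroid membership", {
  case_spec <- phantom_spec(
    geometry = list(type = "rectangle", width = 6, height = 6),
    pattern = list(type = "bilayer", top_fraction = 0.5, E_top = 1000,
                   E_bottom = 500), spacing = 0.5)
  truth <- rasterize_truth(case_spec)
  expect_setequal(unique(truth$rho), c(1, 0.5))
  expect_equal(mean(truth$labels == "top"), 0.5)

  hom <- phantom_spec(geometry = list(type = "rectangle", width = 3,
                                      height = 3),
                      pattern = list(type = "homogeneous", E = 500),
                      spacing = 0.5)
  expect_true(all(rasterize_truth(hom)$rho == 1))

  # zero-radius inclusion captures no element centroid
  inc0 <- phantom_spec(
    geometry = list(type = "rectangle", width = 3, height = 3),
    pattern = list(type = "inclusions", E_background = 500,
                   centers = rbind(c(1.5, 1.5)), radii = 0, moduli = 1500),
    spacing = 0.5)
  expect_true(all(rasterize_truth(inc0)$labels == "background"))
})

test_that("generated displacements honour the loading protocol exactly", {
  case <- coarse_bilayer()
  f <- case$field
  ny <- dim(f$mask)[2]
  # 15% of 6 mm: top pixels at -0.9 mm axially, bottom pixels fixed
  expect_equal(unique(f$components[[2]][, ny]), -0.9)
  expect_equal(unique(f$components[[2]][, 1]), 0)
  expect_equal(unique(f$components[[1]][, 1]), 0)

  zero <- phantom_spec(geometry = list(type = "rectangle", width = 3,
                                       height = 3),
                       pattern = list(type = "homogeneous", E = 500),
                       indent_fraction = 0, spacing = 0.5)
  z <- generate_displacements(zero)
  expect_equal(max(abs(z$field$components[[2]])), 0)
})

test_that("fixtures are deterministic and self-consistent", {
  a <- end_to_end_case("bilayer2d", noise_sigma = 0.1, seed = 7L,
                       spacing = 0.5)
  b <- end_to_end_case("bilayer2d", noise_sigma = 0.1, seed = 7L,
                       spacing = 0.5)
  expect_identical(a$field, b$field)

  # noise-free displacements re-inserted as Dirichlet data reproduce
  # themselves through the forward solver
  case <- coarse_bilayer()
  bc <- dirichlet_bc(case$mesh$boundary_nodes,
                     case$solution$displacements[case$mesh$boundary_nodes, ])
  sol <- solve_forward(case$mesh, material_field(case$truth$rho), bc)
  expect_equal(sol$displacements, case$solution$displacements,
               tolerance = 1e-9)
})

test_that("the 3D cylinder case is a two-layer 2:1 phantom on hexahedra", {
  spec <- phantom_spec(
    geometry = list(type = "cylinder", radius = 5, height = 6),
    pattern = list(type = "bilayer", top_fraction = 1 / 3, E_top = 1000,
                   E_bottom = 500), spacing = 1)
  mesh <- phantom_mesh(spec)
  expect_equal(mesh$family, "hex8")
  expect_equal(mesh$dim, 3L)
  truth <- rasterize_truth(spec, mesh)
  rr <- region_ratio(truth$E, truth$labels)
  expect_equal(unname(rr$ratios["top", "bottom"]), 2)
  # all voxel centres lie inside the cylinder radius
  cen <- element_centroids(mesh)
  ctr <- colMeans(mesh$nodes[, 1:2])
  expect_true(all(sqrt(rowSums(sweep(cen[, 1:2], 2, ctr, `-`)^2)) <= 5))
})

test_that("unknown case names are rejected", {
  expect_error(end_to_end_case("spiral"), "unknown case")
})
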