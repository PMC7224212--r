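test_that("a full rectangle meshes into the expected structured grid", {
  # 6 mm x 6 mm at 0.15 mm elements: 40 x 40 quads, 41 x 41 nodes
  mask <- array(TRUE, c(40L, 40L))
  mesh <- mesh_from_mask(mask, spacing = 0.15)
  expect_equal(nrow(mesh$elements), 1600L)
  expect_equal(nrow(mesh$nodes), 41L^2)
  expect_equal(mesh$family, "quad4")

  # boundary nodes are exactly the perimeter nodes
  onper <- which(mesh$nodes[, 1] %in% range(mesh$nodes[, 1]) |
                 mesh$nodes[, 2] %in% range(mesh$nodes[, 2]))
  expect_setequal(mesh$boundary_nodes, onper)

  # total mesh area equals the masked area
  expect_equal(sum(fdelast:::element_measures(mesh$nodes, mesh$elements,
                                              mesh$family)),
               40^2 * 0.15^2, tolerance = 1e-10)
})

test_that("every interior facet is shared by exactly two elements", {
  mesh <- mesh_from_mask(array(TRUE, c(6L, 5L)), spacing = 1)
  tab <- fdelast:::facet_table(mesh)
  expect_true(all(tab %in% c(1L, 2L)))
  mesh3 <- mesh_from_mask(array(TRUE, c(3L, 3L, 3L)), spacing = 1)
  tab3 <- fdelast:::facet_table(mesh3)
  expect_true(all(tab3 %in% c(1L, 2L)))
  expect_equal(sum(tab3 == 1L), 6L * 9L)  # cube surface quads
})

test_that("a circular mask meshes into valid simplices near the rim", {
  n <- 24L
  xc <- (seq_len(n) - 0.5)
  mask <- outer((xc - n / 2)^2, (xc - n / 2)^2, `+`) <= (n / 2 - 1)^2
  mesh <- mesh_from_mask(mask, spacing = 0.3, family = "tri3",
                         min_feature_mm = 0.1)
  meas <- fdelast:::element_measures(mesh$nodes, mesh$elements, mesh$family)
  expect_true(all(meas > 0))
  # boundary nodes lie within one pixel of the mask rim
  ctr <- c(n / 2, n / 2) * 0.3
  r <- sqrt(rowSums(sweep(mesh$nodes[mesh$boundary_nodes, ], 2, ctr, `-`)^2))
  expect_true(all(r >= (n / 2 - 3) * 0.3))
})

test_that("degenerate masks are rejected with informative errors", {
  expect_error(mesh_from_mask(array(FALSE, c(4L, 4L)), 1), "empty")
  split <- array(TRUE, c(7L, 3L)); split[4L, ] <- FALSE
  expect_error(mesh_from_mask(split, 1), "disconnected")
  expect_error(mesh_from_mask(array(TRUE, c(4L, 4L)), 1,
                              target_element_size = 0.5), ">= pixel spacing")
})

test_that("grid-to-mesh interpolation is exact on coincident and affine data", {
  fld <- affine_field(nx = 13, ny = 11, spacing = 0.4)
  mesh <- mesh_from_mask(array(TRUE, c(12L, 10L)), spacing = 0.4)
  out <- interpolate_to_mesh(fld, mesh)
  # nodes coincide with pixels: exact pass-through
  truth <- cbind(0.02 * mesh$nodes[, 1] + 0.005 * mesh$nodes[, 2] + 0.1,
                 -0.01 * mesh$nodes[, 1] + 0.03 * mesh$nodes[, 2] - 0.2)
  expect_equal(out$values, truth, tolerance = 1e-12)
  expect_length(out$flagged, 0L)

  # coarser mesh nodes between pixels: bilinear reproduces affine exactly
  mesh2 <- mesh_from_mask(array(TRUE, c(12L, 10L)), spacing = 0.4,
                          target_element_size = 0.8)
  out2 <- interpolate_to_mesh(fld, mesh2)
  truth2 <- cbind(0.02 * mesh2$nodes[, 1] + 0.005 * mesh2$nodes[, 2] + 0.1,
                  -0.01 * mesh2$nodes[, 1] + 0.03 * mesh2$nodes[, 2] - 0.2)
  expect_equal(out2$values, truth2, tolerance = 1e-12)
})

test_that("interpolation matches a brute-force bilinear oracle on random data", {
  set.seed(31)
  nx <- 9L; ny <- 8L; sp <- 0.7
  comps <- list(matrix(rnorm(nx * ny), nx, ny), matrix(rnorm(nx * ny), nx, ny))
  fld <- displacement_field(comps, spacing = sp)
  pts <- cbind(runif(40, 0.1, (nx - 1) * sp - 0.1),
               runif(40, 0.1, (ny - 1) * sp - 0.1))
  # brute-force oracle: locate the pixel cell, evaluate the tensor product
  oracle <- function(p, comp) {
    gx <- p[1] / sp + 1; gy <- p[2] / sp + 1
    i <- floor(gx); j <- floor(gy)
    fx <- gx - i; fy <- gy - j
    comp[i, j] * (1 - fx) * (1 - fy) + comp[i + 1, j] * fx * (1 - fy) +
      comp[i, j + 1] * (1 - fx) * fy + comp[i + 1, j + 1] * fx * fy
  }
  mesh <- fe_mesh(nodes = rbind(pts, c(0, 0), c((nx - 1) * sp, 0),
                                c((nx - 1) * sp, (ny - 1) * sp),
                                c(0, (ny - 1) * sp)),
                  elements = cbind(41L, 42L, 43L, 44L), family = "quad4",
                  check = FALSE)
  out <- interpolate_to_mesh(fld, mesh, element_size = max(pts))
  for (k in seq_len(40)) {
    expect_equal(out$values[k, 1], oracle(pts[k, ], comps[[1]]),
                 tolerance = 1e-12)
    expect_equal(out$values[k, 2], oracle(pts[k, ], comps[[2]]),
                 tolerance = 1e-12)
  }
})

test_that("artifact-margin cropping erodes the mask as specified", {
  fld <- affine_field(nx = 40, ny = 40, spacing = 0.15)
  expect_identical(crop_artifact_margin(fld, 0), fld)
  cropped <- crop_artifact_margin(fld, 2)
  expect_equal(sum(cropped$mask), 36L * 36L)
  expect_error(crop_artifact_margin(fld, 60), "empties")
})
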