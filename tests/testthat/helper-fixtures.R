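# Small fixtures shared across tests. Everything is generated in code; sizes
# are kept small so the whole suite stays light.

quick_settings <- function(...) {
  optimizer_settings(max_iterations = 60L, ...)
}

# tiny rectangular displacement field with a linear (affine) pattern
affine_field <- function(nx = 12L, ny = 10L, spacing = 0.5,
                         a = c(0.02, -0.01), b = c(0.005, 0.03),
                         c0 = c(0.1, -0.2)) {
  xs <- (seq_len(nx) - 1) * spacing
  ys <- (seq_len(ny) - 1) * spacing
  X <- matrix(xs, nx, ny)
  Y <- matrix(ys, nx, ny, byrow = TRUE)
  displacement_field(
    components = list(a[1] * X + b[1] * Y + c0[1],
                      a[2] * X + b[2] * Y + c0[2]),
    spacing = spacing)
}

# coarse bilayer bundle used by several inversion tests
coarse_bilayer <- function(spacing = 0.5) {
  end_to_end_case("bilayer2d", spacing = spacing)
}
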