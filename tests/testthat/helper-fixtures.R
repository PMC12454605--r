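# Shared fixtures, built in code. Geometry is millimetres; a "standard"
# vessel is a 0.6 mm radius, 3 mm long tube with a 0.06 mm wall.

cylinder_mesh <- function(n_axial = 26L, n_circ = 32L, radius = 0.6,
                          length = 3, ...) {
  make_tube_mesh(tube_spec(radius = radius, length = length,
                           n_axial = n_axial, n_circ = n_circ, ...))
}

# closed octahedron: a manifold surface with no boundary
octahedron_mesh_raw <- function() {
  v <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
             c(0, 0, 1), c(0, 0, -1))
  f <- rbind(c(1, 3, 5), c(3, 2, 5), c(2, 4, 5), c(4, 1, 5),
             c(3, 1, 6), c(2, 3, 6), c(4, 2, 6), c(1, 4, 6))
  list(vertices = v, triangles = f)
}

test_ctx <- hemo_context()

straight_profile <- function(n_elements = 26L, radius = 0.6, length = 3,
                             ctx = test_ctx) {
  s <- seq(0, 1, length.out = n_elements)
  R <- deflate_radii(rep(radius, n_elements), ctx$wall$thickness, ctx$mu,
                     ctx$hemo$pressure)
  tube_profile(s, R, rep(length / (n_elements - 1L), n_elements - 1L))
}

# growth parameters with uniform targets equal to scale * baseline mean
std_params <- function(profile = straight_profile(), ctx = test_ctx, ...) {
  default_growth_params(ctx, profile, ...)
}

constant_waveform <- function(Q, period = 0.15, n = 100L) {
  structure(list(time = seq(0, period, length.out = n + 1L)[-(n + 1L)],
                 Q = rep(Q, n), period = period, mean_flow = Q),
            class = "flow_waveform")
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual / expected - 1)), tol)
}
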