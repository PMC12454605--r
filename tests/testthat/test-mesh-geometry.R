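test_that("boundary loop detection distinguishes closed and open surfaces", {
  oct <- octahedron_mesh_raw()
  expect_error(surface_mesh(oct$vertices, oct$triangles),
               "expected 2 boundary loops, found 0")

  m <- cylinder_mesh(n_axial = 10L, n_circ = 12L)
  expect_s3_class(m, "surface_mesh")
  expect_length(m$inlet_loop, 12L)
  expect_length(m$outlet_loop, 12L)
  expect_length(intersect(m$inlet_loop, m$outlet_loop), 0L)
  # inlet labelled at the low-z end
  expect_lt(mean(m$vertices[m$inlet_loop, 3]),
            mean(m$vertices[m$outlet_loop, 3]))
})

test_that("mesh validation rejects malformed input", {
  m <- cylinder_mesh(n_axial = 8L, n_circ = 8L)
  expect_error(surface_mesh(m$vertices, rbind(m$triangles, c(1, 1, 2))),
               "degenerate triangle")
  expect_error(surface_mesh(m$vertices, rbind(m$triangles, c(1, 2, 999))),
               "out of range")
  # duplicating one face makes its edges 3-valent
  expect_error(surface_mesh(m$vertices, rbind(m$triangles, m$triangles[1, ])),
               "non-manifold")
})

test_that("write/read round-trips preserve the vertex set for STL, OBJ, VTK", {
  m <- cylinder_mesh(n_axial = 10L, n_circ = 12L)
  for (fmt in c("stl", "obj", "vtk")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_mesh(m, path)
    m2 <- read_mesh(path)
    # same vertex multiset up to reordering (STL re-merges facet corners)
    key <- function(v) sort(apply(signif(v, 6), 1, paste, collapse = ","))
    expect_identical(key(m2$vertices), key(m$vertices))
    expect_identical(nrow(m2$triangles), nrow(m$triangles))
  }
  expect_error(read_mesh(tempfile(fileext = ".stl")), "not found")
})

test_that("binary STL files are read", {
  # two-triangle square patch, written in the 50-byte-record binary layout
  tri <- list(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)),
              rbind(c(0, 0, 0), c(1, 1, 0), c(0, 1, 0)))
  path <- withr::local_tempfile(fileext = ".stl")
  con <- file(path, "wb")
  writeBin(raw(80L), con)
  writeBin(length(tri), con, size = 4L, endian = "little")
  for (p in tri) {
    writeBin(as.numeric(c(0, 0, 1, t(p))), con, size = 4L, endian = "little")
    writeBin(raw(2L), con)
  }
  close(con)
  m <- read_mesh(path, require_tube = FALSE)
  expect_identical(nrow(m$vertices), 4L)
  expect_identical(nrow(m$triangles), 2L)
})

test_that("ring extraction places equally spaced rings along the axial field", {
  m <- cylinder_mesh()
  s <- solve_axial_coordinate(m)
  rs <- extract_rings(m, s, n_rings = 6L)
  expect_identical(rs$n_rings, 6L)
  z_levels <- vapply(rs$rings, function(r) mean(r[, 3]), numeric(1))
  expect_equal(z_levels, seq(0, 3, length.out = 6L), tolerance = 1e-9)
  # each ring planar: all z within the ring identical
  for (r in rs$rings) expect_lt(diff(range(r[, 3])), 1e-9)

  rs2 <- extract_rings(m, s, n_rings = 2L)
  expect_identical(sort(rs2$vertex_ids[[1]]), sort(m$inlet_loop))
  expect_identical(sort(rs2$vertex_ids[[2]]), sort(m$outlet_loop))

  # 7 rings put targets between vertex rows; a vanishing band finds nothing
  expect_error(extract_rings(m, s, n_rings = 7L, band_width = 1e-6),
               "captured no vertices")
})

test_that("rings on a bent tube stay within their axial bands", {
  m <- make_tube_mesh(tube_spec(curvature = 0.15, n_axial = 20L,
                                n_circ = 16L))
  s <- solve_axial_coordinate(m)
  rs <- extract_rings(m, s, n_rings = 6L)
  expect_length(rs$rings, 6L)
  for (j in seq_len(6L)) {
    sv <- s[rs$vertex_ids[[j]]]
    expect_true(all(abs(sv - rs$targets[j]) <= 0.5 / 5 + 1e-12))
  }
})

test_that("ring_radius is the mean distance to the centroid", {
  ang <- 2 * pi * (0:99) / 100
  circ <- cbind(2 * cos(ang), 2 * sin(ang), 0)
  expect_equal(ring_radius(circ), 2, tolerance = 1e-12)
  expect_equal(ring_radius(rbind(c(1, 0, 0), c(-1, 0, 0),
                                 c(0, 1, 0), c(0, -1, 0))), 1)
  expect_error(ring_radius(rbind(c(0, 0, 0), c(1, 0, 0))), "at least 3")
})

test_that("ring_radius is unbiased under small iid noise (Monte Carlo)", {
  # oracle: E[radius] for sigma = 0.01 on R = 1 stays within 0.005 of 1
  set.seed(101)
  ang <- 2 * pi * (0:99) / 100
  base <- cbind(cos(ang), sin(ang), 0)
  est <- vapply(1:1000, function(k)
    ring_radius(base + matrix(rnorm(300, sd = 0.01), ncol = 3)),
    numeric(1))
  expect_lt(abs(mean(est) - 1), 0.005)
})

test_that("ring_radius is invariant under rigid motion", {
  set.seed(5)
  pts <- cbind(cos(1:40), sin(1:40), rnorm(40, sd = 0.05))
  ax <- c(1, 2, 3) / sqrt(14)
  th <- 0.83
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
  Rot <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  moved <- pts %*% t(Rot) + matrix(c(5, -2, 7), 40, 3, byrow = TRUE)
  expect_lt(abs(ring_radius(moved) - ring_radius(pts)), 1e-10)
})

test_that("segment lengths sum to the total polyline length", {
  mk_ring <- function(center) {
    ang <- 2 * pi * (0:23) / 24
    sweep(cbind(0.3 * cos(ang), 0.3 * sin(ang), 0), 2, center, `+`)
  }
  rings <- lapply(0:5, function(z) mk_ring(c(0, 0, z)))
  rm6 <- segment_lengths(rings)
  expect_equal(rm6$segment_lengths, rep(1, 5))
  expect_equal(rm6$total_length, 5)

  expect_warning(segment_lengths(list(mk_ring(c(0, 0, 0)),
                                      mk_ring(c(0, 0, 0)))),
                 "zero segment length")

  # rings along a circular arc: oracle is the independent chord-sum
  arc_centers <- t(vapply(seq(0, pi / 2, length.out = 6),
                          function(a) c(10 * cos(a), 10 * sin(a), 0),
                          numeric(3)))
  rings_arc <- lapply(seq_len(6), function(i) mk_ring(arc_centers[i, ]))
  oracle <- sum(sqrt(rowSums(diff(arc_centers)^2)))
  expect_equal(segment_lengths(rings_arc)$total_length, oracle,
               tolerance = 1e-12)
})

test_that("total length is additive under ring refinement on a straight axis", {
  mk_ring <- function(z) {
    ang <- 2 * pi * (0:23) / 24
    cbind(0.5 * cos(ang), 0.5 * sin(ang), rep(z, 24))
  }
  coarse <- segment_lengths(lapply(seq(0, 4, by = 2), mk_ring))
  fine <- segment_lengths(lapply(seq(0, 4, by = 0.5), mk_ring))
  expect_equal(coarse$total_length, fine$total_length, tolerance = 1e-12)
})

test_that("measured ring radii on an ideal cylinder are exact to 0.5%", {
  m <- cylinder_mesh(n_circ = 64L)
  mm <- measure_mesh(m)
  expect_rel_equal(mm$radii, 0.6, 0.005)
  expect_equal(mm$total_length, 3, tolerance = 1e-6)
})

test_that("ring metrics export as CSV", {
  mm <- measure_mesh(cylinder_mesh(n_axial = 11L, n_circ = 16L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_ring_metrics(mm, path)
  df <- read.csv(path)
  expect_identical(nrow(df), 6L)
  expect_equal(df$radius_mm, mm$radii)
})
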