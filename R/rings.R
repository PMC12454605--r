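# Ring-based geometry measurements: equally spaced rings along the harmonic
# axial coordinate, ring radii as mean point-to-centroid distance, and axial
# segment lengths between consecutive ring centroids.

#' Extract equally spaced rings along an axial field
#'
#' Ring `j` (j = 1..n_rings) collects the mesh vertices whose axial
#' coordinate falls in a half-open band of width `1/(n_rings - 1)` centred on
#' the target value `(j - 1)/(n_rings - 1)`. The first and last bands are
#' clipped at 0 and 1 so the inlet and outlet vertices are always captured.
#'
#' @param mesh a [surface_mesh].
#' @param axial_field per-vertex axial coordinate in `[0, 1]`, typically from
#'   [solve_axial_coordinate()].
#' @param n_rings number of rings (default 6).
#' @param band_width optional band width as a fraction of the inter-ring
#'   spacing; the default (`NULL`) uses an adaptive band that captures the
#'   vertex row nearest each target (the closest vertices plus a 2%-of-
#'   spacing tolerance), which keeps the ring thin so the mean-distance
#'   radius is not inflated by axial spread.
#' @return an object of class `ring_set`: list with `rings` (list of point
#'   matrices, mm), `vertex_ids`, `n_rings`, `targets`.
#' @export
extract_rings <- function(mesh, axial_field, n_rings = 6L, band_width = NULL) {
  n_rings <- as.integer(n_rings)
  if (n_rings < 2L) stop_vg("need at least 2 rings")
  if (length(axial_field) != nrow(mesh$vertices))
    stop_vg("axial_field must have one value per vertex")
  if (any(axial_field < -1e-9 | axial_field > 1 + 1e-9))
    stop_vg("axial_field values must lie in [0, 1]")
  targets <- seq(0, 1, length.out = n_rings)
  spacing <- 1 / (n_rings - 1L)
  rings <- vector("list", n_rings)
  ids <- vector("list", n_rings)
  for (j in seq_len(n_rings)) {
    d <- abs(axial_field - targets[j])
    if (is.null(band_width)) {
      half <- min(d) + 0.02 * spacing
      sel <- d <= half
      if (sum(sel) < 3L) {          # widen to the 3 nearest vertices
        half <- sort(d)[3L]
        sel <- d <= half
      }
    } else {
      half <- 0.5 * band_width * spacing
      lo <- targets[j] - half
      hi <- targets[j] + half
      # half-open bands [lo, hi) except the last, closed at 1
      sel <- if (j == n_rings) axial_field >= lo
             else axial_field >= lo & axial_field < hi
    }
    if (!any(sel))
      stop_vg(paste0("ring %d (s = %.3f) captured no vertices; ",
                     "widen band_width or refine the mesh"), j, targets[j])
    ids[[j]] <- which(sel)
    rings[[j]] <- mesh$vertices[sel, , drop = FALSE]
  }
  structure(list(rings = rings, vertex_ids = ids, n_rings = n_rings,
                 targets = targets),
            class = "ring_set")
}

#' Mean-distance ring radius
#'
#' Radius of a ring of surface points, defined as the mean Euclidean distance
#' from each point to the ring's arithmetic centroid. Invariant under rigid
#' motions of the point set.
#'
#' @param ring numeric k x 3 matrix of point positions (mm), k >= 3.
#' @return radius in mm.
#' @export
ring_radius <- function(ring) {
  ring <- as.matrix(ring)
  if (nrow(ring) < 3L) stop_vg("ring_radius needs at least 3 points")
  ctr <- colMeans(ring)
  mean(sqrt(rowSums(sweep(ring, 2L, ctr)^2)))
}

#' Ring metrics: radii, centroids, segment lengths, total length
#'
#' Computes for every ring the mean-distance radius and centroid, the
#' distances between consecutive centroids (segment lengths `L_c`), and the
#' total axial length `l` as the sum of segment lengths.
#'
#' @param ring_set a [ring_set][extract_rings] (or plain list of point
#'   matrices).
#' @return an object of class `ring_metrics`: `radii` (mm), `centroids`
#'   (n x 3, mm), `segment_lengths` (n-1, mm), `total_length` (mm).
#' @export
segment_lengths <- function(ring_set) {
  rings <- if (inherits(ring_set, "ring_set")) ring_set$rings else ring_set
  if (length(rings) < 2L) stop_vg("need at least 2 rings")
  radii <- vapply(rings, ring_radius, numeric(1))
  centroids <- t(vapply(rings, colMeans, numeric(3)))
  d <- diff(centroids)
  seg <- sqrt(rowSums(d^2))
  if (any(seg == 0))
    warn_vg("coincident ring centroids: zero segment length")
  ring_metrics(radii, seg, centroids = centroids)
}

#' Construct ring metrics directly
#'
#' @param radii per-ring radii (mm), all > 0.
#' @param seg segment lengths between consecutive ring centroids (mm).
#' @param centroids optional n x 3 centroid matrix; defaults to points on the
#'   z axis at cumulative segment positions.
#' @return a `ring_metrics` object.
#' @export
ring_metrics <- function(radii, seg, centroids = NULL) {
  if (any(radii <= 0)) stop_vg("ring radii must be positive")
  if (length(seg) != length(radii) - 1L)
    stop_vg("need one segment length per consecutive ring pair")
  if (is.null(centroids))
    centroids <- cbind(0, 0, c(0, cumsum(seg)))
  structure(list(radii = as.numeric(radii),
                 centroids = as.matrix(centroids),
                 segment_lengths = as.numeric(seg),
                 total_length = sum(seg)),
            class = "ring_metrics")
}

#' @export
print.ring_metrics <- function(x, ...) {
  cat(sprintf("ring_metrics: %d rings, total length %.3f mm\n",
              length(x$radii), x$total_length))
  print(data.frame(ring = seq_along(x$radii),
                   radius_mm = round(x$radii, 4),
                   segment_length_mm = round(c(x$segment_lengths, NA), 4)))
  invisible(x)
}

#' Measure a tube mesh: harmonic coordinate, rings, metrics
#'
#' Convenience wrapper running [solve_axial_coordinate()], [extract_rings()]
#' and [segment_lengths()] on one mesh.
#'
#' @inheritParams extract_rings
#' @return a `ring_metrics` object.
#' @export
measure_mesh <- function(mesh, n_rings = 6L, band_width = NULL) {
  s <- solve_axial_coordinate(mesh)
  segment_lengths(extract_rings(mesh, s, n_rings = n_rings,
                                band_width = band_width))
}

#' Export ring metrics as CSV
#'
#' @param metrics a `ring_metrics` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ring_metrics <- function(metrics, path) {
  df <- data.frame(ring_index = seq_along(metrics$radii),
                   radius_mm = metrics$radii,
                   centroid_x = metrics$centroids[, 1],
                   centroid_y = metrics$centroids[, 2],
                   centroid_z = metrics$centroids[, 3],
                   segment_length_mm = c(metrics$segment_lengths, NA))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
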