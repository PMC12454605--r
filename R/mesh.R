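# Triangulated tube-surface data model and standard-format I/O.
#
# Geometry is kept in millimetres throughout the package. A valid tube wall
# is an orientable manifold triangle mesh with exactly two open boundary
# loops (inlet and outlet).

#' Construct a triangulated surface mesh
#'
#' Builds the package's mesh container from a vertex matrix and a triangle
#' index matrix, checks edge-manifoldness, and detects the open boundary
#' loops. A tube wall must have exactly two boundary loops; they are labelled
#' inlet/outlet by the axial (z) order of their centroids unless overridden.
#'
#' @param vertices numeric n x 3 matrix of vertex positions (mm).
#' @param triangles integer m x 3 matrix of 1-based vertex indices.
#' @param inlet,outlet optional integer vectors giving the boundary loops
#'   explicitly (ordered vertex indices); if `NULL` they are auto-detected.
#' @param require_tube if `TRUE` (default) fail unless exactly two boundary
#'   loops are present.
#' @return an object of class `surface_mesh` with fields `vertices`,
#'   `triangles`, `inlet_loop`, `outlet_loop`.
#' @export
surface_mesh <- function(vertices, triangles, inlet = NULL, outlet = NULL,
                         require_tube = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (ncol(vertices) != 3L) stop_vg("vertices must be an n x 3 matrix")
  if (ncol(triangles) != 3L) stop_vg("triangles must be an m x 3 matrix")
  n <- nrow(vertices)
  if (any(triangles < 1L) || any(triangles > n))
    stop_vg("triangle indices out of range [1, %d]", n)
  if (any(triangles[, 1] == triangles[, 2] |
          triangles[, 2] == triangles[, 3] |
          triangles[, 1] == triangles[, 3]))
    stop_vg("degenerate triangle with repeated vertex index")

  ed <- mesh_edges(triangles)
  if (any(ed$count > 2L))
    stop_vg("non-manifold mesh: edge shared by %d triangles",
            max(ed$count))

  if (is.null(inlet) || is.null(outlet)) {
    loops <- boundary_loops(triangles)
    if (require_tube && length(loops) != 2L)
      stop_vg("expected 2 boundary loops, found %d", length(loops))
    if (length(loops) == 2L) {
      z1 <- mean(vertices[loops[[1]], 3])
      z2 <- mean(vertices[loops[[2]], 3])
      if (z1 <= z2) {
        inlet <- loops[[1]]; outlet <- loops[[2]]
      } else {
        inlet <- loops[[2]]; outlet <- loops[[1]]
      }
    }
  }
  if (!is.null(inlet) && !is.null(outlet) &&
      length(intersect(inlet, outlet)) > 0L)
    stop_vg("inlet and outlet loops must be disjoint")

  structure(list(vertices = vertices, triangles = triangles,
                 inlet_loop = as.integer(inlet),
                 outlet_loop = as.integer(outlet)),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf(
    "surface_mesh: %d vertices, %d triangles, inlet loop %d / outlet loop %d vertices\n",
    nrow(x$vertices), nrow(x$triangles),
    length(x$inlet_loop), length(x$outlet_loop)))
  invisible(x)
}

# Undirected edge table with incidence counts.
mesh_edges <- function(triangles) {
  e <- rbind(triangles[, c(1, 2)], triangles[, c(2, 3)], triangles[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tab <- table(key)
  first <- !duplicated(key)
  list(edges = e[first, , drop = FALSE],
       key = key, count = as.integer(tab[key[first]]))
}

# Ordered boundary loops: boundary edges are those used by exactly one
# triangle; they are chained head-to-tail using the triangle orientation.
boundary_loops <- function(triangles) {
  e <- rbind(triangles[, c(1, 2)], triangles[, c(2, 3)], triangles[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key)
  bnd <- e[cnt[key] == 1L, , drop = FALSE]
  if (nrow(bnd) == 0L) return(list())
  # boundary edges are oriented consistently; map from -> to
  nxt <- integer(0)
  nxt[bnd[, 1]] <- bnd[, 2]
  visited <- rep(FALSE, max(bnd))
  loops <- list()
  for (start in bnd[, 1]) {
    if (visited[start]) next
    loop <- integer(0)
    v <- start
    repeat {
      loop <- c(loop, v)
      visited[v] <- TRUE
      v <- nxt[v]
      if (is.na(v)) stop_vg("open boundary chain: mesh is not manifold")
      if (v == start) break
      if (length(loop) > nrow(bnd)) stop_vg("boundary chaining failed")
    }
    loops[[length(loops) + 1L]] <- loop
  }
  loops
}

#' Read a surface mesh from STL, OBJ or legacy VTK polydata
#'
#' STL files (ASCII or binary, auto-detected) store one vertex triple per
#' facet; coincident vertices are merged before boundary detection. OBJ and
#' legacy ASCII VTK `POLYDATA` files are read directly.
#'
#' @param path file path.
#' @param format one of `"auto"`, `"stl"`, `"obj"`, `"vtk"`; `"auto"` uses
#'   the file extension.
#' @inheritParams surface_mesh
#' @return a [surface_mesh]. Fails with a structured message if the surface
#'   is non-manifold or does not have exactly two boundary loops.
#' @export
read_mesh <- function(path, format = c("auto", "stl", "obj", "vtk"),
                      require_tube = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_vg("mesh file not found: %s", path)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     stl = "stl", obj = "obj", vtk = "vtk",
                     stop_vg("cannot infer mesh format from extension of %s",
                             path))
  }
  raw <- switch(format,
                stl = read_stl(path),
                obj = read_obj(path),
                vtk = read_vtk_polydata(path))
  surface_mesh(raw$vertices, raw$triangles, require_tube = require_tube)
}

read_stl <- function(path) {
  con <- file(path, "rb")
  head <- readBin(con, "raw", 80L)
  close(con)
  txt <- rawToChar(head[head != as.raw(0)])
  if (grepl("^\\s*solid", txt) && is_ascii_stl(path)) {
    read_stl_ascii(path)
  } else {
    read_stl_binary(path)
  }
}

is_ascii_stl <- function(path) {
  lines <- readLines(path, n = 10L, warn = FALSE)
  any(grepl("facet|endsolid", lines))
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex", lines, value = TRUE)
  xyz <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p)
    as.numeric(p[2:4])))
  merge_facet_vertices(xyz)
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80L)
  nf <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  xyz <- matrix(NA_real_, nf * 3L, 3L)
  for (i in seq_len(nf)) {
    rec <- readBin(con, "numeric", 12L, size = 4L, endian = "little")
    xyz[(3 * i - 2):(3 * i), ] <- matrix(rec[4:12], 3L, 3L, byrow = TRUE)
    readBin(con, "raw", 2L)
  }
  merge_facet_vertices(xyz)
}

# STL facets repeat vertices; merge exact duplicates after rounding to
# float precision so that write/read round-trips are stable.
merge_facet_vertices <- function(xyz, digits = 6L) {
  key <- apply(signif(xyz, digits), 1L, paste, collapse = ",")
  idx <- match(key, unique(key))
  verts <- xyz[!duplicated(key), , drop = FALSE]
  tris <- matrix(idx, ncol = 3L, byrow = TRUE)
  list(vertices = verts, triangles = tris)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", lines, value = TRUE)
  fl <- grep("^f\\s", lines, value = TRUE)
  verts <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p)
    as.numeric(p[2:4])))
  tris <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"), function(p) {
    ix <- sub("/.*$", "", p[-1])
    as.integer(ix)[1:3]
  }))
  list(vertices = verts, triangles = tris)
}

read_vtk_polydata <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ip <- grep("^POINTS", lines)
  if (length(ip) != 1L) stop_vg("no POINTS section in VTK file %s", path)
  np <- as.integer(strsplit(lines[ip], "\\s+")[[1]][2])
  nums <- numeric(0)
  i <- ip + 1L
  while (length(nums) < 3L * np) {
    nums <- c(nums, as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    i <- i + 1L
  }
  verts <- matrix(nums[seq_len(3L * np)], ncol = 3L, byrow = TRUE)
  it <- grep("^POLYGONS", lines)
  if (length(it) != 1L) stop_vg("no POLYGONS section in VTK file %s", path)
  hdr <- as.integer(strsplit(lines[it], "\\s+")[[1]][2:3])
  nums <- integer(0)
  i <- it + 1L
  while (length(nums) < hdr[2]) {
    nums <- c(nums, as.integer(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    i <- i + 1L
  }
  tris <- matrix(NA_integer_, hdr[1], 3L)
  pos <- 1L
  for (k in seq_len(hdr[1])) {
    sz <- nums[pos]
    if (sz != 3L) stop_vg("VTK polygon %d has %d vertices; only triangles supported",
                          k, sz)
    tris[k, ] <- nums[(pos + 1L):(pos + 3L)] + 1L
    pos <- pos + sz + 1L
  }
  list(vertices = verts, triangles = tris)
}

#' Write a surface mesh to STL, OBJ or legacy VTK polydata
#'
#' @param mesh a [surface_mesh].
#' @param path output file path.
#' @param format `"stl"` (ASCII), `"obj"` or `"vtk"`; `"auto"` uses the
#'   extension.
#' @param point_data optional named list of per-vertex numeric vectors,
#'   written as VTK `POINT_DATA` arrays (VTK format only).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("auto", "stl", "obj", "vtk"),
                       point_data = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- switch(tolower(tools::file_ext(path)),
                     stl = "stl", obj = "obj", vtk = "vtk",
                     stop_vg("cannot infer mesh format for %s", path))
  v <- mesh$vertices; f <- mesh$triangles
  if (format == "stl") {
    out <- c("solid vesselgrow")
    for (k in seq_len(nrow(f))) {
      p <- v[f[k, ], , drop = FALSE]
      n <- tri_normal(p)
      out <- c(out,
               sprintf("  facet normal %.9g %.9g %.9g", n[1], n[2], n[3]),
               "    outer loop",
               sprintf("      vertex %.9g %.9g %.9g", p[, 1], p[, 2], p[, 3]),
               "    endloop", "  endfacet")
    }
    writeLines(c(out, "endsolid vesselgrow"), path)
  } else if (format == "obj") {
    writeLines(c(sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]),
                 sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3])), path)
  } else {
    out <- c("# vtk DataFile Version 3.0", "vesselgrow surface", "ASCII",
             "DATASET POLYDATA",
             sprintf("POINTS %d double", nrow(v)),
             sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]),
             sprintf("POLYGONS %d %d", nrow(f), 4L * nrow(f)),
             sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L))
    if (!is.null(point_data)) {
      out <- c(out, sprintf("POINT_DATA %d", nrow(v)))
      for (nm in names(point_data)) {
        out <- c(out,
                 sprintf("SCALARS %s double 1", nm),
                 "LOOKUP_TABLE default",
                 sprintf("%.9g", point_data[[nm]]))
      }
    }
    writeLines(out, path)
  }
  invisible(path)
}

tri_normal <- function(p) {
  n <- pracma_cross(p[2, ] - p[1, ], p[3, ] - p[1, ])
  len <- sqrt(sum(n^2))
  if (len < .Machine$double.eps) c(0, 0, 1) else n / len
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Uniform wall specification
#'
#' The wall is treated as a thin membrane with a spatially uniform unloaded
#' thickness, matching the assumption of a constant subject-specific wall
#' thickness along the vessel.
#'
#' @param thickness wall thickness h (mm), > 0.
#' @return an object of class `wall_spec`.
#' @export
wall_spec <- function(thickness) {
  if (!is.numeric(thickness) || length(thickness) != 1L || thickness <= 0)
    stop_vg("wall thickness must be a single positive number (mm)")
  structure(list(thickness = thickness), class = "wall_spec")
}
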