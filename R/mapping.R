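# Harmonic (Laplace) parameterization of the tube surface: an axial
# coordinate s from a Dirichlet solve with s = 0 on the inlet loop and s = 1
# on the outlet loop, and a circumferential coordinate theta from a second
# solve on the mesh cut open along an inlet-to-outlet geodesic path. The
# discretization is the standard cotangent-weight finite-element Laplacian.

# Sparse cotangent Laplacian (positive semi-definite convention: L = D - W).
cotan_laplacian <- function(vertices, triangles) {
  n <- nrow(vertices)
  ii <- integer(0); jj <- integer(0); ww <- numeric(0)
  for (k in 1:3) {
    a <- triangles[, k]
    b <- triangles[, k %% 3 + 1]
    c <- triangles[, (k + 1) %% 3 + 1]
    # cotangent at vertex a, opposite edge (b, c)
    u <- vertices[b, , drop = FALSE] - vertices[a, , drop = FALSE]
    v <- vertices[c, , drop = FALSE] - vertices[a, , drop = FALSE]
    dot <- rowSums(u * v)
    crs <- sqrt(pmax(rowSums(u * u) * rowSums(v * v) - dot^2, 1e-300))
    cot <- dot / crs
    ii <- c(ii, b, c); jj <- c(jj, c, b); ww <- c(ww, cot / 2, cot / 2)
  }
  W <- Matrix::sparseMatrix(i = ii, j = jj, x = ww, dims = c(n, n))
  D <- Matrix::Diagonal(x = Matrix::rowSums(W))
  D - W
}

# Solve L u = 0 with Dirichlet values on given vertex sets.
solve_laplace_dirichlet <- function(vertices, triangles, fixed_idx,
                                    fixed_val) {
  n <- nrow(vertices)
  L <- cotan_laplacian(vertices, triangles)
  free <- setdiff(seq_len(n), fixed_idx)
  u <- numeric(n)
  u[fixed_idx] <- fixed_val
  if (length(free) > 0L) {
    rhs <- -L[free, fixed_idx, drop = FALSE] %*% fixed_val
    sol <- tryCatch(
      Matrix::solve(L[free, free], rhs),
      error = function(e) stop_vg(
        "singular Laplace system (disconnected mesh?): %s", conditionMessage(e)))
    u[free] <- as.numeric(sol)
  }
  u
}

#' Harmonic axial coordinate
#'
#' Solves the discrete Laplace equation on the tube surface with Dirichlet
#' data 0 on the inlet boundary loop and 1 on the outlet loop, using
#' cotangent finite-element weights. On a straight cylinder the solution is
#' the normalized axial position z/L.
#'
#' @param mesh a [surface_mesh] with two labelled boundary loops.
#' @return numeric per-vertex field in `[0, 1]` (exact on the loops).
#' @export
solve_axial_coordinate <- function(mesh) {
  fixed <- c(mesh$inlet_loop, mesh$outlet_loop)
  vals <- c(rep(0, length(mesh$inlet_loop)),
            rep(1, length(mesh$outlet_loop)))
  solve_laplace_dirichlet(mesh$vertices, mesh$triangles, fixed, vals)
}

#' Shortest inlet-to-outlet cut path
#'
#' Approximates the shortest geodesic connecting the inlet to the outlet by
#' the shortest path in the mesh edge graph with Euclidean edge lengths as
#' weights, between the graph-closest inlet/outlet vertex pair (ties broken
#' by lowest vertex index).
#'
#' @param mesh a [surface_mesh].
#' @return integer vector of vertex indices from an inlet vertex to an
#'   outlet vertex; consecutive entries share a mesh edge.
#' @export
geodesic_cut <- function(mesh) {
  ed <- mesh_edges(mesh$triangles)$edges
  len <- sqrt(rowSums((mesh$vertices[ed[, 1], , drop = FALSE] -
                       mesh$vertices[ed[, 2], , drop = FALSE])^2))
  g <- igraph::graph_from_edgelist(ed, directed = FALSE)
  igraph::E(g)$weight <- len
  dm <- igraph::distances(g, v = mesh$inlet_loop, to = mesh$outlet_loop)
  if (all(!is.finite(dm))) stop_vg("no path from inlet to outlet loop")
  best <- which(dm == min(dm), arr.ind = TRUE)
  best <- best[order(mesh$inlet_loop[best[, 1]],
                     mesh$outlet_loop[best[, 2]]), , drop = FALSE][1, ]
  p <- igraph::shortest_paths(g, from = mesh$inlet_loop[best[1]],
                              to = mesh$outlet_loop[best[2]],
                              output = "vpath")$vpath[[1]]
  as.integer(p)
}

# Cut the mesh open along a vertex path. Triangles on the "right" side of
# the directed path are re-indexed to duplicated seam vertices. Returns the
# augmented vertex matrix, re-indexed triangles, and the two seam copies.
cut_mesh_along_path <- function(mesh, path) {
  if (length(path) < 2L) stop_vg("cut path must contain at least 2 vertices")
  v <- mesh$vertices; f <- mesh$triangles
  n <- nrow(v)
  m <- nrow(f)
  path_edges <- cbind(path[-length(path)], path[-1])

  # incidence: triangles touching each path vertex
  inc <- lapply(path, function(p) which(f[, 1] == p | f[, 2] == p | f[, 3] == p))

  # directed half-edge lookup: triangle containing directed edge (a -> b)
  he_key <- c(paste(f[, 1], f[, 2]), paste(f[, 2], f[, 3]), paste(f[, 3], f[, 1]))
  he_tri <- rep(seq_len(m), 3L)
  tri_of <- function(a, b) {
    hit <- he_tri[match(paste(a, b), he_key)]
    hit
  }

  # side assignment per path vertex: split the triangle fan at the path
  # edges; the component containing the left triangle of the outgoing (or
  # incoming, at the last vertex) path edge keeps the original vertex.
  side_b_tris <- integer(0)
  new_index <- integer(length(path))
  v_aug <- v
  for (i in seq_along(path)) {
    p <- path[i]
    tris <- inc[[i]]
    if (length(tris) == 0L) stop_vg("isolated cut vertex %d", p)
    # fan adjacency: two fan triangles adjacent if they share a non-path
    # edge incident to p
    blocked <- character(0)
    if (i > 1L) blocked <- c(blocked, paste(min(path[i - 1], p), max(path[i - 1], p)))
    if (i < length(path)) blocked <- c(blocked, paste(min(path[i + 1], p), max(path[i + 1], p)))
    adj <- matrix(0L, length(tris), length(tris))
    for (a in seq_along(tris)) for (b in seq_along(tris)) {
      if (a >= b) next
      sh <- intersect(f[tris[a], ], f[tris[b], ])
      sh <- setdiff(sh, p)
      if (length(sh) >= 1L) {
        ek <- paste(min(p, sh[1]), max(p, sh[1]))
        if (!(ek %in% blocked)) adj[a, b] <- adj[b, a] <- 1L
      }
    }
    gg <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    comp <- igraph::components(gg)$membership
    if (max(comp) < 2L && length(path) > 2L && i > 1L && i < length(path))
      stop_vg("cut path does not locally separate the surface at vertex %d", p)
    # left triangle of the adjacent directed path edge keeps the original
    ref_edge <- if (i < length(path)) c(p, path[i + 1]) else c(path[i - 1], p)
    left_tri <- tri_of(ref_edge[1], ref_edge[2])
    if (is.na(left_tri)) left_tri <- tri_of(ref_edge[2], ref_edge[1])
    keep_comp <- comp[match(left_tri, tris)]
    side_b <- tris[comp != keep_comp]
    if (length(side_b) > 0L) {
      v_aug <- rbind(v_aug, v[p, , drop = FALSE])
      new_index[i] <- nrow(v_aug)
      for (t in side_b) {
        f[t, f[t, ] == p] <- new_index[i]
      }
    } else {
      new_index[i] <- NA_integer_
    }
    side_b_tris <- union(side_b_tris, side_b)
  }
  dup <- !is.na(new_index)
  list(vertices = v_aug, triangles = f,
       seam_a = path[dup], seam_b = new_index[dup],
       seam_a_all = path, n_original = n)
}

#' Harmonic circumferential coordinate
#'
#' Duplicates the vertices along the cut path into two seam copies, opening
#' the tube into a topological disc, and solves the Laplace equation with
#' Dirichlet value 0 on one seam copy and 1 on the other. The returned field
#' is taken modulo the seam (0 identified with 1), so on a straight cylinder
#' with a generator-line cut it reproduces azimuthal angle / 2*pi.
#'
#' @param mesh a [surface_mesh].
#' @param cut integer vertex path from [geodesic_cut()].
#' @return per-vertex theta in `[0, 1)`; vertices on the cut get 0.
#' @export
solve_circumferential_coordinate <- function(mesh, cut) {
  cm <- cut_mesh_along_path(mesh, cut)
  fixed <- c(cm$seam_a_all, cm$seam_b)
  vals <- c(rep(0, length(cm$seam_a_all)), rep(1, length(cm$seam_b)))
  u <- solve_laplace_dirichlet(cm$vertices, cm$triangles, fixed, vals)
  theta <- u[seq_len(cm$n_original)]
  theta[cm$seam_a_all] <- 0
  theta %% 1
}

#' Full tube parameterization
#'
#' Runs the axial solve, the geodesic cut and the circumferential solve.
#'
#' @param mesh a [surface_mesh].
#' @return an object of class `tube_coordinates`: `s`, `theta` (per vertex),
#'   `cut` (the seam path).
#' @export
tube_coordinates <- function(mesh) {
  s <- solve_axial_coordinate(mesh)
  cut <- geodesic_cut(mesh)
  theta <- solve_circumferential_coordinate(mesh, cut)
  structure(list(s = s, theta = theta, cut = cut),
            class = "tube_coordinates")
}

#' Periodic circumferential distance
#'
#' @param t1,t2 theta values in `[0, 1)`.
#' @return `min(|t1 - t2|, 1 - |t1 - t2|)`.
#' @export
theta_distance <- function(t1, t2) {
  d <- abs(t1 - t2)
  pmin(d, 1 - d)
}

#' Cross-time-point vertex correspondence in (s, theta)
#'
#' For each vertex of mesh A finds the vertex of mesh B closest in the
#' parameter plane, with the periodic metric in theta. Meshes may be
#' triangulated independently (different resolutions).
#'
#' @param coords_a,coords_b [tube_coordinates] of the two meshes.
#' @param s_weight relative weight of the axial distance (default 1).
#' @return integer vector: for vertex i of A, the matched vertex index in B.
#' @export
map_between_geometries <- function(coords_a, coords_b, s_weight = 1) {
  nb <- length(coords_b$s)
  vapply(seq_along(coords_a$s), function(i) {
    d2 <- s_weight * (coords_a$s[i] - coords_b$s)^2 +
      theta_distance(coords_a$theta[i], coords_b$theta)^2
    which.min(d2)
  }, integer(1))
}

#' Export tube coordinates as CSV
#'
#' @param coords a [tube_coordinates] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tube_coordinates <- function(coords, path) {
  utils::write.csv(data.frame(vertex_id = seq_along(coords$s),
                              s = coords$s, theta = coords$theta),
                   path, row.names = FALSE)
  invisible(path)
}
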