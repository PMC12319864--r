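#' Icosphere surface mesh with a medial-wall cap
#'
#' Builds a closed triangulated sphere by repeated edge-midpoint subdivision
#' of a regular icosahedron, as a synthetic stand-in for a cortical
#' hemisphere surface. Two coordinate systems are carried, mirroring
#' surface-based MRI conventions: `sphere` holds unit-norm spherical
#' registration coordinates, and `vertices` holds "white surface"
#' coordinates (here the sphere scaled to a brain-like 60 mm radius). A
#' contiguous geodesic cap around the inferior pole (0, 0, -1) is flagged as
#' the medial wall and excluded from all analyses.
#'
#' Level L has `10 * 4^L + 2` vertices and `20 * 4^L` triangles.
#'
#' @param subdivision_level non-negative integer; 0 is the bare icosahedron
#'   (12 vertices), each level quadruples the triangle count.
#' @param radius white-surface radius in mm.
#' @param medial_angle angular radius, in degrees, of the medial-wall cap
#'   around the (0, 0, -1) pole.
#' @return An object of class `surface_mesh` with fields `vertices` (V x 3
#'   white-surface mm coordinates), `sphere` (V x 3 unit coordinates),
#'   `faces` (F x 3 integer, 1-based) and `medial_wall` (logical V).
#' @examples
#' m <- make_sphere_mesh(2)
#' nrow(m$vertices)  # 162
#' @export
make_sphere_mesh <- function(subdivision_level = 3, radius = 60,
                             medial_angle = 35) {
  if (subdivision_level < 0 || subdivision_level != round(subdivision_level))
    stop("subdivision_level must be a non-negative integer")
  if (radius <= 0) stop("radius must be positive")
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (lev in seq_len(subdivision_level)) {
    n_old <- nrow(v)
    edges <- unique(rbind(
      cbind(pmin(f[, 1], f[, 2]), pmax(f[, 1], f[, 2])),
      cbind(pmin(f[, 2], f[, 3]), pmax(f[, 2], f[, 3])),
      cbind(pmin(f[, 3], f[, 1]), pmax(f[, 3], f[, 1]))))
    mids <- v[edges[, 1], ] + v[edges[, 2], ]
    mids <- mids / sqrt(rowSums(mids^2))
    # integer key per undirected edge -> new vertex index
    key <- (edges[, 1] - 1) * n_old + edges[, 2]
    midx <- integer(n_old * n_old)
    midx[key] <- n_old + seq_len(nrow(edges))
    lookup <- function(a, b) midx[(pmin(a, b) - 1) * n_old + pmax(a, b)]
    ab <- lookup(f[, 1], f[, 2])
    bc <- lookup(f[, 2], f[, 3])
    ca <- lookup(f[, 3], f[, 1])
    f <- rbind(cbind(f[, 1], ab, ca), cbind(f[, 2], bc, ab),
               cbind(f[, 3], ca, bc), cbind(ab, bc, ca))
    v <- rbind(v, mids)
  }
  storage.mode(f) <- "integer"
  polar_angle <- acos(pmin(pmax(-v[, 3], -1), 1))  # angle from (0,0,-1)
  medial <- polar_angle <= medial_angle * pi / 180
  structure(list(vertices = v * radius, sphere = v,
                 faces = unname(f), medial_wall = medial),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices (%d medial wall), %d triangles\n",
              nrow(x$vertices), sum(x$medial_wall), nrow(x$faces)))
  invisible(x)
}

#' Indices of analysed (non-medial-wall) vertices
#' @param mesh a [make_sphere_mesh()] / [read_mesh()] surface.
#' @return Integer vector of 1-based vertex indices outside the medial wall.
#' @export
cortex_indices <- function(mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  which(!mesh$medial_wall)
}

# Undirected edge list (E x 2, 1-based) of a triangle mesh.
mesh_edges <- function(mesh) {
  f <- mesh$faces
  unique(rbind(cbind(pmin(f[, 1], f[, 2]), pmax(f[, 1], f[, 2])),
               cbind(pmin(f[, 2], f[, 3]), pmax(f[, 2], f[, 3])),
               cbind(pmin(f[, 3], f[, 1]), pmax(f[, 3], f[, 1]))))
}

#' Per-vertex surface area
#'
#' Area associated with each vertex: one third of the total area of its
#' incident triangles, computed on the white-surface coordinates. Summing
#' over vertices returns the total mesh area.
#'
#' @param mesh a `surface_mesh`.
#' @return Numeric vector, mm^2, one value per vertex.
#' @export
vertex_areas <- function(mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  f <- mesh$faces
  a <- mesh$vertices[f[, 1], , drop = FALSE]
  b <- mesh$vertices[f[, 2], , drop = FALSE]
  cc <- mesh$vertices[f[, 3], , drop = FALSE]
  u <- b - a
  w <- cc - a
  cr <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
              u[, 3] * w[, 1] - u[, 1] * w[, 3],
              u[, 1] * w[, 2] - u[, 2] * w[, 1])
  tri_area <- 0.5 * sqrt(rowSums(cr^2))
  areas <- numeric(nrow(mesh$vertices))
  for (j in 1:3) {
    acc <- tapply(tri_area, f[, j], sum)
    idx <- as.integer(names(acc))
    areas[idx] <- areas[idx] + acc
  }
  areas / 3
}

# igraph over mesh edges restricted to non-medial-wall vertices, weighted by
# Euclidean white-surface edge length. Vertex names are original indices.
cortex_graph <- function(mesh) {
  keep <- cortex_indices(mesh)
  e <- mesh_edges(mesh)
  e <- e[e[, 1] %in% keep & e[, 2] %in% keep, , drop = FALSE]
  len <- sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                         mesh$vertices[e[, 2], , drop = FALSE])^2))
  g <- igraph::graph_from_edgelist(
    matrix(match(as.vector(e), keep), ncol = 2), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(keep) - igraph::vcount(g)))
  igraph::E(g)$weight <- len
  g
}
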