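#' Threshold-free cluster enhancement on a surface
#'
#' Integrates cluster support over all thresholds without fixing a
#' cluster-forming threshold: for each vertex
#' \deqn{TFCE(v) = \sum_{h = dh, 2dh, \dots} e(h, v)^E \, h^H \, dh,}
#' where `e(h, v)` is the surface area (one-third of incident-triangle
#' areas, summed over member vertices) of the connected supra-threshold
#' component containing `v` at height `h`, with connectivity through shared
#' mesh edges among non-medial-wall vertices. Negative statistics are
#' enhanced on the negated map and re-negated, so both tails are boosted
#' symmetrically.
#'
#' Defaults are the standard surface parameters `H = 2`, `E = 0.5`, with
#' `dh = max(|t|) / 100`.
#'
#' @param statistic numeric vector of per-vertex statistics (e.g. t), one
#'   per non-medial-wall vertex.
#' @param mesh the `surface_mesh` defining adjacency and vertex areas.
#' @param H height exponent (> 0).
#' @param E extent exponent (> 0).
#' @param dh threshold step (> 0); default `max(abs(statistic)) / 100`.
#' @return Numeric vector of enhanced values, same sign structure as the
#'   input.
#' @export
tfce_enhance <- function(statistic, mesh, H = 2, E = 0.5, dh = NULL) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (any(!is.finite(statistic)))
    stop("non-finite values in the statistic map")
  cortex <- cortex_indices(mesh)
  if (length(statistic) != length(cortex))
    stop("statistic must have one value per non-medial-wall vertex (",
         length(cortex), ")")
  if (H <= 0 || E <= 0) stop("H and E must be positive")
  if (all(statistic == 0)) return(numeric(length(statistic)))
  if (is.null(dh)) dh <- max(abs(statistic)) / 100
  if (dh <= 0) stop("dh must be positive")

  areas <- vertex_areas(mesh)[cortex]
  e <- mesh_edges(mesh)
  keep <- e[, 1] %in% cortex & e[, 2] %in% cortex
  edges <- cbind(match(e[keep, 1], cortex), match(e[keep, 2], cortex))

  enhance_positive <- function(stat) {
    out <- numeric(length(stat))
    top <- max(stat)
    if (top <= 0) return(out)
    for (h in seq(dh, top, by = dh)) {
      supra <- stat >= h
      if (!any(supra)) break
      comp <- supra_components(supra, edges, length(stat))
      carea <- rowsum(areas[supra], comp[supra])
      out[supra] <- out[supra] +
        carea[match(comp[supra], as.integer(rownames(carea))), 1]^E *
        h^H * dh
    }
    out
  }
  enhance_positive(statistic) - enhance_positive(-statistic)
}

# Connected-component labels of the supra-threshold vertex set, linked by
# mesh edges. Returns an integer label per vertex (0 = sub-threshold).
supra_components <- function(supra, edges, n) {
  g <- igraph::graph_from_edgelist(
    edges[supra[edges[, 1]] & supra[edges[, 2]], , drop = FALSE],
    directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  labels <- igraph::components(g)$membership
  labels[!supra] <- 0L
  # isolated supra vertices keep their own component label from igraph
  labels
}
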