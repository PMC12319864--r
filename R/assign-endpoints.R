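#' Assign streamline endpoints to cortical vertices
#'
#' Maps each streamline endpoint to the nearest non-medial-wall vertex by
#' Euclidean distance on the white-surface coordinates. If that nearest
#' vertex lies within `radius` mm the streamline's FA weight is added to the
#' (seed, vertex) cell; otherwise the streamline is discarded. Connectivity
#' to a vertex is thus the sum of mean-FA weights of the streamlines
#' terminating there. Medial-wall vertices never receive weight. Distance
#' ties are broken towards the lowest vertex index.
#'
#' @param endpoints data.frame with columns `seed_id`, `x`, `y`, `z`, `fa`
#'   (as written by [simulate_endpoints()] / [read_endpoints()]).
#' @param mesh the surface the endpoints were tracked to.
#' @param radius maximum endpoint-to-vertex distance in mm (default 5).
#' @param seed_ids integer vector defining the seed rows of the output
#'   matrix; defaults to the sorted unique seed ids present in the table.
#'   Pass the full seed list explicitly so that seeds without surviving
#'   streamlines keep an (all-zero) row.
#' @return A [connectivity_matrix()] in state `"raw"`, with one column per
#'   non-medial-wall vertex.
#' @export
assign_endpoints <- function(endpoints, mesh, radius = 5, seed_ids = NULL) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (radius <= 0) stop("radius must be positive")
  req <- c("seed_id", "x", "y", "z", "fa")
  if (!all(req %in% names(endpoints)))
    stop("endpoint table must have columns ", paste(req, collapse = ", "))
  cortex <- cortex_indices(mesh)
  if (is.null(seed_ids)) seed_ids <- sort(unique(endpoints$seed_id))
  n <- length(seed_ids)
  m <- length(cortex)
  vals <- matrix(0, n, m)
  if (nrow(endpoints) == 0) {
    warning("empty endpoint table: returning an all-zero matrix")
    return(connectivity_matrix(vals, seed_ids = seed_ids,
                               vertex_ids = cortex - 1L, state = "raw"))
  }
  if (any(endpoints$fa < 0)) stop("negative FA weight in endpoint table")
  row_of <- match(endpoints$seed_id, seed_ids)
  if (anyNA(row_of))
    stop("endpoint seed id(s) not in the seed list: ",
         paste(utils::head(unique(endpoints$seed_id[is.na(row_of)]), 5),
               collapse = ", "))

  vw <- mesh$vertices[cortex, , drop = FALSE]
  pts <- as.matrix(endpoints[, c("x", "y", "z")])
  vsq <- rowSums(vw^2)
  chunk <- max(1L, floor(4e6 / m))
  for (start in seq(1, nrow(pts), by = chunk)) {
    idx <- start:min(start + chunk - 1, nrow(pts))
    d2 <- outer(rowSums(pts[idx, , drop = FALSE]^2), vsq, "+") -
      2 * pts[idx, , drop = FALSE] %*% t(vw)
    nearest <- max.col(-d2, ties.method = "first")
    dist <- sqrt(pmax(d2[cbind(seq_along(idx), nearest)], 0))
    keep <- dist <= radius
    if (any(keep)) {
      tab <- rowsum(endpoints$fa[idx][keep],
                    group = (nearest[keep] - 1) * n + row_of[idx][keep])
      cells <- as.integer(rownames(tab))
      vals[cbind((cells - 1) %% n + 1, (cells - 1) %/% n + 1)] <-
        vals[cbind((cells - 1) %% n + 1, (cells - 1) %/% n + 1)] + tab[, 1]
    }
  }
  connectivity_matrix(vals, seed_ids = seed_ids, vertex_ids = cortex - 1L,
                      state = "raw")
}
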