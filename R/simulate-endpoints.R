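#' Simulate streamline endpoints from a target connectome
#'
#' Emits a synthetic tractography endpoint table whose endpoint-to-vertex
#' assignment should recover the target connectivity matrix: for each seed,
#' endpoint vertices are drawn multinomially with probability proportional
#' to the seed's target row, placed at the drawn vertex's white-surface
#' position, displaced by isotropic Gaussian jitter, and given a
#' per-streamline mean-FA weight drawn uniformly in \[0.1, 0.5\].
#'
#' Seeds whose target row is all zero emit no streamlines (reported via a
#' message, not an error), mirroring seeds from which tractography fails.
#'
#' @param target_matrix a non-negative [connectivity_matrix()] whose columns
#'   index non-medial-wall vertices of `mesh` (0-based `vertex_ids`).
#' @param mesh the [make_sphere_mesh()] surface the endpoints live on.
#' @param streamlines_per_seed streamlines drawn per seed (>= 1).
#' @param endpoint_jitter_sd isotropic displacement sd in mm.
#' @param rng_seed integer seed.
#' @return A data.frame with columns `seed_id` (0-based), `x`, `y`, `z`
#'   (mm) and `fa`. The exact multinomial draw underlying the table is
#'   attached as `attr(, "draw_counts")` (seeds x vertices) for round-trip
#'   verification.
#' @export
simulate_endpoints <- function(target_matrix, mesh, streamlines_per_seed = 200,
                               endpoint_jitter_sd = 0, rng_seed = 1) {
  stopifnot(inherits(target_matrix, "connectivity_matrix"),
            inherits(mesh, "surface_mesh"))
  if (streamlines_per_seed < 1) stop("streamlines_per_seed must be >= 1")
  if (endpoint_jitter_sd < 0) stop("endpoint_jitter_sd must be >= 0")
  vals <- target_matrix$values
  if (any(vals < 0)) stop("target matrix must be non-negative")
  vert_idx <- target_matrix$vertex_ids + 1L
  if (any(vert_idx < 1 | vert_idx > nrow(mesh$vertices)))
    stop("target matrix vertex ids outside mesh")

  set.seed(rng_seed)
  n <- nrow(vals)
  counts <- matrix(0L, n, ncol(vals))
  rows <- vector("list", n)
  zero_seeds <- 0L
  for (i in seq_len(n)) {
    p <- vals[i, ]
    tot <- sum(p)
    if (tot == 0) {
      zero_seeds <- zero_seeds + 1L
      next
    }
    draw <- as.integer(stats::rmultinom(1, streamlines_per_seed, p / tot))
    counts[i, ] <- draw
    which_v <- rep.int(seq_along(draw), draw)
    pos <- mesh$vertices[vert_idx[which_v], , drop = FALSE]
    if (endpoint_jitter_sd > 0)
      pos <- pos + matrix(stats::rnorm(length(pos), sd = endpoint_jitter_sd),
                          nrow(pos))
    rows[[i]] <- data.frame(seed_id = target_matrix$seed_ids[i],
                            x = pos[, 1], y = pos[, 2], z = pos[, 3],
                            fa = stats::runif(nrow(pos), 0.1, 0.5))
  }
  if (zero_seeds > 0)
    message(zero_seeds, " seed(s) had all-zero target rows and emitted no ",
            "streamlines")
  out <- do.call(rbind, c(rows[!vapply(rows, is.null, logical(1))],
                          list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(seed_id = integer(), x = numeric(), y = numeric(),
                      z = numeric(), fa = numeric())
  attr(out, "draw_counts") <- counts
  out
}
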