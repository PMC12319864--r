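#' Regular seed grid inside an ellipsoidal thalamic mask
#'
#' Places seeds on a regular 3D grid of the given spacing, anchored at the
#' origin, and keeps every grid point inside the axis-aligned ellipsoid
#' `(x/a)^2 + (y/b)^2 + (z/c)^2 <= 1`. The defaults (1.75 mm spacing in a
#' 13 x 10 x 7.5 mm semi-axis ellipsoid) produce 789 seeds, emulating a
#' dense left-thalamus seeding scheme of roughly 800 seeds. Coordinates are
#' in mm, RAS orientation (+x lateral/right, +y anterior, +z superior).
#'
#' @param spacing grid spacing in mm (> 0).
#' @param semi_axes numeric length-3, ellipsoid semi-axes in mm (all > 0).
#' @return An object of class `seed_grid` with fields `coordinates`
#'   (n x 3 matrix, columns x/y/z), `spacing` and `semi_axes`.
#' @examples
#' g <- make_seed_grid(spacing = 2.5, semi_axes = c(13, 10, 7.5))
#' nrow(g$coordinates)
#' @export
make_seed_grid <- function(spacing = 1.75, semi_axes = c(13, 10, 7.5)) {
  if (!is.numeric(spacing) || length(spacing) != 1 || spacing <= 0)
    stop("spacing must be a single positive number")
  if (length(semi_axes) != 3 || any(semi_axes <= 0))
    stop("semi_axes must be three positive numbers")
  axis_points <- function(a) spacing * seq.int(-floor(a / spacing),
                                               floor(a / spacing))
  pts <- as.matrix(expand.grid(x = axis_points(semi_axes[1]),
                               y = axis_points(semi_axes[2]),
                               z = axis_points(semi_axes[3])))
  inside <- (pts[, 1] / semi_axes[1])^2 + (pts[, 2] / semi_axes[2])^2 +
    (pts[, 3] / semi_axes[3])^2 <= 1
  if (!any(inside))
    stop("no grid points of spacing ", spacing,
         " mm fall inside the ellipsoid with semi-axes (",
         paste(semi_axes, collapse = ", "), ") mm")
  coords <- pts[inside, , drop = FALSE]
  # deterministic order: z, then y, then x
  coords <- coords[order(coords[, 3], coords[, 2], coords[, 1]), ,
                   drop = FALSE]
  rownames(coords) <- NULL
  structure(list(coordinates = coords, spacing = spacing,
                 semi_axes = semi_axes),
            class = "seed_grid")
}

#' @export
print.seed_grid <- function(x, ...) {
  cat(sprintf("<seed_grid> %d seeds, %.3g mm spacing, semi-axes (%s) mm\n",
              nrow(x$coordinates), x$spacing,
              paste(x$semi_axes, collapse = ", ")))
  invisible(x)
}
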