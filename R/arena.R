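#' Arena geometries
#'
#' Trajectories are recorded in millimeters. For a circular arena (watch
#' glass) the origin is the arena center. For a rectangular split-dyad tank
#' the origin is the corner where the divider meets the side wall: x runs
#' across the tank width in `[0, W]` and y runs along the tank length in
#' `[0, L]`, increasing toward the wall opposite the divider. The divider
#' therefore sits on the line `y = divider_at`, which must be one of the two
#' end walls (0 or `L`).
#'
#' @param radius Circle radius in mm (> 0).
#' @param center Numeric length-2 circle center, mm. Kept at the origin by
#'   the simulators; accepted for externally-recorded data.
#' @param length Tank length `L` in mm, the divider-normal axis.
#' @param width Tank width `W` in mm.
#' @param divider_at Coordinate of the divider wall along the length axis;
#'   either `0` (default) or `length`.
#' @return An object of class `c("circle_arena"/"rect_arena", "arena")`.
#' @examples
#' circle_arena(20)
#' rect_arena(length = 50, width = 20)
#' @export
circle_arena <- function(radius, center = c(0, 0)) {
  stopifnot(is.numeric(radius), length(radius) == 1L, is.finite(radius),
            radius > 0, length(center) == 2L, all(is.finite(center)))
  structure(list(shape = "circle", radius = radius, center = as.numeric(center)),
            class = c("circle_arena", "arena"))
}

#' @rdname circle_arena
#' @export
rect_arena <- function(length = 50, width = 20, divider_at = 0) {
  stopifnot(is.numeric(length), length > 0, is.numeric(width), width > 0)
  if (!divider_at %in% c(0, length)) {
    stop_zfsocial("arena_error",
                  "divider_at must be 0 or `length` (an end wall), got ",
                  divider_at)
  }
  structure(list(shape = "rectangle", length = length, width = width,
                 divider_at = divider_at),
            class = c("rect_arena", "arena"))
}

#' @export
print.arena <- function(x, ...) {
  if (x$shape == "circle") {
    cat(sprintf("<circular arena> radius %g mm, center (%g, %g)\n",
                x$radius, x$center[1], x$center[2]))
  } else {
    cat(sprintf("<rectangular arena> %g x %g mm, divider at y = %g\n",
                x$length, x$width, x$divider_at))
  }
  invisible(x)
}

is_circle <- function(arena) inherits(arena, "circle_arena")
is_rect <- function(arena) inherits(arena, "rect_arena")

arena_to_list <- function(arena) unclass(arena)

arena_from_list <- function(x) {
  if (identical(x$shape, "circle")) {
    circle_arena(x$radius, unlist(x$center))
  } else {
    rect_arena(x$length, x$width, x$divider_at)
  }
}

# reflect a point back into the arena (specular fold at the walls);
# positions further out than one fold are clamped to the boundary
reflect_into_arena <- function(x, y, arena) {
  if (is_circle(arena)) {
    dx <- x - arena$center[1]; dy <- y - arena$center[2]
    r <- sqrt(dx^2 + dy^2)
    if (r > arena$radius) {
      r2 <- 2 * arena$radius - r
      if (r2 < 0) r2 <- 0.999 * arena$radius
      x <- arena$center[1] + dx * r2 / r
      y <- arena$center[2] + dy * r2 / r
    }
    c(x, y)
  } else {
    fold <- function(u, hi) {
      if (u < 0) u <- -u
      if (u > hi) u <- 2 * hi - u
      min(max(u, 0), hi)
    }
    c(fold(x, arena$width), fold(y, arena$length))
  }
}
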