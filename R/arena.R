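#' Arena configuration
#'
#' Defines the two-dimensional world the simulation runs on: a grid of unit
#' cells with continuous agent coordinates inside it. The default is the
#' 51 x 51 toroidal (wrapped) arena; a reflecting boundary is available for
#' sensitivity analyses of the boundary-handling method.
#'
#' @param width,height Arena dimensions in cells (integers, at least 3).
#' @param boundary_mode `"wrap"` (torus: agents leaving one edge re-enter on
#'   the opposite edge with heading unchanged) or `"reflect"` (agents bounce
#'   off the walls, mirroring the velocity component normal to the wall).
#' @return An object of class `arena_config`.
#' @examples
#' arena_config()
#' arena_config(41, 41, "reflect")
#' @export
arena_config <- function(width = 51L, height = 51L,
                         boundary_mode = c("wrap", "reflect")) {
  boundary_mode <- match.arg(boundary_mode)
  width <- as.integer(width)
  height <- as.integer(height)
  if (is.na(width) || is.na(height) || width < 3L || height < 3L) {
    stop("arena must be at least 3 x 3 cells", call. = FALSE)
  }
  structure(list(width = width, height = height,
                 boundary_mode = boundary_mode),
            class = "arena_config")
}

#' @export
print.arena_config <- function(x, ...) {
  cat(sprintf("<arena %d x %d cells, %s boundary>\n",
              x$width, x$height, x$boundary_mode))
  invisible(x)
}

# Accept either a length-2 numeric c(x, y) or a 2-column matrix of positions;
# returns a matrix plus a flag so callers can restore the input shape.
.as_xy <- function(p) {
  if (is.matrix(p)) {
    if (ncol(p) != 2L) stop("positions must have two columns", call. = FALSE)
    list(m = p, vector = FALSE)
  } else {
    if (length(p) != 2L) stop("a position is a length-2 numeric", call. = FALSE)
    list(m = matrix(as.numeric(p), ncol = 2L), vector = TRUE)
  }
}

#' Wrap a position onto the torus
#'
#' Reduces continuous coordinates modulo the arena dimensions so every
#' position lies in `[0, width) x [0, height)`. Headings are unaffected:
#' an agent crossing an edge keeps its direction of travel.
#'
#' @param p A position `c(x, y)` or a 2-column matrix of positions.
#' @param arena An [arena_config()].
#' @return Coordinates of the same shape as `p`, inside the arena.
#' @examples
#' wrap_position(c(52.3, 10), arena_config())   # -> (1.3, 10)
#' wrap_position(c(-0.5, 25), arena_config())   # -> (50.5, 25)
#' @export
wrap_position <- function(p, arena) {
  xy <- .as_xy(p)
  m <- xy$m
  m[, 1L] <- m[, 1L] %% arena$width
  m[, 2L] <- m[, 2L] %% arena$height
  if (xy$vector) as.numeric(m) else m
}

#' Reflect a position off the arena walls
#'
#' Mirrors any out-of-bounds coordinate back into the arena and negates the
#' velocity component normal to each crossed wall, updating the heading
#' accordingly (x-wall: heading -> 180 - heading; y-wall: heading -> -heading).
#' A corner overshoot composes the two single-axis reflections.
#'
#' @param p A position `c(x, y)` or a 2-column matrix of positions.
#' @param heading Heading(s) in degrees (0 = +x, counter-clockwise).
#' @param arena An [arena_config()].
#' @return A list with elements `position` (same shape as `p`) and `heading`
#'   (degrees, normalized to `[0, 360)`).
#' @examples
#' reflect_position(c(51.4, 10), 0, arena_config())  # x -> 50.6, heading 180
#' @export
reflect_position <- function(p, heading, arena) {
  xy <- .as_xy(p)
  x <- xy$m[, 1L]
  y <- xy$m[, 2L]
  h <- as.numeric(heading)
  W <- arena$width
  H <- arena$height
  repeat {
    fixed <- TRUE
    neg <- x < 0
    if (any(neg)) {
      x[neg] <- -x[neg]
      h[neg] <- 180 - h[neg]
      fixed <- FALSE
    }
    hi <- x >= W
    if (any(hi)) {
      x[hi] <- 2 * W - x[hi]
      h[hi] <- 180 - h[hi]
      # a point landing exactly on the wall is nudged just inside
      x[x >= W] <- W * (1 - 1e-12)
      fixed <- FALSE
    }
    neg <- y < 0
    if (any(neg)) {
      y[neg] <- -y[neg]
      h[neg] <- -h[neg]
      fixed <- FALSE
    }
    hi <- y >= H
    if (any(hi)) {
      y[hi] <- 2 * H - y[hi]
      h[hi] <- -h[hi]
      y[y >= H] <- H * (1 - 1e-12)
      fixed <- FALSE
    }
    if (fixed) break
  }
  m <- cbind(x, y, deparse.level = 0)
  list(position = if (xy$vector) as.numeric(m) else m,
       heading = h %% 360)
}

#' Cell index of a continuous position
#'
#' The arena is divided into unit cells with the half-open convention
#' `[i, i + 1)`; a position maps to the cell `(floor(x), floor(y))`.
#' Capture checks compare cell indices, never raw coordinates.
#'
#' @param p A position `c(x, y)` or a 2-column matrix of positions, already
#'   inside the arena.
#' @return Integer cell indices of the same shape as `p`.
#' @examples
#' cell_index(c(0.99, 0.99))  # (0, 0)
#' cell_index(c(13.0, 7.5))   # (13, 7)
#' @export
cell_index <- function(p) {
  xy <- .as_xy(p)
  m <- xy$m
  m[] <- floor(m)
  storage.mode(m) <- "integer"
  if (xy$vector) as.integer(m) else m
}

#' Torus distance between positions
#'
#' Euclidean distance on the wrapped arena: each coordinate difference is the
#' shorter of the direct and the wrapped-around separation.
#'
#' @param a,b Positions: length-2 numerics or 2-column matrices (recycled
#'   row-wise as in `cbind`).
#' @param arena An [arena_config()].
#' @return Numeric vector of distances.
#' @export
torus_distance <- function(a, b, arena) {
  ma <- .as_xy(a)$m
  mb <- .as_xy(b)$m
  n <- max(nrow(ma), nrow(mb))
  ax <- rep_len(ma[, 1L], n); ay <- rep_len(ma[, 2L], n)
  bx <- rep_len(mb[, 1L], n); by <- rep_len(mb[, 2L], n)
  dx <- abs(ax - bx)
  dy <- abs(ay - by)
  dx <- pmin(dx, arena$width - dx)
  dy <- pmin(dy, arena$height - dy)
  sqrt(dx^2 + dy^2)
}
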