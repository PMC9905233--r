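#' Hexagonal playing board
#'
#' Cells are addressed in axial coordinates `(q, r)` with the origin at the
#' board center; a regular hexagonal board of radius `R` contains every cell
#' with `|q| <= R`, `|r| <= R` and `|q + r| <= R`, i.e. `3R(R+1) + 1` cells
#' (91 for the default radius 5).
#'
#' @param radius board radius in cells.
#' @return A list of class `hex_board` with `radius`, `n_cells` and a
#'   `cells` data frame (`q`, `r`).
#' @export
hex_board <- function(radius = 5L) {
  radius <- as.integer(radius)
  if (radius < 1L) stop("hex_board: radius must be >= 1")
  g <- expand.grid(q = -radius:radius, r = -radius:radius)
  g <- g[abs(g$q + g$r) <= radius, ]
  rownames(g) <- NULL
  structure(list(radius = radius, n_cells = nrow(g), cells = g),
            class = "hex_board")
}

#' @rdname hex_board
#' @param q,r axial coordinates (vectors of equal length).
#' @param board a `hex_board`.
#' @return `on_board()`: logical vector.
#' @export
on_board <- function(q, r, board) {
  abs(q) <= board$radius & abs(r) <= board$radius &
    abs(q + r) <= board$radius
}

#' Hex distance between cells
#'
#' Number of single-cell steps between two cells in axial coordinates:
#' `(|dq| + |dr| + |dq + dr|) / 2`. Vectorized over cells.
#'
#' @param q1,r1,q2,r2 axial coordinates.
#' @return Integer distances in fields.
#' @examples
#' hex_distance(0, 0, 2, 0)  # 2
#' @export
hex_distance <- function(q1, r1, q2, r2) {
  dq <- q2 - q1
  dr <- r2 - r1
  (abs(dq) + abs(dr) + abs(dq + dr)) / 2
}

# The six axial neighbor offsets of any cell.
hex_neighbors <- function() {
  data.frame(q = c(1L, -1L, 0L, 0L, 1L, -1L),
             r = c(0L, 0L, 1L, -1L, -1L, 1L))
}

# Axial -> cartesian (pointy-top layout, unit cell spacing); used for
# fractional targets in the movement generator.
hex_to_cart <- function(q, r) {
  cbind(x = q + r / 2, y = r * sqrt(3) / 2)
}
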