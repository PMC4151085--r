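## Hexagonal cell lattice.
##
## Pointy-top hexagons (flat left/right sides) so that two of the six edge
## normals lie exactly on the proximal-distal axis: outward normals at
## 0, 60, 120, 180, 240, 300 degrees (0 = +x = distal). Rows are offset by
## half a cell; columns index position along the P-D axis.

HEX_EDGE_ANGLES <- c(0, 60, 120, 180, 240, 300)

#' Construct a hexagonal cell grid
#'
#' Builds the lattice used by the polarity model: `n_rows x n_cols` pointy-top
#' hexagonal cells with six edges per cell whose outward unit normals point at
#' 0, 60, 120, 180, 240 and 300 degrees (0 degrees = +x = distal). Apposed
#' edges of neighboring cells are paired into junctions; the partner of edge
#' `e` of cell `i` is edge `opp(e)` (normal rotated 180 degrees) of the
#' neighbor. Outer edges have no real partner (`NA` in `nbr`).
#'
#' @param n_rows,n_cols grid dimensions; default 6 x 30, the arena used for
#'   the polarization-kinetics simulations.
#' @return object of class `hex_grid`: list with `n_rows`, `n_cols`, `n_cells`,
#'   `row`, `col` (per-cell indices), `cx`, `cy` (cell centers, cell width 1),
#'   `nbr` (`n_cells x 6` neighbor index, `NA` at boundary), `opp` (length-6
#'   opposite-edge map), `normal` (`6 x 2` outward unit normals), and
#'   `partner` (`n_cells x 6` linear index into cell-by-edge matrices of the
#'   apposed edge; boundary edges point to themselves, the convention used by
#'   the mirror boundary condition).
#' @examples
#' g <- hex_grid(2, 3)
#' g$n_cells
#' @export
hex_grid <- function(n_rows = 6, n_cols = 30) {
  if (n_rows < 1 || n_cols < 1) stop_param("grid dimensions must be >= 1")
  n <- n_rows * n_cols
  row <- rep(seq_len(n_rows), times = n_cols)
  col <- rep(seq_len(n_cols), each = n_rows)
  cell_id <- function(r, c) (c - 1L) * n_rows + r
  odd <- (row %% 2L) == 0L  # rows 2,4,... offset by +1/2 cell
  cx <- col + 0.5 * odd
  cy <- row * sqrt(3) / 2

  ## neighbor (row, col) offsets per edge, split by row parity.
  ## edge order follows HEX_EDGE_ANGLES; y points down, so +60 deg = down-right.
  nbr <- matrix(NA_integer_, n, 6)
  off_even <- list(c(0, 1), c(1, 0), c(1, -1), c(0, -1), c(-1, -1), c(-1, 0))
  off_odd  <- list(c(0, 1), c(1, 1), c(1, 0),  c(0, -1), c(-1, 0),  c(-1, 1))
  for (e in 1:6) {
    dr_e <- ifelse(odd, off_odd[[e]][1], off_even[[e]][1])
    dc_e <- ifelse(odd, off_odd[[e]][2], off_even[[e]][2])
    rr <- row + dr_e
    cc <- col + dc_e
    ok <- rr >= 1 & rr <= n_rows & cc >= 1 & cc <= n_cols
    nbr[ok, e] <- cell_id(rr[ok], cc[ok])
  }

  opp <- ((seq_len(6) - 1L + 3L) %% 6L) + 1L
  ang <- deg2rad(HEX_EDGE_ANGLES)
  normal <- cbind(nx = cos(ang), ny = sin(ang))

  partner <- matrix(0L, n, 6)
  for (e in 1:6) {
    j <- nbr[, e]
    self <- (e - 1L) * n + seq_len(n)
    partner[, e] <- ifelse(is.na(j), self, (opp[e] - 1L) * n + j)
  }

  structure(
    list(n_rows = n_rows, n_cols = n_cols, n_cells = n,
         row = row, col = col, cx = cx, cy = cy,
         nbr = nbr, opp = opp, normal = normal, partner = partner),
    class = "hex_grid")
}

#' @export
print.hex_grid <- function(x, ...) {
  cat(sprintf("hex_grid: %d x %d cells (%d), P-D axis = +x\n",
              x$n_rows, x$n_cols, x$n_cells))
  invisible(x)
}

#' Cells belonging to given grid columns
#' @param grid a [hex_grid()].
#' @param cols column indices.
#' @return integer vector of cell indices.
#' @export
cells_in_columns <- function(grid, cols) {
  which(grid$col %in% cols)
}

## mean of a per-cell quantity by grid column
column_means <- function(grid, x) {
  as.numeric(tapply(x, grid$col, mean))
}
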