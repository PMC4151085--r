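## Tissue-level expression gradients along the proximal-distal axis.
## One level per grid column; proximal = column 1, distal = last column.

#' Build a P-D expression gradient
#'
#' Per-column expression levels for Ds or Fj along the proximal-distal axis.
#' Shapes mirror the configurations explored in the simulations: a linear
#' ramp, a two-level step, a steep proximal ramp followed by a flat (shallow)
#' distal plateau, the same ramp dropping to exactly zero distally, or
#' user-supplied values.
#'
#' @param kind one of `"linear"`, `"step"`, `"steep_flat"`, `"zero_distal"`,
#'   `"uniform"`, `"custom"`.
#' @param columns number of grid columns (>= 2).
#' @param high,low proximal and distal levels (defaults 1.5 and 0.1).
#' @param ramp_cols for `steep_flat`/`zero_distal`: number of proximal columns
#'   over which the level ramps down (default 8, matching the step position
#'   used in the kinetics figures).
#' @param step_col for `step`: last high column (default 8).
#' @param level for `uniform`: the constant level (default `high`).
#' @param values for `custom`: explicit per-column non-negative levels.
#' @return object of class `gradient_spec`: list with `kind` and `values`
#'   (length `columns`, all >= 0).
#' @examples
#' make_gradient("linear", 30)
#' make_gradient("step", 30, step_col = 8)
#' @export
make_gradient <- function(kind, columns,
                          high = 1.5, low = 0.1,
                          ramp_cols = 8, step_col = 8,
                          level = high, values = NULL) {
  if (columns < 2) stop_param("gradient needs at least 2 columns")
  kind <- match.arg(kind, c("linear", "step", "steep_flat", "zero_distal",
                            "uniform", "custom"))
  v <- switch(kind,
    linear = seq(high, low, length.out = columns),
    step = {
      if (step_col < 1 || step_col >= columns)
        stop_param("step_col must lie inside the grid")
      c(rep(high, step_col), rep(low, columns - step_col))
    },
    steep_flat = {
      if (ramp_cols < 2 || ramp_cols >= columns)
        stop_param("ramp_cols must lie inside the grid")
      c(seq(high, low, length.out = ramp_cols), rep(low, columns - ramp_cols))
    },
    zero_distal = {
      if (ramp_cols < 2 || ramp_cols >= columns)
        stop_param("ramp_cols must lie inside the grid")
      c(seq(high, 0, length.out = ramp_cols), rep(0, columns - ramp_cols))
    },
    uniform = rep(level, columns),
    custom = {
      if (is.null(values)) stop_param("custom gradient needs 'values'")
      values
    })
  if (length(v) != columns) stop_param("gradient length != columns")
  if (any(v < 0)) stop_param("gradient values must be >= 0")
  structure(list(kind = kind, values = as.numeric(v)), class = "gradient_spec")
}

#' @export
print.gradient_spec <- function(x, ...) {
  cat(sprintf("gradient_spec [%s], %d columns, range %.3g..%.3g\n",
              x$kind, length(x$values), max(x$values), min(x$values)))
  invisible(x)
}

## expand a gradient (or scalar, or per-cell vector) to a per-cell vector
per_cell_levels <- function(grid, g, what = "gradient") {
  if (inherits(g, "gradient_spec")) {
    if (length(g$values) != grid$n_cols)
      stop_param("%s has %d columns but grid has %d",
                 what, length(g$values), grid$n_cols)
    return(g$values[grid$col])
  }
  if (length(g) == 1L) return(rep(as.numeric(g), grid$n_cells))
  if (length(g) == grid$n_cells) return(as.numeric(g))
  stop_param("%s must be a gradient_spec, a scalar or a per-cell vector", what)
}
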