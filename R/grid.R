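#' The 24-hour analysis grid
#'
#' All curves in the package live on a common grid of 288 five-minute bins
#' covering the day `[0, 24)` hours. Bins are left-closed/right-open and are
#' labelled by their midpoints, so bin `j` (0-based) is the interval
#' `[5j, 5j+5)` minutes with midpoint `(5j + 2.5)/60` hours. Each grid point
#' carries a quadrature weight of 1/12 hour, so that
#' `sum(f * grid_weight())` approximates the integral of `f` over the day.
#'
#' @return `time_grid()` returns a numeric vector of 288 strictly increasing
#'   bin midpoints in hours; `grid_weight()` returns the scalar quadrature
#'   weight (hours per grid point).
#' @examples
#' t <- time_grid()
#' head(t)
#' sum(rep(1, 288) * grid_weight())  # integral of 1 over the day = 24
#' @export
time_grid <- function() {
  (5 * (0:287) + 2.5) / 60
}

#' @rdname time_grid
#' @export
grid_weight <- function() {
  1 / 12
}

# number of grid points, used internally
N_BINS <- 288L
N_MINUTES <- 1440L

#' Quadrature inner product on the daily grid
#'
#' Inner product `<f, g> = sum_j f(t_j) g(t_j) w` with `w = grid_weight()`.
#' Used for eigenfunction orthonormality and score computation.
#'
#' @param f,g numeric vectors of length 288.
#' @return a scalar.
#' @keywords internal
quad_inner <- function(f, g) {
  sum(f * g) * grid_weight()
}
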