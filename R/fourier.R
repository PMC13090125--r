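#' Frequency grid for mass-tolerant Fourier features
#'
#' The grid concatenates a low-frequency block of reciprocals of the integers
#' `m_max .. 1` (capturing the integer part of a mass; exactly `m_max`
#' entries) with a high-frequency block `1 / (k * m_min)` for
#' `k in {1, 1 + stride, ...}` up to the largest `k` with `k * m_min <= 1`,
#' listed in increasing order so the block ends exactly at `1 / m_min`
#' (capturing the decimal part down to the instrument accuracy `m_min`). With
#' the defaults (`m_min = 1e-4`, `m_max = 1000`, stride 2) the grid has 1000
#' low and 5000 high frequencies, 6000 in total. The stride-2 enumeration of
#' the high block is this package's documented reading of the grid
#' construction.
#'
#' @param m_min minimum decimal mass of interest (Da), in `(0, 1)`.
#' @param m_max maximum integer mass of interest (Da), above 1.
#' @param high_stride stride of the `k` enumeration in the high block.
#' @return a `fourier_grid` with `b` (frequencies), `n_low`, `n_high` and the
#'   construction parameters.
#' @export
fourier_grid <- function(m_min = 1e-4, m_max = 1000, high_stride = 2) {
  stop_if_not(m_min > 0 && m_min < 1, "m_min must lie in (0, 1)")
  stop_if_not(m_max > 1, "m_max must exceed 1")
  stop_if_not(high_stride >= 1, "high_stride must be >= 1")
  m_max <- as.integer(round(m_max))
  low <- 1 / seq(m_max, 1)
  k_max <- floor(1 / m_min + 1e-9)
  ks <- seq(1, k_max, by = high_stride)
  high <- rev(1 / (ks * m_min))
  structure(list(b = c(low, high), n_low = length(low), n_high = length(high),
                 m_min = m_min, m_max = m_max, high_stride = high_stride),
            class = "fourier_grid")
}

#' @export
print.fourier_grid <- function(x, ...) {
  cat(sprintf("<fourier_grid: %d low + %d high = %d frequencies>\n",
              x$n_low, x$n_high, length(x$b)))
  invisible(x)
}

#' Mass-tolerant Fourier features of m/z values
#'
#' Maps each mass to the interleaved vector
#' `(sin(2 pi b_1 m), cos(2 pi b_1 m), sin(2 pi b_2 m), ...)` of length `2B`,
#' every component in `[-1, 1]`.
#'
#' @param m numeric vector of masses (Da).
#' @param grid a [fourier_grid()].
#' @return matrix `length(m)` x `2B`; sine components in odd columns, cosines
#'   in even columns.
#' @export
fourier_features <- function(m, grid) {
  ang <- outer(as.numeric(m), 2 * pi * grid$b)
  B <- length(grid$b)
  out <- matrix(0, nrow = length(m), ncol = 2 * B)
  out[, seq(1, 2 * B, by = 2)] <- sin(ang)
  out[, seq(2, 2 * B, by = 2)] <- cos(ang)
  out
}
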