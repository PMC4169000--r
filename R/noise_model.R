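#' Fit a technical-replicate noise model along the MA plot
#'
#' The MATR calibration estimates the real spread of M as a function of A
#' from a pair of libraries prepared from the same biological condition.
#' Genes are sorted by A and summarized in sliding fixed-count windows
#' (default 500 genes, 50% overlap): each window records its median A, a
#' trimmed mean of M, and the standard deviation of M (floored at
#' \code{sd_floor}). The fitted model interpolates the local mean and SD
#' at arbitrary A inside the observed range and clamps outside it.
#'
#' Genes whose combined count is below \code{min_count} are excluded from
#' the fit: their M values are dominated by count discreteness and would
#' distort the low-A windows.
#'
#' @param rep_a,rep_b Count vectors for the two replicate libraries.
#' @param window_size Genes per window (>= 20; default 500).
#' @param overlap Fraction of window shared with its neighbour (default 0.5).
#' @param trim Trim fraction for the windowed mean of M (default 0.1).
#' @param sd_floor Minimum SD reported for any window (default 1e-3).
#' @param min_count Minimum combined count for a gene to enter the fit.
#' @param pseudocount Pseudocount for the M/A computation.
#' @return An object of class \code{noise_model}: a list with the window
#'   grid (\code{grid_a}), the local \code{mean_m} and \code{sd_m}, and
#'   the per-window gene count \code{n}.
#' @export
fit_noise_model <- function(rep_a, rep_b, window_size = 500, overlap = 0.5,
                            trim = 0.1, sd_floor = 1e-3, min_count = 10,
                            pseudocount = 0.5) {
  stopifnot(length(rep_a) == length(rep_b), window_size >= 20,
            overlap >= 0, overlap < 1, sd_floor > 0)
  keep <- (rep_a + rep_b) >= min_count
  ma <- compute_ma(rep_a[keep], rep_b[keep], pseudocount)
  n <- nrow(ma)
  if (n < window_size) {
    stop("fewer genes (", n, ") than one window (", window_size, ") after ",
         "the combined-count filter")
  }
  ord <- order(ma$A)
  A <- ma$A[ord]
  M <- ma$M[ord]
  step <- max(1L, as.integer(round(window_size * (1 - overlap))))
  starts <- seq(1L, n - window_size + 1L, by = step)
  # make sure the top of the A range is covered
  if (starts[length(starts)] + window_size - 1L < n) {
    starts <- c(starts, n - window_size + 1L)
  }
  grid_a <- numeric(length(starts))
  mean_m <- numeric(length(starts))
  sd_m <- numeric(length(starts))
  for (i in seq_along(starts)) {
    idx <- starts[i]:(starts[i] + window_size - 1L)
    grid_a[i] <- stats::median(A[idx])
    mean_m[i] <- mean(M[idx], trim = trim)
    sd_m[i] <- max(stats::sd(M[idx]), sd_floor)
  }
  # windows can share a median A when counts tie; keep the grid strictly
  # increasing by averaging duplicated grid points
  if (anyDuplicated(grid_a)) {
    mean_m <- as.numeric(tapply(mean_m, grid_a, mean))
    sd_m <- as.numeric(tapply(sd_m, grid_a, mean))
    n_w <- as.numeric(tapply(rep(window_size, length(grid_a)), grid_a, sum))
    grid_a <- sort(unique(grid_a))
  } else {
    n_w <- rep(window_size, length(grid_a))
  }
  structure(
    list(grid_a = grid_a, mean_m = mean_m, sd_m = sd_m, n = n_w,
         sd_floor = sd_floor, window_size = window_size),
    class = "noise_model"
  )
}

#' @export
print.noise_model <- function(x, ...) {
  cat("Technical-replicate noise model (MATR calibration)\n")
  cat(sprintf("  %d windows of %d genes; A range [%.2f, %.2f]\n",
              length(x$grid_a), x$window_size,
              min(x$grid_a), max(x$grid_a)))
  cat(sprintf("  SD(M|A) range [%.4f, %.4f] (floor %.1e)\n",
              min(x$sd_m), max(x$sd_m), x$sd_floor))
  invisible(x)
}

#' Interpolate a noise model at given A values
#'
#' Linear interpolation of the local mean and SD of M; A values outside
#' the fitted range are clamped to the nearest window.
#'
#' @param model A \code{noise_model}.
#' @param A Numeric vector of average log2 expression values.
#' @return data.frame with columns \code{mean_m} and \code{sd_m}.
#' @export
interpolate_noise <- function(model, A) {
  stopifnot(inherits(model, "noise_model"), all(is.finite(A)))
  if (length(model$grid_a) == 1L) {
    return(data.frame(mean_m = rep(model$mean_m, length(A)),
                      sd_m = rep(model$sd_m, length(A))))
  }
  data.frame(
    mean_m = stats::approx(model$grid_a, model$mean_m, xout = A,
                           rule = 2)$y,
    sd_m = stats::approx(model$grid_a, model$sd_m, xout = A, rule = 2)$y
  )
}

#' Replicate-calibrated (MATR) z-score
#'
#' Rescales an observed M by the technical-replicate noise local to its A:
#' \deqn{z = (M - \widehat{mean}(M|A)) / \widehat{SD}(M|A)}
#'
#' @param M,A Numeric vectors of equal length (finite A required).
#' @param model A fitted \code{noise_model}.
#' @return Numeric z vector.
#' @export
matr_zscore <- function(M, A, model) {
  stopifnot(length(M) == length(A))
  loc <- interpolate_noise(model, A)
  (M - loc$mean_m) / loc$sd_m
}

#' Average several noise models pointwise
#'
#' When more than one replicate pair is available (e.g. duplicated control
#' and duplicated knockdown libraries), a model is fitted per pair and the
#' mean/SD curves averaged pointwise on the union of their A grids
#' (restricted to the range common to all models).
#'
#' @param models List of \code{noise_model} objects.
#' @return A combined \code{noise_model}.
#' @export
average_noise_models <- function(models) {
  stopifnot(length(models) >= 1,
            all(vapply(models, inherits, logical(1), "noise_model")))
  if (length(models) == 1L) return(models[[1]])
  lo <- max(vapply(models, function(m) min(m$grid_a), numeric(1)))
  hi <- min(vapply(models, function(m) max(m$grid_a), numeric(1)))
  grid <- sort(unique(unlist(lapply(models, `[[`, "grid_a"))))
  grid <- grid[grid >= lo & grid <= hi]
  if (length(grid) < 2) grid <- c(lo, hi)
  interp <- lapply(models, interpolate_noise, A = grid)
  structure(
    list(
      grid_a = grid,
      mean_m = rowMeans(sapply(interp, `[[`, "mean_m")),
      sd_m = rowMeans(sapply(interp, `[[`, "sd_m")),
      n = rowMeans(sapply(models, function(m) {
        stats::approx(m$grid_a, m$n, xout = grid, rule = 2)$y
      })),
      sd_floor = max(vapply(models, `[[`, numeric(1), "sd_floor")),
      window_size = models[[1]]$window_size
    ),
    class = "noise_model"
  )
}
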