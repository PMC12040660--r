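#' Preprocessing configuration
#'
#' Defaults follow standard practice for near-infrared serum SERS:
#' Savitzky-Golay smoothing with a 15-channel window, polynomial order 1 and
#' no derivative; iterative degree-15 polynomial baseline removal; standard
#' normal variate scaling last.
#'
#' @param sg_window odd smoothing window length in channels (>= 3).
#' @param sg_polyorder polynomial order of the smoother, `< sg_window`.
#' @param sg_deriv derivative order, `<= sg_polyorder` (0 = smoothing only).
#' @param baseline_degree polynomial degree of the baseline estimate.
#' @param baseline_max_iter iteration cap of the clipped refit loop.
#' @param baseline_tol relative tolerance on the residual sd used to stop
#'   the baseline iteration.
#' @param baseline_method `"imodpoly"` (iterative clipped refit, default) or
#'   `"plain"` (single unweighted fit).
#' @return configuration list of class `preprocess_config`.
#' @export
preprocess_config <- function(sg_window = 15, sg_polyorder = 1, sg_deriv = 0,
                              baseline_degree = 15, baseline_max_iter = 100,
                              baseline_tol = 1e-3,
                              baseline_method = c("imodpoly", "plain")) {
  cfg <- list(
    sg_window = as.integer(sg_window), sg_polyorder = as.integer(sg_polyorder),
    sg_deriv = as.integer(sg_deriv), baseline_degree = as.integer(baseline_degree),
    baseline_max_iter = as.integer(baseline_max_iter),
    baseline_tol = baseline_tol, baseline_method = match.arg(baseline_method)
  )
  if (cfg$sg_window < 3 || cfg$sg_window %% 2 == 0) abort("sg_window must be odd and >= 3")
  if (cfg$sg_polyorder < 0 || cfg$sg_polyorder >= cfg$sg_window) {
    abort("need 0 <= sg_polyorder < sg_window")
  }
  if (cfg$sg_deriv < 0 || cfg$sg_deriv > cfg$sg_polyorder) {
    abort("need 0 <= sg_deriv <= sg_polyorder")
  }
  if (cfg$baseline_degree < 0) abort("baseline_degree must be >= 0")
  class(cfg) <- "preprocess_config"
  cfg
}

# convolution weights: least-squares polynomial fit over a centered window,
# evaluated (d-th derivative) at the window center
savgol_kernel <- function(window, polyorder, deriv = 0) {
  h <- (window - 1L) %/% 2L
  A <- outer(seq.int(-h, h), 0:polyorder, `^`)
  G <- solve(crossprod(A), t(A))
  factorial(deriv) * G[deriv + 1L, ]
}

#' Savitzky-Golay smoothing
#'
#' Replaces each point by the center value of a least-squares polynomial fit
#' over a sliding window. Edges are handled by point-symmetric (odd)
#' reflection about the first and last samples, which keeps the output the
#' same length as the input and reproduces affine signals exactly.
#'
#' @param x numeric intensity vector.
#' @param window odd window length, `3 <= window <= length(x)`.
#' @param polyorder fit degree, `< window`.
#' @param deriv derivative order returned (0 = smoothed signal).
#' @return numeric vector, same length as `x`.
#' @export
savgol_smooth <- function(x, window = 15, polyorder = 1, deriv = 0) {
  n <- length(x)
  if (window %% 2 == 0 || window < 3) abort("window must be odd and >= 3")
  if (window > n) abort("window must not exceed the spectrum length")
  if (polyorder >= window) abort("polyorder must be < window")
  if (deriv > polyorder) abort("deriv must be <= polyorder")
  if (!all(is.finite(x))) abort("non-finite intensity values")
  h <- (window - 1L) %/% 2L
  k <- savgol_kernel(window, polyorder, deriv)
  xp <- c(2 * x[1] - x[(h + 1):2], x, 2 * x[n] - x[(n - 1):(n - h)])
  drop(stats::embed(xp, window) %*% rev(k))
}

#' Polynomial baseline correction
#'
#' Estimates the smooth autofluorescent background with a degree-`degree`
#' polynomial and returns both the background and the corrected spectrum
#' (`corrected + baseline` reconstructs the input exactly). The default
#' scheme is the iterative modified polyfit: after each fit, points above
#' the current fit are clipped down to it before refitting, so sharp peaks
#' stop pulling the fit upwards; iteration ends when the residual standard
#' deviation changes by less than `tol` (relative) or after `max_iter`
#' rounds. Fitting uses an orthogonal polynomial basis on the axis rescaled
#' to \[-1, 1\]; a raw monomial basis at degree 15 would be numerically
#' singular.
#'
#' @param x numeric intensity vector (finite).
#' @param degree polynomial degree, `< length(x) - 1`.
#' @param max_iter,tol iteration controls (see above).
#' @param method `"imodpoly"` or `"plain"` (single unweighted fit).
#' @return list with numeric vectors `corrected` and `baseline`.
#' @export
baseline_correct <- function(x, degree = 15, max_iter = 100, tol = 1e-3,
                             method = c("imodpoly", "plain")) {
  method <- match.arg(method)
  n <- length(x)
  if (degree >= n - 1) abort("degree must be < length(x) - 1")
  if (!all(is.finite(x))) abort("non-finite intensity values")
  u <- seq(-1, 1, length.out = n)
  B <- cbind(1, stats::poly(u, degree))
  Q <- qr.Q(qr(B))
  proj <- function(y) drop(Q %*% crossprod(Q, y))
  b <- proj(x)
  if (method == "imodpoly") {
    y <- x
    s_prev <- stats::sd(y - b)
    for (i in seq_len(max_iter)) {
      y <- pmin(y, b)
      b <- proj(y)
      s <- stats::sd(y - b)
      if (s_prev <= 0 || abs(s_prev - s) <= tol * s_prev) break
      s_prev <- s
    }
  }
  list(corrected = x - b, baseline = b)
}

#' Standard normal variate scaling
#'
#' Centers a spectrum to mean zero and scales it to unit sample standard
#' deviation (n - 1 denominator).
#'
#' @param x numeric vector with at least 2 channels and nonzero sd.
#' @return scaled numeric vector.
#' @export
snv <- function(x) {
  if (length(x) < 2) abort("snv needs at least 2 channels")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) abort("snv is undefined for a constant spectrum")
  (x - mean(x)) / s
}

#' Estimate the signal-to-noise ratio of one spectrum
#'
#' SNR is defined as the peak-to-peak range of the smoothed signal divided
#' by the sample standard deviation of the smoothing residual:
#' `(max(smoothed) - min(smoothed)) / sd(raw - smoothed)`. A zero residual
#' (noise-free input) returns `Inf`.
#'
#' @param raw,smoothed numeric vectors of equal length.
#' @return dimensionless ratio.
#' @export
estimate_snr <- function(raw, smoothed) {
  if (length(raw) != length(smoothed)) abort("raw and smoothed differ in length")
  s <- stats::sd(raw - smoothed)
  if (!is.finite(s) || s == 0) return(Inf)
  (max(smoothed) - min(smoothed)) / s
}

#' Preprocess every spectrum of a dataset
#'
#' Applies, row by row and in this fixed order: Savitzky-Golay smoothing,
#' polynomial baseline removal (the corrected part is kept), and standard
#' normal variate scaling. The axis and metadata are unchanged. The order
#' is part of the contract: SNV last guarantees every output row has mean 0
#' and sd 1.
#'
#' @param ds spectra tibble (see [spectra_tbl()]).
#' @param cfg a [preprocess_config()].
#' @param verbose if `TRUE`, print a one-line summary (rows processed, SNR
#'   min/median estimated from the smoothing step).
#' @return spectra tibble of preprocessed intensities.
#' @export
preprocess_dataset <- function(ds, cfg = preprocess_config(), verbose = FALSE) {
  validate_spectra(ds)
  if (nrow(ds) == 0L) return(ds)
  X <- spectra_matrix(ds)
  snr <- numeric(nrow(X))
  out <- matrix(0, nrow(X), ncol(X), dimnames = dimnames(X))
  for (i in seq_len(nrow(X))) {
    res <- tryCatch({
      sm <- savgol_smooth(X[i, ], cfg$sg_window, cfg$sg_polyorder, cfg$sg_deriv)
      snr[i] <- estimate_snr(X[i, ], sm)
      bc <- baseline_correct(sm, cfg$baseline_degree, cfg$baseline_max_iter,
                             cfg$baseline_tol, cfg$baseline_method)
      snv(bc$corrected)
    }, error = function(e) {
      abort(sprintf("preprocessing failed for spectrum '%s': %s",
                    ds$spectrum_id[i], conditionMessage(e)))
    })
    out[i, ] <- res
  }
  if (verbose) {
    message(sprintf("preprocessed %d spectra; SNR min %.1f, median %.1f",
                    nrow(X), min(snr), stats::median(snr)))
  }
  rebuild_spectra(ds, out)
}
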