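#' Fit a univariate-response PLS model by NIPALS
#'
#' Partial least squares regression of a single numeric response on a
#' centered predictor matrix, extracting latent components sequentially by
#' NIPALS with X-deflation: for each component `a`, the weight vector is
#' `w = X'y` normalized to unit length, the score `t = Xw`, the x-loading
#' `p = X't / t't`, the y-loading `q = y't / t't`, and `X` is deflated by
#' `t p'`. Regression coefficients on the original (centered) predictors
#' are assembled as `W (P'W)^{-1} q`. With a dummy-coded class response
#' (Target = 1, Control = 0) this is PLS-DA.
#'
#' @param X numeric matrix, rows = spectra, columns = channels.
#' @param y numeric response; for classification, use `class_code()`.
#' @param ncomp number of latent components `A`,
#'   `1 <= A <= min(nrow(X) - 1, ncol(X))`.
#' @return object of class `plsda_fit` with elements `x_mean`, `y_mean`,
#'   `W`, `P`, `T` (scores), `q`, `coef`, `ncomp`, `axis` (channel names as
#'   wavenumbers, when available).
#' @export
pls_fit <- function(X, y, ncomp) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) abort("length(y) must equal nrow(X)")
  if (ncomp < 1 || ncomp > min(n - 1, p)) {
    abort(sprintf("ncomp must be in [1, %d]", min(n - 1, p)))
  }
  if (stats::sd(y) == 0) abort("response has a single value; need both classes")
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  Xa <- sweep(X, 2, x_mean)
  yc <- y - y_mean
  W <- P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp)
  q <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    w <- crossprod(Xa, yc)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12 * max(1, sqrt(sum(Xa^2)))) {
      abort(sprintf("component %d: X'y has vanished (no residual covariance)", a))
    }
    w <- w / nw
    tt <- Xa %*% w
    t2 <- sum(tt^2)
    if (t2 < .Machine$double.eps * n) {
      abort(sprintf("component %d: degenerate score vector", a))
    }
    W[, a] <- w
    Tm[, a] <- tt
    P[, a] <- crossprod(Xa, tt) / t2
    q[a] <- sum(yc * tt) / t2
    Xa <- Xa - tcrossprod(tt, P[, a])
  }
  coef <- drop(W %*% solve(crossprod(P, W), q))
  axis <- suppressWarnings(as.numeric(colnames(X)))
  if (length(axis) != p || anyNA(axis)) axis <- as.numeric(seq_len(p))
  structure(
    list(x_mean = x_mean, y_mean = y_mean, W = W, P = P, T = Tm, q = q,
         coef = coef, ncomp = as.integer(ncomp), axis = axis),
    class = "plsda_fit"
  )
}

# coefficients using only the first A components of an existing fit
pls_coef_trunc <- function(model, A) {
  W <- model$W[, seq_len(A), drop = FALSE]
  P <- model$P[, seq_len(A), drop = FALSE]
  drop(W %*% solve(crossprod(P, W), model$q[seq_len(A)]))
}

#' Dummy-code a two-class label vector
#' @param group character or factor with values `"Target"` / `"Control"`.
#' @return numeric vector, Target = 1, Control = 0.
#' @export
class_code <- function(group) {
  as.numeric(as.character(group) == "Target")
}

#' Fit PLS-DA to a spectra tibble
#'
#' Data-frame-first wrapper around [pls_fit()]: builds the predictor matrix
#' and the Target = 1 / Control = 0 response from a spectra tibble. If
#' `ncomp` is `NULL` the component count is chosen by subject-grouped
#' stratified k-fold cross-validation ([select_components()]).
#'
#' @param ds spectra tibble (usually preprocessed).
#' @param ncomp number of latent components, or `NULL` to cross-validate.
#' @param k,grid,seed passed to [select_components()] when `ncomp` is `NULL`.
#' @return a `plsda_fit` (with the cross-validation record attached as
#'   `$cv` when selection was used).
#' @export
fit_plsda <- function(ds, ncomp = NULL, k = 7, grid = NULL, seed = 1L) {
  validate_spectra(ds)
  X <- spectra_matrix(ds)
  y <- class_code(ds$group)
  if (length(unique(y)) < 2) abort("dataset must contain both classes")
  cv <- NULL
  if (is.null(ncomp)) {
    cv <- select_components(X, y, ds$subject_id, k = k, grid = grid, seed = seed)
    ncomp <- cv$chosen_A
  }
  fit <- pls_fit(X, y, ncomp)
  fit$cv <- cv
  fit
}

#' Predict class scores and labels from a PLS-DA fit
#'
#' The continuous score is `y_mean + (Xnew - x_mean) %*% coef`; the class
#' rule is Target iff score >= 0.5 (ties go to Target).
#'
#' @param object a `plsda_fit`.
#' @param newdata spectra tibble or numeric matrix with the model's channel
#'   count.
#' @param ... unused.
#' @return tibble with columns `score` (numeric) and `label`
#'   (factor Target/Control).
#' @export
predict.plsda_fit <- function(object, newdata, ...) {
  X <- if (is.data.frame(newdata)) spectra_matrix(newdata) else as.matrix(newdata)
  if (ncol(X) != length(object$x_mean)) {
    abort(sprintf("newdata has %d channels; model expects %d",
                  ncol(X), length(object$x_mean)))
  }
  score <- drop(sweep(X, 2, object$x_mean) %*% object$coef) + object$y_mean
  tibble(
    score = score,
    label = factor(ifelse(score >= 0.5, "Target", "Control"), levels = .group_levels)
  )
}

#' Variable importance in projection
#'
#' For channel `j`,
#' `VIP_j = sqrt( p * sum_a SS_a (w_ja / ||w_a||)^2 / sum_a SS_a )` with
#' `SS_a = q_a^2 t_a't_a`, the y-variance explained by component `a`, and
#' `p` the number of channels. By construction `mean(VIP^2) = 1`, so 1 is
#' the conventional "more important than average" cutoff.
#'
#' @param model a `plsda_fit`.
#' @return tibble of class `vip_profile` with columns `wavenumber`, `vip`.
#' @export
vip <- function(model) {
  stopifnot(inherits(model, "plsda_fit"))
  SS <- model$q^2 * colSums(model$T^2)
  p <- nrow(model$W)
  v <- sqrt(p * drop(model$W^2 %*% SS) / sum(SS))
  out <- tibble(wavenumber = model$axis, vip = v)
  class(out) <- c("vip_profile", class(out))
  out
}

# deterministic subject-grouped, group-stratified fold assignment:
# subjects of each class are shuffled and dealt round-robin over k folds,
# so replicates of one subject can never straddle a fold
make_subject_folds <- function(subject_id, group, k, seed) {
  subj <- unique(tibble(subject_id = subject_id, group = as.character(group)))
  if (nrow(subj) < k) abort("fewer distinct subjects than folds")
  withr::with_seed(seed, {
    out <- subj |>
      dplyr::group_by(.data$group) |>
      dplyr::slice_sample(prop = 1) |>
      dplyr::mutate(fold = rep_len(seq_len(k), dplyr::n())) |>
      dplyr::ungroup()
  })
  out[, c("subject_id", "group", "fold")]
}

#' Choose the number of PLS components by cross-validation
#'
#' Subjects (never individual spectra) are partitioned into `k` folds,
#' stratified by class. For each candidate component count the mean
#' held-out spectrum-level accuracy over folds is computed from a single
#' `max(grid)`-component fit per fold (truncated coefficients give every
#' smaller model for free). The winner maximizes cross-validated accuracy;
#' exact ties go to the smallest count, a parsimony guard against
#' overfitting.
#'
#' @param X predictor matrix (rows = spectra).
#' @param y numeric 0/1 response.
#' @param subject_id per-row subject identifier.
#' @param k number of folds (default 7).
#' @param grid candidate component counts; `NULL` means `1:15` capped at
#'   the rank bound `min(n - 1, p)`. Explicit grid values beyond the bound
#'   are an error.
#' @param seed integer; fold assignment is deterministic given the seed.
#' @return object of class `cv_selection`: `grid`, `cv_accuracy`,
#'   `chosen_A`, `k`, `folds` (subject-to-fold tibble).
#' @export
select_components <- function(X, y, subject_id, k = 7, grid = NULL, seed = 1L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (k < 2) abort("k must be >= 2")
  bound <- min(nrow(X) - 1L, ncol(X))
  if (is.null(grid)) {
    grid <- seq_len(min(15L, bound))
  } else {
    grid <- sort(unique(as.integer(grid)))
    if (length(grid) == 0) abort("grid must be nonempty")
    if (max(grid) > bound) {
      abort(sprintf("grid values exceed the rank bound %d", bound))
    }
  }
  folds <- make_subject_folds(subject_id, ifelse(y == 1, "Target", "Control"),
                              k, seed)
  fold_of <- folds$fold[match(subject_id, folds$subject_id)]
  acc <- matrix(NA_real_, k, length(grid))
  for (f in seq_len(k)) {
    tr <- fold_of != f
    if (length(unique(y[tr])) < 2 || !any(!tr)) next
    a_max <- min(max(grid), sum(tr) - 1L)
    fit <- pls_fit(X[tr, , drop = FALSE], y[tr], a_max)
    Xte <- sweep(X[!tr, , drop = FALSE], 2, fit$x_mean)
    for (gi in seq_along(grid)) {
      A <- grid[gi]
      if (A > a_max) next
      score <- drop(Xte %*% pls_coef_trunc(fit, A)) + fit$y_mean
      acc[f, gi] <- mean((score >= 0.5) == (y[!tr] == 1))
    }
  }
  cv_accuracy <- colMeans(acc, na.rm = TRUE)
  chosen_A <- grid[which.max(cv_accuracy)]
  structure(
    list(grid = grid, cv_accuracy = cv_accuracy, chosen_A = chosen_A,
         k = k, folds = folds, seed = seed),
    class = "cv_selection"
  )
}

#' Serialize a PLS-DA model to JSON
#'
#' Full-precision (round-trip exact) JSON document; [pls_load()] restores a
#' model whose predictions are bit-identical to the original's.
#'
#' @param model a `plsda_fit`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
pls_save <- function(model, path) {
  stopifnot(inherits(model, "plsda_fit"))
  obj <- model[c("x_mean", "y_mean", "q", "coef", "ncomp", "axis")]
  # matrices stored as lists of columns for an unambiguous round trip
  for (nm in c("W", "P", "T")) {
    obj[[nm]] <- list(nrow = nrow(model[[nm]]),
                      cols = asplit(model[[nm]], 2))
  }
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname pls_save
#' @export
pls_load <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("W", "P", "T")) {
    m <- obj[[nm]]
    cols <- if (is.matrix(m$cols)) asplit(m$cols, 1) else as.list(m$cols)
    obj[[nm]] <- matrix(unlist(cols), nrow = m$nrow)
  }
  for (nm in c("x_mean", "y_mean", "q", "coef", "axis")) {
    obj[[nm]] <- as.numeric(obj[[nm]])
  }
  obj$ncomp <- as.integer(obj$ncomp)
  structure(obj, class = "plsda_fit")
}

#' @export
print.plsda_fit <- function(x, ...) {
  cat(sprintf("PLS-DA fit: %d channels, %d latent components\n",
              length(x$coef), x$ncomp))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a PLS-DA fit: one row per channel
#' @param x a `plsda_fit`.
#' @param ... unused.
#' @return tibble with `wavenumber`, `estimate` (regression coefficient)
#'   and `vip`.
#' @exportS3Method generics::tidy
tidy.plsda_fit <- function(x, ...) {
  tibble(wavenumber = x$axis, estimate = x$coef, vip = vip(x)$vip)
}

#' One-row summary of a PLS-DA fit
#' @param x a `plsda_fit`.
#' @param ... unused.
#' @return tibble with `ncomp`, `n` (training spectra), `p` (channels).
#' @exportS3Method generics::glance
glance.plsda_fit <- function(x, ...) {
  tibble(ncomp = x$ncomp, n = nrow(x$T), p = length(x$coef))
}
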