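# One-class PLS: PLS1 regression of a constant unit response on the raw
# (uncentered) feature matrix. Centering X would make every column orthogonal
# to the constant response (X'y = 0) and collapse all weights to zero, so the
# model is fitted without column centering; an audit flag exists but is off.

#' Fit a one-class PLS model
#'
#' Fits a PLS1 model of a constant unit response on the training samples of
#' one batch. Conformity of new samples is later judged from the absolute
#' centered residual (ACR): authentic-like samples predict close to 1 and
#' have ACR near the training spread, while samples off the class subspace
#' have large ACR.
#'
#' The response is all ones and is not centered; the feature matrix is not
#' column-centered either (see Details). Optional unit-variance column
#' scaling accommodates variables on mixed measurement scales.
#'
#' @details Centering the columns of `X` would make each column orthogonal
#'   to the constant response and degenerate every PLS weight vector to
#'   zero, so the one-class construction requires the uncentered fit. The
#'   algorithm is NIPALS PLS1 with standard deflation of `X` only (the
#'   response is constant and is not deflated); with a single response
#'   NIPALS converges in one pass per component.
#'
#' @param data A composition table: `sample_id` column + numeric variables
#'   (see [as_composition()]).
#' @param n_lv Number of latent variables, `1 <= n_lv <= min(n, p)`.
#'   Default 1: the first component tracks the (1/sd-weighted) mean
#'   composition direction, which is the stable choice for conformity
#'   scoring; later components follow within-batch noise.
#' @param scaling `"unit_variance"` (default; divide each column by its
#'   training standard deviation, so trace constituents carry the same
#'   weight as abundant ones) or `"none"`. Zero-variance columns are an
#'   error under `"unit_variance"`.
#' @param center Audit flag; must remain `FALSE` (column centering
#'   degenerates the constant-response fit, see Details).
#' @return An object of class `"ocpls"`: coefficients, per-component
#'   weights/loadings, training scores and their mean/covariance, the mean
#'   training residual `e_bar`, and the preprocessing spec.
#' @examples
#' batch <- tibble::tibble(sample_id = letters[1:3], x = c(1, 2, 3))
#' m <- fit_ocpls(batch, n_lv = 1)
#' predict(m, batch)
#' @seealso [predict.ocpls()], [score_distance()], [build_population()]
#' @export
fit_ocpls <- function(data, n_lv = 1, scaling = c("unit_variance", "none"),
                      center = FALSE) {
  scaling <- match.arg(scaling)
  X <- composition_matrix(data)
  fit <- ocpls_fit_matrix(X, n_lv = n_lv, scaling = scaling, center = center,
                          keep_scores = TRUE)
  structure(
    c(fit, list(variable_names = colnames(X), train_ids = rownames(X))),
    class = "ocpls"
  )
}

# Lean matrix-level fit used both by fit_ocpls() and the Monte Carlo loop.
# Returns coefficients b (on the preprocessed scale), e_bar, and (optionally)
# the score-space pieces needed for score distances.
ocpls_fit_matrix <- function(X, n_lv, scaling = "unit_variance", center = FALSE,
                             keep_scores = FALSE, tol = 1e-12, max_iter = 500) {
  n <- nrow(X)
  p <- ncol(X)
  if (isTRUE(center)) {
    abort(paste0(
      "center = TRUE degenerates the one-class fit: centered columns are ",
      "orthogonal to the constant response, so all PLS weights vanish."
    ))
  }
  if (n_lv < 1 || n_lv != round(n_lv)) abort("`n_lv` must be a positive integer.")
  if (n_lv > min(n, p)) {
    abort(paste0("`n_lv` = ", n_lv, " exceeds min(n = ", n, ", p = ", p, ")."))
  }
  scale_vec <- rep(1, p)
  if (scaling == "unit_variance") {
    sds <- apply(X, 2, sd)
    bad <- which(sds <= 0 | !is.finite(sds))
    if (length(bad)) {
      abort(paste0("zero-variance column under unit_variance scaling: ",
                   paste(colnames(X)[bad], collapse = ", ")))
    }
    scale_vec <- sds
    X <- sweep(X, 2, sds, "/")
  }
  y <- rep(1, n)
  W <- matrix(0, p, n_lv)
  P <- matrix(0, p, n_lv)
  Tm <- matrix(0, n, n_lv)
  q <- numeric(n_lv)
  Xd <- X
  for (a in seq_len(n_lv)) {
    # PLS1 inner NIPALS: with a single (constant) response the weight
    # update is closed-form and converges in one pass.
    w <- crossprod(Xd, y)[, 1]
    nw <- sqrt(sum(w * w))
    if (nw < tol) {
      abort(paste0("deflated X is numerically orthogonal to the response at ",
                   "component ", a, "; reduce `n_lv`."))
    }
    w <- w / nw
    t_a <- Xd %*% w
    tt <- sum(t_a * t_a)
    p_a <- crossprod(Xd, t_a)[, 1] / tt
    q[a] <- sum(t_a) / tt            # t'y with y = 1
    Xd <- Xd - tcrossprod(t_a, p_a)  # deflate X only; y stays constant
    W[, a] <- w
    P[, a] <- p_a
    Tm[, a] <- t_a
  }
  # b maps preprocessed X to y_hat: T = X W (P'W)^-1, y_hat = T q = X b
  R <- W %*% solve(crossprod(P, W))
  b <- (R %*% q)[, 1]
  y_hat <- (X %*% b)[, 1]
  resid <- 1 - y_hat
  e_bar <- mean(resid)
  out <- list(
    n_lv = n_lv, coefficients = b, e_bar = e_bar,
    scaling = scaling, scale = scale_vec, train_size = n
  )
  if (keep_scores) {
    out$weights <- W
    out$x_loadings <- P
    out$y_loadings <- q
    out$rotation <- R
    out$train_scores <- Tm
    out$score_mean <- colMeans(Tm)
    out$score_covariance <- cov(Tm)
    out$train_fitted <- y_hat
    out$train_residuals <- resid
  }
  out
}

# Align a query table's variable columns to the model's, erroring with the
# missing/extra names, and apply the fitted preprocessing.
ocpls_query_matrix <- function(object, new_data) {
  Xq <- composition_matrix(new_data, min_rows = 1)
  want <- object$variable_names
  missing <- setdiff(want, colnames(Xq))
  extra <- setdiff(colnames(Xq), want)
  if (length(missing) || length(extra)) {
    abort(paste0(
      "variable mismatch with the fitted model",
      if (length(missing)) paste0("; missing: ", paste(missing, collapse = ", ")),
      if (length(extra)) paste0("; extra: ", paste(extra, collapse = ", "))
    ))
  }
  Xq <- Xq[, want, drop = FALSE]
  if (object$scaling == "unit_variance") Xq <- sweep(Xq, 2, object$scale, "/")
  Xq
}

#' Predict conformity statistics for new samples
#'
#' Applies a fitted one-class PLS model to a query table and returns, per
#' sample, the predicted response, the raw residual `1 - y_hat`, the
#' residual centered on the training mean residual, the absolute centered
#' residual (ACR), and the score distance (SD).
#'
#' @param object A fitted `"ocpls"` model.
#' @param new_data A composition table with the same variables as the
#'   training data (order-insensitive; matched by name).
#' @param ... Unused.
#' @return A tibble with columns `sample_id`, `y_hat`, `raw_residual`,
#'   `centered_residual`, `acr`, `sd`.
#' @export
predict.ocpls <- function(object, new_data, ...) {
  Xq <- ocpls_query_matrix(object, new_data)
  y_hat <- unname((Xq %*% object$coefficients)[, 1])
  raw <- 1 - y_hat
  centered <- raw - object$e_bar
  tibble(
    sample_id = rownames(Xq),
    y_hat = y_hat,
    raw_residual = raw,
    centered_residual = centered,
    acr = abs(centered),
    sd = score_distance_matrix(object, Xq)
  )
}

#' Score distance from the class center
#'
#' Mahalanobis-type distance of a query sample's latent scores from the
#' training score mean, under the training score covariance (pseudo-inverse
#' when singular). Reported for diagnostics; the detection decision uses
#' ACR only.
#'
#' @inheritParams predict.ocpls
#' @param model A fitted `"ocpls"` model.
#' @return A numeric vector of nonnegative distances, one per query row.
#' @export
score_distance <- function(model, new_data) {
  score_distance_matrix(model, ocpls_query_matrix(model, new_data))
}

score_distance_matrix <- function(object, Xq) {
  scores <- Xq %*% object$rotation
  dev <- sweep(scores, 2, object$score_mean)
  prec <- MASS::ginv(object$score_covariance)
  d2 <- rowSums((dev %*% prec) * dev)
  unname(sqrt(pmax(d2, 0)))
}

#' @export
print.ocpls <- function(x, ...) {
  cat("One-class PLS model\n")
  cat("  training samples:", x$train_size, "\n")
  cat("  variables:       ", length(x$variable_names), "\n")
  cat("  latent variables:", x$n_lv, "\n")
  cat("  scaling:         ", x$scaling, "\n")
  cat("  mean train residual (e_bar):", format(x$e_bar, digits = 6), "\n")
  invisible(x)
}

#' Tidy a one-class PLS model
#'
#' @param x A fitted `"ocpls"` model.
#' @param ... Unused.
#' @return `tidy()`: one row per variable with the regression coefficient
#'   (on the preprocessed scale) and per-component weights. `glance()`: a
#'   one-row model summary.
#' @exportS3Method generics::tidy
tidy.ocpls <- function(x, ...) {
  wt <- as_tibble(x$weights, .name_repair = ~ paste0("w", seq_along(.x)))
  dplyr::bind_cols(
    tibble(variable = x$variable_names, coefficient = unname(x$coefficients)),
    wt
  )
}

#' @rdname tidy.ocpls
#' @exportS3Method generics::glance
glance.ocpls <- function(x, ...) {
  tibble(
    n_train = x$train_size,
    n_vars = length(x$variable_names),
    n_lv = x$n_lv,
    scaling = x$scaling,
    e_bar = x$e_bar,
    train_rss = sum(x$train_residuals^2)
  )
}
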