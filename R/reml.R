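# REML machinery for the per-protein mixed model
#
#   y = X beta + sum_b Z_b u_b + e,   u_b ~ N(0, sigma2 * gamma_b I),
#   e_i ~ N(0, sigma2 / w_i)
#
# Variance ratios gamma_b = sigma_b^2 / sigma^2 are optimized on the log
# scale; sigma2 is profiled out analytically. Coefficients and their
# unscaled covariance come from the mixed-model (Henderson) equations at the
# optimum. The profiled objective is evaluated through the Woodbury identity
# on cross-products that are precomputed once per fit, so each evaluation
# costs O(q^3) in the total number of block columns q, never O(n^3).

ratio_upper <- 1e8

# Precompute the weighted cross-products the Woodbury evaluation needs.
reml_workspace <- function(y, X, Z_blocks, w) {
  U <- if (length(Z_blocks)) do.call(cbind, Z_blocks) else
    matrix(0, length(y), 0)
  list(
    n = length(y), p = ncol(X), q = ncol(U),
    block_sizes = vapply(Z_blocks, ncol, integer(1)),
    UtWU = crossprod(U, w * U),
    UtWX = crossprod(U, w * X),
    UtWy = drop(crossprod(U, w * y)),
    XtWX = crossprod(X, w * X),
    XtWy = drop(crossprod(X, w * y)),
    ytWy = sum(w * y^2),
    sum_log_w = sum(log(w))
  )
}

# -2 * restricted log-likelihood, profiled over sigma2, up to constants.
# gamma is the vector of per-block variance ratios; the numerical kernel is
# compiled (src/reml_eval.cpp).
reml_eval <- function(ws, gamma, details = FALSE) {
  out <- reml_eval_cpp(ws$XtWX, ws$UtWX, ws$UtWU, ws$XtWy, ws$UtWy,
                       ws$ytWy, ws$sum_log_w, ws$n, ws$p, ws$block_sizes,
                       gamma)
  if (out[1] >= 1e300) return(if (details) NULL else 1e300)
  if (details) list(obj = out[1], quad = out[2], gamma = gamma) else out[1]
}

#' Profiled REML objective
#'
#' Exposes the -2 restricted log-likelihood (profiled over the residual
#' variance, up to an additive constant) as a function of the variance
#' ratios, mainly for diagnostics and optimality checks.
#'
#' @param y response vector.
#' @param dm a [design_matrices()] object.
#' @param ratios named or positional vector of variance ratios, one per block.
#' @param weights per-observation weights (default 1).
#' @param opts a [fit_options()] list.
#' @return the objective value (smaller is better).
#' @export
reml_objective <- function(y, dm, ratios, weights = NULL, opts = fit_options()) {
  w <- if (is.null(weights)) rep(1, length(y)) else weights
  ws <- reml_workspace(y, dm$X, dm$Z_blocks, w)
  reml_eval(ws, pmin(pmax(ratios, opts$varcomp_floor), ratio_upper))
}

solve_mme <- function(y, X, Z_blocks, w, gamma, ws) {
  Tmat <- do.call(cbind, c(list(X), Z_blocks))
  p <- ncol(X)
  C0 <- rbind(cbind(ws$XtWX, t(ws$UtWX)),
              cbind(ws$UtWX, ws$UtWU))
  C <- C0
  if (ws$q > 0) {
    idx <- p + seq_len(ws$q)
    diag(C)[idx] <- diag(C)[idx] + 1 / rep(gamma, times = ws$block_sizes)
  }
  Cinv <- tryCatch(chol2inv(chol(C)), error = function(e) NULL)
  if (is.null(Cinv)) {
    Cinv <- tryCatch(solve(C), error = function(e) NULL)
    if (is.null(Cinv)) stop("SingularFit: mixed-model equations not solvable",
                            call. = FALSE)
  }
  coef <- drop(Cinv %*% c(ws$XtWy, ws$UtWy))
  names(coef) <- colnames(Tmat)
  vcov <- (Cinv + t(Cinv)) / 2
  dimnames(vcov) <- list(colnames(Tmat), colnames(Tmat))
  # trace of the weighted hat matrix: tr(T C^{-1} T'W) = tr(C^{-1} T'WT)
  trH <- sum(Cinv * C0)
  list(coef = coef, vcov = vcov, trH = trH, fitted = drop(Tmat %*% coef))
}

#' Fit the per-protein mixed model by REML
#'
#' Maximizes the (weighted) restricted likelihood over the variance ratios of
#' the design's random/ridge blocks — optimized on the log scale with a
#' bounded derivative-free search, residual variance profiled out — then
#' solves the mixed-model equations at the optimum for all coefficients
#' (fixed estimates and shrunken block effects) and their unscaled
#' covariance. Deterministic given its inputs.
#'
#' @param y numeric response (log2 intensities of one protein).
#' @param dm a [design_matrices()] object.
#' @param weights optional per-observation weights (robustness weights).
#' @param opts a [fit_options()] list.
#' @param fix_ratios optional vector of variance ratios; when supplied the
#'   REML optimization is bypassed and the model is solved at these ratios.
#' @param start_ratios optional warm start for the optimizer.
#' @return an object of class `protein_fit`: named `coef`, `vcov_unscaled`,
#'   `sigma2`, `varcomps` (ratios sigma_b^2/sigma^2), `df_res` (effective
#'   residual degrees of freedom, `sum(w) - trace(hat)` clipped to
#'   `[1, n-1]`), `n_obs`, `weights`, `status`, `message`.
#' @export
fit_reml <- function(y, dm, weights = NULL, opts = fit_options(),
                     fix_ratios = NULL, start_ratios = NULL) {
  stopifnot(inherits(dm, "design_matrices"))
  n <- length(y)
  X <- dm$X
  p <- ncol(X)
  if (n <= p) stop("SingularFit: fewer observations than fixed parameters",
                   call. = FALSE)
  w <- if (is.null(weights)) rep(1, n) else weights
  stopifnot(length(w) == n, all(w >= 0))
  w <- pmax(w, 1e-8)
  B <- length(dm$Z_blocks)
  floor <- opts$varcomp_floor
  bounds <- log(c(floor, ratio_upper))
  message <- character()
  ws <- reml_workspace(y, X, dm$Z_blocks, w)
  clamp <- function(lg) exp(pmin(pmax(lg, bounds[1]), bounds[2]))

  if (B == 0) {
    gamma <- numeric(0)
    det <- reml_eval(ws, gamma, details = TRUE)
  } else if (!is.null(fix_ratios)) {
    gamma <- pmin(pmax(fix_ratios, floor), ratio_upper)
    det <- reml_eval(ws, gamma, details = TRUE)
  } else if (B == 1) {
    f <- function(lg) reml_eval(ws, clamp(lg))
    opt <- stats::optimize(f, interval = bounds, tol = 1e-9)
    # golden-section can stall away from a boundary optimum; probe the ends
    cand <- c(opt$minimum, bounds)
    best <- cand[which.min(vapply(cand, f, numeric(1)))]
    det <- reml_eval(ws, clamp(best), details = TRUE)
    gamma <- det$gamma
  } else {
    f <- function(lg) reml_eval(ws, clamp(lg))
    start <- if (is.null(start_ratios)) rep(0, B) else log(pmax(start_ratios, floor))
    opt <- stats::optim(start, f, method = "Nelder-Mead",
                        control = list(reltol = opts$reml_tol,
                                       maxit = opts$max_reml_iter * B))
    if (opt$convergence != 0) {
      message <- c(message, "NonConvergence: REML optimizer hit the iteration limit")
    }
    det <- reml_eval(ws, clamp(opt$par), details = TRUE)
    gamma <- det$gamma
  }
  if (is.null(det)) stop("SingularFit: covariance not positive definite",
                         call. = FALSE)
  sigma2 <- det$quad / (n - p)
  sol <- solve_mme(y, X, dm$Z_blocks, w, gamma, ws)
  df_res <- min(max(sum(w) - sol$trH, 1), n - 1)
  if (B > 0 && any(gamma <= floor * (1 + 1e-8))) {
    message <- c(message,
                 paste0("singular: variance ratio at floor for block(s) ",
                        paste(names(dm$Z_blocks)[gamma <= floor * (1 + 1e-8)],
                              collapse = ", ")))
  }
  structure(
    list(coef = sol$coef, vcov_unscaled = sol$vcov, sigma2 = sigma2,
         varcomps = stats::setNames(gamma, names(dm$Z_blocks)),
         df_res = df_res, n_obs = n, weights = w,
         fitted = sol$fitted, coef_index = dm$coef_index,
         status = "ok", message = paste(message, collapse = "; ")),
    class = "protein_fit"
  )
}

#' Effective residual degrees of freedom of a fit
#'
#' `sum(weights) - trace(H)`, where `H` is the weighted hat matrix of the
#' full mixed-model solve (fixed plus shrunken random part), clipped to
#' `[1, n_obs - 1]`. With no random blocks and unit weights this is exactly
#' `n - p`; as a block's variance ratio goes to zero its columns stop
#' consuming degrees of freedom, and as it grows they behave like fixed
#' columns.
#'
#' @param fit a `protein_fit`.
#' @return the effective residual degrees of freedom.
#' @export
effective_df <- function(fit) fit$df_res

#' Fit the robust (ridge) mixed model
#'
#' Iteratively reweighted REML with Huber weights: starting from unit
#' weights, each iteration standardizes the current residuals by a robust
#' scale (median absolute deviation times 1.4826, recomputed every
#' iteration), maps them through the Huber weight function
#' `w = min(1, k / |r/s|)`, and refits by [fit_reml()]; iteration stops when
#' the largest coefficient change drops below `irls_tol` or after
#' `max_irls_iter` rounds. With `spec$robust = FALSE` this is a single
#' unweighted REML fit. Ridge strength is implicit: each ridge block's
#' penalty is `lambda = 1 / gamma` with `gamma` its REML variance ratio.
#'
#' @inheritParams fit_reml
#' @param spec a [model_spec()] (used for the `robust` switch and options).
#' @return a `protein_fit` (see [fit_reml()]) with the final robustness
#'   weights in `$weights`.
#' @export
fit_robust_ridge <- function(y, dm, spec, opts = spec$options) {
  if (!spec$robust) return(fit_reml(y, dm, opts = opts))
  w <- rep(1, length(y))
  fit <- fit_reml(y, dm, weights = w, opts = opts)
  for (i in seq_len(opts$max_irls_iter)) {
    res <- y - fit$fitted
    s <- stats::mad(res)
    if (s <= 0) break
    z <- abs(res / s)
    w <- ifelse(z <= opts$huber_k, 1, opts$huber_k / z)
    new_fit <- fit_reml(y, dm, weights = w, opts = opts,
                        start_ratios = if (length(fit$varcomps)) fit$varcomps)
    delta <- max(abs(new_fit$coef - fit$coef))
    fit <- new_fit
    if (delta < opts$irls_tol) break
  }
  fit
}

#' @export
print.protein_fit <- function(x, ...) {
  cat(sprintf("<protein_fit> %d coefficients, n=%d, sigma2=%.4g, df=%.2f, status=%s\n",
              length(x$coef), x$n_obs, x$sigma2, x$df_res, x$status))
  invisible(x)
}

#' @rdname tidy.feature_assay
#' @method tidy protein_fit
#' @export
tidy.protein_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coef), estimate = unname(x$coef),
                 std_error = sqrt(pmax(diag(x$vcov_unscaled), 0) * x$sigma2))
}

#' @method glance protein_fit
#' @export
glance.protein_fit <- function(x, ...) {
  tibble::tibble(sigma2 = x$sigma2, df_res = x$df_res, n_obs = x$n_obs,
                 status = x$status)
}
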