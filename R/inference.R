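#' Estimate the empirical-Bayes variance prior across proteins
#'
#' Pools per-protein residual variances by fitting a scaled-F model on the
#' log variances (moment matching through the digamma/trigamma relations of
#' the standard limma empirical-Bayes step). When the observed dispersion of
#' the log variances does not exceed what the chi-square sampling
#' distribution alone explains, the prior degrees of freedom are infinite
#' and every posterior variance collapses to the common value.
#'
#' @param s2 per-protein residual variances.
#' @param df per-protein residual degrees of freedom.
#' @return a `variance_prior` list with `d0` (prior df, possibly `Inf`) and
#'   `s0_sq` (prior variance).
#' @export
estimate_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & is.finite(df) & df > 0 & s2 > 0
  if (sum(ok) < 2) {
    stop("InsufficientProteins: need at least 2 finite variance/df pairs",
         call. = FALSE)
  }
  fit <- limma::fitFDist(s2[ok], df1 = df[ok])
  d0 <- fit$df2
  s0 <- fit$scale
  if (!is.finite(s0) || s0 <= 0) s0 <- exp(mean(log(s2[ok])))
  structure(list(d0 = d0, s0_sq = s0), class = "variance_prior")
}

#' @export
print.variance_prior <- function(x, ...) {
  cat(sprintf("<variance_prior> d0=%s, s0_sq=%.4g\n",
              format(x$d0), x$s0_sq))
  invisible(x)
}

#' Posterior (moderated) residual variance
#'
#' `s2_post = (d0 * s0^2 + df * s2) / (d0 + df)`; with infinite prior df the
#' posterior is the prior variance itself.
#'
#' @param s2 per-protein residual variances.
#' @param df per-protein residual degrees of freedom.
#' @param prior a `variance_prior` from [estimate_variance_prior()].
#' @return vector of posterior variances.
#' @export
posterior_variance <- function(s2, df, prior) {
  if (is.infinite(prior$d0)) {
    return(rep(prior$s0_sq, length(s2)))
  }
  (prior$d0 * prior$s0_sq + df * s2) / (prior$d0 + df)
}

#' Parse a contrast expression against coefficient names
#'
#' Evaluates a linear expression such as `"conditionB - conditionA"` in an
#' environment where every coefficient name is bound to its unit vector,
#' yielding the contrast vector L.
#'
#' @param text contrast expression; coefficient names with non-syntactic
#'   characters can be backtick-quoted.
#' @param coef_names coefficient names to resolve against.
#' @return named numeric vector over `coef_names` (zeros elsewhere), or
#'   `NULL` if a symbol in the expression is not among `coef_names`.
#' @export
parse_contrast <- function(text, coef_names) {
  expr <- str2lang(text)
  syms <- all.vars(expr)
  if (!all(syms %in% coef_names)) return(NULL)
  env <- new.env(parent = baseenv())
  for (i in seq_along(coef_names)) {
    v <- numeric(length(coef_names))
    v[i] <- 1
    assign(coef_names[i], v, envir = env)
  }
  L <- eval(expr, envir = env)
  stats::setNames(as.numeric(L), coef_names)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values, monotone and capped at 1; `NA` entries are
#' ignored and returned as `NA`.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p) {
  stats::p.adjust(p, method = "BH")
}

#' Moderated Wald tests on contrasts across proteins
#'
#' For every protein and contrast: `logFC = L'coef`,
#' `se = sqrt(L' vcov_unscaled L * s2_post)` with the moderated variance from
#' [posterior_variance()], `t = logFC / se`, and a two-sided p-value from the
#' t distribution on `df_res + d0` degrees of freedom (capped at 1e6 when the
#' prior df are infinite). Contrasts may involve ridge-penalized (shrunken)
#' coefficients; their covariance comes from the mixed-model equations.
#' Benjamini-Hochberg adjustment is applied per contrast across the proteins
#' with a successful fit. Failed fits and non-resolvable contrasts are
#' reported with `NA` values and the proper status.
#'
#' @param fits named list of `protein_fit` objects (or `NULL`/error strings
#'   for failed fits), names are protein ids.
#' @param prior a `variance_prior`.
#' @param contrasts named character vector or list of contrast expressions
#'   (see [parse_contrast()]), or a named list of numeric contrast vectors.
#' @return a result tibble: `protein`, `contrast`, `logFC`, `se`, `t`, `df`,
#'   `pvalue`, `adj_pvalue`, `status`.
#' @export
test_contrasts <- function(fits, prior, contrasts) {
  stopifnot(length(contrasts) > 0, !is.null(names(contrasts)))
  d0 <- min(prior$d0, 1e6)
  all_names <- unique(unlist(lapply(fits, function(f) {
    if (inherits(f, "protein_fit")) names(f$coef) else character()
  })))
  for (cn in names(contrasts)) {
    ctr <- contrasts[[cn]]
    if (is.character(ctr)) {
      if (is.null(parse_contrast(ctr, all_names))) {
        stop("UnknownCoefficient: contrast '", cn,
             "' names a coefficient absent from every fit", call. = FALSE)
      }
    }
  }
  proteins <- names(fits)
  fit_ok <- unname(vapply(fits, inherits, logical(1), "protein_fit"))
  n <- length(fits)
  contrast_cache <- new.env(parent = emptyenv())
  resolve <- function(ctr, coef_names) {
    if (is.character(ctr)) {
      key <- paste(c(ctr, coef_names), collapse = "\r")
      if (!is.null(contrast_cache[[key]])) return(contrast_cache[[key]])
      L <- parse_contrast(ctr, coef_names)
      contrast_cache[[key]] <- if (is.null(L)) list(NULL) else L
      if (is.null(L)) list(NULL) else L
    } else {
      if (!all(names(ctr) %in% coef_names)) return(list(NULL))
      v <- stats::setNames(numeric(length(coef_names)), coef_names)
      v[names(ctr)] <- ctr
      v
    }
  }
  out <- purrr::imap(as.list(contrasts), function(ctr, cn) {
    logFC <- se <- tval <- df <- pval <- rep(NA_real_, n)
    status <- ifelse(fit_ok, "ok", "fit_failed")
    for (i in which(fit_ok)) {
      fit <- fits[[i]]
      L <- resolve(ctr, names(fit$coef))
      if (is.list(L)) {
        status[i] <- "not_estimable"
        next
      }
      s2_post <- posterior_variance(fit$sigma2, fit$df_res, prior)
      se_i <- sqrt(max(drop(crossprod(L, fit$vcov_unscaled %*% L)), 0) * s2_post)
      if (!is.finite(se_i) || se_i <= 0) {
        status[i] <- "not_estimable"
        next
      }
      logFC[i] <- sum(L * fit$coef)
      se[i] <- se_i
      tval[i] <- logFC[i] / se_i
      df[i] <- fit$df_res + d0
      pval[i] <- 2 * stats::pt(-abs(tval[i]), df[i])
      if (fit$status == "reduced") status[i] <- "reduced"
    }
    tested <- status %in% c("ok", "reduced")
    adj <- rep(NA_real_, n)
    adj[tested] <- bh_adjust(pval[tested])
    tibble::tibble(protein = proteins, contrast = cn, logFC = logFC, se = se,
                   t = tval, df = df, pvalue = pval, adj_pvalue = adj,
                   status = status)
  })
  dplyr::bind_rows(out) |>
    dplyr::arrange(.data$protein, .data$contrast)
}
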