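#' Fitting options for the mixed-model engine
#'
#' @param huber_k Huber tuning constant for the robustness weights
#'   (default 1.345, 95% efficiency under Gaussian errors).
#' @param reml_tol convergence tolerance on the profiled REML objective.
#' @param max_reml_iter maximum optimizer iterations.
#' @param max_irls_iter maximum robustness reweighting iterations.
#' @param irls_tol convergence tolerance on the maximum coefficient change
#'   between reweighting iterations.
#' @param varcomp_floor lower bound for variance ratios (ratio scale); a
#'   ratio estimated at the floor marks its block as effectively zero.
#' @return a `fit_options` list.
#' @export
fit_options <- function(huber_k = 1.345, reml_tol = 1e-8, max_reml_iter = 200,
                        max_irls_iter = 20, irls_tol = 1e-6,
                        varcomp_floor = 1e-10) {
  opts <- list(huber_k = huber_k, reml_tol = reml_tol,
               max_reml_iter = max_reml_iter, max_irls_iter = max_irls_iter,
               irls_tol = irls_tol, varcomp_floor = varcomp_floor)
  stopifnot(all(vapply(opts, function(x) is.numeric(x) && x > 0, logical(1))))
  structure(opts, class = "fit_options")
}

#' Declarative per-protein model specification
#'
#' Describes the mixed model fitted to every protein: fixed-effect terms
#' built from annotation and feature-metadata columns, random intercept terms
#' over grouping factors (e.g. `run`, `mixture`, `sample`, `psm`), and ridge
#' terms — factors whose full set of level indicators is penalized through a
#' single shared variance component, so their effects shrink symmetrically
#' toward zero (no reference level is dropped). The ridge penalty
#' `lambda = sigma^2 / sigma_term^2` is implied by the REML variance ratio of
#' the block.
#'
#' @param fixed one-sided formula for the fixed effects (default `~ 1`).
#' @param random character vector of grouping columns for random intercepts.
#' @param ridge character vector of factor columns to ridge-penalize.
#' @param robust use Huber M-estimation (IRLS) on the residuals.
#' @param options a [fit_options()] list.
#' @return a `model_spec` object.
#' @export
model_spec <- function(fixed = ~ 1, random = character(), ridge = character(),
                       robust = TRUE, options = fit_options()) {
  stopifnot(inherits(fixed, "formula"))
  overlap <- intersect(all.vars(fixed), ridge)
  if (length(overlap) > 0) {
    stop("terms cannot be both fixed and ridge-penalized: ",
         paste(overlap, collapse = ", "), call. = FALSE)
  }
  if (length(intersect(random, ridge)) > 0) {
    stop("terms cannot be both random and ridge-penalized", call. = FALSE)
  }
  structure(list(fixed = fixed, random = unique(random), ridge = unique(ridge),
                 robust = isTRUE(robust), options = options),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> fixed: %s | random: %s | ridge: %s | %s\n",
              deparse(x$fixed),
              if (length(x$random)) paste(x$random, collapse = " + ") else "(none)",
              if (length(x$ridge)) paste(x$ridge, collapse = " + ") else "(none)",
              if (x$robust) "robust" else "non-robust"))
  invisible(x)
}

indicator_block <- function(f, prefix) {
  f <- factor(f)
  m <- stats::model.matrix(~ 0 + f)
  colnames(m) <- paste0(prefix, levels(f))
  m
}

#' Design matrices container
#'
#' Holds the fixed design `X` (full column rank), the list of random/ridge
#' indicator blocks `Z_blocks` (one shared variance component per block), and
#' the map from coefficient names to positions in the stacked coefficient
#' vector. Mostly produced by [build_design()]; the constructor is exposed so
#' custom designs (e.g. numeric penalized blocks) can be fitted directly.
#'
#' @param X numeric fixed-design matrix (may have zero columns).
#' @param Z_blocks named list of numeric matrices, one per variance component.
#' @param notes character vector of estimability notes.
#' @return a `design_matrices` object.
#' @export
design_matrices <- function(X, Z_blocks = list(), notes = character()) {
  X <- as.matrix(X)
  if (is.null(colnames(X)) && ncol(X) > 0) {
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  }
  Z_blocks <- lapply(Z_blocks, as.matrix)
  cn <- c(colnames(X), unlist(lapply(Z_blocks, colnames)))
  structure(list(X = X, Z_blocks = Z_blocks, notes = notes,
                 coef_index = stats::setNames(seq_along(cn), cn)),
            class = "design_matrices")
}

#' Build design matrices from observation rows and a model specification
#'
#' Fixed factors are treatment-coded; rank-deficient fixed columns are
#' dropped (recorded in `notes`). Ridge terms are encoded as full indicator
#' blocks without a dropped reference level, and random grouping terms as
#' per-level indicator blocks; each block carries one variance-component
#' label.
#'
#' @param rows tibble of observations carrying every column the model
#'   specification references
#'   (annotation and feature metadata joined).
#' @param spec a [model_spec()].
#' @return a [design_matrices()] object.
#' @export
build_design <- function(rows, spec) {
  if (nrow(rows) == 0) stop("NoObservations", call. = FALSE)
  needed <- unique(c(all.vars(spec$fixed), spec$random, spec$ridge))
  absent <- setdiff(needed, names(rows))
  if (length(absent) > 0) {
    stop("UnknownTerm: ", paste(absent, collapse = ", "), call. = FALSE)
  }
  X <- stats::model.matrix(spec$fixed, data = rows)
  notes <- character()
  if (ncol(X) > 0) {
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
      drop <- colnames(X)[qx$pivot[-seq_len(qx$rank)]]
      notes <- c(notes, paste("dropped rank-deficient fixed columns:",
                              paste(drop, collapse = ", ")))
      X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
    }
  }
  Z <- list()
  for (term in spec$ridge) {
    Z[[term]] <- indicator_block(rows[[term]], term)
  }
  for (term in spec$random) {
    Z[[term]] <- indicator_block(rows[[term]], paste0(term, "."))
  }
  design_matrices(X, Z, notes)
}
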