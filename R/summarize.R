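#' Tukey median polish
#'
#' Fits the additive two-way model `overall + row_effect + col_effect` to a
#' numeric matrix by alternately sweeping row and column medians, robust to
#' outliers and tolerant of missing cells (medians are taken over observed
#' cells only). Sweep order is rows first, then columns; after each pair of
#' sweeps the medians of the effect vectors are folded into the overall term.
#' Iteration stops when the change in the L1 norm of the residuals falls
#' below `tol * (1 + L1 norm of the data)` or after `max_iter` iterations
#' (non-convergence is flagged, the best iterate is still returned, since
#' median polish can oscillate on matrices with missing cells).
#'
#' Only fitted values and effect differences are uniquely defined; the
#' allocation between the overall term and the effects depends on the sweep
#' convention documented above. Medians of an even number of values are the
#' mean of the two central values (the R default).
#'
#' @param x numeric matrix, missing values allowed; at least one observed
#'   value is required.
#' @param tol relative convergence tolerance (default 1e-6).
#' @param max_iter maximum number of row+column sweep iterations.
#' @return an object of class `polish_fit`: list with `overall`,
#'   `row_effects`, `col_effects`, `residuals`, `iterations`, `converged`.
#' @export
median_polish <- function(x, tol = 1e-6, max_iter = 100) {
  x <- as.matrix(x)
  if (all(is.na(x))) stop("AllMissing: no observed value to polish", call. = FALSE)
  res <- median_polish_cpp(x, tol, as.integer(max_iter))
  z <- res$residuals
  dimnames(z) <- dimnames(x)
  structure(
    list(overall = res$overall,
         row_effects = stats::setNames(drop(res$row_effects), rownames(x)),
         col_effects = stats::setNames(drop(res$col_effects), colnames(x)),
         residuals = z, iterations = res$iterations,
         converged = res$converged),
    class = "polish_fit"
  )
}

#' @export
print.polish_fit <- function(x, ...) {
  cat(sprintf("<polish_fit> overall=%.4g, %d row x %d col effects, %d iterations%s\n",
              x$overall, length(x$row_effects), length(x$col_effects),
              x$iterations, if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Fitted values of a median polish
#'
#' @param object a `polish_fit`.
#' @param ... unused.
#' @return matrix of `overall + row_effect + col_effect`.
#' @export
fitted.polish_fit <- function(object, ...) {
  object$overall + outer(object$row_effects, object$col_effects, "+")
}

# Stack the PSM rows of one protein within a scope group (a run, or all runs
# of a mixture) into a spectra-by-channels matrix. Each feature contributes
# the row of channels of its own run.
stack_psm_rows <- function(values, meta_rows, ann, sample_cols) {
  chans <- unique(ann$channel[match(sample_cols, ann$sample_id)])
  out <- matrix(NA_real_, nrow = nrow(meta_rows), ncol = length(chans),
                dimnames = list(meta_rows$feature_id, chans))
  for (i in seq_len(nrow(meta_rows))) {
    run_cols <- sample_cols[ann$run[match(sample_cols, ann$sample_id)] == meta_rows$run[i]]
    ch <- ann$channel[match(run_cols, ann$sample_id)]
    out[i, ch] <- values[meta_rows$feature_id[i], run_cols]
  }
  out
}

#' Summarize PSM intensities to protein abundances by median polish
#'
#' For each protein and scope group, the spectra-by-channels submatrix is
#' median-polished and the protein abundance of a sample is
#' `overall + col_effect(channel)`. With `scope = "per_run"` each run is
#' polished separately, giving one value per (protein, run, channel); with
#' `scope = "per_mixture"` the spectra of all technical fraction runs of a
#' mixture are stacked as extra rows, giving a single value per (protein,
#' mixture, channel).
#'
#' @param assay a log2-scale PSM-level [feature_assay()].
#' @param ann sample annotation.
#' @param scope `"per_run"` or `"per_mixture"`.
#' @param tol,max_iter passed to [median_polish()].
#' @return a protein-level [feature_assay()] (for `per_mixture`, its samples
#'   are `"<mixture>:<channel>"`; see [collapse_annotation()]).
#' @export
summarize_protein <- function(assay, ann, scope = c("per_run", "per_mixture"),
                              tol = 1e-6, max_iter = 100) {
  scope <- match.arg(scope)
  if (!assay$log2) stop("summarization needs log2 data", call. = FALSE)
  stopifnot(assay$level == "psm")
  validate_link(assay, ann)
  ann <- ann[match(assay$sample_ids, ann$sample_id), ]
  group_of <- if (scope == "per_run") ann$run else ann$mixture
  groups <- unique(group_of)
  out_ids <- if (scope == "per_run") {
    assay$sample_ids
  } else {
    unique(paste(ann$mixture, ann$channel, sep = ":"))
  }
  proteins <- unique(assay$feature_meta$protein_id)
  values <- matrix(NA_real_, nrow = length(proteins), ncol = length(out_ids),
                   dimnames = list(proteins, out_ids))
  parents <- stats::setNames(vector("list", length(proteins)), proteins)
  meta <- assay$feature_meta
  rows_by_protein <- split(seq_len(nrow(meta)), meta$protein_id)
  cols_by_group <- split(seq_along(assay$sample_ids), group_of)
  run_of_sample <- ann$run[match(assay$sample_ids, ann$sample_id)]
  chan_of_sample <- ann$channel[match(assay$sample_ids, ann$sample_id)]
  for (p in proteins) {
    ridx <- rows_by_protein[[p]]
    parents[[p]] <- meta$feature_id[ridx]
    for (g in groups) {
      cidx <- cols_by_group[[g]]
      if (scope == "per_run") {
        # all spectra of a run share its sample columns: direct slice
        sub <- ridx[meta$run[ridx] == g]
        if (length(sub) == 0) next
        m <- assay$values[sub, cidx, drop = FALSE]
        colnames(m) <- chan_of_sample[cidx]
      } else {
        sub_rows <- meta[ridx, ][meta$run[ridx] %in% run_of_sample[cidx], ]
        if (nrow(sub_rows) == 0) next
        m <- stack_psm_rows(assay$values, sub_rows, ann,
                            assay$sample_ids[cidx])
      }
      m <- m[rowSums(!is.na(m)) > 0, , drop = FALSE]
      if (nrow(m) == 0) next
      fit <- median_polish(m, tol = tol, max_iter = max_iter)
      prof <- fit$overall + fit$col_effects
      observed <- colSums(!is.na(m)) > 0
      out_cols <- paste(g, colnames(m), sep = ":")
      values[p, out_cols[observed]] <- prof[observed]
    }
  }
  feature_assay(values,
                tibble::tibble(feature_id = proteins, protein_id = proteins),
                level = "protein", log2 = TRUE, parents = parents)
}

#' Collapse a sample annotation to mixture level
#'
#' Companion to `summarize_protein(scope = "per_mixture")`: one row per
#' (mixture, channel), sample ids `"<mixture>:<channel>"`. Columns that are
#' constant within a (mixture, channel) group (condition, bio_replicate,
#' is_reference, covariates) are kept; run and tech_rep are collapsed to the
#' mixture and dropped to a single level.
#'
#' @param ann a sample annotation tibble.
#' @return the collapsed annotation.
#' @export
collapse_annotation <- function(ann) {
  ann |>
    dplyr::mutate(sample_id = paste(.data$mixture, .data$channel, sep = ":"),
                  run = .data$mixture, tech_rep = "1") |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
}

#' Median-sweep protein summarization
#'
#' One-step alternative to the full median polish: within each run every
#' spectrum row is centered by its median over observed cells (removing the
#' spectrum-specific effect), then the protein value of a channel is the
#' median of its centered spectrum values. Optionally the protein summaries
#' are column-median normalized afterwards (`normalize = FALSE` reproduces
#' the variant that omits that step).
#'
#' @inheritParams summarize_protein
#' @param normalize subtract the per-channel median of the protein summaries.
#' @return a protein-level [feature_assay()] with one value per
#'   (protein, run, channel).
#' @export
median_sweep_summarize <- function(assay, ann, normalize = TRUE) {
  if (!assay$log2) stop("summarization needs log2 data", call. = FALSE)
  stopifnot(assay$level == "psm")
  validate_link(assay, ann)
  row_med <- apply(assay$values, 1, stats::median, na.rm = TRUE)
  centered <- assay$values - row_med
  proteins <- unique(assay$feature_meta$protein_id)
  values <- matrix(NA_real_, nrow = length(proteins), ncol = ncol(centered),
                   dimnames = list(proteins, colnames(centered)))
  for (p in proteins) {
    rows <- assay$feature_meta$protein_id == p
    values[p, ] <- apply(centered[rows, , drop = FALSE], 2, stats::median, na.rm = TRUE)
  }
  values[is.nan(values)] <- NA_real_
  if (normalize) {
    med <- apply(values, 2, stats::median, na.rm = TRUE)
    med[is.na(med)] <- 0
    values <- sweep(values, 2, med)
  }
  feature_assay(values,
                tibble::tibble(feature_id = proteins, protein_id = proteins),
                level = "protein", log2 = TRUE,
                parents = split(assay$feature_meta$feature_id,
                                assay$feature_meta$protein_id)[proteins])
}
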