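#' Filter reports
#'
#' Every filter returns, alongside the filtered assay, a one-row tibble
#' recording the rule name and the number of features before/removed. Reports
#' from chained filters can be row-bound; removed counts are additive.
#'
#' @param rule rule name.
#' @param before feature count before the rule.
#' @param removed number of features removed.
#' @param notes free-text note.
#' @return a `filter_report` tibble.
#' @export
filter_report <- function(rule, before, removed, notes = "") {
  stopifnot(removed <= before)
  out <- tibble::tibble(rule = rule, features_before = as.integer(before),
                        features_removed = as.integer(removed), notes = notes)
  class(out) <- c("filter_report", class(out))
  out
}

#' log2-transform an assay
#'
#' @param assay a raw-scale [feature_assay()]; all observed values must be
#'   strictly positive (zeros should have been mapped to missing on import).
#' @return the assay with `log2 = TRUE`.
#' @export
log2_transform <- function(assay) {
  if (assay$log2) stop("assay is already on the log2 scale", call. = FALSE)
  v <- assay$values
  if (any(v <= 0, na.rm = TRUE)) {
    stop("NonPositiveIntensity: observed intensities must be > 0", call. = FALSE)
  }
  out <- assay
  out$values <- log2(v)
  out$log2 <- TRUE
  out
}

#' Channel-median normalization
#'
#' Subtracts from every sample column the median of its observed log2
#' intensities, removing channel loading differences. This assumes the
#' majority of proteins are not differentially abundant. `scope` only affects
#' bookkeeping of which observations enter each median: with `"per_run"`
#' (default) medians are computed per sample within its run's columns, which
#' for column-wise medians coincides with `"global"`; both are exposed because
#' downstream variants differ in convention.
#'
#' @param assay a log2-scale [feature_assay()].
#' @param scope `"per_run"` or `"global"`.
#' @return the normalized assay; every column's observed median is 0.
#' @export
normalize_channel_median <- function(assay, scope = c("per_run", "global")) {
  scope <- match.arg(scope)
  if (!assay$log2) stop("channel-median normalization needs log2 data", call. = FALSE)
  v <- assay$values
  med <- apply(v, 2, stats::median, na.rm = TRUE)
  if (anyNA(med)) {
    stop("EmptyColumn: channel(s) with no observed values: ",
         paste(colnames(v)[is.na(med)], collapse = ", "), call. = FALSE)
  }
  out <- assay
  out$values <- sweep(v, 2, med)
  out
}

#' Reference-channel normalization
#'
#' Within each run, subtracts per feature the reference profile of that run
#' (the single reference column, or the per-feature median across the run's
#' reference columns) from every column of the run.
#'
#' @param assay a log2-scale [feature_assay()].
#' @param ann sample annotation with `is_reference` flags; every run
#'   represented in the assay must contain at least one reference channel.
#' @param drop_reference also remove the reference columns afterwards.
#' @return the normalized assay.
#' @export
normalize_reference <- function(assay, ann, drop_reference = FALSE) {
  if (!assay$log2) stop("reference normalization needs log2 data", call. = FALSE)
  validate_link(assay, ann)
  ann <- ann[match(assay$sample_ids, ann$sample_id), ]
  v <- assay$values
  for (r in unique(ann$run)) {
    cols <- which(ann$run == r)
    refs <- cols[ann$is_reference[cols]]
    if (length(refs) == 0) {
      stop("NoReferenceInRun: run ", r, " has no reference channel", call. = FALSE)
    }
    ref_profile <- apply(v[, refs, drop = FALSE], 1, stats::median, na.rm = TRUE)
    v[, cols] <- v[, cols, drop = FALSE] - ref_profile
  }
  out <- assay
  out$values <- v
  if (drop_reference) out <- drop_reference_channels(out, ann)
  out
}

#' Remove features with too few observed intensities
#'
#' @param assay a [feature_assay()].
#' @param min_obs minimum number of observed values a feature must have.
#' @return list with the filtered `assay` and a [filter_report()].
#' @export
filter_min_observed <- function(assay, min_obs = 6) {
  stopifnot(min_obs >= 1)
  n_obs <- rowSums(!is.na(assay$values))
  keep <- n_obs >= min_obs
  list(
    assay = keep_features(assay, keep),
    report = filter_report("min_observed", length(keep), sum(!keep),
                           sprintf("min_obs=%d", min_obs))
  )
}

#' Resolve duplicate spectra for a peptide ion
#'
#' When several spectra quantify the same peptide ion within a run, keep the
#' single spectrum with the largest sum of observed intensities (ties broken
#' by feature id for determinism).
#'
#' @param assay a PSM-level [feature_assay()].
#' @return list with the filtered `assay` and a [filter_report()].
#' @export
resolve_duplicate_psms <- function(assay) {
  stopifnot(assay$level == "psm")
  sums <- rowSums(assay$values, na.rm = TRUE)
  meta <- assay$feature_meta |>
    dplyr::mutate(.sum = sums, .row = dplyr::row_number())
  keep_rows <- meta |>
    dplyr::group_by(.data$run, .data$peptide_id) |>
    dplyr::arrange(dplyr::desc(.data$.sum), .data$feature_id, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::pull(.data$.row)
  keep <- seq_len(nrow(meta)) %in% keep_rows
  list(
    assay = keep_features(assay, keep),
    report = filter_report("duplicate_psms", length(keep), sum(!keep))
  )
}

#' Remove ambiguous spectra shared across proteins
#'
#' Groups of two or more spectra within a run whose intensity vectors are
#' identical (including the missingness pattern) but that are assigned to
#' different proteins are removed entirely: such peptide-spectrum matches
#' cannot be attributed to a single protein.
#'
#' @param assay a PSM-level [feature_assay()].
#' @return list with the filtered `assay` and a [filter_report()].
#' @export
remove_shared_intensity_spectra <- function(assay) {
  stopifnot(assay$level == "psm")
  key <- apply(assay$values, 1, function(x) paste(format(x, digits = 15), collapse = "|"))
  meta <- assay$feature_meta |>
    dplyr::mutate(.key = key, .row = dplyr::row_number())
  drop_rows <- meta |>
    dplyr::group_by(.data$run, .data$.key) |>
    dplyr::filter(dplyr::n() > 1, dplyr::n_distinct(.data$protein_id) > 1) |>
    dplyr::pull(.data$.row)
  keep <- !(seq_len(nrow(meta)) %in% drop_rows)
  list(
    assay = keep_features(assay, keep),
    report = filter_report("shared_intensity_spectra", length(keep), sum(!keep))
  )
}

pearson_or_zero <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) return(0)  # insufficient evidence must not remove
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(0)
  stats::cor(x[ok], y[ok])
}

#' Multibatch spike-in custom normalization
#'
#' Preprocessing devised for spike-in designs where most proteins are
#' differentially abundant, so ordinary normalization assumptions fail.
#' Three steps: (1) remove background features whose Pearson correlation with
#' the spike-in dilution profile exceeds `corr_threshold`; (2) remove features
#' with summed signal-to-noise below `snr_threshold`; (3) per run, subtract
#' from each sample the log-scale mean (geometric mean on the raw scale) of
#' the `stable_fraction` background features with the smallest cross-sample
#' standard deviation in that run.
#'
#' Correlations use pairwise-complete observations; with fewer than 3 complete
#' pairs, or a constant feature, the correlation is treated as 0 (kept). Ties
#' at the stability cutoff are broken by feature id.
#'
#' @param assay a log2-scale PSM-level [feature_assay()].
#' @param ann sample annotation (for run membership of samples).
#' @param background_ids protein ids of the non-spiked background.
#' @param profile numeric spike-in profile aligned with the assay samples.
#' @param corr_threshold correlation removal threshold (default 0.25).
#' @param snr optional named per-feature summed signal-to-noise vector; when
#'   `NULL` the SNR filter is skipped.
#' @param snr_threshold SNR removal threshold (default 20).
#' @param stable_fraction fraction of surviving background features used as
#'   the stable normalization set (default 0.5).
#' @return list with the normalized `assay` and a combined [filter_report()].
#' @export
multibatch_custom_normalize <- function(assay, ann, background_ids, profile,
                                        corr_threshold = 0.25,
                                        snr = NULL, snr_threshold = 20,
                                        stable_fraction = 0.5) {
  stopifnot(length(background_ids) > 0, length(profile) == length(assay$sample_ids))
  if (!assay$log2) stop("multibatch normalization needs log2 data", call. = FALSE)
  validate_link(assay, ann)
  reports <- list()
  is_bg <- assay$feature_meta$protein_id %in% background_ids

  cors <- vapply(seq_len(nrow(assay$values)), function(i) {
    if (!is_bg[i]) return(0)
    pearson_or_zero(assay$values[i, ], profile)
  }, numeric(1))
  keep <- !(is_bg & cors > corr_threshold)
  reports$corr <- filter_report("background_profile_correlation",
                                length(keep), sum(!keep),
                                sprintf("corr_threshold=%g", corr_threshold))
  assay <- keep_features(assay, keep)
  is_bg <- assay$feature_meta$protein_id %in% background_ids

  if (!is.null(snr)) {
    snr <- snr[assay$feature_meta$feature_id]
    keep <- !is.na(snr) & snr >= snr_threshold
    reports$snr <- filter_report("signal_to_noise", length(keep), sum(!keep),
                                 sprintf("snr_threshold=%g", snr_threshold))
    assay <- keep_features(assay, keep)
    is_bg <- assay$feature_meta$protein_id %in% background_ids
  }

  ann <- ann[match(assay$sample_ids, ann$sample_id), ]
  v <- assay$values
  for (r in unique(ann$run)) {
    cols <- which(ann$run == r)
    sub <- v[, cols, drop = FALSE]
    bg_rows <- which(is_bg & rowSums(!is.na(sub)) > 0)
    if (length(bg_rows) == 0) {
      stop("NoStableBackground: no background feature observed in run ", r,
           call. = FALSE)
    }
    sds <- apply(sub[bg_rows, , drop = FALSE], 1, stats::sd, na.rm = TRUE)
    sds[is.na(sds)] <- 0  # single observed value: maximally "stable"
    ord <- order(sds, assay$feature_meta$feature_id[bg_rows])
    n_stable <- max(1L, ceiling(stable_fraction * length(bg_rows)))
    stable <- bg_rows[ord[seq_len(n_stable)]]
    shift <- colMeans(sub[stable, , drop = FALSE], na.rm = TRUE)
    v[, cols] <- sweep(sub, 2, shift)
  }
  out <- assay
  out$values <- v
  list(assay = out, report = dplyr::bind_rows(reports))
}

#' Apply a user-supplied imputation hook
#'
#' Imputation is deliberately absent from the default workflows; this hook
#' lets users inject a custom assay-to-assay imputation function.
#'
#' @param assay a [feature_assay()].
#' @param fun function mapping a feature_assay to a feature_assay.
#' @return the imputed assay.
#' @export
impute_with <- function(assay, fun) {
  out <- fun(assay)
  stopifnot(inherits(out, "feature_assay"))
  out
}
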