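#' Multi-level feature assay container
#'
#' A `feature_assay` holds a features-by-samples intensity matrix at a declared
#' quantification level (`"psm"` or `"protein"`) together with per-feature
#' metadata and an optional link to the parent features it was derived from
#' (e.g. protein rows link back to the PSM rows they summarize). Missing
#' intensities are always the explicit `NA` sentinel, never zero.
#'
#' @param values numeric matrix, features in rows and samples in columns.
#'   Rownames are taken as feature ids when `feature_meta` is missing them.
#' @param feature_meta tibble with one row per feature: `feature_id`,
#'   `protein_id`, `peptide_id` and, at PSM level, `spectrum_id`.
#' @param level `"psm"` or `"protein"`.
#' @param log2 logical; `TRUE` once intensities are on the log2 scale.
#' @param parents optional named list mapping `feature_id` to a character
#'   vector of parent feature ids in the assay this one was derived from.
#'
#' @return an object of class `feature_assay`.
#' @export
feature_assay <- function(values, feature_meta, level = c("psm", "protein"),
                          log2 = FALSE, parents = NULL) {
  level <- match.arg(level)
  values <- as.matrix(values)
  if (is.null(colnames(values)) && ncol(values) > 0) {
    stop("`values` must have column names (sample ids)", call. = FALSE)
  }
  if (is.null(colnames(values))) colnames(values) <- character(0)
  feature_meta <- tibble::as_tibble(feature_meta)
  if (!"feature_id" %in% names(feature_meta)) {
    stop("`feature_meta` must contain a feature_id column", call. = FALSE)
  }
  feature_meta$feature_id <- as.character(feature_meta$feature_id)
  if (anyDuplicated(feature_meta$feature_id)) {
    stop("feature ids must be unique", call. = FALSE)
  }
  if (nrow(feature_meta) != nrow(values)) {
    stop("`feature_meta` and `values` disagree on the number of features",
         call. = FALSE)
  }
  rownames(values) <- feature_meta$feature_id
  if (level == "protein") {
    if (!"protein_id" %in% names(feature_meta)) {
      stop("protein-level assays need a protein_id column", call. = FALSE)
    }
    if (anyDuplicated(feature_meta$protein_id)) {
      stop("protein-level assays must map feature ids 1:1 to proteins",
           call. = FALSE)
    }
  }
  structure(
    list(
      values = values,
      feature_meta = feature_meta,
      sample_ids = colnames(values),
      level = level,
      log2 = isTRUE(log2),
      parents = parents
    ),
    class = "feature_assay"
  )
}

#' @export
print.feature_assay <- function(x, ...) {
  cat(sprintf(
    "<feature_assay> %d features x %d samples (level=%s, %s scale, %.1f%% missing)\n",
    nrow(x$values), ncol(x$values), x$level,
    if (x$log2) "log2" else "raw",
    100 * mean(is.na(x$values))
  ))
  invisible(x)
}

#' @export
dim.feature_assay <- function(x) dim(x$values)

#' Long tidy view of an assay
#'
#' @param x a [feature_assay()].
#' @param ... unused.
#' @return tibble with one row per observed cell: feature metadata columns,
#'   `sample_id` and `intensity`.
#' @method tidy feature_assay
#' @export
tidy.feature_assay <- function(x, ...) {
  long <- tibble::as_tibble(x$values, rownames = "feature_id") |>
    tidyr::pivot_longer(-"feature_id", names_to = "sample_id",
                        values_to = "intensity") |>
    dplyr::filter(!is.na(.data$intensity))
  dplyr::left_join(long, x$feature_meta, by = "feature_id") |>
    dplyr::relocate("sample_id", "intensity", .after = dplyr::last_col())
}

#' @method glance feature_assay
#' @export
glance.feature_assay <- function(x, ...) {
  tibble::tibble(
    level = x$level,
    log2 = x$log2,
    n_features = nrow(x$values),
    n_samples = ncol(x$values),
    n_proteins = dplyr::n_distinct(x$feature_meta$protein_id),
    missing_fraction = mean(is.na(x$values))
  )
}

keep_features <- function(assay, keep) {
  # keep: logical or character over feature ids; preserves order, no mutation
  if (is.character(keep)) keep <- assay$feature_meta$feature_id %in% keep
  feature_assay(
    assay$values[keep, , drop = FALSE],
    assay$feature_meta[keep, , drop = FALSE],
    level = assay$level, log2 = assay$log2,
    parents = if (!is.null(assay$parents)) {
      assay$parents[assay$feature_meta$feature_id[keep]]
    }
  )
}

keep_samples <- function(assay, keep) {
  if (is.character(keep)) keep <- assay$sample_ids %in% keep
  feature_assay(
    assay$values[, keep, drop = FALSE],
    assay$feature_meta,
    level = assay$level, log2 = assay$log2, parents = assay$parents
  )
}

#' Validate the assay / annotation link
#'
#' Checks that every assay sample id is annotated. The annotation may contain
#' additional samples (subsetting is allowed).
#'
#' @param assay a [feature_assay()].
#' @param ann a sample annotation tibble (see [read_sample_annotation()]).
#' @return invisibly, a list with the validated `assay` and `ann`.
#' @export
validate_link <- function(assay, ann) {
  stopifnot(inherits(assay, "feature_assay"))
  missing_ids <- setdiff(assay$sample_ids, ann$sample_id)
  if (length(missing_ids) > 0) {
    stop("UnannotatedSample: assay samples absent from annotation: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  invisible(list(assay = assay, ann = ann))
}

#' Remove reference channels from an assay
#'
#' Drops the sample columns flagged `is_reference` in the annotation. Feature
#' rows left without any observed value are retained; filtering is a separate
#' step.
#'
#' @inheritParams validate_link
#' @return a [feature_assay()] without the reference columns.
#' @export
drop_reference_channels <- function(assay, ann) {
  validate_link(assay, ann)
  ref_ids <- ann$sample_id[ann$is_reference]
  keep <- !(assay$sample_ids %in% ref_ids)
  if (!any(keep)) {
    warning("all channels are flagged as reference; returning an empty assay",
            call. = FALSE)
  }
  keep_samples(assay, keep)
}

#' Ordered chain of linked assays
#'
#' An `assay_chain` keeps every intermediate assay of an analysis alongside a
#' shared sample annotation, so raw input is never lost: each transformation
#' appends a new named assay and a log record of the operation that produced
#' it.
#'
#' @param assay the starting [feature_assay()].
#' @param ann the shared sample annotation.
#' @param name name of the first assay.
#' @return an object of class `assay_chain`.
#' @export
assay_chain <- function(assay, ann, name = "input") {
  validate_link(assay, ann)
  structure(
    list(assays = stats::setNames(list(assay), name), annotation = ann,
         log = tibble::tibble(assay = name, operation = "input")),
    class = "assay_chain"
  )
}

#' Append a derived assay to a chain
#'
#' @param chain an [assay_chain()].
#' @param name name for the new assay.
#' @param assay the derived [feature_assay()].
#' @param operation character description of the producing operation.
#' @return the extended chain (the input chain is not modified).
#' @export
chain_add <- function(chain, name, assay, operation) {
  stopifnot(inherits(chain, "assay_chain"))
  validate_link(assay, chain$annotation)
  chain$assays[[name]] <- assay
  chain$log <- dplyr::bind_rows(chain$log,
                                tibble::tibble(assay = name, operation = operation))
  chain
}

#' @export
print.assay_chain <- function(x, ...) {
  cat(sprintf("<assay_chain> %d assay(s): %s\n", length(x$assays),
              paste(names(x$assays), collapse = " -> ")))
  invisible(x)
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @importFrom rlang .data
NULL

#' @export
generics::glance
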