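guess_delim <- function(path, delim = NULL) {
  if (!is.null(delim)) return(delim)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

read_table_file <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  readr::read_delim(path, delim = guess_delim(path, delim),
                    show_col_types = FALSE, progress = FALSE)
}

default_column_map <- function() {
  list(protein = "Protein", peptide = "Peptide", spectrum = "Spectrum",
       run = "Run", channel = "Channel", intensity = "Intensity")
}

#' Read a PSM quantification table
#'
#' Reads a Proteome-Discoverer-style PSM table, in long layout (one row per
#' reporter-ion observation) or wide layout (one row per spectrum, one column
#' per channel), into a PSM-level [feature_assay()]. Samples are identified as
#' `"<run>:<channel>"`; feature rows are identified as `"<run>:<spectrum>"`
#' (a spectrum belongs to a single run).
#'
#' @param path file path; delimiter inferred from the extension
#'   (`.csv` comma, otherwise tab) unless `delim` is given.
#' @param layout `"long"` or `"wide"`.
#' @param column_map named list mapping the roles `protein`, `peptide`,
#'   `spectrum`, `run`, and for long layouts `channel` and `intensity`, to the
#'   column names of the file.
#' @param channel_prefix for wide layouts, the prefix identifying channel
#'   columns; the channel name is the remainder of the column name.
#' @param zero_is_missing treat zero intensities as missing (default `TRUE`;
#'   a zero reporter intensity is non-physical).
#' @param delim optional delimiter override.
#' @return a raw-scale PSM-level [feature_assay()].
#' @export
read_psm_table <- function(path, layout = c("long", "wide"),
                           column_map = default_column_map(),
                           channel_prefix = "channel_",
                           zero_is_missing = TRUE, delim = NULL) {
  layout <- match.arg(layout)
  column_map <- utils::modifyList(default_column_map(), column_map)
  tab <- read_table_file(path, delim)

  required <- c("protein", "peptide", "spectrum", "run")
  if (layout == "long") required <- c(required, "channel", "intensity")
  need <- unlist(column_map[required])
  absent <- setdiff(need, names(tab))
  if (length(absent) > 0) {
    stop("MissingColumn: ", paste(absent, collapse = ", "), call. = FALSE)
  }

  if (layout == "long") {
    long <- tibble::tibble(
      protein_id = as.character(tab[[column_map$protein]]),
      peptide_id = as.character(tab[[column_map$peptide]]),
      spectrum_id = as.character(tab[[column_map$spectrum]]),
      run = as.character(tab[[column_map$run]]),
      channel = as.character(tab[[column_map$channel]]),
      intensity = tab[[column_map$intensity]]
    )
  } else {
    chan_cols <- grep(paste0("^", channel_prefix), names(tab), value = TRUE)
    if (length(chan_cols) == 0) {
      stop("MissingColumn: no columns with prefix '", channel_prefix, "'",
           call. = FALSE)
    }
    long <- tibble::tibble(
      protein_id = as.character(tab[[column_map$protein]]),
      peptide_id = as.character(tab[[column_map$peptide]]),
      spectrum_id = as.character(tab[[column_map$spectrum]]),
      run = as.character(tab[[column_map$run]])
    )
    long <- dplyr::bind_cols(long, tab[chan_cols]) |>
      tidyr::pivot_longer(dplyr::all_of(chan_cols), names_to = "channel",
                          values_to = "intensity",
                          names_prefix = channel_prefix)
    long$intensity <- as_numeric_intensity(long$intensity)
  }
  long$intensity <- as_numeric_intensity(long$intensity)
  if (zero_is_missing) long$intensity[!is.na(long$intensity) & long$intensity == 0] <- NA

  dup <- long |>
    dplyr::count(.data$run, .data$spectrum_id, .data$channel) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("DuplicateCell: repeated (spectrum, run, channel): ",
         paste(utils::head(paste(dup$run, dup$spectrum_id, dup$channel, sep = ":"), 3),
               collapse = ", "), call. = FALSE)
  }

  long$feature_id <- paste(long$run, long$spectrum_id, sep = ":")
  long$sample_id <- paste(long$run, long$channel, sep = ":")
  meta <- long |>
    dplyr::distinct(.data$feature_id, .data$protein_id, .data$peptide_id,
                    .data$spectrum_id, .data$run)
  if (anyDuplicated(meta$feature_id)) {
    stop("DuplicateCell: a (run, spectrum) pair maps to several protein/peptide ids",
         call. = FALSE)
  }
  wide <- long |>
    dplyr::select("feature_id", "sample_id", "intensity") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "intensity")
  values <- as.matrix(wide[-1])
  rownames(values) <- wide$feature_id
  meta <- meta[match(wide$feature_id, meta$feature_id), ]
  feature_assay(values, meta, level = "psm", log2 = FALSE)
}

as_numeric_intensity <- function(x) {
  if (is.numeric(x)) return(x)
  out <- suppressWarnings(as.numeric(x))
  bad <- !is.na(x) & x != "" & x != "NA" & is.na(out)
  if (any(bad)) {
    stop("NonNumericIntensity: ", paste(utils::head(unique(x[bad]), 3), collapse = ", "),
         call. = FALSE)
  }
  out
}

#' Write a PSM-level assay as a long table
#'
#' Writes one row per observed cell with columns Protein, Peptide, Spectrum,
#' Run, Channel, Intensity so the file round-trips through
#' [read_psm_table()].
#'
#' @param assay a PSM-level [feature_assay()].
#' @param path output path (`.csv` comma, otherwise tab).
#' @return `path`, invisibly.
#' @export
write_psm_table <- function(assay, path) {
  stopifnot(assay$level == "psm")
  long <- tidy(assay) |>
    tidyr::separate_wider_delim("sample_id", ":", names = c("run2", "Channel"),
                                too_many = "merge") |>
    dplyr::transmute(
      Protein = .data$protein_id, Peptide = .data$peptide_id,
      Spectrum = .data$spectrum_id, Run = .data$run, Channel = .data$Channel,
      Intensity = .data$intensity
    ) |>
    dplyr::arrange(.data$Run, .data$Spectrum, .data$Channel)
  readr::write_delim(long, path, delim = guess_delim(path))
  invisible(path)
}

#' Read a sample annotation table
#'
#' The annotation has one row per quantified sample. `run` and `channel` are
#' required; `sample_id` is synthesized as `"<run>:<channel>"` when absent;
#' `is_reference` defaults to `FALSE`, `mixture` to the run, and
#' `bio_replicate`/`tech_rep` to sensible one-level defaults. Column name
#' matching is case-insensitive against the conventional Run, Channel,
#' Mixture, Condition, BioReplicate, TechRep, IsReference headers.
#'
#' @inheritParams read_psm_table
#' @return a tibble with columns `sample_id`, `run`, `channel`, `mixture`,
#'   `bio_replicate`, `tech_rep`, `is_reference`, plus any condition and
#'   covariate columns found in the file.
#' @export
read_sample_annotation <- function(path, delim = NULL) {
  tab <- read_table_file(path, delim)
  canon <- c(run = "run", channel = "channel", mixture = "mixture",
             bioreplicate = "bio_replicate", bio_replicate = "bio_replicate",
             techrep = "tech_rep", tech_rep = "tech_rep",
             isreference = "is_reference", is_reference = "is_reference",
             sample_id = "sample_id", sampleid = "sample_id",
             condition = "condition")
  low <- tolower(names(tab))
  hit <- low %in% names(canon)
  names(tab)[hit] <- unname(canon[low[hit]])
  if (!all(c("run", "channel") %in% names(tab))) {
    stop("MissingRequired: annotation needs run and channel columns",
         call. = FALSE)
  }
  tab$run <- as.character(tab$run)
  tab$channel <- as.character(tab$channel)
  if (anyDuplicated(tab[c("run", "channel")])) {
    stop("DuplicateSample: repeated (run, channel) pair", call. = FALSE)
  }
  auto_id <- paste(tab$run, tab$channel, sep = ":")
  if ("sample_id" %in% names(tab)) {
    if (!identical(as.character(tab$sample_id), auto_id)) {
      stop("DuplicateSample: explicit sample_id collides with the <run>:<channel> convention",
           call. = FALSE)
    }
  }
  tab$sample_id <- auto_id
  if (!"mixture" %in% names(tab)) tab$mixture <- tab$run
  tab$mixture <- as.character(tab$mixture)
  if (anyNA(tab$run) || anyNA(tab$channel) || anyNA(tab$mixture)) {
    stop("MissingRequired: run/channel/mixture must have no missing values",
         call. = FALSE)
  }
  run_mix <- dplyr::distinct(tab, .data$run, .data$mixture)
  if (anyDuplicated(run_mix$run)) {
    stop("MissingRequired: every run must belong to exactly one mixture",
         call. = FALSE)
  }
  if (!"is_reference" %in% names(tab)) tab$is_reference <- FALSE
  tab$is_reference <- as.logical(tab$is_reference) %in% TRUE
  if (!"bio_replicate" %in% names(tab)) tab$bio_replicate <- tab$sample_id
  if (!"tech_rep" %in% names(tab)) tab$tech_rep <- "1"
  tab$bio_replicate <- as.character(tab$bio_replicate)
  tab$tech_rep <- as.character(tab$tech_rep)
  dplyr::relocate(tibble::as_tibble(tab), "sample_id", "run", "channel",
                  "mixture", "bio_replicate", "tech_rep", "is_reference")
}

#' Write a sample annotation table
#'
#' @param ann annotation tibble as returned by [read_sample_annotation()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sample_annotation <- function(ann, path) {
  readr::write_delim(ann, path, delim = guess_delim(path))
  invisible(path)
}

result_columns <- c("protein", "contrast", "logFC", "se", "t", "df",
                    "pvalue", "adj_pvalue", "status")

#' Write a differential-abundance result table
#'
#' Tab-separated, fixed column order (protein, contrast, logFC, se, t, df,
#' pvalue, adj_pvalue, status), rows ordered lexicographically by protein then
#' contrast; `NA` serialized literally.
#'
#' @param results a result tibble (see [test_contrasts()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(results, path) {
  out <- results |>
    dplyr::select(dplyr::all_of(result_columns)) |>
    dplyr::arrange(.data$protein, .data$contrast)
  readr::write_tsv(out, path, na = "NA")
  invisible(path)
}

#' Read a result table written by [write_result_table()]
#'
#' @param path file path.
#' @return a result tibble.
#' @export
read_result_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    protein = "c", contrast = "c", logFC = "d", se = "d",
                    t = "d", df = "d", pvalue = "d", adj_pvalue = "d",
                    status = "c"
                  ))
}
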