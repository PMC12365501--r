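#' Benchmark confusion counts
#'
#' @param tp,fp,fn,tn non-negative counts at a decision threshold.
#' @return a `benchmark_counts` list.
#' @export
benchmark_counts <- function(tp, fp, fn, tn = 0) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  structure(list(TP = tp, FP = fp, FN = fn, TN = tn),
            class = "benchmark_counts")
}

#' True positive rate
#'
#' `TPR = TP / (TP + FN)`, the fraction of truly differentially abundant
#' proteins that were called.
#'
#' @param counts a [benchmark_counts()].
#' @return a proportion.
#' @export
tpr <- function(counts) {
  if (counts$TP + counts$FN <= 0) {
    stop("NoPositives: no truly differential protein evaluated", call. = FALSE)
  }
  counts$TP / (counts$TP + counts$FN)
}

#' False discovery proportion
#'
#' `FDP = FP / (TP + FP)`, the fraction of called proteins that are not truly
#' differentially abundant; defined as 0 when nothing is called.
#'
#' @param counts a [benchmark_counts()].
#' @return a proportion.
#' @export
fdp <- function(counts) {
  if (counts$TP + counts$FP == 0) return(0)
  counts$FP / (counts$TP + counts$FP)
}

join_truth <- function(results, truth) {
  unknown <- setdiff(results$protein, truth$protein_id)
  if (length(unknown) > 0) {
    stop("UnknownProtein: results contain proteins absent from the truth: ",
         paste(utils::head(unknown, 3), collapse = ", "), call. = FALSE)
  }
  dplyr::left_join(results,
                   dplyr::select(truth, protein = "protein_id", "is_da"),
                   by = "protein")
}

#' Confusion counts at an FDR threshold
#'
#' Proteins with BH-adjusted p-value at or below `level` are calls; rows with
#' failed fits or non-estimable contrasts count as negatives (not called).
#' With a multi-contrast result table the counts accumulate over all
#' (protein, contrast) rows.
#'
#' @param results a result tibble (see [test_contrasts()]).
#' @param truth truth tibble from [simulate_spikein()].
#' @param level FDR threshold (default 0.05).
#' @return a [benchmark_counts()].
#' @export
counts_at_fdr <- function(results, truth, level = 0.05) {
  tab <- join_truth(results, truth)
  called <- !is.na(tab$adj_pvalue) & tab$adj_pvalue <= level &
    tab$status %in% c("ok", "reduced")
  benchmark_counts(
    tp = sum(called & tab$is_da),
    fp = sum(called & !tab$is_da),
    fn = sum(!called & tab$is_da),
    tn = sum(!called & !tab$is_da)
  )
}

#' TPR-FDP curve for one contrast
#'
#' Proteins are ranked by p-value (ties: larger `|t|` first, then protein
#' id); walking down the ranking accumulates true and false positives,
#' producing the curve. The marked point is the operating point at the BH
#' `fdr_mark` threshold.
#'
#' @param results result tibble restricted to a single contrast.
#' @param truth truth tibble.
#' @param fdr_mark FDR level of the marked point (default 0.05).
#' @return a `tpr_fdp_curve`: list with `points` (tibble `rank`, `pvalue`,
#'   `tpr`, `fdp`) and `mark` (list `tpr`, `fdp`, `level`).
#' @export
tpr_fdp_curve <- function(results, truth, fdr_mark = 0.05) {
  stopifnot(dplyr::n_distinct(results$contrast) == 1)
  tab <- join_truth(results, truth) |>
    dplyr::filter(.data$status %in% c("ok", "reduced"), !is.na(.data$pvalue)) |>
    dplyr::arrange(.data$pvalue, dplyr::desc(abs(.data$t)), .data$protein)
  n_da <- sum(tab$is_da)
  cum_tp <- cumsum(tab$is_da)
  cum_fp <- cumsum(!tab$is_da)
  points <- tibble::tibble(
    rank = seq_len(nrow(tab)),
    pvalue = tab$pvalue,
    tpr = if (n_da > 0) cum_tp / n_da else NA_real_,
    fdp = ifelse(cum_tp + cum_fp > 0, cum_fp / (cum_tp + cum_fp), 0)
  )
  mk <- counts_at_fdr(results, truth, fdr_mark)
  structure(
    list(points = points,
         mark = list(tpr = if (mk$TP + mk$FN > 0) tpr(mk) else NA_real_,
                     fdp = fdp(mk), level = fdr_mark)),
    class = "tpr_fdp_curve"
  )
}

#' @export
print.tpr_fdp_curve <- function(x, ...) {
  cat(sprintf("<tpr_fdp_curve> %d ranked proteins; at %.0f%% FDR: TPR=%.3f FDP=%.3f\n",
              nrow(x$points), 100 * x$mark$level, x$mark$tpr, x$mark$fdp))
  invisible(x)
}

#' log2 fold-change error summary per truth class
#'
#' Groups the (protein, contrast) rows by their true log2 fold change (the
#' `"null"` class has truth 0) and reports the bias (mean estimate minus
#' truth), standard deviation and median of the estimates.
#'
#' @param results result tibble.
#' @param truth truth tibble.
#' @return tibble with `contrast`, `class`, `truth`, `n`, `bias`, `sd`,
#'   `median`.
#' @export
logfc_error_summary <- function(results, truth) {
  tab <- join_truth(results, truth) |>
    dplyr::filter(.data$status %in% c("ok", "reduced"), !is.na(.data$logFC))
  tab$true_lfc <- 0
  for (cn in unique(tab$contrast)) {
    idx <- tab$contrast == cn
    lfc <- true_logfc(truth, cn)
    tab$true_lfc[idx] <- lfc[match(tab$protein[idx], truth$protein_id)]
  }
  tab |>
    dplyr::mutate(class = ifelse(.data$is_da,
                                 sprintf("lfc=%g", .data$true_lfc), "null"),
                  truth = ifelse(.data$is_da, .data$true_lfc, 0)) |>
    dplyr::group_by(.data$contrast, .data$class, .data$truth) |>
    dplyr::summarise(n = dplyr::n(),
                     bias = mean(.data$logFC) - .data$truth[1],
                     sd = stats::sd(.data$logFC),
                     median = stats::median(.data$logFC),
                     .groups = "drop")
}

#' Uniformity diagnostics for null p-values
#'
#' Kolmogorov-Smirnov distance of the p-values from the uniform
#' distribution, a fixed 20-bin histogram, and the mass at exactly 1 reported
#' separately (ridge-penalized null proteins shrink to log2FC 0, producing a
#' spike of p-values at 1).
#'
#' @param p numeric p-values, or a result tibble (rows with successful fits
#'   are used).
#' @return list with `ks`, `spike_mass_at_1`, `n` and `histogram` (tibble
#'   `bin_lower`, `bin_upper`, `count`).
#' @export
pvalue_uniformity <- function(p) {
  if (is.data.frame(p)) {
    p <- p$pvalue[p$status %in% c("ok", "reduced") & !is.na(p$pvalue)]
  }
  stopifnot(length(p) > 0, all(p >= 0 & p <= 1))
  n <- length(p)
  s <- sort(p)
  ks <- max(pmax(seq_len(n) / n - s, s - (seq_len(n) - 1) / n))
  breaks <- seq(0, 1, length.out = 21)
  counts <- table(cut(p, breaks, include.lowest = TRUE))
  list(
    ks = ks,
    spike_mass_at_1 = mean(p >= 1 - 1e-12),
    n = n,
    histogram = tibble::tibble(bin_lower = breaks[-21], bin_upper = breaks[-1],
                               count = as.integer(counts))
  )
}
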