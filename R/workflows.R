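#' Workflow configuration
#'
#' Bundles the switches of the named end-to-end workflows. The four named
#' workflows pin their model defaults; `"custom"` requires an explicit
#' [model_spec()]. The `robust` and `ridge` switches span the ablation grid
#' (lmm / rlmm / rilmm / rrilmm) at either quantification level.
#'
#' @param workflow one of `"protein_rrilmm"`, `"protein_rrilmm_mixture"`,
#'   `"psm_rrilmm"`, `"psm_rrilmm_refit"`, `"custom"`.
#' @param condition annotation column holding the condition of interest.
#' @param contrasts named character vector of contrast expressions; `NULL`
#'   derives all pairwise condition contrasts from the annotation.
#' @param fdr FDR level used by reporting helpers.
#' @param robust,ridge enable Huber M-estimation / ridge penalization of the
#'   condition effects.
#' @param drop_reference remove reference channels before analysis.
#' @param normalize apply channel-median normalization.
#' @param min_obs optional minimum observed values per feature
#'   (see [filter_min_observed()]).
#' @param random optional override of the random-term columns.
#' @param spec explicit [model_spec()] for `workflow = "custom"`.
#' @param options a [fit_options()] list.
#' @return a `workflow_config` list.
#' @export
workflow_config <- function(workflow = c("protein_rrilmm",
                                         "protein_rrilmm_mixture",
                                         "psm_rrilmm", "psm_rrilmm_refit",
                                         "custom"),
                            condition = "condition", contrasts = NULL,
                            fdr = 0.05, robust = TRUE, ridge = TRUE,
                            drop_reference = TRUE, normalize = TRUE,
                            min_obs = NULL, random = NULL, spec = NULL,
                            options = fit_options()) {
  workflow <- match.arg(workflow)
  if (workflow == "custom" && is.null(spec)) {
    stop("custom workflows need an explicit model_spec", call. = FALSE)
  }
  structure(list(workflow = workflow, condition = condition,
                 contrasts = contrasts, fdr = fdr, robust = isTRUE(robust),
                 ridge = isTRUE(ridge), drop_reference = isTRUE(drop_reference),
                 normalize = isTRUE(normalize), min_obs = min_obs,
                 random = random, spec = spec, options = options),
            class = "workflow_config")
}

#' All pairwise condition contrasts
#'
#' @param levels condition level names.
#' @param prefix coefficient prefix (the condition column name).
#' @return named character vector of `"<prefix><b> - <prefix><a>"`
#'   expressions for every unordered pair (later level minus earlier).
#' @export
pairwise_contrasts <- function(levels, prefix = "condition") {
  levels <- sort(unique(levels))
  pairs <- utils::combn(levels, 2, simplify = FALSE)
  out <- vapply(pairs, function(pr) {
    sprintf("%s%s - %s%s", prefix, pr[2], prefix, pr[1])
  }, character(1))
  stats::setNames(out, out)
}

condition_spec <- function(cfg) {
  if (!is.null(cfg$spec)) return(cfg$spec)
  if (cfg$ridge) {
    model_spec(fixed = ~ 1, ridge = cfg$condition, robust = cfg$robust,
               options = cfg$options)
  } else {
    model_spec(fixed = stats::as.formula(paste("~ 0 +", cfg$condition)),
               robust = cfg$robust, options = cfg$options)
  }
}

default_contrasts <- function(cfg, ann) {
  if (!is.null(cfg$contrasts)) {
    ctr <- cfg$contrasts
    if (is.null(names(ctr))) names(ctr) <- as.character(ctr)
    return(ctr)
  }
  lev <- ann[[cfg$condition]]
  lev <- unique(lev[!is.na(lev) & !ann$is_reference])
  pairwise_contrasts(lev, prefix = cfg$condition)
}

fallback_prior <- function(s2) {
  # too few successful fits to pool: no moderation
  structure(list(d0 = 0, s0_sq = if (length(s2)) mean(s2) else 1),
            class = "variance_prior")
}

# Per-protein observation rows: observed long intensities joined with the
# annotation, plus the grouping columns the mixed models use.
protein_rows <- function(assay, ann) {
  long <- tidy(assay)
  long <- dplyr::inner_join(long, ann, by = "sample_id",
                            suffix = c(".feat", ""))
  long$sample <- long$sample_id
  long$psm <- long$feature_id
  long
}

fit_all_proteins <- function(assay, ann, spec, strict = TRUE, refit = FALSE,
                             notes = NULL) {
  long <- protein_rows(assay, ann)
  split_rows <- split(long, long$protein_id)
  fits <- lapply(split_rows, function(rows) {
    tryCatch({
      sp <- spec
      # single-level grouping factors carry no information: drop with a note
      multi <- vapply(sp$random, function(t) {
        length(unique(rows[[t]])) > 1
      }, logical(1))
      if (!all(multi) && !is.null(notes)) {
        notes$push(sprintf("%s: dropped single-level random term(s) %s",
                           rows$protein_id[1],
                           paste(sp$random[!multi], collapse = ", ")))
      }
      sp$random <- sp$random[multi]
      if (strict) {
        ohw <- detect_one_hit_wonder(rows, sp)
        if (ohw$one_hit) {
          stop("fit error: random term(s) confounded with the residual: ",
               paste(ohw$confounded, collapse = ", "), call. = FALSE)
        }
      }
      dm <- build_design(rows, sp)
      fit_robust_ridge(rows$intensity, dm, sp)
    }, error = function(e) {
      if (!refit) return(conditionMessage(e))
      tryCatch({
        sp_red <- reduce_model(spec, rows)
        sp_red$random <- sp_red$random[vapply(sp_red$random, function(t) {
          length(unique(rows[[t]])) > 1
        }, logical(1))]
        dm <- build_design(rows, sp_red)
        fit <- fit_robust_ridge(rows$intensity, dm, sp_red)
        fit$status <- "reduced"
        fit
      }, error = function(e2) conditionMessage(e2))
    })
  })
  fits
}

moderated_results <- function(fits, contrasts) {
  ok <- purrr::keep(fits, inherits, "protein_fit")
  prior <- if (length(ok) >= 2) {
    tryCatch(
      estimate_variance_prior(vapply(ok, `[[`, numeric(1), "sigma2"),
                              vapply(ok, `[[`, numeric(1), "df_res")),
      error = function(e) fallback_prior(vapply(ok, `[[`, numeric(1), "sigma2"))
    )
  } else {
    fallback_prior(vapply(ok, `[[`, numeric(1), "sigma2"))
  }
  res <- test_contrasts(fits, prior, contrasts)
  attr(res, "prior") <- prior
  res
}

note_collector <- function() {
  env <- new.env()
  env$notes <- character()
  list(push = function(x) env$notes <- c(env$notes, x),
       get = function() env$notes)
}

prepare_psm <- function(assay, ann, cfg, notes) {
  validate_link(assay, ann)
  if (cfg$drop_reference && any(ann$is_reference)) {
    assay <- drop_reference_channels(assay, ann)
    notes$push("dropped reference channels")
  }
  if (!assay$log2) assay <- log2_transform(assay)
  if (!is.null(cfg$min_obs)) {
    flt <- filter_min_observed(assay, cfg$min_obs)
    assay <- flt$assay
    notes$push(sprintf("min_observed filter removed %d features",
                       flt$report$features_removed))
  }
  if (cfg$normalize) assay <- normalize_channel_median(assay)
  assay
}

finish_results <- function(res, notes, cfg) {
  attr(res, "notes") <- notes$get()
  attr(res, "fdr") <- cfg$fdr
  res
}

#' Protein-level robust ridge mixed-model workflow
#'
#' log2 transformation, channel-median normalization, per-run median-polish
#' summarization to the protein level, then a per-protein mixed model with a
#' ridge-penalized condition effect and random intercepts for run (and for
#' mixture when mixtures span several runs), robustified by Huber
#' M-estimation, followed by empirical-Bayes moderation and Wald tests on
#' the condition contrasts.
#'
#' @param assay a PSM-level [feature_assay()] (raw or log2 scale).
#' @param ann sample annotation tibble.
#' @param cfg a [workflow_config()].
#' @return result tibble with one row per protein and contrast; fitting
#'   notes, the variance prior and the protein fits are attached as
#'   attributes.
#' @export
run_protein_rrilmm <- function(assay, ann, cfg = workflow_config("protein_rrilmm")) {
  notes <- note_collector()
  assay <- prepare_psm(assay, ann, cfg, notes)
  ann_used <- ann[match(assay$sample_ids, ann$sample_id), ]
  prot <- summarize_protein(assay, ann_used, scope = "per_run")
  random <- cfg$random
  if (is.null(random)) {
    random <- "run"
    runs_per_mix <- dplyr::distinct(ann_used, .data$run, .data$mixture) |>
      dplyr::count(.data$mixture)
    if (any(runs_per_mix$n > 1)) random <- c("run", "mixture")
  }
  spec <- condition_spec(cfg)
  spec$random <- random
  fits <- fit_all_proteins(prot, ann_used, spec, strict = TRUE, notes = notes)
  res <- moderated_results(fits, default_contrasts(cfg, ann_used))
  attr(res, "fits") <- fits
  finish_results(res, notes, cfg)
}

#' Protein-level workflow with per-mixture summarization
#'
#' As [run_protein_rrilmm()], but peptide spectra of all technical fraction
#' runs of a mixture are summarized together, giving a single protein value
#' per biological replicate; the run random term is replaced by mixture.
#'
#' @inheritParams run_protein_rrilmm
#' @return result tibble (see [run_protein_rrilmm()]).
#' @export
run_protein_rrilmm_mixture <- function(assay, ann,
                                       cfg = workflow_config("protein_rrilmm_mixture")) {
  notes <- note_collector()
  assay <- prepare_psm(assay, ann, cfg, notes)
  ann_used <- ann[match(assay$sample_ids, ann$sample_id), ]
  prot <- summarize_protein(assay, ann_used, scope = "per_mixture")
  ann_mix <- collapse_annotation(ann_used)
  random <- if (is.null(cfg$random)) "mixture" else cfg$random
  spec <- condition_spec(cfg)
  spec$random <- random
  fits <- fit_all_proteins(prot, ann_mix, spec, strict = TRUE, notes = notes)
  res <- moderated_results(fits, default_contrasts(cfg, ann_mix))
  attr(res, "fits") <- fits
  finish_results(res, notes, cfg)
}

#' PSM-level robust ridge mixed-model workflow
#'
#' Models the normalized PSM intensities directly with random intercepts for
#' sample (run:channel), spectrum and run, a ridge-penalized condition
#' effect, and Huber M-estimation. One-hit-wonder proteins — a single
#' spectrum per run, confounding the sample term with the residual — are
#' reported as `fit_failed`; no silent model reduction is performed (see
#' [run_psm_rrilmm_refit()]).
#'
#' @inheritParams run_protein_rrilmm
#' @return result tibble (see [run_protein_rrilmm()]).
#' @export
run_psm_rrilmm <- function(assay, ann, cfg = workflow_config("psm_rrilmm")) {
  notes <- note_collector()
  assay <- prepare_psm(assay, ann, cfg, notes)
  ann_used <- ann[match(assay$sample_ids, ann$sample_id), ]
  random <- if (is.null(cfg$random)) c("sample", "psm", "run") else cfg$random
  spec <- condition_spec(cfg)
  spec$random <- random
  fits <- fit_all_proteins(assay, ann_used, spec, strict = TRUE, notes = notes)
  res <- moderated_results(fits, default_contrasts(cfg, ann_used))
  attr(res, "fits") <- fits
  finish_results(res, notes, cfg)
}

#' PSM-level workflow with automatic refit of one-hit wonders
#'
#' Identical to [run_psm_rrilmm()], but proteins whose full model cannot be
#' fitted are retried under [reduce_model()] (spectrum term dropped first,
#' then sample) and reported with status `"reduced"`, so one-hit-wonder
#' proteins still receive results.
#'
#' @inheritParams run_protein_rrilmm
#' @return result tibble (see [run_protein_rrilmm()]).
#' @export
run_psm_rrilmm_refit <- function(assay, ann,
                                 cfg = workflow_config("psm_rrilmm_refit")) {
  notes <- note_collector()
  assay <- prepare_psm(assay, ann, cfg, notes)
  ann_used <- ann[match(assay$sample_ids, ann$sample_id), ]
  random <- if (is.null(cfg$random)) c("sample", "psm", "run") else cfg$random
  spec <- condition_spec(cfg)
  spec$random <- random
  fits <- fit_all_proteins(assay, ann_used, spec, strict = TRUE, refit = TRUE,
                           notes = notes)
  res <- moderated_results(fits, default_contrasts(cfg, ann_used))
  attr(res, "fits") <- fits
  finish_results(res, notes, cfg)
}

#' Run a named workflow
#'
#' @param assay a PSM-level [feature_assay()].
#' @param ann sample annotation tibble.
#' @param cfg a [workflow_config()]; its `workflow` field selects the
#'   pipeline (`"custom"` runs the explicit spec at the PSM level).
#' @return result tibble.
#' @export
run_workflow <- function(assay, ann, cfg) {
  switch(cfg$workflow,
    protein_rrilmm = run_protein_rrilmm(assay, ann, cfg),
    protein_rrilmm_mixture = run_protein_rrilmm_mixture(assay, ann, cfg),
    psm_rrilmm = run_psm_rrilmm(assay, ann, cfg),
    psm_rrilmm_refit = run_psm_rrilmm_refit(assay, ann, cfg),
    custom = {
      notes <- note_collector()
      assay <- prepare_psm(assay, ann, cfg, notes)
      ann_used <- ann[match(assay$sample_ids, ann$sample_id), ]
      fits <- fit_all_proteins(assay, ann_used, cfg$spec, strict = TRUE,
                               notes = notes)
      res <- moderated_results(fits, default_contrasts(cfg, ann_used))
      attr(res, "fits") <- fits
      finish_results(res, notes, cfg)
    },
    stop("unknown workflow: ", cfg$workflow, call. = FALSE)
  )
}
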