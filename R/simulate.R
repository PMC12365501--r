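#' Spike-in simulation design
#'
#' Describes a hierarchical multiplexed spike-in experiment: channels within
#' runs, runs within mixtures, technical repeat runs, reference channels,
#' background vs differentially abundant (DA) proteins, missingness and
#' outliers. The default template mirrors a classic TMT10 spike-in layout:
#' five mixtures of ten channels, two reference channels, four conditions
#' with two channels each whose log2 abundance profile follows the dilution
#' series 1, 0.667, 0.5, 0.125.
#'
#' Effects are generated on the log2 scale: a DA protein with effect size
#' `delta` (drawn from `log2fc_grid`) has condition offset
#' `delta * condition_profile[t]`, so the true log2 fold change between two
#' conditions is `delta` times their profile difference. Spectrum (PSM)
#' counts per protein are zero-truncated Poisson, so one-hit-wonder proteins
#' occur with positive probability. Missingness is missing-at-random given
#' the peptide baseline, `P(missing) = plogis(miss_intercept -
#' miss_slope * baseline)` (low-abundance biased; set `miss_slope = 0` for a
#' completely-at-random ablation). Outliers add `outlier_magnitude` log2
#' units, positive or negative with equal probability, to a random fraction
#' of observed cells.
#'
#' @param n_mixtures,runs_per_mixture,n_channels plex layout.
#' @param n_reference_channels leading channels flagged as pooled reference.
#' @param conditions condition labels, recycled over the non-reference
#'   channels in order.
#' @param condition_profile named per-condition log2 abundance offsets.
#' @param n_proteins,background_fraction number of proteins and the fraction
#'   that is non-DA background.
#' @param log2fc_grid effect sizes cycled over DA proteins.
#' @param psm_mean mean of the zero-truncated Poisson spectrum count.
#' @param baseline_mean,baseline_sd protein log2 baseline distribution.
#' @param sd_peptide spread of peptide-ion baselines within a protein.
#' @param sd_run,sd_mixture,sd_sample,sd_psm,sd_resid variance components
#'   (log2 scale standard deviations).
#' @param miss_intercept,miss_slope missingness logistic parameters.
#' @param outlier_fraction,outlier_magnitude outlier contamination.
#' @param seed integer seed; the simulation is fully reproducible from it.
#' @return a `sim_design` list.
#' @export
sim_design <- function(n_mixtures = 5, runs_per_mixture = 1, n_channels = 10,
                       n_reference_channels = 2,
                       conditions = c("A", "B", "C", "D"),
                       condition_profile = stats::setNames(
                         log2(c(1, 0.667, 0.5, 0.125)), c("A", "B", "C", "D")),
                       n_proteins = 1000, background_fraction = 0.9,
                       log2fc_grid = 1, psm_mean = 3,
                       baseline_mean = 16, baseline_sd = 1.5, sd_peptide = 1,
                       sd_run = 0.3, sd_mixture = 0.1, sd_sample = 0.2,
                       sd_psm = 0.5, sd_resid = 0.25,
                       miss_intercept = 6.3, miss_slope = 0.5,
                       outlier_fraction = 0, outlier_magnitude = 5,
                       seed = 1) {
  design <- as.list(environment())
  sds <- c(design$sd_run, design$sd_mixture, design$sd_sample, design$sd_psm,
           design$sd_resid, design$sd_peptide, design$baseline_sd)
  if (any(sds < 0) || design$background_fraction < 0 ||
      design$background_fraction > 1 || design$outlier_fraction < 0 ||
      design$outlier_fraction > 1 || design$psm_mean <= 0) {
    stop("InvalidDesign: negative spread or fraction outside [0, 1]",
         call. = FALSE)
  }
  n_cond_channels <- n_channels - n_reference_channels
  if (n_cond_channels < length(conditions)) {
    stop("InvalidDesign: more conditions than non-reference channels",
         call. = FALSE)
  }
  if (!all(conditions %in% names(condition_profile))) {
    stop("InvalidDesign: condition_profile must cover every condition",
         call. = FALSE)
  }
  structure(design, class = "sim_design")
}

rztpois <- function(n, mean) {
  # zero-truncated Poisson via inverse cdf conditioned on > 0
  lambda <- mean
  u <- stats::runif(n, stats::dpois(0, lambda), 1)
  stats::qpois(u, lambda)
}

with_preserved_rng <- function(code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  force(code)
}

#' Simulate a hierarchical spike-in experiment
#'
#' Generates a raw-scale PSM-level [feature_assay()], its sample annotation,
#' and the per-protein ground truth, following the generative model of
#' [sim_design()]: per protein a zero-truncated number of peptide ions, one
#' spectrum per peptide ion per run, Gaussian mixture/run/sample/spectrum
#' random effects and residual noise on the log2 scale, condition effects for
#' DA proteins (reference channels receive the condition-average profile),
#' logistic missing-at-random dropout on the peptide baseline, and additive
#' log2 outliers. Deterministic given the design's seed.
#'
#' @param design a [sim_design()].
#' @return list with `assay` (raw scale, PSM level), `ann` (annotation
#'   tibble) and `truth` (tibble `protein_id`, `is_da`, `delta`, with the
#'   condition profile attached as attribute `"condition_profile"`).
#' @export
simulate_spikein <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  with_preserved_rng({
    set.seed(design$seed)
    d <- design

    mixtures <- sprintf("M%d", seq_len(d$n_mixtures))
    runs <- tibble::tibble(
      mixture = rep(mixtures, each = d$runs_per_mixture),
      tech_rep = as.character(rep(seq_len(d$runs_per_mixture), d$n_mixtures))
    )
    runs$run <- paste0(runs$mixture, "R", runs$tech_rep)
    channels <- sprintf("C%02d", seq_len(d$n_channels))
    is_ref_channel <- seq_len(d$n_channels) <= d$n_reference_channels
    cond_of_channel <- rep(NA_character_, d$n_channels)
    cond_of_channel[!is_ref_channel] <-
      rep(d$conditions, length.out = sum(!is_ref_channel))

    ann <- tidyr::expand_grid(runs, channel = channels) |>
      dplyr::mutate(
        sample_id = paste(.data$run, .data$channel, sep = ":"),
        is_reference = is_ref_channel[match(.data$channel, channels)],
        condition = cond_of_channel[match(.data$channel, channels)],
        bio_replicate = paste(.data$mixture, .data$channel, sep = "."),
      ) |>
      dplyr::relocate("sample_id", "run", "channel", "mixture",
                      "bio_replicate", "tech_rep", "is_reference", "condition")

    n_bg <- round(d$background_fraction * d$n_proteins)
    proteins <- sprintf("P%04d", seq_len(d$n_proteins))
    is_da <- c(rep(FALSE, n_bg), rep(TRUE, d$n_proteins - n_bg))
    delta <- ifelse(is_da, rep(d$log2fc_grid, length.out = d$n_proteins), 0)
    truth <- tibble::tibble(protein_id = proteins, is_da = is_da, delta = delta)
    attr(truth, "condition_profile") <- d$condition_profile[d$conditions]

    npep <- rztpois(d$n_proteins, d$psm_mean)
    prot_base <- stats::rnorm(d$n_proteins, d$baseline_mean, d$baseline_sd)

    # one peptide-ion record per (protein, peptide)
    pep <- tibble::tibble(
      protein_id = rep(proteins, npep),
      pep_idx = sequence(npep),
      baseline = rep(prot_base, npep) + stats::rnorm(sum(npep), 0, d$sd_peptide)
    )
    pep$peptide_id <- paste0(pep$protein_id, "pep", pep$pep_idx)

    # protein-specific deviations: this is what the per-protein mixed model's
    # random effects describe (global loading shifts are a normalization
    # matter, not a variance component)
    run_eff <- matrix(stats::rnorm(d$n_proteins * nrow(runs), 0, d$sd_run),
                      d$n_proteins, nrow(runs))
    mix_eff <- matrix(stats::rnorm(d$n_proteins * length(mixtures), 0,
                                   d$sd_mixture),
                      d$n_proteins, length(mixtures))
    samp_eff <- matrix(stats::rnorm(d$n_proteins * nrow(ann), 0, d$sd_sample),
                       d$n_proteins, nrow(ann))

    # spectra: each peptide ion yields one spectrum per run
    spectra <- tidyr::expand_grid(pep, run = runs$run)
    spectra$spectrum_id <- paste0(spectra$peptide_id, ".", spectra$run)
    spectra$psm_eff <- stats::rnorm(nrow(spectra), 0, d$sd_psm)

    cells <- tidyr::expand_grid(spectra, channel = channels)
    cells$sample_id <- paste(cells$run, cells$channel, sep = ":")
    idx_p <- match(cells$protein_id, proteins)
    cond <- cond_of_channel[match(cells$channel, channels)]
    profile <- d$condition_profile
    cond_shift <- ifelse(is.na(cond),
                         mean(profile[d$conditions]),
                         profile[cond])
    idx_r <- match(cells$run, runs$run)
    idx_m <- match(sub("R[0-9]+$", "", cells$run), mixtures)
    idx_s <- match(cells$sample_id, ann$sample_id)
    y <- cells$baseline +
      delta[idx_p] * cond_shift +
      run_eff[cbind(idx_p, idx_r)] +
      mix_eff[cbind(idx_p, idx_m)] +
      samp_eff[cbind(idx_p, idx_s)] +
      cells$psm_eff +
      stats::rnorm(nrow(cells), 0, d$sd_resid)

    p_miss <- stats::plogis(d$miss_intercept - d$miss_slope * cells$baseline)
    miss <- stats::runif(nrow(cells)) < p_miss
    y[miss] <- NA_real_
    if (d$outlier_fraction > 0) {
      obs <- which(!miss)
      n_out <- round(d$outlier_fraction * length(obs))
      if (n_out > 0) {
        hit <- sample(obs, n_out)
        y[hit] <- y[hit] + sample(c(-1, 1), n_out, replace = TRUE) *
          d$outlier_magnitude
      }
    }
    cells$intensity <- 2^y

    feat <- spectra |>
      dplyr::mutate(feature_id = paste(.data$run, .data$spectrum_id, sep = ":")) |>
      dplyr::select("feature_id", "protein_id", "peptide_id", "spectrum_id",
                    "run")
    values <- matrix(NA_real_, nrow = nrow(feat), ncol = nrow(ann),
                     dimnames = list(feat$feature_id, ann$sample_id))
    values[cbind(match(paste(cells$run, cells$spectrum_id, sep = ":"),
                       feat$feature_id),
                 match(cells$sample_id, ann$sample_id))] <- cells$intensity
    assay <- feature_assay(values, feat, level = "psm", log2 = FALSE)
    list(assay = assay, ann = ann, truth = truth)
  })
}

#' True log2 fold change implied by the ground truth for a contrast
#'
#' @param truth truth tibble from [simulate_spikein()].
#' @param contrast contrast expression over `condition<level>` coefficient
#'   names, e.g. `"conditionB - conditionA"`.
#' @return numeric vector of per-protein true log2 fold changes.
#' @export
true_logfc <- function(truth, contrast) {
  profile <- attr(truth, "condition_profile")
  coef_names <- paste0("condition", names(profile))
  L <- parse_contrast(contrast, coef_names)
  if (is.null(L)) stop("contrast does not resolve against the condition profile",
                       call. = FALSE)
  unit <- sum(L * profile)
  truth$delta * unit
}

#' Randomly split samples into two mock conditions
#'
#' Within each stratum, samples are split as evenly as possible into two mock
#' condition labels, uniformly at random. Used for permutation-style null
#' analyses on real designs: no protein is differentially abundant between
#' the mock groups, so their p-values should be uniform.
#'
#' @param ann sample annotation tibble.
#' @param strata character vector of annotation columns defining the strata
#'   (e.g. mixture and treatment combination).
#' @param seed integer seed.
#' @return the annotation with a `mock_condition` column (`"mock1"`,
#'   `"mock2"`); reference channels are left `NA` and not assigned.
#' @export
permute_mock_labels <- function(ann, strata, seed = 1) {
  stopifnot(all(strata %in% names(ann)))
  with_preserved_rng({
    set.seed(seed)
    target <- ann[!ann$is_reference, ]
    key <- interaction(target[strata], drop = TRUE)
    sizes <- table(key)
    if (any(sizes < 2)) {
      stop("StratumTooSmall: strata with fewer than 2 samples: ",
           paste(names(sizes)[sizes < 2], collapse = ", "), call. = FALSE)
    }
    mock <- rep(NA_character_, nrow(target))
    for (k in levels(key)) {
      idx <- which(key == k)
      n1 <- ceiling(length(idx) / 2)
      pick <- sample(idx, n1)
      mock[pick] <- "mock1"
      mock[setdiff(idx, pick)] <- "mock2"
    }
    out <- ann
    out$mock_condition <- NA_character_
    out$mock_condition[match(target$sample_id, ann$sample_id)] <- mock
    out
  })
}
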