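test_that("the simulator is deterministic and validates its design", {
  d <- sim_design(n_proteins = 30, n_mixtures = 2, seed = 61)
  s1 <- simulate_spikein(d)
  s2 <- simulate_spikein(d)
  expect_identical(s1$assay$values, s2$assay$values)
  expect_identical(s1$truth, s2$truth)

  expect_error(sim_design(sd_run = -1), "InvalidDesign")
  expect_error(sim_design(background_fraction = 1.2), "InvalidDesign")
  expect_error(sim_design(n_channels = 3, n_reference_channels = 0,
                          conditions = c("A", "B", "C", "D")),
               "InvalidDesign")
})

test_that("with all spreads and effects zero every protein is flat", {
  d <- sim_design(n_proteins = 5, n_mixtures = 2, n_channels = 4,
                  n_reference_channels = 0, conditions = c("A", "B"),
                  condition_profile = c(A = 0, B = 0),
                  background_fraction = 1, baseline_sd = 0, sd_peptide = 0,
                  sd_run = 0, sd_mixture = 0, sd_sample = 0, sd_psm = 0,
                  sd_resid = 0, miss_intercept = -50, seed = 62)
  sim <- simulate_spikein(d)
  l2 <- log2(sim$assay$values)
  for (p in unique(sim$assay$feature_meta$protein_id)) {
    rows <- sim$assay$feature_meta$protein_id == p
    vals <- l2[rows, ][!is.na(l2[rows, ])]
    expect_lt(diff(range(vals)), 1e-9)
  }
})

test_that("variance components are recoverable from the simulated hierarchy", {
  d <- sim_design(n_proteins = 1000, n_mixtures = 5, n_channels = 4,
                  n_reference_channels = 0, conditions = "A",
                  condition_profile = c(A = 0), background_fraction = 1,
                  psm_mean = 3, sd_peptide = 0, sd_psm = 0, sd_mixture = 0,
                  sd_run = 0.3, sd_sample = 0.2, sd_resid = 0.25,
                  miss_intercept = -50, seed = 63)
  sim <- simulate_spikein(d)
  long <- tidy(log2_transform(sim$assay))
  long <- dplyr::inner_join(long, sim$ann, by = "sample_id",
                            suffix = c(".feat", ""))
  # method of moments through half-variances of within-group differences:
  # same sample: 2 sigma^2; same run, different channel: + 2 sigma_samp^2;
  # different run: + 2 sigma_run^2
  centered <- long |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::mutate(dev = .data$intensity - mean(.data$intensity)) |>
    dplyr::ungroup()
  pair_var <- function(tab, same_run, same_sample) {
    set.seed(1)
    vals <- numeric(0)
    by_prot <- split(tab, tab$protein_id)
    for (pt in by_prot) {
      n <- nrow(pt)
      if (n < 2) next
      i <- sample(n, min(n, 20), replace = TRUE)
      j <- sample(n, min(n, 20), replace = TRUE)
      keep <- i != j &
        (pt$run[i] == pt$run[j]) == same_run &
        (pt$sample_id[i] == pt$sample_id[j]) == same_sample
      vals <- c(vals, (pt$intensity[i][keep] - pt$intensity[j][keep])^2 / 2)
    }
    mean(vals)
  }
  v_same_sample <- pair_var(centered, TRUE, TRUE)
  v_same_run <- pair_var(centered, TRUE, FALSE)
  v_diff_run <- pair_var(centered, FALSE, FALSE)
  expect_lt(abs(sqrt(v_same_sample) / 0.25 - 1), 0.1)
  expect_lt(abs(sqrt(v_same_run - v_same_sample) / 0.2 - 1), 0.1)
  expect_lt(abs(sqrt(v_diff_run - v_same_run) / 0.3 - 1), 0.1)
})

test_that("the marginal missingness rate matches the logistic intercept", {
  d <- sim_design(n_proteins = 400, n_mixtures = 3, n_channels = 10,
                  psm_mean = 3, miss_intercept = qlogis(0.3), miss_slope = 0,
                  seed = 64)
  sim <- simulate_spikein(d)
  expect_gt(length(sim$assay$values), 1e5)
  # structural NAs (a spectrum lives in one run) are not dropout; count
  # missingness within each spectrum's own run
  meta <- sim$assay$feature_meta
  own <- matrix(FALSE, nrow(meta), ncol(sim$assay$values))
  ann_run <- sim$ann$run[match(colnames(sim$assay$values), sim$ann$sample_id)]
  for (r in unique(meta$run)) {
    own[meta$run == r, ann_run == r] <- TRUE
  }
  miss_rate <- mean(is.na(sim$assay$values[own]))
  expect_lt(abs(miss_rate - 0.3), 0.02)
})

test_that("one-hit-wonder proteins arise with the expected frequency", {
  d <- sim_design(n_proteins = 2000, n_mixtures = 1, psm_mean = 2, seed = 65)
  sim <- simulate_spikein(d)
  counts <- table(sim$assay$feature_meta$protein_id)
  frac_one <- mean(counts == 1)
  p1 <- 2 * exp(-2) / (1 - exp(-2))  # zero-truncated Poisson mass at 1
  expect_lt(abs(frac_one - p1), 0.04)
})

test_that("mock label permutation splits strata evenly and reproducibly", {
  ann <- toy_annotation(n_runs = 2, n_channels = 9, conditions = "X")
  ann$mixture <- ann$run
  m1 <- permute_mock_labels(ann, strata = "run", seed = 7)
  tab <- table(m1$run, m1$mock_condition)
  expect_true(all(tab %in% c(4, 5)))  # stratum of 9: 5/4 split
  expect_identical(permute_mock_labels(ann, strata = "run", seed = 7), m1)
  expect_false(identical(permute_mock_labels(ann, strata = "run", seed = 8), m1))

  ann4 <- toy_annotation(n_runs = 1, n_channels = 4, conditions = "X")
  m4 <- permute_mock_labels(ann4, strata = "run", seed = 1)
  expect_equal(as.integer(table(m4$mock_condition)), c(2L, 2L))

  tiny <- toy_annotation(n_runs = 1, n_channels = 1, conditions = "X")
  expect_error(permute_mock_labels(tiny, strata = "run"), "StratumTooSmall")
})

test_that("TPR and FDP follow their defining formulas", {
  expect_equal(tpr(benchmark_counts(40, 0, 0)), 1)
  expect_equal(tpr(benchmark_counts(0, 3, 10)), 0)
  expect_error(tpr(benchmark_counts(0, 3, 0)), "NoPositives")
  expect_equal(fdp(benchmark_counts(0, 0, 5)), 0)
  set.seed(66)
  for (i in 1:20) {
    cnt <- benchmark_counts(sample(0:50, 1), sample(0:50, 1), sample(1:50, 1))
    expect_equal(tpr(cnt), cnt$TP / (cnt$TP + cnt$FN))
    expect_equal(fdp(cnt), if (cnt$TP + cnt$FP == 0) 0 else
      cnt$FP / (cnt$TP + cnt$FP))
  }
})

make_results <- function(p, truth_da, t = NULL, protein = NULL) {
  n <- length(p)
  if (is.null(t)) t <- qnorm(1 - p / 2)
  if (is.null(protein)) protein <- sprintf("P%04d", seq_len(n))
  tibble::tibble(protein = protein, contrast = "c", logFC = t / 10, se = 0.1,
                 t = t, df = 10, pvalue = p, adj_pvalue = bh_adjust(p),
                 status = "ok")
}

test_that("counts at an FDR threshold match a manual audit", {
  truth <- tibble::tibble(protein_id = paste0("P", 1:6),
                          is_da = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
                          delta = c(1, 1, 1, 0, 0, 0))
  res <- tibble::tibble(
    protein = paste0("P", 1:6), contrast = "c",
    logFC = c(2, 1.5, 0.1, 1.8, 0, 0), se = 0.2, t = 1, df = 10,
    pvalue = c(0.001, 0.004, 0.6, 0.002, 0.9, NA),
    adj_pvalue = c(0.004, 0.008, 0.8, 0.006, 0.95, NA),
    status = c(rep("ok", 5), "fit_failed")
  )
  cnt <- counts_at_fdr(res, truth, 0.05)
  expect_equal(c(cnt$TP, cnt$FP, cnt$FN, cnt$TN), c(2, 1, 1, 2))
  expect_equal(cnt$TP + cnt$FP + cnt$FN + cnt$TN, 6)

  all_called <- counts_at_fdr(res, truth, 1)
  expect_equal(all_called$TP + all_called$FP, 5)  # failed fit never called

  null_truth <- dplyr::mutate(truth, is_da = FALSE, delta = 0)
  res_nocall <- dplyr::mutate(res, adj_pvalue = 1)
  cnt0 <- counts_at_fdr(res_nocall, null_truth, 0.05)
  expect_equal(cnt0$TP + cnt0$FP, 0)

  expect_error(counts_at_fdr(make_results(c(0.1), TRUE), truth,
                             0.05), "UnknownProtein")
})

test_that("TPR-FDP curves rank correctly and behave at the extremes", {
  truth <- tibble::tibble(protein_id = sprintf("P%04d", 1:20),
                          is_da = rep(c(TRUE, FALSE), each = 10),
                          delta = rep(c(1, 0), each = 10))
  perfect <- make_results(c(seq(0.0001, 0.001, length.out = 10),
                            seq(0.5, 0.9, length.out = 10)),
                          truth$is_da)
  cv <- tpr_fdp_curve(perfect, truth)
  expect_equal(cv$points$fdp[10], 0)
  expect_equal(cv$points$tpr[10], 1)

  reversed <- make_results(rev(perfect$pvalue), truth$is_da,
                           protein = perfect$protein)
  cr <- tpr_fdp_curve(reversed, truth)
  expect_true(all(cv$points$tpr >= cr$points$tpr))

  set.seed(67)
  n <- 10000
  truth_big <- tibble::tibble(protein_id = sprintf("P%05d", 1:n),
                              is_da = runif(n) < 0.5,
                              delta = 0)
  rand <- tibble::tibble(protein = truth_big$protein_id, contrast = "c",
                         logFC = 0, se = 1, t = rnorm(n), df = 10,
                         pvalue = runif(n), adj_pvalue = 1, status = "ok")
  curve <- tpr_fdp_curve(rand, truth_big)
  terminal <- tail(curve$points$fdp, 1)
  expect_lt(abs(terminal - mean(!truth_big$is_da)), 0.02)
})

test_that("logFC error summaries aggregate by truth class", {
  truth <- tibble::tibble(protein_id = paste0("P", 1:4),
                          is_da = c(TRUE, TRUE, FALSE, FALSE),
                          delta = c(1, 1, 0, 0))
  attr(truth, "condition_profile") <- c(A = 0, B = 1)
  res <- tibble::tibble(protein = paste0("P", 1:4),
                        contrast = "conditionB - conditionA",
                        logFC = c(1, 1, 0, 0), se = 0.1, t = 1, df = 5,
                        pvalue = 0.5, adj_pvalue = 0.5, status = "ok")
  s <- logfc_error_summary(res, truth)
  expect_equal(s$bias, c(0, 0))
  expect_equal(s$sd, c(0, 0))

  shifted <- dplyr::mutate(res, logFC = logFC + 0.1)
  s2 <- logfc_error_summary(shifted, truth)
  expect_equal(s2$bias, c(0.1, 0.1), tolerance = 1e-12)

  set.seed(68)
  res3 <- dplyr::mutate(res, logFC = rnorm(4))
  s3 <- logfc_error_summary(res3, truth)
  truth_lfc <- c(1, 1, 0, 0)
  for (k in seq_len(nrow(s3))) {
    idx <- if (s3$class[k] == "null") 3:4 else 1:2
    expect_equal(s3$bias[k], mean(res3$logFC[idx]) - truth_lfc[idx][1])
    expect_equal(s3$median[k], median(res3$logFC[idx]))
  }
})

test_that("p-value uniformity diagnostics report KS distance and the spike at 1", {
  n <- 50
  grid <- (seq_len(n) - 0.5) / n
  u <- pvalue_uniformity(grid)
  expect_equal(u$ks, 1 / (2 * n), tolerance = 1e-12)

  all_one <- pvalue_uniformity(rep(1, 20))
  expect_equal(all_one$ks, 1)
  expect_equal(all_one$spike_mass_at_1, 1)

  set.seed(69)
  p <- runif(10000)
  u2 <- pvalue_uniformity(p)
  expect_lt(u2$ks, 1.63 / sqrt(10000))  # 1% critical value
  expect_equal(sum(u2$histogram$count), 10000)
})

test_that("true log fold changes derive from the condition profile", {
  truth <- tibble::tibble(protein_id = c("P1", "P2"), is_da = c(TRUE, FALSE),
                          delta = c(2, 0))
  attr(truth, "condition_profile") <- c(A = 0, B = -1)
  expect_equal(true_logfc(truth, "conditionB - conditionA"), c(-2, 0))
  expect_error(true_logfc(truth, "conditionZ - conditionA"), "resolve")
})
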