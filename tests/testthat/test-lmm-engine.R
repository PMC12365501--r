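test_that("design construction encodes fixed, ridge and random terms", {
  rows <- tibble::tibble(
    condition = rep(c("A", "B"), 6),
    sample = rep(paste0("s", 1:4), 3),
    psm = rep(paste0("f", 1:3), each = 4),
    run = rep(c("R1", "R2"), each = 6),
    x = rnorm(12)
  )
  dm <- build_design(rows, model_spec(~ 1, random = c("sample", "psm", "run")))
  expect_named(dm$Z_blocks, c("sample", "psm", "run"))
  expect_equal(vapply(dm$Z_blocks, ncol, integer(1)),
               c(sample = 4L, psm = 3L, run = 2L))

  dmr <- build_design(rows, model_spec(~ 1, ridge = "condition"))
  expect_equal(ncol(dmr$Z_blocks$condition), 2L)  # no reference level dropped
  expect_equal(colnames(dmr$Z_blocks$condition), c("conditionA", "conditionB"))

  # fixed part matches the standard formula expansion
  dmx <- build_design(rows, model_spec(~ condition + x))
  expect_equal(unname(dmx$X),
               unname(stats::model.matrix(~ condition + x, rows)))

  # rank-deficient fixed columns are dropped with a note
  rows$dup <- rows$x
  dmd <- build_design(rows, model_spec(~ x + dup))
  expect_equal(ncol(dmd$X), 2L)
  expect_match(dmd$notes, "rank-deficient")

  expect_error(build_design(rows, model_spec(~ nope)), "UnknownTerm")
  expect_error(build_design(rows[0, ], model_spec(~ 1)), "NoObservations")
})

test_that("REML reduces to classical answers in closed-form cases", {
  dm <- design_matrices(matrix(1, 3, 1, dimnames = list(NULL, "(Intercept)")))
  fit <- fit_reml(c(1, 2, 3), dm)
  expect_equal(unname(fit$coef), 2)
  expect_equal(fit$sigma2, 1)  # n - 1 denominator
  expect_equal(fit$df_res, 2)

  # balanced one-way layouts: REML equals the ANOVA estimators
  set.seed(31)
  for (i in 1:10) {
    g <- sample(4:8, 1); n <- sample(4:10, 1)
    grp <- rep(paste0("g", seq_len(g)), each = n)
    y <- rep(rnorm(g, 0, 2), each = n) + rnorm(g * n, 0, 0.5)
    dm <- build_design(tibble::tibble(grp = grp), model_spec(~ 1, random = "grp"))
    fit <- fit_reml(y, dm)
    msb <- n * var(tapply(y, grp, mean))
    msw <- mean(tapply(y, grp, var))
    expect_equal(fit$sigma2, msw, tolerance = 1e-6)
    expect_equal(unname(fit$varcomps["grp"] * fit$sigma2),
                 max(0, (msb - msw) / n), tolerance = 1e-6)
  }
})

test_that("the returned optimum beats random variance-ratio probes", {
  set.seed(32)
  for (i in 1:3) {
    rows <- tibble::tibble(
      run = sample(paste0("R", 1:4), 40, replace = TRUE),
      samp = sample(paste0("s", 1:8), 40, replace = TRUE)
    )
    y <- rnorm(40) + rnorm(4)[as.integer(factor(rows$run))]
    dm <- build_design(rows, model_spec(~ 1, random = c("run", "samp")))
    fit <- fit_reml(y, dm)
    obj_opt <- reml_objective(y, dm, fit$varcomps)
    probes <- matrix(exp(runif(200, log(1e-8), log(1e4))), ncol = 2)
    for (j in seq_len(nrow(probes))) {
      expect_gte(reml_objective(y, dm, probes[j, ]) + 1e-6, obj_opt)
    }
  }
})

test_that("with no random terms and unit weights REML is ordinary least squares", {
  set.seed(33)
  X <- cbind(1, rnorm(25), runif(25))
  colnames(X) <- c("(Intercept)", "x1", "x2")
  y <- X %*% c(1, 2, -1) + rnorm(25)
  fit <- fit_reml(drop(y), design_matrices(X))
  ls <- lm(y ~ X - 1)
  expect_equal(unname(fit$coef), unname(coef(ls)), tolerance = 1e-10)
  expect_equal(unname(fit$vcov_unscaled * fit$sigma2), unname(vcov(ls)),
               tolerance = 1e-10)
  expect_equal(fit$df_res, 22)
})

test_that("pinned-ratio ridge blocks match the closed-form ridge solution", {
  set.seed(34)
  for (i in 1:5) {
    n <- 20; k <- 5
    X <- scale(matrix(rnorm(n * k), n, k), scale = FALSE)
    colnames(X) <- paste0("b", seq_len(k))
    y <- rnorm(n)
    lambda <- exp(runif(1, -2, 3))
    fit <- fit_reml(y, design_matrices(matrix(0, n, 0), list(blk = X)),
                    fix_ratios = 1 / lambda)
    closed <- solve(crossprod(X) + lambda * diag(k), crossprod(X, y))
    expect_equal(unname(fit$coef), unname(drop(closed)), tolerance = 1e-8)
  }
})

test_that("ridge shrinkage is monotone in the penalty", {
  set.seed(35)
  for (i in 1:50) {
    n <- 15; k <- 4
    X <- scale(matrix(rnorm(n * k), n, k), scale = FALSE)
    colnames(X) <- paste0("b", seq_len(k))
    y <- rnorm(n, sd = 2)
    dm <- design_matrices(matrix(0, n, 0), list(blk = X))
    norms <- vapply(c(0.01, 0.1, 1, 10, 100), function(lambda) {
      sqrt(sum(fit_reml(y, dm, fix_ratios = 1 / lambda)$coef^2))
    }, numeric(1))
    expect_true(all(diff(norms) <= 1e-10))
  }
})

test_that("REML agrees with lme4 on crossed random intercepts", {
  set.seed(36)
  rows <- tibble::tibble(
    run = rep(paste0("R", 1:5), each = 12),
    samp = rep(paste0("s", 1:20), 3),
    condition = rep(c("A", "B"), 30)
  )
  y <- rnorm(60) + rep(rnorm(5, 0, 0.8), each = 12) +
    rnorm(20, 0, 0.5)[as.integer(factor(rows$samp))] +
    ifelse(rows$condition == "B", 1, 0)
  dm <- build_design(rows, model_spec(~ condition, random = c("run", "samp")))
  fit <- fit_reml(y, dm)
  lf <- lme4::lmer(y ~ condition + (1 | run) + (1 | samp), data = rows,
                   REML = TRUE,
                   control = lme4::lmerControl(
                     optCtrl = list(xtol_abs = 1e-12, ftol_abs = 1e-12)))
  vc <- as.data.frame(lme4::VarCorr(lf))
  expect_equal(unname(fit$coef[1:2]), unname(lme4::fixef(lf)), tolerance = 1e-4)
  expect_equal(fit$sigma2, vc$vcov[vc$grp == "Residual"], tolerance = 5e-3)
  expect_equal(unname(fit$varcomps["samp"] * fit$sigma2),
               vc$vcov[vc$grp == "samp"], tolerance = 5e-3)
  expect_equal(unname(fit$varcomps["run"] * fit$sigma2),
               vc$vcov[vc$grp == "run"], tolerance = 5e-3)
})

test_that("robustness weights are inert without outliers and help with them", {
  set.seed(37)
  x <- rnorm(30)
  rows <- tibble::tibble(x = x)
  y <- 1 + 0.5 * x + rnorm(30, 0, 0.3)
  spec <- model_spec(~ x, robust = TRUE)
  dm <- build_design(rows, spec)
  rfit <- fit_robust_ridge(y, dm, spec)
  plain <- fit_reml(y, dm)
  if (all(abs(y - plain$fitted) / (stats::mad(y - plain$fitted)) <= 1.345)) {
    expect_equal(rfit$coef, plain$coef, tolerance = 1e-12)
    expect_true(all(rfit$weights == 1))
  }

  # Monte-Carlo: robust slope beats the non-robust slope under contamination
  err_rob <- err_ols <- numeric(500)
  for (i in 1:500) {
    x <- rnorm(20)
    y <- 2 * x + rnorm(20, 0, 0.5)
    out <- sample(20, 2)
    y[out] <- y[out] + 10 * 0.5
    dm <- build_design(tibble::tibble(x = x), spec)
    err_rob[i] <- (fit_robust_ridge(y, dm, spec)$coef[["x"]] - 2)^2
    err_ols[i] <- (fit_reml(y, dm)$coef[["x"]] - 2)^2
  }
  expect_lt(mean(err_rob), mean(err_ols))
})

test_that("effective degrees of freedom interpolate between fixed and null blocks", {
  set.seed(38)
  n <- 24
  rows <- tibble::tibble(grp = rep(paste0("g", 1:6), each = 4))
  y <- rnorm(n)
  dm <- build_design(rows, model_spec(~ 1, random = "grp"))
  # variance ratio ~ 0: the block vanishes, df -> n - p
  f0 <- fit_reml(y, dm, fix_ratios = 1e-10)
  expect_equal(f0$df_res, n - 1, tolerance = 1e-6)
  # variance ratio huge: the block behaves like fixed effects;
  # one direction is confounded with the intercept, df -> n - p - q + 1
  finf <- fit_reml(y, dm, fix_ratios = 1e8)
  expect_equal(finf$df_res, n - 1 - 5, tolerance = 1e-3)
})

test_that("scale equivariance: scaling y scales coefficients and variance", {
  set.seed(39)
  rows <- tibble::tibble(grp = rep(paste0("g", 1:5), each = 5),
                         condition = rep(c("A", "B"), length.out = 25))
  y <- rnorm(25, 10)
  spec <- model_spec(~ 1, random = "grp", ridge = "condition", robust = FALSE)
  dm <- build_design(rows, spec)
  f1 <- fit_robust_ridge(y, dm, spec)
  f2 <- fit_robust_ridge(3 * y, dm, spec)
  expect_lt(max(abs(f2$coef - 3 * f1$coef) / pmax(abs(3 * f1$coef), 1e-8)),
            1e-6)
  expect_equal(f2$sigma2, 9 * f1$sigma2, tolerance = 1e-6)
})

test_that("one-hit wonders are detected exactly as single-observation groupings", {
  rows_ohw <- tibble::tibble(sample = paste0("s", 1:8),
                             psm = rep(paste0("f", 1:4), 2),
                             run = rep(c("R1", "R2"), each = 4))
  spec <- model_spec(~ 1, random = c("sample", "psm", "run"))
  det <- detect_one_hit_wonder(rows_ohw, spec)
  expect_true(det$one_hit)
  expect_equal(det$confounded, "sample")

  rows_ok <- dplyr::mutate(rows_ohw, sample = rep(paste0("s", 1:4), 2))
  expect_false(detect_one_hit_wonder(rows_ok, spec)$one_hit)

  set.seed(40)
  for (i in 1:20) {
    n <- sample(5:15, 1)
    rows <- tibble::tibble(g = sample(paste0("l", 1:n), n, replace = TRUE))
    det <- detect_one_hit_wonder(rows, model_spec(~ 1, random = "g"))
    expect_equal(det$one_hit, all(table(rows$g) <= 1))
  }
})

test_that("model reduction retains the largest identifiable sub-model", {
  rows <- tibble::tibble(
    intensity = rnorm(8), condition = rep(c("A", "B"), 4),
    sample = paste0("s", 1:8), psm = paste0("f", rep(1:4, 2)),
    run = rep(c("R1", "R2"), each = 4)
  )
  rows$psm <- paste0("f", 1:8)  # one spectrum per observation too
  spec <- model_spec(~ 1, random = c("sample", "psm", "run"),
                     ridge = "condition")
  red <- reduce_model(spec, rows)
  expect_equal(red$random, "run")
  expect_setequal(attr(red, "reduced_terms"), c("sample", "psm"))

  rows_ok <- dplyr::mutate(rows, sample = rep(paste0("s", 1:2), 4),
                           psm = rep(paste0("f", 1:2), each = 4))
  red2 <- reduce_model(spec, rows_ok)
  expect_setequal(red2$random, c("sample", "psm", "run"))

  # random degenerate layouts always yield a fittable reduced model
  set.seed(41)
  for (i in 1:15) {
    n <- sample(6:14, 1)
    rows <- tibble::tibble(
      intensity = rnorm(n),
      condition = sample(c("A", "B"), n, replace = TRUE),
      sample = sample(paste0("s", 1:n), n, replace = TRUE),
      psm = sample(paste0("f", 1:n), n, replace = TRUE),
      run = sample(c("R1", "R2"), n, replace = TRUE)
    )
    red <- reduce_model(spec, rows)
    red$random <- red$random[vapply(red$random, function(t) {
      length(unique(rows[[t]])) > 1
    }, logical(1))]
    dm <- build_design(rows, red)
    expect_s3_class(fit_robust_ridge(rows$intensity, dm, red), "protein_fit")
  }
})

test_that("variance components are recovered across simulated proteins", {
  d <- sim_design(n_proteins = 500, n_mixtures = 10, n_channels = 5,
                  n_reference_channels = 0, conditions = "A",
                  condition_profile = c(A = 0), background_fraction = 1,
                  psm_mean = 3, sd_peptide = 0, sd_psm = 0, sd_mixture = 0,
                  sd_run = 0.3, sd_sample = 0.2, sd_resid = 0.25,
                  miss_intercept = -50, seed = 42)
  sim <- simulate_spikein(d)
  a <- log2_transform(sim$assay)
  long <- dplyr::inner_join(tidy(a), sim$ann, by = "sample_id",
                            suffix = c(".feat", ""))
  long$sample <- long$sample_id
  spec <- model_spec(~ 1, random = c("run", "sample"), robust = FALSE)
  ests <- long |>
    dplyr::group_by(protein_id) |>
    dplyr::group_map(function(rows, key) {
      fit <- fit_reml(rows$intensity, build_design(rows, spec))
      c(run = unname(fit$varcomps["run"] * fit$sigma2),
        sample = unname(fit$varcomps["sample"] * fit$sigma2),
        resid = fit$sigma2)
    })
  ests <- do.call(rbind, ests)
  # the per-protein estimates are noisy; their medians recover the truth
  expect_lt(abs(median(ests[, "run"]) / 0.3^2 - 1), 0.15)
  expect_lt(abs(median(ests[, "sample"]) / 0.2^2 - 1), 0.15)
  expect_lt(abs(median(ests[, "resid"]) / 0.25^2 - 1), 0.15)
})
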