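# Independent reference implementations used as oracles. These deliberately
# repeat logic in plain loops so they stay independent of the package code
# paths they check.

# Tukey median polish, straightforward loop with the same sweep order and
# stopping rule as the documented contract (rows first, effect medians folded
# into the overall term, L1 stopping relative to 1 + L1 of the data).
ref_median_polish <- function(x, tol = 1e-6, max_iter = 100) {
  z <- as.matrix(x)
  nr <- nrow(z); nc <- ncol(z)
  r <- numeric(nr); cl <- numeric(nc); t0 <- 0
  scale <- 1 + sum(abs(z), na.rm = TRUE)
  oldsum <- sum(abs(z), na.rm = TRUE)
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    for (i in seq_len(nr)) {
      v <- z[i, ][!is.na(z[i, ])]
      if (length(v) == 0) next
      m <- median(v)
      z[i, ] <- z[i, ] - m
      r[i] <- r[i] + m
    }
    dlt <- median(cl)
    cl <- cl - dlt; t0 <- t0 + dlt
    for (j in seq_len(nc)) {
      v <- z[, j][!is.na(z[, j])]
      if (length(v) == 0) next
      m <- median(v)
      z[, j] <- z[, j] - m
      cl[j] <- cl[j] + m
    }
    dlt <- median(r)
    r <- r - dlt; t0 <- t0 + dlt
    newsum <- sum(abs(z), na.rm = TRUE)
    if (abs(newsum - oldsum) < tol * scale) { converged <- TRUE; break }
    oldsum <- newsum
  }
  list(overall = t0, row_effects = r, col_effects = cl, residuals = z,
       iterations = iter, converged = converged)
}

# Benjamini-Hochberg step-up by direct enumeration of the definition:
# adj(i) = min over j >= i of m * p(j) / j, capped at 1.
ref_bh <- function(p) {
  ok <- !is.na(p)
  q <- p[ok]
  m <- length(q)
  ord <- order(q)
  adj_sorted <- numeric(m)
  for (i in seq_len(m)) {
    adj_sorted[i] <- min(1, min(m * q[ord][i:m] / (i:m)))
  }
  out <- rep(NA_real_, length(p))
  out[ok][ord] <- adj_sorted
  out
}

# small assay fixtures -------------------------------------------------------

toy_annotation <- function(n_runs = 2, n_channels = 4, n_ref = 0,
                           conditions = c("A", "B"),
                           mixtures = NULL) {
  runs <- paste0("R", seq_len(n_runs))
  channels <- paste0("C", seq_len(n_channels))
  if (is.null(mixtures)) mixtures <- runs
  grid <- tidyr::expand_grid(run = runs, channel = channels)
  is_ref <- rep(seq_len(n_channels) <= n_ref, n_runs)
  cond <- rep(NA_character_, n_channels)
  cond[seq_len(n_channels) > n_ref] <-
    rep(conditions, length.out = n_channels - n_ref)
  tibble::tibble(
    sample_id = paste(grid$run, grid$channel, sep = ":"),
    run = grid$run, channel = grid$channel,
    mixture = rep(mixtures, each = n_channels),
    bio_replicate = paste(grid$run, grid$channel, sep = "."),
    tech_rep = "1",
    is_reference = is_ref,
    condition = cond[match(grid$channel, channels)]
  )
}

# PSM assay with explicit control over rows; each spectrum belongs to one run
# and is observed in that run's channels only when `ann` spans several runs.
toy_psm_assay <- function(values, protein, peptide = NULL, run = NULL,
                          ann = NULL, log2 = TRUE) {
  values <- as.matrix(values)
  n <- nrow(values)
  if (is.null(peptide)) peptide <- paste0("pep", seq_len(n))
  if (is.null(run)) run <- rep("R1", n)
  spectrum <- paste0("sp", seq_len(n))
  meta <- tibble::tibble(
    feature_id = paste(run, spectrum, sep = ":"),
    protein_id = protein, peptide_id = peptide, spectrum_id = spectrum,
    run = run
  )
  if (is.null(colnames(values))) {
    colnames(values) <- paste("R1", paste0("C", seq_len(ncol(values))), sep = ":")
  }
  feature_assay(values, meta, level = "psm", log2 = log2)
}

random_long_psm_table <- function(n_prot = 3, n_pep = 2, n_runs = 2,
                                  n_channels = 3, missing = 0.1) {
  rows <- tidyr::expand_grid(
    Protein = paste0("P", seq_len(n_prot)),
    pep = seq_len(n_pep),
    Run = paste0("R", seq_len(n_runs)),
    Channel = paste0("C", seq_len(n_channels))
  )
  rows$Peptide <- paste0(rows$Protein, "pep", rows$pep)
  rows$Spectrum <- paste0(rows$Peptide, ".", rows$Run)
  rows$Intensity <- round(2^runif(nrow(rows), 10, 20), 4)
  rows$Intensity[runif(nrow(rows)) < missing] <- NA
  rows[!is.na(rows$Intensity),
       c("Protein", "Peptide", "Spectrum", "Run", "Channel", "Intensity")]
}
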