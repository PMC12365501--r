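# Degenerate-model detection and automatic reduction for one-hit wonders.

term_confounded <- function(rows, term) {
  # a random intercept term is confounded with the residual when every level
  # of its grouping factor carries at most one observation
  counts <- table(rows[[term]])
  all(counts <= 1)
}

#' Detect one-hit-wonder proteins
#'
#' A protein quantified by a single spectrum per run makes random terms such
#' as the sample (run:channel) or spectrum effect unidentifiable: every level
#' of the grouping factor holds at most one observation, so the term is
#' confounded with the residual and the mixed model cannot be fitted.
#'
#' @param rows observation tibble of one protein (annotation and feature
#'   metadata joined).
#' @param spec a [model_spec()].
#' @return list with `one_hit` (logical: any confounded random term) and
#'   `confounded` (the offending term names).
#' @export
detect_one_hit_wonder <- function(rows, spec) {
  confounded <- spec$random[vapply(spec$random, function(t) {
    term_confounded(rows, t)
  }, logical(1))]
  list(one_hit = length(confounded) > 0, confounded = confounded)
}

#' Reduce a model specification to its largest identifiable sub-model
#'
#' Removes random terms that are confounded with the residual (or that have
#' a single level) in a fixed order — the spectrum-level term first, then the
#' sample-level term, then any remaining confounded terms — returning the
#' largest sub-model that remains identifiable on the given observations.
#'
#' @inheritParams detect_one_hit_wonder
#' @param psm_term,sample_term the column names playing the spectrum- and
#'   sample-level grouping roles (dropped first, in that order).
#' @return the reduced [model_spec()]; dropped terms are recorded in the
#'   `"reduced_terms"` attribute (empty when nothing was dropped).
#' @export
reduce_model <- function(spec, rows, psm_term = "psm", sample_term = "sample") {
  droppable <- function(t) {
    term_confounded(rows, t) || length(unique(rows[[t]])) < 2
  }
  order_terms <- c(intersect(psm_term, spec$random),
                   intersect(sample_term, spec$random),
                   setdiff(spec$random, c(psm_term, sample_term)))
  dropped <- character()
  remaining <- spec$random
  for (t in order_terms) {
    if (t %in% remaining && droppable(t)) {
      remaining <- setdiff(remaining, t)
      dropped <- c(dropped, t)
    }
  }
  out <- spec
  out$random <- remaining
  # the reduced model must still be estimable for the fixed part
  X <- stats::model.matrix(out$fixed, data = rows)
  if (nrow(rows) <= qr(X)$rank) {
    stop("IrreducibleModel: no identifiable sub-model for these observations",
         call. = FALSE)
  }
  attr(out, "reduced_terms") <- dropped
  out
}
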