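#' Compositional isotemporal substitution
#'
#' Estimates the outcome z-score difference when `delta` minutes are moved
#' from one behaviour to another, starting from a reference composition
#' (conventionally the sample's compositional geometric mean). The new
#' composition keeps the other three behaviours fixed, so total time stays
#' at 1440 min. The estimate is the difference in the compositional part of
#' the linear predictor, d = ilr(new) - ilr(base) projected on the fitted
#' coefficients; because the model has no composition-by-covariate
#' interaction, covariate values cancel exactly. The variance is d' V d
#' with V the ilr-coefficient covariance block; the CI uses the t
#' distribution on the residual df.
#'
#' @param fit A `coda_fit`.
#' @param base Reference composition (five parts, minutes/day, sum 1440).
#' @param from_part,to_part Behaviour names; `delta` minutes move from the
#'   first to the second.
#' @param delta Minutes reallocated, default 30.
#' @param level Confidence level, default 0.95.
#' @return data.frame (one row): outcome, from, to, delta_min, estimate,
#'   se, ci_low, ci_high.
#' @export
substitute_time <- function(fit, base, from_part, to_part, delta = 30,
                            level = 0.95) {
  stopifnot(inherits(fit, "coda_fit"))
  if (!from_part %in% BEHAVIOUR_PARTS || !to_part %in% BEHAVIOUR_PARTS) {
    stop("unknown behaviour name")
  }
  if (from_part == to_part) stop("from_part and to_part must differ")
  if (delta <= 0) stop("delta must be positive")
  base <- as_composition_vector(base)
  new <- base
  new[from_part] <- new[from_part] - delta
  new[to_part] <- new[to_part] + delta
  if (any(new <= 0)) {
    stop("infeasible substitution: ", from_part, " - ", delta,
         " min is not positive")
  }
  d <- ilr_transform(new, fit$basis) - ilr_transform(base, fit$basis)
  ilr_terms <- paste0("ilr", seq_len(fit$basis$D - 1))
  beta <- fit$coefficients[ilr_terms]
  V <- fit$vcov[ilr_terms, ilr_terms]
  est <- sum(d * beta)
  se <- sqrt(drop(t(d) %*% V %*% d))
  tcrit <- stats::qt(1 - (1 - level) / 2, fit$df_residual)
  data.frame(outcome = fit$outcome, from = from_part, to = to_part,
             delta_min = delta, estimate = est, se = se,
             ci_low = est - tcrit * se, ci_high = est + tcrit * se,
             row.names = NULL)
}

#' All pairwise isotemporal substitutions
#'
#' Evaluates [substitute_time()] for every ordered pair of distinct
#' behaviours (20 pairs for five behaviours), including reallocations to
#' and from sleeping. Infeasible pairs (the source behaviour would go
#' non-positive) are skipped with a warning.
#'
#' @inheritParams substitute_time
#' @return data.frame with up to 20 rows in deterministic (from, to) order.
#' @export
substitution_matrix <- function(fit, base, delta = 30, level = 0.95) {
  rows <- list()
  for (from_part in BEHAVIOUR_PARTS) {
    for (to_part in setdiff(BEHAVIOUR_PARTS, from_part)) {
      r <- tryCatch(
        substitute_time(fit, base, from_part, to_part, delta, level),
        error = function(e) {
          warning("skipped ", from_part, " -> ", to_part, ": ",
                  conditionMessage(e))
          NULL
        })
      rows[[paste(from_part, to_part)]] <- r
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
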