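#' Covariate specification for compositional models
#'
#' Describes the adjustment set: continuous covariates (age in years, diet
#' quality score 0-140), categorical covariates (sex, education, smoking,
#' and — for overall-sample analyses — diabetes status), and the optional
#' waist-circumference sensitivity adjustment. Waist adjustment is
#' automatically disabled when the outcome is waist circumference or CMR.
#'
#' @param continuous Character vector of continuous covariate columns.
#' @param categorical Character vector of categorical covariate columns.
#' @param adjust_waist Add waist circumference as a covariate (sensitivity
#'   analysis), auto-dropped for waist/CMR outcomes.
#' @return Object of class `covariate_spec`.
#' @export
covariate_spec <- function(continuous = c("age", "diet_score"),
                           categorical = c("sex", "education", "smoking",
                                           "diabetes_status"),
                           adjust_waist = FALSE) {
  structure(list(continuous = continuous, categorical = categorical,
                 adjust_waist = adjust_waist), class = "covariate_spec")
}

# Effective covariate columns for an outcome (waist rule applied).
spec_covariates <- function(spec, outcome) {
  covs <- c(spec$continuous, spec$categorical)
  if (isTRUE(spec$adjust_waist) &&
      !sub("^y_", "", outcome) %in% c("waist", "cmr")) {
    covs <- c(covs, "waist")
  }
  covs
}

# Build the model frame: ilr coordinate columns + covariates, complete cases.
build_model_frame <- function(data, outcome, spec, basis) {
  covs <- spec_covariates(spec, outcome)
  missing_cols <- setdiff(c(outcome, BEHAVIOUR_PARTS, covs), names(data))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  z <- ilr_transform(as.matrix(data[, BEHAVIOUR_PARTS]), basis)
  mf <- data.frame(.outcome = data[[outcome]], z, data[, covs, drop = FALSE])
  for (cc in intersect(spec$categorical, names(mf))) {
    if (!is.factor(mf[[cc]])) mf[[cc]] <- factor(mf[[cc]])
  }
  cc <- stats::complete.cases(mf)
  mf[cc, , drop = FALSE]
}

#' Fit a compositional linear regression
#'
#' Ordinary least squares of an outcome z-score on the four pivot ilr
#' coordinates plus covariates. By the permutation principle the fit
#' (fitted values, predictions, R squared) does not depend on which
#' behaviour leads the basis; the lead choice only selects which balance
#' the first coefficient describes. Continuous covariates are centred
#' (this cannot change composition effects); categorical covariates use
#' treatment contrasts with the first level alphabetically as reference.
#'
#' @param data Participant table: five behaviour columns (minutes/day),
#'   the outcome column (already z-scaled), covariate columns.
#' @param outcome Name of the outcome column.
#' @param spec A [covariate_spec()].
#' @param basis An [ilr_basis()]; default leads with sitting.
#' @return Object of class `coda_fit`: coefficients, covariance matrix,
#'   residual df, basis, spec, covariate centring, n used, and the
#'   underlying `lm` fit.
#' @export
fit_compositional_model <- function(data, outcome, spec = covariate_spec(),
                                    basis = ilr_basis()) {
  mf <- build_model_frame(data, outcome, spec, basis)
  p <- ncol(mf) - 1
  if (nrow(mf) < p + 2) stop("too few complete-case rows (", nrow(mf), ")")
  centres <- numeric(0)
  for (cc in intersect(spec$continuous, names(mf))) {
    centres[cc] <- mean(mf[[cc]])
    mf[[cc]] <- mf[[cc]] - centres[cc]
  }
  if ("waist" %in% names(mf) && !"waist" %in% names(centres)) {
    centres["waist"] <- mean(mf$waist)
    mf$waist <- mf$waist - centres["waist"]
  }
  fit <- stats::lm(.outcome ~ ., data = mf)
  beta <- stats::coef(fit)
  if (anyNA(beta)) {
    stop("rank-deficient design; collinear column(s): ",
         paste(names(beta)[is.na(beta)], collapse = ", "))
  }
  structure(list(outcome = outcome,
                 coefficients = beta,
                 vcov = stats::vcov(fit),
                 df_residual = fit$df.residual,
                 basis = basis,
                 spec = spec,
                 centres = centres,
                 xlevels = fit$xlevels,
                 n = nrow(mf),
                 r_squared = summary(fit)$r.squared,
                 lm = fit),
            class = "coda_fit")
}

#' @export
print.coda_fit <- function(x, ...) {
  cat("Compositional linear model for '", x$outcome, "' (n = ", x$n,
      ", R^2 = ", signif(x$r_squared, 3), ")\n", sep = "")
  cat("ilr basis lead:", x$basis$part_order[1], "\n")
  print(signif(x$coefficients[paste0("ilr", 1:4)], 4))
  invisible(x)
}

#' Coefficient summary table for a compositional fit
#'
#' @param fit A `coda_fit`.
#' @param level Confidence level, default 0.95.
#' @return data.frame: term, estimate, se, t, p, ci_low, ci_high.
#' @export
coef_table <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "coda_fit"))
  est <- fit$coefficients
  se <- sqrt(diag(fit$vcov))
  tval <- est / se
  pval <- 2 * stats::pt(abs(tval), fit$df_residual, lower.tail = FALSE)
  tcrit <- stats::qt(1 - (1 - level) / 2, fit$df_residual)
  data.frame(term = names(est), estimate = unname(est), se = unname(se),
             t = unname(tval), p = unname(pval),
             ci_low = unname(est - tcrit * se),
             ci_high = unname(est + tcrit * se), row.names = NULL)
}

#' Predict the outcome z-score for a composition and covariates
#'
#' Evaluates the linear predictor: intercept + ilr(composition) x beta +
#' covariates x gamma. Covariate values must use levels seen at fit time.
#'
#' @param object A `coda_fit`.
#' @param composition Five-part composition (minutes/day) or matrix of them.
#' @param covariates One-row data.frame (or list) of covariate values;
#'   recycled across compositions.
#' @param ... Unused.
#' @return Predicted outcome z-score(s).
#' @export
predict.coda_fit <- function(object, composition, covariates, ...) {
  z <- ilr_transform(composition, object$basis)
  if (is.null(dim(z))) z <- matrix(z, nrow = 1, dimnames = list(NULL, names(z)))
  nd <- as.data.frame(z)
  cov_df <- as.data.frame(covariates)
  for (cc in names(cov_df)) {
    if (cc %in% names(object$xlevels)) {
      lev <- object$xlevels[[cc]]
      if (!all(as.character(cov_df[[cc]]) %in% lev)) {
        stop("unseen level for covariate '", cc, "'")
      }
      cov_df[[cc]] <- factor(as.character(cov_df[[cc]]), levels = lev)
    } else if (cc %in% names(object$centres)) {
      cov_df[[cc]] <- cov_df[[cc]] - object$centres[[cc]]
    }
  }
  m <- max(nrow(nd), nrow(cov_df))
  nd <- cbind(nd[rep_len(seq_len(nrow(nd)), m), , drop = FALSE],
              cov_df[rep_len(seq_len(nrow(cov_df)), m), , drop = FALSE])
  unname(stats::predict(object$lm, newdata = nd))
}

#' Test composition-by-stratum interaction
#'
#' F-test comparing the covariate-adjusted model with common composition
#' slopes against the model with stratum-specific slopes for all four ilr
#' coordinates (numerator df = 4 x (levels - 1)). Per-stratum ilr1
#' coefficients are reported from the nested parameterisation
#' (stratum-specific slopes fitted directly).
#'
#' @param data Participant table.
#' @param outcome Outcome column name.
#' @param spec A [covariate_spec()]; the stratum variable is removed from
#'   the covariate set automatically.
#' @param stratum Stratifying column, "sex" or "diabetes_status".
#' @param basis An [ilr_basis()].
#' @param alpha Flagging level for the interaction, default 0.05.
#' @return List: `F`, `df1`, `df2`, `p`, `significant`, and
#'   `beta1_by_stratum` (named vector of ilr1 slopes per stratum level).
#' @export
test_interaction <- function(data, outcome, spec = covariate_spec(),
                             stratum = "diabetes_status",
                             basis = ilr_basis(), alpha = 0.05) {
  spec2 <- spec
  spec2$categorical <- unique(c(setdiff(spec$categorical, stratum), stratum))
  mf <- build_model_frame(data, outcome, spec2, basis)
  names(mf)[names(mf) == stratum] <- ".stratum"
  mf$.stratum <- droplevels(factor(mf$.stratum))
  g <- mf$.stratum
  if (nlevels(g) < 2) stop("stratum needs at least two levels present")
  ilr_terms <- paste0("ilr", 1:4)
  covs <- setdiff(names(mf), c(".outcome", ilr_terms, ".stratum"))
  rhs_base <- paste(c(ilr_terms, covs, ".stratum"), collapse = " + ")
  f_reduced <- stats::as.formula(paste(".outcome ~", rhs_base))
  f_full <- stats::as.formula(paste(
    ".outcome ~", paste(c(covs, ".stratum"), collapse = " + "),
    "+ .stratum:(", paste(ilr_terms, collapse = " + "), ")"))
  fit_r <- stats::lm(f_reduced, data = mf)
  fit_f <- stats::lm(f_full, data = mf)
  an <- stats::anova(fit_r, fit_f)
  beta <- stats::coef(fit_f)
  b1 <- beta[paste0(".stratum", levels(g), ":ilr1")]
  names(b1) <- levels(g)
  list(F = an$F[2], df1 = an$Df[2], df2 = an$Res.Df[2], p = an$`Pr(>F)`[2],
       significant = an$`Pr(>F)`[2] < alpha, beta1_by_stratum = b1)
}

#' Fit one compositional model per stratum level
#'
#' Independent fits within each level of the stratifying variable; the
#' stratum is dropped from the covariate set. Levels with too few rows are
#' skipped with a warning.
#'
#' @inheritParams test_interaction
#' @return Named list of `coda_fit` objects, one per stratum level.
#' @export
fit_stratified <- function(data, outcome, spec = covariate_spec(),
                           stratum = "diabetes_status", basis = ilr_basis()) {
  spec2 <- spec
  spec2$categorical <- setdiff(spec$categorical, stratum)
  levs <- levels(factor(data[[stratum]]))
  fits <- list()
  for (lv in levs) {
    sub <- data[!is.na(data[[stratum]]) & data[[stratum]] == lv, , drop = FALSE]
    fits[[lv]] <- tryCatch(
      fit_compositional_model(sub, outcome, spec2, basis),
      error = function(e) {
        warning("stratum '", lv, "' skipped: ", conditionMessage(e))
        NULL
      })
  }
  Filter(Negate(is.null), fits)
}
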