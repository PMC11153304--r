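#' Matsuda whole-body insulin sensitivity index (ISI-M)
#'
#' ISI-M = 10000 / sqrt( (FPG * FPI) * (mean OGTT glucose * mean OGTT
#' insulin) ). Higher values indicate higher insulin sensitivity. Absolute
#' levels depend on the concentration units supplied; z-scores downstream
#' are invariant to multiplicative unit changes.
#'
#' @param fpg Fasting plasma glucose.
#' @param fpi Fasting plasma insulin.
#' @param mean_g Mean OGTT glucose.
#' @param mean_i Mean OGTT insulin.
#' @return Numeric ISI-M values.
#' @examples
#' matsuda_index(5, 10, 7, 50)  # 10000/sqrt(17500)
#' @export
matsuda_index <- function(fpg, fpi, mean_g, mean_i) {
  if (any(c(fpg, fpi, mean_g, mean_i) <= 0)) {
    stop("all glucose/insulin inputs must be positive")
  }
  10000 / sqrt((fpg * fpi) * (mean_g * mean_i))
}

#' Average blood pressure
#'
#' Mean of systolic and diastolic pressure, the BP summary entering the
#' clustered cardiometabolic risk score.
#'
#' @param sbp Systolic BP, mmHg.
#' @param dbp Diastolic BP, mmHg.
#' @return (sbp + dbp)/2 in mmHg. Rows with dbp > sbp are kept but flagged
#'   with a warning.
#' @export
mean_bp <- function(sbp, dbp) {
  if (any(dbp <= 0)) stop("blood pressures must be positive")
  if (any(dbp > sbp)) {
    warning("diastolic exceeds systolic for ", sum(dbp > sbp), " row(s); kept")
  }
  (sbp + dbp) / 2
}

# Sample z-score with the n-1 SD; errors on degenerate (constant) samples.
zscore <- function(x, what = "value") {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    stop("degenerate sample: zero SD for ", what)
  }
  (x - mean(x)) / s
}

#' Clustered cardiometabolic risk score (CMR)
#'
#' Five components — waist circumference, ln FPG, ln triacylglycerol,
#' ln HDL-cholesterol (added in inverse) and average BP — are z-scored
#' against the sample (n-1 SD) and averaged:
#' CMR = (z(waist) + z(ln FPG) + z(ln TG) - z(ln HDL) + z(meanBP)) / 5.
#' The sample mean of CMR is zero by construction; higher values indicate
#' higher cardiometabolic risk relative to the sample.
#'
#' @param markers data.frame with columns `waist`, `fpg`, `tg`, `hdl`,
#'   `sbp`, `dbp` (or a precomputed `mean_bp` column).
#' @return Numeric vector of per-participant CMR values.
#' @export
cmr_score <- function(markers) {
  stopifnot(is.data.frame(markers), nrow(markers) >= 2)
  bp <- if ("mean_bp" %in% names(markers)) markers$mean_bp
        else mean_bp(markers$sbp, markers$dbp)
  if (any(markers$fpg <= 0 | markers$tg <= 0 | markers$hdl <= 0 |
          markers$waist <= 0)) {
    stop("waist, FPG, TG and HDL must be positive")
  }
  (zscore(markers$waist, "waist") +
     zscore(log(markers$fpg), "ln FPG") +
     zscore(log(markers$tg), "ln TG") -
     zscore(log(markers$hdl), "ln HDL") +
     zscore(bp, "mean BP")) / 5
}

#' Convert HbA1c percent (NGSP) to mmol/mol (IFCC)
#'
#' Standard affine relation: mmol/mol = (percent - 2.15) * 10.929. The two
#' unit scales are affine rather than proportional, so log-scale z-scores
#' differ between them; all internal computation uses mmol/mol.
#'
#' @param percent HbA1c in NGSP %.
#' @return HbA1c in IFCC mmol/mol.
#' @export
hba1c_percent_to_mmol <- function(percent) (percent - 2.15) * 10.929

#' Build the six outcome z-scores
#'
#' Constructs waist circumference, FPG, 2-h post-load glucose, HbA1c,
#' ISI-M and CMR as analysis-ready z-scores. FPG, 2hPLG and HbA1c are
#' z-scored on the natural-log scale (their residual distributions are
#' right-skewed); waist and ISI-M on the identity scale. CMR is computed
#' with [cmr_score()] and, by default, re-z-scored so all six effect sizes
#' are on a strictly comparable per-SD scale.
#'
#' @param markers data.frame with columns `waist`, `fpg`, `two_h_plg`,
#'   `hba1c` (mmol/mol), `fpi`, `mean_ogtt_glucose`, `mean_ogtt_insulin`,
#'   `tg`, `hdl`, `sbp`, `dbp`.
#' @param rescale_cmr Re-z-score the CMR score (default TRUE).
#' @param log_isim Also log-transform ISI-M before z-scoring (sensitivity
#'   option; default FALSE).
#' @return List with `z` (data.frame of six z-score columns `waist`, `fpg`,
#'   `two_h_plg`, `hba1c`, `isim`, `cmr`), `scaler` (a `zscaler` storing
#'   per-outcome transform, mean and SD for reuse on new data), and
#'   `direction` (named vector: "lower" = lower is better, "higher" for
#'   ISI-M).
#' @export
zscore_outcomes <- function(markers, rescale_cmr = TRUE, log_isim = FALSE) {
  stopifnot(is.data.frame(markers), nrow(markers) >= 2)
  isim <- matsuda_index(markers$fpg, markers$fpi,
                        markers$mean_ogtt_glucose, markers$mean_ogtt_insulin)
  cmr <- cmr_score(markers)
  raw <- list(waist = markers$waist, fpg = markers$fpg,
              two_h_plg = markers$two_h_plg, hba1c = markers$hba1c,
              isim = isim, cmr = cmr)
  transform <- c(waist = "identity", fpg = "log", two_h_plg = "log",
                 hba1c = "log", isim = if (log_isim) "log" else "identity",
                 cmr = if (rescale_cmr) "identity" else "none")
  z <- list(); centre <- numeric(0); scale <- numeric(0)
  for (nm in names(raw)) {
    v <- raw[[nm]]
    if (transform[[nm]] == "log") {
      if (any(v <= 0)) stop("non-positive values for log-scaled outcome ", nm)
      v <- log(v)
    }
    if (transform[[nm]] == "none") {
      z[[nm]] <- v; centre[nm] <- 0; scale[nm] <- 1
    } else {
      centre[nm] <- mean(v)
      scale[nm] <- stats::sd(v)
      if (scale[nm] == 0) stop("degenerate sample: zero SD for outcome ", nm)
      z[[nm]] <- (v - centre[nm]) / scale[nm]
    }
  }
  scaler <- structure(list(transform = transform, centre = centre,
                           scale = scale), class = "zscaler")
  list(z = as.data.frame(z), scaler = scaler,
       direction = c(waist = "lower", fpg = "lower", two_h_plg = "lower",
                     hba1c = "lower", isim = "higher", cmr = "lower"))
}

#' Apply a stored z-scaler to new marker values
#'
#' @param scaler A `zscaler` from [zscore_outcomes()].
#' @param values Numeric vector of raw outcome values.
#' @param outcome Outcome name (one of the six).
#' @return z-scores on the scaler's fitting scale.
#' @export
apply_zscaler <- function(scaler, values, outcome) {
  stopifnot(inherits(scaler, "zscaler"), outcome %in% names(scaler$transform))
  v <- values
  if (scaler$transform[[outcome]] == "log") v <- log(v)
  (v - scaler$centre[[outcome]]) / scaler$scale[[outcome]]
}

#' Classify glycaemic status per WHO 2006 cut-points
#'
#' Labels each participant NGM (normal glucose metabolism), IGM (impaired
#' glucose metabolism: impaired fasting glucose and/or impaired glucose
#' tolerance) or T2D (type 2 diabetes) from fasting plasma glucose (FPG),
#' 2-h post-load glucose (2hPLG, both mmol/l) and glucose-lowering
#' medication use. Bands: IGT is FPG < 7.0 with 7.8 <= 2hPLG < 11.1; IFG is
#' 6.1 <= FPG < 7.0 with 2hPLG < 7.8. T2D is FPG >= 7.0 or 2hPLG >= 11.1
#' (conjunction = "or", the WHO reading) or both thresholds jointly
#' (conjunction = "and"); medication use always classifies as T2D.
#'
#' @param fpg,two_h_plg Positive glucose values, mmol/l.
#' @param med_flag Logical, glucose-lowering medication use.
#' @param conjunction "or" (default) or "and" for the T2D glucose rule.
#' @return Factor with levels NGM, IGM, T2D.
#' @export
classify_glycaemic_status <- function(fpg, two_h_plg, med_flag = FALSE,
                                      conjunction = c("or", "and")) {
  conjunction <- match.arg(conjunction)
  stopifnot(all(fpg > 0), all(two_h_plg > 0))
  n <- max(length(fpg), length(two_h_plg), length(med_flag))
  fpg <- rep_len(fpg, n); two_h_plg <- rep_len(two_h_plg, n)
  med_flag <- rep_len(as.logical(med_flag), n)
  t2d_glucose <- if (conjunction == "or") {
    fpg >= 7.0 | two_h_plg >= 11.1
  } else {
    fpg >= 7.0 & two_h_plg >= 11.1
  }
  igt <- fpg < 7.0 & two_h_plg >= 7.8 & two_h_plg < 11.1
  ifg <- fpg >= 6.1 & fpg < 7.0 & two_h_plg < 7.8
  lab <- ifelse(med_flag | t2d_glucose, "T2D",
                ifelse(igt | ifg, "IGM", "NGM"))
  factor(lab, levels = c("NGM", "IGM", "T2D"))
}
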