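#' Pipeline configuration
#'
#' Collects the analysis constants: the 30-min substitution delta, 95% CI
#' level, top-5% selection fraction escalating to 10%, the 10-min grid
#' step, the waist-adjustment sensitivity flag, the T2D conjunction rule,
#' and the stratifying variable.
#'
#' @param delta Minutes reallocated in substitutions, default 30.
#' @param level Confidence level, default 0.95.
#' @param fraction Optimal-zone selection fraction, default 0.05.
#' @param max_fraction Overlap escalation ceiling, default 0.10.
#' @param step Grid step in minutes (must divide 1440), default 10.
#' @param adjust_waist Waist-circumference sensitivity adjustment.
#' @param t2d_conjunction "or" or "and" for the glucose T2D rule.
#' @param stratum Stratifying variable for interaction/stratified fits.
#' @param seed Integer seed recorded in the manifest.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(delta = 30, level = 0.95, fraction = 0.05,
                            max_fraction = 0.10, step = 10,
                            adjust_waist = FALSE,
                            t2d_conjunction = c("or", "and"),
                            stratum = "diabetes_status", seed = 1L) {
  t2d_conjunction <- match.arg(t2d_conjunction)
  if (delta <= 0) stop("delta must be positive")
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  if (max_fraction < fraction || max_fraction > 1) {
    stop("max_fraction must be in [fraction, 1]")
  }
  if (step <= 0 || DAY_MINUTES %% step != 0) stop("step must divide 1440")
  structure(list(delta = delta, level = level, fraction = fraction,
                 max_fraction = max_fraction, step = step,
                 adjust_waist = adjust_waist,
                 t2d_conjunction = t2d_conjunction, stratum = stratum,
                 seed = as.integer(seed)), class = "pipeline_config")
}

OUTCOMES <- c("waist", "fpg", "two_h_plg", "hba1c", "isim", "cmr")

#' Run the full compositional analysis pipeline
#'
#' End to end over a participant table: WHO 2006 glycaemic classification,
#' outcome z-score construction, compositional regression per outcome,
#' composition-by-stratum interaction tests, all pairwise 30-min
#' isotemporal substitutions from the compositional mean (overall and per
#' stratum), footprint estimation, grid enumeration, per-outcome optimal
#' zones and the cross-outcome overlap, and tetrahedron coordinates at the
#' 8-h sleep slice. Deterministic given the input table and config.
#'
#' @param participants data.frame with the five behaviour columns
#'   (minutes/day, closed to 1440), covariates (age, sex, education,
#'   smoking, diet_score), raw markers (waist, fpg, two_h_plg, hba1c, fpi,
#'   mean_ogtt_glucose, mean_ogtt_insulin, tg, hdl, sbp, dbp) and
#'   `glucose_lowering_med`.
#' @param config A [pipeline_config()].
#' @param footprint_override Optional `grid_footprint` to use instead of
#'   the sample-estimated one (e.g. externally published bounds).
#' @return List of class `pipeline_result`: `data`, `scaler`, `fits`,
#'   `interactions`, `substitutions`, `substitutions_by_stratum`,
#'   `footprint`, `grid`, `zone`, `tetra`, `manifest`.
#' @export
run_pipeline <- function(participants, config = pipeline_config(),
                         footprint_override = NULL) {
  stopifnot(is.data.frame(participants))
  d <- participants
  d$diabetes_status <- classify_glycaemic_status(
    d$fpg, d$two_h_plg, d$glucose_lowering_med,
    conjunction = config$t2d_conjunction)

  zo <- zscore_outcomes(d)
  for (oc in OUTCOMES) d[[paste0("y_", oc)]] <- zo$z[[oc]]

  spec <- covariate_spec(adjust_waist = config$adjust_waist)
  basis <- ilr_basis()
  fits <- list(); interactions <- list()
  for (oc in OUTCOMES) {
    yname <- paste0("y_", oc)
    fits[[oc]] <- fit_compositional_model(d, yname, spec, basis)
    fits[[oc]]$outcome <- oc
    interactions[[oc]] <- test_interaction(d, yname, spec, config$stratum,
                                           basis)
  }

  comp_mat <- as.matrix(d[, BEHAVIOUR_PARTS])
  base <- geometric_mean_composition(comp_mat)
  subs <- do.call(rbind, lapply(fits, substitution_matrix, base = base,
                                delta = config$delta, level = config$level))
  rownames(subs) <- NULL

  subs_strat <- list()
  for (lv in levels(d$diabetes_status)) {
    in_lv <- d$diabetes_status == lv
    if (sum(in_lv) < 30) next
    base_lv <- geometric_mean_composition(comp_mat[in_lv, , drop = FALSE])
    spec_lv <- spec
    spec_lv$categorical <- setdiff(spec$categorical, config$stratum)
    rows_lv <- lapply(OUTCOMES, function(oc) {
      f <- fit_compositional_model(d[in_lv, ], paste0("y_", oc), spec_lv,
                                   basis)
      f$outcome <- oc
      cbind(stratum = lv,
            substitution_matrix(f, base_lv, config$delta, config$level))
    })
    subs_strat[[lv]] <- do.call(rbind, rows_lv)
  }
  subs_strat <- do.call(rbind, subs_strat)
  rownames(subs_strat) <- NULL

  fp <- if (is.null(footprint_override)) {
    compute_footprint(comp_mat, step = config$step)
  } else footprint_override
  grid <- enumerate_grid(fp)
  zone <- overlap_zone(fits, grid, directions = zo$direction,
                       start_fraction = config$fraction,
                       max_fraction = config$max_fraction)
  tetra <- export_tetrahedron_coords(zone, grid)

  manifest <- list(n = nrow(d), n_stratum = table(d$diabetes_status),
                   grid_size = nrow(grid),
                   fraction_used = zone$fraction_used,
                   overlap_empty = zone$empty, config = unclass(config))
  structure(list(data = d, scaler = zo$scaler, direction = zo$direction,
                 fits = fits, interactions = interactions,
                 substitutions = subs, substitutions_by_stratum = subs_strat,
                 footprint = fp, grid = grid, zone = zone, tetra = tetra,
                 manifest = manifest), class = "pipeline_result")
}

#' Write a pipeline result to CSV/YAML files
#'
#' Emits model summary tables, substitution tables, the footprint, zone
#' and overlap reports, and tetrahedron coordinates under `dir`. All files
#' have stable row and column order so reruns are byte-identical.
#'
#' @param result A `pipeline_result`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_report_bundle <- function(result, dir) {
  stopifnot(inherits(result, "pipeline_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  wr <- function(x, name) {
    path <- file.path(dir, name)
    utils::write.csv(x, path, row.names = FALSE)
    files <<- c(files, path)
  }
  coefs <- do.call(rbind, lapply(names(result$fits), function(oc) {
    cbind(outcome = oc, coef_table(result$fits[[oc]]))
  }))
  wr(coefs, "model_coefficients.csv")
  wr(result$substitutions, "substitutions_overall.csv")
  if (!is.null(result$substitutions_by_stratum)) {
    wr(result$substitutions_by_stratum, "substitutions_by_stratum.csv")
  }
  zs <- lapply(names(result$zone$per_outcome), function(oc) {
    s <- result$zone$per_outcome[[oc]]$summary
    data.frame(outcome = oc, behaviour = BEHAVIOUR_PARTS,
               centre_min = unname(s$centre[BEHAVIOUR_PARTS]),
               centre_hmm = format_hmm(s$centre[BEHAVIOUR_PARTS]),
               min = unname(s$range["min", ]), max = unname(s$range["max", ]))
  })
  wr(do.call(rbind, zs), "optimal_zones.csv")
  if (!result$zone$empty) {
    s <- result$zone$overlap$summary
    wr(data.frame(behaviour = BEHAVIOUR_PARTS,
                  centre_min = unname(s$centre[BEHAVIOUR_PARTS]),
                  centre_hmm = format_hmm(s$centre[BEHAVIOUR_PARTS]),
                  min = unname(s$range["min", ]),
                  max = unname(s$range["max", ]),
                  fraction_used = result$zone$fraction_used),
       "overlap_zone.csv")
  }
  wr(result$tetra, "tetrahedron_coords.csv")
  fp_path <- file.path(dir, "footprint.yaml")
  yaml::write_yaml(list(lower = as.list(result$footprint$lower),
                        upper = as.list(result$footprint$upper),
                        step = result$footprint$step), fp_path)
  files <- c(files, fp_path)
  man_path <- file.path(dir, "manifest.yaml")
  man <- result$manifest
  man$n_stratum <- as.list(man$n_stratum)
  yaml::write_yaml(man, man_path)
  files <- c(files, man_path)
  invisible(files)
}
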