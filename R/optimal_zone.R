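#' Empirical footprint of a compositional sample
#'
#' Per-behaviour lower and upper bounds at the 1st and 99th percentiles
#' (linear-interpolation quantiles), rounded to the nearest grid step. The
#' footprint restricts the grid search for optimal compositions to time
#' uses actually observed in the sample.
#'
#' @param comps Matrix or data.frame of compositions (canonical columns,
#'   minutes/day).
#' @param lower_pct,upper_pct Percentile bounds, default 1 and 99.
#' @param step Grid step in minutes, default 10.
#' @return Object of class `grid_footprint`: `lower`, `upper` (named
#'   vectors, multiples of `step`), `step`, `total`.
#' @export
compute_footprint <- function(comps, lower_pct = 1, upper_pct = 99,
                              step = 10) {
  if (is.data.frame(comps)) comps <- as.matrix(comps[, BEHAVIOUR_PARTS])
  if (nrow(comps) < 100) {
    warning("footprint estimated from fewer than 100 participants")
  }
  lo <- apply(comps, 2, stats::quantile, probs = lower_pct / 100, names = FALSE)
  hi <- apply(comps, 2, stats::quantile, probs = upper_pct / 100, names = FALSE)
  footprint(round(lo / step) * step, round(hi / step) * step, step)
}

#' Construct a grid footprint from explicit bounds
#'
#' @param lower,upper Named vectors of per-behaviour bounds in minutes
#'   (multiples of `step`), canonical order.
#' @param step Grid step, minutes.
#' @param total Compositional total, default 1440.
#' @return A `grid_footprint`.
#' @export
footprint <- function(lower, upper, step = 10, total = DAY_MINUTES) {
  lower <- as_composition_vector(lower)
  upper <- as_composition_vector(upper)
  if (any(lower > upper)) stop("lower bound exceeds upper bound")
  if (any(c(lower, upper) %% step != 0)) {
    stop("bounds must be multiples of the grid step")
  }
  if (sum(lower) > total || sum(upper) < total) {
    stop("infeasible footprint: bounds cannot sum to ", total)
  }
  structure(list(lower = lower, upper = upper, step = step, total = total),
            class = "grid_footprint")
}

#' @export
print.grid_footprint <- function(x, ...) {
  cat("grid footprint (step", x$step, "min):\n")
  for (p in BEHAVIOUR_PARTS) {
    cat(sprintf("  %-9s %s-%s\n", p, format_hmm(x$lower[p]),
                format_hmm(x$upper[p])))
  }
  invisible(x)
}

#' Enumerate all grid compositions inside a footprint
#'
#' Every combination of the five behaviours on the step lattice, each part
#' within its inclusive bounds, summing exactly to the 24-h total. The
#' first four behaviours are enumerated and the fifth is determined by the
#' total, then filtered against its bounds. Rows are in deterministic
#' lexicographic order (sitting varying slowest).
#'
#' @param fp A `grid_footprint`.
#' @return Integer matrix, one composition per row, canonical columns.
#' @export
enumerate_grid <- function(fp) {
  stopifnot(inherits(fp, "grid_footprint"))
  s <- fp$step
  seqs <- lapply(BEHAVIOUR_PARTS[1:4], function(p) {
    seq(fp$lower[[p]], fp$upper[[p]], by = s)
  })
  names(seqs) <- BEHAVIOUR_PARTS[1:4]
  g <- as.matrix(expand.grid(rev(seqs), KEEP.OUT.ATTRS = FALSE)[, 4:1])
  sleeping <- fp$total - rowSums(g)
  keep <- sleeping >= fp$lower[["sleeping"]] & sleeping <= fp$upper[["sleeping"]]
  out <- cbind(g[keep, , drop = FALSE], sleeping = sleeping[keep])
  colnames(out) <- BEHAVIOUR_PARTS
  ord <- do.call(order, as.data.frame(out[, 1:4, drop = FALSE]))
  storage.mode(out) <- "integer"
  out[ord, , drop = FALSE]
}

#' Rank grid compositions and select the top fraction
#'
#' Scores every grid composition by the compositional part of the fitted
#' linear predictor, ilr(x) x beta (covariate terms are constant across the
#' grid and cancel in ranking). The best `ceiling(fraction * N)`
#' compositions are kept: the lowest predicted values when `direction` is
#' "lower" (lower outcome = better), the highest when "higher" (ISI-M).
#' Ties are broken by predicted value then lexicographic composition.
#'
#' @param fit A `coda_fit`.
#' @param grid Matrix from [enumerate_grid()].
#' @param fraction Fraction to keep, in (0, 1]; default 0.05.
#' @param direction "lower" or "higher": which end of the outcome is
#'   optimal.
#' @return List: `index` (selected row indices into `grid`, ranked best
#'   first), `selected` (the compositions), `score` (all grid scores),
#'   `fraction`, `direction`.
#' @export
rank_and_select <- function(fit, grid, fraction = 0.05,
                            direction = c("lower", "higher")) {
  direction <- match.arg(direction)
  stopifnot(inherits(fit, "coda_fit"), nrow(grid) >= 1)
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  ilr_terms <- paste0("ilr", seq_len(fit$basis$D - 1))
  score <- drop(ilr_transform(grid, fit$basis) %*%
                  fit$coefficients[ilr_terms])
  k <- ceiling(fraction * nrow(grid))
  key <- if (direction == "lower") score else -score
  ord <- do.call(order, c(list(key), as.data.frame(grid)))
  idx <- ord[seq_len(k)]
  list(index = idx, selected = grid[idx, , drop = FALSE], score = score,
       fraction = fraction, direction = direction)
}

#' Summarise a selected compositional zone
#'
#' Compositional centre (part-wise geometric mean closed to 1440, then
#' each part rounded to the nearest 10 min — so the rounded parts may not
#' sum exactly to 24 h) and per-behaviour min-max ranges over the set.
#'
#' @param selected Matrix of selected compositions.
#' @param round_to Rounding for the centre, minutes; default 10.
#' @return List: `centre` (rounded), `centre_exact`, `range` (2 x 5 matrix
#'   with rows min/max).
#' @export
zone_summary <- function(selected, round_to = 10) {
  if (NROW(selected) == 0) stop("empty selection")
  centre <- geometric_mean_composition(selected)
  rng <- rbind(min = apply(selected, 2, min), max = apply(selected, 2, max))
  list(centre = round(centre / round_to) * round_to,
       centre_exact = centre, range = rng[, BEHAVIOUR_PARTS])
}

#' Cross-outcome overlapping optimal zone
#'
#' Intersects the per-outcome optimal selections over a shared grid. The
#' selection fraction starts at `start_fraction` for every outcome and is
#' escalated in `step_fraction` increments (applied to all outcomes
#' simultaneously) until the intersection is non-empty or `max_fraction`
#' is reached. Records the fraction used; an empty overlap at the maximum
#' fraction is returned as a result (with pairwise overlap counts for
#' diagnosis), not an error.
#'
#' @param fits Named list of `coda_fit` objects (>= 2 outcomes).
#' @param grid Matrix from [enumerate_grid()].
#' @param directions Named character vector ("lower"/"higher") per outcome;
#'   defaults to "lower" except "higher" for `isim`.
#' @param start_fraction,max_fraction,step_fraction Escalation schedule,
#'   default 5% to 10% by 1%.
#' @return Object of class `optimal_zone`: `per_outcome` (selection +
#'   summary at the final fraction), `overlap` (index, selected, summary or
#'   NULL), `fraction_used`, `empty` flag, `pairwise` overlap counts.
#' @export
overlap_zone <- function(fits, grid, directions = NULL,
                         start_fraction = 0.05, max_fraction = 0.10,
                         step_fraction = 0.01) {
  stopifnot(length(fits) >= 2, !is.null(names(fits)))
  if (is.null(directions)) {
    directions <- stats::setNames(
      ifelse(names(fits) == "isim", "higher", "lower"), names(fits))
  }
  fractions <- seq(start_fraction, max_fraction, by = step_fraction)
  sel_at <- function(fr) {
    lapply(names(fits), function(nm) {
      rank_and_select(fits[[nm]], grid, fr, directions[[nm]])
    })
  }
  fraction_used <- NA_real_
  overlap_idx <- integer(0)
  sels <- NULL
  for (fr in fractions) {
    sels <- sel_at(fr)
    overlap_idx <- Reduce(intersect, lapply(sels, `[[`, "index"))
    if (length(overlap_idx) > 0) { fraction_used <- fr; break }
  }
  names(sels) <- names(fits)
  per_outcome <- lapply(sels, function(s) {
    c(s[c("index", "fraction", "direction")],
      list(summary = zone_summary(s$selected)))
  })
  pairwise <- outer(names(fits), names(fits), Vectorize(function(a, b) {
    length(intersect(sels[[a]]$index, sels[[b]]$index))
  }))
  dimnames(pairwise) <- list(names(fits), names(fits))
  empty <- length(overlap_idx) == 0
  structure(list(
    per_outcome = per_outcome,
    overlap = if (!empty) list(
      index = overlap_idx,
      selected = grid[overlap_idx, , drop = FALSE],
      summary = zone_summary(grid[overlap_idx, , drop = FALSE])) else NULL,
    fraction_used = if (empty) max_fraction else fraction_used,
    empty = empty,
    pairwise = pairwise), class = "optimal_zone")
}

#' @export
print.optimal_zone <- function(x, ...) {
  if (x$empty) {
    cat("no mutual overlap up to fraction", x$fraction_used, "\n")
  } else {
    s <- x$overlap$summary
    cat("overlapped optimal zone at top ", 100 * x$fraction_used, "% (",
        length(x$overlap$index), " compositions)\n", sep = "")
    for (p in BEHAVIOUR_PARTS) {
      cat(sprintf("  %-9s %s (%s-%s)\n", p, format_hmm(s$centre[p]),
                  format_hmm(s$range["min", p]), format_hmm(s$range["max", p])))
    }
  }
  invisible(x)
}

# Vertices of a regular tetrahedron (edge length 2*sqrt(2)), centred at 0.
TETRA_VERTICES <- matrix(c(1, 1, 1,
                           1, -1, -1,
                           -1, 1, -1,
                           -1, -1, 1), nrow = 4, byrow = TRUE,
                         dimnames = list(c("sitting", "standing", "lpa",
                                           "mvpa"), c("x", "y", "z")))

#' Export tetrahedron coordinates for optimal-zone visualisation
#'
#' Takes grid compositions at a fixed sleeping time (default 8 h),
#' renormalises the four waking behaviours to shares of waking time, and
#' maps the shares as barycentric weights onto the vertices of a regular
#' tetrahedron. A corner corresponds to 100% of waking time in one
#' behaviour; the centroid to equal 25% shares. Set-membership flags mark
#' which per-outcome zones (and the overlap) each point belongs to.
#'
#' @param zone An `optimal_zone`.
#' @param grid The grid matrix the zone was computed on.
#' @param sleep_fixed Sleeping time slice in minutes, default 480 (8 h). If
#'   no grid point has exactly this sleeping time, the nearest available
#'   level is used with a warning.
#' @return data.frame: the four waking shares, `x`, `y`, `z`, one logical
#'   membership column per outcome, and `overlap`.
#' @export
export_tetrahedron_coords <- function(zone, grid, sleep_fixed = 480) {
  stopifnot(inherits(zone, "optimal_zone"))
  levels_present <- sort(unique(grid[, "sleeping"]))
  if (!sleep_fixed %in% levels_present) {
    nearest <- levels_present[which.min(abs(levels_present - sleep_fixed))]
    warning("no grid point with sleeping = ", sleep_fixed,
            " min; using nearest level ", nearest)
    sleep_fixed <- nearest
  }
  idx <- which(grid[, "sleeping"] == sleep_fixed)
  waking <- grid[idx, c("sitting", "standing", "lpa", "mvpa"), drop = FALSE]
  shares <- waking / rowSums(waking)
  xyz <- shares %*% TETRA_VERTICES
  out <- data.frame(shares, xyz)
  for (nm in names(zone$per_outcome)) {
    out[[nm]] <- idx %in% zone$per_outcome[[nm]]$index
  }
  out$overlap <- if (zone$empty) FALSE else idx %in% zone$overlap$index
  out
}
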