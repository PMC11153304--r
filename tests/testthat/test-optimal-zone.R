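test_that("footprint construction validates bounds and feasibility", {
  expect_error(footprint(lower = c(sitting = 400, standing = 100, lpa = 30,
                                   mvpa = 10, sleeping = 380),
                         upper = c(sitting = 390, standing = 470, lpa = 140,
                                   mvpa = 140, sleeping = 640)),
               "lower bound exceeds")
  expect_error(footprint(lower = c(sitting = 405, standing = 100, lpa = 30,
                                   mvpa = 10, sleeping = 380),
                         upper = c(sitting = 800, standing = 470, lpa = 140,
                                   mvpa = 140, sleeping = 640)),
               "multiples")
  expect_error(footprint(lower = c(sitting = 10, standing = 10, lpa = 10,
                                   mvpa = 10, sleeping = 10),
                         upper = c(sitting = 20, standing = 20, lpa = 20,
                                   mvpa = 20, sleeping = 20)),
               "infeasible")
})

test_that("empirical footprints round percentiles to the grid step", {
  comps <- random_compositions(500, seed = 15)
  fp <- compute_footprint(comps)
  expect_true(all(fp$lower %% 10 == 0 & fp$upper %% 10 == 0))
  # bounds bracket the bulk of the sample
  expect_true(all(fp$lower <= apply(comps, 2, median)))
  expect_true(all(fp$upper >= apply(comps, 2, median)))
  # identical sample: lower = upper = rounded parts
  one <- close_composition(c(543.6, 250, 66.4, 50, 530))
  same <- suppressWarnings(compute_footprint(rbind(one, one, one)))
  expect_equal(same$lower, same$upper)
  expect_equal(unname(same$lower[["sitting"]]), round(543.6 / 10) * 10)
  # nearest-step rounding, not truncation: 343.6 rounds to 340
  expect_equal(round(343.6 / 10) * 10, 340)
})

test_that("grid enumeration matches a nested-loop brute force", {
  for (seed in 1:8) {
    fp <- random_footprint(seed)
    fast <- enumerate_grid(fp)
    slow <- brute_force_grid(fp)
    if (is.null(slow)) {
      expect_equal(nrow(fast), 0)
    } else {
      slow <- slow[do.call(order, as.data.frame(slow[, 1:4, drop = FALSE])), ,
                   drop = FALSE]
      expect_equal(unname(fast) * 1.0, unname(slow) * 1.0)
    }
  }
})

test_that("degenerate footprints enumerate to a single composition", {
  fp <- footprint(lower = c(sitting = 560, standing = 250, lpa = 60,
                            mvpa = 50, sleeping = 520),
                  upper = c(sitting = 560, standing = 250, lpa = 60,
                            mvpa = 50, sleeping = 520))
  g <- enumerate_grid(fp)
  expect_equal(nrow(g), 1)
  expect_equal(unname(g[1, ]), c(560, 250, 60, 50, 520))
})

test_that("every grid row is in-footprint and sums to 24 h", {
  fp <- random_footprint(99)
  g <- enumerate_grid(fp)
  expect_true(all(rowSums(g) == 1440))
  for (p in BEHAVIOUR_PARTS) {
    expect_true(all(g[, p] >= fp$lower[[p]] & g[, p] <= fp$upper[[p]]))
  }
})

# A coda_fit driven by a chosen log-contrast vector (plus tiny noise).
contrast_fit <- function(a, n = 400, seed = 33, noise = 0.01) {
  comps <- random_compositions(n, seed = seed)
  cov <- fake_covariates(n, seed = seed + 1)
  set.seed(seed + 2)
  y <- drop(log(comps) %*% (a - mean(a))) + rnorm(n, 0, noise)
  d <- cbind(as.data.frame(comps), cov, y = y)
  fit_compositional_model(d, "y")
}

test_that("selection keeps ceil(fraction * N) best compositions", {
  fp <- random_footprint(7)
  g <- enumerate_grid(fp)
  fit <- contrast_fit(c(1, 0, 0, -1, 0))
  sel <- rank_and_select(fit, g, fraction = 1)
  expect_equal(nrow(sel$selected), nrow(g))
  sel5 <- rank_and_select(fit, g, fraction = 0.05)
  expect_equal(nrow(sel5$selected), ceiling(0.05 * nrow(g)))
  expect_error(rank_and_select(fit, g, fraction = 0), "fraction")
  expect_error(rank_and_select(fit, g, fraction = 1.5), "fraction")
})

test_that("selection is invariant to basis lead and covariates", {
  fp <- random_footprint(13)
  g <- enumerate_grid(fp)
  comps <- random_compositions(300, seed = 44)
  cov <- fake_covariates(300, seed = 45)
  set.seed(46)
  y <- drop(log(comps) %*% c(0.4, -0.1, -0.1, -0.1, -0.1)) +
    0.03 * cov$age + rnorm(300, 0, 0.2)
  d <- cbind(as.data.frame(comps), cov, y = y)
  ref <- rank_and_select(fit_compositional_model(d, "y"), g, 0.05)
  for (lead in c("mvpa", "sleeping")) {
    alt <- rank_and_select(
      fit_compositional_model(d, "y", basis = ilr_basis(lead)), g, 0.05)
    expect_equal(sort(alt$index), sort(ref$index))
  }
})

test_that("a model rewarding MVPA selects the maximum-MVPA grid point", {
  fp <- random_footprint(21)
  g <- enumerate_grid(fp)
  # outcome decreases with the MVPA-vs-rest balance; direction "lower"
  fit <- contrast_fit(c(0.25, 0.25, 0.25, -1, 0.25))
  sel <- rank_and_select(fit, g, fraction = 0.05, direction = "lower")
  # the true-model optimum (scored by the exact log-contrast) must be kept
  true_score <- drop(log(g) %*% c(0.25, 0.25, 0.25, -1, 0.25))
  expect_true(which.min(true_score) %in% sel$index)
  expect_gte(max(g[sel$index, "mvpa"]), max(g[, "mvpa"]) - 10)
})

test_that("zone centres tighten toward the optimum as fraction shrinks", {
  fp <- random_footprint(27)
  g <- enumerate_grid(fp)
  fit <- contrast_fit(c(1, -0.25, -0.25, -0.25, -0.25))  # sitting adverse
  centres <- sapply(c(0.5, 0.2, 0.05), function(fr) {
    zone_summary(rank_and_select(fit, g, fr)$selected)$centre_exact["sitting"]
  })
  expect_true(all(diff(centres) < 10))  # monotone toward low sitting
})

test_that("zone summaries report the closed rounded geometric centre", {
  sel <- rbind(c(360, 240, 60, 60, 720), c(440, 200, 80, 40, 680))
  colnames(sel) <- BEHAVIOUR_PARTS
  s <- zone_summary(sel)
  manual <- close_composition(sqrt(sel[1, ] * sel[2, ]))
  expect_equal(s$centre_exact, manual)
  expect_equal(s$centre, round(manual / 10) * 10)
  expect_equal(unname(s$range["min", ]), unname(pmin(sel[1, ], sel[2, ])))
  expect_equal(unname(s$range["max", ]), unname(pmax(sel[1, ], sel[2, ])))
  expect_error(zone_summary(sel[0, , drop = FALSE]), "empty")
  # the full grid's ranges equal the attainable footprint bounds
  fp <- published_footprint()
  g <- enumerate_grid(fp)
  s_all <- zone_summary(g)
  expect_equal(unname(s_all$range["min", ]), unname(fp$lower))
  expect_equal(unname(s_all$range["max", ]), unname(fp$upper))
})

test_that("identical outcomes overlap fully at the starting fraction", {
  fp <- random_footprint(35)
  g <- enumerate_grid(fp)
  fit <- contrast_fit(c(0.5, 0, 0, -0.5, 0))
  zone <- overlap_zone(list(a = fit, b = fit), g,
                       directions = c(a = "lower", b = "lower"))
  expect_equal(zone$fraction_used, 0.05)
  expect_false(zone$empty)
  expect_equal(sort(zone$overlap$index),
               sort(rank_and_select(fit, g, 0.05)$index))
})

test_that("opposed outcomes escalate the fraction or report no overlap", {
  fp <- random_footprint(41)
  g <- enumerate_grid(fp)
  up <- contrast_fit(c(1, -0.25, -0.25, -0.25, -0.25), seed = 61)
  down <- contrast_fit(c(-1, 0.25, 0.25, 0.25, 0.25), seed = 62)
  zone <- overlap_zone(list(a = up, b = down), g,
                       directions = c(a = "lower", b = "lower"))
  if (zone$empty) {
    expect_equal(zone$fraction_used, 0.10)
    expect_null(zone$overlap)
    expect_true(all(dim(zone$pairwise) == c(2, 2)))
  } else {
    expect_gt(zone$fraction_used, 0.05)
    # minimality: one step earlier the intersection was empty
    prev <- overlap_zone(list(a = up, b = down), g,
                         directions = c(a = "lower", b = "lower"),
                         max_fraction = zone$fraction_used - 0.01)
    expect_true(prev$empty)
  }
})

test_that("the overlap set is contained in every per-outcome set", {
  fp <- random_footprint(49)
  g <- enumerate_grid(fp)
  fits <- list(a = contrast_fit(c(0.6, -0.2, -0.1, -0.2, -0.1), seed = 71),
               b = contrast_fit(c(0.4, -0.4, 0.1, -0.1, 0), seed = 72),
               c = contrast_fit(c(0.5, 0, -0.3, -0.1, -0.1), seed = 73))
  zone <- overlap_zone(fits, g, directions = c(a = "lower", b = "lower",
                                               c = "lower"))
  expect_true(all(diag(zone$pairwise) ==
                    lengths(lapply(zone$per_outcome, `[[`, "index"))))
  if (!zone$empty) {
    for (nm in names(fits)) {
      expect_true(all(zone$overlap$index %in% zone$per_outcome[[nm]]$index))
    }
  }
})

test_that("tetrahedron coordinates map shares to barycentric points", {
  fp <- published_footprint()
  g <- enumerate_grid(fp)
  fit <- contrast_fit(c(0.5, -0.1, -0.1, -0.2, -0.1), seed = 81)
  zone <- overlap_zone(list(a = fit, b = fit), g,
                       directions = c(a = "lower", b = "lower"))
  tc <- export_tetrahedron_coords(zone, g, sleep_fixed = 480)
  expect_true(nrow(tc) > 0)
  shares <- as.matrix(tc[, c("sitting", "standing", "lpa", "mvpa")])
  expect_true(all(shares >= 0 & shares <= 1))
  expect_equal(unname(rowSums(shares)), rep(1, nrow(tc)), tolerance = 1e-12)
  # all points inside the hull: distance from centroid bounded by vertex
  expect_true(all(rowSums(tc[, c("x", "y", "z")]^2) <= 3 + 1e-9))
  # membership flags are consistent with the zone
  expect_true(all(tc$overlap == (tc$a & tc$b)))
})

test_that("pure and equal waking shares hit vertex and centroid", {
  # direct barycentric check on the vertex matrix used by the export
  shares_vertex <- c(1, 0, 0, 0)
  shares_centre <- rep(0.25, 4)
  v <- timeuse24:::TETRA_VERTICES
  expect_equal(drop(shares_vertex %*% v), v["sitting", ])
  expect_equal(unname(drop(shares_centre %*% v)), c(0, 0, 0))
})

test_that("a missing sleep slice falls back to the nearest level", {
  fp <- footprint(lower = c(sitting = 500, standing = 200, lpa = 50,
                            mvpa = 40, sleeping = 600),
                  upper = c(sitting = 600, standing = 300, lpa = 100,
                            mvpa = 80, sleeping = 650))
  g <- enumerate_grid(fp)
  fit <- contrast_fit(c(0.5, -0.1, -0.1, -0.2, -0.1), seed = 91)
  zone <- overlap_zone(list(a = fit, b = fit), g,
                       directions = c(a = "lower", b = "lower"))
  expect_warning(tc <- export_tetrahedron_coords(zone, g, sleep_fixed = 480),
                 "nearest")
  expect_true(nrow(tc) > 0)
})
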