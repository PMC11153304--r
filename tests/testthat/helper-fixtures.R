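# Shared fixtures: small synthetic cohorts and random compositions.

# A small cohort reused across test files (generated once per run).
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_cohort(
        synthetic_config(n_stratum = c(NGM = 220, IGM = 120, T2D = 160),
                         seed = 42L))
    }
    cache
  }
})

# n random positive compositions closed to 1440, as a matrix.
random_compositions <- function(n, seed = 1) {
  set.seed(seed)
  x <- matrix(exp(rnorm(n * 5, log(c(540, 250, 70, 50, 490)), 0.4)),
              ncol = 5, byrow = TRUE, dimnames = list(NULL, BEHAVIOUR_PARTS))
  t(apply(x, 1, close_composition))
}

# Minimal covariate frame for constructed regression fixtures.
fake_covariates <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    age = rnorm(n, 60, 8),
    diet_score = pmin(pmax(rnorm(n, 84, 15), 0), 140),
    sex = sample(c("M", "F"), n, replace = TRUE),
    education = sample(c("low", "medium", "high"), n, replace = TRUE),
    smoking = sample(c("never", "former", "current"), n, replace = TRUE),
    diabetes_status = sample(c("NGM", "IGM", "T2D"), n, replace = TRUE))
}

# Brute-force nested-loop grid enumerator (independent oracle for
# enumerate_grid): five explicit loops over the lattice.
brute_force_grid <- function(fp) {
  s <- fp$step
  out <- list()
  for (a in seq(fp$lower[["sitting"]], fp$upper[["sitting"]], s))
    for (b in seq(fp$lower[["standing"]], fp$upper[["standing"]], s))
      for (cc in seq(fp$lower[["lpa"]], fp$upper[["lpa"]], s))
        for (d in seq(fp$lower[["mvpa"]], fp$upper[["mvpa"]], s))
          for (e in seq(fp$lower[["sleeping"]], fp$upper[["sleeping"]], s))
            if (a + b + cc + d + e == fp$total)
              out[[length(out) + 1]] <- c(a, b, cc, d, e)
  m <- do.call(rbind, out)
  if (!is.null(m)) colnames(m) <- BEHAVIOUR_PARTS
  m
}

# Random feasible small footprints for enumeration property tests.
random_footprint <- function(seed) {
  set.seed(seed)
  repeat {
    lo <- c(sitting = sample(seq(300, 500, 10), 1),
            standing = sample(seq(100, 250, 10), 1),
            lpa = sample(seq(20, 80, 10), 1),
            mvpa = sample(seq(10, 60, 10), 1),
            sleeping = sample(seq(350, 500, 10), 1))
    hi <- lo + 10 * sample(2:6, 5, replace = TRUE)
    if (sum(lo) <= 1440 && sum(hi) >= 1440) {
      return(footprint(lower = lo, upper = hi))
    }
  }
}

# The published 1st-99th percentile footprint (h:mm bounds in minutes).
published_footprint <- function() {
  footprint(lower = c(sitting = 340, standing = 100, lpa = 30, mvpa = 10,
                      sleeping = 380),
            upper = c(sitting = 800, standing = 470, lpa = 140, mvpa = 140,
                      sleeping = 640))
}
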