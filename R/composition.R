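#' Canonical behaviour part names
#'
#' The five daily behaviours in canonical order: sitting, standing, light
#' physical activity (LPA), moderate-to-vigorous physical activity (MVPA),
#' sleeping. This order defines the default pivot basis, in which the first
#' isometric log-ratio coordinate contrasts sitting against the geometric
#' mean of the remaining four behaviours.
#'
#' @format Character vector of length 5.
#' @export
BEHAVIOUR_PARTS <- c("sitting", "standing", "lpa", "mvpa", "sleeping")

#' Minutes in a day: the compositional total
#' @export
DAY_MINUTES <- 1440

#' Close a vector of durations to a fixed total
#'
#' Rescales strictly positive parts proportionally so they sum to `total`
#' (the closure operation of compositional data analysis). Durations of zero
#' are a hard error: log-ratio methods are undefined on zeros and no
#' imputation is performed.
#'
#' @param parts Named or unnamed numeric vector of five positive durations
#'   (minutes/day). If unnamed, canonical order is assumed.
#' @param total Target total, default 1440 minutes.
#' @return Named numeric vector in canonical order summing to `total`.
#' @examples
#' close_composition(c(480, 240, 120, 120, 240))
#' @export
close_composition <- function(parts, total = DAY_MINUTES) {
  parts <- as_composition_vector(parts)
  if (total <= 0) stop("total must be positive")
  bad <- parts <= 0 | !is.finite(parts)
  if (any(bad)) {
    stop("zero or non-positive part(s): ", paste(names(parts)[bad], collapse = ", "),
         " (log-ratio analysis is undefined on zeros)")
  }
  parts * (total / sum(parts))
}

# Coerce to a named 5-vector in canonical order; tolerant of name order.
as_composition_vector <- function(parts) {
  parts <- unlist(parts)
  if (length(parts) != length(BEHAVIOUR_PARTS)) {
    stop("a composition has exactly ", length(BEHAVIOUR_PARTS), " parts")
  }
  if (is.null(names(parts)) || !all(nzchar(names(parts)))) {
    names(parts) <- BEHAVIOUR_PARTS
  } else {
    if (!setequal(names(parts), BEHAVIOUR_PARTS)) {
      stop("part names must be: ", paste(BEHAVIOUR_PARTS, collapse = ", "))
    }
    parts <- parts[BEHAVIOUR_PARTS]
  }
  stats::setNames(as.numeric(parts), BEHAVIOUR_PARTS)
}

#' Construct a pivot-coordinate ilr basis
#'
#' Builds the sequential pivot basis for a five-part composition. Coordinate
#' j contrasts the j-th part in `part_order` against the geometric mean of
#' all later parts, scaled by sqrt((D-j)/(D-j+1)); for D = 5 the first
#' coefficient is sqrt(4/5).
#'
#' @param lead_part Behaviour placed first (its balance against all others
#'   becomes coordinate 1). Default "sitting".
#' @param part_order Full explicit order (overrides `lead_part`).
#' @return Object of class `ilr_basis` with elements `part_order`, `D`,
#'   `coefficients`, and the D x (D-1) contrast matrix `V` satisfying
#'   z = t(V) %*% log(x).
#' @export
ilr_basis <- function(lead_part = "sitting", part_order = NULL) {
  if (is.null(part_order)) {
    if (!lead_part %in% BEHAVIOUR_PARTS) {
      stop("unknown part name: '", lead_part, "'")
    }
    part_order <- c(lead_part, setdiff(BEHAVIOUR_PARTS, lead_part))
  }
  if (!identical(sort(part_order), sort(BEHAVIOUR_PARTS))) {
    stop("part_order must be a permutation of the five canonical names")
  }
  D <- length(part_order)
  j <- seq_len(D - 1)
  coef <- sqrt((D - j) / (D - j + 1))
  V <- matrix(0, nrow = D, ncol = D - 1,
              dimnames = list(part_order, paste0("ilr", j)))
  for (k in j) {
    V[k, k] <- coef[k]
    V[(k + 1):D, k] <- -coef[k] / (D - k)
  }
  structure(list(part_order = part_order, D = D, coefficients = coef, V = V),
            class = "ilr_basis")
}

#' @export
print.ilr_basis <- function(x, ...) {
  cat("ilr pivot basis:", paste(x$part_order, collapse = " > "), "\n")
  invisible(x)
}

#' Reorder a pivot basis to lead with a different part
#'
#' Implements the permutation principle: the lead part moves to the front
#' and the remaining parts keep their relative order. Fitted values and
#' predictions of a compositional regression are invariant to this choice;
#' only the interpretation of coordinate 1 changes.
#'
#' @param basis An `ilr_basis`.
#' @param lead_part One of the five behaviour names.
#' @return A new `ilr_basis`.
#' @export
reorder_basis <- function(basis, lead_part) {
  stopifnot(inherits(basis, "ilr_basis"))
  if (!lead_part %in% basis$part_order) {
    stop("unknown part name: '", lead_part, "'")
  }
  ilr_basis(part_order = c(lead_part, setdiff(basis$part_order, lead_part)))
}

#' Isometric log-ratio (pivot coordinate) transform
#'
#' Maps five-part compositions to four unconstrained real coordinates.
#' Coordinate j equals sqrt((D-j)/(D-j+1)) * ln(x_j / geometric mean of the
#' parts after position j in the basis order). The transform depends only on
#' ratios, so it is invariant to closure.
#'
#' @param comp Numeric vector of 5 positive parts, or a matrix/data.frame
#'   with one composition per row (columns named by behaviour).
#' @param basis An `ilr_basis` (default: canonical, sitting first).
#' @return Numeric vector of length 4, or an n x 4 matrix, columns
#'   `ilr1`..`ilr4`.
#' @examples
#' ilr_transform(c(480, 300, 90, 60, 510))
#' @export
ilr_transform <- function(comp, basis = ilr_basis()) {
  stopifnot(inherits(basis, "ilr_basis"))
  if (is.data.frame(comp)) comp <- as.matrix(comp[, BEHAVIOUR_PARTS])
  if (is.matrix(comp)) {
    if (is.null(colnames(comp))) colnames(comp) <- BEHAVIOUR_PARTS
    if (any(comp <= 0)) stop("compositions must be strictly positive")
    return(log(comp[, basis$part_order, drop = FALSE]) %*% basis$V)
  }
  x <- as_composition_vector(comp)
  if (any(x <= 0)) stop("compositions must be strictly positive")
  drop(log(x[basis$part_order]) %*% basis$V)
}

#' Inverse ilr transform
#'
#' Reconstructs the composition whose pivot coordinates are `z`, closed to
#' `total` minutes.
#'
#' @param z Numeric vector of 4 coordinates or an n x 4 matrix.
#' @param basis The `ilr_basis` used for the forward transform.
#' @param total Closure total in minutes, default 1440.
#' @return Named composition vector (or matrix) in canonical part order.
#' @export
ilr_inverse <- function(z, basis = ilr_basis(), total = DAY_MINUTES) {
  stopifnot(inherits(basis, "ilr_basis"))
  if (is.matrix(z)) {
    if (any(!is.finite(z))) stop("non-finite ilr coordinates")
    lx <- z %*% t(basis$V)
    x <- exp(lx)
    x <- x / rowSums(x) * total
    colnames(x) <- basis$part_order
    return(x[, BEHAVIOUR_PARTS, drop = FALSE])
  }
  if (length(z) != basis$D - 1 || any(!is.finite(z))) {
    stop("ilr coordinates must be ", basis$D - 1, " finite numbers")
  }
  x <- exp(drop(basis$V %*% z))
  names(x) <- basis$part_order
  close_composition(x[BEHAVIOUR_PARTS], total)
}

#' Compositional (geometric) mean of a sample
#'
#' Part-wise geometric mean, closed to `total`. This is the reference
#' composition from which isotemporal substitutions are evaluated and the
#' "compositional centre" used to summarise optimal zones.
#'
#' @param comps Matrix or data.frame of compositions (one per row, canonical
#'   columns), or a list of 5-vectors.
#' @param total Closure total, default 1440 minutes.
#' @return Named composition vector summing to `total`.
#' @export
geometric_mean_composition <- function(comps, total = DAY_MINUTES) {
  if (is.list(comps) && !is.data.frame(comps)) {
    comps <- do.call(rbind, lapply(comps, as_composition_vector))
  }
  if (is.data.frame(comps)) comps <- as.matrix(comps[, BEHAVIOUR_PARTS])
  if (is.null(dim(comps))) comps <- matrix(comps, nrow = 1,
                                           dimnames = list(NULL, BEHAVIOUR_PARTS))
  if (nrow(comps) == 0) stop("empty sample of compositions")
  if (is.null(colnames(comps))) colnames(comps) <- BEHAVIOUR_PARTS
  if (any(comps <= 0)) stop("compositions must be strictly positive")
  gm <- exp(colMeans(log(comps[, BEHAVIOUR_PARTS, drop = FALSE])))
  close_composition(gm, total)
}

#' Format minutes as h:mm
#'
#' Report-friendly rendering of durations, e.g. 400 -> "6:40". Minutes are
#' rounded to the nearest integer first.
#'
#' @param minutes Numeric vector of minutes.
#' @return Character vector like "6:40".
#' @export
format_hmm <- function(minutes) {
  m <- round(minutes)
  sprintf("%d:%02d", m %/% 60, m %% 60)
}

#' Parse "h:mm" strings to minutes
#' @param hmm Character vector like "6:40".
#' @return Numeric minutes.
#' @export
parse_hmm <- function(hmm) {
  parts <- strsplit(hmm, ":", fixed = TRUE)
  vapply(parts, function(p) as.numeric(p[1]) * 60 + as.numeric(p[2]), numeric(1))
}
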