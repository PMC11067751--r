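# Coordinate-precision estimation (Cruickshank diffraction precision
# index) and propagation into bond-distance uncertainties and
# "equal within error" verdicts.

#' Refinement statistics for one crystal structure
#'
#' @param n_atoms Number of atoms in the model.
#' @param n_reflections Number of unique reflections.
#' @param completeness Data completeness as a fraction in (0, 1].
#' @param r_free Free R factor (fraction).
#' @param d_min High-resolution limit in Angstrom.
#' @param r_factor Working R factor (optional; needed for the R-based DPI
#'   variant).
#' @param n_params Number of refined parameters (optional; needed for the
#'   R-based DPI variant).
#' @param avg_b Mean atomic B factor in Angstrom^2 (optional; needed for
#'   per-atom B scaling of uncertainties).
#' @return An object of class `refinement_stats`.
#' @export
refinement_stats <- function(n_atoms, n_reflections, completeness,
                             r_free, d_min, r_factor = NA_real_,
                             n_params = NA_real_, avg_b = NA_real_) {
  if (!is.finite(n_atoms) || n_atoms <= 0) stop("n_atoms must be positive")
  if (!is.finite(n_reflections) || n_reflections <= n_atoms)
    stop("n_reflections must exceed n_atoms")
  if (!is.finite(completeness) || completeness <= 0 || completeness > 1)
    stop("completeness must be in (0, 1]")
  if (!is.finite(r_free) || r_free <= 0 || r_free >= 1)
    stop("r_free must be in (0, 1)")
  if (!is.finite(d_min) || d_min <= 0) stop("d_min must be positive")
  structure(list(n_atoms = n_atoms, n_reflections = n_reflections,
                 completeness = completeness, r_free = r_free,
                 d_min = d_min, r_factor = r_factor, n_params = n_params,
                 avg_b = avg_b),
            class = "refinement_stats")
}

#' Cruickshank diffraction precision index
#'
#' Closed-form estimate of the average atomic coordinate uncertainty:
#' \deqn{DPI = \sqrt{N_{atoms}/n_{refl}} \; C^{-1/3} \; R_{free} \; d_{min}}
#' for the `rfree` variant, or with \eqn{n_{refl} - n_{params}} in the
#' denominator and the working R factor for the `r` variant.
#'
#' @param stats A [refinement_stats()].
#' @param variant `"rfree"` (default, the usual server convention) or `"r"`.
#' @return DPI in Angstrom.
#' @examples
#' s <- refinement_stats(1000, 40000, 1.0, r_free = 0.20, d_min = 1.2)
#' cruickshank_dpi(s)  # sqrt(0.025) * 0.20 * 1.2
#' @export
cruickshank_dpi <- function(stats, variant = c("rfree", "r")) {
  variant <- match.arg(variant)
  if (variant == "rfree") {
    sqrt(stats$n_atoms / stats$n_reflections) *
      stats$completeness^(-1 / 3) * stats$r_free * stats$d_min
  } else {
    if (!is.finite(stats$n_params))
      stop("n_params is required for the R-based DPI variant")
    if (stats$n_reflections <= stats$n_params)
      stop("n_reflections must exceed n_params for the R-based DPI variant")
    if (!is.finite(stats$r_factor)) stop("r_factor is required")
    sqrt(stats$n_atoms / (stats$n_reflections - stats$n_params)) *
      stats$completeness^(-1 / 3) * stats$r_factor * stats$d_min
  }
}

#' Precision model attached to a structure
#'
#' @param dpi Coordinate uncertainty in Angstrom, e.g. from
#'   [cruickshank_dpi()].
#' @param variant Which DPI variant produced it.
#' @param per_atom_scaling Scale per-atom uncertainties by
#'   `sqrt(B / avg_b)` (default off: it is not established that the usual
#'   server convention applies such scaling).
#' @return An object of class `precision_model`.
#' @export
precision_model <- function(dpi, variant = "rfree", per_atom_scaling = FALSE) {
  if (!is.finite(dpi) || dpi <= 0) stop("dpi must be positive")
  structure(list(dpi = dpi, variant = variant,
                 per_atom_scaling = per_atom_scaling),
            class = "precision_model")
}

#' Standard uncertainty of one atomic position
#'
#' @param model A [precision_model()].
#' @param b_factor Atom B factor (Angstrom^2), used only with per-atom
#'   scaling.
#' @param avg_b Structure-average B factor, required with per-atom scaling.
#' @return Positional su in Angstrom.
#' @export
atom_su <- function(model, b_factor = NA_real_, avg_b = NA_real_) {
  if (!model$per_atom_scaling) return(model$dpi)
  if (!is.finite(avg_b) || avg_b <= 0)
    stop("avg_b must be positive for per-atom B scaling")
  model$dpi * sqrt(b_factor / avg_b)
}

#' Standard uncertainty of a distance between two positions
#'
#' Quadrature combination of the two positional uncertainties.
#'
#' @param su_a,su_b Positional uncertainties in Angstrom (>= 0).
#' @return `sqrt(su_a^2 + su_b^2)`.
#' @export
distance_su <- function(su_a, su_b) {
  if (any(c(su_a, su_b) < 0)) stop("uncertainties must be >= 0")
  sqrt(su_a^2 + su_b^2)
}

#' Are two distances equal within error?
#'
#' Compares an observed distance with a reference at `k` combined standard
#' uncertainties and reports the z-score alongside the verdict, so looser
#' or stricter notions of "within error" stay auditable.
#'
#' @param d_obs,su_obs Observed distance and its su (Angstrom).
#' @param d_ref,su_ref Reference distance and its su.
#' @param k Tolerance multiplier (default 2).
#' @return List with `consistent` (logical), `z` (|difference| / combined
#'   su; `Inf` when both sus are zero and the values differ) and `delta`.
#' @export
within_error <- function(d_obs, su_obs, d_ref, su_ref, k = 2) {
  if (su_obs < 0 || su_ref < 0) stop("uncertainties must be >= 0")
  delta <- abs(d_obs - d_ref)
  s <- distance_su(su_obs, su_ref)
  z <- if (s == 0) {
    if (delta == 0) 0 else Inf
  } else delta / s
  list(consistent = is.finite(z) && z <= k, z = z, delta = delta)
}

#' Round an uncertainty to one significant digit
#'
#' Crystallographic bracket convention: the su is quoted to one
#' significant digit and the value to the matching decimal place.
#'
#' @param su Standard uncertainty.
#' @return su rounded to 1 significant digit.
#' @export
round_su <- function(su) signif(su, 1)

#' Format a value with its su in bracket notation
#'
#' @param value The value (e.g. a distance in Angstrom).
#' @param su Its standard uncertainty.
#' @return Character such as `"2.28 (4)"`, meaning 2.28 +/- 0.04 on the
#'   last quoted digit.
#' @examples
#' format_bracket(2.28, 0.0368)  # "2.28 (4)"
#' @export
format_bracket <- function(value, su) {
  su1 <- round_su(su)
  if (!is.finite(su1) || su1 <= 0) return(format(value))
  if (su1 >= 1) {
    return(sprintf("%.0f (%.0f)", round(value), su1))
  }
  digits <- -floor(log10(su1))
  bracket <- round(su1 * 10^digits)
  sprintf("%.*f (%d)", digits, round(value, digits), bracket)
}
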