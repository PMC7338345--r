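# Upstream bioprocess measurement calculators: titration-based acidity
# index and FFA conversion, p-NPB hydrolytic activity, immobilization
# parameters, and first-order thermal-deactivation half-life.

#' Titration record for an acidity-index determination
#'
#' @param sample_mass Mass of the titrated aliquot, g (> 0).
#' @param titrant_molarity NaOH molarity, mol/L (> 0).
#' @param titrant_volume NaOH volume spent, mL (>= 0).
#' @param correction_factor Standardization correction factor (> 0).
#' @param molar_mass Titrant molar mass, g/mol (default 40.00 for NaOH;
#'   override for other titrants).
#' @return An object of class `titration_record`.
#' @export
titration_record <- function(sample_mass, titrant_molarity, titrant_volume,
                             correction_factor = 1, molar_mass = 40.00) {
  if (!is.numeric(sample_mass) || sample_mass <= 0)
    stop("invalid mass: sample_mass must be > 0 g", call. = FALSE)
  if (titrant_molarity <= 0 || correction_factor <= 0 || molar_mass <= 0)
    stop("titrant molarity, correction factor and molar mass must be > 0",
         call. = FALSE)
  if (titrant_volume < 0)
    stop("titrant_volume must be >= 0 mL", call. = FALSE)
  structure(list(sample_mass = sample_mass,
                 titrant_molarity = titrant_molarity,
                 titrant_volume = titrant_volume,
                 correction_factor = correction_factor,
                 molar_mass = molar_mass),
            class = "titration_record")
}

#' Acidity index from a titration record
#'
#' Milligrams of NaOH needed to neutralize the free acid in 1 g of sample:
#' \deqn{AI = \frac{MM_{NaOH} \cdot M_{NaOH} \cdot f \cdot V_{NaOH}}{m}}
#' with the volume in mL, so the result is in mg NaOH per g sample.
#'
#' @param rec A [titration_record()].
#' @return Acidity index, mg/g.
#' @examples
#' acidity_index(titration_record(1, 0.1, 1))  # 4 mg/g
#' @export
acidity_index <- function(rec) {
  stopifnot(inherits(rec, "titration_record"))
  rec$molar_mass * rec$titrant_molarity * rec$correction_factor *
    rec$titrant_volume / rec$sample_mass
}

#' FFA-to-ester conversion from blank and sample acidity indices
#'
#' \deqn{Conversion = 100 \cdot \frac{AI_B - AI_S}{AI_B}}
#' where `ai_blank` is the acidity of the reaction without biocatalyst and
#' `ai_sample` with it. The result is not clamped: values outside
#' \[0, 100\] (acid formation, titration error) are returned as-is with a
#' warning so measurement problems stay visible.
#'
#' @param ai_blank Acidity index of the blank, mg/g (> 0).
#' @param ai_sample Acidity index of the biocatalyst sample, mg/g.
#' @return Conversion, percent.
#' @export
ffa_conversion <- function(ai_blank, ai_sample) {
  if (!is.numeric(ai_blank) || any(ai_blank <= 0))
    stop("invalid blank: ai_blank must be > 0", call. = FALSE)
  conv <- 100 * (ai_blank - ai_sample) / ai_blank
  if (any(conv < 0))
    warning("negative conversion (sample more acidic than blank): ",
            "check the titration", call. = FALSE)
  conv
}

#' Spectrophotometric p-NPB activity assay record
#'
#' Defaults follow the standard p-nitrophenyl butyrate assay: 50 uL enzyme
#' + 50 uL substrate + 2.5 mL buffer read at 348 nm, where the p-nitrophenol
#' extinction coefficient is 5150 /M/cm.
#'
#' @param absorbance_rate Absorbance increase per minute at 348 nm.
#' @param reaction_volume Total assay volume, mL (default 2.6).
#' @param enzyme_volume Enzyme aliquot volume, mL (default 0.05).
#' @param dilution Enzyme predilution factor (default 1).
#' @param extinction_coefficient Molar extinction coefficient, /M/cm
#'   (default 5150).
#' @param path_length Cuvette path length, cm (default 1).
#' @return An object of class `activity_assay`.
#' @export
activity_assay <- function(absorbance_rate, reaction_volume = 2.6,
                           enzyme_volume = 0.05, dilution = 1,
                           extinction_coefficient = 5150, path_length = 1) {
  if (extinction_coefficient <= 0 || path_length <= 0)
    stop("invalid assay: extinction coefficient and path length must be > 0",
         call. = FALSE)
  if (reaction_volume <= 0 || enzyme_volume <= 0 || dilution <= 0)
    stop("invalid assay: volumes and dilution must be > 0", call. = FALSE)
  structure(list(absorbance_rate = absorbance_rate,
                 reaction_volume = reaction_volume,
                 enzyme_volume = enzyme_volume,
                 dilution = dilution,
                 extinction_coefficient = extinction_coefficient,
                 path_length = path_length),
            class = "activity_assay")
}

#' Hydrolytic activity from a p-NPB assay
#'
#' Beer-Lambert converts the absorbance slope to a product formation rate,
#' `dA/dt / (eps * l)` in mol/L/min; scaling by the assay volume and the
#' enzyme aliquot gives units of activity (1 U = 1 umol substrate
#' hydrolyzed per minute) per mL of enzyme preparation:
#' \deqn{U/mL = \frac{\Delta A/\Delta t}{\varepsilon \ell} \cdot 1000 \cdot
#'   \frac{V_{rxn} \cdot dilution}{V_{enz}}}
#'
#' @param assay An [activity_assay()].
#' @param support_conc Optional biocatalyst suspension concentration,
#'   g support per mL; when given the specific activity in U/g is also
#'   returned.
#' @return U per mL of enzyme preparation, or a named vector
#'   `c(u_per_ml, u_per_g)` when `support_conc` is given.
#' @examples
#' hydrolytic_activity(activity_assay(0.515))  # 5.2 U/mL
#' @export
hydrolytic_activity <- function(assay, support_conc = NULL) {
  stopifnot(inherits(assay, "activity_assay"))
  molar_rate <- assay$absorbance_rate /
    (assay$extinction_coefficient * assay$path_length)   # mol/L/min
  u_per_ml <- molar_rate * 1000 * assay$reaction_volume *
    assay$dilution / assay$enzyme_volume                 # umol/min per mL
  if (is.null(support_conc)) return(u_per_ml)
  if (support_conc <= 0)
    stop("invalid assay: support_conc must be > 0 g/mL", call. = FALSE)
  c(u_per_ml = u_per_ml, u_per_g = u_per_ml / support_conc)
}

#' Immobilization yield from supernatant activities
#'
#' Percent of offered enzyme activity removed from the supernatant, hence
#' retained on the support:
#' \deqn{IY = 100 \cdot \frac{A_i - A_f}{A_i}}
#' A final activity above the initial one (apparent negative retention)
#' returns the negative value with a warning instead of an error.
#'
#' @param a_initial Supernatant activity before immobilization, U/mL (> 0).
#' @param a_final Supernatant activity after immobilization, U/mL.
#' @return Immobilization yield, percent.
#' @export
immobilization_yield <- function(a_initial, a_final) {
  if (!is.numeric(a_initial) || any(a_initial <= 0))
    stop("initial activity must be > 0", call. = FALSE)
  if (any(a_final > a_initial))
    warning("final supernatant activity exceeds initial: ",
            "negative retention flagged", call. = FALSE)
  100 * (a_initial - a_final) / a_initial
}

#' Theoretical activity of the immobilized biocatalyst
#'
#' Activity expected on the support from the offered enzyme load and the
#' immobilization yield: `At_T = offered * IY / 100` (U per g support).
#'
#' @param offered_activity Enzyme activity offered per g of support, U/g.
#' @param iy Immobilization yield, percent.
#' @return Theoretical activity, U/g.
#' @export
theoretical_activity <- function(offered_activity, iy) {
  if (any(offered_activity < 0) || any(iy < 0))
    stop("offered activity and yield must be non-negative", call. = FALSE)
  offered_activity * iy / 100
}

#' Recovered (expressed) activity of the immobilized biocatalyst
#'
#' Measured biocatalyst activity as a percentage of the theoretical
#' activity: `At_R = 100 * At_B / At_T`.
#'
#' @param at_b Measured biocatalyst activity, U/g.
#' @param at_t Theoretical activity, U/g (> 0).
#' @return Recovered activity, percent.
#' @examples
#' recovered_activity(341.3, 458.0)  # 74.5%
#' @export
recovered_activity <- function(at_b, at_t) {
  if (!is.numeric(at_t) || any(at_t <= 0))
    stop("invalid theoretical activity: at_t must be > 0", call. = FALSE)
  100 * at_b / at_t
}

#' First-order thermal-deactivation half-life
#'
#' Fits single-exponential decay `A(t) = A0 * exp(-k t)` by ordinary least
#' squares on the log scale (`lm(log(activity) ~ time)`) and reports
#' `t_1/2 = ln(2) / k` together with the rate constant and the R-squared of
#' the log-linear fit as a lack-of-fit diagnostic. Two points determine the
#' fit exactly; for the series (0, 100), (t*, 50) the half-life is t* by
#' definition.
#'
#' @param times Incubation times, minutes; strictly increasing, >= 2 points.
#' @param activity Residual activity, percent of initial; all > 0.
#' @return An object of class `decay_fit`: list with `t_half` (min), `k`
#'   (/min), `a0` (fitted intercept, %), `r_squared` and `n`.
#' @examples
#' half_life(c(0, 30, 60, 90), 100 * exp(-0.01 * c(0, 30, 60, 90)))
#' @export
half_life <- function(times, activity) {
  if (length(times) != length(activity) || length(times) < 2L)
    stop("need >= 2 (time, activity) points with equal lengths",
         call. = FALSE)
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (any(activity <= 0))
    stop("activities must be > 0 (log-scale fit)", call. = FALSE)
  fit <- stats::lm(log(activity) ~ times)
  k <- -unname(stats::coef(fit)[2L])
  if (!is.finite(k) || k <= 0)
    stop("no decay: fitted rate constant is not positive", call. = FALSE)
  # direct R^2: summary.lm warns on numerically perfect (noiseless) fits
  tss <- sum((log(activity) - mean(log(activity)))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else 1
  structure(list(t_half = log(2) / k,
                 k = k,
                 a0 = exp(unname(stats::coef(fit)[1L])),
                 r_squared = r2,
                 n = length(times)),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    "First-order deactivation: t1/2 = %.2f min (k = %.4g /min, A0 = %.1f%%, R^2 = %.4f, n = %d)\n",
    x$t_half, x$k, x$a0, x$r_squared, x$n))
  invisible(x)
}

#' Thermal stabilization factor
#'
#' Ratio of the immobilized enzyme's half-life to the free enzyme's under
#' the same incubation conditions.
#'
#' @param t_half_immobilized Half-life of the immobilized biocatalyst, min.
#' @param t_half_free Half-life of the free enzyme, min.
#' @return Dimensionless ratio.
#' @export
stabilization_factor <- function(t_half_immobilized, t_half_free) {
  if (any(t_half_immobilized <= 0) || any(t_half_free <= 0))
    stop("half-lives must be > 0", call. = FALSE)
  t_half_immobilized / t_half_free
}
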