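#' T7E1 mismatch-cleavage indel estimate
#'
#' Converts band densitometry from a T7 endonuclease 1 assay into the
#' percent of alleles carrying an indel, via
#' `100 * (1 - sqrt(1 - f))` with `f` the cleaved fraction of total band
#' intensity. The square root reflects the random re-annealing of cleaved
#' heteroduplexes.
#'
#' @param cleaved Intensities of the cleaved band(s) (numeric vector,
#'   summed).
#' @param uncleaved Intensity of the uncleaved band.
#' @return Percent indels, in `[0, 100]`.
#' @export
t7e1_indel_percent <- function(cleaved, uncleaved) {
  if (any(cleaved < 0) || uncleaved < 0) abort("band intensities must be >= 0")
  total <- sum(cleaved) + uncleaved
  if (total <= 0) abort("total band intensity must be > 0")
  f <- sum(cleaved) / total
  100 * (1 - sqrt(1 - f))
}

#' Detection factor of a template from a balanced mixture experiment
#'
#' Ratio of the observed count of a template's clones to the count expected
#' from the known mixing fraction: `observed / (expected_fraction * total)`.
#' A factor below 1 indicates under-detection (longer amplicons clone less
#' efficiently). For the canonical 1:1 Success:mutant experiment, 16
#' observed of 53 clones gives 16/26.5 = 0.60; the Success:deletion
#' comparison gives 16/30.5 = 0.52.
#'
#' @param observed_success Observed clones of the template of interest.
#' @param total_clones Total clones typed.
#' @param expected_fraction True mixing fraction of the template (default
#'   0.5, a 1:1 mixture).
#' @return The detection factor.
#' @export
detection_factor <- function(observed_success, total_clones,
                             expected_fraction = 0.5) {
  if (total_clones <= 0) abort("total_clones must be > 0")
  if (expected_fraction <= 0 || expected_fraction > 1) {
    abort("expected_fraction must be in (0, 1]")
  }
  observed_success / (expected_fraction * total_clones)
}

#' Detection model (observed vs true Success percent)
#'
#' Manual constructor, for supplying externally fitted slope/intercept
#' (e.g. published calibration values) to [correct_observed()] and
#' [efficiency_report()]. Use [fit_detection_model()] to fit one from a
#' mixture series.
#'
#' @param slope,intercept Regression coefficients, percent scale.
#' @param r_squared,n_points Optional fit diagnostics.
#' @return An object of class `detection_model`.
#' @export
detection_model <- function(slope, intercept, r_squared = NA_real_,
                            n_points = NA_integer_) {
  if (slope <= 0) abort("detection model slope must be > 0")
  structure(list(slope = slope, intercept = intercept,
                 r_squared = r_squared, n_points = n_points, fit = NULL),
            class = "detection_model")
}

#' @export
print.detection_model <- function(x, ...) {
  cat(sprintf("<detection_model> observed%% = %.4g * true%% + %.4g (r2 = %.4g, n = %s)\n",
              x$slope, x$intercept, x$r_squared, x$n_points))
  invisible(x)
}

#' Fit the detection-bias model from a mixture series
#'
#' Ordinary least squares of observed percent Success (vertical) on true
#' percent Success (horizontal), both on the percent scale, over the
#' mixture series. The fitted line is inverted by [correct_observed()] to
#' recover true rates from observed ones.
#'
#' @param mix A data frame with `true_fraction` and either
#'   `observed_fraction` or `observed_success` + `n_clones` (as returned by
#'   [simulate_mixture_series()]).
#' @return A `detection_model` with `slope`, `intercept`, `r_squared`,
#'   `n_points` and the underlying `lm` fit.
#' @export
fit_detection_model <- function(mix) {
  mix <- tibble::as_tibble(mix)
  if (!"observed_fraction" %in% names(mix)) {
    mix$observed_fraction <- mix$observed_success / mix$n_clones
  }
  if (length(unique(mix$true_fraction)) < 2) {
    abort("fit requires at least 2 distinct true fractions")
  }
  d <- tibble::tibble(true_pct = 100 * mix$true_fraction,
                      observed_pct = 100 * mix$observed_fraction)
  fit <- stats::lm(observed_pct ~ true_pct, data = d)
  co <- stats::coef(fit)
  if (co[["true_pct"]] <= 0) {
    abort("fitted slope is not positive; observed rates do not increase with truth")
  }
  # r^2 computed directly (summary.lm warns on an exactly collinear fit)
  r2 <- 1 - sum(stats::residuals(fit)^2) /
    sum((d$observed_pct - mean(d$observed_pct))^2)
  structure(list(slope = unname(co[["true_pct"]]),
                 intercept = unname(co[["(Intercept)"]]),
                 r_squared = r2,
                 n_points = nrow(d), fit = fit),
            class = "detection_model")
}

#' Invert the detection model: correct an observed percent
#'
#' `(observed - intercept) / slope`, on the percent scale. With the
#' canonical calibration (slope 0.528, intercept -0.154) an observed
#' absolute Success rate of 4.7% corrects to (4.7 + 0.154)/0.528 = 9.185%.
#'
#' @param observed_percent Observed rate(s), percent scale.
#' @param model A `detection_model`.
#' @return Corrected percent(s); not clamped here (see
#'   [efficiency_report()] for clamping with warning).
#' @export
correct_observed <- function(observed_percent, model) {
  if (!inherits(model, "detection_model")) abort("model must be a detection_model")
  if (model$slope <= 0) abort("detection model slope must be > 0")
  (observed_percent - model$intercept) / model$slope
}

#' Absolute editing rate among rod photoreceptors
#'
#' Converts a whole-sample clone fraction to a rod-level rate by dividing
#' by the assumed rod proportion among retinal cells:
#' `100 * (success / total) / rod_fraction`.
#'
#' @param success Success clone count.
#' @param total_clones Total classified clones.
#' @param rod_fraction Proportion of rods among retinal cells (default
#'   0.75).
#' @return Percent.
#' @export
absolute_rod_rate <- function(success, total_clones, rod_fraction = 0.75) {
  if (total_clones <= 0) abort("total_clones must be > 0")
  if (success > total_clones) abort("success cannot exceed total_clones")
  if (rod_fraction <= 0 || rod_fraction > 1) abort("rod_fraction must be in (0, 1]")
  100 * (success / total_clones) / rod_fraction
}

#' Success rate among genome-edited clones
#'
#' @param success Success clone count.
#' @param edited Total edited (non-Unedited) clone count.
#' @return Percent, `100 * success / edited`.
#' @export
relative_success_rate <- function(success, edited) {
  if (edited == 0) abort("relative success rate undefined with zero edited clones")
  if (success > edited) abort("success cannot exceed edited")
  100 * success / edited
}

#' Efficiency report for a classified clone set
#'
#' Assembles the editing-efficiency statistics from a clone count table:
#' observed and (if a detection model is supplied) bias-corrected Success
#' fractions, absolute rod-level rates, and the relative Success rate among
#' edited clones. The correction is applied only to the Success and
#' Unedited (mutant) shares — the calibration experiment measured their
#' mutual detection bias — with the Unedited share absorbing the shift so
#' all category shares still sum to 1; it assumes the detection-efficiency
#' difference is constant across mixing ratios. Corrected values are
#' clamped to `[0, 100]` with a warning if the inversion overshoots.
#'
#' @param table A `clone_count_table` from [classify_set()].
#' @param model Optional `detection_model`.
#' @param rod_fraction Rod proportion among retinal cells (default 0.75).
#' @return An object of class `efficiency_report`; see [tidy.efficiency_report()]
#'   and [glance.efficiency_report()].
#' @export
efficiency_report <- function(table, model = NULL, rod_fraction = 0.75) {
  total <- sum(table$n)
  if (total == 0) abort("efficiency report undefined for zero clones")
  s <- count_of(table, "Success")
  u <- count_of(table, "Unedited")
  edited <- total - u

  shares <- table |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(n = sum(.data$n), .groups = "drop") |>
    dplyr::mutate(observed_share = .data$n / total)

  obs_frac <- s / total
  abs_unc <- absolute_rod_rate(s, total, rod_fraction)
  corr_frac <- NA_real_
  abs_corr <- NA_real_
  if (!is.null(model)) {
    abs_corr <- clamp_pct(correct_observed(abs_unc, model), "corrected absolute rate")
    s_pct_corr <- clamp_pct(correct_observed(100 * obs_frac, model),
                            "corrected Success share")
    corr_frac <- s_pct_corr / 100
    delta <- corr_frac - obs_frac
    u_share_corr <- u / total - delta
    if (u_share_corr < 0) {
      warn("corrected Unedited share fell below 0; clamping and renormalizing")
      u_share_corr <- 0
    }
    shares$corrected_share <- shares$observed_share
    shares$corrected_share[shares$category == "Success"] <- corr_frac
    shares$corrected_share[shares$category == "Unedited"] <- u_share_corr
    shares$corrected_share <- shares$corrected_share / sum(shares$corrected_share)
  }
  structure(
    list(observed_success_fraction = obs_frac,
         corrected_success_fraction = corr_frac,
         absolute_rod_rate_uncorrected = abs_unc,
         absolute_rod_rate_corrected = abs_corr,
         relative_success_among_edited =
           if (edited > 0) relative_success_rate(s, edited) else NA_real_,
         rod_fraction = rod_fraction,
         total_clones = total,
         shares = shares,
         model = model),
    class = "efficiency_report"
  )
}

clamp_pct <- function(x, what) {
  if (x < 0 || x > 100) {
    warn(sprintf("%s (%.3f%%) outside [0, 100]; clamped", what, x))
    x <- min(100, max(0, x))
  }
  x
}

#' @export
print.efficiency_report <- function(x, ...) {
  cat("<efficiency_report>\n")
  cat(sprintf("  total clones:                 %d\n", x$total_clones))
  cat(sprintf("  observed Success fraction:    %.4f\n", x$observed_success_fraction))
  cat(sprintf("  absolute rod rate (uncorr.):  %.2f%%\n", x$absolute_rod_rate_uncorrected))
  if (!is.na(x$absolute_rod_rate_corrected)) {
    cat(sprintf("  absolute rod rate (corrected):%.2f%%\n", x$absolute_rod_rate_corrected))
  }
  if (!is.na(x$relative_success_among_edited)) {
    cat(sprintf("  Success among edited:         %.1f%%\n", x$relative_success_among_edited))
  }
  invisible(x)
}

#' Relative expression rescue from qPCR CT values
#'
#' Fits a standard curve (CT versus log10 relative quantity) from a
#' dilution series of the control sample, interpolates the quantities of
#' treated and control CT values on it, and reports
#' `100 * mean(treated quantity) / mean(control quantity)`. Optionally
#' normalizes both by a reference-gene quantity computed the same way.
#'
#' @param ct_treated,ct_control CT values (numeric vectors).
#' @param standard_curve Data frame with columns `rel_quantity` (relative
#'   template quantity of each dilution, e.g. 1, 0.5, 0.25, ...) and `ct`.
#' @param ref Optional list with elements `ct_treated`, `ct_control`,
#'   `standard_curve` for a reference gene.
#' @return Percent rescue efficiency.
#' @export
rna_rescue_efficiency <- function(ct_treated, ct_control, standard_curve,
                                  ref = NULL) {
  interpolator <- function(curve) {
    curve <- tibble::as_tibble(curve)
    if (nrow(curve) < 2) abort("standard curve needs at least 2 points")
    d <- tibble::tibble(lq = log10(curve$rel_quantity), ct = curve$ct)
    fit <- stats::lm(ct ~ lq, data = d)
    slope <- stats::coef(fit)[["lq"]]
    if (!is.finite(slope) || abs(slope) < 1e-12) {
      abort("singular standard-curve fit")
    }
    if (slope > 0) {
      warn("standard curve CT increases with quantity; dilution labels may be reversed")
    }
    intercept <- stats::coef(fit)[["(Intercept)"]]
    function(cts) {
      if (!all(is.finite(cts))) abort("CT values must be finite")
      10^((cts - intercept) / slope)
    }
  }
  q <- interpolator(standard_curve)
  eff <- 100 * mean(q(ct_treated)) / mean(q(ct_control))
  if (!is.null(ref)) {
    qr <- interpolator(ref$standard_curve)
    ref_eff <- 100 * mean(qr(ref$ct_treated)) / mean(qr(ref$ct_control))
    eff <- eff / (ref_eff / 100)
  }
  eff
}

#' ERG-based rescue efficiency
#'
#' Treated-eye flicker ERG amplitude as a percentage of the mean amplitude
#' in control eyes (default 41.5 uV).
#'
#' @param treated_amplitude_uV Amplitude(s) in microvolts.
#' @param control_mean_uV Control mean amplitude (default 41.5).
#' @return Percent.
#' @export
erg_rescue_efficiency <- function(treated_amplitude_uV, control_mean_uV = 41.5) {
  if (control_mean_uV <= 0) abort("control_mean_uV must be > 0")
  100 * treated_amplitude_uV / control_mean_uV
}

#' Light-sensitivity threshold from an intensity series
#'
#' Returns the dimmest stimulus intensity whose response amplitude exceeds
#' the criterion (default 25 uV), the standard threshold rule for flash
#' visually evoked potentials.
#'
#' @param amplitudes Data frame with columns `intensity` (log cd s m^-2,
#'   strictly increasing) and `amplitude` (uV).
#' @param criterion_uV Threshold criterion (default 25).
#' @return The threshold intensity, or `NA` (non-detectable) when no
#'   intensity qualifies.
#' @export
light_sensitivity_threshold <- function(amplitudes, criterion_uV = 25) {
  amplitudes <- tibble::as_tibble(amplitudes)
  if (is.unsorted(amplitudes$intensity, strictly = TRUE)) {
    abort("intensities must be strictly increasing")
  }
  hit <- which(amplitudes$amplitude > criterion_uV)
  if (length(hit) == 0) return(NA_real_)
  amplitudes$intensity[hit[1]]
}
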