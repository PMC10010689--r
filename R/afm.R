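#' Hertz force for a spherical indenter
#'
#' Contact force of a rigid sphere of radius `R_um` indenting an elastic
#' half-space by `delta_nm`:
#' `F = (4/3) * (E / (1 - nu^2)) * sqrt(R) * delta^(3/2)`,
#' returned in nanonewtons for E in pascals and lengths in nanometres /
#' micrometres.
#'
#' @param delta_nm indentation depth(s), nm (>= 0).
#' @param E_pa Young's modulus, Pa (> 0).
#' @param nu Poisson's ratio (0 <= nu <= 0.5).
#' @param R_um indenter radius, um (5 for a 10 um bead).
#' @return force in nN, same length as `delta_nm`.
#' @export
hertz_force <- function(delta_nm, E_pa, nu = 0.5, R_um = 5) {
  if (any(delta_nm < 0)) stop("indentation depth must be >= 0")
  stopifnot(E_pa > 0, nu >= 0, nu <= 0.5, R_um > 0)
  R_nm <- R_um * 1000
  (4 / 3) * (E_pa / (1 - nu^2)) * sqrt(R_nm) * delta_nm^1.5 * 1e-9
}

# Analytic inversion of the sphere model from one (delta, F) sample.
hertz_modulus_from_sample <- function(delta_nm, force_nN, nu = 0.5, R_um = 5) {
  stopifnot(delta_nm > 0)
  3 * force_nN * (1 - nu^2) / (4 * sqrt(R_um * 1000) * delta_nm^1.5) * 1e9
}

#' Specification of a synthetic Hertz force curve
#'
#' Forward model of a force-spectroscopy approach curve on an elastic sample
#' with a spherical indenter: below the contact point the force is baseline
#' noise only; beyond it the indentation follows from the piezo travel minus
#' the cantilever bending, solved self-consistently (`delta = (z - z0) -
#' F(delta)/k`). Defaults mirror the acquisition conditions modelled
#' throughout: 10 um bead (R = 5 um), 7.5 N/m tipless cantilever, about
#' 800 nm of indentation at a force comparable to a 450 nN setpoint, and an
#' incompressible-tissue Poisson ratio of 0.5.
#'
#' @param E_pa true Young's modulus, Pa.
#' @param nu Poisson's ratio.
#' @param R_um indenter radius, um.
#' @param k_n_per_m cantilever stiffness, N/m.
#' @param z0_nm true contact point (piezo height), nm.
#' @param z_range_nm piezo travel sampled uniformly from 0, nm.
#' @param n_samples number of samples (>= 10).
#' @param noise_sd_nN additive Gaussian force noise sd, nN.
#' @param seed RNG seed.
#' @return a `hertz_curve_spec` list.
#' @export
hertz_curve_spec <- function(E_pa = 150e3, nu = 0.5, R_um = 5,
                             k_n_per_m = 7.5, z0_nm = 2000,
                             z_range_nm = 3000, n_samples = 601L,
                             noise_sd_nN = 0, seed = 1L) {
  stopifnot(E_pa > 0, nu >= 0, nu <= 0.5, R_um > 0, k_n_per_m > 0,
            z0_nm >= 0, z_range_nm > z0_nm, n_samples >= 10,
            noise_sd_nN >= 0)
  structure(list(E_pa = E_pa, nu = nu, R_um = R_um, k_n_per_m = k_n_per_m,
                 z0_nm = z0_nm, z_range_nm = z_range_nm,
                 n_samples = as.integer(n_samples),
                 noise_sd_nN = noise_sd_nN, seed = as.integer(seed)),
            class = "hertz_curve_spec")
}

# Self-consistent indentation for one piezo position past contact:
# delta = (z - z0) - F(delta)/k, solved by fixed-point iteration to 1e-6 nm.
solve_indentation <- function(travel_nm, E_pa, nu, R_um, k_n_per_m) {
  delta <- travel_nm
  for (it in 1:200) {
    f <- hertz_force(delta, E_pa, nu, R_um)
    new <- travel_nm - f / k_n_per_m   # F[nN] / k[N/m] = deflection[nm]
    if (new < 0) new <- 0
    if (abs(new - delta) < 1e-6) return(new)
    delta <- new
  }
  delta
}

#' Generate a synthetic AFM approach curve
#'
#' @param spec a [hertz_curve_spec()].
#' @return a `force_curve`: data frame columns `z_nm` (strictly increasing)
#'   and `force_nN`, with the generating spec and the noiseless ground truth
#'   (`truth$delta_nm`, `truth$force_nN`) attached as attributes for
#'   round-trip validation.
#' @export
generate_force_curve <- function(spec) {
  stopifnot(inherits(spec, "hertz_curve_spec"))
  z <- seq(0, spec$z_range_nm, length.out = spec$n_samples)
  delta <- vapply(pmax(z - spec$z0_nm, 0), function(tr) {
    if (tr <= 0) 0 else solve_indentation(tr, spec$E_pa, spec$nu, spec$R_um,
                                          spec$k_n_per_m)
  }, numeric(1))
  f_true <- hertz_force(delta, spec$E_pa, spec$nu, spec$R_um)
  f <- f_true
  if (spec$noise_sd_nN > 0) {
    f <- f + with_seed(spec$seed + 31L,
                       stats::rnorm(length(f), 0, spec$noise_sd_nN))
  }
  structure(data.frame(z_nm = z, force_nN = f),
            spec = spec, truth = list(z0_nm = spec$z0_nm, delta_nm = delta,
                                      force_nN = f_true),
            class = c("force_curve", "data.frame"))
}

as_force_curve <- function(df) {
  stopifnot(all(c("z_nm", "force_nN") %in% names(df)))
  if (nrow(df) < 10) stop("a force curve needs at least 10 samples")
  dz <- diff(df$z_nm)
  if (!all(dz > 0) && !all(dz < 0)) stop("`z_nm` must be strictly monotone")
  if (all(dz < 0)) df <- df[rev(seq_len(nrow(df))), , drop = FALSE]
  if (!all(is.finite(df$z_nm)) || !all(is.finite(df$force_nN))) {
    stop("force-curve samples must be finite")
  }
  structure(data.frame(z_nm = df$z_nm, force_nN = df$force_nN),
            class = c("force_curve", "data.frame"))
}

baseline_index <- function(curve, baseline_fraction) {
  n <- nrow(curve)
  m <- floor(n * baseline_fraction)
  if (m < 3) stop("too few baseline samples: increase `baseline_fraction`")
  seq_len(m)
}

#' Zero the baseline of a force curve
#'
#' Fits a straight line to the far (non-contact) fraction of the approach and
#' subtracts it from the whole curve, removing constant offset and linear
#' drift; the baseline mean becomes 0 within noise.
#'
#' @param curve a `force_curve` (or data frame with `z_nm`, `force_nN`).
#' @param baseline_fraction fraction of the lowest-z samples treated as
#'   non-contact, in (0, 0.8].
#' @return the baseline-corrected `force_curve`.
#' @export
zero_baseline <- function(curve, baseline_fraction = 0.3) {
  if (baseline_fraction <= 0 || baseline_fraction > 0.8) {
    stop("`baseline_fraction` must be in (0, 0.8]")
  }
  curve <- as_force_curve(curve)
  idx <- baseline_index(curve, baseline_fraction)
  fit <- stats::lm(force_nN ~ z_nm, data = curve[idx, ])
  corrected <- curve$force_nN - stats::predict(fit, newdata = curve)
  structure(data.frame(z_nm = curve$z_nm, force_nN = corrected),
            baseline_fit = stats::coef(fit),
            class = c("force_curve", "data.frame"))
}

#' Locate the tip-sample contact point
#'
#' On a baseline-zeroed approach curve, contact is declared at the first
#' sample whose force exceeds three times the baseline noise sd and stays
#' above it for at least `min_run` consecutive samples; the returned `z0` is
#' the last sub-threshold piezo height before that run, so on noiseless
#' curves it is within one sample spacing of the true contact point.
#'
#' @param curve baseline-zeroed `force_curve`.
#' @param noise_sd_estimate baseline noise sd; estimated from the baseline
#'   fraction when `NULL`.
#' @param baseline_fraction fraction used for the noise estimate.
#' @param min_run consecutive above-threshold samples required.
#' @return contact point `z0` in nm, with attribute `threshold_nN`.
#' @export
find_contact_point <- function(curve, noise_sd_estimate = NULL,
                               baseline_fraction = 0.3, min_run = 5L) {
  curve <- as_force_curve(curve)
  if (is.null(noise_sd_estimate)) {
    noise_sd_estimate <- stats::sd(curve$force_nN[baseline_index(curve, baseline_fraction)])
  }
  thr <- max(3 * noise_sd_estimate, 1e-12)
  above <- curve$force_nN > thr
  n <- length(above)
  run <- 0L
  start <- NA_integer_
  for (i in seq_len(n)) {
    if (above[i]) {
      run <- run + 1L
      if (run == as.integer(min_run)) {
        start <- i - run + 1L
        break
      }
    } else run <- 0L
  }
  if (is.na(start)) stop("no contact detected: force never sustainably exceeds the noise band")
  z0 <- if (start == 1L) curve$z_nm[1] else curve$z_nm[start - 1L]
  structure(z0, threshold_nN = thr)
}

#' Convert a force curve to an indentation curve
#'
#' Subtracts the cantilever bending: for samples past the contact point,
#' `delta = (z - z0) - F/k`. Samples at or before contact are excluded;
#' slightly negative indentations produced by noise just past contact are
#' dropped.
#'
#' @param curve baseline-zeroed `force_curve`.
#' @param k_n_per_m cantilever stiffness, N/m (> 0).
#' @param z0_nm contact point, nm.
#' @return an `indentation_curve`: data frame `delta_nm`, `force_nN`, with
#'   `z0_nm` attached.
#' @export
to_indentation <- function(curve, k_n_per_m, z0_nm) {
  if (k_n_per_m <= 0) stop("`k_n_per_m` must be > 0")
  curve <- as_force_curve(curve)
  sel <- curve$z_nm > z0_nm
  delta <- (curve$z_nm[sel] - z0_nm) - curve$force_nN[sel] / k_n_per_m
  keep <- delta >= 0
  structure(data.frame(delta_nm = delta[keep], force_nN = curve$force_nN[sel][keep]),
            z0_nm = as.numeric(z0_nm),
            class = c("indentation_curve", "data.frame"))
}

#' Fit the spherical Hertz model to an indentation curve
#'
#' Least-squares estimate of Young's modulus from `F = c * delta^(3/2)` over
#' a fractional indentation window, with an optional contact-point refinement
#' that co-fits a small shift of the contact point (profiled closed-form
#' amplitude, 1-D minimisation of the residual sum of squares). The estimate
#' is invariant to sample order.
#'
#' @param ind an `indentation_curve`.
#' @param nu Poisson's ratio used in the conversion to modulus.
#' @param R_um indenter radius, um.
#' @param fit_window fractions (low, high) of the maximum indentation
#'   delimiting the fitted samples.
#' @param refine_z0 refine the contact point within about one sample spacing.
#' @return a `hertz_fit` list: `E_pa`, `nu`, `R_um`, `z0_nm` (refined),
#'   `z0_shift_nm`, `rms_residual_nN`, `n_fit`, `converged`.
#' @export
fit_hertz_sphere <- function(ind, nu = 0.5, R_um = 5,
                             fit_window = c(0.1, 0.9), refine_z0 = TRUE) {
  stopifnot(inherits(ind, "data.frame"),
            all(c("delta_nm", "force_nN") %in% names(ind)),
            length(fit_window) == 2, fit_window[1] >= 0,
            fit_window[2] > fit_window[1], fit_window[2] <= 1)
  dmax <- max(ind$delta_nm)
  sel <- ind$delta_nm >= fit_window[1] * dmax & ind$delta_nm <= fit_window[2] * dmax
  d <- ind$delta_nm[sel]
  f <- ind$force_nN[sel]
  if (length(d) < 5) stop("fewer than 5 samples in the fit window")
  amp_rss <- function(shift) {
    dd <- d - shift
    ok <- dd > 0
    if (sum(ok) < 5) return(list(c = NA_real_, rss = Inf, n = sum(ok)))
    x <- dd[ok]^1.5
    cc <- sum(f[ok] * x) / sum(x * x)
    list(c = cc, rss = sum((f[ok] - cc * x)^2) +
           sum(f[!ok]^2), n = sum(ok))
  }
  shift <- 0
  if (refine_z0) {
    # the 3-sigma contact detector fires late on noisy curves, so allow the
    # co-fitted contact offset to move well before the detected point
    opt <- stats::optimize(function(s) amp_rss(s)$rss,
                           interval = c(-0.4 * dmax, 0.3 * dmax),
                           tol = 1e-8)
    shift <- opt$minimum
  }
  best <- amp_rss(shift)
  converged <- is.finite(best$c) && best$c > 0
  E <- if (converged) {
    best$c * 3 * (1 - nu^2) / (4 * sqrt(R_um * 1000)) * 1e9
  } else NA_real_
  z0 <- attr(ind, "z0_nm")
  structure(list(E_pa = E, nu = nu, R_um = R_um,
                 z0_nm = if (!is.null(z0)) z0 + shift else NA_real_,
                 z0_shift_nm = shift,
                 rms_residual_nN = sqrt(best$rss / max(length(d), 1)),
                 n_fit = best$n, converged = converged),
            class = "hertz_fit")
}

#' @export
print.hertz_fit <- function(x, ...) {
  cat(sprintf("<hertz_fit> E = %s kPa (nu %.2f, R %.1f um), rms %.3g nN, n = %d%s\n",
              if (x$converged) sprintf("%.2f", x$E_pa / 1000) else "NA",
              x$nu, x$R_um, x$rms_residual_nN, x$n_fit,
              if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Process one raw approach curve end to end
#'
#' Baseline zeroing, contact-point detection, bending subtraction and Hertz
#' sphere fit, returning the fit together with the detected contact point.
#'
#' @param curve raw `force_curve`.
#' @param k_n_per_m cantilever stiffness, N/m.
#' @param nu,R_um,fit_window,baseline_fraction passed to the stages.
#' @return a `hertz_fit` (its `z0_nm` is the refined contact point).
#' @export
process_force_curve <- function(curve, k_n_per_m, nu = 0.5, R_um = 5,
                                fit_window = c(0.1, 0.9),
                                baseline_fraction = 0.3) {
  zc <- zero_baseline(curve, baseline_fraction)
  z0 <- find_contact_point(zc, baseline_fraction = baseline_fraction)
  ind <- to_indentation(zc, k_n_per_m, as.numeric(z0))
  fit_hertz_sphere(ind, nu = nu, R_um = R_um, fit_window = fit_window)
}
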