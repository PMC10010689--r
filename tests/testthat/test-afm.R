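test_that("the sphere force law matches its closed form and scaling", {
  expect_equal(hertz_force(0, 1e5), 0)
  # E = 100 kPa, nu = 0.5, R = 5 um, delta = 800 nm
  expected <- (4 / 3) * (1e5 / 0.75) * sqrt(5e-6) * (800e-9)^1.5 * 1e9
  expect_equal(hertz_force(800, 1e5, 0.5, 5), expected)
  expect_equal(expected, 284.44, tolerance = 1e-4)
  expect_equal(hertz_force(1600, 1e5) / hertz_force(800, 1e5), 2^1.5)
  expect_error(hertz_force(-1, 1e5), ">= 0")
})

test_that("noiseless curves are zero before contact and invert exactly", {
  cv <- generate_force_curve(hertz_curve_spec(noise_sd_nN = 0))
  spec <- attr(cv, "spec"); truth <- attr(cv, "truth")
  expect_true(all(cv$force_nN[cv$z_nm <= spec$z0_nm] == 0))
  # E recovered analytically from every post-contact sample
  sel <- truth$delta_nm > 1
  E <- 3 * truth$force_nN[sel] * (1 - spec$nu^2) /
    (4 * sqrt(spec$R_um * 1000) * truth$delta_nm[sel]^1.5) * 1e9
  expect_equal(E, rep(spec$E_pa, sum(sel)), tolerance = 1e-5)
  # self-consistency of the sampled geometry: delta + F/k = z - z0
  expect_equal(truth$delta_nm[sel] + truth$force_nN[sel] / spec$k_n_per_m,
               cv$z_nm[sel] - spec$z0_nm, tolerance = 1e-5)
})

test_that("force-curve generation is deterministic and noise is seeded", {
  sp <- hertz_curve_spec(noise_sd_nN = 5, seed = 4L)
  expect_identical(generate_force_curve(sp), generate_force_curve(sp))
  sp2 <- hertz_curve_spec(noise_sd_nN = 5, seed = 5L)
  expect_false(identical(generate_force_curve(sp)$force_nN,
                         generate_force_curve(sp2)$force_nN))
})

test_that("baseline zeroing removes offsets and linear drift", {
  cv <- generate_force_curve(hertz_curve_spec())
  idx <- seq_len(floor(nrow(cv) * 0.3))
  off <- cv; off$force_nN <- off$force_nN + 12.5
  z1 <- zero_baseline(off)
  expect_equal(z1$force_nN[idx], rep(0, length(idx)), tolerance = 1e-9)
  drift <- cv; drift$force_nN <- drift$force_nN + 0.01 * drift$z_nm - 3
  z2 <- zero_baseline(drift)
  expect_equal(z2$force_nN[idx], rep(0, length(idx)), tolerance = 1e-9)
  # contact region shape preserved (drift removed, not the indentation law)
  expect_equal(diff(range(z2$force_nN - cv$force_nN)), 0, tolerance = 1e-6)
  expect_error(zero_baseline(cv, 0.001), "baseline samples")
})

test_that("contact point is found within one sample spacing, and shifts with z", {
  cv <- zero_baseline(generate_force_curve(hertz_curve_spec(z0_nm = 2000)))
  spacing <- diff(cv$z_nm[1:2])
  z0 <- as.numeric(find_contact_point(cv))
  expect_lte(abs(z0 - 2000), spacing)
  shifted <- data.frame(z_nm = cv$z_nm + 137, force_nN = cv$force_nN)
  expect_equal(as.numeric(find_contact_point(shifted)), z0 + 137)
  flat <- data.frame(z_nm = cv$z_nm,
                     force_nN = with_seed_local(1, rnorm(nrow(cv), 0, 1)))
  expect_error(find_contact_point(flat), "no contact")
})

test_that("bending subtraction reproduces the generator's indentation", {
  sp <- hertz_curve_spec()
  cv <- generate_force_curve(sp)
  truth <- attr(cv, "truth")
  ind <- to_indentation(zero_baseline(cv), sp$k_n_per_m, sp$z0_nm)
  expect_equal(ind$delta_nm, truth$delta_nm[cv$z_nm > sp$z0_nm],
               tolerance = 1e-3)
  # F = 0 everywhere: delta equals piezo travel
  flat <- data.frame(z_nm = seq(0, 100, 10), force_nN = numeric(11))
  ind0 <- to_indentation(flat, 7.5, 40)
  expect_equal(ind0$delta_nm, seq(50, 100, 10) - 40)
  # F/k arithmetic: 450 nN on a 7.5 N/m lever bends 60 nm
  one <- data.frame(z_nm = seq(0, 1000, 100), force_nN = c(rep(0, 10), 450))
  expect_equal(max(to_indentation(one, 7.5, 0)$delta_nm), 1000 - 60)
  expect_error(to_indentation(flat, -1, 0), "k_n_per_m")
})

test_that("Hertz fits recover the modulus and flag degenerate input", {
  fit <- process_force_curve(generate_force_curve(hertz_curve_spec(E_pa = 150e3)), 7.5)
  expect_true(fit$converged)
  expect_lt(abs(fit$E_pa - 150e3) / 150e3, 0.001)
  expect_lt(fit$rms_residual_nN / 450, 1e-6)
  # linearity: scaling forces scales the fitted modulus
  sp <- hertz_curve_spec()
  cv <- generate_force_curve(sp)
  ind <- to_indentation(cv, sp$k_n_per_m, sp$z0_nm)
  f1 <- fit_hertz_sphere(ind, refine_z0 = FALSE)
  ind2 <- ind; ind2$force_nN <- 2 * ind2$force_nN
  f2 <- fit_hertz_sphere(ind2, refine_z0 = FALSE)
  expect_equal(f2$E_pa / f1$E_pa, 2, tolerance = 1e-9)
  # order invariance
  shuf <- ind[with_seed_local(8, sample(nrow(ind))), ]
  attr(shuf, "z0_nm") <- attr(ind, "z0_nm")
  expect_equal(fit_hertz_sphere(shuf)$E_pa, fit_hertz_sphere(ind)$E_pa)
  # all-zero force: flagged, not silent
  zero <- data.frame(delta_nm = seq(1, 500, length.out = 50),
                     force_nN = numeric(50))
  fz <- fit_hertz_sphere(zero)
  expect_false(fz$converged)
  expect_true(is.na(fz$E_pa))
})

test_that("the full processing chain recovers E across seeds and noise", {
  errs <- vapply(1:20, function(i) {
    cv <- generate_force_curve(hertz_curve_spec(E_pa = 120e3, seed = i))
    abs(process_force_curve(cv, 7.5)$E_pa - 120e3) / 120e3
  }, numeric(1))
  expect_true(all(errs < 0.01))
  E_noisy <- vapply(1:20, function(i) {
    cv <- generate_force_curve(hertz_curve_spec(E_pa = 120e3, noise_sd_nN = 9,
                                                seed = 100L + i))
    process_force_curve(cv, 7.5)$E_pa
  }, numeric(1))
  expect_lt(abs(stats::median(E_noisy) - 120e3) / 120e3, 0.10)
})
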