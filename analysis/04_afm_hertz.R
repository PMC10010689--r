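#!/usr/bin/env Rscript
# Force-curve processing and Hertz spherical-indenter fits: one noiseless
# curve (sanity: machine-precision recovery) and fifty noisy curves at 2% of
# the 450 nN setpoint, reporting the median recovered Young's modulus.

library(meisoquant)

out <- "results/afm"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

E_true <- 150e3  # Pa
sp0 <- hertz_curve_spec(E_pa = E_true)
cv0 <- generate_force_curve(sp0)
write_force_curve(cv0, file.path(out, "curve_noiseless.csv"))
fit0 <- process_force_curve(cv0, sp0$k_n_per_m)
cat(sprintf("noiseless: E = %.2f kPa (true %.0f), contact %.0f nm (true %.0f), rms %.2g nN\n",
            fit0$E_pa / 1000, E_true / 1000, fit0$z0_nm, sp0$z0_nm,
            fit0$rms_residual_nN))

fits <- do.call(rbind, lapply(1:50, function(i) {
  sp <- hertz_curve_spec(E_pa = E_true, noise_sd_nN = 9, seed = i)
  fit <- process_force_curve(generate_force_curve(sp), sp$k_n_per_m)
  data.frame(curve = i, E_fit_pa = fit$E_pa, z0_fit_nm = fit$z0_nm,
             rms_residual_nN = fit$rms_residual_nN, converged = fit$converged)
}))
write.csv(fits, file.path(out, "hertz_fits_noisy.csv"), row.names = FALSE)
cat(sprintf("noisy (sd 9 nN, 50 curves): median E %.1f kPa (%.1f%% from truth), IQR %.1f kPa, %d/%d converged\n",
            median(fits$E_fit_pa) / 1000,
            100 * abs(median(fits$E_fit_pa) - E_true) / E_true,
            IQR(fits$E_fit_pa) / 1000, sum(fits$converged), nrow(fits)))
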