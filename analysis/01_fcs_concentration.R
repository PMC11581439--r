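#!/usr/bin/env Rscript
# FCS chain: confocal geometry -> focal volume -> occupancy -> molar
# concentration, plus fit behaviour on synthetic autocorrelation curves.
library(crowdscope)
dir.create("results", showWarnings = FALSE)

br <- theoretical_beam_radii(wavelength = 0.488, num_aperture = 1.2,
                             ref_index = 1.33)
v <- effective_volume(br$omega_xy, br$omega_z)
n <- number_density_from_g0(1.028)
conc <- concentration_from_counts(n, v)

cat(sprintf("beam radii: wxy = %.0f nm, wz = %.0f nm (S = %.3f)\n",
            br$omega_xy * 1e3, br$omega_z * 1e3, br$omega_z / br$omega_xy))
cat(sprintf("effective confocal volume: %.3f fL\n", v))
cat(sprintf("G0 = 1.028 -> N = %.3f molecules in focus\n", n))
cat(sprintf("concentration: %.0f nM (stock after x1000 dilution: %.0f uM)\n",
            conc * 1e9, conc * 1e9 * 1000 / 1000))

# fit of a synthetic curve at the same study conditions, with 1% noise
s <- synth_traces("fcs", params = list(nmol = n, tau_d = 170e-6),
                  noise = 0.01, seed = 7)
fit <- fit_fcs(s$data)
cat(sprintf("fit on 1%%-noise curve: N = %.2f, tau_d = %.0f us, D = %.1f um2/s\n",
            fit$nmol, fit$tau_d * 1e6, fcs_diffusion_coeff(br$omega_xy, fit$tau_d)))

write.csv(data.frame(
  quantity = c("omega_xy_nm", "omega_z_nm", "v_eff_fL", "n_molecules",
               "concentration_nM", "stock_uM", "fit_n", "fit_taud_us"),
  value = c(br$omega_xy * 1e3, br$omega_z * 1e3, v, n, conc * 1e9,
            conc * 1e9, fit$nmol, fit$tau_d * 1e6)),
  "results/fcs_chain.csv", row.names = FALSE)
cat("wrote results/fcs_chain.csv\n")
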