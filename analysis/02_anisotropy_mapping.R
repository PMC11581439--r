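#!/usr/bin/env Rscript
# Full wide-field anisotropy pipeline on a synthetic spread-cell scene:
# imposed r field -> dual-view frame -> background subtraction -> bead
# registration -> G-factor correction -> r map -> per-cell modal stats.
library(crowdscope)
dir.create("results", showWarnings = FALSE)
set.seed(11)

nr <- 200; nc <- 240
X <- matrix(rep(0:(nc - 1), each = nr), nr, nc)
Y <- matrix(rep(0:(nr - 1), nc), nr, nc)
rad <- sqrt((X - 120)^2 + (Y - 100)^2)

# cell geography: low-r lamella rim, dominant high-r perinuclear body
cell <- rad <= 85
rstar <- matrix(0.19, nr, nc)          # lamella baseline
rstar[rad <= 70] <- 0.22               # perinuclear region (majority of pixels)
intensity <- matrix(3000, nr, nc)      # out-of-cell background level
intensity[cell] <- 40000
gstar <- 1 + 0.1 * X / nc              # vignetted G field
shift <- c(2.6, -1.3); bg <- 350

scene <- synth_polarized_scene(rstar, intensity, gstar, background = bg,
                               shift = shift, noise = "poisson", seed = 11)

# bead calibration (once per setup)
pos <- cbind(runif(40, 15, nc - 15), runif(40, 15, nr - 15))
tr <- estimate_transform(
  detect_beads(synth_bead_image(pos, shape = c(nr, nc))$image, threshold = 500),
  detect_beads(synth_bead_image(sweep(pos, 2, shift, "+"),
                                shape = c(nr, nc))$image, threshold = 500),
  "similarity")
cat(sprintf("registration: |b - true| = %.3f px, rms = %.3f px (%d inliers)\n",
            sqrt(sum((tr$b + shift)^2)), tr$residual_rms, tr$n_inliers))
write_transform(tr, "results/channel_transform.json")

# G-factor from fluorescein-like references (uniform depolarized field)
refs <- lapply(1:4, function(i)
  split_dual_view(synth_polarized_scene(matrix(0, nr, nc),
                                        matrix(30000, nr, nc), gstar,
                                        noise = "poisson",
                                        seed = 100 + i)$frame))
refs <- lapply(refs, function(p) { p$registered <- TRUE; p })
gmap <- compute_gfactor_map(refs)
cat(sprintf("G-factor recovery: max rel err %.4f\n",
            max(abs(gmap$g - gstar) / gstar, na.rm = TRUE)))

pair <- split_dual_view(subtract_background(scene$frame,
                                            dual_view_frame(matrix(bg, nr, 2 * nc))))
pair <- apply_transform(pair, tr)
amap <- compute_anisotropy_map(pair, gmap, 15000, 50000)
write_map(amap$r, "results/anisotropy_map.tif")

rec <- modal_anisotropy(amap, matrix(as.integer(cell), nr, nc),
                        pixel_size = 0.65)
print(rec)
cat(sprintf("modal r = %.4f (imposed dominant region: 0.22)\n", rec$modal_r))
write.csv(rec, "results/cell_records.csv", row.names = FALSE)
cat("wrote results/anisotropy_map.tif, results/cell_records.csv\n")
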