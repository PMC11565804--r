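#!/usr/bin/env Rscript
# Nonlinear curve fitting: one-site specific binding (fluorescence
# polarization style titrations, K_D) and one-phase association (FRAP
# recovery halftime), including FRAP normalization from a raw series and
# the stochastic parameter-recovery protocol used by the acceptance tests.
#
# Finding: noiseless fits recover generating parameters to numerical
# precision; at 2% noise the means over 200 replicates stay within a few
# percent of K_D = 0.30 uM and t_half = 13 s; the printed slow/fast
# halftime pair (450 s vs 34 s) corresponds to a ~13-fold rate change.

suppressMessages(library(g4kit))
dir.create("results", showWarnings = FALSE)

conc <- 10^seq(log10(0.01), log10(10), length.out = 12)

# single noisy titration
cur <- generate_curves("one_site", list(K_D = 0.30, B_max = 1, baseline = 0),
                       conc, noise_sd = 0.02, seed = 11)[[1]]
fit <- fit_one_site(cur)
cat(sprintf("One-site fit: K_D = %.3f +/- %.3f uM, B_max = %.3f\n",
            fit$parameters["K_D"], fit$stderr["K_D"], fit$parameters["B_max"]))

# stochastic recovery, 200 replicates
reps <- generate_curves("one_site", list(K_D = 0.30, B_max = 1, baseline = 0),
                        conc, noise_sd = 0.02, n_replicates = 200, seed = 1)
kds <- vapply(reps, function(d) fit_one_site(d)$parameters[["K_D"]], numeric(1))
cat(sprintf("K_D recovery over 200 fits: mean %.4f uM (generating 0.30)\n",
            mean(kds)))

# FRAP: normalize a raw bleach series, then fit
raw_t <- seq(-4, 120, 2)
true_rec <- one_phase_model(pmax(raw_t, 0), t_half = 13, Y0 = 0.05,
                            plateau = 0.95)
raw_i <- ifelse(raw_t < 0, 1, true_rec) * 1000
rc <- normalize_frap(raw_t, raw_i, prebleach = 1:2,
                     bleach_index = which(raw_t == 0))
ffit <- fit_one_phase_association(rc)
cat(sprintf("FRAP fit: t_half = %.2f s, mobile fraction = %.2f\n",
            ffit$derived$t_half, ffit$derived$mobile_fraction))

times <- seq(0, 120, length.out = 60)
reps2 <- generate_curves("one_phase_assoc",
                         list(t_half = 13, Y0 = 0, plateau = 1),
                         times, noise_sd = 0.02, n_replicates = 200, seed = 1)
th <- vapply(reps2, function(d) fit_one_phase_association(d)$derived$t_half,
             numeric(1))
cat(sprintf("t_half recovery over 200 fits: mean %.3f s (generating 13)\n",
            mean(th)))

# fold change between the printed slow and fast condensate halftimes
fold <- (log(2) / 34) / (log(2) / 450)
cat(sprintf("Halftime fold change, 450 s vs 34 s: %.1f-fold\n", fold))

write.csv(data.frame(replicate = seq_along(kds), K_D = kds),
          "results/kd_recovery.csv", row.names = FALSE)
write.csv(data.frame(replicate = seq_along(th), t_half = th),
          "results/thalf_recovery.csv", row.names = FALSE)
write.csv(rc, "results/frap_normalized_curve.csv", row.names = FALSE)
cat("written: results/kd_recovery.csv, thalf_recovery.csv,",
    "frap_normalized_curve.csv\n")
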