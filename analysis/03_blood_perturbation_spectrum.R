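#!/usr/bin/env Rscript
# Simulate the differential-absorbance change caused by a +50% relative
# blood-volume change in the two blood-net dermal layers, decomposed into
# its absorption and scattering channels. The absorption channel carries
# the chromophore band structure at tight standard errors (path-reweighted
# estimator); the scattering channel is larger and spectrally flatter, with
# wider errors where photons penetrate deepest.

library(nirglucosim)

dir.create("results", showWarnings = FALSE)
seed <- 1
n_photons <- 3e5   # per arm and band; enough to rank the six bands

chrom <- gen_chromophore_fixture()
model <- default_skin_model()
spec <- perturbation_spec()   # +50% in upper and deep blood net dermis

out <- NULL
for (ch in c("both", "absorption_only", "scattering_only")) {
  d <- suppressWarnings(blood_perturbation_spectrum(
    model, chrom, spec, channels = ch,
    config = mc_config(n_photons = n_photons, seed = seed), n_blocks = 6))
  cat(sprintf("\nchannel = %s\n", ch))
  print(round(d, 5), row.names = FALSE)
  out <- rbind(out, cbind(channel = ch, d))
}
write_csv_meta(out, "results/blood_perturbation_spectrum.csv",
               meta = list(seed = seed, n_photons = n_photons,
                           delta_CB_rel = 0.5, pair = "0.9/2.3 mm"))

both <- out[out$channel == "both", ]
peak <- both$wavelength_nm[which.max(abs(both$delta_ad))]
cat(sprintf("\nLargest |dA_D| band (full perturbation): %g nm\n", peak))
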