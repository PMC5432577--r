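#!/usr/bin/env Rscript
# Simulate one exemplar subject (cyclic trial + 80% MVC reference), write
# the trial containers to scratch/, read them back and summarize what was
# generated. Later stages consume the on-disk containers.

suppressPackageStartupMessages(library(semgfatigue))

cfg <- synthetic_config(seed = 2026)
trial <- simulate_subject(cfg, subject_id = "EX01", age = 47, sex = "female")
dir <- "scratch/example_subject"
write_subject(trial, dir)

cyc <- read_recording(file.path(dir, "cyclic"))
mvc <- read_recording(file.path(dir, "mvc80"))
stopifnot(identical(cyc$semg, trial$cyclic$semg))   # round trip is exact

cat("Simulated subject EX01 ->", dir, "\n")
cat(sprintf("  cyclic: %d cycles x %g s, %d SEMG channels @ %g Hz, accel @ %g Hz\n",
            cfg$n_cycles, cfg$cycle_duration, ncol(cyc$semg), cyc$semg_rate,
            cyc$accel_rate))
cat(sprintf("  mvc80 : %.0f s reference, target RMS %.1f uV per channel\n",
            nrow(mvc$semg) / mvc$semg_rate, cfg$mvc_rms))
gt <- trial$ground_truth
cat(sprintf("  imposed: conc/ecc RMS ratio %.2f; normalized slopes (%%/s) RMS %+.2f/%+.2f, IMDF %+.2f/%+.2f\n",
            gt$conc_ecc_amplitude_ratio,
            gt$normalized_slope_pct_per_s$rms_concentric,
            gt$normalized_slope_pct_per_s$rms_eccentric,
            gt$normalized_slope_pct_per_s$imdf_concentric,
            gt$normalized_slope_pct_per_s$imdf_eccentric))
cat(sprintf("  initial IMDF per level: L1 %.0f, L2 %.0f, L5 %.0f Hz\n",
            gt$imdf_initial_hz$L1, gt$imdf_initial_hz$L2, gt$imdf_initial_hz$L5))
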