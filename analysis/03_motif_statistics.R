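#!/usr/bin/env Rscript
# Step 3 - full statistical pipeline: planted-effect run vs null run.
#
# Runs the complete pipeline twice with the phase-kind generator: once with
# the default planted bd-post hypersynchronisation on FMC-rIPL and once with
# both groups maturing identically. Reports the recovered motif (corrected
# p, per-group degree, Cohen's d, LOO accuracy, centroids) and verifies the
# null run stays quiet. Writes the machine-readable reports under
# results/pipeline_demo and results/pipeline_null.

suppressMessages(library(plvmotif))
dir.create("results", showWarnings = FALSE)

cat("== planted-effect run ==\n")
rep_demo <- run_pipeline(demo_config(seed = 11, n_trials = 15,
                                     out_dir = "results/pipeline_demo"))
pr <- rep_demo$bands$theta[["FMC-rIPL"]]
cat(sprintf("FMC-rIPL universe: %d links, %d significant\n",
            pr$n_links, pr$n_significant_links))
for (m in pr$motifs) {
  cat(sprintf("motif: %d nodes, %d links, mass %.1f, corrected p = %.4g\n",
              length(m$nodes), m$n_links, m$mass, m$p_corrected))
  cat(sprintf("  degree bd %.3f +/- %.3f | control %.3f +/- %.3f\n",
              m$degree_mean_bd, m$degree_sd_bd,
              m$degree_mean_control, m$degree_sd_control))
  cat(sprintf("  ANCOVA p (x5) = %.4g, Cohen's d = %.2f, LOO accuracy = %.0f%%\n",
              m$ancova_p_corrected, m$cohen_d, 100 * m$accuracy))
  cat(sprintf("  t-test vs 1: bd t = %.2f (p = %.3g), control t = %.2f (p = %.3g)\n",
              m$ttest_bd$t, m$ttest_bd$p, m$ttest_control$t, m$ttest_control$p))
}

cat("\n== null run (both groups mature alike) ==\n")
rep_null <- run_pipeline(null_config(seed = 11, n_trials = 15,
                                     out_dir = "results/pipeline_null"))
cat(sprintf("significant motifs in null run: %d\n",
            rep_null$n_significant_motifs))
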