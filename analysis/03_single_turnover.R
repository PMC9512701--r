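#!/usr/bin/env Rscript
# The pulsed single-turnover experiment: pulse-duration comparison of
# first-step FRET-change histograms and their two-Gaussian decomposition.

library(lagoon)
dir.create("results", showWarnings = FALSE)

ex <- single_turnover_experiment(durations = c(0.03, 0.09, 0.18),
                                 n_traces = 500, seed = 1)

cat(sprintf("calibrated binding rate: k_on = %.4f uM^-1 s^-1\n",
            ex$kinetics$k_on))
cat("compound-step component weight by pulse duration:\n")
tab <- transform(ex$table, compound_pct = 100 * compound_fraction)
print(tab, row.names = FALSE)
cat(sprintf("reference (180 ms) mixture: mu = %.3f / %.3f, sigma = %.3f / %.3f\n",
            ex$reference$mean[1], ex$reference$mean[2],
            ex$reference$sigma[1], ex$reference$sigma[2]))

write.csv(tab, "results/single_turnover_summary.csv", row.names = FALSE)
sizes <- do.call(rbind, lapply(names(ex$runs), function(d)
  data.frame(duration = as.numeric(d), first_step = ex$runs[[d]]$sizes)))
write.csv(sizes, "results/single_turnover_first_steps.csv",
          row.names = FALSE)

# per-pulse turnover statistics of the underlying simulations
st <- do.call(rbind, lapply(names(ex$runs), function(d) {
  s <- ex$runs[[d]]$stats
  data.frame(duration = as.numeric(d), p0 = s$p0, p1 = s$p1,
             p_multi = s$p_multi,
             mean_per_pulse = s$mean_turnovers_per_pulse)
}))
write.csv(st, "results/single_turnover_pulse_stats.csv", row.names = FALSE)
cat("per-pulse turnover statistics:\n")
print(st, row.names = FALSE)
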