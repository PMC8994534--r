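#!/usr/bin/env Rscript
# Open-field locomotion (speed, thigmotaxis) of simulated agents and the
# stunted-growth classifier in two regimes: a clean wild-type baseline with
# mutant-confined stunting, and a mixed regime in which wt and het larvae
# carry stunting too. Writes results/openfield.csv and
# results/stunted_classification.csv.

library(zfsocial)

dir.create("results", showWarnings = FALSE)

## locomotor metrics over 20 asocial sessions
of <- do.call(rbind, lapply(1:20, function(s) {
  tbl <- simulate_agent(agent_params(), NULL, fps = 30, seed = 50 + s,
                        duration = 300)
  data.frame(seed = 50 + s, speed_mm_s = average_speed(tbl),
             thigmotaxis = as.numeric(thigmotaxis_index(tbl)))
}))
write.csv(of, "results/openfield.csv", row.names = FALSE)
cat(sprintf("open field (n = 20): speed %.2f +/- %.2f mm/s, thigmotaxis %.3f +/- %.3f\n",
            mean(of$speed_mm_s), sd(of$speed_mm_s),
            mean(of$thigmotaxis), sd(of$thigmotaxis)))

## stunted classifier
regimes <- list(
  mut_confined = generate_length_cohort(600, 1200, 600, stunt_shift = 3,
                                        stunt_rates = c(wt = 0, het = 0,
                                                        mut = 0.78), seed = 61),
  mixed = generate_length_cohort(600, 1200, 600, seed = 62))

rows <- list()
for (nm in names(regimes)) {
  cls <- classify_stunted(regimes[[nm]])
  for (g in c("wt", "het", "mut")) {
    sel <- cls$genotype == g
    rows[[paste(nm, g)]] <- data.frame(
      regime = nm, genotype = g, n = sum(sel),
      planted_frac = mean(cls$stunted_true[sel]),
      flagged_frac = mean(cls$stunted[sel]),
      threshold_mm = attr(cls, "threshold"))
  }
}
stun <- do.call(rbind, rows)
write.csv(stun, "results/stunted_classification.csv", row.names = FALSE)
print(stun, row.names = FALSE)
cat("\nmut-confined regime: flagged mutant fraction recovers the planted 78%;\n",
    "mixed regime: planted stunted wt inflate the wt SD, the threshold drops,\n",
    "and recovery falls -- the 1.5-SD rule assumes a mostly healthy baseline\n")
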