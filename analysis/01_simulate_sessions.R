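#!/usr/bin/env Rscript
# Simulate example sessions of every assay and write them as frame-stream
# CSVs (+ JSON sidecars) under results/sessions/. These files are the same
# format the downstream scoring scripts read, so the whole pipeline can be
# exercised from disk exactly as it would be on recorded data.

library(zfsocial)

out_dir <- "results/sessions"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

## Virtual biological-motion assay: a 4 mm dot on a knot path for 5 min,
## one solitary agent per attraction gain (asocial, weak, social, avoider).
stim <- simulate_knot_stimulus(knot_path_params(), stimulus_program(4),
                               fps = 30, seed = 1)
gains <- c(asocial = 0, weak = 1, social = 5, avoider = -20)
for (i in seq_along(gains)) {
  tbl <- simulate_agent(agent_params(k = gains[i]), stim, fps = 30, seed = 10 + i)
  write_frames(tbl, file.path(out_dir, sprintf("virtual_%s.csv", names(gains)[i])))
}
cat("virtual assay: 4 sessions,", nrow(stim), "frames each\n")

## Split dyad: social focal animal vs asocial partner, 5 + 5 min at 10 fps.
d <- simulate_dyad(agent_params(k = 10), agent_params(k = 0), seed = 21)
write_frames(d$A, file.path(out_dir, "dyad_focal.csv"))
write_frames(d$B, file.path(out_dir, "dyad_partner.csv"))
cat("dyad: divider removed at", d$t_divider_removed, "s\n")

## Looming session: six final sizes, both sides, one repetition (12 min).
sch <- build_schedule(c(0, 2, 4, 6, 8, 12), reps = 1, seed = 31)
ls <- simulate_loom_session(agent_params(), sch, seed = 32)
write_frames(ls$table, file.path(out_dir, "loom_session.csv"))
write.csv(ls$schedule$events, file.path(out_dir, "loom_schedule.csv"),
          row.names = FALSE)
cat("loom: ", nrow(ls$schedule$events), "events,",
    sum(ls$schedule$events$escaped_true), "planted escapes\n")

## Body-length cohort emulating a het-incross clutch series.
coh <- generate_length_cohort(600, 1200, 600, seed = 41)
write.csv(coh, file.path(out_dir, "length_cohort.csv"), row.names = FALSE)
cat("cohort:", nrow(coh), "animals,", sum(coh$stunted_true), "planted stunted\n")
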