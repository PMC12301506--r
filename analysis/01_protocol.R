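#!/usr/bin/env Rscript
# Stimulation protocol: the four median-nerve train types and one
# pseudorandom measurement run. Writes the train table and the block
# schedule used by the downstream steps.

library(megdot)
dir.create("results", showWarnings = FALSE)

trains <- do.call(rbind, lapply(c(0.5, 1, 2, 4), function(f) {
  tr <- make_stimulus_train(f)
  data.frame(frequency_hz = f, n_stimuli = tr$n_stimuli,
             isi_s = tr$isi, duration_s = tr$duration)
}))
write.csv(trains, "results/stimulus_trains.csv", row.names = FALSE)
print(trains)
message("every train spans ", unique(trains$duration_s),
        " s from first pulse onset to last pulse offset")

sch <- make_run_schedule(seed = 1)
write.csv(as.data.frame(sch), "results/run_schedule_seed1.csv",
          row.names = FALSE)
message(nrow(sch), " blocks per run (15 per frequency), total run length ",
        round(attr(sch, "duration") / 60, 1), " min; rests ",
        min(sch$rest_after), "-", max(sch$rest_after), " s")
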