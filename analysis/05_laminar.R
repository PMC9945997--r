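#!/usr/bin/env Rscript
# Laminar characterization of the simulated probe: stimulus-locked CSD,
# multiunit response latency per contact, layer assignment (input layer =
# early sink + fastest latency), and contact-count-normalized ripple rates
# per layer.

library(ripplepipe)
dir.create("results", showWarnings = FALSE)

cfg <- synthetic_config()
sim <- simulate_session(cfg, n_trials = 80, seed = 801)
rec <- sim$recordings$V1

avg <- trial_average(rec, sim$trials, pre_s = 0.1, post_s = 0.25)
csd <- compute_csd(avg)
lat <- response_latency(rec, sim$trials)
layers <- assign_layers(csd, lat, all_contact_ids = rec$contact_ids)
write_layers(layers, "results/layers.csv")

print(merge(layers$labels, lat, by = "contact_id"))
cat(sprintf("input layer: contacts %s (generator truth: %s)\n",
            paste(layers$labels$contact_id[layers$labels$label == "input"],
                  collapse = ","),
            paste(attr(rec, "true_input_contacts"), collapse = ",")))

ev <- detect_ripples(bipolar_rereference(rec))
ev <- assign_epochs(ev, sim$trials)
lr <- layer_ripple_rates(ev, layers, sim$trials,
                         canonical_epochs()$sustained)
print(lr, digits = 3)
write.csv(lr, "results/layer_rates.csv", row.names = FALSE)
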