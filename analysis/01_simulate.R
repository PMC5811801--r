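#!/usr/bin/env Rscript
# Generate the two synthetic study datasets with full ground truth and
# write them out in the package's standard text formats. Raw per-subject
# recordings are bulky and go under scratch/; small manifests and the
# truth records go under results/.

suppressMessages(library(scrlti))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1L

dir.create("scratch/datasets", showWarnings = FALSE, recursive = TRUE)
dir.create("results", showWarnings = FALSE)

message("Simulating the intraneural-recording study (exp1 style) ...")
cfg1 <- synth_config("exp1", seed = seed)
ds1 <- generate_dataset(cfg1)
message(sprintf("  %d subjects, %d events, hash %s",
                length(ds1$subjects), nrow(as.data.frame(ds1$schedule)),
                substr(dataset_hash(ds1), 1, 12)))

message("Simulating the intraneural-stimulation study (exp2 style) ...")
cfg2 <- synth_config("exp2", seed = seed)
ds2 <- generate_dataset(cfg2)
message(sprintf("  %d subjects, %d stimulation epochs, %d stimulations, hash %s",
                length(ds2$subjects), nrow(ds2$epochs),
                nrow(as.data.frame(ds2$schedule)),
                substr(dataset_hash(ds2), 1, 12)))

files <- character(0)
for (ds in list(ds1, ds2)) {
  tag <- ds$style
  write_events_csv(ds$schedule, sprintf("scratch/datasets/%s_events.csv", tag))
  files <- c(files, sprintf("%s_events.csv", tag))
  for (s in names(ds$subjects)) {
    for (ch in names(ds$subjects[[s]])) {
      path <- sprintf("scratch/datasets/%s_%s_%s.csv", tag, s, ch)
      write_timeseries_csv(ds$subjects[[s]][[ch]], path)
      files <- c(files, basename(path))
    }
  }
  yaml::write_yaml(
    list(theta = lapply(ds$truth$theta, unclass),
         bursts = lapply(ds$truth$bursts, unclass)),
    sprintf("scratch/datasets/%s_truth.yaml", tag))
  utils::write.csv(ds$truth$gains,
                   sprintf("scratch/datasets/%s_truth_gains.csv", tag),
                   row.names = FALSE)
}

manifest <- list(
  seed = seed,
  exp1 = list(hash = dataset_hash(ds1), subjects = length(ds1$subjects),
              events = nrow(as.data.frame(ds1$schedule))),
  exp2 = list(hash = dataset_hash(ds2), subjects = length(ds2$subjects),
              epochs = nrow(ds2$epochs),
              stimulations = nrow(as.data.frame(ds2$schedule))),
  files = files
)
jsonlite::write_json(manifest, "results/simulation_manifest.json",
                     auto_unbox = TRUE, pretty = TRUE)
message("Wrote scratch/datasets/ and results/simulation_manifest.json")
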