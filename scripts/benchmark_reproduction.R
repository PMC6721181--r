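#!/usr/bin/env Rscript
# Optional reproduction on the public UCI gas-sensor-array drift benchmark.
#
# The benchmark is NOT bundled (it must be downloaded manually from the UCI
# machine-learning repository: "Gas Sensor Array Drift Dataset", 10 files
# batch1.dat .. batch10.dat, libsvm-style sparse text, 128 features,
# 6 classes). Point --data at the directory holding those files:
#
#   Rscript scripts/benchmark_reproduction.R --data /path/to/driftdataset
#
# Runs the long-term protocol with the dynamic-clustering error-reduction
# selector at a budget of 20 labels per batch and prints per-batch and
# average accuracies. Expect an average in the low 90s (%); exact values
# depend on the pool/test split seed.

suppressPackageStartupMessages({
  library(optparse)
  library(driftal)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--data", type = "character"),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--n_select", type = "integer", default = 20L),
  make_option("--strategy", type = "character", default = "aldc_er")
)))

if (is.null(opts$data) || !dir.exists(opts$data))
  stop("--data must point at the downloaded benchmark directory")
files <- file.path(opts$data, paste0("batch", 1:10, ".dat"))
if (!all(file.exists(files)))
  stop("expected batch1.dat .. batch10.dat under ", opts$data)

batches <- lapply(1:10, function(i)
  read_batch_file(files[i], dimension = 128, batch_id = i))
seq <- drift_batch_seq(batches)

cfg <- run_config(strategy = opts$strategy, n_select = opts$n_select,
                  normalize = TRUE, eval_each_step = FALSE,
                  metric = list(loss = "log", pool_cap = 200L),
                  seed = opts$seed)
res <- run_setting1(seq, cfg)
print(res$batch_results)
cat(sprintf("average accuracy (%s, N=%d): %.2f%%\n", opts$strategy,
            opts$n_select, 100 * mean(res$batch_results$accuracy)))
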