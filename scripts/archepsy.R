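#!/usr/bin/env Rscript
# Thin command-line wrapper over the archepsy package.
#
#   Rscript scripts/archepsy.R simulate  --out <dir> [--seed N] [--subjects N] [--duration S] [--effect E]
#   Rscript scripts/archepsy.R run-all   --out <dir> [--seed N] [--subjects N] [--duration S] [--effect E]
#   Rscript scripts/archepsy.R compare   --features <tsv> --sam <tsv> --out <dir> [--seed N]
#
# `simulate` writes raw channel tables plus a manifest; `run-all` executes
# the full pipeline into a run directory; `compare` reruns the triplet
# comparisons from saved feature/SAM tables.

suppressPackageStartupMessages(library(archepsy))

args <- commandArgs(trailingOnly = TRUE)
if (!length(args)) stop("usage: archepsy.R <simulate|run-all|compare> ...")
cmd <- args[1]
args <- args[-1]

get_opt <- function(flag, default = NULL) {
  i <- which(args == flag)
  if (!length(i)) return(default)
  args[i + 1]
}
num <- function(x) if (is.null(x)) NULL else as.numeric(x)

seed <- as.integer(get_opt("--seed", "1"))
out <- get_opt("--out", "archepsy_run")

if (cmd == "simulate") {
  cfg <- cohort_config(
    n_subjects = as.integer(get_opt("--subjects", "25")),
    stimulus_duration = num(get_opt("--duration", "300")),
    effect_size = num(get_opt("--effect", "1")),
    seed = seed)
  write_cohort(generate_cohort(cfg), out)
  cat("cohort written to", out, "\n")
} else if (cmd == "run-all") {
  cfg <- study_config(
    n_subjects = as.integer(get_opt("--subjects", "25")),
    stimulus_duration = num(get_opt("--duration", "300")),
    effect_size = num(get_opt("--effect", "1")),
    seed = seed)
  st <- run_study(cfg, out_dir = out, verbose = TRUE)
  print(st)
} else if (cmd == "compare") {
  features <- read_feature_matrix(get_opt("--features"))
  sam <- read.table(get_opt("--sam"), header = TRUE, sep = "\t")
  res <- run_comparisons(features, sam, seed = seed)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  write.table(res$comparisons, file.path(out, "comparisons.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(res$group_summary, file.path(out, "group_summary.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(res$groups, file.path(out, "groups.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  print(res$comparisons)
} else {
  stop("unknown command: ", cmd)
}
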