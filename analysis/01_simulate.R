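#!/usr/bin/env Rscript
# Stage 1: simulate a FAERS-like spontaneous-report database with one
# planted drug-event association, and write it in the three-table layout.
#
# The generated database mimics the structure the screen consumes: 50,000
# reports over the packaged 21-drug antihypertensive vocabulary and the
# five urate-related study PTs plus ten background PTs. One association is
# planted — furosemide reports carry hyperuricaemia at five times the
# 0.002 background reporting probability — so the downstream screen has a
# known ground truth to recover.
#
#   Rscript analysis/01_simulate.R [--seed <int>] [--out <dir>]

suppressPackageStartupMessages({
  library(prrscreen)
  library(jsonlite)
})

args <- commandArgs(trailingOnly = TRUE)
opt <- list(seed = 20240801L, out = "results/synthetic")
i <- 1
while (i <= length(args)) {
  if (args[i] == "--seed") { opt$seed <- as.integer(args[i + 1]); i <- i + 2 }
  else if (args[i] == "--out") { opt$out <- args[i + 1]; i <- i + 2 }
  else stop("unknown argument: ", args[i])
}

vocab <- load_vocabulary(prrscreen_example("antihypertensives.yaml"))
study_pts <- c("Hyperuricaemia", "Gout", "Gouty arthritis", "Gouty tophus",
               "Urate nephropathy")
noise_pts <- c("Nausea", "Headache", "Dizziness", "Fatigue", "Rash",
               "Cough", "Pyrexia", "Vomiting", "Arthralgia", "Insomnia")
planted <- data.frame(drug = "furosemide", pt = "Hyperuricaemia", lambda = 5)

cfg <- synthetic_config(
  n_reports = 50000,
  vocab = vocab,
  pt_catalog = c(study_pts, noise_pts),
  background_event_prob = 0.002,
  planted = planted,
  duplicate_case_prob = 0.05,
  seed = opt$seed
)

message("generating ", cfg$n_reports, " reports (seed ", opt$seed, ") ...")
rs <- generate_reports(cfg)
print(rs)

write_report_tables(rs, opt$out)
write_json(
  list(seed = opt$seed, n_reports = cfg$n_reports,
       background_event_prob = 0.002,
       planted = planted,
       expected_prr = expected_prr(cfg, "furosemide", "Hyperuricaemia")),
  file.path(opt$out, "truth.json"), auto_unbox = TRUE, digits = NA)

message("wrote demo.csv, drug.csv, reac.csv and truth.json under ", opt$out)
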