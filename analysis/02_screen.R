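#!/usr/bin/env Rscript
# Stage 2: the full disproportionality screen over the simulated database.
#
# Reads the three-table database written by stage 1, deduplicates to one
# record per case, screens every (drug, event) pair with PRR / chi-squared
# and the Evans criterion, and writes per-event signal tables, the
# cross-event overlap table, per-event demographic overviews, and a run
# manifest. The planted furosemide-hyperuricaemia pair should emerge as a
# positive signal with PRR near the planted multiplier of 5; unplanted
# pairs should almost all stay negative.
#
#   Rscript analysis/02_screen.R [--in <dir>] [--out <dir>] [--no-yates]

suppressPackageStartupMessages({
  library(prrscreen)
  library(jsonlite)
})

args <- commandArgs(trailingOnly = TRUE)
opt <- list(input = "results/synthetic", out = "results/screen",
            yates = TRUE)
i <- 1
while (i <= length(args)) {
  if (args[i] == "--in") { opt$input <- args[i + 1]; i <- i + 2 }
  else if (args[i] == "--out") { opt$out <- args[i + 1]; i <- i + 2 }
  else if (args[i] == "--no-yates") { opt$yates <- FALSE; i <- i + 1 }
  else stop("unknown argument: ", args[i])
}
dir.create(opt$out, recursive = TRUE, showWarnings = FALSE)

vocab <- load_vocabulary(prrscreen_example("antihypertensives.yaml"))
events <- load_event_definitions(prrscreen_example("events.yaml"))

rs <- read_report_tables(file.path(opt$input, "demo.csv"),
                         file.path(opt$input, "drug.csv"),
                         file.path(opt$input, "reac.csv"))
message("reports read: ", n_reports(rs))
rs <- deduplicate(rs)
message("after deduplication: ", n_reports(rs), " cases")

res <- run_screen(rs, vocab, events, yates = opt$yates)
print(res)

for (lab in names(res$per_event)) {
  rows <- group_by_class(res, vocab, lab, positives_only = FALSE)
  write_signal_table(rows,
                     file.path(opt$out, paste0("signals_",
                                               gsub(" ", "_", lab),
                                               ".csv")))
}
write_overlap_table(res, file.path(opt$out, "overlap.csv"))
write_overview_table(lapply(events, function(ev) summarize_event(rs, ev)),
                     file.path(opt$out, "overview.csv"))

# compare the screen's estimate for the planted pair with the generator's
# ground truth, if stage 1 left one
truth_path <- file.path(opt$input, "truth.json")
if (file.exists(truth_path)) {
  truth <- read_json(truth_path, simplifyVector = TRUE)
  pe <- res$per_event[["hyperuricaemia"]]
  hit <- pe[pe$drug == truth$planted$drug, ]
  message(sprintf(
    "planted pair %s / hyperuricaemia: N=%d PRR=%.2f chi2=%.1f positive=%s (expected PRR %.2f)",
    truth$planted$drug, hit$n_cases, hit$prr, hit$chi2, hit$positive,
    truth$expected_prr))
}

manifest <- list(
  inputs = normalizePath(file.path(opt$input, c("demo.csv", "drug.csv",
                                                "reac.csv"))),
  input_md5 = unname(tools::md5sum(file.path(opt$input,
                                             c("demo.csv", "drug.csv",
                                               "reac.csv")))),
  vocabulary = "antihypertensives.yaml",
  events = "events.yaml",
  yates = opt$yates,
  n_reports = n_reports(rs),
  positives = lapply(names(res$per_event),
                     function(l) count_positive(res, l)) |>
    setNames(names(res$per_event))
)
write_json(manifest, file.path(opt$out, "manifest.json"),
           auto_unbox = TRUE, digits = NA, pretty = TRUE)
message("outputs written under ", opt$out)
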