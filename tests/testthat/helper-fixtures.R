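# Fixtures are built in code: a small drug vocabulary, event definitions,
# and random report sets sampled with base R so they are independent of the
# package's own generator.

write_tiny_vocab <- function(path = tempfile(fileext = ".yaml")) {
  writeLines(c(
    "class_order: [Diuretics, Beta blockers, Compound preparations]",
    "drugs:",
    "  - canonical: furosemide",
    "    class: Diuretics",
    "    synonyms: [Lasix, FUROSEMIDE 40MG]",
    "  - canonical: metoprolol",
    "    class: Beta blockers",
    "    synonyms: [Lopressor]",
    "  - canonical: Hyzaar (losartan potassium and hydrochlorothiazide)",
    "    class: Compound preparations",
    "    synonyms: [Hyzaar]"
  ), path)
  path
}

tiny_vocab <- function() load_vocabulary(write_tiny_vocab())

gout_event <- function() event_definition("gout", c("Gout", "Gouty arthritis"))

# random report set over the tiny vocabulary's names (verbatim variants and
# junk names included), sampled with plain base R
random_report_set <- function(n, seed, p_drug = 0.4, p_pt = 0.3) {
  set.seed(seed)
  names_pool <- c("furosemide", "Lasix", "FUROSEMIDE 40MG", "metoprolol",
                  "Lopressor", "Hyzaar", "notadrug", "aspirin")
  pt_pool <- c("Gout", "Gouty arthritis", "Nausea", "Headache")
  ids <- sprintf("R%04d", seq_len(n))
  demo <- tibble::tibble(
    report_id = ids,
    case_id = ids,
    version = 1L,
    sex = sample(c("male", "female", "unknown"), n, replace = TRUE),
    age_value = ifelse(runif(n) < 0.3, NA, sample(1:90, n, replace = TRUE)),
    age_unit = NA_character_,
    country = sample(c("US", "JP", NA), n, replace = TRUE)
  )
  demo$age_unit[!is.na(demo$age_value)] <- "years"
  drugs <- do.call(rbind, lapply(seq_len(n), function(i) {
    k <- 1 + rbinom(1, 3, p_drug)
    data.frame(report_id = ids[i],
               drug_name = sample(names_pool, k, replace = TRUE))
  }))
  reac <- do.call(rbind, lapply(seq_len(n), function(i) {
    k <- rbinom(1, 3, p_pt)
    if (k == 0) return(NULL)
    data.frame(report_id = ids[i],
               pt = sample(pt_pool, k, replace = TRUE))
  }))
  if (is.null(reac)) {
    reac <- data.frame(report_id = character(), pt = character())
  }
  report_set(demo, drugs, reac, provenance = "test fixture")
}

# three-table CSVs for a small hand-written database
write_demo_fixture <- function(dir = tempfile()) {
  dir.create(dir)
  writeLines(c(
    "report_id,case_id,version,sex,age_value,age_unit,country",
    "R1,C1,1,male,63,years,US",
    "R2,C2,1,female,17,years,JP",
    "R3,C3,2,unknown,,,"
  ), file.path(dir, "demo.csv"))
  writeLines(c(
    "report_id,drug_name",
    "R1,Lasix",
    "R1,metoprolol",
    "R2,FUROSEMIDE 40MG",
    "R3,Hyzaar"
  ), file.path(dir, "drug.csv"))
  writeLines(c(
    "report_id,pt",
    "R1,Gout",
    "R2,Nausea",
    "R2,Gouty arthritis"
  ), file.path(dir, "reac.csv"))
  dir
}

study_pts <- c("Hyperuricaemia", "Gout", "Gouty arthritis", "Gouty tophus",
               "Urate nephropathy")
noise_pts <- c("Nausea", "Headache", "Dizziness", "Fatigue", "Rash",
               "Cough", "Pyrexia", "Vomiting", "Arthralgia", "Insomnia")

example_vocab <- function() {
  load_vocabulary(prrscreen_example("antihypertensives.yaml"))
}
example_events <- function() {
  load_event_definitions(prrscreen_example("events.yaml"))
}
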