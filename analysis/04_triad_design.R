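#!/usr/bin/env Rscript
# Stage 4 — stimulus design.
#
# Kin-discrimination triads (parent target, offspring match, age/sex/
# lighting-matched decoy unrelated for two generations) and individual-
# discrimination triads (frontal target, 45-degree view of the same animal,
# matched decoy), then one restricted-randomized 44-trial session per
# participant. The validator re-checks every constraint independently.

library(kinfaces)

ped <- read_pedigree("results/pedigree.tsv")
inventory <- read.delim("results/inventory.tsv", stringsAsFactors = FALSE)
inventory$photo_date <- as.Date(inventory$photo_date)

kd <- build_kd_triads(ped, inventory, n_per_condition = 8L,
                      shared_targets = 5L, seed = 3)
used <- unique(c(kd$target_id, kd$match_id, kd$decoy_id))
id <- build_id_triads(ped, inventory, exclude = used, seed = 3)

n_participants <- 59L
schedules <- lapply(seq_len(n_participants), function(i) {
  randomize_session(kd, id, sprintf("P%03d", i), seed = 100L + i)
})

violations <- validate_design(kd, id, schedules, ped, inventory)
stopifnot(length(violations) == 0)

if (requireNamespace("jsonlite", quietly = TRUE)) {
  jsonlite::write_json(list(kd = kd, id = id), "results/triads.json",
                       dataframe = "rows", pretty = TRUE)
}
write.table(do.call(rbind, schedules), "results/sessions.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("KD triads: %d (8 per condition), distinct animals: %d\n",
            nrow(kd), length(used)))
cat(sprintf("ID triads: %d (%s)\n", nrow(id),
            paste(names(table(id$condition)), table(id$condition),
                  collapse = ", ", sep = "=")))
cat(sprintf("Sessions: %d x 44 trials, validator violations: %d\n",
            n_participants, length(violations)))
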