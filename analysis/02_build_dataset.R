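#!/usr/bin/env Rscript
# Window the simulated visit histories into train/test samples: prune
# everything before any inter-visit gap over three years, then form up to
# four training input-output pairs per visitor (inputs of at most five
# consecutive visits, output the next visit) and one test pair ending at
# the final visit. Writes the audit manifest and the visit-count tally.

library(nextvisit)

cohort <- read_cohort("scratch/analysis/cohort/visits.csv")
ds <- assemble_dataset(cohort, window_config(n1 = 5, n2 = 4,
                                             max_gap_years = 3))
saveRDS(ds, "scratch/analysis/dataset.rds")
write_sample_manifest(ds, "scratch/analysis/sample_manifest.csv")

tally <- as.data.frame(ds$tally)
write.csv(tally, "results/sample_tally.csv", row.names = FALSE)

cat(sprintf("visits surviving gap pruning: %d of %d\n",
            nrow(ds$visits), nrow(cohort)))
cat(sprintf("train samples: %d, test samples: %d\n",
            sum(ds$samples$split == "train"),
            sum(ds$samples$split == "test")))
print(ds$tally)
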