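#!/usr/bin/env Rscript
# Stage 2: inclusion criteria, nominal encoding, complete-case filtering.
#
# Applies the ordered criteria (visit code -> age 53-95 -> Hispanic/Latino
# -> column pruning), encodes diagnosis/gender/marital status to nominal
# codes, removes incomplete rows, and writes the cleaned table plus the
# per-criterion drop report and per-group mean/SD summaries.

library(cogstage)

raw <- read_cohort("results/raw_cohort.csv")
fl <- apply_inclusion_criteria(raw)
enc <- encode_and_complete(fl$cohort, fl$report)

write_cohort(enc$cohort, "results/original_dataset.csv", enc$report,
             "results/inclusion_report.json")
utils::write.csv(summarize_groups(enc$cohort),
                 "results/group_summaries.csv", row.names = FALSE)

rep <- enc$report
cat(sprintf("Input rows:            %d\n", rep$n_input))
cat(sprintf("After criteria:        %d  (drops: viscode=%d age=%d ethnicity=%d)\n",
            rep$n_after_criteria, rep$per_criterion_drops["viscode"],
            rep$per_criterion_drops["age"],
            rep$per_criterion_drops["ethnicity"]))
cat(sprintf("Complete cases:        %d  (%d features)\n", rep$n_final,
            length(enc$cohort$feature_names)))
print(enc$cohort)
cat("Wrote results/original_dataset.csv, inclusion_report.json,",
    "group_summaries.csv\n")
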