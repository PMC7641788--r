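#!/usr/bin/env Rscript

# Step 2: learn per-nutrient upper limits per food portion on the T1
# training phase, then clean the held-out T2 phase.
#
# For each nutrient the candidate limit sweeps upward; at each candidate
# the app values above it are excluded and the participant-level
# correlation between app and reference daily intakes is recomputed. The
# limit maximizing that correlation (ties to the largest candidate,
# i.e. fewest removals) is kept and applied to T2: app values above it
# become missing.

library(nutripair)

cohort <- read_diary_csv("results/cohort.csv")
t1 <- cohort[cohort$phase == "T1", ]
t2 <- cohort[cohort$phase == "T2", ]

limits <- learn_limits(t1)
cat("learned upper limits per food portion (T1 training):\n")
for (i in seq_len(nrow(limits))) {
  cat(sprintf("  %-13s %8.0f %-4s (%s)\n", limits$nutrient[i],
              limits$limit[i], limits$unit[i], limits$assoc[i]))
}

res <- apply_limits(t2, limits)
rep <- res$report
cat(sprintf("\ncleaning T2 removed values from %d of %d items (%.1f%%)\n",
            rep$n_items_affected, rep$total_items,
            100 * rep$fraction_items_affected))
print(as.data.frame(rep$per_nutrient), row.names = FALSE)

write_limits(limits, "results/limits.csv")
utils::write.csv(as.data.frame(rep$per_nutrient),
                 "results/cleaning_report.csv", row.names = FALSE)
write_diary_csv(res$entries, "results/cohort_t2_cleaned.csv")
cat("wrote results/limits.csv, results/cleaning_report.csv, results/cohort_t2_cleaned.csv\n")
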