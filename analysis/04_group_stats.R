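#!/usr/bin/env Rscript

# Stage 4: group-level inference.
#
# (a) Three-way mixed ANOVA of per-epoch ASPL (Group between; Condition and
#     Time within), on the untransformed long table from stage 2.
# (b) Behavioral monotone proportions per group, compared with Fisher's
#     exact test.
# (c) Pooled edge-weight distributions per group x condition; the
#     lower-coupling patient group should sit left of the controls.

suppressMessages({
  library(monoconn)
  library(dplyr)
})

aspl_tab <- read.delim("scratch/metrics/aspl_metrics.tsv")
edges <- read.delim("scratch/metrics/edges.tsv")
cohort <- read_cohort("scratch/cohort_demo")

## (a) mixed ANOVA -------------------------------------------------------
an <- aspl_anova(aspl_tab)
write.table(an, "results/aspl_anova.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("three-way mixed ANOVA of ASPL:\n")
print(as.data.frame(an))
cat(sprintf("\nGroup effect: F(%d, %d) = %.2f, p = %.3g\n",
            an$df_num[an$effect == "Group"], an$df_den[an$effect == "Group"],
            an$F[an$effect == "Group"], an$p_value[an$effect == "Group"]))

## (b) behavioral monotonicity -------------------------------------------
beh <- bind_rows(lapply(cohort$participants, function(p) {
  v <- classify_monotonicity(rowMeans(p$behavior))
  tibble::tibble(participant = p$participant_id, group = p$group,
                 monotone = v$direction == "increasing")
}))
counts <- beh |>
  group_by(group) |>
  summarise(n = n(), k_monotone = sum(monotone),
            pct_monotone = 100 * mean(monotone), .groups = "drop")
ft <- monotonic_proportion_test(
  counts$k_monotone[counts$group == "control"],
  counts$n[counts$group == "control"],
  counts$k_monotone[counts$group == "patient"],
  counts$n[counts$group == "patient"])
write.table(counts, "results/behavior_counts.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nbehavioral monotone proportions (control should exceed patient):\n")
print(as.data.frame(counts))
cat(sprintf("Fisher's exact test: OR = %.2f, p = %.3g\n",
            ft$odds_ratio, ft$p_value))

## (c) edge-weight distributions -----------------------------------------
ews <- edge_weight_summary(edges[, c("group", "condition", "z")])
write.table(ews$summary, "results/edge_weight_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
shift <- ews$summary |>
  group_by(condition) |>
  summarise(control_minus_patient =
              mean[group == "control"] - mean[group == "patient"],
            .groups = "drop")
cat("\nmean Fisher-Z edge weight, control minus patient, by condition\n")
cat("(positive = leftward patient shift):\n")
print(as.data.frame(shift))
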