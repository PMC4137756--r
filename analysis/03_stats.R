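#!/usr/bin/env Rscript
# Step 3: inferential statistics on the freezing effects.
#
# Within each group, one-sample t-tests ask whether the log10 ratios differ
# from 0 (no freezing effect), Holm-adjusted within each group x measure
# family of 6 cells (3 joints x 2 directions). Group differences are
# assessed per cell with a Type-II Group x Lab ANOVA (controlling the
# group/lab confound of the split design); only the Group effect is kept.

library(bowfreeze)

eff <- utils::read.delim("results/freeze_effects.tsv", comment.char = "#")
st <- freeze_stats(eff)

write_result_table(st$t_tests, "results/stats_t_tests.tsv")
write_result_table(st$group_anova, "results/stats_group_anova.tsv")

sig <- subset(st$t_tests, p_adj < 0.05)
cat(sprintf("one-sample t-tests: %d of %d cells significant after Holm\n",
            nrow(sig), nrow(st$t_tests)))
cat("\nsignificant freezing effects (per group):\n")
print(sig[order(sig$group, sig$measure, sig$joint),
          c("group", "joint", "measure", "direction",
            "mean_log10_ratio", "t", "df", "p_adj")],
      digits = 3, row.names = FALSE)

siga <- subset(st$group_anova, p_adj < 0.05)
cat(sprintf("\ngroup comparisons: %d of %d cells significant after Holm\n",
            nrow(siga), nrow(st$group_anova)))
cat("tables written to results/stats_t_tests.tsv / stats_group_anova.tsv\n")
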