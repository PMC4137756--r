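#!/usr/bin/env Rscript
# Step 4: figure-style summaries of the freezing effects.
#
# One bar chart per performance measure: mean log10 surrogate/original
# ratio per joint x bow direction, split by group, error bars = SE across
# participants (the layout used to report freezing analyses).

library(bowfreeze)
library(ggplot2)

eff <- utils::read.delim("results/freeze_effects.tsv", comment.char = "#")
dir.create("results/figures", recursive = TRUE, showWarnings = FALSE)

summ <- aggregate(log10_ratio ~ group + joint + measure + direction, eff,
                  function(x) c(mean = mean(x), se = sd(x) / sqrt(length(x))))
summ <- cbind(summ[1:4], as.data.frame(summ$log10_ratio))
summ$joint <- factor(summ$joint, c("shoulder", "elbow", "wrist"))

for (m in unique(summ$measure)) {
  d <- subset(summ, measure == m)
  p <- ggplot(d, aes(joint, mean, fill = direction)) +
    geom_col(position = position_dodge(0.9)) +
    geom_errorbar(aes(ymin = mean - se, ymax = mean + se),
                  width = 0.25, position = position_dodge(0.9)) +
    geom_hline(yintercept = 0, linewidth = 0.3) +
    facet_wrap(~group) +
    labs(title = sprintf("Freezing effect on %s", m),
         x = "frozen joint",
         y = "log10(surrogate / original)") +
    theme_minimal()
  out <- file.path("results/figures", paste0("freeze_", m, ".png"))
  ggsave(out, p, width = 7, height = 4, dpi = 150)
  cat("wrote", out, "\n")
}
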