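#!/usr/bin/env Rscript
# Stage 4: group-level statistics on the cohort accuracies.
#
# Per region x hemisphere: one-tailed one-sample t-test against the 1/3
# chance level.  Across regions: paired left-right t-tests and the
# 2 (hemisphere) x 3 (region) repeated-measures ANOVA whose interaction is
# the signature of a unilateral non-decodable hippocampus.  Accuracy is
# also correlated (Pearson) with left-HC volume.  Writes summary tables and
# a mean +/- SEM figure with the chance line.

library(mtlmvpa)

acc <- read.csv("results/accuracies.csv")
gs <- group_statistics(acc)

summ <- do.call(rbind, lapply(split(acc, list(acc$region, acc$hemisphere)),
  function(d) data.frame(region = d$region[1], hemisphere = d$hemisphere[1],
                         mean_accuracy = mean(d$accuracy),
                         mean_accuracy_pct = 100 * mean(d$accuracy),
                         sem = sd(d$accuracy) / sqrt(nrow(d)))))
rownames(summ) <- NULL
write.csv(summ, "results/summary.csv", row.names = FALSE)

report <- list(
  vs_chance = lapply(gs$vs_chance, function(t)
    if (is.null(t)) NULL else list(t = t$statistic, df = t$df, p = t$p)),
  paired_lr = lapply(gs$pairwise_lr, function(t)
    if (is.null(t)) NULL else list(t = t$statistic, df = t$df, p = t$p)),
  anova = list(
    hemisphere = list(F = gs$anova$hemisphere$statistic,
                      p = gs$anova$hemisphere$p),
    region = list(F = gs$anova$region$statistic, p = gs$anova$region$p),
    interaction = list(F = gs$anova$interaction$statistic,
                       df = gs$anova$interaction$df,
                       p = gs$anova$interaction$p)),
  volume_cor = if (is.null(gs$volume_cor)) NULL else
    list(r = gs$volume_cor$r, p = gs$volume_cor$p))
jsonlite::write_json(report, "results/group_stats.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)

message("-- accuracy vs chance (1/3), one-tailed t --")
for (nm in names(gs$vs_chance))
  if (!is.null(gs$vs_chance[[nm]]))
    message(sprintf("  %-6s t(%d) = %6.2f, p = %.4g", nm,
                    gs$vs_chance[[nm]]$df, gs$vs_chance[[nm]]$statistic,
                    gs$vs_chance[[nm]]$p))
message(sprintf("hemisphere x region interaction: F(%g, %g) = %.3f, p = %.4g",
                gs$anova$interaction$df[1], gs$anova$interaction$df[2],
                gs$anova$interaction$statistic, gs$anova$interaction$p))
if (!is.null(gs$pairwise_lr$HC))
  message(sprintf("paired HC L vs R: t(%d) = %.3f, p = %.4g",
                  gs$pairwise_lr$HC$df, gs$pairwise_lr$HC$statistic,
                  gs$pairwise_lr$HC$p))
if (!is.null(gs$volume_cor))
  message(sprintf("left-HC accuracy ~ volume: r = %.3f, p = %.3g",
                  gs$volume_cor$r, gs$volume_cor$p))

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  summ$region <- factor(summ$region, levels = c("HC", "EPC", "PHC"))
  p <- ggplot(summ, aes(region, mean_accuracy, fill = hemisphere)) +
    geom_col(position = position_dodge(0.8), width = 0.7) +
    geom_errorbar(aes(ymin = mean_accuracy - sem,
                      ymax = mean_accuracy + sem),
                  position = position_dodge(0.8), width = 0.2) +
    geom_hline(yintercept = 1 / 3, linetype = "dashed") +
    labs(y = "classification accuracy", x = NULL,
         title = "Decoding accuracy per MTL region (mean ± SEM)",
         subtitle = "dashed line: 1/3 chance; left HC simulated sclerotic") +
    theme_minimal()
  dir.create("scratch", showWarnings = FALSE)
  ggsave("scratch/fig_accuracy.pdf", p, width = 6, height = 4)
  message("figure written to scratch/fig_accuracy.pdf")
}
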