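#!/usr/bin/env Rscript
# Learning-curve figure: mean sqrt-SCR to CS+ and CS- per trial, phase and
# age group (reads the profile written by 04_fit_models.R).

suppressPackageStartupMessages({
  library(ggplot2)
})

prof <- read.csv("results/phase_profile.csv")
prof$phase <- factor(prof$phase, levels = c("habituation", "acquisition",
                                            "extinction", "retention"))
prof$group <- factor(prof$group, levels = c("child", "adolescent", "adult"))

p <- ggplot(prof, aes(trial_index, mean_scr_sqrt,
                      colour = trial_type, group = trial_type)) +
  geom_line() +
  geom_pointrange(aes(ymin = mean_scr_sqrt - se, ymax = mean_scr_sqrt + se),
                  size = 0.2) +
  facet_grid(group ~ phase, scales = "free_x", space = "free_x") +
  scale_colour_manual(values = c("CS+" = "#c0392b", "CS-" = "#2980b9")) +
  labs(x = "trial", y = expression(sqrt(SCR) ~ (sqrt(mu * S))),
       colour = NULL,
       title = "Differential conditioning across phases and age groups") +
  theme_minimal(base_size = 10) +
  theme(legend.position = "bottom")

ggsave("results/fig_learning_curves.pdf", p, width = 9, height = 6)
cat("wrote results/fig_learning_curves.pdf\n")
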