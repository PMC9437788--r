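#!/usr/bin/env Rscript
# Plot mean weekly log-in days per recovered trajectory group (the
# tabular version is written by analysis/02_cluster.R as
# group_summary.csv). Requires ggplot2; writes PDFs under results/<arm>/.

library(engtraj)
library(ggplot2)

for (arm in c("icanquit", "quitguide")) {
  path <- file.path("results", arm, "group_summary.csv")
  if (!file.exists(path)) stop("run analysis/02_cluster.R first")
  summ <- utils::read.csv(path, check.names = FALSE)
  weeks <- grep("^week", names(summ), value = TRUE)
  long <- data.frame(
    group = rep(sprintf("%s (%.1f%%)", summ$group, 100 * summ$share),
                times = length(weeks)),
    week = rep(seq_along(weeks), each = nrow(summ)),
    logins = unlist(summ[weeks], use.names = FALSE)
  )
  p <- ggplot(long, aes(week, logins, colour = group)) +
    geom_line(linewidth = 0.8) +
    geom_point(size = 1.2) +
    scale_y_continuous(limits = c(0, 7), breaks = 0:7) +
    labs(
      x = "Week since randomization", y = "Mean log-in days per week",
      colour = NULL,
      title = sprintf("Mean weekly log-ins by trajectory group (%s arm)", arm)
    ) +
    theme_minimal() +
    theme(legend.position = "bottom")
  out <- file.path("results", arm, "weekly_logins.pdf")
  ggsave(out, p, width = 7, height = 4.5)
  cat("wrote", out, "\n")
}
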