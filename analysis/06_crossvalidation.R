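#!/usr/bin/env Rscript
## Leave-one-plot-out cross-validation of both model families: each plot
## is held out in turn, the model refit, and the held-out plot predicted
## with the random effect at its population mean. Static model scored on
## log N; mortality model on count, count per ha, and per-tree rate.

library(selfthin)

per <- utils::read.csv("results/data/periods_filtered.csv",
                       stringsAsFactors = FALSE)
plots <- utils::read.csv("results/data/plots.csv", stringsAsFactors = FALSE)
per <- per[per$retained, ]

ctrl <- control_plots(per, plots)
dat <- per[per$plot_id %in% ctrl, ]
dat <- data.frame(plot_id = dat$plot_id, D = dat$D_start, N = dat$N_start,
                  mat_longterm = dat$mat_longterm)
cat("Static model:", length(ctrl), "control-plot folds...\n")
cv_s <- loo_plot_cv(dat, "static")
print(cv_s$pooled$logN)

cat("\nMortality model:", length(unique(per$plot_id)), "folds",
    "(this refits the GLMM once per plot)...\n")
cv_m <- loo_plot_cv(per, "composite")
for (m in cv_m$pooled) print(m)

rows <- do.call(rbind, lapply(c(cv_s$pooled, cv_m$pooled), function(m)
  data.frame(response = m$response_label, r2 = m$r2, rmse = m$rmse,
             bias = m$bias, n = m$n)))
utils::write.csv(rows, "results/crossvalidation.csv", row.names = FALSE)
cat("Wrote results/crossvalidation.csv\n")
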