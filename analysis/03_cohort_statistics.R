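#!/usr/bin/env Rscript
# Step 3: aggregate fiber fits to hearts and run the group comparisons.
#
# QC-passing fibers are averaged per heart; control vs IUGR contrasts are
# computed for SL, ABL and TTIL with both the paired t-test and a classical
# one-way ANOVA, at each age stage. Outputs a heart summary table and a
# results table shaped like the study's prose summary (variable, age,
# control mean +/- SD, IUGR mean +/- SD, p).

suppressMessages({
  library(sarcomorph)
  library(dplyr)
})

all_rows <- list()
for (age in c("fetal", "adult")) {
  fits <- read_table_csv(sprintf("results/%s_fiber_fits.csv", age))
  hearts <- summarize_hearts(fits[fits$qc_pass, ])
  write_table_csv(hearts, sprintf("results/%s_heart_summaries.csv", age))

  for (v in c("sl_um", "abl_um", "ttil_um")) {
    for (tst in c("paired_t", "anova")) {
      cmp <- compare_groups(hearts, v, tst)
      cmp$age <- age
      all_rows[[length(all_rows) + 1]] <- cmp
    }
  }

  ratio_c <- cohort_mean(hearts, "sl_um", "control") /
    cohort_mean(hearts, "abl_um", "control")
  ratio_i <- cohort_mean(hearts, "sl_um", "iugr") /
    cohort_mean(hearts, "abl_um", "iugr")
  message(sprintf("%s cohort SL/ABL ratio: control %.3f, IUGR %.3f",
                  age, ratio_c, ratio_i))
}

results <- bind_rows(all_rows) |>
  mutate(control = sprintf("%.3f +/- %.3f", .data$mean_control,
                           .data$sd_control),
         iugr = sprintf("%.3f +/- %.3f", .data$mean_iugr, .data$sd_iugr)) |>
  select("variable", "age", "test", "control", "iugr",
         "statistic", "p_value", "degenerate")
write_table_csv(results, "results/group_comparisons.csv")

message("group comparisons:")
for (i in seq_len(nrow(results))) {
  message(sprintf("  %-8s %-5s %-8s control %s vs IUGR %s  p = %.4f",
                  results$variable[i], results$age[i], results$test[i],
                  results$control[i], results$iugr[i], results$p_value[i]))
}
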