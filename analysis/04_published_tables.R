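#!/usr/bin/env Rscript
# Reanalysis of the published table counts: recompute every crude odds
# ratio with its Woolf interval from the printed cell counts, and the
# additive-interaction statistics from the printed adjusted odds ratios.

suppressPackageStartupMessages(library(saltsynergy))

dir.create("results", showWarnings = FALSE)
pc <- read.csv(system.file("extdata", "published_counts.csv",
                           package = "saltsynergy"))

recomputed <- do.call(rbind, lapply(seq_len(nrow(pc)), function(i) {
  est <- crude_odds_ratio(two_by_two(pc$a[i], pc$b[i], pc$c[i], pc$d[i]))
  data.frame(table = pc$table[i], label = pc$label[i],
             printed_or = pc$printed_or[i],
             or = round(est$or_point, 2),
             ci_low = round(est$ci_low, 2), ci_high = round(est$ci_high, 2),
             p = signif(est$p_value, 2))
}))
write.csv(recomputed, "results/published_tables_recomputed.csv",
          row.names = FALSE)

agree <- sum(abs(recomputed$or - recomputed$printed_or) <= 0.011)
cat(sprintf("Recomputed %d published crude ORs; %d agree to the printed digits\n",
            nrow(recomputed), agree))

ap <- attributable_proportion(or11 = 3.23, or10 = 1.08, or01 = 1.51)
s <- synergy_index(or11 = 3.23, or10 = 1.08, or01 = 1.51)
cat(sprintf("From the printed adjusted ORs (3.23, 1.08, 1.51):\n"))
cat(sprintf("  RERI %.2f  AP %.4f (printed 0.51)  S %.4f (printed 3.79, from unrounded fits)\n",
            reri(3.23, 1.08, 1.51), ap, as.numeric(s)))
cat("Table written to results/published_tables_recomputed.csv\n")
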