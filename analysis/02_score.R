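#!/usr/bin/env Rscript
# Step 2: validate the respondent file and score the nine diet quality
# indicators for every respondent.

suppressPackageStartupMessages(library(dqqkit))

pop <- read_respondents("results/data/respondents.csv", policy = "strict")
scores <- score_respondents(pop)
write_scores(scores, "results/data/scores.csv")

cat(sprintf("Scored %d respondents\n", nrow(scores)))
cat(sprintf("  median FGDS %g (IQR %g-%g), median GDR %g\n",
            median_iqr(scores$fgds)$median, median_iqr(scores$fgds)$q1,
            median_iqr(scores$fgds)$q3, median_iqr(scores$gdr)$median))
cat(sprintf("  All-5 %.1f%%, sweet beverage %.1f%%, unhealthy/UPF %.1f%%\n",
            100 * mean(scores$all5), 100 * mean(scores$sweet_beverage),
            100 * mean(scores$unhealthy_upf)))
cat(sprintf("  MDD-W (women 15-49 y): %.1f%% of %d eligible\n",
            100 * mean(scores$mddw, na.rm = TRUE), sum(!is.na(scores$mddw))))
cat("Wrote results/data/scores.csv\n")
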