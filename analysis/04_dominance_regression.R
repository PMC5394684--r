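#!/usr/bin/env Rscript
# Stage 4: within each study group, regress delayed free recall on the
# non-memory battery plus learning (backward elimination at alpha 0.10),
# decompose the explained variance by general dominance analysis, screen the
# weights for bootstrap stability, and report only predictors that are both
# retained and stable.

library(adsubtype)

seed <- 42L
cs <- read_cohort_csv("results/cross_section.csv")
labels <- read_cohort_csv("results/labels.csv")
comp <- derive_components(cs)

d <- merge(cs, comp[c("id", "learning", "delayed")], by = "id")
d$group_lab <- ifelse(d$dx == "CN", "hc",
                      labels$subtype[match(d$id, labels$id)])
d <- d[!is.na(d$group_lab), ]

res <- dominance_table(
  d, outcome = "delayed",
  predictors = c("tmtb", "ds", "bnt", "vegetables", "learning"),
  group = "group_lab", alpha = 0.10, B = 1000, seed = seed, floor = 0.01)

rows <- do.call(rbind, lapply(names(res), function(g) {
  r <- res[[g]]
  data.frame(group = g,
             r2 = r$dominance$r2,
             retained = paste(r$fit$retained, collapse = "+"),
             reported = paste(r$reported$reported$predictor, collapse = "+"),
             rejected = paste(r$reported$rejected$predictor, collapse = "+"))
}))
write.csv(rows, "results/dominance_summary.csv", row.names = FALSE)

for (g in names(res)) {
  cat("\n==", g, "==\n")
  print(res[[g]]$fit)
  print(res[[g]]$stability)
  if (nrow(res[[g]]$reported$rejected))
    cat("Rejected for instability:",
        paste(res[[g]]$reported$rejected$predictor, collapse = ", "), "\n")
}
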