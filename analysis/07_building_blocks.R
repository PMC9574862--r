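#!/usr/bin/env Rscript
# Building-block pair analysis on the packaged printed values: does the
# solubility ordering of the varied building block predict the ordering of
# the PROTAC pair?
suppressMessages(library(protacsol))

bb <- read.csv(system.file("extdata", "building_block_pairs.csv",
                           package = "protacsol"),
               stringsAsFactors = FALSE, na.strings = c("NA", ""))
sol <- unique(bb[, c("protac_id", "protac_log_s", "protac_censored")])
names(sol) <- c("compound_id", "log_s", "censored")

dir.create("results", showWarnings = FALSE)
rows <- lapply(unique(bb$pair), function(p) {
  sub <- bb[bb$pair == p, ]
  rep <- compare_pair(sub$protac_id, sub$varied[1], sol,
                      data.frame(protac_id = sub$protac_id, bb_id = sub$bb_id,
                                 log_s = sub$bb_log_s, censor = sub$bb_censor))
  print(rep)
  data.frame(pair = p, varied = rep$varied, protac_a = rep$pair_ids[1],
             protac_b = rep$pair_ids[2], delta_log_s = rep$delta_log_s,
             concordance = rep$concordance)
})
write.csv(do.call(rbind, rows), "results/building_block_pairs_report.csv",
          row.names = FALSE)
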