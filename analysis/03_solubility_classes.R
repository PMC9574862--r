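#!/usr/bin/env Rscript
# Solubility classification summary: GSK class populations, censoring, and
# the quantitative subset used by all regressions.
suppressMessages(library(protacsol))

sol <- read.csv("results/synthetic/solubility.csv", stringsAsFactors = FALSE)
quant <- filter_quantitative(sol)
write.csv(quant, "results/synthetic/solubility_quantitative.csv",
          row.names = FALSE)

message(sprintf("%d of %d compounds quantitative; %d censored (assigned to the low class)",
                attr(quant, "n_quantitative"), nrow(sol), sum(sol$censored)))
tab <- table(factor(sol$gsk_class, levels = c("low", "intermediate", "high")))
message("GSK classes: ", paste(names(tab), tab, sep = " = ", collapse = ", "))
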