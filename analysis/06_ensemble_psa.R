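#!/usr/bin/env Rscript
# Conformer-ensemble 3D-PSA statistics on toy ensembles, and the regressions
# of log S on the five representative statistics.
suppressMessages(library(protacsol))

sol <- read.csv("results/synthetic/solubility.csv", stringsAsFactors = FALSE)
quant <- filter_quantitative(sol)
ids <- head(quant$compound_id, 10)

dists <- lapply(seq_along(ids), function(i) {
  d <- ensemble_psa_distribution(
    generate_toy_ensemble(30, seed = 100 + i, jitter = 0.3))
  d$compound_id <- ids[i]
  d
})

summ <- do.call(rbind, lapply(dists, function(d)
  data.frame(compound_id = d$compound_id, lower_adjacent = d$lower_adjacent,
             q1 = d$q1, median = d$median, q3 = d$q3,
             upper_adjacent = d$upper_adjacent)))
write.csv(summ, "results/synthetic/psa_summary.csv", row.names = FALSE)
long <- do.call(rbind, lapply(dists, function(d)
  data.frame(compound_id = d$compound_id, psa = d$per_conformer_psa)))
write.csv(long, "results/synthetic/psa_per_conformer.csv", row.names = FALSE)

log_s <- setNames(quant$log_s[match(ids, quant$compound_id)], ids)
tab <- representative_psa_regressions(dists, log_s)
write.csv(tab, "results/synthetic/psa_regressions.csv", row.names = FALSE)
message("log S vs representative PSA statistics (toy ensembles are not 3D structures of the compounds, so R2 is expected to be near 0):")
print(tab, digits = 3)
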