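#!/usr/bin/env Rscript
# Descriptor-solubility regressions on the quantitative subset, and the
# plot-ready chemical-space exports.
suppressMessages(library(protacsol))

desc <- read.csv("results/synthetic/chromatographic_descriptors.csv",
                 stringsAsFactors = FALSE)
gen <- read.csv("results/synthetic/descriptors.csv", stringsAsFactors = FALSE)
sol <- read.csv("results/synthetic/solubility.csv", stringsAsFactors = FALSE)
comp <- read.csv("results/synthetic/compounds.csv", stringsAsFactors = FALSE)

quant <- filter_quantitative(sol)
m <- match(quant$compound_id, desc$compound_id)
g <- match(quant$compound_id, gen$id)

fits <- list(
  brlogd = fit_linear(desc$brlogd[m], quant$log_s, "brlogd", "log_s"),
  log_kw_iam = fit_linear(desc$log_kw_iam[m], quant$log_s, "log_kw_iam", "log_s"),
  delta_log_kw_iam = fit_linear(desc$delta_log_kw_iam[m], quant$log_s,
                                "delta_log_kw_iam", "log_s"),
  tpsa = fit_linear(gen$tpsa[g], quant$log_s, "tpsa", "log_s"))
tab <- do.call(rbind, lapply(fits, function(f)
  data.frame(x = f$x_name, slope = f$slope, intercept = f$intercept,
             r2 = f$r2, n = f$n)))
write.csv(tab, "results/synthetic/regressions.csv", row.names = FALSE)
for (f in fits) print(f)

ds <- protac_dataset(comp, solubility = sol,
                     descriptors = merge(gen, desc, by.x = "id",
                                         by.y = "compound_id",
                                         suffixes = c("_gen", "")))
space <- chemical_space_export(ds, axes = c("log_kw_iam", "brlogd", "tpsa"))
write.csv(space, "results/synthetic/chemical_space.csv", row.names = FALSE)
message(sprintf("chemical-space export: %d compounds on (log kw(IAM), BRlogD, TPSA)",
                nrow(space)))
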