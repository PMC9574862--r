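#!/usr/bin/env Rscript
# Generate the synthetic 21-compound PROTAC study that the downstream
# analyses consume: descriptor vectors over the study ranges, solubilities
# from the log S ~ BRlogD line with calibrated noise, LOQ censoring, GSK
# classes, and raw retention tables consistent with the descriptors.
suppressMessages(library(protacsol))

out <- "results/synthetic"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
cfg <- generator_config(n_compounds = 21, seed = 2022)
ds <- generate_dataset(cfg)
stopifnot(nrow(validate_dataset(ds)) == 0)

ret <- generate_retention_tables(ds, tau = 0.02)
write.csv(ds$compounds, file.path(out, "compounds.csv"), row.names = FALSE)
write.csv(ds$descriptors, file.path(out, "descriptors.csv"), row.names = FALSE)
write.csv(ds$solubility, file.path(out, "solubility.csv"), row.names = FALSE)
write.csv(ret, file.path(out, "retention.csv"), row.names = FALSE)
write_profiles(ds, file.path(out, "profiles.csv"))

message(sprintf("generated %d compounds (%d censored below LOQ %.1f)",
                nrow(ds$compounds), sum(ds$solubility$censored),
                cfg$loq_log_s))
message("class counts: ",
        paste(names(table(ds$solubility$gsk_class)),
              table(ds$solubility$gsk_class), collapse = ", "))
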