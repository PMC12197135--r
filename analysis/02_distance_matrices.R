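#!/usr/bin/env Rscript
# Measure the reference-to-target Euclidean distance matrix of every scan:
# 6 bony references x 7 targets = 42 distances per condition. These
# intra-scan distances are the raw material of the registration-free
# displacement statistic.
suppressPackageStartupMessages(library(pneumoshift))

sets <- read_long_csv("results/landmarks.csv")
distances <- distance_table(sets)
utils::write.csv(distances, "results/distances.csv", row.names = FALSE)

message("Measured ", nrow(distances), " reference-to-target distances over ",
        length(sets), " scans.")
message("Distance range: ", round(min(distances$distance_mm), 1), " to ",
        round(max(distances$distance_mm), 1), " mm.")
message("Wrote results/distances.csv")
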