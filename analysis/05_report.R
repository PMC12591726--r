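#!/usr/bin/env Rscript
# Stage 5 - render the four result tables of the run as a plain-text report.

suppressPackageStartupMessages(library(trialecon))

out <- "results/trial"
report <- render_tables(out, file = file.path(out, "report.txt"))
writeLines(report)
cat("\nReport written to", file.path(out, "report.txt"), "\n")
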