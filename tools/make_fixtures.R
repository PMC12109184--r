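#!/usr/bin/env Rscript
# Regenerates the shipped synthetic cardiogenic-shock fixture from the
# packaged healthy reference via the deterministic tuner. Run from the
# repository root after changing the healthy parameter file or the tuner:
#
#   Rscript tools/make_fixtures.R
suppressPackageStartupMessages(library(cardioloop))
cs <- make_cs_patient(verbose = TRUE)
write_patient_config(cs, "inst/extdata/cs_patient_synthetic.yaml")
cat("wrote inst/extdata/cs_patient_synthetic.yaml\n")
str(cs$meta$criteria)
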