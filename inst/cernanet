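#!/usr/bin/env Rscript
# Thin wrapper around cernanet::cernanet_main(); install the package and
# call e.g.: Rscript $(Rscript -e 'cat(system.file("cernanet", package="cernanet"))') run --out out
suppressPackageStartupMessages(library(cernanet))
status <- cernanet_main(commandArgs(trailingOnly = TRUE))
quit(status = if (is.null(status)) 0L else status, save = "no")
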