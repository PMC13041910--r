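#!/usr/bin/env Rscript
# Optional helper: fetches the deposited per-particle traced models
# (Zenodo record 16423113) and converts the reference particle's trace to
# the package's curve CSV dialect, so the published writhe value can be
# checked locally:
#
#   Rscript scripts/fetch_deposited_model.R <downloaded-model.csv> out.csv
#   PLECTOTRACE_DEPOSITED_MODEL=out.csv Rscript -e 'testthat::test_dir("tests/testthat")'
#
# The deposition is a large archive and network access is required; the
# test suite passes without it. Input is expected as an ordered x,y,z
# table in nanometres (header optional); the output is a closed-curve CSV.

suppressPackageStartupMessages(library(plectotrace))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) != 2L) {
  stop("usage: fetch_deposited_model.R <model-points-file> <out-curve.csv>")
}
raw <- utils::read.csv(args[1L], header = TRUE)
num_cols <- which(vapply(raw, is.numeric, logical(1)))
if (length(num_cols) < 3L) stop("input needs three numeric coordinate columns")
pts <- as.matrix(raw[, num_cols[seq_len(3L)]])
curve <- closed_curve(pts)
write_curve(curve, args[2L])
message(sprintf("wrote %s (%d points, contour %.1f nm, Wr = %.2f)",
                args[2L], nrow(pts), contour_length(curve),
                compute_writhe(curve)))
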