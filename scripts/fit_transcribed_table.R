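#!/usr/bin/env Rscript
# Fit the six-feature QSAR model to a user-transcribed fingerprint table.
#
# The training fingerprints of the original study live in a supplementary
# PDF that is not redistributed here. Users who transcribe it (tab-
# separated, header FP1 FP2 FP3 FP4 FP5 FP6 logRBA, one row per ligand
# with a measured RBA; censored/zero RBA rows omitted) can reproduce the
# reported self-consistency (R^2 about 0.96) and leave-one-out predictive
# ability (Q^2 about 0.93):
#
#   Rscript scripts/fit_transcribed_table.R path/to/table.tsv

suppressPackageStartupMessages(library(hydroqsar))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1) {
  stop("usage: Rscript scripts/fit_transcribed_table.R <table.tsv>\n",
       "  (no transcribed fingerprint table supplied)", call. = FALSE)
}
path <- args[1]
if (!file.exists(path)) {
  stop("fingerprint table not found: ", path, call. = FALSE)
}

df <- read_fingerprint_table(path)
X <- as.matrix(df[, fingerprint_bits()])
y <- df$logRBA

fit <- fit_mlr(X, y)
q2 <- loo_q2(X, y)

cat(sprintf("n            %d\n", nrow(X)))
for (b in names(fit$coefficients)) {
  cat(sprintf("c(%s)       %8.3f\n", b, fit$coefficients[[b]]))
}
cat(sprintf("intercept    %8.3f\n", fit$intercept))
cat(sprintf("R2           %8.3f\n", fit$diagnostics$R2))
cat(sprintf("LOO Q2       %8.3f\n", q2))
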