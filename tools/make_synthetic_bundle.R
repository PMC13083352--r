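#!/usr/bin/env Rscript
# Regenerates inst/extdata/synthetic_cvrl/, the packaged SYNTHETIC
# standard-observer bundle: analytic stand-ins (Gaussian fundamentals,
# V(lambda), CMF lobes, density templates) for the real observer tables.
# For production stimulus design regenerate a real bundle with
# tools/fetch_cvrl.R instead; the two are interchangeable on disk.
# Run from the package root: Rscript tools/make_synthetic_bundle.R

devtools::load_all(".", quiet = TRUE)

dir <- file.path("inst", "extdata", "synthetic_cvrl")
write_observer_bundle(dir,
                      obs = synthetic_observer(),
                      vlambda = synthetic_vlambda(),
                      templates = synthetic_templates(),
                      cmfs = synthetic_cmfs())
cat("wrote synthetic bundle to", dir, "\n")
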