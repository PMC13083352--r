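#!/usr/bin/env Rscript
# Builds a REAL standard-observer bundle from the public Colour & Vision
# Research Laboratory downloads (http://www.cvrl.org/), in the same on-disk
# dialect as the packaged synthetic bundle. Requires network access; the
# package and its tests never need this script (they use the synthetic
# stand-ins), but production stimulus design should.
#
# Usage: Rscript tools/fetch_cvrl.R <output-dir>
#
# Tables to fetch (390-780 nm; resampled to 2 nm on import):
#   - Stockman & Sharpe 10-deg cone fundamentals (linear energy) -> fundamentals.csv (L,M,S)
#   - CIE scotopic luminous efficiency V'(lambda)                -> scotopic.csv (rod)
#   - CIE S 026 melanopic action spectrum                        -> melanopsin.csv (mel)
#   - Photopic luminous efficiency V(lambda), 10-deg based       -> vlambda.csv
#   - Stockman, Sharpe & Fach macular pigment optical density,
#     peak-normalized to 1                                       -> macular.csv
#   - Pokorny, Smith & Lutze lens density components TL1, TL2    -> lens.csv
#   - CIE 1964 10-deg colour-matching functions                  -> cmf1964.csv (xbar,ybar,zbar)

args <- commandArgs(trailingOnly = TRUE)
if (length(args) != 1) stop("usage: Rscript tools/fetch_cvrl.R <output-dir>")
out <- args[[1]]

devtools::load_all(".", quiet = TRUE)

urls <- c(
  fundamentals = "http://www.cvrl.org/database/data/cones/linss10e_1.csv",
  scotopic     = "http://www.cvrl.org/database/data/lum/scvle_1.csv",
  vlambda      = "http://www.cvrl.org/database/data/lum/linCIE2008v10e_1.csv",
  macular      = "http://www.cvrl.org/database/data/maccorr/macss_1.csv",
  lens         = "http://www.cvrl.org/database/data/lenscorr/lenssmj10_1.csv",
  cmf1964      = "http://www.cvrl.org/database/data/cmfs/ciexyz64_1.csv"
)
# Melanopic action spectrum: CIE S 026 toolbox, https://cie.co.at/data-tables

grid <- canonical_grid()
dir.create(out, showWarnings = FALSE, recursive = TRUE)

fetch <- function(url) {
  tab <- utils::read.csv(url, header = FALSE)
  tab[] <- lapply(tab, function(x) suppressWarnings(as.numeric(x)))
  tab[stats::complete.cases(tab[[1]]), ]
}

as_spec <- function(tab, col, unit = "sensitivity") {
  v <- tab[[col]]
  v[is.na(v)] <- 0
  resample_spectrum(spectrum(tab[[1]], v, unit = unit), grid)
}

message("fetching CVRL tables ...")
cones <- fetch(urls["fundamentals"])
write_spectra(list(L = as_spec(cones, 2), M = as_spec(cones, 3),
                   S = as_spec(cones, 4)),
              file.path(out, "fundamentals.csv"))
sco <- fetch(urls["scotopic"])
write_spectra(list(rod = as_spec(sco, 2)), file.path(out, "scotopic.csv"))
vl <- fetch(urls["vlambda"])
write_spectra(list(vlambda = as_spec(vl, 2)), file.path(out, "vlambda.csv"))
mac <- fetch(urls["macular"])
m <- as_spec(mac, 2, unit = "OD")
m$values <- m$values / max(m$values)  # template is peak-normalized
write_spectra(list(macular = m), file.path(out, "macular.csv"))
lens <- fetch(urls["lens"])
write_spectra(list(TL1 = as_spec(lens, 2, unit = "OD"),
                   TL2 = as_spec(lens, 3, unit = "OD")),
              file.path(out, "lens.csv"))
cmf <- fetch(urls["cmf1964"])
write_spectra(list(xbar = as_spec(cmf, 2), ybar = as_spec(cmf, 3),
                   zbar = as_spec(cmf, 4)),
              file.path(out, "cmf1964.csv"))
stop("melanopsin.csv must be added manually from the CIE S 026 toolbox; ",
     "all other tables were written to ", out)
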