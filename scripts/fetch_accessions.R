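#!/usr/bin/env Rscript
# Optional helper (requires network access; nothing in the package or
# its tests depends on it): downloads the deposited Nanorana mitogenome
# accessions from NCBI as GenBank flat files and runs the pipeline on
# them, so the sequence-derived published values (overall and
# control-region A+T content, per-gene skews, codon counts) can be
# compared directly.
#
#   Rscript scripts/fetch_accessions.R --out <dir>
#
# Accessions: NC_026789 (N. parkeri), KY594708 (N. ventripunctata),
# NC_016119 (N. pleskei), NC_024272 (N. taihangnica).

suppressPackageStartupMessages(library(mitoprofiler))

args <- commandArgs(trailingOnly = TRUE)
out <- "accession-run"
i <- 1L
while (i <= length(args)) {
  if (args[[i]] == "--out") { out <- args[[i + 1L]]; i <- i + 2L }
  else stop("unknown argument: ", args[[i]])
}
dir.create(out, showWarnings = FALSE, recursive = TRUE)

acc <- c(parkeri = "NC_026789", ventripunctata = "KY594708",
         pleskei = "NC_016119", taihangnica = "NC_024272")
base <- paste0("https://eutils.ncbi.nlm.nih.gov/entrez/eutils/",
               "efetch.fcgi?db=nuccore&rettype=gb&retmode=text&id=")
paths <- character(0)
for (nm in names(acc)) {
  dest <- file.path(out, paste0(acc[[nm]], ".gb"))
  if (!file.exists(dest)) {
    message("fetching ", acc[[nm]], " ...")
    utils::download.file(paste0(base, acc[[nm]]), dest, quiet = TRUE)
    Sys.sleep(1)  # NCBI rate limit
  }
  paths[nm] <- dest
}

bundle <- runAll(as.list(paths), file.path(out, "reports"))
for (nm in names(bundle)) {
  sk <- bundle[[nm]]$skew
  if (is.null(sk)) next
  ov <- sk[sk$region == "Overall", ]
  cat(sprintf("%s: overall A+T %.2f%%, AT-skew %.3f, GC-skew %.3f\n",
              nm, 100 * ov$at_fraction, ov$at_skew, ov$gc_skew))
}
cat("reports written under ", file.path(out, "reports"), "\n")
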