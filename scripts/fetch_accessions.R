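#!/usr/bin/env Rscript
# NETWORK-DEPENDENT helper: downloads the GenBank protein fixtures used by
# the published-accession acceptance check and stores them under
# inst/extdata/accessions/.  Run from the repository root:
#   Rscript scripts/fetch_accessions.R
# The package itself never fetches anything; without these fixtures the
# accession-reproduction test reports them as absent.

accessions <- c(
  "RCJ37125.1",       # Nostoc punctiforme NIES-2108, "N" isoform
  "XP_005536287.1",   # Cyanidioschyzon merolae, "E" isoform
  "OAO95078.1"        # Arabidopsis thaliana AtPCS1 (triad 56/162/180)
)

outDir <- file.path("inst", "extdata", "accessions")
dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

url <- paste0(
  "https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi?",
  "db=protein&rettype=fasta&retmode=text&id=",
  paste(accessions, collapse = ","))
dest <- file.path(outDir, "accessions.fasta")
status <- tryCatch(utils::download.file(url, dest, quiet = TRUE),
                   error = function(e) 1L)
if (!identical(status, 0L) || !file.exists(dest) ||
    file.size(dest) < 100) {
  if (file.exists(dest)) unlink(dest)
  stop("could not fetch accessions from NCBI (network required)")
}

# normalise headers to bare accession identifiers
lines <- readLines(dest)
hdr <- startsWith(lines, ">")
lines[hdr] <- sub("^>(\\S+).*$", ">\\1", lines[hdr])
writeLines(lines, dest)
cat("fetched", sum(hdr), "records into", dest, "\n")
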