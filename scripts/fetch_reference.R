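#!/usr/bin/env Rscript
# Fetch the CdzC/CdzD reference proteins (Caulobacter crescentus NA1000
# locus tags CCNA_03932 and CCNA_03933) from NCBI efetch and write them as
# a two-record protein FASTA. Network access is required; the cdzminer
# library itself never fetches remote data, so this stays a stand-alone
# documented script used by the accession-based acceptance checks.
#
# usage: Rscript scripts/fetch_reference.R [--out PATH]

args <- commandArgs(trailingOnly = TRUE)
out <- "cdz_reference.faa"
if (length(args) >= 2 && args[1] == "--out") out <- args[2]

tags <- c(CdzC = "CCNA_03932", CdzD = "CCNA_03933")
url <- paste0("https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi",
              "?db=protein&rettype=fasta&retmode=text&id=",
              paste(tags, collapse = ","))
tmp <- tempfile(fileext = ".faa")
status <- tryCatch(utils::download.file(url, tmp, quiet = TRUE, mode = "wb"),
                   error = function(e) {
                     message("download failed: ", conditionMessage(e)); 1L
                   })
if (!identical(as.integer(status), 0L) || !file.exists(tmp) ||
    file.size(tmp) == 0) {
  stop("could not fetch ", paste(tags, collapse = "/"),
       " from NCBI (offline?)")
}
file.copy(tmp, out, overwrite = TRUE)
cat("wrote", out, "\n")
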