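#!/usr/bin/env Rscript

# One-time retrieval of the public reference sequences used by two of the
# acceptance checks (network required; everything else in the package is
# generated locally):
#
#   * the DNA duplex sequences of PDB templates 1SAX, 1U8R, 1Z9C
#     (written to inst/extdata/reference/template_dna.fasta)
#   * the Slr1738 (PerR-like regulator, Synechocystis sp. PCC 6803)
#     protein sequence (written to inst/extdata/reference/slr1738.fasta)
#
# Run from the repository root:  Rscript scripts/fetch_reference_data.R

suppressPackageStartupMessages(library(furdock))

dest_dir <- file.path("inst", "extdata", "reference")
dir.create(dest_dir, showWarnings = FALSE, recursive = TRUE)

fetch <- function(url, dest) {
  message("fetching ", url)
  utils::download.file(url, dest, quiet = TRUE, mode = "wb")
  dest
}

## template DNA duplexes -----------------------------------------------------
ids <- c("1SAX", "1U8R", "1Z9C")
fasta <- character(0)
for (id in ids) {
  pdb <- tempfile(fileext = ".pdb")
  fetch(sprintf("https://files.rcsb.org/download/%s.pdb", id), pdb)
  s <- read_structure(pdb)
  dch <- dna_chains(s)
  if (length(dch) < 1) stop("no DNA chains found in ", id)
  # record the top strand of the duplex (longest DNA chain)
  lens <- vapply(dch, function(ch) {
    length(unique(s$resno[s$chain == ch]))
  }, integer(1))
  top <- dch[which.max(lens)]
  seq <- structure_sequence(s, top)
  fasta <- c(fasta, sprintf(">%s duplex top strand (chain %s)", id, top), seq)
  message(sprintf("%s: %d bp, AT content %.0f%%", id, nchar(seq),
                  100 * at_content(seq)))
}
writeLines(fasta, file.path(dest_dir, "template_dna.fasta"))

## Slr1738 protein sequence ---------------------------------------------------
# UniProt cross-reference for the slr1738 gene product
url <- "https://rest.uniprot.org/uniprotkb/search?query=gene:slr1738+AND+organism_id:1111708&format=fasta"
fetch(url, file.path(dest_dir, "slr1738.fasta"))
lines <- readLines(file.path(dest_dir, "slr1738.fasta"), warn = FALSE)
seq <- paste(lines[!grepl("^>", lines)], collapse = "")
message("slr1738 product length: ", nchar(seq), " residues")

message("done; re-install the package so the snapshots are available via system.file()")
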