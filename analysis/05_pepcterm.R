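#!/usr/bin/env Rscript
# Stage 5: PEP-CTERM sorting-signal scan.
#
# Scans the proteome for the C-terminal sorting signal of the
# exosortase/EpsH system: a Pro-Glu-Pro motif near the C-terminus, a
# hydrophobic transmembrane segment right after it, and a terminal cluster
# of basic residues. Hits are written as TSV and protein-space GFF3.

library(omprofiler)

src <- "results/simulated"
out <- "results/pepcterm"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

records <- read_fasta(file.path(src, "proteome.fasta"))
hits <- scan_proteome(records)
write.table(hits, file.path(out, "pepcterm_hits.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write_pepcterm_gff3(hits, file.path(out, "pepcterm_hits.gff3"))

truth <- read.delim(file.path(src, "ground_truth.tsv"))
planted <- truth$protein_id[truth$pepcterm]
cat(sprintf("PEP-CTERM hits: %d of %d proteins\n", nrow(hits), nrow(records)))
cat(sprintf("Planted recall: %d/%d; false hits: %d\n",
            length(intersect(hits$protein_id, planted)), length(planted),
            sum(!hits$protein_id %in% planted)))
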