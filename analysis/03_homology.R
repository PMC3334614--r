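#!/usr/bin/env Rscript
# Stage 3 -- align cluster consensuses to the reference gene models,
# chain HSPs into CIP/CALP scores, call one-to-one orthologs at
# CIP >= 60 / CALP >= 0.70, classify COS/CNV/PAV, count homoeolog
# copies per reference gene, and score ancestral paralog pair
# retention against the planted truth.

suppressMessages(library(polyfate))

clusters <- polyfate:::read_fasta("results/clusters.fasta")
ref <- polyfate:::read_fasta("results/simulation/genome.fasta")
genes <- read.delim("results/simulation/genes.gff3", header = FALSE,
                    comment.char = "#",
                    col.names = c("chromosome", "source", "type", "start",
                                  "end", "score", "strand", "phase",
                                  "attributes"))
genes$gene_id <- sub("^ID=([^;]+).*", "\\1", genes$attributes)
genes$start <- genes$start - 1L   # back to 0-based half-open

hsps <- align_sequences(clusters, ref)
write_m8(hsps, "results/hits.m8")
scores <- score_all_pairs(hsps, nchar(clusters))
cos <- call_orthologs(scores, cip_min = 60, calp_min = 0.70)
write.table(cos, "results/cos_pairs.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

calls <- classify_cnv_pav(scores, cos,
                          genes[, c("gene_id", "chromosome", "start")])
write.table(calls, "results/homology_calls.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cc <- count_homoeolog_copies(cos)

rel <- read.delim("results/simulation/truth_copies.tsv")
truth_rel <- unique(genes$gene_id[grepl("paralog_partner", genes$attributes)])
pp <- sub("^.*paralog_partner=([^;]+).*", "\\1",
          genes$attributes[grepl("paralog_partner", genes$attributes)])
pair_tab <- unique(data.frame(
  gene_a = pmin(truth_rel, pp), gene_b = pmax(truth_rel, pp)))
status <- paralog_pair_status(pair_tab, unique(cos$reference_gene))
write.table(data.frame(status = c("both", "one", "none"),
                       count = c(status$both, status$one, status$none)),
            "results/paralog_status.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("%d/%d clusters pass the ortholog filter\n",
            nrow(cos), length(clusters)))
cat(sprintf("relation calls: %s\n",
            paste(names(table(calls$relation)), table(calls$relation),
                  collapse = ", ", sep = "=")))
cat(sprintf("copy histogram 1/2/3: %s; triplet fraction %.1f%%\n",
            paste(cc$histogram, collapse = "/"), cc$triplet_fraction))
cat(sprintf("paralog pairs both/one/none matched: %d/%d/%d (both %.1f%%)\n",
            status$both, status$one, status$none, status$both_pct))
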