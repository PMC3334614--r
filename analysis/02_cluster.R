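#!/usr/bin/env Rscript
# Stage 2 -- assemble the simulated reads into unigene clusters and
# profile their coverage.  Reads are error-free, so we cluster with the
# canonical 40-base overlap at 99 % overlap identity.  Even so, sibling
# subgenome copies co-assemble whenever a single read overlap happens to
# contain no homoeo-SNP (transitive single-linkage then merges the
# copies): the merged-homoeolog phenomenon.  The coverage profile
# quantifies it, and clusters with read counts above 3.5x the
# single-copy centre are flagged as putatively merged.

suppressMessages(library(polyfate))

reads <- Biostrings::readDNAStringSet("results/simulation/reads.fasta")
reads <- stats::setNames(as.character(reads), sub(" .*", "", names(reads)))
cat(sprintf("clustering %d reads...\n", length(reads)))

cl <- cluster_reads(reads, min_overlap = 40, min_identity = 0.99)
cp <- coverage_profile(cl)
flags <- flag_merged_homoeologs(cp, k = 3.5)

dir.create("results", showWarnings = FALSE)
write.table(cl$clusters[, c("cluster_id", "n_reads", "coverage")],
            "results/coverage.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(cl$members, "results/clusters_members.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
seqs <- stats::setNames(cl$clusters$consensus, cl$clusters$cluster_id)
polyfate:::write_fasta(seqs, "results/clusters.fasta")
writeLines(flags$flagged, "results/merged_homoeolog_flags.txt")

cat(sprintf("%d clusters; mean %.1f reads, mean coverage %.1fx\n",
            nrow(cl$clusters), cp$mean_reads, cp$mean_coverage))
cat(sprintf("%d clusters flagged as putatively merged homoeologs (>%.0f reads)\n",
            length(flags$flagged), flags$threshold))

# measure the true merged fraction against the planted read map
truth <- read.delim("results/simulation/truth_reads.tsv")
mm <- merge(cl$members, truth[, c("read_id", "copy_id")])
n_src <- tapply(mm$copy_id, mm$cluster_id, function(x) length(unique(x)))
cat(sprintf("truth: %d/%d clusters contain reads of >1 transcript copy (mean coverage is inflated accordingly)\n",
            sum(n_src > 1), length(n_src)))
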