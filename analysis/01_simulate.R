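#!/usr/bin/env Rscript
# Stage 1 -- simulate the study system: a diploid reference genome and a
# derived allohexaploid grain transcriptome with planted truth.
#
# The study conditions: three subgenomes at a 2 % pairwise homoeo-SNP
# density (an exaggerated but in-range density so that homoeologs are
# separable by overlap identity), 20 % homoeolog loss, 30 % expression
# divergence, 20 % of genes in ancestral duplication blocks with 40 %
# ancient paralog loss, 10 % tandem CNVs, ~25x read depth over five
# grain developmental stages.

suppressMessages(library(polyfate))

out_dir <- "results/simulation"
cfg <- sim_config(n_chromosomes = 2, genes_per_chromosome = 20,
                  gene_length_mean = 1000,
                  paralog_block_fraction = 0.2, paralog_loss_prob = 0.4,
                  homoeolog_snp_rate = 0.02, homoeolog_loss_prob = 0.2,
                  expr_divergence_prob = 0.3, cnv_prob = 0.1,
                  mean_coverage = 25, n_stages = 5, seed = 20260920L)

sim <- simulate_transcriptome(cfg)
write_simulation(sim, out_dir)

n_genes <- nrow(sim$genome$genes)
n_pairs <- sum(sim$genome$relationships$type == "paralog_pair")
n_tand <- sum(sim$genome$relationships$type == "tandem")
cat(sprintf("simulated %d gene models (%d paralog pairs, %d tandem CNVs)\n",
            n_genes, n_pairs, n_tand))
cat(sprintf("transcript copies: %d, of which %d deleted (%.1f%%)\n",
            nrow(sim$copies), sum(sim$copies$deleted),
            100 * mean(sim$copies$deleted)))
cat(sprintf("sampled %d reads into %s\n", length(sim$reads), out_dir))
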