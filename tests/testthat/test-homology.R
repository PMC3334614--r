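test_that("CIP/CALP reproduce hand-computed chained-HSP scores", {
  # single full-length perfect HSP
  s <- score_alignment(hsp(qs = 0, qe = 200, ids = 200), 200)
  expect_equal(s$CIP, 100)
  expect_equal(s$CALP, 1)

  # two disjoint HSPs: (100, 90 id) + (50, 45 id) over a 200-base query
  h <- rbind(hsp(qs = 0, qe = 100, ids = 90),
             hsp(qs = 120, qe = 170, ids = 45, bits = 50))
  s2 <- score_alignment(h, 200)
  expect_equal(s2$AL, 150)
  expect_equal(s2$CIP, 90)
  expect_equal(s2$CALP, 0.75)

  # contract violations
  expect_error(score_alignment(h[0, ], 200))
  bad <- rbind(hsp(q = "q1", qs = 0, qe = 10),
               hsp(q = "q2", qs = 0, qe = 10))
  expect_error(score_alignment(bad, 100), "one query")
})

test_that("scoring matches a per-column brute-force oracle on fuzzed HSPs", {
  set.seed(2024)
  for (rep in 1:1000) {
    qlen <- sample(50:300, 1)
    n <- sample(1:6, 1)
    qs <- sample(0:(qlen - 10), n, replace = TRUE)
    qe <- pmin(qlen, qs + sample(5:80, n, replace = TRUE))
    ids <- mapply(function(a, b) sample(0:(b - a), 1), qs, qe)
    h <- data.frame(query_id = "q", subject_id = "s",
                    q_start = qs, q_end = qe, s_start = qs, s_end = qe,
                    length = qe - qs, n_identities = ids,
                    bitscore = sample(10:500, n, replace = TRUE))
    got <- score_alignment(h, qlen)
    want <- score_alignment_oracle(h, qlen)
    expect_equal(got$AL, want$AL)
    expect_equal(got$CIP, want$CIP, tolerance = 1e-12)
    expect_equal(got$CALP, want$CALP, tolerance = 1e-12)
  }
})

test_that("scores are invariant to HSP order and to splitting an HSP", {
  set.seed(7)
  h <- rbind(hsp(qs = 0, qe = 100, ids = 95, bits = 90),
             hsp(qs = 150, qe = 250, ids = 80, bits = 70),
             hsp(qs = 90, qe = 160, ids = 60, bits = 50))
  base <- score_alignment(h, 300)
  for (i in 1:5) {
    perm <- h[sample(nrow(h)), ]
    s <- score_alignment(perm, 300)
    expect_equal(s$CIP, base$CIP)
    expect_equal(s$CALP, base$CALP)
  }
  # splitting one HSP into two abutting halves with prorated identities
  whole <- hsp(qs = 0, qe = 100, ids = 80, bits = 60)
  halves <- rbind(hsp(qs = 0, qe = 50, ids = 40, bits = 60),
                  hsp(qs = 50, qe = 100, ids = 40, bits = 60))
  expect_equal(score_alignment(whole, 200)$CIP,
               score_alignment(halves, 200)$CIP)
  expect_equal(score_alignment(whole, 200)$CALP,
               score_alignment(halves, 200)$CALP)
})

test_that("ortholog thresholds are inclusive and best-hit ranking holds", {
  mk <- function(q, s, cip, calp) {
    data.frame(query_id = q, subject_id = s, AL = 100, CIP = cip,
               CALP = calp, n_hsps = 1, stringsAsFactors = FALSE)
  }
  # boundary: CIP 59.9 fails, 60.0 passes
  expect_equal(nrow(call_orthologs(mk("q", "s", 59.9, 0.8))), 0)
  expect_equal(nrow(call_orthologs(mk("q", "s", 60.0, 0.70))), 1)
  expect_equal(nrow(call_orthologs(mk("q", "s", 60.0, 0.699))), 0)

  # best-subject ranking: highest CIP wins over higher CALP
  sc <- rbind(mk("q", "s1", 95, 0.90), mk("q", "s2", 80, 0.95))
  expect_equal(call_orthologs(sc)$reference_gene, "s1")
  # tie on CIP -> higher CALP; tie on both -> lexicographic subject
  sc2 <- rbind(mk("q", "sB", 90, 0.90), mk("q", "sA", 90, 0.95))
  expect_equal(call_orthologs(sc2)$reference_gene, "sA")
  sc3 <- rbind(mk("q", "sB", 90, 0.9), mk("q", "sA", 90, 0.9))
  expect_equal(call_orthologs(sc3)$reference_gene, "sA")
  expect_equal(nrow(call_orthologs(sc3[0, ])), 0)
})

test_that("protein-identity homolog calls split shared and specific", {
  ps <- data.frame(
    query_id = c("c1", "c1", "c2", "c3"),
    proteome = c("rice", "brachypodium", "rice", "maize"),
    identity = c(0.8, 0.55, 0.49, 0.50))
  res <- call_domain_homologs(ps)
  expect_setequal(res$specific, "c2")          # best hit 0.49 < 0.50
  expect_equal(unname(res$shared_by["2"]), 1)  # c1 in two proteomes
  expect_equal(unname(res$shared_by["1"]), 1)  # c3, inclusive boundary
  # all clusters perfect -> no specific
  ps2 <- data.frame(query_id = c("a", "b"), proteome = "rice",
                    identity = 1)
  expect_length(call_domain_homologs(ps2)$specific, 0)
})

test_that("homoeolog copy counting reproduces the histogram arithmetic", {
  # the printed worked example: {1: 6024, 2: 941, 3: 193} -> 2.7 %
  counts <- c(rep(1L, 6024), rep(2L, 941), rep(3L, 193))
  res <- count_homoeolog_copies(counts)
  expect_equal(unname(res$histogram), c(6024L, 941L, 193L))
  expect_equal(res$triplet_fraction, 2.7)
  # all triplets
  expect_equal(count_homoeolog_copies(rep(3L, 10))$triplet_fraction, 100)
  # supernumerary matches are capped but reported
  res2 <- count_homoeolog_copies(c(1L, 5L))
  expect_equal(unname(res2$histogram), c(1L, 0L, 1L))
  expect_equal(res2$supernumerary, 1L)
})

test_that("simulated homoeolog loss is recovered through ortholog calls", {
  cfg <- sim_config(n_chromosomes = 4, genes_per_chromosome = 250,
                    gene_length_mean = 400, paralog_block_fraction = 0,
                    cnv_prob = 0, homoeolog_loss_prob = 0.2,
                    expr_divergence_prob = 0, mean_coverage = 0,
                    seed = 77)
  g <- generate_genome(cfg)
  copies <- generate_hexaploid(g, cfg)
  kept <- copies[!copies$deleted, ]
  # perfect clustering: each retained copy is its own cluster
  pairs <- data.frame(cluster = kept$copy_id,
                      reference_gene = kept$gene_id)
  res <- count_homoeolog_copies(pairs)
  p3 <- 0.8^3 / (1 - 0.2^3)      # triplet share among matched genes
  se <- sqrt(p3 * (1 - p3) / res$n_genes)
  expect_lt(abs(res$triplet_fraction / 100 - p3), 3 * se)
})

test_that("toy-aligned clusters recover their source genes", {
  cfg <- sim_config(n_chromosomes = 2, genes_per_chromosome = 30,
                    gene_length_mean = 500, paralog_block_fraction = 0,
                    cnv_prob = 0, homoeolog_loss_prob = 0,
                    expr_divergence_prob = 0, mean_coverage = 0, seed = 55)
  g <- generate_genome(cfg)
  copies <- generate_hexaploid(g, cfg)
  queries <- stats::setNames(copies$sequence, copies$copy_id)
  hsps <- align_sequences(queries, g$sequences)
  scores <- score_all_pairs(hsps, nchar(queries))
  cos <- call_orthologs(scores)
  hit <- cos$reference_gene ==
    copies$gene_id[match(cos$cluster, copies$copy_id)]
  expect_gte(mean(hit), 0.95)
  expect_gte(nrow(cos) / nrow(copies), 0.95)
})

test_that("CNV/PAV classification follows match structure and position", {
  genes <- data.frame(gene_id = c("gA", "gB", "gC", "gD"),
                      chromosome = c("chr1", "chr1", "chr1", "chr2"),
                      start = c(0, 1000, 2000, 0))
  mk <- function(q, s, cip = 95, calp = 0.9) {
    data.frame(query_id = q, subject_id = s, AL = 100, CIP = cip,
               CALP = calp, n_hsps = 1, stringsAsFactors = FALSE)
  }
  # all single-matched -> all COS, unmatched -> PAV
  scores <- rbind(mk("c1", "gA"), mk("c2", "gB"))
  cos <- call_orthologs(scores)
  calls <- classify_cnv_pav(scores, cos, genes)
  expect_equal(calls$relation[calls$reference_gene_id == "gA"], "COS")
  expect_equal(calls$relation[calls$reference_gene_id == "gC"], "PAV")
  expect_equal(calls$copy_count[calls$reference_gene_id == "gC"], 0)
  expect_equal(calls$copy_count[calls$reference_gene_id == "gD"], 0)
  # a cluster hitting two adjacent genes marks them CNV
  scores2 <- rbind(mk("c1", "gA"), mk("c1", "gB", cip = 92),
                   mk("c2", "gB"))
  cos2 <- call_orthologs(scores2)
  calls2 <- classify_cnv_pav(scores2, cos2, genes)
  expect_equal(calls2$relation[calls2$reference_gene_id == "gA"], "CNV")
  # unknown gene id in pairs is a contract violation
  badpairs <- data.frame(cluster = "c1", reference_gene = "nope")
  expect_error(classify_cnv_pav(scores, badpairs, genes), "unknown")
})

test_that("planted tandem duplicates are classified as CNV", {
  cfg <- sim_config(n_chromosomes = 2, genes_per_chromosome = 15,
                    gene_length_mean = 500, paralog_block_fraction = 0,
                    cnv_prob = 0.25, homoeolog_loss_prob = 0,
                    expr_divergence_prob = 0, mean_coverage = 0, seed = 42)
  g <- generate_genome(cfg)
  copies <- generate_hexaploid(g, cfg)
  queries <- stats::setNames(copies$sequence, copies$copy_id)
  hsps <- align_sequences(queries, g$sequences)
  scores <- score_all_pairs(hsps, nchar(queries))
  cos <- call_orthologs(scores)
  calls <- classify_cnv_pav(scores, cos, g$genes)
  tandems <- g$relationships[g$relationships$type == "tandem", ]
  expect_gt(nrow(tandems), 0)
  for (i in seq_len(nrow(tandems))) {
    call_parent <- calls$relation[
      calls$reference_gene_id == tandems$gene_a[i]]
    expect_equal(call_parent, "CNV")
  }
  # genes without tandem context stay COS
  plain <- setdiff(g$genes$gene_id[is.na(g$genes$tandem_parent)],
                   tandems$gene_a)
  expect_true(all(calls$relation[
    calls$reference_gene_id %in% plain] %in% c("COS", "PAV")))
})

test_that("coverage flagging finds merged-homoeolog clusters", {
  tab <- data.frame(cluster_id = sprintf("c%02d", 1:10),
                    n_reads = rep(40, 10), coverage = 25)
  expect_length(flag_merged_homoeologs(tab)$flagged, 0)
  tab$n_reads[1] <- 150
  res <- flag_merged_homoeologs(tab, k = 3.5)
  expect_equal(res$flagged, "c01")
  expect_error(flag_merged_homoeologs(tab[0, ]), "at least one")

  # planted merged homoeologs (SNP-free B/D siblings) inflate coverage
  cfg <- sim_config(n_chromosomes = 2, genes_per_chromosome = 10,
                    gene_length_mean = 1000, paralog_block_fraction = 0,
                    cnv_prob = 0, homoeolog_loss_prob = 0,
                    expr_divergence_prob = 0, seed = 3)
  sim <- simulate_transcriptome(cfg)
  merged_genes <- unique(sim$copies$gene_id)[1:2]
  # zero out homoeo-SNPs for the merged genes: all copies share sequence
  for (gid in merged_genes) {
    idx <- which(sim$copies$gene_id == gid)
    sim$copies$sequence[idx] <- sim$copies$sequence[idx[1]]
  }
  keep_a <- sim$read_truth$subgenome == "A" |
    sim$read_truth$gene_id %in% merged_genes
  rs <- sample_reads(sim$copies, cfg)
  reads <- rs$reads[rs$truth$read_id[rs$truth$subgenome == "A" |
                                       rs$truth$gene_id %in% merged_genes]]
  cl <- cluster_reads(reads)
  expect_equal(nrow(cl$clusters), 20)   # merged siblings co-assemble
  res2 <- flag_merged_homoeologs(coverage_profile(cl), k = 2)
  mm <- merge(cl$members, rs$truth[, c("read_id", "gene_id")])
  flagged_genes <- unique(mm$gene_id[mm$cluster_id %in% res2$flagged])
  expect_setequal(flagged_genes, merged_genes)
})

test_that("paralog pair retention arithmetic matches printed rates", {
  # 862 pairs of which 166 both-matched -> 19.3 % / 80.7 %
  pairs <- data.frame(gene_a = sprintf("a%03d", 1:862),
                      gene_b = sprintf("b%03d", 1:862))
  matched <- c(sprintf("a%03d", 1:400), sprintf("b%03d", 1:166),
               sprintf("b%03d", 500:600))
  res <- paralog_pair_status(pairs, matched)
  expect_equal(res$both, 166)
  expect_equal(res$both_pct, 19.3)
  expect_equal(res$not_both_pct, 80.7)
  expect_equal(res$both + res$one + res$none, 862)
  # nothing matched
  res0 <- paralog_pair_status(pairs, character(0))
  expect_equal(res0$both, 0)
  expect_equal(res0$none, 862)
  expect_equal(res0$both_pct, 0)
})

test_that("m8 round-trip preserves HSPs and coordinate conventions", {
  h <- rbind(hsp(q = "q1", s = "s1", qs = 10, qe = 110, ids = 95),
             hsp(q = "q2", s = "s2", qs = 0, qe = 50, ids = 50, bits = 80))
  h$orient <- "+"
  path <- tempfile(fileext = ".m8")
  write_m8(h, path)
  back <- read_m8(path)
  expect_equal(back$q_start, h$q_start)
  expect_equal(back$q_end, h$q_end)
  expect_equal(back$n_identities, h$n_identities)
  expect_equal(back$bitscore, h$bitscore)
})
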