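test_that("presence calling binarises levels against the threshold", {
  expect_equal(unname(call_presence(c(0, 0, 0))), c(FALSE, FALSE, FALSE))
  expect_equal(unname(call_presence(c(5, 0, 3), threshold = 1)),
               c(TRUE, FALSE, TRUE))
  expect_true(all(call_presence(c(5, 2, 3), threshold = 1.9)
                  [c(1, 3)]))
  expect_true(all(call_presence(c(5, 2, 3), threshold = 0)))
  expect_error(call_presence(c(-1, 2)), "non-negative")
})

test_that("triplet fate labels follow copy counts and profile identity", {
  p <- matrix(TRUE, nrow = 3, ncol = 5)
  expect_equal(classify_triplet_fate(p), "conserved")
  expect_equal(classify_triplet_fate(p[1:2, ]), "structural_loss")
  p2 <- p; p2[2, 3] <- FALSE
  expect_setequal(classify_triplet_fate(p2), "diverged_within_kinetic")
  # two copies that also diverge: both labels
  expect_setequal(classify_triplet_fate(p2[1:2, ] != p[1:2, ] | p2[1:2, ]),
                  "structural_loss")
  p3 <- p; tis <- matrix(TRUE, 3, 3); tis[1, 2] <- FALSE
  expect_setequal(classify_triplet_fate(p3, tis),
                  "diverged_between_tissues")
  expect_error(classify_triplet_fate(p[0, , drop = FALSE]), "zero")
})

test_that("fate summary reproduces small-panel percent arithmetic", {
  # 79 structurally assigned (43 with loss), 91 expression-assayed
  # (33 within-kinetic, 45 between-tissue), 27 fully conserved
  fs <- fate_summary(79, 43, 91, 33, 45, 27)
  expect_equal(fs$percent, c(54, 36, 49, 34))
  expect_equal(fs$count, c(43, 33, 45, 27))
  expect_equal(fs$denominator, c(79, 91, 91, 79))
  expect_error(fate_summary(79, 80, 91, 33, 45, 27))
})

test_that("fate classification aggregates match planted simulation rates", {
  cfg <- sim_config(n_chromosomes = 4, genes_per_chromosome = 500,
                    gene_length_mean = 400, paralog_block_fraction = 0,
                    cnv_prob = 0, homoeolog_loss_prob = 0.2,
                    expr_divergence_prob = 0.3, mean_coverage = 0,
                    seed = 61)
  copies <- generate_hexaploid(generate_genome(cfg), cfg)
  pm <- presence_matrix(copies)
  genes <- unique(copies$gene_id)
  labels <- lapply(genes, function(gid) {
    idx <- which(copies$gene_id == gid & !copies$deleted)
    if (length(idx) == 0) return(NULL)
    classify_triplet_fate(pm[idx, , drop = FALSE])
  })
  assayed <- !vapply(labels, is.null, logical(1))
  labels <- labels[assayed]
  n <- length(labels)
  # structural loss among assayed genes: 1 - p^3 / (1 - q^3), p = 0.8
  est_loss <- mean(vapply(labels, function(l)
    "structural_loss" %in% l, logical(1)))
  p_loss <- (1 - 0.8^3 - (1 - 0.8)^3) / (1 - 0.2^3)
  expect_lt(abs(est_loss - p_loss), 3 * sqrt(p_loss * (1 - p_loss) / n))
  # divergence among genes with >= 2 retained copies involves at least
  # one diverged copy; a diverged copy always alters its profile
  multi <- vapply(labels, function(l)
    !("structural_loss" %in% l) || TRUE, logical(1))
  est_div <- mean(vapply(labels, function(l)
    "diverged_within_kinetic" %in% l, logical(1)))
  expect_gt(est_div, 0.2)   # loose sanity bound; exact rate is compound
})

test_that("concerted expression rate matches printed truncation rules", {
  stages <- 5
  mk_profiles <- function(ids, flip = character(0)) {
    m <- matrix(TRUE, nrow = length(ids), ncol = stages,
                dimnames = list(ids))
    m[flip, 1] <- FALSE
    m
  }
  # 6760 pairs, 2600 concerted -> 38.4 (truncated, not rounded to 38.5)
  ids_a <- sprintf("w%04d", 1:6760)
  ids_b <- sprintf("r%04d", 1:6760)
  disc <- 2601:6760
  pa <- mk_profiles(ids_a, ids_a[disc])
  pb <- mk_profiles(ids_b)
  pairs <- data.frame(id_a = ids_a, id_b = ids_b)
  res <- concerted_expression_rate(pa, pb, pairs)
  expect_equal(res$n_concerted, 2600)
  expect_equal(res$percent, 38.4)

  # paralog rescue raises concerted pairs to 2944 -> 43.5 (truncated)
  rescue <- ids_a[2601:2944]
  par_ids <- paste0(rescue, "p")
  pa2 <- rbind(pa, mk_profiles(par_ids))
  paralogs_a <- stats::setNames(par_ids, rescue)
  res2 <- concerted_expression_rate(pa2, pb, pairs,
                                    paralogs_a = paralogs_a,
                                    include_paralogs = TRUE)
  expect_equal(res2$n_concerted, 2944)
  expect_equal(res2$percent, 43.5)

  # identical matrices: 100 %
  res3 <- concerted_expression_rate(pb, pb,
                                    data.frame(id_a = ids_b, id_b = ids_b))
  expect_equal(res3$percent, 100)
})

test_that("chi-square bias test flags inflated categories only", {
  set.seed(15)
  bg <- c(500, 300, 200, 100, 50)
  cats <- paste0("GO", seq_along(bg))
  # observed proportional to background: nothing flagged
  counts <- data.frame(category = cats, observed = bg / 10,
                       background = bg)
  res <- go_bias_test(counts)
  expect_false(any(res$biased))
  # one category inflated threefold at n = 1000
  obs <- round(bg / sum(bg) * 1000)
  obs[3] <- obs[3] * 3
  counts2 <- data.frame(category = cats, observed = obs,
                        background = bg)
  res2 <- go_bias_test(counts2)
  expect_true(res2$biased[3])
  # p-values match the reference chi-square implementation to 1e-9
  for (i in seq_len(nrow(counts2))) {
    tab <- matrix(c(counts2$observed[i], sum(counts2$observed) -
                      counts2$observed[i],
                    counts2$background[i], sum(counts2$background) -
                      counts2$background[i]), nrow = 2)
    ref <- stats::chisq.test(tab, correct = FALSE)
    expect_equal(res2$p_value[i], unname(ref$p.value), tolerance = 1e-9)
    expect_equal(res2$statistic[i], unname(ref$statistic),
                 tolerance = 1e-9)
  }
  # zero-margin categories are skipped with a warning, others reported
  counts3 <- rbind(counts2,
                   data.frame(category = "GOempty", observed = 0,
                              background = 0))
  expect_warning(res3 <- go_bias_test(counts3), "zero-margin")
  expect_equal(sum(res3$tested), 5)
  expect_equal(nrow(res3), 6)
})

test_that("network enrichment reproduces the pre-WGD reconstruction", {
  net <- starch_network_example()
  expect_equal(nrow(net), 170)
  res <- network_wgd_enrichment(net)
  expect_equal(res$n_pairs, 20)
  expect_equal(res$enrichment_percent, 12)
  expect_equal(res$pre_wgd_gene_count, 150)
  expect_equal(res$n_matched, 84)
  expect_equal(res$n_triplet, 6)
  expect_equal(res$triplet_percent, 7)
  # no pairs: zero enrichment, pre-WGD size = network size
  net0 <- data.frame(gene_id = letters[1:10],
                     duplicate_pair_id = NA_character_)
  res0 <- network_wgd_enrichment(net0)
  expect_equal(res0$enrichment_percent, 0)
  expect_equal(res0$pre_wgd_gene_count, 10)
  # a pair member outside the network is a contract violation
  bad <- data.frame(gene_id = letters[1:3],
                    duplicate_pair_id = c("d1", NA, NA))
  expect_error(network_wgd_enrichment(bad), "exactly 2")
})

test_that("differential expression calls planted shifts and nothing else", {
  set.seed(33)
  n_genes <- 100
  mat <- matrix(stats::rnorm(n_genes * 6, mean = 10), nrow = n_genes,
                dimnames = list(sprintf("gene%03d", 1:n_genes), NULL))
  groups <- rep(c("early", "late"), each = 3)
  # null: no calls expected at alpha 0.05 after Bonferroni
  res0 <- differential_expression(mat, groups)
  expect_equal(sum(res0$called), 0)
  # a planted shift must exceed ~8.6 pooled-SD units to clear the
  # Bonferroni threshold at df = 4 and m = 100 (t oracle:
  # qt(1 - 0.025/100, 4) * sqrt(2/3) = 8.61); plant 12 SD units
  mat2 <- mat
  mat2["gene050", 4:6] <- mat2["gene050", 4:6] + 12
  res <- differential_expression(mat2, groups)
  expect_true(res$called[res$gene == "gene050"])
  expect_equal(sum(res$called), 1)
  # p-values agree with the reference equal-variance t-test
  for (g in c("gene001", "gene050", "gene099")) {
    ref <- stats::t.test(mat2[g, 1:3], mat2[g, 4:6], var.equal = TRUE)
    row <- res[res$gene == g, ]
    if (!row$excluded) {
      expect_equal(row$p_value, ref$p.value, tolerance = 1e-12)
    }
  }
  # Bonferroni with a single tested gene equals the raw p-value
  res1 <- differential_expression(mat2[1, , drop = FALSE], groups,
                                  var_quantiles = c(0, 1))
  expect_equal(res1$p_bonferroni, res1$p_value)
  # constant-zero genes are excluded and recorded
  mat3 <- rbind(mat2, zero = 0)
  res3 <- differential_expression(mat3, groups)
  expect_true(res3$excluded[res3$gene == "zero"])
  expect_equal(res3$exclude_reason[res3$gene == "zero"], "constant_zero")
  # extreme-variance genes are excluded before testing
  expect_true(any(res3$exclude_reason == "extreme_variance"))
})
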