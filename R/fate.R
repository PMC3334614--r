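#' Binarise expression levels into a presence profile
#'
#' @param levels non-negative numeric vector (or matrix, entities x
#'   stages) of abundances
#' @param threshold presence threshold; a stage is present iff
#'   `level > threshold`
#' @return logical vector/matrix of presence flags
#' @export
call_presence <- function(levels, threshold = 0) {
  if (any(levels < 0, na.rm = TRUE)) {
    stop("expression levels must be non-negative", call. = FALSE)
  }
  levels > threshold
}

#' Classify the fate of one homoeolog triplet
#'
#' Given the grain-stage presence profiles of the detected copies of one
#' gene (and optionally whole-tissue presence flags), returns the fate
#' label set:
#' \itemize{
#'   \item `structural_loss` iff fewer than 3 copies were detected;
#'   \item `diverged_within_kinetic` iff the detected copies' grain-stage
#'     profiles differ;
#'   \item `diverged_between_tissues` iff tissue-level presence differs;
#'   \item `conserved` iff all 3 copies are present with identical
#'     profiles everywhere.
#' }
#'
#' @param grain_profiles logical matrix (copies x stages) for the
#'   detected copies; at least one row
#' @param tissue_profiles optional logical matrix (copies x tissues)
#' @return character vector of fate labels
#' @export
classify_triplet_fate <- function(grain_profiles, tissue_profiles = NULL) {
  if (is.null(dim(grain_profiles))) {
    grain_profiles <- matrix(grain_profiles, nrow = 1)
  }
  n_copies <- nrow(grain_profiles)
  if (n_copies == 0L) {
    stop("gene not assayed: zero detected copies", call. = FALSE)
  }
  labels <- character(0)
  if (n_copies < 3L) labels <- c(labels, "structural_loss")
  same_grain <- all(apply(grain_profiles, 2, function(col)
    length(unique(col)) == 1L))
  if (!same_grain) labels <- c(labels, "diverged_within_kinetic")
  same_tissue <- TRUE
  if (!is.null(tissue_profiles)) {
    if (is.null(dim(tissue_profiles))) {
      tissue_profiles <- matrix(tissue_profiles, nrow = 1)
    }
    same_tissue <- all(apply(tissue_profiles, 2, function(col)
      length(unique(col)) == 1L))
    if (!same_tissue) labels <- c(labels, "diverged_between_tissues")
  }
  if (n_copies == 3L && same_grain && same_tissue) {
    labels <- c(labels, "conserved")
  }
  labels
}

#' Summarise duplicate fates over their assay denominators
#'
#' Counts come from per-gene fate labels; structural loss and full
#' conservation are scored over the structurally assigned genes,
#' expression divergence over the expression-assayed genes.  Percentages
#' are rounded half-up to integers (the convention of small-panel assay
#' reporting).
#'
#' @param n_structural_assayed genes successfully assigned structurally
#' @param n_structural_loss genes with at least one copy lost
#' @param n_expr_assayed genes assayed for expression
#' @param n_expr_loss_within genes with divergence within the
#'   developmental kinetic
#' @param n_expr_loss_between genes with divergence between tissues
#' @param n_fully_conserved genes with 3 copies and identical profiles
#' @return data frame with one row per fate: count, denominator, percent
#' @export
fate_summary <- function(n_structural_assayed, n_structural_loss,
                         n_expr_assayed, n_expr_loss_within,
                         n_expr_loss_between, n_fully_conserved) {
  stopifnot(n_structural_loss <= n_structural_assayed,
            n_expr_loss_within <= n_expr_assayed,
            n_expr_loss_between <= n_expr_assayed,
            n_fully_conserved <= n_structural_assayed)
  data.frame(
    fate = c("structural_loss", "diverged_within_kinetic",
             "diverged_between_tissues", "fully_conserved"),
    count = c(n_structural_loss, n_expr_loss_within,
              n_expr_loss_between, n_fully_conserved),
    denominator = c(n_structural_assayed, n_expr_assayed,
                    n_expr_assayed, n_structural_assayed),
    percent = c(pct_round(n_structural_loss, n_structural_assayed),
                pct_round(n_expr_loss_within, n_expr_assayed),
                pct_round(n_expr_loss_between, n_expr_assayed),
                pct_round(n_fully_conserved, n_structural_assayed)),
    stringsAsFactors = FALSE)
}

#' Concerted presence/absence expression across two species
#'
#' An ortholog pair is concerted iff the two members' presence/absence
#' profiles over the shared stages are identical.  With
#' `include_paralogs = TRUE` a pair also counts if either member's
#' within-genome paralog has a profile identical to the partner's.  The
#' percentage is truncated (not rounded) to one decimal.
#'
#' @param profiles_a,profiles_b logical matrices (entities x stages)
#'   with entity row names
#' @param pairs data frame with columns id_a, id_b
#' @param paralogs_a,paralogs_b optional named character vectors mapping
#'   an entity to its paralog in the same genome
#' @param include_paralogs whether paralog profiles can stand in
#' @return list with `n_pairs`, `n_concerted`, `percent`
#' @export
concerted_expression_rate <- function(profiles_a, profiles_b, pairs,
                                      paralogs_a = NULL, paralogs_b = NULL,
                                      include_paralogs = FALSE) {
  stopifnot(nrow(pairs) >= 1L)
  prof <- function(m, id) {
    if (!is.null(id) && !is.na(id) && id %in% rownames(m)) m[id, ] else NULL
  }
  concerted <- vapply(seq_len(nrow(pairs)), function(i) {
    a <- prof(profiles_a, pairs$id_a[i])
    b <- prof(profiles_b, pairs$id_b[i])
    if (is.null(a) || is.null(b)) return(FALSE)
    if (identical(unname(a), unname(b))) return(TRUE)
    if (include_paralogs) {
      pa <- prof(profiles_a, unname(paralogs_a[pairs$id_a[i]]))
      pb <- prof(profiles_b, unname(paralogs_b[pairs$id_b[i]]))
      if (!is.null(pa) && identical(unname(pa), unname(b))) return(TRUE)
      if (!is.null(pb) && identical(unname(a), unname(pb))) return(TRUE)
    }
    FALSE
  }, logical(1))
  list(n_pairs = nrow(pairs),
       n_concerted = sum(concerted),
       percent = pct_trunc(sum(concerted), nrow(pairs), 1))
}

#' Chi-square bias test of gene-ontology category representation
#'
#' For each category, a 2x2 Pearson chi-square (no continuity
#' correction) of in-category versus rest, in the study set versus the
#' genome-wide background; categories with `p < alpha` are flagged.  No
#' multiplicity correction is applied.  Zero-margin tables are skipped
#' with a warning.
#'
#' @param counts data frame: category, observed (study-set counts),
#'   background (genome-wide counts)
#' @param alpha per-test significance threshold (default 0.01)
#' @return data frame: category, statistic, p_value, biased, tested
#' @export
go_bias_test <- function(counts, alpha = 0.01) {
  tot_obs <- sum(counts$observed)
  tot_bg <- sum(counts$background)
  stopifnot(tot_bg > 0)
  out <- lapply(seq_len(nrow(counts)), function(i) {
    a <- as.numeric(counts$observed[i]); b <- tot_obs - a
    c_ <- as.numeric(counts$background[i]); d <- tot_bg - c_
    tab <- matrix(c(a, b, c_, d), nrow = 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      warning("zero-margin table for category '", counts$category[i],
              "'; skipped", call. = FALSE)
      return(data.frame(category = counts$category[i],
                        statistic = NA_real_, p_value = NA_real_,
                        biased = NA, tested = FALSE,
                        stringsAsFactors = FALSE))
    }
    n <- sum(tab)
    # Pearson X^2 for a 2x2 table, closed form
    stat <- n * (a * d - b * c_)^2 /
      ((a + b) * (c_ + d) * (a + c_) * (b + d))
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    data.frame(category = counts$category[i], statistic = stat,
               p_value = p, biased = p < alpha, tested = TRUE,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Whole-genome-duplication enrichment of a gene network
#'
#' Given the members of a metabolic network annotated with retained
#' duplicate pairs, the enrichment is the share of genes that are the
#' "extra" member of a retained pair (integer percent) and the inferred
#' pre-duplication network size is the member count minus the number of
#' retained pairs.  If a homoeolog `copy_count` column is present, the
#' triplet rate among matched genes is reported as well.
#'
#' @param network data frame: gene_id, duplicate_pair_id (NA when the
#'   gene is not part of a retained pair), optionally copy_count
#' @return list: n_genes, n_pairs, enrichment_percent,
#'   pre_wgd_gene_count, and (with copy counts) n_matched, n_triplet,
#'   triplet_percent
#' @export
network_wgd_enrichment <- function(network) {
  pair_ids <- network$duplicate_pair_id[!is.na(network$duplicate_pair_id)]
  if (length(pair_ids) > 0L) {
    sizes <- table(pair_ids)
    if (any(sizes != 2L)) {
      stop("every duplicate pair must have exactly 2 members inside ",
           "the network", call. = FALSE)
    }
  }
  n <- nrow(network)
  n_pairs <- length(unique(pair_ids))
  out <- list(n_genes = n, n_pairs = n_pairs,
              enrichment_percent = if (n_pairs > 0L)
                pct_round(n_pairs, n) else 0,
              pre_wgd_gene_count = n - n_pairs)
  if ("copy_count" %in% names(network)) {
    matched <- network$copy_count > 0L
    out$n_matched <- sum(matched)
    out$n_triplet <- sum(network$copy_count == 3L)
    out$triplet_percent <- if (out$n_matched > 0L)
      pct_round(out$n_triplet, out$n_matched) else 0
  }
  out
}

#' Two-group equal-variance differential expression
#'
#' Per-gene homoscedastic (pooled-variance) t-tests between two sample
#' groups.  Genes with extreme pooled variance (outside
#' `var_quantiles`) and all-zero genes are excluded before testing; raw
#' p-values are Bonferroni-adjusted over the tested genes and a gene is
#' called differentially expressed iff the adjusted p-value is below
#' `alpha`.
#'
#' @param mat numeric matrix, genes x samples
#' @param groups factor (or vector) of two group labels, one per column
#' @param alpha familywise threshold on the Bonferroni-adjusted p-value
#' @param var_quantiles lower/upper pooled-variance quantiles kept
#' @return data frame: gene, mean_1, mean_2, t, df, p_value,
#'   p_bonferroni, called, excluded, exclude_reason
#' @export
differential_expression <- function(mat, groups, alpha = 0.05,
                                    var_quantiles = c(0.005, 0.995)) {
  groups <- as.factor(groups)
  stopifnot(nlevels(groups) == 2L, length(groups) == ncol(mat),
            all(table(groups) >= 2L))
  g1 <- groups == levels(groups)[1]
  g2 <- !g1
  n1 <- sum(g1); n2 <- sum(g2)
  m1 <- rowMeans(mat[, g1, drop = FALSE])
  m2 <- rowMeans(mat[, g2, drop = FALSE])
  v1 <- apply(mat[, g1, drop = FALSE], 1, stats::var)
  v2 <- apply(mat[, g2, drop = FALSE], 1, stats::var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)

  excluded <- rep(FALSE, nrow(mat))
  reason <- rep("", nrow(mat))
  allzero <- rowSums(mat != 0) == 0L
  excluded[allzero] <- TRUE
  reason[allzero] <- "constant_zero"
  q <- stats::quantile(sp2[!excluded], probs = var_quantiles)
  extreme <- !excluded & (sp2 < q[1] | sp2 > q[2])
  excluded[extreme] <- TRUE
  reason[extreme] <- "extreme_variance"

  tstat <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  dfree <- n1 + n2 - 2
  p <- 2 * stats::pt(abs(tstat), df = dfree, lower.tail = FALSE)
  p[excluded] <- NA_real_
  m_tests <- sum(!excluded)
  p_bonf <- pmin(p * m_tests, 1)
  genes <- if (is.null(rownames(mat))) as.character(seq_len(nrow(mat)))
  else rownames(mat)
  data.frame(gene = genes, mean_1 = m1, mean_2 = m2, t = tstat,
             df = dfree, p_value = p, p_bonferroni = p_bonf,
             called = !excluded & !is.na(p_bonf) & p_bonf < alpha,
             excluded = excluded, exclude_reason = reason,
             row.names = NULL, stringsAsFactors = FALSE)
}
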