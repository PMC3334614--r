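#' Read tabular pairwise alignments (12-column "m8" format)
#'
#' Columns: qid sid pident length mismatch gapopen qstart qend sstart
#' send evalue bitscore, with 1-based inclusive coordinates on disk;
#' they are converted to 0-based half-open on read.  `n_identities` is
#' reconstructed as `round(pident / 100 * length)`.
#'
#' @param path file path
#' @return HSP data frame (query_id, subject_id, q_start, q_end,
#'   s_start, s_end, length, n_identities, bitscore)
#' @export
read_m8 <- function(path) {
  x <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                         col.names = c("qid", "sid", "pident", "length",
                                       "mismatch", "gapopen", "qstart",
                                       "qend", "sstart", "send", "evalue",
                                       "bitscore"))
  data.frame(query_id = x$qid, subject_id = x$sid,
             q_start = pmin(x$qstart, x$qend) - 1L,
             q_end = pmax(x$qstart, x$qend),
             s_start = pmin(x$sstart, x$send) - 1L,
             s_end = pmax(x$sstart, x$send),
             length = x$length,
             n_identities = as.integer(round(x$pident / 100 * x$length)),
             bitscore = x$bitscore,
             stringsAsFactors = FALSE)
}

#' Chain the HSPs of one query-subject pair into AL, CIP and CALP
#'
#' The aligned length AL is the total span of the HSP query intervals
#' after merging; where HSPs overlap on the query, the overlapped region
#' is credited to the higher-bitscore HSP and identities are prorated by
#' the fraction of the HSP's query span retained.  The cumulative
#' identity percentage is `CIP = 100 * sum(identities) / AL` and the
#' cumulative alignment length percentage is `CALP = AL / query_length`;
#' merging guarantees `CALP <= 1`.
#'
#' @param hsps HSP data frame for a single query-subject pair
#'   (0-based half-open query coordinates)
#' @param query_length query sequence length in bases
#' @return one-row data frame: query_id, subject_id, AL, CIP, CALP,
#'   n_hsps
#' @export
score_alignment <- function(hsps, query_length) {
  stopifnot(nrow(hsps) > 0L, query_length > 0)
  if (length(unique(hsps$query_id)) != 1L ||
      length(unique(hsps$subject_id)) != 1L) {
    stop("all HSPs must share one query and one subject", call. = FALSE)
  }
  stopifnot(all(hsps$q_start < hsps$q_end),
            all(hsps$n_identities >= 0),
            all(hsps$n_identities <= hsps$length))
  ord <- order(-hsps$bitscore, hsps$q_start, hsps$s_start)
  hsps <- hsps[ord, , drop = FALSE]
  covered <- IRanges::IRanges()
  al <- 0L
  ids <- 0
  for (i in seq_len(nrow(hsps))) {
    span <- IRanges::IRanges(start = hsps$q_start[i] + 1L,
                             end = hsps$q_end[i])
    new <- IRanges::setdiff(span, covered)
    w <- sum(IRanges::width(new))
    if (w > 0L) {
      qspan <- hsps$q_end[i] - hsps$q_start[i]
      ids <- ids + hsps$n_identities[i] * w / qspan
      al <- al + w
      covered <- IRanges::union(covered, span)
    }
  }
  data.frame(query_id = hsps$query_id[1], subject_id = hsps$subject_id[1],
             AL = al, CIP = 100 * ids / al, CALP = al / query_length,
             n_hsps = nrow(hsps), stringsAsFactors = FALSE)
}

#' Score every query-subject pair of an HSP table
#'
#' @param hsps HSP data frame (possibly many pairs)
#' @param query_lengths named numeric vector of query lengths
#' @return data frame of alignment scores, one row per pair
#' @export
score_all_pairs <- function(hsps, query_lengths) {
  if (nrow(hsps) == 0L) {
    return(data.frame(query_id = character(0), subject_id = character(0),
                      AL = integer(0), CIP = numeric(0), CALP = numeric(0),
                      n_hsps = integer(0), stringsAsFactors = FALSE))
  }
  key <- paste(hsps$query_id, hsps$subject_id, sep = "\r")
  out <- lapply(split(seq_len(nrow(hsps)), key), function(idx) {
    q <- hsps$query_id[idx[1]]
    score_alignment(hsps[idx, , drop = FALSE], query_lengths[[q]])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$query_id, res$subject_id), , drop = FALSE]
}

#' Call one-to-one ortholog (COS) pairs from alignment scores
#'
#' Retains pairs with `CIP >= cip_min` and `CALP >= calp_min` (the
#' boundaries are inclusive) and keeps, for each query, the best subject:
#' highest CIP, ties broken by CALP, then by lexicographic subject id.
#'
#' @param scores alignment-score data frame from [score_all_pairs()]
#' @param cip_min minimum cumulative identity percentage (default 60)
#' @param calp_min minimum cumulative alignment length proportion
#'   (default 0.70)
#' @return data frame of (cluster, reference_gene, CIP, CALP) pairs
#' @export
call_orthologs <- function(scores, cip_min = 60, calp_min = 0.70) {
  keep <- scores[scores$CIP >= cip_min & scores$CALP >= calp_min, ,
                 drop = FALSE]
  if (nrow(keep) == 0L) {
    return(data.frame(cluster = character(0), reference_gene = character(0),
                      CIP = numeric(0), CALP = numeric(0),
                      stringsAsFactors = FALSE))
  }
  keep <- keep[order(keep$query_id, -keep$CIP, -keep$CALP,
                     keep$subject_id), , drop = FALSE]
  best <- keep[!duplicated(keep$query_id), , drop = FALSE]
  out <- data.frame(cluster = best$query_id,
                    reference_gene = best$subject_id,
                    CIP = best$CIP, CALP = best$CALP,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Protein-level domain homologs against multiple reference proteomes
#'
#' A cluster is a homolog of a proteome if any subject in it reaches
#' `identity_min` (inclusive); clusters matching no proteome are
#' "putative species-specific".
#'
#' @param protein_scores data frame with columns query_id, proteome,
#'   identity (proportion in [0, 1])
#' @param identity_min protein identity threshold (default 0.50)
#' @return list with `homologs` (query_id, proteome), `specific`
#'   (character vector of species-specific query ids, given the queries
#'   present in the table) and `shared_by` (table: number of proteomes
#'   matched -> number of clusters)
#' @export
call_domain_homologs <- function(protein_scores, identity_min = 0.50) {
  hit <- protein_scores[protein_scores$identity >= identity_min, ,
                        drop = FALSE]
  hit <- unique(hit[, c("query_id", "proteome")])
  all_q <- unique(protein_scores$query_id)
  n_prot <- table(factor(hit$query_id, levels = all_q))
  list(homologs = hit,
       specific = all_q[n_prot == 0L],
       shared_by = table(as.integer(n_prot[n_prot > 0L])))
}

#' Classify reference genes as COS, tandem CNV or PAV
#'
#' Reference genes with no passing match are PAV (copy count 0).  A
#' matched gene is called CNV when its matches are entangled with a
#' tandem-adjacent reference copy: some cluster passes the thresholds
#' against both the gene and another reference gene within
#' `tandem_window` positions on the same chromosome (the neighbour need
#' not win any best-hit itself).  All other matched genes are COS.  Copy counts are distinct best-matching clusters,
#' capped at 3 (supernumerary matches are reported separately).
#'
#' @param scores full alignment-score table (used to detect clusters
#'   that hit two tandem-adjacent reference genes)
#' @param cos_pairs best-hit pairs from [call_orthologs()]
#' @param reference_genes gene-model table (gene_id, chromosome, start)
#' @param tandem_window tandem neighbourhood in gene positions
#' @param cip_min,calp_min thresholds used for the cross-hit test
#' @return data frame: reference_gene_id, relation, copy_count,
#'   supernumerary, matched_cluster_ids (comma-separated)
#' @export
classify_cnv_pav <- function(scores, cos_pairs, reference_genes,
                             tandem_window = 1L,
                             cip_min = 60, calp_min = 0.70) {
  if (!all(cos_pairs$reference_gene %in% reference_genes$gene_id)) {
    stop("cos_pairs reference unknown gene ids", call. = FALSE)
  }
  g <- reference_genes[order(reference_genes$chromosome,
                             reference_genes$start), , drop = FALSE]
  g$rank <- stats::ave(seq_len(nrow(g)), g$chromosome, FUN = seq_along)
  matched <- split(cos_pairs$cluster, cos_pairs$reference_gene)
  passing <- scores[scores$CIP >= cip_min & scores$CALP >= calp_min, ,
                    drop = FALSE]
  hit_genes <- split(passing$subject_id, passing$query_id)

  out <- lapply(seq_len(nrow(g)), function(i) {
    gid <- g$gene_id[i]
    cl <- matched[[gid]]
    if (is.null(cl) || length(cl) == 0L) {
      return(data.frame(reference_gene_id = gid, relation = "PAV",
                        copy_count = 0L, supernumerary = 0L,
                        matched_cluster_ids = "",
                        stringsAsFactors = FALSE))
    }
    nb <- g$gene_id[g$chromosome == g$chromosome[i] &
                      abs(g$rank - g$rank[i]) <= tandem_window &
                      g$gene_id != gid]
    is_cnv <- FALSE
    if (length(nb) > 0L) {
      # any passing cluster hitting both this gene and a matched neighbour
      both_hitters <- vapply(hit_genes, function(s)
        gid %in% s && any(nb %in% s), logical(1))
      is_cnv <- any(both_hitters)
    }
    nc <- length(unique(cl))
    data.frame(reference_gene_id = gid,
               relation = if (is_cnv) "CNV" else "COS",
               copy_count = min(nc, 3L),
               supernumerary = max(0L, nc - 3L),
               matched_cluster_ids = paste(sort(unique(cl)),
                                           collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Homoeolog copy-count histogram and triplet fraction
#'
#' Counts distinct matched clusters per reference gene (capped at 3) and
#' reports the histogram \{1: n1, 2: n2, 3: n3\} together with the
#' triplet fraction `100 * n3 / (n1 + n2 + n3)` rounded half-up to one
#' decimal.
#'
#' @param cos_pairs data frame with columns `cluster` and
#'   `reference_gene` (one row per matched cluster), or a precomputed
#'   integer vector of per-gene copy counts
#' @return list with `histogram` (named counts for 1..3),
#'   `triplet_fraction` (percent, one decimal), `n_genes`, and
#'   `supernumerary` (genes with more than 3 matches beyond the cap)
#' @export
count_homoeolog_copies <- function(cos_pairs) {
  counts <- if (is.numeric(cos_pairs)) {
    as.integer(cos_pairs)
  } else {
    as.integer(table(cos_pairs$reference_gene)[
      unique(cos_pairs$reference_gene)])
  }
  counts <- counts[counts > 0L]
  supern <- sum(counts > 3L)
  capped <- pmin(counts, 3L)
  hist <- vapply(1:3, function(k) sum(capped == k), integer(1))
  names(hist) <- as.character(1:3)
  list(histogram = hist,
       triplet_fraction = pct_round(hist[["3"]], sum(hist), 1),
       n_genes = sum(hist),
       supernumerary = supern)
}

#' Flag putatively merged-homoeolog clusters by read coverage
#'
#' Homoeologous copies without distinguishing SNPs inside the sequenced
#' region co-assemble into one cluster, inflating its read count.
#' Clusters with more than `k` times the single-copy centre of the
#' read-count distribution are flagged; the centre is estimated by the
#' median, which is insensitive to the inflated tail being flagged (the
#' default multiplier 3.5 reproduces a 140-read flag against a ~40-read
#' single-copy mean).
#'
#' @param coverage_table data frame (cluster_id, n_reads, ...) or the
#'   list returned by [coverage_profile()]
#' @param k multiplier over the global mean read count
#' @return list with `flagged` (cluster ids), `fraction` of all
#'   clusters, `threshold` (reads) and `mean_reads`
#' @export
flag_merged_homoeologs <- function(coverage_table, k = 3.5) {
  tab <- if (is.list(coverage_table) && !is.data.frame(coverage_table)) {
    coverage_table$table
  } else coverage_table
  if (is.null(tab) || nrow(tab) == 0L) {
    stop("coverage table must contain at least one cluster", call. = FALSE)
  }
  m <- stats::median(tab$n_reads)
  thr <- k * m
  flagged <- tab$cluster_id[tab$n_reads > thr]
  list(flagged = flagged,
       fraction = length(flagged) / nrow(tab),
       threshold = thr,
       mean_reads = m)
}

#' Retention status of ancestral paralog pairs in the target gene set
#'
#' @param paralog_pairs data frame with columns gene_a, gene_b
#' @param matched_genes character vector of reference genes with at
#'   least one expressed match in the target
#' @return list of counts \{both, one, none\}, `n_pairs`,
#'   `both_pct` and `not_both_pct` (one decimal, rounded half-up)
#' @export
paralog_pair_status <- function(paralog_pairs, matched_genes) {
  n <- nrow(paralog_pairs)
  if (n == 0L) {
    return(list(both = 0L, one = 0L, none = 0L, n_pairs = 0L,
                both_pct = 0, not_both_pct = 0))
  }
  a <- paralog_pairs$gene_a %in% matched_genes
  b <- paralog_pairs$gene_b %in% matched_genes
  both <- sum(a & b)
  one <- sum(xor(a, b))
  none <- sum(!a & !b)
  list(both = both, one = one, none = none, n_pairs = n,
       both_pct = pct_round(both, n, 1),
       not_both_pct = pct_round(one + none, n, 1))
}
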