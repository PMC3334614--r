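# small simulation used by several tests
small_config <- function(...) {
  defaults <- list(n_chromosomes = 2, genes_per_chromosome = 10,
                   gene_length_mean = 1000, paralog_block_fraction = 0,
                   paralog_loss_prob = 0, cnv_prob = 0,
                   homoeolog_loss_prob = 0, expr_divergence_prob = 0,
                   seed = 11)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

# build an HSP row in the internal 0-based half-open form
hsp <- function(q = "q1", s = "s1", qs, qe, ss = qs, se = qe,
                ids = qe - qs, bits = 100) {
  data.frame(query_id = q, subject_id = s, q_start = qs, q_end = qe,
             s_start = ss, s_end = se, length = qe - qs,
             n_identities = ids, bitscore = bits,
             stringsAsFactors = FALSE)
}

# brute-force per-column CIP/CALP oracle: each query column belongs to
# the covering HSP with the highest bitscore (ties: q_start, s_start
# order); identity credited at that HSP's per-column identity density
score_alignment_oracle <- function(hsps, query_length) {
  ord <- order(-hsps$bitscore, hsps$q_start, hsps$s_start)
  hsps <- hsps[ord, , drop = FALSE]
  owner <- rep(NA_integer_, query_length)
  for (i in seq_len(nrow(hsps))) {
    cols <- (hsps$q_start[i] + 1):hsps$q_end[i]
    free <- cols[is.na(owner[cols])]
    owner[free] <- i
  }
  al <- sum(!is.na(owner))
  dens <- hsps$n_identities / (hsps$q_end - hsps$q_start)
  ids <- sum(dens[owner[!is.na(owner)]])
  list(AL = al, CIP = 100 * ids / al, CALP = al / query_length)
}

# brute-force maximal-run block oracle: from each unassigned position,
# extend to the longest valid monotone run with rank gaps <= gap_limit
detect_blocks_oracle <- function(ranks, gap_limit) {
  n <- length(ranks)
  valid_run <- function(i, j) {
    if (i == j) return(TRUE)
    d <- diff(ranks[i:j])
    if (any(d == 0)) return(FALSE)
    if (length(unique(sign(d))) > 1) return(FALSE)
    all(abs(d) - 1 <= gap_limit)
  }
  assignment <- integer(n)
  blk <- 0L
  i <- 1L
  while (i <= n) {
    j <- i
    for (jj in n:i) {
      if (valid_run(i, jj)) { j <- jj; break }
    }
    blk <- blk + 1L
    assignment[i:j] <- blk
    i <- j + 1L
  }
  assignment
}

random_reads_from <- function(seq, n, len, seed) {
  set.seed(seed)
  starts <- sample(nchar(seq) - len + 1, n, replace = TRUE)
  reads <- substring(seq, starts, starts + len - 1)
  names(reads) <- sprintf("rr%03d", seq_len(n))
  reads
}
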