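#' Simulation configuration for a synthetic allohexaploid transcriptome
#'
#' Builds and validates the parameter set controlling the synthetic
#' diploid reference genome and the derived three-subgenome (A/B/D)
#' transcriptome.  The defaults emulate the statistical structure of a
#' hexaploid grain transcriptome assayed by long expressed-sequence
#' reads: sibling subgenome copies differing at ~1 SNP per 500 bp,
#' ~25x read coverage per transcript copy, read lengths of 400-900
#' bases, and five developmental stages of grain filling.
#'
#' @param n_chromosomes number of chromosomes in the reference genome
#' @param genes_per_chromosome gene models per chromosome
#' @param gene_length_mean mean gene (transcript) length in bases
#' @param paralog_block_fraction fraction of genes lying inside ancestral
#'   whole-genome-duplication paralog blocks (each such gene has a
#'   collinear partner on another chromosome)
#' @param paralog_loss_prob probability that a paleoparalog copy has been
#'   anciently deleted (it then contributes no transcript copies)
#' @param homoeolog_snp_rate pairwise substitution density between sibling
#'   subgenome copies, per base (default 1/500)
#' @param homoeolog_loss_prob probability that each A/B/D copy of a gene
#'   is independently deleted
#' @param expr_divergence_prob probability that a retained copy diverges
#'   from the ancestral stage-presence profile
#' @param cnv_prob probability that a gene carries a tandem extra copy
#' @param mean_coverage expected read depth per expressed transcript copy
#' @param read_length_range integer (min, max) read length in bases
#' @param n_stages number of developmental stages
#' @param seed integer random seed; identical seed and config give
#'   bit-identical outputs
#' @return an object of class `sim_config`
#' @export
sim_config <- function(n_chromosomes = 2,
                       genes_per_chromosome = 50,
                       gene_length_mean = 1200,
                       paralog_block_fraction = 0.2,
                       paralog_loss_prob = 0.4,
                       homoeolog_snp_rate = 1 / 500,
                       homoeolog_loss_prob = 0.2,
                       expr_divergence_prob = 0.3,
                       cnv_prob = 0.05,
                       mean_coverage = 25,
                       read_length_range = c(400L, 900L),
                       n_stages = 5,
                       seed = 1L) {
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes),
    genes_per_chromosome = as.integer(genes_per_chromosome),
    gene_length_mean = as.integer(gene_length_mean),
    paralog_block_fraction = paralog_block_fraction,
    paralog_loss_prob = paralog_loss_prob,
    homoeolog_snp_rate = homoeolog_snp_rate,
    homoeolog_loss_prob = homoeolog_loss_prob,
    expr_divergence_prob = expr_divergence_prob,
    cnv_prob = cnv_prob,
    mean_coverage = mean_coverage,
    read_length_range = as.integer(read_length_range),
    n_stages = as.integer(n_stages),
    seed = as.integer(seed)
  )
  probs <- c("paralog_block_fraction", "paralog_loss_prob",
             "homoeolog_loss_prob", "expr_divergence_prob", "cnv_prob")
  for (p in probs) {
    if (!is.numeric(cfg[[p]]) || cfg[[p]] < 0 || cfg[[p]] > 1) {
      stop("`", p, "` must be a probability in [0, 1]", call. = FALSE)
    }
  }
  if (cfg$homoeolog_snp_rate <= 0 || cfg$homoeolog_snp_rate > 0.05) {
    stop("`homoeolog_snp_rate` must lie in (0, 0.05]", call. = FALSE)
  }
  for (p in c("n_chromosomes", "genes_per_chromosome", "gene_length_mean",
              "n_stages")) {
    if (cfg[[p]] <= 0L) stop("`", p, "` must be strictly positive",
                             call. = FALSE)
  }
  if (cfg$mean_coverage < 0) stop("`mean_coverage` must be >= 0",
                                  call. = FALSE)
  if (length(cfg$read_length_range) != 2L ||
      any(cfg$read_length_range <= 0L) ||
      cfg$read_length_range[1] > cfg$read_length_range[2]) {
    stop("`read_length_range` must be positive (min, max)", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

INTERGENIC_GAP <- 200L

#' Generate a toy diploid reference genome
#'
#' Lays out gene models along chromosomes, plants ancestral
#' whole-genome-duplication paralog blocks (collinear runs of genes whose
#' diverged sequence copies sit on a different chromosome) and tandem
#' copy-number-variant genes, and records every planted relationship in a
#' truth table.  Coordinates are 0-based half-open internally; the GFF3
#' writer converts to 1-based closed.
#'
#' Exactly `round(paralog_block_fraction * n_genes)` genes (rounded down
#' to an even count) are placed inside paralog blocks; tandem copies are
#' drawn per-gene with probability `cnv_prob`.  Paralog partner sequences
#' diverge from their source at an ancient-duplication substitution rate
#' (8\% per base); tandem copies inherit the parent sequence with fresh
#' substitutions at the homoeolog rate, so they are distinguishable from
#' homoeologs only by genomic position.
#'
#' @param config a [sim_config()]
#' @return list with `genes` (gene-model table: gene_id, chromosome,
#'   start, end, strand, paralog_partner, tandem_parent), `sequences`
#'   (named character, ancestral transcript per gene) and
#'   `relationships` (truth table of planted paralog pairs and tandems)
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 1L))
  n_genes <- config$n_chromosomes * config$genes_per_chromosome

  chroms <- rep(paste0("chr", seq_len(config$n_chromosomes)),
                each = config$genes_per_chromosome)
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  lens <- pmax(300L, as.integer(round(stats::rnorm(
    n_genes, config$gene_length_mean, config$gene_length_mean / 10))))

  genes <- data.frame(
    gene_id = gene_ids, chromosome = chroms,
    start = NA_integer_, end = NA_integer_,
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    paralog_partner = NA_character_, tandem_parent = NA_character_,
    stringsAsFactors = FALSE
  )
  sequences <- vapply(lens, random_dna, character(1))
  names(sequences) <- gene_ids

  # ancestral WGD paralog blocks: pair collinear runs across chromosomes
  rel <- list()
  n_in_blocks <- round(config$paralog_block_fraction * n_genes)
  n_pairs <- n_in_blocks %/% 2L
  if (n_pairs > 0L) {
    if (config$n_chromosomes < 2L) {
      stop("paralog blocks need at least 2 chromosomes", call. = FALSE)
    }
    block_len <- 4L
    used <- rep(FALSE, n_genes)
    idx_of <- function(chr, pos) (chr - 1L) * config$genes_per_chromosome + pos
    remaining <- n_pairs
    guard <- 0L
    while (remaining > 0L && guard < 10000L) {
      guard <- guard + 1L
      L <- min(block_len, remaining)
      ca <- sample(config$n_chromosomes, 1L)
      others <- setdiff(seq_len(config$n_chromosomes), ca)
      cb <- others[sample.int(length(others), 1L)]
      if (config$genes_per_chromosome < L) L <- config$genes_per_chromosome
      pa <- sample(config$genes_per_chromosome - L + 1L, 1L)
      pb <- sample(config$genes_per_chromosome - L + 1L, 1L)
      ia <- idx_of(ca, pa:(pa + L - 1L))
      ib <- idx_of(cb, pb:(pb + L - 1L))
      if (any(used[c(ia, ib)])) next
      used[c(ia, ib)] <- TRUE
      genes$paralog_partner[ia] <- gene_ids[ib]
      genes$paralog_partner[ib] <- gene_ids[ia]
      # partner sequences descend from the source at ancient divergence
      for (k in seq_len(L)) {
        sequences[[ib[k]]] <- mutate_sequence(sequences[[ia[k]]], 0.08)$seq
        rel[[length(rel) + 1L]] <- data.frame(
          type = "paralog_pair", gene_a = gene_ids[ia[k]],
          gene_b = gene_ids[ib[k]], stringsAsFactors = FALSE)
      }
      remaining <- remaining - L
    }
    if (remaining > 0L) {
      stop("could not place the requested paralog blocks", call. = FALSE)
    }
  }

  # tandem CNV copies, adjacent on the same chromosome
  tandem_rows <- list()
  tandem_seqs <- character(0)
  is_tandem <- stats::runif(n_genes) < config$cnv_prob
  for (i in which(is_tandem)) {
    tid <- paste0(gene_ids[i], "t")
    tandem_rows[[length(tandem_rows) + 1L]] <- data.frame(
      gene_id = tid, chromosome = genes$chromosome[i],
      start = NA_integer_, end = NA_integer_, strand = genes$strand[i],
      paralog_partner = NA_character_, tandem_parent = gene_ids[i],
      stringsAsFactors = FALSE)
    tandem_seqs[tid] <-
      mutate_sequence(sequences[[i]], config$homoeolog_snp_rate / 2)$seq
    rel[[length(rel) + 1L]] <- data.frame(
      type = "tandem", gene_a = gene_ids[i], gene_b = tid,
      stringsAsFactors = FALSE)
  }
  if (length(tandem_rows) > 0L) {
    genes <- rbind(genes, do.call(rbind, tandem_rows))
    sequences <- c(sequences, tandem_seqs)
  }

  # lay out coordinates: tandem copies immediately follow their parent
  genes$pos_key <- match(ifelse(is.na(genes$tandem_parent),
                                genes$gene_id, genes$tandem_parent),
                         gene_ids) + ifelse(is.na(genes$tandem_parent), 0, 0.5)
  genes <- genes[order(genes$chromosome, genes$pos_key), ]
  for (chr in unique(genes$chromosome)) {
    sel <- which(genes$chromosome == chr)
    cursor <- 0L
    for (i in sel) {
      len <- nchar(sequences[[genes$gene_id[i]]])
      genes$start[i] <- cursor
      genes$end[i] <- cursor + len
      cursor <- cursor + len + INTERGENIC_GAP
    }
  }
  genes$pos_key <- NULL
  rownames(genes) <- NULL

  relationships <- if (length(rel) > 0L) do.call(rbind, rel) else
    data.frame(type = character(0), gene_a = character(0),
               gene_b = character(0), stringsAsFactors = FALSE)
  list(genes = genes, sequences = sequences, relationships = relationships)
}

# ancestral stage-presence profile: each stage present w.p. 0.8, >= 1 present
ancestral_profile <- function(n_stages) {
  repeat {
    p <- stats::runif(n_stages) < 0.8
    if (any(p)) return(p)
  }
}

# divergence mechanism: flip each stage flag w.p. rate/n_stages, force one
# flip if none occurred, so the marginal per-copy divergence rate is exact
diverge_profile <- function(profile, rate) {
  n <- length(profile)
  flip <- stats::runif(n) < rate / n
  if (!any(flip)) flip[sample(n, 1L)] <- TRUE
  xor(profile, flip)
}

#' Derive allohexaploid transcript copies from a reference genome
#'
#' Each gene model (unless its whole locus was anciently lost as a
#' paleoparalog) yields three transcript copies on the A, B and D
#' subgenomes.  Copies are independently deleted with
#' `homoeolog_loss_prob`; retained copies are mutated from the ancestral
#' sequence at `homoeolog_snp_rate / 2` per base so that sibling pairs
#' differ at the configured pairwise homoeo-SNP density; each copy
#' diverges from the ancestral stage-presence profile with
#' `expr_divergence_prob`.
#'
#' @param genome output of [generate_genome()]
#' @param config the same [sim_config()]
#' @return data frame of transcript copies: copy_id, gene_id, subgenome,
#'   deleted, ancient_loss, diverged, sequence, presence (0/1 string over
#'   stages) and levels (comma-joined abundances)
#' @export
generate_hexaploid <- function(genome, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 2L))
  genes <- genome$genes
  n_stages <- config$n_stages

  anc_profiles <- lapply(seq_len(nrow(genes)),
                         function(i) ancestral_profile(n_stages))
  names(anc_profiles) <- genes$gene_id
  # tandem copies share the parent's ancestral profile
  for (i in which(!is.na(genes$tandem_parent))) {
    anc_profiles[[genes$gene_id[i]]] <-
      anc_profiles[[genes$tandem_parent[i]]]
  }

  ancient_lost <- !is.na(genes$paralog_partner) &
    stats::runif(nrow(genes)) < config$paralog_loss_prob

  rows <- vector("list", nrow(genes) * 3L)
  k <- 0L
  for (i in seq_len(nrow(genes))) {
    gid <- genes$gene_id[i]
    anc_seq <- genome$sequences[[gid]]
    anc_prof <- anc_profiles[[gid]]
    for (sg in c("A", "B", "D")) {
      k <- k + 1L
      deleted <- ancient_lost[i] ||
        stats::runif(1) < config$homoeolog_loss_prob
      seq <- mutate_sequence(anc_seq, config$homoeolog_snp_rate / 2)$seq
      diverged <- stats::runif(1) < config$expr_divergence_prob
      prof <- if (diverged) {
        diverge_profile(anc_prof, config$expr_divergence_prob)
      } else anc_prof
      lev <- ifelse(prof, round(stats::rlnorm(n_stages, log(20), 0.5), 1), 0)
      rows[[k]] <- data.frame(
        copy_id = paste0(gid, "_", sg), gene_id = gid, subgenome = sg,
        deleted = deleted, ancient_loss = ancient_lost[i],
        diverged = diverged, sequence = seq,
        presence = paste(as.integer(prof), collapse = ""),
        levels = paste(lev, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Stage-presence matrix from a transcript-copy table
#'
#' @param copies output of [generate_hexaploid()]
#' @return logical matrix, copies x stages
#' @export
presence_matrix <- function(copies) {
  m <- t(vapply(strsplit(copies$presence, ""),
                function(x) as.integer(x) == 1L,
                logical(nchar(copies$presence[1]))))
  rownames(m) <- copies$copy_id
  colnames(m) <- paste0("stage", seq_len(ncol(m)))
  m
}

#' Sample expressed-sequence reads from transcript copies
#'
#' Reads are drawn only from copies that are not deleted and are present
#' in at least one stage.  Per-copy read counts are Poisson with mean
#' `mean_coverage * copy_length / mean(read_length_range)` so the
#' expected depth per copy equals `mean_coverage`; read lengths are
#' uniform over `read_length_range` (clipped to the copy length), start
#' positions uniform, and strands random.  Read identifiers are opaque;
#' the source of every read is recorded only in the returned truth map.
#'
#' @param copies output of [generate_hexaploid()]
#' @param config the same [sim_config()]
#' @return list with `reads` (named character vector of sequences) and
#'   `truth` (read_id, copy_id, gene_id, subgenome, start, strand)
#' @export
sample_reads <- function(copies, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 3L))
  expressed <- copies[!copies$deleted &
                        vapply(strsplit(copies$presence, ""),
                               function(x) any(x == "1"), logical(1)), ,
                      drop = FALSE]
  mean_rl <- mean(config$read_length_range)
  seqs <- character(0)
  truth <- list()
  for (i in seq_len(nrow(expressed))) {
    s <- expressed$sequence[i]
    len <- nchar(s)
    n <- stats::rpois(1, config$mean_coverage * len / mean_rl)
    if (n == 0L) next
    rlens <- seq(config$read_length_range[1], config$read_length_range[2])
    rl <- pmin(len, rlens[sample.int(length(rlens), n, replace = TRUE)])
    st <- vapply(rl, function(l) sample(len - l + 1L, 1L) - 1L, integer(1))
    strand <- sample(c("+", "-"), n, replace = TRUE)
    rs <- substring(s, st + 1L, st + rl)
    rs[strand == "-"] <- vapply(rs[strand == "-"], revcomp, character(1))
    seqs <- c(seqs, rs)
    truth[[length(truth) + 1L]] <- data.frame(
      copy_id = expressed$copy_id[i], gene_id = expressed$gene_id[i],
      subgenome = expressed$subgenome[i], start = st, strand = strand,
      stringsAsFactors = FALSE)
  }
  if (length(seqs) == 0L) {
    return(list(reads = stats::setNames(character(0), character(0)),
                truth = data.frame(read_id = character(0),
                                   copy_id = character(0),
                                   gene_id = character(0),
                                   subgenome = character(0),
                                   start = integer(0),
                                   strand = character(0),
                                   stringsAsFactors = FALSE)))
  }
  truth <- do.call(rbind, truth)
  ord <- sample(length(seqs))
  seqs <- seqs[ord]
  truth <- truth[ord, , drop = FALSE]
  ids <- sprintf("r%06d", seq_along(seqs))
  names(seqs) <- ids
  truth <- cbind(data.frame(read_id = ids, stringsAsFactors = FALSE), truth)
  rownames(truth) <- NULL
  list(reads = seqs, truth = truth)
}

#' Run the full transcriptome simulation
#'
#' @param config a [sim_config()]
#' @return list with `config`, `genome`, `copies`, `reads`, `read_truth`
#' @export
simulate_transcriptome <- function(config) {
  genome <- generate_genome(config)
  copies <- generate_hexaploid(genome, config)
  rs <- sample_reads(copies, config)
  list(config = config, genome = genome, copies = copies,
       reads = rs$reads, read_truth = rs$truth)
}

#' Write simulation outputs to a directory
#'
#' Emits reads.fasta, genome.fasta, genes.gff3 (1-based closed
#' coordinates), truth_copies.tsv, truth_reads.tsv and
#' expression_truth.tsv.
#'
#' @param sim output of [simulate_transcriptome()]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$reads, file.path(dir, "reads.fasta"))
  write_fasta(sim$genome$sequences, file.path(dir, "genome.fasta"))
  g <- sim$genome$genes
  gff <- data.frame(
    seqid = g$chromosome, source = "polyfate", type = "gene",
    start = g$start + 1L, end = g$end, score = ".", strand = g$strand,
    phase = ".",
    attributes = paste0("ID=", g$gene_id,
                        ifelse(is.na(g$paralog_partner), "",
                               paste0(";paralog_partner=",
                                      g$paralog_partner)),
                        ifelse(is.na(g$tandem_parent), "",
                               paste0(";tandem_parent=", g$tandem_parent))),
    stringsAsFactors = FALSE)
  con <- file(file.path(dir, "genes.gff3"), "w")
  writeLines("##gff-version 3", con)
  utils::write.table(gff, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  close(con)
  write_tsv(sim$copies[, setdiff(names(sim$copies), "sequence")],
            file.path(dir, "truth_copies.tsv"))
  write_tsv(sim$read_truth, file.path(dir, "truth_reads.tsv"))
  pm <- presence_matrix(sim$copies)
  expr <- data.frame(copy_id = sim$copies$copy_id,
                     gene_id = sim$copies$gene_id,
                     subgenome = sim$copies$subgenome,
                     pm * 1L, stringsAsFactors = FALSE)
  write_tsv(expr, file.path(dir, "expression_truth.tsv"))
  invisible(dir)
}
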