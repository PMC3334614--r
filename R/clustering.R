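#' Screen reads against contaminant references
#'
#' A read is removed iff some local alignment to a contaminant sequence
#' reaches `min_identity` over at least `min_cov` of the read length
#' (both orientations are tried).  With an empty reference set nothing
#' is removed.
#'
#' @param reads named character vector of read sequences
#' @param contaminant_refs named character vector of contaminant
#'   reference sequences (vectors, rRNA, organelles, ...); may be empty
#' @param min_identity minimum alignment identity (proportion)
#' @param min_cov minimum fraction of the read covered by the alignment
#' @return list with `clean` and `removed` (both named character vectors;
#'   their union is the input, disjoint)
#' @export
screen_contaminants <- function(reads, contaminant_refs,
                                min_identity = 0.9, min_cov = 0.8) {
  if (length(contaminant_refs) == 0L || length(reads) == 0L) {
    return(list(clean = reads,
                removed = reads[0]))
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2)
  hit <- vapply(reads, function(r) {
    for (ref in contaminant_refs) {
      for (q in c(r, revcomp(r))) {
        aln <- Biostrings::pairwiseAlignment(
          q, ref, type = "local", substitutionMatrix = mat,
          gapOpening = 4, gapExtension = 2)
        alen <- Biostrings::nchar(aln)
        if (alen == 0) next
        ident <- Biostrings::nmatch(aln) / alen
        cov <- Biostrings::width(Biostrings::pattern(aln)) / nchar(r)
        if (ident >= min_identity && cov >= min_cov) return(TRUE)
      }
    }
    FALSE
  }, logical(1))
  list(clean = reads[!hit], removed = reads[hit])
}

# ungapped overlap identity between strings a and b at a given offset:
# position p of `a` aligns position p - off of `b`.  The read model has
# substitutions only (no indels), so ungapped extension around an exact
# shared seed is an exact verification.
overlap_identity <- function(ra, rb, off) {
  na <- length(ra); nb <- length(rb)
  a0 <- max(1L, off + 1L)
  a1 <- min(na, off + nb)
  len <- a1 - a0 + 1L
  if (len <= 0L) return(c(len = 0L, ident = 0))
  m <- sum(ra[a0:a1] == rb[(a0 - off):(a1 - off)])
  c(len = len, ident = m / len)
}

#' Cluster reads into unigene sequence clusters
#'
#' Greedy transitive (single-linkage) clustering: two reads fall in the
#' same cluster iff they are connected by a chain of pairwise overlaps of
#' at least `min_overlap` bases at `min_identity` or better.  Candidate
#' pairs are proposed by shared exact k-mers (seed length 16) in either
#' orientation and verified by ungapped extension around the seed, which
#' is exact for the substitution-only read model.  The consensus is the
#' per-column majority base over the cluster pileup (ties broken by the
#' first-placed base) and the coverage is the mean read depth per
#' consensus position.
#'
#' Reads are processed in a canonical order (decreasing length, then
#' sequence), so the result is invariant to input order up to cluster
#' relabelling.
#'
#' @param reads named character vector of read sequences
#' @param min_overlap minimum overlap length in bases
#' @param min_identity minimum identity within the overlap
#' @param k seed k-mer length
#' @param probe_stride query k-mers are probed every `probe_stride`
#'   positions; every indexed read contributes all of its k-mers, so any
#'   overlap of `min_overlap` bases is still seen by several probes
#' @return list with `clusters` (cluster_id, consensus, n_reads,
#'   coverage) and `members` (cluster_id, read_id)
#' @export
cluster_reads <- function(reads, min_overlap = 40, min_identity = 0.90,
                          k = 16L, probe_stride = 8L) {
  stopifnot(length(reads) > 0L, !is.null(names(reads)))
  ord <- order(-nchar(reads), reads)
  reads <- reads[ord]
  n <- length(reads)
  raws <- lapply(reads, function(s) charToRaw(s))
  rc_seqs <- vapply(reads, revcomp, character(1))
  rc_raws <- lapply(rc_seqs, charToRaw)

  parent <- seq_len(n)
  uf_find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  # placement of each read in its cluster frame: orientation and start
  pl_or <- rep("+", n)
  pl_start <- rep(0L, n)

  index <- new.env(hash = TRUE, parent = emptyenv(), size = 1048576L)
  add_to_index <- function(i) {
    s <- reads[[i]]
    len <- nchar(s)
    if (len < k) return(invisible())
    starts <- seq_len(len - k + 1L)
    kms <- substring(s, starts, starts + k - 1L)
    keep <- !duplicated(kms)
    kms <- kms[keep]; starts <- starts[keep]
    for (j in seq_along(kms)) {
      key <- kms[j]
      cur <- index[[key]]
      index[[key]] <- if (is.null(cur)) list(c(i, starts[j])) else
        c(cur, list(c(i, starts[j])))
    }
    invisible()
  }

  # component placements: store per-read (orientation, start) lazily via
  # spanning-tree edges applied at union time.  When two components merge
  # we shift/flip the smaller component into the frame of the larger.
  comp_members <- as.list(seq_len(n))

  merge_into <- function(ri, rj, new_or, new_start, i) {
    # read i (currently root of its placement frame = component ri) gets
    # placement (new_or, new_start) in component rj's frame; every member
    # of ri is transformed accordingly.
    old_or <- pl_or[i]; old_start <- pl_start[i]
    for (m in comp_members[[ri]]) {
      lm <- nchar(reads[[m]])
      # express m's placement relative to read i's old frame, then map
      if (old_or == "+") {
        rel_or <- pl_or[m]
        rel_start <- pl_start[m] - old_start
      } else {
        li <- nchar(reads[[i]])
        rel_or <- ifelse(pl_or[m] == "+", "-", "+")
        rel_start <- old_start + li - (pl_start[m] + lm)
      }
      if (new_or == "+") {
        pl_or[m] <<- rel_or
        pl_start[m] <<- new_start + rel_start
      } else {
        li <- nchar(reads[[i]])
        pl_or[m] <<- ifelse(rel_or == "+", "-", "+")
        pl_start[m] <<- new_start + li - (rel_start + lm)
      }
    }
    parent[ri] <<- rj
    comp_members[[rj]] <<- c(comp_members[[rj]], comp_members[[ri]])
    comp_members[[ri]] <<- integer(0)
  }

  for (i in seq_len(n)) {
    s <- reads[[i]]
    len <- nchar(s)
    if (len >= k) {
      probes <- seq(1L, len - k + 1L, by = probe_stride)
      if (probes[length(probes)] != len - k + 1L) {
        probes <- c(probes, len - k + 1L)
      }
      for (orient in c("+", "-")) {
        qseq <- if (orient == "+") s else rc_seqs[[i]]
        qraw <- if (orient == "+") raws[[i]] else rc_raws[[i]]
        kms <- substring(qseq, probes, probes + k - 1L)
        seen_cand <- character(0)
        for (j in seq_along(kms)) {
          hits <- index[[kms[j]]]
          if (is.null(hits)) next
          for (h in hits) {
            tgt <- h[1]
            off <- probes[j] - h[2]
            key <- paste0(tgt, ":", off)
            if (key %in% seen_cand) next
            seen_cand <- c(seen_cand, key)
            ri <- uf_find(i)
            rj <- uf_find(tgt)
            if (ri == rj) next
            ov <- overlap_identity(qraw, raws[[tgt]], off)
            if (ov["len"] >= min_overlap && ov["ident"] >= min_identity) {
              # place read i relative to tgt's frame
              if (pl_or[tgt] == "+") {
                new_or <- orient
                new_start <- pl_start[tgt] - off
              } else {
                lt <- nchar(reads[[tgt]])
                new_or <- ifelse(orient == "+", "-", "+")
                new_start <- pl_start[tgt] + lt + off - len
              }
              merge_into(ri, rj, new_or, new_start, i)
            }
          }
        }
      }
    }
    add_to_index(i)
  }

  roots <- vapply(seq_len(n), function(x) uf_find(x), integer(1))
  comp_ids <- unique(roots)
  clusters <- vector("list", length(comp_ids))
  for (ci in seq_along(comp_ids)) {
    mem <- which(roots == comp_ids[ci])
    starts <- pl_start[mem]
    shift <- min(starts)
    starts <- starts - shift
    lens <- nchar(reads[mem])
    clen <- max(starts + lens)
    counts <- matrix(0L, nrow = 4L, ncol = clen)
    firstbase <- integer(clen)
    base_code <- c(A = 1L, C = 2L, G = 3L, T = 4L, N = 0L)
    for (m in seq_along(mem)) {
      idx <- mem[m]
      oriented <- if (pl_or[idx] == "+") reads[[idx]] else rc_seqs[[idx]]
      codes <- base_code[strsplit(oriented, "")[[1]]]
      pos <- starts[m] + seq_len(lens[m])
      ok <- !is.na(codes) & codes > 0L
      counts[cbind(codes[ok], pos[ok])] <-
        counts[cbind(codes[ok], pos[ok])] + 1L
      newly <- ok & firstbase[pos] == 0L
      firstbase[pos[newly]] <- codes[newly]
    }
    cons <- vapply(seq_len(clen), function(p) {
      col <- counts[, p]
      mx <- max(col)
      if (mx == 0L) return("N")
      winners <- which(col == mx)
      pick <- if (length(winners) > 1L && firstbase[p] %in% winners) {
        firstbase[p]
      } else winners[1]
      c("A", "C", "G", "T")[pick]
    }, character(1))
    clusters[[ci]] <- list(
      consensus = paste(cons, collapse = ""),
      member_reads = names(reads)[mem],
      n_reads = length(mem),
      coverage = sum(lens) / clen)
  }
  # canonical cluster order: most reads first, ties by consensus
  ord2 <- order(-vapply(clusters, `[[`, integer(1), "n_reads"),
                vapply(clusters, `[[`, character(1), "consensus"))
  clusters <- clusters[ord2]
  ids <- sprintf("cl%04d", seq_along(clusters))
  tab <- data.frame(
    cluster_id = ids,
    consensus = vapply(clusters, `[[`, character(1), "consensus"),
    n_reads = vapply(clusters, `[[`, integer(1), "n_reads"),
    coverage = vapply(clusters, `[[`, numeric(1), "coverage"),
    stringsAsFactors = FALSE)
  members <- do.call(rbind, lapply(seq_along(clusters), function(ci) {
    data.frame(cluster_id = ids[ci],
               read_id = clusters[[ci]]$member_reads,
               stringsAsFactors = FALSE)
  }))
  rownames(members) <- NULL
  list(clusters = tab, members = members)
}

#' Per-cluster read counts and coverage
#'
#' @param clustering output of [cluster_reads()]
#' @return list with `table` (cluster_id, n_reads, coverage) and
#'   `mean_reads` / `mean_coverage`, the global means later used to flag
#'   putatively merged homoeolog clusters
#' @export
coverage_profile <- function(clustering) {
  tab <- clustering$clusters[, c("cluster_id", "n_reads", "coverage")]
  stopifnot(nrow(tab) > 0L)
  list(table = tab,
       mean_reads = mean(tab$n_reads),
       mean_coverage = mean(tab$coverage))
}
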