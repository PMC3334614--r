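#' Exact toy nucleotide aligner emitting HSP tables
#'
#' A deterministic local aligner for pipeline tests and small analyses:
#' candidate subjects are proposed by shared exact k-mers in either
#' orientation and each candidate pair is aligned with a Smith-Waterman
#' local alignment (match +1, mismatch -2, affine gaps), emitting one
#' HSP per pair in the same 0-based half-open form as [read_m8()].
#' It does not replace a production aligner; alignment generation is
#' external to the homology module's contract.
#'
#' @param queries named character vector (e.g. cluster consensuses)
#' @param subjects named character vector (e.g. reference transcripts)
#' @param k seed k-mer length for candidate pairing
#' @param min_shared_kmers minimum shared k-mers to attempt an alignment
#' @return HSP data frame (query_id, subject_id, q_start, q_end,
#'   s_start, s_end, length, n_identities, bitscore)
#' @export
align_sequences <- function(queries, subjects, k = 16L,
                            min_shared_kmers = 3L) {
  stopifnot(!is.null(names(queries)), !is.null(names(subjects)))
  kmerset <- function(s) {
    if (nchar(s) < k) return(character(0))
    starts <- seq_len(nchar(s) - k + 1L)
    unique(substring(s, starts, starts + k - 1L))
  }
  # subject k-mer index
  index <- new.env(hash = TRUE, parent = emptyenv())
  for (j in seq_along(subjects)) {
    for (km in kmerset(subjects[[j]])) {
      index[[km]] <- c(index[[km]], j)
    }
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2)
  rows <- list()
  for (i in seq_along(queries)) {
    q <- queries[[i]]
    for (orient in c("+", "-")) {
      qs <- if (orient == "+") q else revcomp(q)
      hits <- integer(0)
      for (km in kmerset(qs)) {
        hits <- c(hits, index[[km]])
      }
      if (length(hits) == 0L) next
      tab <- table(hits)
      cand <- as.integer(names(tab)[tab >= min_shared_kmers])
      for (j in cand) {
        aln <- Biostrings::pairwiseAlignment(
          qs, subjects[[j]], type = "local", substitutionMatrix = mat,
          gapOpening = 4, gapExtension = 2)
        alen <- Biostrings::nchar(aln)
        if (alen < k) next
        pr <- Biostrings::pattern(aln)
        sr <- Biostrings::subject(aln)
        qa <- Biostrings::start(pr); qb <- Biostrings::end(pr)
        if (orient == "-") {
          nq <- nchar(q)
          tmp <- qa
          qa <- nq - qb + 1L
          qb <- nq - tmp + 1L
        }
        rows[[length(rows) + 1L]] <- data.frame(
          query_id = names(queries)[i], subject_id = names(subjects)[j],
          q_start = qa - 1L, q_end = qb,
          s_start = Biostrings::start(sr) - 1L,
          s_end = Biostrings::end(sr),
          length = alen,
          n_identities = Biostrings::nmatch(aln),
          bitscore = Biostrings::score(aln),
          orient = orient,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(query_id = character(0), subject_id = character(0),
                      q_start = integer(0), q_end = integer(0),
                      s_start = integer(0), s_end = integer(0),
                      length = integer(0), n_identities = integer(0),
                      bitscore = numeric(0), orient = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  # keep the better orientation per query-subject pair
  key <- paste(out$query_id, out$subject_id, sep = "\r")
  out <- out[order(key, -out$bitscore), , drop = FALSE]
  out <- out[!duplicated(paste(out$query_id, out$subject_id, sep = "\r")), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an HSP table in 12-column tabular format
#'
#' Converts 0-based half-open coordinates back to 1-based inclusive.
#'
#' @param hsps HSP data frame as returned by [align_sequences()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_m8 <- function(hsps, path) {
  pident <- 100 * hsps$n_identities / hsps$length
  out <- data.frame(hsps$query_id, hsps$subject_id,
                    sprintf("%.2f", pident), hsps$length,
                    hsps$length - hsps$n_identities, 0L,
                    hsps$q_start + 1L, hsps$q_end,
                    hsps$s_start + 1L, hsps$s_end,
                    0, hsps$bitscore)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
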