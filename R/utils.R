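#' Round-half-up percentage
#'
#' Percentage of `num` over `den` rounded half-up to `digits` decimals.
#' `round()` in R rounds half-to-even, which does not reproduce printed
#' values such as 43/79 = 54.43 -> 54; this helper always rounds .5 up.
#'
#' @param num numerator count
#' @param den denominator count
#' @param digits decimals kept (0 for integer percents)
#' @return numeric percentage
#' @export
pct_round <- function(num, den, digits = 0) {
  stopifnot(den > 0)
  x <- 100 * num / den
  f <- 10^digits
  floor(x * f + 0.5) / f
}

#' Truncated percentage
#'
#' Percentage of `num` over `den` truncated (not rounded) to `digits`
#' decimals, e.g. 2600/6760 = 38.46\% -> 38.4.
#'
#' @inheritParams pct_round
#' @return numeric percentage
#' @export
pct_trunc <- function(num, den, digits = 1) {
  stopifnot(den > 0)
  f <- 10^digits
  floor(100 * num / den * f) / f
}

# deterministic sub-seed per pipeline stage, kept inside 32-bit range
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1103L + offset) %% 2147483647)
}

DNA_BASES <- c("A", "C", "G", "T")

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Mutate a nucleotide sequence by uniform random substitution
#'
#' Each position is substituted independently with probability `rate`;
#' a substituted base is drawn uniformly from the three other bases.
#' No indels, no transition/transversion bias.
#'
#' @param seq nucleotide string
#' @param rate per-base substitution probability
#' @return list with `seq` (mutated string) and `n_sub` (positions changed)
#' @export
mutate_sequence <- function(seq, rate) {
  stopifnot(rate >= 0, rate <= 1)
  chars <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(DNA_BASES, chars[i]), 1)
  }
  list(seq = paste(chars, collapse = ""), n_sub = length(hit))
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# write a named character vector of sequences as FASTA
write_fasta <- function(seqs, path, width = 70) {
  stopifnot(!is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, ...)
}
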