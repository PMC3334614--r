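#' Detect collinear synteny blocks among ortholog anchors
#'
#' Anchors carry the ordinal position (`reference_rank`) of a target
#' gene's ortholog along a reference chromosome.  Within each
#' (reference, reference chromosome), blocks are maximal runs of
#' consecutive anchors whose ranks are monotonic in either direction
#' with rank gaps (missing anchors between neighbours) of at most
#' `gap_limit`.  Anchors are scanned in `target_order` when that column
#' is present, otherwise in rank order (where only the gap rule can
#' split).  Each anchor belongs to at most one block per reference:
#' scanning is greedy, assigning the longest valid run starting at each
#' unassigned anchor.
#'
#' @param anchors data frame: target_gene_id, reference_name,
#'   reference_chromosome, reference_rank, optionally target_order
#' @param gap_limit maximum number of missing anchors between block
#'   neighbours (default 5)
#' @return the anchor table with an added `block_id` column
#' @export
detect_blocks <- function(anchors, gap_limit = 5L) {
  stopifnot(nrow(anchors) > 0L, all(anchors$reference_rank >= 0))
  anchors$block_id <- NA_character_
  counter <- 0L
  grp <- paste(anchors$reference_name, anchors$reference_chromosome,
               sep = "\r")
  for (gkey in unique(grp)) {
    idx <- which(grp == gkey)
    sub <- anchors[idx, , drop = FALSE]
    ord <- if ("target_order" %in% names(sub)) {
      order(sub$target_order)
    } else {
      order(sub$reference_rank, sub$target_gene_id)
    }
    idx <- idx[ord]
    ranks <- anchors$reference_rank[idx]
    i <- 1L
    while (i <= length(idx)) {
      j <- i
      dir <- 0L
      while (j < length(idx)) {
        step <- ranks[j + 1L] - ranks[j]
        if (step == 0L) break
        if (abs(step) - 1L > gap_limit) break
        if (dir == 0L) {
          dir <- sign(step)
        } else if (sign(step) != dir) {
          break
        }
        j <- j + 1L
      }
      counter <- counter + 1L
      anchors$block_id[idx[i:j]] <- sprintf("blk%04d", counter)
      i <- j + 1L
    }
  }
  anchors
}

#' Build a consensus virtual gene order from prioritised references
#'
#' Genes anchored in the top-priority reference are ordered by its
#' ranks.  Genes absent there are inserted by the next reference in
#' priority, interpolated between their nearest neighbours that are
#' already placed: a gene goes immediately after its nearest placed
#' predecessor in the deciding reference's order, provided that
#' predecessor precedes the nearest placed successor in the current
#' consensus (a contradictory pair sends the gene to the unplaced list,
#' never dropped).  Several genes interpolated into one interval are
#' ordered by the deciding reference's ranks, then gene id.  Adding a
#' lower-priority reference never reorders genes already placed.
#'
#' @param anchors data frame: target_gene_id, reference_name,
#'   reference_rank (one anchor per gene and reference; ranks are the
#'   ordinal positions along the relevant reference chromosome)
#' @param priority character vector of reference names, highest first;
#'   must cover every reference present
#' @return list with `order` (gene_id, position, source_reference) and
#'   `unplaced` (gene_id, reason)
#' @export
build_consensus_order <- function(anchors, priority) {
  refs <- unique(anchors$reference_name)
  if (!all(refs %in% priority)) {
    stop("priority must cover every reference present", call. = FALSE)
  }
  placed <- character(0)
  source_ref <- character(0)
  unplaced <- data.frame(gene_id = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  for (ref in priority[priority %in% refs]) {
    sub <- anchors[anchors$reference_name == ref, , drop = FALSE]
    sub <- sub[order(sub$reference_rank, sub$target_gene_id), ,
               drop = FALSE]
    if (length(placed) == 0L) {
      placed <- sub$target_gene_id
      source_ref <- rep(ref, length(placed))
      next
    }
    todo <- sub[!(sub$target_gene_id %in% placed), , drop = FALSE]
    if (nrow(todo) == 0L) next
    # nearest placed neighbours of each new gene along this reference
    ref_genes <- sub$target_gene_id
    is_placed <- ref_genes %in% placed
    ins_after <- character(nrow(todo))   # placed gene to insert after
    ok <- logical(nrow(todo))
    for (t in seq_len(nrow(todo))) {
      pos_in_ref <- match(todo$target_gene_id[t], ref_genes)
      prev <- rev(ref_genes[seq_len(pos_in_ref - 1L)])
      prev <- prev[prev %in% placed][1]
      nxt <- ref_genes[-seq_len(pos_in_ref)]
      nxt <- nxt[nxt %in% placed][1]
      if (is.na(prev) && is.na(nxt)) {
        unplaced <- rbind(unplaced, data.frame(
          gene_id = todo$target_gene_id[t], reason = "no placed neighbour",
          stringsAsFactors = FALSE))
        next
      }
      if (!is.na(prev) && !is.na(nxt) &&
          match(prev, placed) >= match(nxt, placed)) {
        unplaced <- rbind(unplaced, data.frame(
          gene_id = todo$target_gene_id[t],
          reason = "contradictory neighbours",
          stringsAsFactors = FALSE))
        next
      }
      ins_after[t] <- if (!is.na(prev)) prev else ""
      ok[t] <- TRUE
    }
    todo <- todo[ok, , drop = FALSE]
    ins_after <- ins_after[ok]
    if (nrow(todo) == 0L) next
    # rebuild the consensus, appending interpolated genes after their
    # anchor gene ("" = before the first placed gene), in rank order
    ord <- order(ins_after, todo$reference_rank, todo$target_gene_id)
    todo <- todo[ord, , drop = FALSE]
    ins_after <- ins_after[ord]
    new_placed <- character(0)
    new_source <- character(0)
    head_sel <- ins_after == ""
    if (any(head_sel)) {
      new_placed <- todo$target_gene_id[head_sel]
      new_source <- rep(ref, sum(head_sel))
    }
    for (p in seq_along(placed)) {
      new_placed <- c(new_placed, placed[p])
      new_source <- c(new_source, source_ref[p])
      sel <- ins_after == placed[p]
      if (any(sel)) {
        new_placed <- c(new_placed, todo$target_gene_id[sel])
        new_source <- c(new_source, rep(ref, sum(sel)))
      }
    }
    placed <- new_placed
    source_ref <- new_source
  }
  # a gene unresolvable under one reference may be rescued by a later
  # one; keep only those that never made it in
  unplaced <- unplaced[!(unplaced$gene_id %in% placed) &
                         !duplicated(unplaced$gene_id), , drop = FALSE]
  # genes with anchors that never got placed and were not yet reported
  leftovers <- setdiff(unique(anchors$target_gene_id),
                       c(placed, unplaced$gene_id))
  if (length(leftovers) > 0L) {
    unplaced <- rbind(unplaced, data.frame(
      gene_id = leftovers, reason = "unresolved",
      stringsAsFactors = FALSE))
  }
  list(order = data.frame(gene_id = placed,
                          position = seq_along(placed),
                          source_reference = source_ref,
                          stringsAsFactors = FALSE),
       unplaced = unplaced)
}
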