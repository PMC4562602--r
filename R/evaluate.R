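# Parameter-recovery evaluation against simulated ground truth.

# collapse a chain to the ordered (parent, orientation) sequence, merging
# consecutive fragments of one parent
chain_parent_path <- function(chains, fragments, cid) {
  sel <- which(chains$chain_id == cid)
  sel <- sel[order(chains$position[sel])]
  par <- fragments$parent[match(chains$fragment_id[sel], fragments$fragment_id)]
  ori <- chains$orientation[sel]
  keep <- c(TRUE, par[-1] != par[-length(par)])
  data.frame(parent = par[keep], orientation = ori[keep],
             stringsAsFactors = FALSE)
}

#' Score recovered scaffold adjacencies against simulation truth
#'
#' True adjacencies are consecutive scaffolds along each simulated
#' chromosome, with relative orientation.  Recovered adjacencies are
#' consecutive distinct parents in each chain.  An adjacency matches in
#' either reading direction (a whole chain may be globally flipped).
#'
#' @param chains chain table from [chain_scaffolds()].
#' @param fragments fragment table.
#' @param truth `pet_sim_truth` from [simulate_genome()].
#' @return list `recall, precision, n_true, n_recovered, n_correct`.
#' @export
evaluate_adjacency_recovery <- function(chains, fragments, truth) {
  adj <- truth$adjacency
  true_keys <- character()
  for (ch in unique(adj$chrom)) {
    a <- adj[adj$chrom == ch, , drop = FALSE]
    a <- a[order(a$ord), , drop = FALSE]
    if (nrow(a) < 2) next
    for (k in seq_len(nrow(a) - 1L)) {
      true_keys <- c(true_keys,
                     adj_key(a$scaffold[k], a$orientation[k],
                             a$scaffold[k + 1L], a$orientation[k + 1L]))
    }
  }
  true_keys <- unique(true_keys)
  rec_keys <- character()
  for (cid in unique(chains$chain_id)) {
    p <- chain_parent_path(chains, fragments, cid)
    if (nrow(p) < 2) next
    for (k in seq_len(nrow(p) - 1L)) {
      rec_keys <- c(rec_keys,
                    adj_key(p$parent[k], p$orientation[k],
                            p$parent[k + 1L], p$orientation[k + 1L]))
    }
  }
  rec_keys <- unique(rec_keys)
  n_correct <- sum(rec_keys %in% true_keys)
  list(recall = if (length(true_keys)) n_correct / length(true_keys) else NA_real_,
       precision = if (length(rec_keys)) n_correct / length(rec_keys) else NA_real_,
       n_true = length(true_keys), n_recovered = length(rec_keys),
       n_correct = n_correct)
}

# canonical key for an oriented adjacency, invariant to reading direction
adj_key <- function(a, oa, b, ob) {
  flip <- function(o) if (o == "+") "-" else "+"
  k1 <- paste(a, oa, b, ob)
  k2 <- paste(b, flip(ob), a, flip(oa))
  if (k1 < k2) k1 else k2
}
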