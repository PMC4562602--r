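# shared fixtures: the two mate-pair libraries with their printed
# concordant span ranges, and small helpers for building tag tables

lib10 <- function() library_profile("IXT010", 9600, 5997, 11961)
lib17 <- function() library_profile("IXT011", 9318 + (22026 - 9318) / 2,
                                    9318, 22026)
lib17_real <- function() library_profile("IXT011", 17500, 9318, 22026)

# build one tag pair from compact arguments (27 bp tags)
make_pair <- function(ref1, s1, st1, ref2, s2, st2, id = "p1",
                      lib = "IXT010", tag_len = 27L) {
  data.frame(pair_id = id, lib = lib,
             ref1 = ref1, start1 = s1, end1 = s1 + tag_len, strand1 = st1,
             ref2 = ref2, start2 = s2, end2 = s2 + tag_len, strand2 = st2,
             stringsAsFactors = FALSE)
}

# pair in perfect concordant geometry with a given span on one ref
concordant_pair <- function(ref, start, span, strand = "+", id = "p1",
                            tag_len = 27L) {
  if (strand == "+")
    make_pair(ref, start, "+", ref, start + span - tag_len, "+", id = id)
  else
    make_pair(ref, start + span - tag_len, "-", ref, start, "-", id = id)
}

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# independent exhaustive optimum of the conflict-aware chain score over
# all edge-disjoint acyclic edge subsets (oracle for chain_scaffolds)
exhaustive_chain_score <- function(edges) {
  n_e <- nrow(edges)
  best <- -Inf
  for (mask in 0:(2^n_e - 1)) {
    sel <- as.logical(bitwAnd(mask, 2^(seq_len(n_e) - 1L)) > 0)
    ends <- c(paste(edges$node_a[sel], edges$end_a[sel]),
              paste(edges$node_b[sel], edges$end_b[sel]))
    if (anyDuplicated(ends)) next
    nodes <- unique(c(edges$node_a, edges$node_b))
    parent <- stats::setNames(nodes, nodes)
    findp <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
    ok <- TRUE
    for (i in which(sel)) {
      ra <- findp(edges$node_a[i]); rb <- findp(edges$node_b[i])
      if (ra == rb) { ok <- FALSE; break }
      parent[[ra]] <- rb
    }
    if (!ok) next
    used <- unique(ends)
    conflict <- !sel & (paste(edges$node_a, edges$end_a) %in% used |
                          paste(edges$node_b, edges$end_b) %in% used)
    sc <- sum(edges$weight[sel]) - sum(edges$weight[conflict])
    if (sc > best) best <- sc
  }
  best
}

# random scaffold-graph instance on n_nodes fragments
rand_chain_graph <- function(n_nodes, n_edges) {
  fragments <- data.frame(fragment_id = LETTERS[seq_len(n_nodes)],
                          parent = LETTERS[seq_len(n_nodes)],
                          p_start = 0L, p_end = 10000L, length = 10000L,
                          stringsAsFactors = FALSE)
  ab <- t(replicate(n_edges, sort(sample.int(n_nodes, 2))))
  edges <- data.frame(node_a = LETTERS[ab[, 1]],
                      end_a = sample(c("head", "tail"), n_edges, TRUE),
                      node_b = LETTERS[ab[, 2]],
                      end_b = sample(c("head", "tail"), n_edges, TRUE),
                      lib = "L", weight = sample(4:20, n_edges, TRUE),
                      est_link_len = sample(100:5000, n_edges, TRUE),
                      kind = "dpet", stringsAsFactors = FALSE)
  edges <- edges[!duplicated(edges[, c("node_a", "end_a", "node_b", "end_b")]), ]
  list(fragments = fragments, edges = edges)
}
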