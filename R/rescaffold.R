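# Graph-based re-scaffolding: split scaffolds at large unspanned gaps and
# at breakpoints, mask repeat-dense windows, build the dPET scaffold graph
# and chain fragments into hyper-scaffolds with conflict-aware scoring.

new_fragments <- function(parent, p_start, p_end) {
  df <- data.frame(parent = parent, p_start = p_start, p_end = p_end,
                   stringsAsFactors = FALSE)
  df <- df[order(df$parent, df$p_start), , drop = FALSE]
  part <- stats::ave(df$p_start, df$parent, FUN = seq_along)
  df$fragment_id <- sprintf("%s.p%d", df$parent, as.integer(part))
  df$length <- df$p_end - df$p_start
  rownames(df) <- NULL
  df[, c("fragment_id", "parent", "p_start", "p_end", "length")]
}

#' Split scaffolds at large, unspanned assembly gaps
#'
#' Scaffolds are split at every N-run of at least `min_n_run` bp that no
#' concordant PET fragment spans (covers entirely); the N-run itself is
#' dropped, to be re-filled by re-scaffolding.  Splitting at smaller gaps
#' would over-fragment the assembly relative to the library insert size.
#'
#' @param assembly a [pet_assembly].
#' @param cpets cPET table (used to find spanning fragments); may have
#'   zero rows.
#' @param min_n_run minimum N-run length to split at (default 10,000).
#' @return fragment table: `fragment_id, parent, p_start, p_end, length`.
#' @export
split_at_gaps <- function(assembly, cpets, min_n_run = 10000L) {
  gaps <- assembly$gaps[assembly$gaps$annotated_len >= min_n_run, , drop = FALSE]
  if (nrow(gaps) && nrow(cpets)) {
    frag <- pair_fragment(cpets)
    gr_g <- GenomicRanges::GRanges(gaps$scaffold,
                                   IRanges::IRanges(gaps$start + 1L, gaps$end))
    gr_f <- GenomicRanges::GRanges(frag$ref,
                                   IRanges::IRanges(frag$start + 1L, frag$end))
    spanned <- IRanges::overlapsAny(gr_g, gr_f, type = "within")
    gaps <- gaps[!spanned, , drop = FALSE]
  }
  parent <- character(); p_start <- integer(); p_end <- integer()
  for (i in seq_len(nrow(assembly$scaffolds))) {
    sc <- assembly$scaffolds$name[i]
    L <- assembly$scaffolds$length[i]
    g <- gaps[gaps$scaffold == sc, , drop = FALSE]
    cuts_s <- c(0L, g$end)
    cuts_e <- c(g$start, L)
    keep <- cuts_e > cuts_s
    parent <- c(parent, rep(sc, sum(keep)))
    p_start <- c(p_start, cuts_s[keep])
    p_end <- c(p_end, cuts_e[keep])
  }
  new_fragments(parent, p_start, p_end)
}

#' Split fragments at assembly breakpoints
#'
#' Each breakpoint whose midpoint is strictly interior to a fragment of
#' the same parent scaffold splits that fragment in two at the midpoint
#' (no sequence is removed).  Breakpoints falling outside every fragment
#' (e.g. coincident with an already-removed gap) are ignored with a
#' warning count.
#'
#' @param fragments fragment table from [split_at_gaps()].
#' @param breakpoints breakpoint table from [detect_breakpoints()].
#' @return updated fragment table (ids reassigned per parent).
#' @export
split_at_breakpoints <- function(fragments, breakpoints) {
  parent <- fragments$parent
  p_start <- fragments$p_start
  p_end <- fragments$p_end
  ignored <- 0L
  if (nrow(breakpoints)) {
    for (i in seq_len(nrow(breakpoints))) {
      mid <- (breakpoints$start[i] + breakpoints$end[i]) %/% 2L
      hit <- which(parent == breakpoints$scaffold[i] &
                     p_start < mid & mid < p_end)
      if (length(hit) != 1L) { ignored <- ignored + 1L; next }
      p_s <- p_start[hit]; p_e <- p_end[hit]; pa <- parent[hit]
      parent <- c(parent[-hit], pa, pa)
      p_start <- c(p_start[-hit], p_s, mid)
      p_end <- c(p_end[-hit], mid, p_e)
    }
  }
  if (ignored) warning(ignored, " breakpoint(s) outside any fragment ignored")
  out <- new_fragments(parent, p_start, p_end)
  attr(out, "ignored_breakpoints") <- ignored
  out
}

#' Mask repeat-dense windows by tag density
#'
#' All mapped tag positions (both mates of every pair) are counted in
#' non-overlapping windows; windows with strictly more than `max_density`
#' tags are masked.  PETs with a tag starting in a masked window should be
#' excluded from edge building (see [filter_masked_pairs()]).
#'
#' @param pairs tag-pair table.
#' @param assembly a [pet_assembly].
#' @param window window width in bp (default 1,000).
#' @param max_density mask when tag count exceeds this (default 500).
#' @return BED-style data.frame `chrom, start, end, count` of masked windows.
#' @export
mask_repeats <- function(pairs, assembly, window = 1000L, max_density = 500L) {
  tags <- data.frame(ref = c(pairs$ref1, pairs$ref2),
                     start = c(pairs$start1, pairs$start2))
  res <- list()
  for (i in seq_len(nrow(assembly$scaffolds))) {
    sc <- assembly$scaffolds$name[i]
    L <- assembly$scaffolds$length[i]
    pos <- tags$start[tags$ref == sc]
    if (!length(pos)) next
    nb <- as.integer(ceiling(L / window))
    cnt <- tabulate(pos %/% window + 1L, nbins = nb)
    w <- which(cnt > max_density)
    if (length(w)) {
      res[[length(res) + 1L]] <- data.frame(
        chrom = sc, start = (w - 1L) * window,
        end = pmin(w * window, L), count = cnt[w], stringsAsFactors = FALSE)
    }
  }
  if (!length(res))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), count = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, res)
}

#' Drop pairs with a tag in a masked window
#' @param pairs tag-pair table.
#' @param masked masked-window table from [mask_repeats()].
#' @export
filter_masked_pairs <- function(pairs, masked) {
  if (nrow(masked) == 0 || nrow(pairs) == 0) return(pairs)
  gr_m <- GenomicRanges::GRanges(masked$chrom,
                                 IRanges::IRanges(masked$start + 1L, masked$end))
  in_mask <- function(ref, pos) {
    gr <- GenomicRanges::GRanges(ref, IRanges::IRanges(pos + 1L, pos + 1L))
    IRanges::overlapsAny(gr, gr_m)
  }
  bad <- in_mask(pairs$ref1, pairs$start1) | in_mask(pairs$ref2, pairs$start2)
  out <- pairs[!bad, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# map tags (parent scaffold coords) onto fragments; returns fragment index
# (NA when a tag does not fall fully inside one fragment) and local coords
map_tags_to_fragments <- function(ref, start, end, fragments) {
  idx <- rep(NA_integer_, length(ref))
  for (pa in unique(ref)) {
    fr <- which(fragments$parent == pa)
    if (!length(fr)) next
    sel <- which(ref == pa)
    fi <- findInterval(start[sel], fragments$p_start[fr])
    ok <- fi >= 1L
    ok[ok] <- end[sel][ok] <= fragments$p_end[fr][fi[ok]] &
      start[sel][ok] >= fragments$p_start[fr][fi[ok]]
    idx[sel[ok]] <- fr[fi[ok]]
  }
  list(frag = idx,
       local_start = start - fragments$p_start[idx],
       local_end = end - fragments$p_start[idx])
}

# which fragment end a tag's mate lies beyond, from mate-pair geometry:
# the fragment molecule continues 3' of a 5'(first) tag and 5' of a
# 3'(second) tag
attachment_end <- function(is_first, strand) {
  ifelse(is_first == (strand == "+"), "tail", "head")
}

#' Build dPET scaffold-graph edges
#'
#' Deduplicated pairs whose two tags map to different fragments are
#' grouped by (fragment pair, attachment ends); both tags must lie within
#' `lib$span_max` of their attachment end.  Edge weight is the group
#' size; edges are built per library and edges with weight below
#' `min_weight` are discarded (low-confidence background).  The estimated
#' link length is the mean of `insert_mean - dist_a - dist_b`.
#'
#' @param pairs tag-pair table for one library (already deduplicated and
#'   repeat-filtered); same-parent pairs straddling a split point also
#'   contribute.
#' @param fragments fragment table.
#' @param lib the [library_profile].
#' @param min_weight minimum retained weight (default 4, i.e. weight > 3).
#' @return edge table `node_a, end_a, node_b, end_b, lib, weight,
#'   est_link_len, kind`.
#' @export
build_edges <- function(pairs, fragments, lib, min_weight = 4L) {
  empty <- data.frame(node_a = character(), end_a = character(),
                      node_b = character(), end_b = character(),
                      lib = character(), weight = integer(),
                      est_link_len = numeric(), kind = character(),
                      stringsAsFactors = FALSE)
  if (nrow(pairs) == 0) return(empty)
  m1 <- map_tags_to_fragments(pairs$ref1, pairs$start1, pairs$end1, fragments)
  m2 <- map_tags_to_fragments(pairs$ref2, pairs$start2, pairs$end2, fragments)
  ok <- !is.na(m1$frag) & !is.na(m2$frag) & m1$frag != m2$frag
  if (!any(ok)) return(empty)
  e1 <- attachment_end(TRUE, pairs$strand1[ok])
  e2 <- attachment_end(FALSE, pairs$strand2[ok])
  L1 <- fragments$length[m1$frag[ok]]
  L2 <- fragments$length[m2$frag[ok]]
  d1 <- ifelse(e1 == "tail", L1 - m1$local_start[ok], m1$local_end[ok])
  d2 <- ifelse(e2 == "tail", L2 - m2$local_start[ok], m2$local_end[ok])
  near <- d1 <= lib$span_max & d2 <= lib$span_max
  if (!any(near)) return(empty)
  fa <- m1$frag[ok][near]; fb <- m2$frag[ok][near]
  ea <- e1[near]; eb <- e2[near]
  da <- d1[near]; db <- d2[near]
  swap <- fa > fb
  tmp <- fa[swap]; fa[swap] <- fb[swap]; fb[swap] <- tmp
  tmp <- ea[swap]; ea[swap] <- eb[swap]; eb[swap] <- tmp
  tmp <- da[swap]; da[swap] <- db[swap]; db[swap] <- tmp
  link <- lib$insert_mean - da - db
  key <- paste(fa, ea, fb, eb, sep = "\r")
  agg <- tapply(link, key, mean)
  cnt <- tapply(link, key, length)
  parts <- strsplit(names(agg), "\r", fixed = TRUE)
  out <- data.frame(
    node_a = fragments$fragment_id[as.integer(vapply(parts, `[`, "", 1L))],
    end_a = vapply(parts, `[`, "", 2L),
    node_b = fragments$fragment_id[as.integer(vapply(parts, `[`, "", 3L))],
    end_b = vapply(parts, `[`, "", 4L),
    lib = lib$library_id,
    weight = as.integer(cnt),
    est_link_len = as.numeric(agg),
    kind = "dpet", stringsAsFactors = FALSE)
  out <- out[out$weight >= min_weight, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Weight-1 provenance edges between adjacent fragments of one parent
#'
#' These record the pre-split order and are traversed during chaining only
#' when no dPET edge claims either end.
#'
#' @param fragments fragment table.
#' @return edge table in the [build_edges()] layout, `kind = "provenance"`;
#'   `est_link_len` is the removed inter-fragment region length.
#' @export
provenance_edges <- function(fragments) {
  res <- list()
  for (pa in unique(fragments$parent)) {
    fr <- which(fragments$parent == pa)
    if (length(fr) < 2) next
    fr <- fr[order(fragments$p_start[fr])]
    for (k in seq_len(length(fr) - 1L)) {
      res[[length(res) + 1L]] <- data.frame(
        node_a = fragments$fragment_id[fr[k]], end_a = "tail",
        node_b = fragments$fragment_id[fr[k + 1L]], end_b = "head",
        lib = "provenance", weight = 1L,
        est_link_len = as.numeric(fragments$p_start[fr[k + 1L]] -
                                    fragments$p_end[fr[k]]),
        kind = "provenance", stringsAsFactors = FALSE)
    }
  }
  if (!length(res))
    return(build_edges(data.frame(pair_id = character(), lib = character(),
                                  ref1 = character(), start1 = integer(),
                                  end1 = integer(), strand1 = character(),
                                  ref2 = character(), start2 = integer(),
                                  end2 = integer(), strand2 = character(),
                                  stringsAsFactors = FALSE)[0, ],
                       fragments, library_profile("x", 2, 1, 3)))
  do.call(rbind, res)
}

# sum weights per library for identical (nodes, ends) links
combine_edge_libraries <- function(edges) {
  if (nrow(edges) == 0) return(edges)
  key <- paste(edges$node_a, edges$end_a, edges$node_b, edges$end_b,
               edges$kind, sep = "\r")
  w <- tapply(edges$weight, key, sum)
  ll <- tapply(edges$weight * edges$est_link_len, key, sum) / w
  first <- !duplicated(key)
  out <- edges[first, , drop = FALSE]
  out$weight <- as.integer(w[key[first]])
  out$est_link_len <- as.numeric(ll[key[first]])
  out$lib <- "combined"
  rownames(out) <- NULL
  out
}

# conflict-aware path score: sum of traversed weights minus the weight of
# every non-traversed edge incident to an occupied fragment end
score_edge_set <- function(accepted, edges) {
  used <- unique(c(paste(edges$node_a[accepted], edges$end_a[accepted]),
                   paste(edges$node_b[accepted], edges$end_b[accepted])))
  rej <- !accepted
  conflict <- rej & (paste(edges$node_a, edges$end_a) %in% used |
                       paste(edges$node_b, edges$end_b) %in% used)
  sum(edges$weight[accepted]) - sum(edges$weight[conflict])
}

# connected components (by fragment) of an edge subset; named vector of
# component representatives
build_components <- function(accepted, edges, nodes) {
  parent <- stats::setNames(nodes, nodes)
  findp <- function(x) { while (parent[[x]] != x) { parent[[x]] <<- parent[[parent[[x]]]]; x <- parent[[x]] }; x }
  for (i in which(accepted)) {
    ra <- findp(edges$node_a[i]); rb <- findp(edges$node_b[i])
    if (ra != rb) parent[[ra]] <- rb
  }
  vapply(nodes, findp, "")
}

# is an edge subset a valid partial path cover (each fragment end used at
# most once, no cycles)?
valid_edge_set <- function(sel, edges) {
  ends <- c(paste(edges$node_a[sel], edges$end_a[sel]),
            paste(edges$node_b[sel], edges$end_b[sel]))
  if (anyDuplicated(ends)) return(FALSE)
  nodes <- unique(c(edges$node_a, edges$node_b))
  parent <- stats::setNames(nodes, nodes)
  findp <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (i in which(sel)) {
    ra <- findp(edges$node_a[i]); rb <- findp(edges$node_b[i])
    if (ra == rb) return(FALSE)
    parent[[ra]] <- rb
  }
  TRUE
}

# exact optimum over all valid edge subsets of one (small) component
solve_component_exact <- function(edges) {
  m <- nrow(edges)
  best <- -Inf; best_sel <- logical(m)
  for (mask in 0:(2^m - 1)) {
    sel <- as.logical(bitwAnd(mask, 2^(seq_len(m) - 1L)) > 0)
    if (!valid_edge_set(sel, edges)) next
    sc <- score_edge_set(sel, edges)
    if (sc > best) { best <- sc; best_sel <- sel }
  }
  best_sel
}

# greedy by descending weight plus single-edge-swap improvement
solve_component_greedy <- function(edges) {
  m <- nrow(edges)
  accepted <- logical(m)
  end_used <- character()
  comp <- build_components(accepted, edges,
                           unique(c(edges$node_a, edges$node_b)))
  ord <- order(-edges$weight, abs(edges$est_link_len),
               edges$node_a, edges$node_b)
  for (i in ord) {
    ends <- c(paste(edges$node_a[i], edges$end_a[i]),
              paste(edges$node_b[i], edges$end_b[i]))
    if (any(ends %in% end_used)) next
    cand <- accepted; cand[i] <- TRUE
    if (!valid_edge_set(cand, edges)) next
    accepted <- cand
    end_used <- c(end_used, ends)
  }
  improve <- TRUE; pass <- 0L
  cur <- score_edge_set(accepted, edges)
  while (improve && pass < 20L) {
    improve <- FALSE; pass <- pass + 1L
    for (i in seq_len(m)) {
      cand <- accepted
      if (accepted[i]) {
        cand[i] <- FALSE                 # removal move
      } else {                           # insertion move, evicting blockers
        ends <- c(paste(edges$node_a[i], edges$end_a[i]),
                  paste(edges$node_b[i], edges$end_b[i]))
        occ <- paste(edges$node_a, edges$end_a) %in% ends |
          paste(edges$node_b, edges$end_b) %in% ends
        cand[occ & accepted] <- FALSE
        cand[i] <- TRUE
        if (!valid_edge_set(cand, edges)) next
      }
      sc <- score_edge_set(cand, edges)
      if (sc > cur) { accepted <- cand; cur <- sc; improve <- TRUE }
    }
  }
  accepted
}

#' Chain fragments into hyper-scaffolds
#'
#' Candidate edges (per-library dPET edges combined by summing weights on
#' identical links, plus provenance edges whose ends no dPET edge claims)
#' are decomposed into connected components.  Each component is solved for
#' the conflict-aware path score -- traversed weight minus the weight of
#' edges incident to an occupied fragment end -- exactly when it has at
#' most `exact_limit` edges (scaffold-graph components are small: bubbles
#' are common, forks rare), and by greedy descending-weight construction
#' with add/remove local moves otherwise.  Every fragment appears in
#' exactly one chain (singletons allowed); chains are acyclic by
#' construction.
#'
#' @param edges edge table from [build_edges()] (several libraries may be
#'   stacked) plus optional [provenance_edges()].
#' @param fragments fragment table.
#' @param exact_limit maximum component size (edges) solved exactly.
#' @return chain table `chain_id, position, fragment_id, orientation,
#'   gap_before` with attributes `score` and `edges_used`.
#' @export
chain_scaffolds <- function(edges, fragments, exact_limit = 12L) {
  dp <- combine_edge_libraries(edges[edges$kind == "dpet", , drop = FALSE])
  pv <- edges[edges$kind == "provenance", , drop = FALSE]
  if (nrow(pv)) {
    claims <- c(paste(dp$node_a, dp$end_a), paste(dp$node_b, dp$end_b))
    ok <- !(paste(pv$node_a, pv$end_a) %in% claims) &
      !(paste(pv$node_b, pv$end_b) %in% claims)
    pv <- pv[ok, , drop = FALSE]
  }
  all_e <- rbind(dp, pv)
  nodes <- fragments$fragment_id
  n_e <- nrow(all_e)
  accepted <- logical(n_e)
  if (n_e) {
    comp <- build_components(rep(TRUE, n_e), all_e, nodes)
    edge_comp <- comp[all_e$node_a]
    for (cc in unique(edge_comp)) {
      idx <- which(edge_comp == cc)
      sub <- all_e[idx, , drop = FALSE]
      accepted[idx] <- if (length(idx) <= exact_limit)
        solve_component_exact(sub) else solve_component_greedy(sub)
    }
  }

  # assemble chains from the accepted edge set
  adj <- list()
  for (i in which(accepted)) {
    a <- all_e$node_a[i]; b <- all_e$node_b[i]
    adj[[a]] <- c(adj[[a]], i); adj[[b]] <- c(adj[[b]], i)
  }
  visited <- stats::setNames(rep(FALSE, length(nodes)), nodes)
  rows <- list()
  chain_id <- 0L
  for (start_node in nodes) {
    if (visited[[start_node]]) next
    deg <- length(adj[[start_node]])
    if (deg == 2L) next                 # interior; handled from an endpoint
    chain_id <- chain_id + 1L
    node <- start_node
    prev_edge <- NA_integer_
    pos <- 0L
    repeat {
      visited[[node]] <- TRUE
      pos <- pos + 1L
      nxt <- setdiff(adj[[node]], prev_edge)
      if (length(nxt)) {
        i <- nxt[1]
        exit_end <- if (all_e$node_a[i] == node) all_e$end_a[i] else all_e$end_b[i]
        ori <- if (exit_end == "tail") "+" else "-"
      } else if (!is.na(prev_edge)) {
        i0 <- prev_edge
        entry_end <- if (all_e$node_a[i0] == node) all_e$end_a[i0] else all_e$end_b[i0]
        ori <- if (entry_end == "head") "+" else "-"
      } else ori <- "+"
      rows[[length(rows) + 1L]] <- data.frame(
        chain_id = chain_id, position = pos, fragment_id = node,
        orientation = ori,
        gap_before = if (is.na(prev_edge)) NA_real_ else all_e$est_link_len[prev_edge],
        stringsAsFactors = FALSE)
      if (!length(nxt)) break
      i <- nxt[1]
      node <- if (all_e$node_a[i] == node) all_e$node_b[i] else all_e$node_a[i]
      prev_edge <- i
    }
  }
  chains <- do.call(rbind, rows)
  attr(chains, "score") <- if (n_e) score_edge_set(accepted, all_e) else 0
  attr(chains, "edges_used") <- if (n_e) all_e[accepted, , drop = FALSE] else all_e
  chains
}

#' Report assembly-gap fill-ins
#'
#' A fill-in occurs when a chain routes fragments of other parents between
#' two consecutive fragments of one parent (the removed gap is occupied by
#' smaller scaffolds).
#'
#' @param chains chain table from [chain_scaffolds()].
#' @param fragments fragment table.
#' @return data.frame `chain_id, parent, left_fragment, right_fragment,
#'   n_fillers, fillers`; attribute `n_fillins` holds the total count of
#'   filling fragments.
#' @export
fill_gaps <- function(chains, fragments) {
  res <- list()
  par <- fragments$parent[match(chains$fragment_id, fragments$fragment_id)]
  for (cid in unique(chains$chain_id)) {
    sel <- which(chains$chain_id == cid)
    sel <- sel[order(chains$position[sel])]
    p <- par[sel]
    occ <- split(seq_along(sel), p)
    for (pa in names(occ)) {
      o <- occ[[pa]]
      if (length(o) < 2) next
      for (k in seq_len(length(o) - 1L)) {
        i <- o[k]; j <- o[k + 1L]
        if (j - i <= 1L) next
        mid <- sel[(i + 1L):(j - 1L)]
        if (any(par[mid] == pa)) next
        res[[length(res) + 1L]] <- data.frame(
          chain_id = cid, parent = pa,
          left_fragment = chains$fragment_id[sel[i]],
          right_fragment = chains$fragment_id[sel[j]],
          n_fillers = length(mid),
          fillers = paste(chains$fragment_id[mid], collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(chain_id = integer(), parent = character(),
               left_fragment = character(), right_fragment = character(),
               n_fillers = integer(), fillers = character(),
               stringsAsFactors = FALSE)
  attr(out, "n_fillins") <- sum(out$n_fillers)
  out
}

#' N50 of a set of lengths
#' @param lengths numeric vector of scaffold lengths.
#' @export
n50 <- function(lengths) {
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}

#' Before/after assembly statistics
#'
#' @param before,after numeric vectors of scaffold / hyper-scaffold
#'   lengths.
#' @param chains optional chain table for the chain-length distribution.
#' @return list with per-assembly `n, total, n50, max`, the deltas, and
#'   `chain_length_dist` when chains are given.
#' @export
assembly_stats <- function(before, after, chains = NULL) {
  st <- function(x) list(n = length(x), total = sum(x), n50 = n50(x),
                         max = max(x))
  out <- list(before = st(before), after = st(after))
  out$scaffold_reduction <- 1 - out$after$n / out$before$n
  out$n50_ratio <- out$after$n50 / out$before$n50
  out$max_ratio <- out$after$max / out$before$max
  if (!is.null(chains)) {
    cl <- table(table(chains$chain_id))
    out$chain_length_dist <- stats::setNames(as.integer(cl), names(cl))
    sizes <- as.integer(table(chains$chain_id))
    out$mean_chain_length <- mean(sizes)
    out$median_chain_length <- median(sizes)
  }
  out
}

#' Chain lengths in bp (fragments plus estimated inter-fragment gaps)
#' @param chains chain table.
#' @param fragments fragment table.
#' @export
chain_lengths <- function(chains, fragments) {
  fl <- fragments$length[match(chains$fragment_id, fragments$fragment_id)]
  gaps <- ifelse(is.na(chains$gap_before), 0, pmax(1, chains$gap_before))
  as.numeric(tapply(fl + gaps, chains$chain_id, sum))
}
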