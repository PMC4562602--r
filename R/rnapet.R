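# RNA-PET ditag annotation: 3'-signature classification (HT/TT/HH),
# transcript-boundary clustering under stringent/relaxed parameters with
# promotion, noise filtering against RNA-Seq support, gene-model
# coalescing, and comparison with an existing annotation.

#' Search a read for the 3' signature
#'
#' Ungapped local alignment of the 8 bp signature against every window of
#' the read (match +1, mismatch -1, indels disallowed over the window,
#' which reduces to minimum Hamming distance).  The signature is found iff
#' the best window has at most `max_mismatch` mismatches.
#'
#' @param reads character vector of read sequences.
#' @param signature signature sequence (default `AACTGCTG`).
#' @param max_mismatch maximum tolerated mismatches (default 2).
#' @return data.frame `found, mismatches, pos` (`pos` = 0-based offset of
#'   the best window, NA when the read is shorter than the signature).
#' @export
find_signature <- function(reads, signature = "AACTGCTG", max_mismatch = 2L) {
  k <- nchar(signature)
  sig <- strsplit(toupper(signature), "")[[1]]
  n <- length(reads)
  best <- rep(NA_integer_, n)
  pos <- rep(NA_integer_, n)
  lens <- nchar(reads)
  for (L in unique(lens)) {
    if (L < k) next
    sel <- which(lens == L)
    mat <- matrix(unlist(strsplit(toupper(reads[sel]), "")),
                  nrow = length(sel), byrow = TRUE)
    bm <- rep(k + 1L, length(sel)); bp <- rep(0L, length(sel))
    for (off in 0:(L - k)) {
      mm <- rowSums(mat[, off + seq_len(k), drop = FALSE] !=
                      matrix(sig, length(sel), k, byrow = TRUE))
      better <- mm < bm
      bm[better] <- mm[better]; bp[better] <- off
    }
    best[sel] <- as.integer(bm); pos[sel] <- bp
  }
  data.frame(found = !is.na(best) & best <= max_mismatch,
             mismatches = best, pos = pos)
}

#' Classify ditags by signature content
#'
#' HT: exactly one read carries the 3' signature (usable full-length
#' evidence); TT: both (noise); HH: neither (noise, mostly sequencing
#' errors inside the 8 bp signature).
#'
#' @param read1,read2 character vectors of mate sequences.
#' @inheritParams find_signature
#' @return data.frame `class` (factor HT/TT/HH), `signature_end`
#'   (1, 2, "both" or "none"), `mm1, mm2`.
#' @export
classify_ditags <- function(read1, read2, signature = "AACTGCTG",
                            max_mismatch = 2L) {
  s1 <- find_signature(read1, signature, max_mismatch)
  s2 <- find_signature(read2, signature, max_mismatch)
  cls <- ifelse(s1$found & s2$found, "TT",
                ifelse(s1$found | s2$found, "HT", "HH"))
  send <- ifelse(s1$found & s2$found, "both",
                 ifelse(s1$found, "1", ifelse(s2$found, "2", "none")))
  data.frame(class = factor(cls, levels = c("HT", "TT", "HH")),
             signature_end = send, mm1 = s1$mismatches, mm2 = s2$mismatches,
             stringsAsFactors = FALSE)
}

#' Orient HT ditag pairs
#'
#' Only HT pairs pass.  The read carrying the signature is the 3' tag, the
#' other the 5' tag; transcript strand is the mapped strand of the 5' tag.
#'
#' @param pairs mapped tag-pair table (tag1 = read1, tag2 = read2).
#' @param classes classification from [classify_ditags()] (same order).
#' @return data.frame `pair_id, ref5, ref3, strand, p5_start, p5_end,
#'   p3_start, p3_end`.
#' @export
orient_pairs <- function(pairs, classes) {
  keep <- classes$class == "HT"
  p <- pairs[keep, , drop = FALSE]
  sig2 <- classes$signature_end[keep] == "2"
  out <- data.frame(
    pair_id = p$pair_id,
    ref5 = ifelse(sig2, p$ref1, p$ref2),
    ref3 = ifelse(sig2, p$ref2, p$ref1),
    strand = ifelse(sig2, p$strand1, p$strand2),
    p5_start = ifelse(sig2, p$start1, p$start2),
    p5_end = ifelse(sig2, p$end1, p$end2),
    p3_start = ifelse(sig2, p$start2, p$start1),
    p3_end = ifelse(sig2, p$end2, p$end1),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Cluster oriented PETs into transcript-boundary clusters
#'
#' Single-pass greedy aggregation per (reference, strand): input is sorted
#' by 5'-tag start and a PET joins the open cluster when its 5' tag
#' overlaps the cluster's 5'-tag window extended by `slack` bp (stringent
#' slack 0; relaxed slack > 0).  The cluster span runs from the outermost
#' 5' boundary to the outermost 3' boundary.  Cross-reference pairs are
#' ignored here (see [detect_split_genes()]).
#'
#' @param oriented oriented pairs from [orient_pairs()].
#' @param slack 5'-window extension in bp.
#' @param parameter_set label stored on the clusters.
#' @return data.frame `cluster_id, ref, strand, start, end, span,
#'   pet_count, tss, tts, parameter_set`.
#' @export
cluster_pets <- function(oriented, slack = 0L, parameter_set = "stringent") {
  o <- oriented[oriented$ref5 == oriented$ref3, , drop = FALSE]
  empty <- data.frame(cluster_id = character(), ref = character(),
                      strand = character(), start = integer(),
                      end = integer(), span = integer(),
                      pet_count = integer(), tss = integer(),
                      tts = integer(), parameter_set = character(),
                      stringsAsFactors = FALSE)
  if (nrow(o) == 0) return(empty)
  o <- o[order(o$ref5, o$strand, o$p5_start, o$p5_end, o$p3_start), , drop = FALSE]
  res <- list()
  grp <- paste(o$ref5, o$strand, sep = "\r")
  for (g in unique(grp)) {
    x <- o[grp == g, , drop = FALSE]
    wmin <- x$p5_start[1]; wmax <- x$p5_end[1]
    members <- 1L
    flush <- function(members) {
      m <- x[members, , drop = FALSE]
      st <- min(m$p5_start, m$p3_start); en <- max(m$p5_end, m$p3_end)
      data.frame(cluster_id = NA_character_, ref = m$ref5[1],
                 strand = m$strand[1], start = st, end = en, span = en - st,
                 pet_count = nrow(m),
                 tss = if (m$strand[1] == "+") min(m$p5_start) else max(m$p5_end) - 1L,
                 tts = if (m$strand[1] == "+") max(m$p3_end) - 1L else min(m$p3_start),
                 parameter_set = parameter_set, stringsAsFactors = FALSE)
    }
    if (nrow(x) > 1) {
      for (i in 2:nrow(x)) {
        if (x$p5_start[i] < wmax + slack) {      # overlap with extended window
          members <- c(members, i)
          wmax <- max(wmax, x$p5_end[i])
        } else {
          res[[length(res) + 1L]] <- flush(members)
          members <- i; wmin <- x$p5_start[i]; wmax <- x$p5_end[i]
        }
      }
    }
    res[[length(res) + 1L]] <- flush(members)
  }
  out <- do.call(rbind, res)
  out <- out[order(out$ref, out$strand, out$start), , drop = FALSE]
  out$cluster_id <- sprintf("%s_c%05d", parameter_set, seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

#' RNA-Seq read density over an interval, in reads per kb
#'
#' @param rnaseq named list of per-base coverage vectors with attribute
#'   `read_len` (default 50 when absent).
#' @param ref,start,end interval (0-based half-open).
#' @export
rnaseq_density <- function(rnaseq, ref, start, end) {
  read_len <- attr(rnaseq, "read_len") %||% 50
  cov <- rnaseq[[ref]]
  if (is.null(cov)) return(0)
  s <- max(start, 0L); e <- min(end, length(cov))
  if (e <= s) return(0)
  reads <- sum(cov[(s + 1L):e]) / read_len
  reads / ((end - start) / 1000)
}

#' Promote between stringent and relaxed cluster sets
#'
#' Per transcription unit (maximal overlap group across both sets, same
#' reference and strand) the longer relaxed model is chosen unless it
#' spans two or more stringent clusters separated by an internal window of
#' at least `min_sep` bp whose RNA-Seq density falls below
#' `min_reads_per_kb` (the over-clustering test) -- then the stringent
#' models are kept.  This adapts clustering stringency to local context.
#'
#' @param stringent,relaxed cluster tables from [cluster_pets()].
#' @param rnaseq RNA-Seq coverage (see [rnaseq_density()]).
#' @param min_sep minimum unsupported gulf width in bp (default 1,000).
#' @param min_reads_per_kb support threshold (default 5).
#' @return promoted cluster table.
#' @export
promote <- function(stringent, relaxed, rnaseq, min_sep = 1000L,
                    min_reads_per_kb = 5) {
  both <- rbind(stringent, relaxed)
  if (nrow(both) == 0) return(both)
  gr <- GenomicRanges::GRanges(paste(both$ref, both$strand),
                               IRanges::IRanges(both$start + 1L, both$end))
  comp <- igraph_free_components(gr)
  res <- list()
  for (cc in unique(comp)) {
    idx <- which(comp == cc)
    sset <- both[idx[both$parameter_set[idx] == "stringent"], , drop = FALSE]
    rset <- both[idx[both$parameter_set[idx] != "stringent"], , drop = FALSE]
    pick_relaxed <- nrow(rset) > 0
    if (pick_relaxed && nrow(sset) >= 2) {
      # does the longest relaxed model bridge an unsupported gulf?
      top <- rset[which.max(rset$span), , drop = FALSE]
      inside <- sset[sset$start >= top$start & sset$end <= top$end, , drop = FALSE]
      if (nrow(inside) >= 2) {
        inside <- inside[order(inside$start), , drop = FALSE]
        for (k in seq_len(nrow(inside) - 1L)) {
          gs <- inside$end[k]; ge <- inside$start[k + 1L]
          if (ge - gs >= min_sep &&
              rnaseq_density(rnaseq, top$ref, gs, ge) < min_reads_per_kb) {
            pick_relaxed <- FALSE
            break
          }
        }
      }
    }
    res[[length(res) + 1L]] <-
      if (pick_relaxed && nrow(rset)) rset[which.max(rset$span), , drop = FALSE]
      else if (nrow(sset)) sset
      else rset
  }
  out <- do.call(rbind, res)
  out <- out[order(out$ref, out$strand, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# connected components of an overlap graph over GRanges (reduce-based)
igraph_free_components <- function(gr) {
  red <- GenomicRanges::reduce(gr)
  GenomicRanges::findOverlaps(gr, red, select = "first")
}

#' Filter transcript clusters
#'
#' Drops clusters with span below `min_span` (the low-PET-count noise
#' mode of the cluster-span distribution) and clusters whose RNA-Seq
#' density over their span is below `min_reads_per_kb`.
#'
#' @param clusters cluster table.
#' @param rnaseq RNA-Seq coverage (see [rnaseq_density()]).
#' @param min_span minimum span in bp (default 2,000).
#' @param min_reads_per_kb minimum RNA-Seq support (default 5).
#' @export
filter_clusters <- function(clusters, rnaseq, min_span = 2000L,
                            min_reads_per_kb = 5) {
  if (nrow(clusters) == 0) return(clusters)
  dens <- vapply(seq_len(nrow(clusters)), function(i)
    rnaseq_density(rnaseq, clusters$ref[i], clusters$start[i], clusters$end[i]),
    0)
  out <- clusters[clusters$span >= min_span & dens >= min_reads_per_kb, ,
                  drop = FALSE]
  rownames(out) <- NULL
  out
}

# deduplicate positions within a radius (greedy left-to-right)
dedup_positions <- function(pos, radius) {
  pos <- sort(unique(pos))
  if (length(pos) <= 1) return(pos)
  keep <- pos[1]
  out <- pos[1]
  for (p in pos[-1]) {
    if (p - keep > radius) { out <- c(out, p); keep <- p }
  }
  out
}

#' Coalesce clusters into gene models
#'
#' Same-reference, same-strand clusters with overlapping spans are merged
#' transitively (connected components of the overlap graph).  TSS/TTS sets
#' are the distinct cluster boundary positions, deduplicated within
#' `merge_radius` bp.
#'
#' @param clusters filtered cluster table.
#' @param merge_radius TSS/TTS deduplication radius in bp (default 10).
#' @return data.frame `gene_id, ref, strand, start, end, n_clusters` with
#'   list-columns `tss_set`, `tts_set`.
#' @export
coalesce_clusters <- function(clusters, merge_radius = 10L) {
  empty <- data.frame(gene_id = character(), ref = character(),
                      strand = character(), start = integer(),
                      end = integer(), n_clusters = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(clusters) == 0) { empty$tss_set <- list(); empty$tts_set <- list(); return(empty) }
  gr <- GenomicRanges::GRanges(paste(clusters$ref, clusters$strand),
                               IRanges::IRanges(clusters$start + 1L, clusters$end))
  comp <- igraph_free_components(gr)
  res <- list()
  for (cc in sort(unique(comp))) {
    m <- clusters[comp == cc, , drop = FALSE]
    res[[length(res) + 1L]] <- data.frame(
      gene_id = NA_character_, ref = m$ref[1], strand = m$strand[1],
      start = min(m$start), end = max(m$end), n_clusters = nrow(m),
      stringsAsFactors = FALSE)
    res[[length(res)]]$tss_set <- list(dedup_positions(m$tss, merge_radius))
    res[[length(res)]]$tts_set <- list(dedup_positions(m$tts, merge_radius))
  }
  out <- do.call(rbind, res)
  out <- out[order(out$ref, out$start, out$strand), , drop = FALSE]
  out$gene_id <- sprintf("PETG%05d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

#' Compare a new annotation with an existing one
#'
#' Genes are matched by reciprocal best overlap (same reference and
#' strand).  A matched gene is flagged extended when `new/old > ratio` or
#' `new - old > abs_bp`.  Also reports counts of matched, novel (new gene
#' with no overlap) and silent (existing gene with no overlap) genes, and
#' the fraction of RNA-Seq signal inside each annotation's spans.
#'
#' @param genes new gene table (`gene_id, ref, strand, start, end`).
#' @param existing existing annotation in the same layout.
#' @param rnaseq optional RNA-Seq coverage.
#' @param ratio,abs_bp extension thresholds (defaults 1.3 and 5,000).
#' @return list with `pairs` (per-match table), `n_matched, n_novel,
#'   n_silent, extended_fraction, rnaseq_fraction_new,
#'   rnaseq_fraction_old`.
#' @export
compare_annotation <- function(genes, existing, rnaseq = NULL,
                               ratio = 1.3, abs_bp = 5000) {
  gr_n <- GenomicRanges::GRanges(paste(genes$ref, genes$strand),
                                 IRanges::IRanges(genes$start + 1L, genes$end))
  gr_o <- GenomicRanges::GRanges(paste(existing$ref, existing$strand),
                                 IRanges::IRanges(existing$start + 1L, existing$end))
  hits <- GenomicRanges::findOverlaps(gr_n, gr_o)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  ov <- IRanges::width(IRanges::pintersect(IRanges::ranges(gr_n)[qh],
                                           IRanges::ranges(gr_o)[sh]))
  pairs <- NULL
  if (length(qh)) {
    best_for_new <- tapply(seq_along(qh), qh, function(i) i[which.max(ov[i])])
    best_for_old <- tapply(seq_along(sh), sh, function(i) i[which.max(ov[i])])
    recip <- intersect(unlist(best_for_new), unlist(best_for_old))
    if (length(recip)) {
      nlen <- genes$end[qh[recip]] - genes$start[qh[recip]]
      olen <- existing$end[sh[recip]] - existing$start[sh[recip]]
      pairs <- data.frame(
        gene_id = genes$gene_id[qh[recip]],
        existing_id = existing$gene_id[sh[recip]],
        new_len = nlen, old_len = olen,
        length_ratio = nlen / olen,
        extended = nlen / olen > ratio | nlen - olen > abs_bp,
        stringsAsFactors = FALSE)
    }
  }
  if (is.null(pairs))
    pairs <- data.frame(gene_id = character(), existing_id = character(),
                        new_len = integer(), old_len = integer(),
                        length_ratio = numeric(), extended = logical(),
                        stringsAsFactors = FALSE)
  frac <- function(tab) {
    if (is.null(rnaseq)) return(NA_real_)
    tot <- sum(vapply(rnaseq, sum, 0))
    if (tot == 0) return(NA_real_)
    inside <- 0
    for (sc in names(rnaseq)) {
      g <- tab[tab$ref == sc, , drop = FALSE]
      if (!nrow(g)) next
      covered <- IRanges::reduce(IRanges::IRanges(g$start + 1L, g$end))
      for (k in seq_along(covered)) {
        s <- max(IRanges::start(covered)[k], 1L)
        e <- min(IRanges::end(covered)[k], length(rnaseq[[sc]]))
        if (e >= s) inside <- inside + sum(rnaseq[[sc]][s:e])
      }
    }
    inside / tot
  }
  list(pairs = pairs,
       n_matched = nrow(pairs),
       n_novel = sum(!seq_len(nrow(genes)) %in% qh),
       n_silent = sum(!seq_len(nrow(existing)) %in% sh),
       extended_fraction = if (nrow(pairs)) mean(pairs$extended) else NA_real_,
       rnaseq_fraction_new = frac(genes),
       rnaseq_fraction_old = frac(existing))
}

#' Detect gene models split across two scaffolds
#'
#' Oriented HT pairs whose 5' and 3' tags map to different scaffolds are
#' clustered by scaffold pair and 5'-tag proximity; each resulting split
#' model is flagged `same_chain` when the two scaffolds co-occur in one
#' hyper-scaffold chain (cross-validation of DNA-PET and RNA-PET).
#'
#' @param oriented oriented pairs from [orient_pairs()].
#' @param chains chain table from [chain_scaffolds()]; may be NULL.
#' @param fragments fragment table matching `chains`.
#' @param slack 5'-position grouping slack in bp (default 1,000).
#' @return data.frame `ref5, ref3, strand, p5, p3, pet_count, same_chain`.
#' @export
detect_split_genes <- function(oriented, chains = NULL, fragments = NULL,
                               slack = 1000L) {
  x <- oriented[oriented$ref5 != oriented$ref3, , drop = FALSE]
  empty <- data.frame(ref5 = character(), ref3 = character(),
                      strand = character(), p5 = integer(), p3 = integer(),
                      pet_count = integer(), same_chain = logical(),
                      stringsAsFactors = FALSE)
  if (nrow(x) == 0) return(empty)
  x <- x[order(x$ref5, x$ref3, x$strand, x$p5_start), , drop = FALSE]
  grp <- paste(x$ref5, x$ref3, x$strand, sep = "\r")
  chain_of <- NULL
  if (!is.null(chains) && !is.null(fragments)) {
    par <- fragments$parent[match(chains$fragment_id, fragments$fragment_id)]
    chain_of <- split(chains$chain_id, par)
  }
  res <- list()
  for (g in unique(grp)) {
    m <- x[grp == g, , drop = FALSE]
    brk <- c(0L, which(diff(m$p5_start) > slack), nrow(m))
    for (k in seq_len(length(brk) - 1L)) {
      mm <- m[(brk[k] + 1L):brk[k + 1L], , drop = FALSE]
      same <- FALSE
      if (!is.null(chain_of)) {
        c5 <- chain_of[[mm$ref5[1]]]; c3 <- chain_of[[mm$ref3[1]]]
        same <- length(intersect(c5, c3)) > 0
      }
      res[[length(res) + 1L]] <- data.frame(
        ref5 = mm$ref5[1], ref3 = mm$ref3[1], strand = mm$strand[1],
        p5 = min(mm$p5_start), p3 = max(mm$p3_end),
        pet_count = nrow(mm), same_chain = same, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, res)
}
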