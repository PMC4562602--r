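# Deterministic synthetic-data generator with ground truth: a "true"
# chromosome cut into scaffolds with mis-annotated internal gaps (optional
# second alleles and planted chimeric mis-joins), DNA-PET mate-pair
# libraries drawn on true coordinates, and a transcriptome emitting
# signature-bearing RNA-PET ditags plus strand-specific RNA-Seq coverage.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a fragmented genome with ground truth
#'
#' One or more "true" chromosomes are cut into scaffolds separated by
#' unsequenced inter-scaffold gaps (the adjacencies re-scaffolding must
#' recover).  Scaffolds carry internal assembly gaps (N-runs) whose true
#' length is log-normal (median ~500 bp, matching the typical real size of
#' placeholder gaps) while a configurable fraction is annotated at a fixed
#' placeholder length (50 bp).  A fraction of gaps can be biallelic
#' (structural polymorphism) and chimeric mis-joins can be planted for
#' breakpoint tests.
#'
#' @param seed integer seed; fixes all randomness.
#' @param n_chrom number of chromosomes (default 1).
#' @param chrom_len true chromosome length in bp.
#' @param n_fragments scaffolds per chromosome.
#' @param gap_rate expected internal gaps per bp (default 1/20,000).
#' @param gap_meanlog,gap_sdlog log-normal parameters of true gap length
#'   (defaults give median 500 bp).
#' @param frac_fixed_annotation fraction of internal gaps annotated at
#'   `fixed_annotated_len` regardless of true length (default 0.5).
#' @param fixed_annotated_len the placeholder annotation (default 50 bp).
#' @param biallelic_frac fraction of internal gaps with a second allele.
#' @param biallelic_delta second-allele length offset in bp (default 2,500).
#' @param inter_gap_range range of true inter-scaffold gaps (default
#'   500-8,000 bp; links beyond the library span cannot be recovered).
#' @param n_chimera number of planted chimeric scaffold joins.
#' @param random_orientation emit scaffolds in random orientation.
#' @param emit_sequence generate actual sequence (set FALSE for large,
#'   coordinate-only simulations).
#' @return list with `assembly` (a [pet_assembly]) and `truth` (class
#'   `pet_sim_truth`: `contigs`, `gaps`, `adjacency`, `junctions`,
#'   `chrom_len`).
#' @export
simulate_genome <- function(seed, n_chrom = 1L, chrom_len = 1e6,
                            n_fragments = 20L, gap_rate = 1 / 20000,
                            gap_meanlog = log(500), gap_sdlog = 0.7,
                            frac_fixed_annotation = 0.5,
                            fixed_annotated_len = 50L,
                            biallelic_frac = 0, biallelic_delta = 2500,
                            inter_gap_range = c(500, 8000),
                            n_chimera = 0L, random_orientation = TRUE,
                            emit_sequence = TRUE) {
  set.seed(seed)
  stopifnot(n_fragments >= 1, chrom_len > 0)
  contigs <- list(); gaps <- list(); adjacency <- list()
  scaffold_names <- character(); scaffold_len <- integer()
  sc_chrom <- character()
  actual_chrom_len <- numeric(n_chrom)
  sn <- 0L
  for (ch in seq_len(n_chrom)) {
    chrom <- sprintf("chr%d", ch)
    nf <- n_fragments
    inter <- if (nf > 1) round(runif(nf - 1, inter_gap_range[1], inter_gap_range[2])) else numeric(0)
    w <- 0.5 + runif(nf)
    flen <- floor((chrom_len - sum(inter)) * w / sum(w))
    if (any(flen < 5000)) flen <- pmax(flen, 5000)
    t0 <- cumsum(c(0, head(flen, -1) + inter))
    actual_chrom_len[ch] <- t0[nf] + flen[nf]
    for (k in seq_len(nf)) {
      sn <- sn + 1L
      sc <- sprintf("scaffold_%d", sn)
      fl <- flen[k]
      # internal gaps: true interval carved out of the fragment
      ng <- rpois(1, fl * gap_rate)
      g <- NULL
      if (ng > 0) {
        tl <- pmax(50L, round(rlnorm(ng, gap_meanlog, gap_sdlog)))
        margin <- 3000L
        avail <- fl - 2L * margin - sum(tl) - (ng - 1L) * 3000L
        if (avail > 0) {
          offs <- sort(sample.int(avail, ng))
          gs <- margin + offs + c(0L, cumsum(head(tl, -1) + 3000L))
          fixed <- runif(ng) < frac_fixed_annotation
          ann <- ifelse(fixed, fixed_annotated_len, tl)
          bi <- runif(ng) < biallelic_frac
          g <- data.frame(rel_start = gs, true_len = tl, annotated = ann,
                          allele2_len = ifelse(bi, tl + biallelic_delta, NA_real_),
                          allele2_frac = ifelse(bi, 0.5, NA_real_))
        }
      }
      ori <- if (random_orientation && runif(1) < 0.5) "-" else "+"
      # contigs in fragment-relative then scaffold coordinates ('+' first)
      if (is.null(g) || nrow(g) == 0) {
        cst <- 0L; cen <- fl
        ann_cum <- integer(0)
      } else {
        cst <- c(0L, g$rel_start + g$true_len)
        cen <- c(g$rel_start, fl)
      }
      clen <- cen - cst
      # scaffold coordinate of each contig start ('+' orientation)
      ann_before <- if (is.null(g) || nrow(g) == 0) rep(0L, length(cst)) else
        c(0L, cumsum(g$annotated))
      removed_before <- if (is.null(g) || nrow(g) == 0) rep(0L, length(cst)) else
        c(0L, cumsum(g$true_len))
      s_start_plus <- cst - removed_before + ann_before
      scafL <- as.integer(fl - sum(if (is.null(g)) 0L else g$true_len) +
                            sum(if (is.null(g)) 0L else g$annotated))
      if (ori == "+") {
        s_start <- s_start_plus
        s_end <- s_start + clen
        cstrand <- rep("+", length(cst))
      } else {
        s_end <- scafL - s_start_plus
        s_start <- s_end - clen
        cstrand <- rep("-", length(cst))
      }
      contigs[[length(contigs) + 1L]] <- data.frame(
        chrom = chrom, t_start = t0[k] + cst, t_end = t0[k] + cen,
        scaffold = sc, s_start = s_start, s_end = s_end, strand = cstrand,
        stringsAsFactors = FALSE)
      if (!is.null(g) && nrow(g)) {
        gs_plus <- g$rel_start - (removed_before[-1] - g$true_len) +
          ann_before[seq_len(nrow(g))]
        if (ori == "+") {
          gstart <- gs_plus
        } else {
          gstart <- scafL - (gs_plus + g$annotated)
        }
        gaps[[length(gaps) + 1L]] <- data.frame(
          scaffold = sc, s_start = as.integer(gstart),
          s_end = as.integer(gstart + g$annotated),
          annotated = as.integer(g$annotated), true_len = g$true_len,
          allele2_len = g$allele2_len, allele2_frac = g$allele2_frac,
          chrom = chrom, t_start = t0[k] + g$rel_start,
          t_end = t0[k] + g$rel_start + g$true_len,
          kind = "internal", stringsAsFactors = FALSE)
      }
      adjacency[[length(adjacency) + 1L]] <- data.frame(
        chrom = chrom, ord = k, scaffold = sc, orientation = ori,
        gap_after = if (k < nf) inter[k] else NA_real_,
        stringsAsFactors = FALSE)
      scaffold_names <- c(scaffold_names, sc)
      scaffold_len <- c(scaffold_len, scafL)
      sc_chrom <- c(sc_chrom, chrom)
    }
  }
  contigs <- do.call(rbind, contigs)
  gaps <- if (length(gaps)) do.call(rbind, gaps) else
    data.frame(scaffold = character(), s_start = integer(), s_end = integer(),
               annotated = integer(), true_len = numeric(),
               allele2_len = numeric(), allele2_frac = numeric(),
               chrom = character(), t_start = numeric(), t_end = numeric(),
               kind = character(), stringsAsFactors = FALSE)
  adjacency <- do.call(rbind, adjacency)
  junctions <- data.frame(scaffold = character(), s_start = integer(),
                          s_end = integer(), left = character(),
                          right = character(), stringsAsFactors = FALSE)

  # planted chimeric mis-joins: fuse pairs of non-adjacent scaffolds
  if (n_chimera > 0) {
    idx <- seq_along(scaffold_names)
    cand <- idx
    pairs <- list()
    while (length(pairs) < n_chimera && length(cand) >= 2) {
      i <- cand[1]
      far <- cand[abs(cand - i) > 1 | sc_chrom[cand] != sc_chrom[i]]
      if (!length(far)) break
      j <- far[length(far) %/% 2 + 1L]
      pairs[[length(pairs) + 1L]] <- c(i, j)
      cand <- setdiff(cand, c(i, j))
    }
    pairs <- lapply(pairs, function(p) scaffold_names[p])
    for (p in pairs) {
      a <- p[1]; b <- p[2]
      newn <- paste0(a, "x")
      ia <- match(a, scaffold_names); ib <- match(b, scaffold_names)
      La <- scaffold_len[ia]
      off <- La + 50L
      contigs$s_start[contigs$scaffold == b] <- contigs$s_start[contigs$scaffold == b] + off
      contigs$s_end[contigs$scaffold == b] <- contigs$s_end[contigs$scaffold == b] + off
      contigs$scaffold[contigs$scaffold %in% c(a, b)] <- newn
      if (nrow(gaps)) {
        sel <- gaps$scaffold == b
        gaps$s_start[sel] <- gaps$s_start[sel] + off
        gaps$s_end[sel] <- gaps$s_end[sel] + off
        gaps$scaffold[gaps$scaffold %in% c(a, b)] <- newn
      }
      gaps <- rbind(gaps, data.frame(
        scaffold = newn, s_start = La, s_end = La + 50L, annotated = 50L,
        true_len = NA_real_, allele2_len = NA_real_, allele2_frac = NA_real_,
        chrom = NA_character_, t_start = NA_real_, t_end = NA_real_,
        kind = "junction", stringsAsFactors = FALSE))
      junctions <- rbind(junctions, data.frame(
        scaffold = newn, s_start = La, s_end = La + 50L, left = a, right = b,
        stringsAsFactors = FALSE))
      adjacency$scaffold[adjacency$scaffold %in% c(a, b)] <- newn
      scaffold_len[ia] <- La + 50L + scaffold_len[ib]
      scaffold_names[ia] <- newn
      scaffold_names <- scaffold_names[-ib]
      scaffold_len <- scaffold_len[-ib]
      sc_chrom <- sc_chrom[-ib]
    }
  }

  seqs <- NULL
  if (emit_sequence) {
    chrom_seq <- lapply(seq_len(n_chrom), function(ch) random_dna(chrom_len))
    names(chrom_seq) <- sprintf("chr%d", seq_len(n_chrom))
    build <- vapply(seq_along(scaffold_names), function(i) {
      sc <- scaffold_names[i]
      s <- strrep("N", scaffold_len[i])
      co <- contigs[contigs$scaffold == sc, , drop = FALSE]
      for (k in seq_len(nrow(co))) {
        piece <- substr(chrom_seq[[co$chrom[k]]], co$t_start[k] + 1L, co$t_end[k])
        if (co$strand[k] == "-")
          piece <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(piece)))
        substr(s, co$s_start[k] + 1L, co$s_end[k]) <- piece
      }
      s
    }, "")
    seqs <- Biostrings::DNAStringSet(build)
    names(seqs) <- scaffold_names
  }
  assembly <- pet_assembly(
    data.frame(name = scaffold_names, length = scaffold_len,
               stringsAsFactors = FALSE),
    if (nrow(gaps)) data.frame(scaffold = gaps$scaffold, start = gaps$s_start,
                               end = gaps$s_end,
                               annotated_len = gaps$annotated,
                               stringsAsFactors = FALSE) else NULL,
    seq = seqs)
  truth <- structure(list(contigs = contigs, gaps = gaps,
                          adjacency = adjacency, junctions = junctions,
                          chrom_len = actual_chrom_len,
                          n_chrom = n_chrom, seed = seed),
                     class = "pet_sim_truth")
  list(assembly = assembly, truth = truth)
}

# project true-coordinate tag intervals onto scaffold coordinates;
# returns NA rows for tags not fully inside one contig
project_tags <- function(truth, chrom, start, end, strand) {
  co <- truth$contigs
  ref <- rep(NA_character_, length(start))
  s_out <- rep(NA_integer_, length(start))
  e_out <- rep(NA_integer_, length(start))
  st_out <- rep(NA_character_, length(start))
  for (ch in unique(chrom)) {
    cc <- co[co$chrom == ch, , drop = FALSE]
    cc <- cc[order(cc$t_start), , drop = FALSE]
    sel <- which(chrom == ch)
    fi <- findInterval(start[sel], cc$t_start)
    ok <- fi >= 1L
    ok[ok] <- end[sel][ok] <= cc$t_end[fi[ok]] & start[sel][ok] >= cc$t_start[fi[ok]]
    i <- sel[ok]; f <- fi[ok]
    plus <- cc$strand[f] == "+"
    s_out[i] <- ifelse(plus, cc$s_start[f] + (start[i] - cc$t_start[f]),
                       cc$s_start[f] + (cc$t_end[f] - end[i]))
    e_out[i] <- s_out[i] + (end[i] - start[i])
    ref[i] <- cc$scaffold[f]
    st_out[i] <- ifelse(plus == (strand[i] == "+"), "+", "-")
  }
  data.frame(ref = ref, start = s_out, end = e_out, strand = st_out,
             stringsAsFactors = FALSE)
}

#' Simulate a DNA-PET mate-pair library
#'
#' Fragments are drawn on true chromosome coordinates with insert length
#' Normal(`lib$insert_mean`, `insert_sd`), read in random orientation, and
#' their terminal tags projected to scaffold coordinates.  Tags falling in
#' unsequenced regions are unmappable and the pair is dropped.  Fragments
#' crossing a biallelic gap draw an allele, shifting the far tag by the
#' allele length difference.  A `chimera_rate` fraction of pairs is
#' replaced by artefactual random tag pairs (discordant background).
#'
#' @param truth `pet_sim_truth` from [simulate_genome()].
#' @param lib a [library_profile].
#' @param coverage target fragment (physical) coverage (default 20).
#' @param insert_sd insert-length sd; default 500 bp below 13 kb mean,
#'   else 1,000 bp.
#' @param chimera_rate artefactual-pair fraction (default 0).
#' @param seed integer seed.
#' @param tag_len mapped tag length (default 27).
#' @param coverage_bias_sd log-normal sd of a smooth per-20kb coverage
#'   landscape shared by all libraries simulated on one genome (derived
#'   from the genome seed, emulating mappability/GC bias).  0 (default)
#'   gives a uniform fragment process.
#' @return tag-pair data.frame; attribute `n_dropped` counts unmappable
#'   pairs.
#' @export
simulate_dnapet <- function(truth, lib, coverage = 20, insert_sd = NULL,
                            chimera_rate = 0, seed = 1L, tag_len = 27L,
                            coverage_bias_sd = 0) {
  block <- 20000L
  bias <- NULL
  if (coverage_bias_sd > 0) {
    set.seed(truth$seed + 1000003L)     # shared across libraries
    bias <- lapply(truth$chrom_len, function(L)
      rlnorm(ceiling(L / block), 0, coverage_bias_sd))
  }
  set.seed(seed)
  if (is.null(insert_sd)) insert_sd <- if (lib$insert_mean < 13000) 500 else 1000
  total <- sum(truth$chrom_len)
  n <- round(coverage * total / lib$insert_mean)
  ci_chrom <- sample.int(truth$n_chrom, n, replace = TRUE,
                         prob = truth$chrom_len / total)
  chrom <- sprintf("chr%d", ci_chrom)
  len <- pmax(2 * tag_len + 10, round(rnorm(n, lib$insert_mean, insert_sd)))
  maxs <- truth$chrom_len[ci_chrom] - len
  if (is.null(bias)) {
    s <- floor(runif(n) * pmax(maxs, 1))
  } else {
    s <- integer(n)
    for (ch in unique(ci_chrom)) {
      sel <- which(ci_chrom == ch)
      b <- sample.int(length(bias[[ch]]), length(sel), replace = TRUE,
                      prob = bias[[ch]])
      s[sel] <- (b - 1L) * block + floor(runif(length(sel)) * block)
    }
    s <- pmin(s, pmax(maxs, 1))
  }
  e <- s + len
  # biallelic gaps shift the 3' end by the allele length difference
  bi <- truth$gaps[!is.na(truth$gaps$allele2_len), , drop = FALSE]
  if (nrow(bi)) {
    for (k in seq_len(nrow(bi))) {
      spans <- chrom == bi$chrom[k] & s < bi$t_start[k] & e > bi$t_end[k]
      pick2 <- spans & runif(n) < bi$allele2_frac[k]
      e[pick2] <- e[pick2] - (bi$allele2_len[k] - bi$true_len[k])
    }
  }
  ori <- ifelse(runif(n) < 0.5, "+", "-")
  t1s <- ifelse(ori == "+", s, e - tag_len)
  t2s <- ifelse(ori == "+", e - tag_len, s)
  p1 <- project_tags(truth, chrom, t1s, t1s + tag_len, ori)
  p2 <- project_tags(truth, chrom, t2s, t2s + tag_len, ori)
  ok <- !is.na(p1$ref) & !is.na(p2$ref)
  df <- data.frame(pair_id = sprintf("%s_%06d", lib$library_id, seq_len(n)[ok]),
                   lib = lib$library_id,
                   ref1 = p1$ref[ok], start1 = p1$start[ok], end1 = p1$end[ok],
                   strand1 = p1$strand[ok],
                   ref2 = p2$ref[ok], start2 = p2$start[ok], end2 = p2$end[ok],
                   strand2 = p2$strand[ok], stringsAsFactors = FALSE)
  if (chimera_rate > 0 && nrow(df)) {
    co <- truth$contigs
    swap <- which(runif(nrow(df)) < chimera_rate)
    rand_tag <- function(m) {
      ci <- sample.int(nrow(co), m, replace = TRUE,
                       prob = co$s_end - co$s_start)
      pos <- co$s_start[ci] +
        floor(runif(m) * pmax(co$s_end[ci] - co$s_start[ci] - tag_len, 1))
      data.frame(ref = co$scaffold[ci], start = pos, end = pos + tag_len,
                 strand = sample(c("+", "-"), m, replace = TRUE),
                 stringsAsFactors = FALSE)
    }
    if (length(swap)) {
      r1 <- rand_tag(length(swap)); r2 <- rand_tag(length(swap))
      df[swap, c("ref1", "start1", "end1", "strand1")] <- r1
      df[swap, c("ref2", "start2", "end2", "strand2")] <- r2
    }
  }
  rownames(df) <- NULL
  attr(df, "n_dropped") <- as.integer(n - nrow(df))
  df
}

#' Simulate a transcriptome with RNA-PET ditags and RNA-Seq coverage
#'
#' Transcripts with defined TSS/TTS are placed inside single contigs (in
#' scaffold coordinates); optionally `n_split` transcripts straddle a true
#' scaffold adjacency.  Each expressed transcript emits ditags whose 3'
#' read carries the 8 bp `AACTGCTG` signature after the 27 bp tag, with a
#' per-base substitution error; 5' reads are generated signature-free.
#' Strand-specific RNA-Seq coverage is uniform over each transcript span,
#' and a deliberately truncated "old" annotation is emitted for
#' extension-statistics tests.
#'
#' @param truth `pet_sim_truth` from [simulate_genome()].
#' @param n_genes number of transcripts.
#' @param ditags_per_gene expected ditags per transcript; drawn Poisson
#'   unless `fixed_ditags = TRUE`.
#' @param fixed_ditags use exactly `ditags_per_gene` ditags per gene.
#' @param error_rate per-base substitution error on ditag reads.
#' @param seed integer seed.
#' @param gene_meanlog,gene_sdlog log-normal transcript length (default
#'   median ~15 kb).
#' @param min_gene_len minimum transcript length (default 3,000 bp).
#' @param rnaseq_rpkb RNA-Seq support density in reads per kb (default 50).
#' @param rnaseq_read_len RNA-Seq read length (default 50).
#' @param truncate_frac fraction of genes truncated in the old annotation.
#' @param truncate_factor old/new length factor for truncated genes
#'   (default 0.6, i.e. extension ratio ~1.67).
#' @param zero_expression_frac fraction of genes with expression 0.
#' @param n_split transcripts planted across a scaffold adjacency.
#' @param signature 3' signature sequence.
#' @param tag_len,read_len ditag tag and read lengths (27 and 36).
#' @return list with `genes` (truth), `ditag_reads`, `ditag_pairs` (mapped
#'   tag table, tag1 = read1), `rnaseq` (per-scaffold coverage, attribute
#'   `read_len`), `old_annotation`.
#' @export
simulate_transcriptome_and_ditags <- function(truth, n_genes = 100L,
                                              ditags_per_gene = 10,
                                              fixed_ditags = FALSE,
                                              error_rate = 0, seed = 1L,
                                              gene_meanlog = log(15000),
                                              gene_sdlog = 0.5,
                                              min_gene_len = 3000L,
                                              rnaseq_rpkb = 50,
                                              rnaseq_read_len = 50L,
                                              truncate_frac = 0.4,
                                              truncate_factor = 0.6,
                                              zero_expression_frac = 0,
                                              n_split = 0L,
                                              signature = "AACTGCTG",
                                              tag_len = 27L, read_len = 36L) {
  set.seed(seed)
  co <- truth$contigs
  co$len <- co$s_end - co$s_start
  genes <- list()
  placed <- list()  # per scaffold: occupied intervals
  gid <- 0L
  tries <- 0L
  while (gid < n_genes - n_split && tries < n_genes * 60L) {
    tries <- tries + 1L
    glen <- max(min_gene_len, round(rlnorm(1, gene_meanlog, gene_sdlog)))
    ok <- which(co$len >= glen + 200L)
    if (!length(ok)) next
    ci <- ok[sample.int(length(ok), 1L, prob = co$len[ok])]
    st <- co$s_start[ci] + 100L +
      floor(runif(1) * (co$len[ci] - glen - 200L))
    en <- st + glen
    sc <- co$scaffold[ci]
    occ <- placed[[sc]]
    if (!is.null(occ) && any(st < occ$end & en > occ$start)) next
    placed[[sc]] <- rbind(occ, data.frame(start = st, end = en))
    gid <- gid + 1L
    genes[[gid]] <- data.frame(gene_id = sprintf("G%04d", gid), ref = sc,
                               strand = sample(c("+", "-"), 1L),
                               start = st, end = en, split = FALSE,
                               ref3 = sc, stringsAsFactors = FALSE)
  }
  # planted split transcripts across a true '+/+' adjacency
  if (n_split > 0) {
    adj <- truth$adjacency
    cand <- which(!is.na(adj$gap_after))
    cand <- cand[adj$orientation[cand] == "+" & adj$orientation[cand + 1L] == "+"]
    cand <- cand[adj$scaffold[cand] != adj$scaffold[cand + 1L]]
    for (k in seq_len(min(n_split, length(cand)))) {
      i <- cand[k]
      a <- adj$scaffold[i]; b <- adj$scaffold[i + 1L]
      La <- max(co$s_end[co$scaffold == a])
      gid <- gid + 1L
      genes[[gid]] <- data.frame(gene_id = sprintf("G%04d", gid), ref = a,
                                 strand = "+", start = max(0L, La - 5000L),
                                 end = 5000L, split = TRUE, ref3 = b,
                                 stringsAsFactors = FALSE)
    }
  }
  genes <- do.call(rbind, genes)
  genes$expression <- ifelse(runif(nrow(genes)) < zero_expression_frac, 0,
                             ditags_per_gene)
  genes$n_ditags <- if (fixed_ditags) ifelse(genes$expression > 0,
                                             as.integer(ditags_per_gene), 0L)
  else rpois(nrow(genes), genes$expression)
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  genes$tts <- ifelse(genes$strand == "+", genes$end - 1L, genes$start)

  # ditag reads and mapped tag coordinates
  bases <- c("A", "C", "G", "T")
  sig_len <- nchar(signature)
  make_read5 <- function() {
    repeat {
      r <- random_dna(read_len)
      if (!find_signature(r, signature, 2L)$found) return(r)
    }
  }
  add_errors <- function(reads, rate) {
    if (rate <= 0) return(reads)
    vapply(reads, function(r) {
      n <- nchar(r)
      hit <- which(runif(n) < rate)
      if (!length(hit)) return(r)
      ch <- strsplit(r, "")[[1]]
      ch[hit] <- sample(bases, length(hit), replace = TRUE)
      paste(ch, collapse = "")
    }, "", USE.NAMES = FALSE)
  }
  rows <- list(); reads <- list()
  pid <- 0L
  for (i in seq_len(nrow(genes))) {
    nd <- genes$n_ditags[i]
    if (nd == 0) next
    g <- genes[i, ]
    for (d in seq_len(nd)) {
      pid <- pid + 1L
      if (g$strand == "+") {
        p5 <- c(g$start, g$start + tag_len)
        p3 <- c(g$end - tag_len, g$end)
        s5 <- "+"; s3 <- "-"
      } else {
        p5 <- c(g$end - tag_len, g$end)
        p3 <- c(g$start, g$start + tag_len)
        s5 <- "-"; s3 <- "+"
      }
      rows[[pid]] <- data.frame(
        pair_id = sprintf("dt%06d", pid), lib = "rnapet",
        ref1 = g$ref, start1 = p5[1], end1 = p5[2], strand1 = s5,
        ref2 = g$ref3, start2 = p3[1], end2 = p3[2], strand2 = s3,
        gene_id = g$gene_id, stringsAsFactors = FALSE)
      r3 <- paste0(random_dna(tag_len), signature,
                   random_dna(read_len - tag_len - sig_len))
      reads[[pid]] <- data.frame(pair_id = sprintf("dt%06d", pid),
                                 read1 = make_read5(), read2 = r3,
                                 stringsAsFactors = FALSE)
    }
  }
  ditag_pairs <- if (length(rows)) do.call(rbind, rows) else NULL
  ditag_reads <- if (length(reads)) do.call(rbind, reads) else NULL
  if (!is.null(ditag_reads)) {
    ditag_reads$read1 <- add_errors(ditag_reads$read1, error_rate)
    ditag_reads$read2 <- add_errors(ditag_reads$read2, error_rate)
  }

  # strand-specific RNA-Seq: uniform coverage over expressed spans
  sc_names <- unique(co$scaffold)
  sc_len <- vapply(sc_names, function(s) max(co$s_end[co$scaffold == s]), 0)
  rnaseq <- lapply(sc_len, function(L) numeric(L))
  names(rnaseq) <- sc_names
  depth <- rnaseq_rpkb * rnaseq_read_len / 1000
  for (i in seq_len(nrow(genes))) {
    if (genes$expression[i] == 0 || genes$split[i]) next
    sc <- genes$ref[i]
    idx <- (genes$start[i] + 1L):genes$end[i]
    rnaseq[[sc]][idx] <- rnaseq[[sc]][idx] + depth
  }
  attr(rnaseq, "read_len") <- rnaseq_read_len

  # truncated old annotation
  old <- genes[!genes$split, c("gene_id", "ref", "strand", "start", "end")]
  old$gene_id <- sub("^G", "E", old$gene_id)
  trunc <- runif(nrow(old)) < truncate_frac
  mid <- (old$start + old$end) %/% 2L
  half <- floor((old$end - old$start) * truncate_factor / 2)
  old$start[trunc] <- mid[trunc] - half[trunc]
  old$end[trunc] <- mid[trunc] + half[trunc]
  old$truncated <- trunc
  genes$truncated_in_old <- c(trunc, rep(NA, sum(genes$split)))[seq_len(nrow(genes))]

  list(genes = genes, ditag_reads = ditag_reads, ditag_pairs = ditag_pairs,
       rnaseq = rnaseq, old_annotation = old)
}
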