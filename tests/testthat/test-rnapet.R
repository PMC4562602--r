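# rnapet_annot: signature search, ditag classes, clustering, promotion,
# filtering, coalescing, comparison, split genes

SIG <- "AACTGCTG"

# independent brute-force oracle: min Hamming distance of the signature
# over all windows of the read
hamming_oracle <- function(read, sig = SIG) {
  k <- nchar(sig); L <- nchar(read)
  if (L < k) return(NA_integer_)
  min(vapply(0:(L - k), function(off) {
    sum(strsplit(substr(read, off + 1, off + k), "")[[1]] !=
          strsplit(sig, "")[[1]])
  }, 0L))
}

test_that("find_signature matches the Hamming oracle on crafted reads", {
  set.seed(4)
  pad <- function(core) paste0(rand_seq(10), core, rand_seq(36 - 10 - nchar(core)))
  r0 <- pad(SIG)                          # exact
  r2 <- pad("AACTGgTc")                   # 2 mismatches
  r3 <- pad("AtCTGgTc")                   # 3 mismatches
  got <- find_signature(c(r0, r2, r3))
  want_mm <- vapply(c(r0, r2, r3), hamming_oracle, 0L, USE.NAMES = FALSE)
  expect_equal(got$mismatches, want_mm)
  expect_equal(got$found, want_mm <= 2)
  # read shorter than the signature: absent
  short <- find_signature("ACGT")
  expect_false(short$found)
  expect_true(is.na(short$mismatches))
})

test_that("find_signature agrees with exhaustive Hamming enumeration on
           random reads with planted variants", {
  set.seed(12)
  n <- 2000
  reads <- vapply(seq_len(n), function(i) {
    r <- rand_seq(36)
    d <- sample(0:4, 1)
    sig <- strsplit(SIG, "")[[1]]
    if (d > 0) {
      pos <- sample(8, d)
      for (p in pos) sig[p] <- sample(setdiff(c("A", "C", "G", "T"), sig[p]), 1)
    }
    off <- sample(0:(36 - 8), 1)
    paste0(substr(r, 1, off), paste(sig, collapse = ""),
           substr(r, off + 9, 36))
  }, "")
  got <- find_signature(reads)
  want <- vapply(reads, hamming_oracle, 0L, USE.NAMES = FALSE)
  expect_equal(got$mismatches, want)
  expect_equal(got$found, want <= 2L)
})

test_that("ditag classes partition the set and follow the signature rule", {
  set.seed(31)
  clean <- function() {
    repeat { r <- rand_seq(36); if (hamming_oracle(r) > 2) return(r) }
  }
  with_sig <- function() paste0(rand_seq(5), SIG, rand_seq(23))
  r1 <- c(with_sig(), with_sig(), clean(), clean())
  r2 <- c(clean(), with_sig(), with_sig(), clean())
  cls <- classify_ditags(r1, r2)
  expect_equal(as.character(cls$class), c("HT", "TT", "HT", "HH"))
  expect_equal(cls$signature_end, c("1", "both", "2", "none"))
  expect_equal(sum(table(cls$class)), 4L)
})

test_that("HT recall under sequencing error matches the binomial
           expectation", {
  sim <- simulate_genome(seed = 41, chrom_len = 1e6, n_fragments = 4,
                         gap_rate = 0, emit_sequence = FALSE)
  err <- 0.02
  tx <- simulate_transcriptome_and_ditags(sim$truth, n_genes = 60,
                                          ditags_per_gene = 18,
                                          fixed_ditags = TRUE,
                                          error_rate = err, seed = 42)
  cls <- classify_ditags(tx$ditag_reads$read1, tx$ditag_reads$read2)
  n <- nrow(cls)
  # a ditag stays HT iff <= 2 errors hit the 8 signature bases (errors may
  # also create a spurious signature elsewhere; that effect is tiny)
  p_keep <- pbinom(2, 8, err * 3 / 4 + err / 4 * 0)  # substitution may keep base
  # substitutions draw uniformly from 4 bases: P(base changes) = 3/4 * err
  p_eff <- err * 3 / 4
  p_keep <- pbinom(2, 8, p_eff)
  recall <- mean(cls$class == "HT")
  expect_lt(abs(recall - p_keep), 3 * sqrt(p_keep * (1 - p_keep) / n) + 0.01)
})

test_that("orient_pairs keeps HT only and assigns 5'/3' roles", {
  pairs <- rbind(make_pair("s1", 100, "+", "s1", 5000, "-", id = "ht1"),
                 make_pair("s1", 9000, "-", "s1", 4000, "+", id = "ht2"),
                 make_pair("s1", 200, "+", "s1", 6000, "-", id = "hh"))
  cls <- data.frame(class = factor(c("HT", "HT", "HH"),
                                   levels = c("HT", "TT", "HH")),
                    signature_end = c("2", "1", "none"),
                    mm1 = c(5L, 1L, 6L), mm2 = c(0L, 7L, 7L),
                    stringsAsFactors = FALSE)
  o <- orient_pairs(pairs, cls)
  expect_equal(nrow(o), 2L)
  # signature on read2: read1 is the 5' tag
  expect_equal(o$p5_start[o$pair_id == "ht1"], 100)
  expect_equal(o$strand[o$pair_id == "ht1"], "+")
  # signature on read1: read2 is the 5' tag
  expect_equal(o$p5_start[o$pair_id == "ht2"], 4000)
  expect_equal(o$strand[o$pair_id == "ht2"], "+")
})

oriented_pet <- function(ref, p5, p3, strand = "+", id = "d1") {
  data.frame(pair_id = id, ref5 = ref, ref3 = ref, strand = strand,
             p5_start = p5, p5_end = p5 + 27, p3_start = p3 - 27,
             p3_end = p3, stringsAsFactors = FALSE)
}

test_that("greedy 5'-overlap clustering follows the slack rule", {
  # single PET: one cluster spanning the fragment
  one <- oriented_pet("s1", 1000, 9000)
  c1 <- cluster_pets(one)
  expect_equal(nrow(c1), 1L)
  expect_equal(c(c1$start, c1$end, c1$pet_count), c(1000, 9000, 1))
  # overlapping 5' tags merge; union span
  two <- rbind(oriented_pet("s1", 1000, 9000, id = "a"),
               oriented_pet("s1", 1010, 9500, id = "b"))
  c2 <- cluster_pets(two)
  expect_equal(nrow(c2), 1L)
  expect_equal(c(c2$start, c2$end), c(1000, 9500))
  # 5' tags 10Kb apart: two clusters under stringent slack 0
  far <- rbind(oriented_pet("s1", 1000, 9000, id = "a"),
               oriented_pet("s1", 11000, 19000, id = "b"))
  expect_equal(nrow(cluster_pets(far, slack = 0)), 2L)
  # merge under relaxed only when slack covers the gap
  gap <- 11000 - (1000 + 27)
  expect_equal(nrow(cluster_pets(far, slack = gap - 1)), 2L)
  expect_equal(nrow(cluster_pets(far, slack = gap + 1)), 1L)
  # strands cluster separately
  mixed <- rbind(oriented_pet("s1", 1000, 9000, id = "a"),
                 oriented_pet("s1", 1000, 9000, strand = "-", id = "b"))
  expect_equal(nrow(cluster_pets(mixed)), 2L)
})

test_that("clustering is invariant to input order", {
  set.seed(55)
  pets <- do.call(rbind, lapply(1:60, function(i)
    oriented_pet("s1", sample.int(50000, 1), sample(60000:90000, 1),
                 strand = sample(c("+", "-"), 1), id = paste0("d", i))))
  a <- cluster_pets(pets, slack = 100)
  b <- cluster_pets(pets[sample.int(nrow(pets)), ], slack = 100)
  expect_equal(a, b)
})

flat_cov <- function(len, intervals, depth = 10) {
  v <- numeric(len)
  for (iv in intervals) v[(iv[1] + 1):iv[2]] <- depth
  structure(list(s1 = v), read_len = 50)
}

test_that("promotion keeps the relaxed model only without an unsupported
           gulf", {
  stringent <- rbind(
    data.frame(cluster_id = "s_1", ref = "s1", strand = "+", start = 1000L,
               end = 6000L, span = 5000L, pet_count = 10L, tss = 1000L,
               tts = 5999L, parameter_set = "stringent"),
    data.frame(cluster_id = "s_2", ref = "s1", strand = "+", start = 11000L,
               end = 16000L, span = 5000L, pet_count = 8L, tss = 11000L,
               tts = 15999L, parameter_set = "stringent"))
  relaxed <- data.frame(cluster_id = "r_1", ref = "s1", strand = "+",
                        start = 1000L, end = 16000L, span = 15000L,
                        pet_count = 18L, tss = 1000L, tts = 15999L,
                        parameter_set = "relaxed")
  # 5Kb zero-coverage gulf between the stringent pair: keep stringent
  cov_gulf <- flat_cov(20000, list(c(1000, 6000), c(11000, 16000)))
  got <- promote(stringent, relaxed, cov_gulf)
  expect_equal(sort(got$cluster_id), c("s_1", "s_2"))
  # continuous coverage: relaxed wins
  cov_full <- flat_cov(20000, list(c(1000, 16000)))
  got2 <- promote(stringent, relaxed, cov_full)
  expect_equal(got2$cluster_id, "r_1")
  # identical models: that model
  got3 <- promote(stringent[1, ], {
    r <- stringent[1, ]; r$parameter_set <- "relaxed"; r
  }, cov_full)
  expect_equal(nrow(got3), 1L)
  expect_equal(c(got3$start, got3$end), c(1000L, 6000L))
})

test_that("cluster filters are enforced literally", {
  mk <- function(id, start, span) data.frame(
    cluster_id = id, ref = "s1", strand = "+", start = start,
    end = start + span, span = span, pet_count = 5L, tss = start,
    tts = start + span - 1L, parameter_set = "stringent",
    stringsAsFactors = FALSE)
  clusters <- rbind(mk("small", 100L, 1500L),      # span < 2,000: dropped
                    mk("weak", 30000L, 10000L),    # low RNA-Seq: dropped
                    mk("good", 5000L, 10000L))
  cov <- structure(list(s1 = numeric(60000)), read_len = 50)
  cov$s1[5001:15000] <- 10                          # 200 reads/Kb for "good"
  cov$s1[30001:40000] <- 0.15                       # 3 reads/Kb for "weak"
  cov$s1[101:1600] <- 10
  got <- filter_clusters(clusters, cov)
  expect_equal(got$cluster_id, "good")
  # every survivor satisfies both filters, re-checked directly
  expect_true(all(got$span >= 2000))
  dens <- vapply(seq_len(nrow(got)), function(i)
    rnaseq_density(cov, got$ref[i], got$start[i], got$end[i]), 0)
  expect_true(all(dens >= 5))
})

test_that("coalescing equals connected components of the overlap graph", {
  mk <- function(id, start, end, strand = "+") data.frame(
    cluster_id = id, ref = "s1", strand = strand, start = start, end = end,
    span = end - start, pet_count = 5L, tss = start, tts = end - 1L,
    parameter_set = "stringent", stringsAsFactors = FALSE)
  # overlapping same-strand: one gene; opposite strands: two genes
  expect_equal(nrow(coalesce_clusters(rbind(mk("a", 100, 5000),
                                            mk("b", 4000, 9000)))), 1L)
  expect_equal(nrow(coalesce_clusters(rbind(mk("a", 100, 5000),
                                            mk("b", 4000, 9000, "-")))), 2L)
  # random interval set vs an independent union-find components oracle
  set.seed(66)
  n <- 80
  st <- sample.int(200000, n)
  cl <- do.call(rbind, lapply(seq_len(n), function(i)
    mk(paste0("c", i), st[i], st[i] + sample(500:8000, 1))))
  genes <- coalesce_clusters(cl)
  comp_oracle <- local({
    parent <- seq_len(n)
    findp <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (cl$start[i] < cl$end[j] && cl$start[j] < cl$end[i])
        parent[findp(i)] <- findp(j)
    }
    length(unique(vapply(seq_len(n), findp, 0L)))
  })
  expect_equal(nrow(genes), comp_oracle)
  # genes cover their member clusters
  expect_true(all(vapply(seq_len(nrow(genes)), function(i)
    genes$n_clusters[i] >= 1 && length(genes$tss_set[[i]]) >= 1, TRUE)))
})

test_that("TSS deduplication respects the merge radius", {
  mk <- function(id, start) data.frame(
    cluster_id = id, ref = "s1", strand = "+", start = start,
    end = start + 5000L, span = 5000L, pet_count = 2L, tss = start,
    tts = start + 4999L, parameter_set = "stringent", stringsAsFactors = FALSE)
  g <- coalesce_clusters(rbind(mk("a", 1000L), mk("b", 1005L), mk("c", 1030L)),
                         merge_radius = 10L)
  expect_equal(g$tss_set[[1]], c(1000L, 1030L))
})

test_that("annotation comparison applies both extension rules", {
  mk <- function(id, start, end) data.frame(gene_id = id, ref = "s1",
                                            strand = "+", start = start,
                                            end = end, stringsAsFactors = FALSE)
  new <- rbind(mk("n1", 0, 10000),        # same as old: not extended
               mk("n2", 50000, 64000),    # ratio 1.4: extended
               mk("n3", 100000, 206000),  # +6Kb at ratio 1.06: extended
               mk("n4", 500000, 505000))  # novel
  old <- rbind(mk("o1", 0, 10000),
               mk("o2", 50000, 60000),
               mk("o3", 100000, 200000),
               mk("o5", 700000, 705000))  # silent
  cmp <- compare_annotation(new, old)
  p <- cmp$pairs[order(cmp$pairs$gene_id), ]
  expect_equal(p$extended, c(FALSE, TRUE, TRUE))
  expect_equal(cmp$n_matched, 3L)
  expect_equal(cmp$n_novel, 1L)
  expect_equal(cmp$n_silent, 1L)
})

test_that("split genes are detected and rescued through chains", {
  o <- data.frame(pair_id = c("d1", "d2", "d3"),
                  ref5 = c("A", "A", "B"), ref3 = c("B", "B", "B"),
                  strand = "+",
                  p5_start = c(45000, 45010, 100), p5_end = c(45027, 45037, 127),
                  p3_start = c(4000, 4010, 8000), p3_end = c(4027, 4037, 8027),
                  stringsAsFactors = FALSE)
  fragments <- data.frame(fragment_id = c("A.p1", "B.p1", "C.p1"),
                          parent = c("A", "B", "C"), p_start = 0L,
                          p_end = 50000L, length = 50000L,
                          stringsAsFactors = FALSE)
  chains <- data.frame(chain_id = c(1L, 1L, 2L), position = c(1L, 2L, 1L),
                       fragment_id = c("A.p1", "B.p1", "C.p1"),
                       orientation = "+", gap_before = c(NA, 500, NA),
                       stringsAsFactors = FALSE)
  sp <- detect_split_genes(o, chains, fragments)
  expect_equal(nrow(sp), 1L)               # d3 is not cross-reference
  expect_equal(sp$pet_count, 2L)
  expect_true(sp$same_chain)
  # across unconnected scaffolds: split but not rescued
  o2 <- o; o2$ref3[1:2] <- "C"
  sp2 <- detect_split_genes(o2, chains, fragments)
  expect_equal(nrow(sp2), 1L)
  expect_false(sp2$same_chain)
})
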