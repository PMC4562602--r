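# rescaffold: splitting, masking, edge building, chaining, statistics

test_that("split_at_gaps honours the size threshold and spanning PETs", {
  mk <- function(gap_len) pet_assembly(
    data.frame(name = "s1", length = 40000L + gap_len),
    data.frame(scaffold = "s1", start = 20000L, end = 20000L + gap_len,
               annotated_len = gap_len))
  none <- concordant_pair("s1", 0, 1)[0, ]
  # 12,000-N gap, no spanning PET: 2 fragments
  expect_equal(nrow(split_at_gaps(mk(12000L), none)), 2L)
  # 5,000-N gap: below threshold
  expect_equal(nrow(split_at_gaps(mk(5000L), none)), 1L)
  # 10,500-N gap spanned by one cPET: no split
  spanning <- concordant_pair("s1", 14000, 20000)   # covers [14000, 34000)
  expect_equal(nrow(split_at_gaps(mk(10500L), spanning)), 1L)
  # the N-run itself is dropped from the fragments
  fr <- split_at_gaps(mk(12000L), none)
  expect_equal(fr$p_end[1], 20000L)
  expect_equal(fr$p_start[2], 32000L)
  expect_equal(sum(fr$length), 40000L)
})

test_that("split_at_breakpoints splits interior fragments once", {
  a <- pet_assembly(data.frame(name = "s1", length = 50000L))
  fr <- split_at_gaps(a, concordant_pair("s1", 0, 1)[0, ])
  bp <- data.frame(scaffold = "s1", start = 24000L, end = 26000L)
  fr2 <- split_at_breakpoints(fr, bp)
  expect_equal(nrow(fr2), 2L)
  expect_equal(fr2$p_end[1], 25000L)           # midpoint split
  expect_equal(sum(fr2$length), 50000L)        # conservation
  # a breakpoint inside an already-removed gap region is ignored
  a2 <- pet_assembly(data.frame(name = "s2", length = 52000L),
                     data.frame(scaffold = "s2", start = 20000L,
                                end = 32000L, annotated_len = 12000L))
  fr3 <- split_at_gaps(a2, concordant_pair("s2", 0, 1)[0, ])
  expect_warning(fr4 <- split_at_breakpoints(
    fr3, data.frame(scaffold = "s2", start = 25000L, end = 26000L)),
    "outside")
  expect_equal(nrow(fr4), nrow(fr3))
})

test_that("repeat masking uses a strict > threshold per 1Kb window", {
  a <- pet_assembly(data.frame(name = "s1", length = 10000L))
  # 600 tag pairs in window [0,1000): 1200 tag positions there
  dense <- do.call(rbind, lapply(1:600, function(i)
    make_pair("s1", i %% 900, "+", "s1", 5000 + i, "+", id = paste0("d", i))))
  m <- mask_repeats(dense, a)
  expect_true(any(m$start == 0))
  # exactly 500 tags in a window: not masked
  exact <- do.call(rbind, lapply(1:500, function(i)
    make_pair("s1", 2000 + (i %% 900), "+", "s1", 9000 + (i %% 800), "+",
              id = paste0("e", i))))
  m2 <- mask_repeats(exact, a)
  expect_false(any(m2$start == 2000))
  # uniform low coverage: nothing masked
  sparse <- do.call(rbind, lapply(1:50, function(i)
    make_pair("s1", i * 90, "+", "s1", 5000 + i * 7, "+", id = paste0("s", i))))
  expect_equal(nrow(mask_repeats(sparse, a)), 0L)
  # PETs with a tag in a masked window are excluded
  kept <- filter_masked_pairs(rbind(dense, sparse), m)
  expect_true(all(kept$pair_id %in% sparse$pair_id))
})

test_that("build_edges groups dPETs, applies the weight filter and
           estimates link length", {
  fragments <- data.frame(fragment_id = c("A.p1", "B.p1"),
                          parent = c("A", "B"), p_start = c(0L, 0L),
                          p_end = c(30000L, 30000L),
                          length = c(30000L, 30000L), stringsAsFactors = FALSE)
  l <- lib10()
  # A tail joined to B head, true inter-fragment gap 2,000:
  # tag1 near A's end on '+', tag2 in B's start region on '+'
  mk_link <- function(i, d_a, d_b) make_pair(
    "A", 30000 - d_a, "+", "B", d_b - 27, "+", id = paste0("lk", i))
  set.seed(2)
  n <- 30
  d_a <- sample(500:4000, n); d_b <- pmax(9600 - 2000 - d_a +
                                            round(rnorm(n, 0, 300)), 100)
  pairs <- do.call(rbind, lapply(seq_len(n), function(i)
    mk_link(i, d_a[i], d_b[i])))
  e <- build_edges(pairs, fragments, l)
  expect_equal(nrow(e), 1L)
  expect_equal(e$weight, n)
  expect_equal(c(e$end_a, e$end_b), c("tail", "head"))
  # arithmetic oracle for the link estimate
  expect_equal(e$est_link_len, mean(l$insert_mean - d_a - d_b),
               tolerance = 1e-9)
  expect_lt(abs(e$est_link_len - 2000), 3 * 300 / sqrt(n))
  # 3 supporting dPETs: edge discarded; 5: kept
  expect_equal(nrow(build_edges(pairs[1:3, ], fragments, l)), 0L)
  expect_equal(nrow(build_edges(pairs[1:5, ], fragments, l)), 1L)
  # tags beyond span_max of the attachment end do not contribute
  far <- make_pair("A", 5000, "+", "B", 2000, "+", id = "far")
  expect_equal(build_edges(rbind(pairs, far), fragments, l)$weight, n)
})

test_that("simple chaining cases score as expected", {
  g <- rand_chain_graph(3, 1)
  g$edges$node_a <- "A"; g$edges$node_b <- "B"
  g$edges$end_a <- "tail"; g$edges$end_b <- "head"; g$edges$weight <- 10L
  ch <- chain_scaffolds(g$edges, g$fragments[1:2, ])
  expect_equal(attr(ch, "score"), 10)
  expect_equal(nrow(ch), 2L)
  expect_equal(length(unique(ch$chain_id)), 1L)
  # A-B weight 10 and A-B' weight 5 on the same end of A: B chosen, 10-5
  e2 <- data.frame(node_a = c("A", "A"), end_a = c("tail", "tail"),
                   node_b = c("B", "C"), end_b = c("head", "head"),
                   lib = "L", weight = c(10L, 5L),
                   est_link_len = c(100, 100), kind = "dpet",
                   stringsAsFactors = FALSE)
  fr3 <- rand_chain_graph(3, 1)$fragments
  ch2 <- chain_scaffolds(e2, fr3)
  expect_equal(attr(ch2, "score"), 5)
  expect_equal(exhaustive_chain_score(e2), 5)
  used <- attr(ch2, "edges_used")
  expect_equal(used$node_b, "B")
})

test_that("greedy+swap chaining matches the exhaustive optimum on random
           small graphs and never exceeds it", {
  set.seed(99)
  n_match <- 0L
  n_runs <- 100L
  for (r in seq_len(n_runs)) {
    g <- rand_chain_graph(sample(4:8, 1), sample(4:9, 1))
    ch <- chain_scaffolds(g$edges, g$fragments)
    got <- attr(ch, "score")
    best <- exhaustive_chain_score(g$edges)
    expect_lte(got, best)
    if (got == best) n_match <- n_match + 1L
    # partition property: every fragment in exactly one chain
    expect_setequal(ch$fragment_id, g$fragments$fragment_id)
    expect_equal(anyDuplicated(ch$fragment_id), 0L)
  }
  expect_gte(n_match, 95L)
})

test_that("provenance edges only join ends unclaimed by dPET edges", {
  fragments <- data.frame(fragment_id = c("P.p1", "P.p2", "Q.p1"),
                          parent = c("P", "P", "Q"),
                          p_start = c(0L, 20000L, 0L),
                          p_end = c(10000L, 30000L, 10000L),
                          length = c(10000L, 10000L, 10000L),
                          stringsAsFactors = FALSE)
  pv <- provenance_edges(fragments)
  expect_equal(nrow(pv), 1L)
  expect_equal(pv$weight, 1L)
  # alone, the provenance edge restores the original order
  ch <- chain_scaffolds(pv, fragments)
  expect_equal(sum(table(ch$chain_id) == 2), 1L)
  # a dPET edge claiming P.p1 tail suppresses the provenance join
  dp <- data.frame(node_a = "P.p1", end_a = "tail", node_b = "Q.p1",
                   end_b = "head", lib = "L", weight = 10L,
                   est_link_len = 500, kind = "dpet", stringsAsFactors = FALSE)
  ch2 <- chain_scaffolds(rbind(dp, pv), fragments)
  used <- attr(ch2, "edges_used")
  expect_false("provenance" %in% used$kind)
})

test_that("fill_gaps spots interleaved fragments", {
  fragments <- data.frame(fragment_id = c("P.p1", "P.p2", "Q.p1"),
                          parent = c("P", "P", "Q"),
                          p_start = c(0L, 25000L, 0L),
                          p_end = c(12000L, 40000L, 9000L),
                          length = c(12000L, 15000L, 9000L),
                          stringsAsFactors = FALSE)
  chains <- data.frame(chain_id = 1L, position = 1:3,
                       fragment_id = c("P.p1", "Q.p1", "P.p2"),
                       orientation = "+", gap_before = c(NA, 100, 200),
                       stringsAsFactors = FALSE)
  fi <- fill_gaps(chains, fragments)
  expect_equal(attr(fi, "n_fillins"), 1L)
  expect_equal(fi$fillers, "Q.p1")
  # no interleaving: nothing reported
  chains2 <- chains; chains2$fragment_id <- c("P.p1", "P.p2", "Q.p1")
  expect_equal(attr(fill_gaps(chains2, fragments), "n_fillins"), 0L)
})

test_that("assembly statistics match their definitions", {
  expect_equal(n50(c(1, 2, 3, 4, 10)), 10)
  expect_equal(n50(c(10, 10, 10)), 10)
  st <- assembly_stats(rep(100, 5), 520)
  expect_equal(st$scaffold_reduction, 0.8)
  st0 <- assembly_stats(c(5, 10), c(5, 10))
  expect_equal(st0$scaffold_reduction, 0)
  expect_equal(st0$n50_ratio, 1)
})

test_that("non-N sequence length is conserved through split + chain", {
  sim <- simulate_genome(seed = 61, chrom_len = 1.5e6, n_fragments = 12,
                         emit_sequence = FALSE)
  l <- lib10()
  p <- simulate_dnapet(sim$truth, l, coverage = 15, seed = 62)
  res <- run_rescaffold_pipeline(sim$assembly,
                                 list(IXT010 = list(pairs = p, profile = l)))
  gap_bp <- sum(sim$assembly$gaps$annotated_len)
  non_n_before <- sum(sim$assembly$scaffolds$length) - gap_bp
  # fragments partition the non-gap sequence, except gaps >= 10Kb dropped
  dropped <- sum(sim$assembly$gaps$annotated_len[
    sim$assembly$gaps$annotated_len >= 10000])
  kept_gap_bp <- gap_bp - dropped
  expect_equal(sum(res$fragments$length), non_n_before + kept_gap_bp)
  expect_equal(anyDuplicated(res$chains$fragment_id), 0L)
  expect_setequal(res$chains$fragment_id, res$fragments$fragment_id)
})

test_that("reverse-complementing the world mirrors the chains", {
  sim <- simulate_genome(seed = 71, chrom_len = 8e5, n_fragments = 6,
                         gap_rate = 0, emit_sequence = FALSE,
                         random_orientation = FALSE)
  l <- lib10()
  p <- simulate_dnapet(sim$truth, l, coverage = 20, seed = 72)
  fr <- split_at_gaps(sim$assembly, p[classify_pairs(p, l) == "cPET", ])
  e <- build_edges(dedup_pairs(p), fr, l)
  ch <- chain_scaffolds(e, fr)
  # mirror: flip every tag (coordinate and strand) within its scaffold
  lens <- stats::setNames(sim$assembly$scaffolds$length,
                          sim$assembly$scaffolds$name)
  flip <- function(d) {
    s1 <- lens[d$ref1] - d$end1; s2 <- lens[d$ref2] - d$end2
    data.frame(pair_id = d$pair_id, lib = d$lib,
               ref1 = d$ref1, start1 = s1, end1 = s1 + (d$end1 - d$start1),
               strand1 = ifelse(d$strand1 == "+", "-", "+"),
               ref2 = d$ref2, start2 = s2, end2 = s2 + (d$end2 - d$start2),
               strand2 = ifelse(d$strand2 == "+", "-", "+"),
               stringsAsFactors = FALSE)
  }
  e2 <- build_edges(dedup_pairs(flip(p)), fr, l)
  ch2 <- chain_scaffolds(e2, fr)
  expect_equal(attr(ch2, "score"), attr(ch, "score"))
  # same membership, orientations flipped relative to each other
  m1 <- ch[order(ch$fragment_id), ]
  m2 <- ch2[order(ch2$fragment_id), ]
  expect_equal(m1$fragment_id, m2$fragment_id)
  expect_true(all(m1$orientation != m2$orientation) ||
                all(m1$orientation == m2$orientation))
})
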