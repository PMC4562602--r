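# DNA-PET quality control: cPET/dPET classification, insert-size
# estimation, concordant-coverage tracks, assembly-gap length
# re-estimation (with bimodality detection) and breakpoint calling.

#' Library profile for a mate-pair library
#'
#' @param library_id identifier (e.g. `"IXT010"`).
#' @param insert_mean expected insert size in bp.
#' @param span_min,span_max concordant genome-span range in bp.
#' @return object of class `library_profile`.
#' @export
library_profile <- function(library_id, insert_mean, span_min, span_max) {
  if (!(0 < span_min && span_min < insert_mean && insert_mean < span_max))
    pf_stop("need 0 < span_min < insert_mean < span_max")
  structure(list(library_id = library_id, insert_mean = insert_mean,
                 span_min = span_min, span_max = span_max),
            class = "library_profile")
}

# genome span of a pair: 5'-most tag start to 3'-most tag end
pair_span <- function(pairs) {
  pmax(pairs$end1, pairs$end2) - pmin(pairs$start1, pairs$start2)
}

# fragment interval covered by a pair on its (single) reference
pair_fragment <- function(pairs) {
  data.frame(ref = pairs$ref1,
             start = pmin(pairs$start1, pairs$start2),
             end = pmax(pairs$end1, pairs$end2))
}

# mate-pair geometry: both tags on the same strand, tag1 (the fragment's
# 5' tag) upstream on '+' and downstream on '-'
concordant_orientation <- function(pairs) {
  same <- pairs$strand1 == pairs$strand2
  ord <- ifelse(pairs$strand1 == "+",
                pairs$start1 <= pairs$start2,
                pairs$start2 <= pairs$start1)
  same & ord
}

#' Classify mate pairs as concordant or discordant
#'
#' A pair is a cPET iff both tags map to the same reference, on the same
#' strand, in the correct 5'-to-3' ordering for mate-pair geometry, and
#' its genome span lies within the library's concordant range.  All other
#' same-reference pairs are `dPET_same_ref`; cross-reference pairs are
#' `dPET_diff_ref`.  The three classes partition the input exactly.
#'
#' @param pairs tag-pair data.frame.
#' @param lib a [library_profile].
#' @return factor with levels `cPET`, `dPET_same_ref`, `dPET_diff_ref`.
#' @export
classify_pairs <- function(pairs, lib) {
  same_ref <- pairs$ref1 == pairs$ref2
  span <- pair_span(pairs)
  conc <- same_ref & concordant_orientation(pairs) &
    span >= lib$span_min & span <= lib$span_max
  factor(ifelse(conc, "cPET",
                ifelse(same_ref, "dPET_same_ref", "dPET_diff_ref")),
         levels = c("cPET", "dPET_same_ref", "dPET_diff_ref"))
}

#' Collapse duplicate pairs
#'
#' Pairs with identical tag coordinates on both ends are counted once, so
#' all downstream statistics use independent, non-redundant PETs.
#' @param pairs tag-pair data.frame.
#' @export
dedup_pairs <- function(pairs) {
  key <- paste(pairs$lib, pairs$ref1, pairs$start1, pairs$end1, pairs$strand1,
               pairs$ref2, pairs$start2, pairs$end2, pairs$strand2, sep = "\r")
  out <- pairs[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Estimate the insert size of a library from cPET spans
#'
#' @param spans numeric vector of cPET genome spans (or a cPET table, in
#'   which case spans are computed).
#' @param trim_fraction fraction trimmed from each tail before the mean/sd.
#' @return list with `mean`, `sd` (corrected for the truncation the trim
#'   induces, so it estimates the full-distribution sd under normality),
#'   `sd_trimmed` (raw sd of the kept spans), `n`.
#' @export
estimate_insert_size <- function(spans, trim_fraction = 0.05) {
  if (is.data.frame(spans)) spans <- pair_span(spans)
  if (length(spans) < 30) pf_stop("need >= 30 cPETs to estimate insert size")
  q <- quantile(spans, c(trim_fraction, 1 - trim_fraction), names = FALSE)
  kept <- spans[spans >= q[1] & spans <= q[2]]
  s_t <- sd(kept)
  corr <- if (trim_fraction > 0) {
    z <- qnorm(1 - trim_fraction)
    sqrt(1 - 2 * z * dnorm(z) / (1 - 2 * trim_fraction))
  } else 1
  list(mean = mean(kept), sd = s_t / corr, sd_trimmed = s_t,
       n = length(spans))
}

#' Subset cPETs whose fragment interval overlaps no assembly gap
#'
#' Useful for unbiased insert-size estimation: spans across mis-annotated
#' gaps mix the gap-length error into the span distribution.
#'
#' @param cpets cPET table.
#' @param assembly a [pet_assembly].
#' @export
gap_free_cpets <- function(cpets, assembly) {
  if (nrow(assembly$gaps) == 0 || nrow(cpets) == 0) return(cpets)
  frag <- pair_fragment(cpets)
  gr_f <- GenomicRanges::GRanges(frag$ref,
                                 IRanges::IRanges(frag$start + 1L, frag$end))
  gr_g <- GenomicRanges::GRanges(assembly$gaps$scaffold,
                                 IRanges::IRanges(assembly$gaps$start + 1L,
                                                  assembly$gaps$end))
  out <- cpets[!IRanges::overlapsAny(gr_f, gr_g), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Concordant-coverage track
#'
#' `window_count` mode counts cPETs whose fragment interval overlaps each
#' sliding window; `per_base_fragment` mode counts, at every base, the
#' number of cPET fragments (tag1 start to tag2 end) covering it.
#'
#' @param cpets cPET table restricted to one scaffold.
#' @param scaffold scaffold name.
#' @param scaffold_len scaffold length in bp.
#' @param window_size window width (window mode), default 20 kb.
#' @param step window step; default `window_size / 4` ("sliding").
#' @param mode `"window_count"` or `"per_base_fragment"`.
#' @return list of class `coverage_track` with `scaffold`, `window_size`,
#'   `step`, `mode`, `counts` and (window mode) `starts`.
#' @export
coverage_track <- function(cpets, scaffold, scaffold_len,
                           window_size = 20000L, step = window_size %/% 4L,
                           mode = c("window_count", "per_base_fragment")) {
  mode <- match.arg(mode)
  frag <- pair_fragment(cpets)
  frag <- frag[frag$ref == scaffold, , drop = FALSE]
  frag$start <- pmax(frag$start, 0L)
  frag$end <- pmin(frag$end, scaffold_len)
  frag <- frag[frag$end > frag$start, , drop = FALSE]
  if (mode == "per_base_fragment") {
    counts <- per_base_coverage(frag$start, frag$end, scaffold_len)
    starts <- NULL
  } else {
    if (window_size >= scaffold_len) {
      starts <- 0L
    } else {
      starts <- seq(0L, scaffold_len - window_size, by = step)
      if (tail(starts, 1L) + window_size < scaffold_len)
        starts <- c(starts, scaffold_len - window_size)
    }
    if (nrow(frag)) {
      ir_w <- IRanges::IRanges(start = starts + 1L, width = pmin(window_size, scaffold_len))
      ir_f <- IRanges::IRanges(start = frag$start + 1L, end = frag$end)
      counts <- IRanges::countOverlaps(ir_w, ir_f)
    } else counts <- integer(length(starts))
  }
  structure(list(scaffold = scaffold, window_size = window_size, step = step,
                 mode = mode, counts = as.numeric(counts), starts = starts),
            class = "coverage_track")
}

# per-base interval stabbing count via difference array
per_base_coverage <- function(starts, ends, len) {
  d <- numeric(len + 1L)
  if (length(starts)) {
    tb <- tabulate(starts + 1L, nbins = len + 1L) -
      tabulate(pmin(ends, len) + 1L, nbins = len + 1L)
    d <- tb
  }
  cumsum(d)[seq_len(len)]
}

#' Pearson correlation of two window-coverage tracks
#'
#' @param track_a,track_b [coverage_track]s over the same windows.
#' @return Pearson r, or NA if either track has zero variance.
#' @export
library_coverage_correlation <- function(track_a, track_b) {
  stopifnot(length(track_a$counts) == length(track_b$counts))
  if (sd(track_a$counts) == 0 || sd(track_b$counts) == 0) return(NA_real_)
  cor(track_a$counts, track_b$counts)
}

# 1-D Gaussian mixture by EM; returns list(mu, sigma, w, loglik, bic).
# With sigma_fixed the component sd is known (measurement noise) and only
# means/weights are estimated -- this is the right model when each point
# carries the library's insert-length noise.
fit_gmm1d <- function(x, k, max_iter = 200, tol = 1e-8, sigma_fixed = NULL) {
  n <- length(x)
  known_s <- !is.null(sigma_fixed)
  if (k == 1) {
    mu <- mean(x)
    s <- if (known_s) sigma_fixed else max(sd(x), 1e-6)
    ll <- sum(dnorm(x, mu, s, log = TRUE))
    npar <- if (known_s) 1 else 2
    return(list(mu = mu, sigma = s, w = 1,
                loglik = ll, bic = -2 * ll + npar * log(n)))
  }
  # init by splitting at the widest spacing in the sorted sample: exact
  # for well-separated modes, isolates tail points (later rejected by the
  # minor-weight rule) when the sample is unimodal
  o <- sort(x)
  gap_at <- which.max(diff(o))
  grp <- x > o[gap_at]
  if (all(grp) || !any(grp)) grp <- seq_len(n) > n / 2
  mu <- c(mean(x[!grp]), mean(x[grp]))
  s <- if (known_s) rep(sigma_fixed, 2) else rep(max(sd(x) / 2, 1e-6), 2)
  w <- c(mean(!grp), mean(grp))
  ll_old <- -Inf; ll <- -Inf
  for (it in seq_len(max_iter)) {
    dens <- cbind(w[1] * dnorm(x, mu[1], s[1]), w[2] * dnorm(x, mu[2], s[2]))
    tot <- rowSums(dens)
    tot[tot == 0] <- .Machine$double.xmin
    r <- dens / tot
    ll <- sum(log(tot))
    nk <- colSums(r)
    if (any(nk < 1e-8)) break
    w <- nk / n
    mu <- colSums(r * x) / nk
    if (!known_s)
      s <- sqrt(pmax(colSums(r * (x - rep(mu, each = n))^2) / nk, 1e-6))
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  npar <- if (known_s) 3 else 5
  list(mu = mu, sigma = s, w = w, loglik = ll,
       bic = -2 * ll + npar * log(n))
}

#' Re-estimate assembly gap lengths from spanning PETs
#'
#' For each gap, same-reference pairs in concordant mate-pair orientation
#' whose fragment interval fully contains that gap and overlaps no other
#' gap contribute one estimate: `annotated_len + (insert_mean -
#' observed_span)` (a gap longer than annotated shortens the observed
#' span).  Per gap the mean and median are reported; a
#' one-vs-two-component Gaussian mixture (chosen by BIC) flags bimodal
#' gaps, which report both component means and weights (structural
#' polymorphism between alleles).  Negative estimates are reported as-is
#' with a `polymorphism` flag, never clamped.
#'
#' @param pairs tag-pair table (one library).
#' @param assembly a [pet_assembly] providing the gap table.
#' @param lib the pairs' [library_profile]; `insert_mean` should be the
#'   re-measured (trimmed-mean) insert of this library.
#' @param min_support minimum supporting PETs per gap (default 5).
#' @param insert_sd known insert-length sd of the library (the measurement
#'   noise of every per-PET estimate).  When given, the mixture is fitted
#'   with fixed component sd, which makes bimodality detection well
#'   calibrated at the 10-30 supporting PETs typical of one gap; when
#'   NULL, component sds are estimated from the data.
#' @param bimodal_min_sep bimodal only if component means differ by more
#'   than this multiple of the (pooled or known) component sd (default 2).
#' @param bimodal_min_weight minimum minor-component weight (default 0.15).
#' @return data.frame, one row per gap, with `est_mean, est_median,
#'   n_support, n_components, mu1, mu2, w1, w2, polymorphism`; gaps below
#'   `min_support` get NA estimates.  Attribute `assembly_delta` holds
#'   the summed (estimate - annotated) over estimated gaps.
#' @export
estimate_gap_sizes <- function(pairs, assembly, lib, min_support = 5,
                               insert_sd = NULL,
                               bimodal_min_sep = 2, bimodal_min_weight = 0.15) {
  gaps <- assembly$gaps
  out <- data.frame(gaps,
                    est_mean = NA_real_, est_median = NA_real_,
                    n_support = 0L, n_components = NA_integer_,
                    mu1 = NA_real_, mu2 = NA_real_,
                    w1 = NA_real_, w2 = NA_real_,
                    polymorphism = FALSE, stringsAsFactors = FALSE)
  if (nrow(gaps) == 0 || nrow(pairs) == 0) {
    attr(out, "assembly_delta") <- 0
    return(out)
  }
  same <- pairs$ref1 == pairs$ref2 & concordant_orientation(pairs)
  p <- pairs[same, , drop = FALSE]
  if (nrow(p) == 0) { attr(out, "assembly_delta") <- 0; return(out) }
  frag <- pair_fragment(p)
  span <- pair_span(p)
  gr_g <- GenomicRanges::GRanges(gaps$scaffold,
                                 IRanges::IRanges(gaps$start + 1L, gaps$end))
  gr_f <- GenomicRanges::GRanges(frag$ref,
                                 IRanges::IRanges(frag$start + 1L, frag$end))
  hits <- GenomicRanges::findOverlaps(gr_f, gr_g)
  if (length(hits) == 0) { attr(out, "assembly_delta") <- 0; return(out) }
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  n_ov <- tabulate(qh, nbins = nrow(frag))
  full <- frag$start[qh] <= gaps$start[sh] & frag$end[qh] >= gaps$end[sh]
  usable <- n_ov[qh] == 1L & full
  qh <- qh[usable]; sh <- sh[usable]
  if (length(qh) == 0) { attr(out, "assembly_delta") <- 0; return(out) }
  # a gap longer than annotated shortens the observed scaffold span, so
  # the correction is expected minus observed
  est <- gaps$annotated_len[sh] + (lib$insert_mean - span[qh])
  by_gap <- split(est, sh)
  for (g in names(by_gap)) {
    i <- as.integer(g)
    e <- by_gap[[g]]
    out$n_support[i] <- length(e)
    if (length(e) < min_support) next
    out$est_mean[i] <- mean(e)
    out$est_median[i] <- median(e)
    out$n_components[i] <- 1L
    out$mu1[i] <- mean(e); out$w1[i] <- 1
    if (length(e) >= 2 * min_support && sd(e) > 0) {
      f1 <- fit_gmm1d(e, 1L, sigma_fixed = insert_sd)
      f2 <- fit_gmm1d(e, 2L, sigma_fixed = insert_sd)
      pooled_sd <- sqrt(sum(f2$w * f2$sigma^2))
      if (f2$bic < f1$bic &&
          abs(diff(f2$mu)) > bimodal_min_sep * pooled_sd &&
          min(f2$w) >= bimodal_min_weight) {
        ord <- order(f2$mu)
        out$n_components[i] <- 2L
        out$mu1[i] <- f2$mu[ord[1]]; out$mu2[i] <- f2$mu[ord[2]]
        out$w1[i] <- f2$w[ord[1]]; out$w2[i] <- f2$w[ord[2]]
      }
    }
    if (out$est_mean[i] < 0 || (!is.na(out$mu1[i]) && out$mu1[i] < 0))
      out$polymorphism[i] <- TRUE
  }
  est_ok <- !is.na(out$est_mean)
  attr(out, "assembly_delta") <- sum(out$est_mean[est_ok] - out$annotated_len[est_ok])
  out
}

#' Detect assembly breakpoints as zero-coverage intervals
#'
#' A breakpoint is a maximal interval where the per-base concordant-PET
#' fragment coverage is exactly zero, excluding a terminal margin (default
#' the library's `span_max`) at each scaffold end where coverage must
#' vanish by geometry.  Each breakpoint is annotated with any overlapping
#' assembly gap and with the number of discordant cross-reference PET tags
#' clustering within `span_max` on either side.
#'
#' @param pairs tag-pair table for one scaffold set (one library).
#' @param assembly a [pet_assembly].
#' @param lib the [library_profile].
#' @param margin terminal margin in bp; default `lib$span_max`.
#' @param scaffolds restrict to these scaffolds (default all).
#' @return data.frame with `scaffold, start, end, at_gap, gap_start,
#'   dpet_left, dpet_right`.
#' @export
detect_breakpoints <- function(pairs, assembly, lib, margin = lib$span_max,
                               scaffolds = NULL) {
  cls <- classify_pairs(pairs, lib)
  cpets <- pairs[cls == "cPET", , drop = FALSE]
  dd <- pairs[cls == "dPET_diff_ref", , drop = FALSE]
  dpos <- data.frame(ref = c(dd$ref1, dd$ref2), start = c(dd$start1, dd$start2))
  if (is.null(scaffolds)) scaffolds <- assembly$scaffolds$name
  res <- list()
  for (sc in scaffolds) {
    L <- scaffold_length(assembly, sc)
    if (L <= 2 * margin) next
    cov <- coverage_track(cpets, sc, L, mode = "per_base_fragment")$counts
    r <- rle(cov == 0)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths
    zi <- which(r$values)
    for (k in zi) {
      s <- starts[k]; e <- ends[k]
      if (s < margin || e > L - margin) next
      g <- assembly$gaps[assembly$gaps$scaffold == sc &
                           assembly$gaps$start < e &
                           assembly$gaps$end > s, , drop = FALSE]
      dl <- sum(dpos$ref == sc & dpos$start >= s - margin & dpos$start < s)
      dr <- sum(dpos$ref == sc & dpos$start >= e & dpos$start < e + margin)
      res[[length(res) + 1L]] <- data.frame(
        scaffold = sc, start = s, end = e,
        at_gap = nrow(g) > 0,
        gap_start = if (nrow(g)) g$start[1] else NA_integer_,
        dpet_left = dl, dpet_right = dr, stringsAsFactors = FALSE)
    }
  }
  if (!length(res))
    return(data.frame(scaffold = character(), start = integer(),
                      end = integer(), at_gap = logical(),
                      gap_start = integer(), dpet_left = integer(),
                      dpet_right = integer(), stringsAsFactors = FALSE))
  do.call(rbind, res)
}
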