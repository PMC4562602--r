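# Domain containers and readers/writers for the standard formats the
# toolkit touches: FASTA assemblies, tag-pair tables (TSV or SAM), BED6,
# GFF3, AGP v2.0 and bedGraph.

#' Construct an assembly object
#'
#' An assembly bundles scaffold names and lengths, the table of assembly
#' gaps (maximal N-runs), and optionally the sequences themselves.
#'
#' @param scaffolds data.frame with columns `name`, `length`.
#' @param gaps data.frame with columns `scaffold`, `start`, `end`
#'   (0-based half-open) and `annotated_len`; may have zero rows.
#' @param seq optional [Biostrings::DNAStringSet] named by scaffold.
#' @return object of class `pet_assembly`.
#' @export
pet_assembly <- function(scaffolds, gaps = NULL, seq = NULL) {
  stopifnot(is.data.frame(scaffolds), all(c("name", "length") %in% names(scaffolds)))
  scaffolds$name <- as.character(scaffolds$name)
  if (anyDuplicated(scaffolds$name))
    pf_stop("duplicate scaffold names in assembly")
  if (any(scaffolds$length < 1)) pf_stop("scaffold length must be >= 1")
  if (is.null(gaps) || nrow(gaps) == 0) {
    gaps <- data.frame(scaffold = character(), start = integer(),
                       end = integer(), annotated_len = integer(),
                       stringsAsFactors = FALSE)
  } else {
    gaps <- gaps[order(gaps$scaffold, gaps$start), , drop = FALSE]
    rownames(gaps) <- NULL
    gaps$annotated_len <- gaps$end - gaps$start
    if (any(gaps$annotated_len <= 0)) pf_stop("gap with non-positive length")
    len <- scaffolds$length[match(gaps$scaffold, scaffolds$name)]
    if (any(is.na(len)) || any(gaps$start < 0) || any(gaps$end > len))
      pf_stop("gap outside its scaffold")
    by_sc <- split(seq_len(nrow(gaps)), gaps$scaffold)
    for (idx in by_sc) {
      if (length(idx) > 1 && any(gaps$start[idx][-1] < gaps$end[idx][-length(idx)]))
        pf_stop("overlapping gaps on one scaffold")
    }
  }
  structure(list(scaffolds = scaffolds, gaps = gaps, seq = seq),
            class = "pet_assembly")
}

#' @export
print.pet_assembly <- function(x, ...) {
  cat(sprintf("pet_assembly: %d scaffolds, %s bp total, %d gaps%s\n",
              nrow(x$scaffolds), format(sum(x$scaffolds$length), big.mark = ","),
              nrow(x$gaps), if (is.null(x$seq)) " (no sequence)" else ""))
  invisible(x)
}

scaffold_length <- function(assembly, name) {
  assembly$scaffolds$length[match(name, assembly$scaffolds$name)]
}

# locate maximal runs of N/n in one sequence string; 0-based half-open
find_n_runs <- function(s) {
  m <- gregexpr("[Nn]+", s, perl = TRUE)[[1]]
  if (m[1] == -1)
    return(data.frame(start = integer(), end = integer()))
  st <- as.integer(m) - 1L
  data.frame(start = st, end = st + attr(m, "match.length"))
}

#' Read a FASTA assembly
#'
#' Every maximal run of one or more `N`/`n` becomes an assembly gap.
#'
#' @param path FASTA file.
#' @param keep_seq keep the sequences in the returned object.
#' @return a [pet_assembly].
#' @export
read_assembly <- function(path, keep_seq = TRUE) {
  dss <- Biostrings::readDNAStringSet(path)
  if (length(dss) == 0) pf_stop("empty FASTA: ", path)
  names(dss) <- sub("\\s.*$", "", names(dss))
  if (anyDuplicated(names(dss))) pf_stop("duplicate scaffold names in ", path)
  chars <- as.character(dss)
  gl <- lapply(seq_along(chars), function(i) {
    g <- find_n_runs(chars[[i]])
    if (nrow(g)) g$scaffold <- names(dss)[i]
    g
  })
  gl <- gl[vapply(gl, nrow, 1L) > 0]
  gaps <- if (length(gl)) {
    g <- do.call(rbind, gl)
    data.frame(scaffold = g$scaffold, start = g$start, end = g$end,
               annotated_len = g$end - g$start, stringsAsFactors = FALSE)
  } else NULL
  pet_assembly(data.frame(name = names(dss), length = Biostrings::width(dss),
                          stringsAsFactors = FALSE),
               gaps, seq = if (keep_seq) dss else NULL)
}

#' Write an assembly to FASTA
#'
#' @param assembly a [pet_assembly] carrying sequences.
#' @param path output file.
#' @export
write_assembly <- function(assembly, path) {
  if (is.null(assembly$seq)) pf_stop("assembly carries no sequence")
  Biostrings::writeXStringSet(assembly$seq, path, width = 70L)
  invisible(path)
}

TAG_COLS <- c("pair_id", "lib", "ref1", "start1", "end1", "strand1",
              "ref2", "start2", "end2", "strand2")

validate_tag_pairs <- function(df) {
  miss <- setdiff(TAG_COLS, names(df))
  if (length(miss)) pf_stop("tag table missing columns: ", paste(miss, collapse = ", "))
  if (nrow(df)) {
    if (any(df$end1 <= df$start1) || any(df$end2 <= df$start2))
      pf_stop("tag with end <= start")
    if (any(df$end1 - df$start1 > 36) || any(df$end2 - df$start2 > 36))
      pf_stop("tag longer than 36 bp")
    if (!all(df$strand1 %in% c("+", "-")) || !all(df$strand2 %in% c("+", "-")))
      pf_stop("strand must be '+' or '-'")
  }
  df
}

#' Read mapped tag pairs
#'
#' Accepts either a tab-delimited tag table (columns `pair_id, lib, ref1,
#' start1, end1, strand1, ref2, start2, end2, strand2`; 0-based half-open)
#' or a SAM/BAM file with paired records.  Only pairs with both mates
#' mapped are returned; orphan and unmapped records are counted in the
#' `orphans` attribute.  If `assembly` is given, pairs on unknown
#' references are skipped and counted in the `skipped` attribute.
#'
#' @param path input file.
#' @param format `"tsv"` or `"sam"`; default guessed from the extension.
#' @param assembly optional [pet_assembly] used to check reference names.
#' @param lib library id used for SAM input (SAM has no library column).
#' @return data.frame of tag pairs with attributes `orphans`, `skipped`.
#' @export
read_tag_pairs <- function(path, format = NULL, assembly = NULL, lib = "lib1") {
  if (is.null(format)) {
    format <- if (grepl("\\.(sam|bam)$", path, ignore.case = TRUE)) "sam" else "tsv"
  }
  format <- match.arg(format, c("tsv", "sam"))
  orphans <- 0L
  if (format == "tsv") {
    df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  } else {
    p <- Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "qwidth", "strand"))
    bam <- if (grepl("\\.sam$", path, ignore.case = TRUE)) {
      tmp <- tempfile(fileext = ".bam")
      on.exit(unlink(c(tmp, paste0(tmp, ".bai")), force = TRUE), add = TRUE)
      Rsamtools::asBam(path, sub("\\.bam$", "", tmp), overwrite = TRUE,
                       indexDestination = FALSE)
    } else path
    b <- Rsamtools::scanBam(bam, param = p)[[1]]
    mapped <- !is.na(b$pos) & !is.na(b$rname)
    d <- data.frame(qname = b$qname[mapped],
                    ref = as.character(b$rname)[mapped],
                    start = b$pos[mapped] - 1L,
                    end = b$pos[mapped] - 1L + b$qwidth[mapped],
                    strand = as.character(b$strand)[mapped],
                    first = bitwAnd(b$flag[mapped], 64L) > 0L,
                    stringsAsFactors = FALSE)
    cnt <- table(d$qname)
    paired <- names(cnt)[cnt == 2L]
    orphans <- sum(!mapped) + sum(cnt == 1L)
    d <- d[d$qname %in% paired, , drop = FALSE]
    d <- d[order(d$qname, !d$first), , drop = FALSE]
    i1 <- seq(1L, nrow(d), by = 2L)
    i2 <- i1 + 1L
    df <- data.frame(pair_id = d$qname[i1], lib = lib,
                     ref1 = d$ref[i1], start1 = d$start[i1], end1 = d$end[i1],
                     strand1 = d$strand[i1],
                     ref2 = d$ref[i2], start2 = d$start[i2], end2 = d$end[i2],
                     strand2 = d$strand[i2], stringsAsFactors = FALSE)
  }
  df <- validate_tag_pairs(df)
  skipped <- 0L
  if (!is.null(assembly)) {
    known <- df$ref1 %in% assembly$scaffolds$name & df$ref2 %in% assembly$scaffolds$name
    skipped <- sum(!known)
    if (skipped) warning(skipped, " pair(s) on unknown reference skipped")
    df <- df[known, , drop = FALSE]
    rownames(df) <- NULL
  }
  attr(df, "orphans") <- as.integer(orphans)
  attr(df, "skipped") <- as.integer(skipped)
  df
}

#' Write a tag-pair table as TSV
#' @param pairs tag-pair data.frame.
#' @param path output file.
#' @export
write_tag_pairs <- function(pairs, path) {
  validate_tag_pairs(pairs)
  write.table(pairs[, TAG_COLS], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write / read BED6 intervals
#'
#' Intervals are 0-based half-open, matching BED natively.
#'
#' @param intervals data.frame with `chrom, start, end, name, score, strand`.
#' @param path file path.
#' @export
write_bed <- function(intervals, path) {
  df <- data.frame(chrom = intervals$chrom, start = intervals$start,
                   end = intervals$end,
                   name = intervals$name %||% ".",
                   score = intervals$score %||% 0,
                   strand = intervals$strand %||% ".")
  if (nrow(df) && any(df$end <= df$start)) pf_stop("BED interval with end <= start")
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             name = if (!is.null(gr$name)) gr$name else ".",
             score = if (!is.null(gr$score)) gr$score else 0,
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

genes_to_granges <- function(genes) {
  GenomicRanges::GRanges(
    seqnames = genes$ref,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand,
    type = "gene",
    source = genes$source %||% "petforge",
    ID = genes$gene_id)
}

#' Write / read gene models as GFF3
#'
#' Internal 0-based half-open coordinates are converted to the 1-based
#' inclusive GFF3 convention on write (and back on read).
#'
#' @param genes data.frame with `gene_id, ref, start, end, strand` and
#'   optional `source`; zero rows produce a valid header-only file.
#' @param path file path.
#' @export
write_gff3 <- function(genes, path) {
  if (nrow(genes) == 0) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  if (any(genes$end <= genes$start)) pf_stop("gene with end <= start")
  rtracklayer::export(genes_to_granges(genes), path, format = "gff3")
  invisible(path)
}

#' @rdname write_gff3
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0)
    return(data.frame(gene_id = character(), ref = character(),
                      start = integer(), end = integer(),
                      strand = character(), source = character(),
                      stringsAsFactors = FALSE))
  data.frame(gene_id = as.character(gr$ID),
             ref = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             source = as.character(gr$source),
             stringsAsFactors = FALSE)
}

#' Write per-base coverage as bedGraph
#'
#' @param cov named list of per-base numeric coverage vectors (one per
#'   scaffold, 0-based positions).
#' @param path file path.
#' @export
write_bedgraph <- function(cov, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("track type=bedGraph", con)
  for (sc in names(cov)) {
    r <- rle(as.numeric(cov[[sc]]))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (any(keep)) {
      writeLines(sprintf("%s\t%d\t%d\t%g", sc, starts[keep], ends[keep],
                         r$values[keep]), con)
    }
  }
  invisible(path)
}

#' Read a bedGraph file into per-base coverage vectors
#' @param path bedGraph file.
#' @param lengths named integer vector of scaffold lengths.
#' @export
read_bedgraph <- function(path, lengths) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|#)", lines)]
  cov <- lapply(lengths, function(L) numeric(L))
  if (length(lines)) {
    d <- read.table(text = lines, sep = "\t", stringsAsFactors = FALSE)
    for (i in seq_len(nrow(d))) {
      sc <- d[[1]][i]
      if (!sc %in% names(cov)) next
      cov[[sc]][(d[[2]][i] + 1L):d[[3]][i]] <- d[[4]][i]
    }
  }
  cov
}

#' Write chains as AGP v2.0
#'
#' Each chain becomes one AGP object: `W` lines for fragments and `N`/`U`
#' gap lines between them.  Estimated link lengths are clamped to >= 1
#' (AGP requires positive gaps); unknown links are written as `U 100`.
#'
#' @param chains chain table from [chain_scaffolds()] (columns `chain_id,
#'   position, fragment_id, orientation, gap_before`).
#' @param fragments fragment table (columns `fragment_id, parent, p_start,
#'   p_end, length`).
#' @param path output file.
#' @export
write_agp <- function(chains, fragments, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##agp-version\t2.0", con)
  fi <- match(chains$fragment_id, fragments$fragment_id)
  if (anyNA(fi)) pf_stop("chain references unknown fragment")
  for (cid in unique(chains$chain_id)) {
    rows <- which(chains$chain_id == cid)
    rows <- rows[order(chains$position[rows])]
    obj <- sprintf("hyper_%s", cid)
    pos <- 1L
    part <- 1L
    for (k in seq_along(rows)) {
      r <- rows[k]
      f <- fi[r]
      if (k > 1) {
        g <- chains$gap_before[r]
        known <- is.finite(g)
        glen <- if (known) max(1L, as.integer(round(g))) else 100L
        writeLines(sprintf("%s\t%d\t%d\t%d\t%s\t%d\tscaffold\tyes\tpaired-ends",
                           obj, pos, pos + glen - 1L, part,
                           if (known) "N" else "U", glen), con)
        pos <- pos + glen
        part <- part + 1L
      }
      L <- fragments$length[f]
      writeLines(sprintf("%s\t%d\t%d\t%d\tW\t%s\t%d\t%d\t%s",
                         obj, pos, pos + L - 1L, part,
                         fragments$fragment_id[f], 1L, L,
                         chains$orientation[r]), con)
      pos <- pos + L
      part <- part + 1L
    }
  }
  invisible(path)
}

#' Read an AGP v2.0 file written by [write_agp()]
#' @param path AGP file.
#' @return data.frame with `chain_id, position, fragment_id, orientation,
#'   gap_before`.
#' @export
read_agp <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  d <- read.table(text = lines, sep = "\t", stringsAsFactors = FALSE,
                  col.names = paste0("V", 1:9), fill = TRUE)
  out <- list()
  for (obj in unique(d$V1)) {
    rows <- d[d$V1 == obj, , drop = FALSE]
    gap_before <- NA_real_
    pos <- 0L
    for (i in seq_len(nrow(rows))) {
      if (rows$V5[i] %in% c("N", "U")) {
        gap_before <- if (rows$V5[i] == "N") as.numeric(rows$V6[i]) else NA_real_
      } else {
        pos <- pos + 1L
        out[[length(out) + 1L]] <- data.frame(
          chain_id = sub("^hyper_", "", obj), position = pos,
          fragment_id = rows$V6[i], orientation = rows$V9[i],
          gap_before = if (pos == 1L) NA_real_ else gap_before,
          stringsAsFactors = FALSE)
        gap_before <- NA_real_
      }
    }
  }
  do.call(rbind, out)
}

#' Quick structural validation of a file
#'
#' @param path file to check.
#' @param kind one of `"fasta"`, `"tags"`, `"bed"`, `"gff3"`, `"agp"`,
#'   `"bedgraph"`.
#' @return TRUE invisibly on success; error otherwise.
#' @export
io_validate <- function(path, kind = c("fasta", "tags", "bed", "gff3",
                                       "agp", "bedgraph")) {
  kind <- match.arg(kind)
  switch(kind,
         fasta = read_assembly(path, keep_seq = FALSE),
         tags = read_tag_pairs(path),
         bed = read_bed(path),
         gff3 = read_gff3(path),
         agp = read_agp(path),
         bedgraph = readLines(path))
  invisible(TRUE)
}
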