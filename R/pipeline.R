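# End-to-end workflow wrappers with config resolution, run manifests and a
# thin command-line entry point.

default_rescaffold_config <- function() {
  list(window_size = 20000, min_support = 5, min_n_run = 10000,
       repeat_window = 1000, repeat_max_density = 500,
       min_edge_weight = 4, trim_fraction = 0.05, seed = 1)
}

default_annotation_config <- function() {
  list(signature = "AACTGCTG", max_mismatch = 2, slack_stringent = 0,
       slack_relaxed = 1000, min_span = 2000, min_reads_per_kb = 5,
       min_sep = 1000, merge_radius = 10, body_bins = 100,
       flank_bp = 10000, seed = 1)
}

resolve_config <- function(config, defaults) {
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    pf_stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  utils::modifyList(defaults, config)
}

write_manifest <- function(config, outdir, stage) {
  if (is.null(outdir)) return(invisible(NULL))
  manifest <- list(tool = "petforge",
                   version = as.character(utils::packageVersion("petforge")),
                   stage = stage, config = config)
  jsonlite::write_json(manifest, file.path(outdir, paste0(stage, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(NULL)
}

#' Run the full DNA-PET re-scaffolding pipeline
#'
#' classify -> insert-size -> gap re-estimation -> breakpoints -> split at
#' gaps and breakpoints -> repeat masking -> edge building -> chaining ->
#' statistics, in order.  Deterministic given identical inputs and config.
#'
#' @param assembly a [pet_assembly].
#' @param libraries named list: per library, `list(pairs = <tag table>,
#'   profile = <library_profile>)`.
#' @param config list overriding `default_rescaffold_config()` keys.
#' @param outdir optional output directory for AGP, breakpoint BED, gap
#'   table TSV, chain report TSV and the run manifest.
#' @return list with `classes, insert_sizes, gap_table, breakpoints,
#'   fragments, edges, chains, fillins, stats, config`.
#' @export
run_rescaffold_pipeline <- function(assembly, libraries, config = list(),
                                    outdir = NULL) {
  if (is.null(assembly)) pf_stop("rescaffold: missing assembly input")
  if (!length(libraries)) pf_stop("rescaffold: missing DNA-PET libraries")
  if (is.null(names(libraries)))
    names(libraries) <- vapply(libraries, function(l)
      l$profile$library_id, "")
  cfg <- resolve_config(config, default_rescaffold_config())
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)

  classes <- list(); insert_sizes <- list()
  all_cpets <- list(); gap_tables <- list(); bp_list <- list()
  for (nm in names(libraries)) {
    li <- libraries[[nm]]
    pairs <- dedup_pairs(li$pairs)
    cls <- classify_pairs(pairs, li$profile)
    classes[[nm]] <- table(cls)
    cp <- pairs[cls == "cPET", , drop = FALSE]
    all_cpets[[nm]] <- cp
    ins <- tryCatch(estimate_insert_size(gap_free_cpets(cp, assembly),
                                         cfg$trim_fraction),
                    error = function(e) list(mean = li$profile$insert_mean,
                                             sd = NA, n = nrow(cp)))
    insert_sizes[[nm]] <- ins
    prof <- li$profile
    prof$insert_mean <- ins$mean          # re-measured insert for estimation
    gap_tables[[nm]] <- estimate_gap_sizes(pairs, assembly, prof,
                                           min_support = cfg$min_support,
                                           insert_sd = ins$sd)
    bp_list[[nm]] <- detect_breakpoints(pairs, assembly, li$profile)
    libraries[[nm]]$pairs <- pairs
    libraries[[nm]]$profile <- prof
  }
  gap_table <- gap_tables[[1]]
  breakpoints <- unique(do.call(rbind, bp_list))

  cpets <- do.call(rbind, all_cpets)
  fragments <- split_at_gaps(assembly, cpets, min_n_run = cfg$min_n_run)
  fragments <- split_at_breakpoints(fragments, breakpoints)

  all_pairs <- do.call(rbind, lapply(libraries, `[[`, "pairs"))
  masked <- mask_repeats(all_pairs, assembly, window = cfg$repeat_window,
                         max_density = cfg$repeat_max_density)
  edges <- do.call(rbind, lapply(libraries, function(li)
    build_edges(filter_masked_pairs(li$pairs, masked), fragments, li$profile,
                min_weight = cfg$min_edge_weight)))
  edges <- rbind(edges, provenance_edges(fragments))
  chains <- chain_scaffolds(edges, fragments)
  fillins <- fill_gaps(chains, fragments)
  stats <- assembly_stats(assembly$scaffolds$length,
                          chain_lengths(chains, fragments), chains)

  if (!is.null(outdir)) {
    write_agp(chains, fragments, file.path(outdir, "hyper_scaffolds.agp"))
    if (nrow(breakpoints))
      write_bed(data.frame(chrom = breakpoints$scaffold,
                           start = breakpoints$start, end = breakpoints$end,
                           name = "breakpoint", score = 0, strand = "."),
                file.path(outdir, "breakpoints.bed"))
    write.table(gap_table, file.path(outdir, "gap_estimates.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(chains, file.path(outdir, "chains.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_manifest(cfg, outdir, "rescaffold")
  }
  list(classes = classes, insert_sizes = insert_sizes, gap_table = gap_table,
       breakpoints = breakpoints, fragments = fragments, edges = edges,
       chains = chains, fillins = fillins, stats = stats, config = cfg)
}

#' Run the full RNA-PET annotation pipeline
#'
#' classify ditags -> orient -> cluster (stringent and relaxed) ->
#' promote -> filter -> coalesce -> compare with the existing annotation
#' -> metagene profile.
#'
#' @param ditag_pairs mapped ditag tag-pair table (tag1 = read1).
#' @param ditag_reads data.frame `pair_id, read1, read2` (sequences).
#' @param rnaseq per-scaffold RNA-Seq coverage list.
#' @param existing optional existing annotation table.
#' @param config list overriding `default_annotation_config()` keys.
#' @param outdir optional output directory (gene GFF3, cluster BED,
#'   TSS/TTS BED, comparison TSV, manifest).
#' @return list with `ditag_classes, oriented, clusters, genes,
#'   comparison, metagene, config`.
#' @export
run_annotation_pipeline <- function(ditag_pairs, ditag_reads, rnaseq,
                                    existing = NULL, config = list(),
                                    outdir = NULL) {
  if (is.null(ditag_pairs) || is.null(ditag_reads))
    pf_stop("annotation: missing RNA-PET input")
  if (is.null(rnaseq)) pf_stop("annotation: missing RNA-Seq coverage input")
  cfg <- resolve_config(config, default_annotation_config())
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)

  reads <- ditag_reads[match(ditag_pairs$pair_id, ditag_reads$pair_id), ]
  cls <- classify_ditags(reads$read1, reads$read2, cfg$signature,
                         cfg$max_mismatch)
  oriented <- orient_pairs(ditag_pairs, cls)
  if (nrow(oriented) == 0)
    warning("zero HT ditags: annotation will be empty")
  stringent <- cluster_pets(oriented, slack = cfg$slack_stringent,
                            parameter_set = "stringent")
  relaxed <- cluster_pets(oriented, slack = cfg$slack_relaxed,
                          parameter_set = "relaxed")
  promoted <- promote(stringent, relaxed, rnaseq, min_sep = cfg$min_sep,
                      min_reads_per_kb = cfg$min_reads_per_kb)
  filtered <- filter_clusters(promoted, rnaseq, min_span = cfg$min_span,
                              min_reads_per_kb = cfg$min_reads_per_kb)
  genes <- coalesce_clusters(filtered, merge_radius = cfg$merge_radius)
  comparison <- if (!is.null(existing) && nrow(genes))
    compare_annotation(genes, existing, rnaseq) else NULL
  mg <- if (nrow(genes))
    metagene_profile(rnaseq, genes, body_bins = cfg$body_bins,
                     flank_bp = cfg$flank_bp) else NULL

  if (!is.null(outdir)) {
    gdf <- genes[, c("gene_id", "ref", "start", "end", "strand")]
    gdf$source <- "rnapet"
    write_gff3(gdf, file.path(outdir, "genes.gff3"))
    if (nrow(filtered))
      write_bed(data.frame(chrom = filtered$ref, start = filtered$start,
                           end = filtered$end, name = filtered$cluster_id,
                           score = filtered$pet_count,
                           strand = filtered$strand),
                file.path(outdir, "clusters.bed"))
    if (nrow(genes)) {
      tss <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i)
        data.frame(chrom = genes$ref[i], start = genes$tss_set[[i]],
                   end = genes$tss_set[[i]] + 1L, name = genes$gene_id[i],
                   score = 0, strand = genes$strand[i])))
      write_bed(tss, file.path(outdir, "tss.bed"))
    }
    if (!is.null(comparison))
      write.table(comparison$pairs, file.path(outdir, "comparison.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    write_manifest(cfg, outdir, "annotation")
  }
  list(ditag_classes = table(cls$class), oriented = oriented,
       clusters = list(stringent = stringent, relaxed = relaxed,
                       promoted = promoted, filtered = filtered),
       genes = genes, comparison = comparison, metagene = mg, config = cfg)
}

#' Command-line entry point
#'
#' Thin dispatcher used by the `inst/cli/petforge` script:
#' `petforge io validate <file> [kind]`, `petforge simulate genome --seed N
#' --out DIR`, `petforge run rescaffold|annotation --config cfg.json`.
#' Exit codes: 0 ok, 2 bad input, 3 internal error.
#'
#' @param args character vector of command-line arguments.
#' @return integer exit status, invisibly.
#' @export
petforge_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(args) < 1) pf_stop("usage: petforge <io|simulate|run> ...",
                                  class = "petforge_usage")
    cmd <- args[1]
    opt <- function(flag, default = NULL) {
      i <- which(args == flag)
      if (length(i) && i < length(args)) args[i + 1L] else default
    }
    if (cmd == "io" && length(args) >= 3 && args[2] == "validate") {
      io_validate(args[3], if (length(args) >= 4) args[4] else "fasta")
      message("OK: ", args[3])
    } else if (cmd == "simulate" && length(args) >= 2 && args[2] == "genome") {
      seed <- as.integer(opt("--seed", "1"))
      out <- opt("--out", ".")
      if (!dir.exists(out)) dir.create(out, recursive = TRUE)
      sim <- simulate_genome(seed = seed)
      write_assembly(sim$assembly, file.path(out, "assembly.fasta"))
      message("wrote ", file.path(out, "assembly.fasta"))
    } else if (cmd == "run" && length(args) >= 2) {
      cfg_path <- opt("--config")
      if (is.null(cfg_path) || !file.exists(cfg_path))
        pf_stop("run: --config file required", class = "petforge_usage")
      cfg <- jsonlite::read_json(cfg_path, simplifyVector = FALSE)
      out <- opt("--out", "petforge_out")
      if (args[2] == "rescaffold") {
        assembly <- read_assembly(cfg$assembly)
        libs <- lapply(cfg$libraries, function(l)
          list(pairs = read_tag_pairs(l$pairs, assembly = assembly,
                                      lib = l$id),
               profile = library_profile(l$id, l$insert_mean, l$span_min,
                                         l$span_max)))
        run_rescaffold_pipeline(assembly, libs,
                                config = cfg$params %||% list(), outdir = out)
      } else pf_stop("unknown run stage: ", args[2], class = "petforge_usage")
      message("results in ", out)
    } else pf_stop("unknown command: ", cmd, class = "petforge_usage")
    0L
  },
  petforge_usage = function(e) { message(conditionMessage(e)); 2L },
  petforge_error = function(e) { message("input error: ", conditionMessage(e)); 2L },
  error = function(e) { message("internal error: ", conditionMessage(e)); 3L })
  invisible(status)
}
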