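# Run configuration and the end-to-end pipeline: search (or ingest) ->
# annotate -> risk -> report -> export.

DB_LAYERS <- c("gene_models", "promoters", "enhancers", "regulator_peaks",
               "protein_domains", "mirna_genes", "mirna_targets",
               "phenotypes", "cancer", "tf", "rbp", "expression")

TRACK_LAYER_KIND <- c(promoters = "promoter", enhancers = "enhancer",
                      regulator_peaks = "regulator_peak",
                      protein_domains = "protein_domain",
                      mirna_genes = "mirna_gene", mirna_targets = "mirna_target")

#' Load a run configuration from YAML
#'
#' Relative paths in the file are resolved against the YAML's own directory.
#' Any subset of database layers may be present; omitted layers are skipped
#' with a notice at run time. Recognized keys: `genome`, `guides` (list of
#' protospacers) or `sites` (BED/TSV path), `pam`, `search`
#' (`max_mismatches`, `max_dna_bulges`, `max_rna_bulges`, `both_strands`),
#' `databases` (per-layer paths), `promoter_window` (`upstream`,
#' `downstream`, to derive promoters from gene models when no promoter BED
#' is given), `out_dir`, `formats`, `seed`.
#'
#' @param path Path to the YAML file.
#' @param overrides Named list applied over the file's values (CLI flags).
#' @return A `run_config` list.
#' @export
load_run_config <- function(path = NULL, overrides = list()) {
  cfg <- if (!is.null(path)) yaml::read_yaml(path) else list()
  base <- if (!is.null(path)) dirname(normalizePath(path)) else getwd()
  for (nm in names(overrides)) {
    v <- overrides[[nm]]
    if (!is.null(v)) cfg[[nm]] <- v
  }
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (!grepl("^(/|[A-Za-z]:)", p)) p <- file.path(base, p)
    p
  }
  cfg$genome <- resolve(cfg$genome)
  cfg$sites <- resolve(cfg$sites)
  cfg$guide_file <- resolve(cfg$guide_file)
  dbs <- cfg$databases %||% list()
  unknown <- setdiff(names(dbs), DB_LAYERS)
  if (length(unknown) > 0L) {
    stop("unknown database layer(s) in config: ", paste(unknown, collapse = ", "))
  }
  cfg$databases <- lapply(dbs, resolve)
  cfg$out_dir <- resolve(cfg$out_dir %||% "out")
  search <- cfg$search %||% list()
  cfg$search <- search_params(
    max_mismatches = search$max_mismatches %||% 4L,
    max_dna_bulges = search$max_dna_bulges %||% 0L,
    max_rna_bulges = search$max_rna_bulges %||% 0L,
    both_strands = search$both_strands %||% TRUE)
  cfg$pam <- cfg$pam %||% "NGG"
  cfg$formats <- unlist(cfg$formats %||% "csv")
  pw <- cfg$promoter_window %||% list()
  cfg$promoter_window <- list(upstream = pw$upstream %||% 499L,
                              downstream = pw$downstream %||% 100L)
  for (nm in c("genome", "sites", "guide_file")) {
    if (!is.null(cfg[[nm]]) && !file.exists(cfg[[nm]])) {
      stop(sprintf("config %s path does not exist: %s", nm, cfg[[nm]]))
    }
  }
  for (nm in names(cfg$databases)) {
    if (!is.null(cfg$databases[[nm]]) && !file.exists(cfg$databases[[nm]])) {
      stop(sprintf("config database '%s' path does not exist: %s", nm,
                   cfg$databases[[nm]]))
    }
  }
  structure(cfg, class = "run_config")
}

warn_chrom_consistency <- function(genome_names, other, what) {
  if (length(other) == 0L) return(invisible())
  unshared <- setdiff(other, genome_names)
  if (length(unshared) > 0L) {
    warning(sprintf(
      "chromosome naming mismatch: %s uses name(s) not in the genome: %s",
      what, paste(sort(unique(unshared)), collapse = ", ")), call. = FALSE)
  }
  invisible()
}

#' Run the full off-target risk pipeline
#'
#' Searches the genome for off-target sites of the configured guide(s) (or
#' ingests a user-supplied site list), annotates every site against the
#' configured annotation layers, assigns risk labels, and writes the summary
#' table, per-database tables, chart data and site BED to the output
#' directory.
#'
#' @param config A `run_config` from [load_run_config()], or a path to a
#'   YAML config.
#' @param quiet Suppress progress notices.
#' @return Invisibly, a list with `sites`, `annotations`, `labels`,
#'   `summary`, `charts`, `tables` and `files`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- load_run_config(config)
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  if (!is.null(config$seed)) set.seed(config$seed)
  if (is.null(config$genome)) stop("config is missing the genome path")
  genome <- load_genome(config$genome)

  guides <- list()
  if (!is.null(config$guides)) {
    guides <- lapply(config$guides, parse_guide, pam_pattern = config$pam)
    for (i in seq_along(guides)) {
      if (guides[[i]]$name == "guide") guides[[i]]$name <- sprintf("guide_%d", i)
    }
  } else if (!is.null(config$guide_file)) {
    guides <- read_guides(config$guide_file, pam_pattern = config$pam)
  }

  if (!is.null(config$sites)) {
    say("reading user-supplied sites from %s", config$sites)
    ext <- tolower(tools::file_ext(config$sites))
    sites <- if (ext %in% c("tsv", "txt")) {
      read_sites_tsv(config$sites)
    } else {
      read_sites_bed(config$sites)
    }
    sites <- fill_site_sequences(sites, genome,
                                 guide = if (length(guides) == 1L) guides[[1L]] else NULL)
  } else {
    if (length(guides) == 0L) stop("config needs either guides or a sites path")
    say("searching %d guide(s), max mismatches %d", length(guides),
        config$search$max_mismatches)
    found <- lapply(guides, function(g) find_offtargets(genome, g, config$search))
    sites <- dedupe_sites(do.call(rbind, found))
    sites$name <- sprintf("site_%d", seq_len(nrow(sites)))
  }
  say("%d site(s) to annotate", nrow(sites))

  dbs <- config$databases %||% list()
  gene_models <- NULL
  if (!is.null(dbs$gene_models)) {
    gene_models <- load_gene_models(dbs$gene_models)
  } else {
    say("gene_models layer omitted; skipping gene annotation")
  }
  tracks <- list()
  for (layer in names(TRACK_LAYER_KIND)) {
    if (!is.null(dbs[[layer]])) {
      tracks[[layer]] <- load_track(dbs[[layer]], TRACK_LAYER_KIND[[layer]])
    } else {
      say("%s layer omitted; skipping", layer)
    }
  }
  if (is.null(dbs$promoters) && !is.null(gene_models)) {
    say("deriving promoters from gene models (-%d..+%d around TSS)",
        config$promoter_window$upstream, config$promoter_window$downstream)
    lens <- stats::setNames(Biostrings::width(genome), names(genome))
    tracks$promoters <- derive_promoters(
      gene_models, config$promoter_window$upstream,
      config$promoter_window$downstream, seqlengths = lens)
  }
  fn_layers <- c("phenotypes", "cancer", "tf", "rbp", "expression")
  function_index <- do.call(load_function_tables, dbs[intersect(names(dbs), fn_layers)])

  genome_names <- names(genome)
  if (!is.null(gene_models)) {
    warn_chrom_consistency(genome_names, gene_models$genes$chrom, "gene models")
  }
  for (layer in names(tracks)) {
    warn_chrom_consistency(genome_names, tracks[[layer]]$records$chrom, layer)
  }
  warn_chrom_consistency(genome_names, sites$chrom, "site list")

  annotations <- annotate_sites(sites, gene_models, tracks, function_index)
  labels <- lapply(annotations, assign_risk)
  summary <- build_summary(annotations, labels)
  charts <- build_charts(annotations, labels, function_index)
  tables <- build_db_tables(annotations, labels, function_index)
  files <- export_results(summary, charts, tables, sites, config$out_dir,
                          config$formats)
  say("wrote %d file(s) to %s", length(files), config$out_dir)
  invisible(list(sites = sites, annotations = annotations, labels = labels,
                 summary = summary, charts = charts, tables = tables,
                 files = files))
}
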