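# End-to-end orchestration: config file parsing, the staged pipeline
# (seed -> assign -> prune -> optimize -> rescue-from-unassigned ->
# gene-rescue -> finalize -> specificity -> associates -> supergroups ->
# validate), run manifest, and a small command-line entry point.

#' Parse a plain-text pipeline config file
#'
#' Lines of `key = value`; keys with dots address per-species inputs
#' (`peptides.sp01`, `genome.sp01`, `gff.sp01`, `ortholog_table.sp01`,
#' `outgroup.ogsp = level:path`). Pipeline threshold keys override the
#' [pipeline_config()] defaults.
#'
#' @param path config file path.
#' @return a list with `config` (a `pipeline_config`), `species`,
#'   `reference_species`, `inputs` (paths) and `out_dir`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  eq <- regexpr("=", lines, fixed = TRUE)
  if (any(eq < 0L))
    stopf("malformed config line: '%s'", lines[eq < 0L][1])
  keys <- trimws(substr(lines, 1L, eq - 1L))
  vals <- trimws(substr(lines, eq + 1L, nchar(lines)))
  getv <- function(k, required = TRUE) {
    i <- which(keys == k)
    if (length(i) == 0L) {
      if (required) stopf("config key missing: %s", k)
      return(NULL)
    }
    vals[i[1]]
  }
  species <- strsplit(getv("species"), ",")[[1]]
  refs <- strsplit(getv("reference_species"), ",")[[1]]
  if (length(refs) != 2L) stopf("exactly two reference_species required")

  per_species <- function(prefix) {
    out <- list()
    for (sp in species) {
      v <- getv(paste0(prefix, ".", sp), required = FALSE)
      if (!is.null(v)) out[[sp]] <- v
    }
    out
  }
  inputs <- list(peptides = per_species("peptides"),
                 genome = per_species("genome"),
                 gff = per_species("gff"))
  missing_peps <- setdiff(species, names(inputs$peptides))
  if (length(missing_peps))
    stopf("config missing peptide FASTA for species: %s",
          paste(missing_peps, collapse = ", "))
  inputs$ortholog_table <- list()
  for (ref in refs) {
    v <- getv(paste0("ortholog_table.", ref))
    inputs$ortholog_table[[ref]] <- v
  }
  og <- grep("^outgroup\\.", keys)
  inputs$outgroups <- list()
  for (i in og) {
    sp <- sub("^outgroup\\.", "", keys[i])
    parts <- strsplit(vals[i], ":", fixed = TRUE)[[1]]
    inputs$outgroups[[sp]] <- list(level = parts[1],
                                   path = paste(parts[-1], collapse = ":"))
  }

  # pipeline parameter overrides
  cfg_args <- list()
  for (k in c("r_min", "delta_improve", "cluster_identity_pct",
              "min_present_fraction", "max_rescued",
              "specificity_cutoff", "min_raw_bits", "max_passes")) {
    v <- getv(k, required = FALSE)
    if (!is.null(v)) cfg_args[[k]] <- as.numeric(v)
  }
  config <- do.call(pipeline_config, cfg_args)
  config$species_order <- sort(species)

  list(config = config, species = species, reference_species = refs,
       inputs = inputs, out_dir = getv("out_dir", required = FALSE))
}

#' Run the full pipeline from a config file
#'
#' Executes seed, exclusive assignment, sparse pruning, per-group
#' optimization, rescue from unassigned peptides, gene rescue from genomic
#' sequence, the universality filter, specificity scoring, associate
#' assignment and supergroup detection, writing all tables plus a JSON run
#' manifest with input digests and stage timings. Identical inputs and
#' config produce byte-identical outputs.
#'
#' @param config_path path to a plain-text config file (see
#'   [read_pipeline_config()]), or the already-parsed list.
#' @param out_dir output directory (overrides the config's `out_dir`).
#' @param skip character vector of stages to skip: any of
#'   `"rescue"`, `"specificity"`, `"associates"`, `"supergroups"`.
#' @param quiet suppress progress messages.
#' @return invisible list with `groups` (the final `group_set`), `pep_db`,
#'   `specificity`, `associates`, `supergroups`, `manifest`.
#' @export
run_pipeline <- function(config_path, out_dir = NULL, skip = character(0),
                         quiet = FALSE) {
  t_all <- list()
  tic <- function() proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    t0 <- tic()
    r <- force(expr)
    t_all[[name]] <<- round(tic() - t0, 3)
    if (!quiet) msg_info("stage %-22s %8.2fs", name, t_all[[name]])
    r
  }
  cf <- if (is.character(config_path)) read_pipeline_config(config_path)
        else config_path
  config <- cf$config
  out_dir <- out_dir %||% cf$out_dir %||% stop("no out_dir given")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  pep_sets <- stage("read_inputs", {
    lapply(stats::setNames(cf$species, cf$species), function(sp)
      read_peptides(cf$inputs$peptides[[sp]], sp))
  })
  pep_db <- build_pep_db(pep_sets)
  ref_tables <- lapply(cf$reference_species, function(ref)
    read_ortholog_table(cf$inputs$ortholog_table[[ref]], ref))

  gs <- stage("seed_groups",
              seed_groups(ref_tables, NULL, pep_db, NULL, config))
  gs <- stage("assign_exclusive", assign_exclusive(gs, config))
  gs <- stage("prune_sparse", prune_sparse(gs, config))
  sp_order <- config$species_order
  gs <- stage("optimize", {
    for (gid in sort(names(gs$groups))) {
      if (gs$groups[[gid]]$status == "discarded") next
      gs$groups[[gid]] <- optimize_group(gs$groups[[gid]], config,
                                         pep_db, sp_order)
    }
    gs
  })
  gs <- stage("rescue_unassigned",
              rescue_from_unassigned(gs, pep_db, config, sp_order))

  adopted <- NULL
  if (!("rescue" %in% skip) && length(cf$inputs$genome) > 0L) {
    res <- stage("gene_rescue", {
      genomes <- lapply(cf$inputs$genome, identity)
      annotations <- lapply(
        stats::setNames(names(cf$inputs$gff), names(cf$inputs$gff)),
        function(sp) read_annotations(cf$inputs$gff[[sp]], sp))
      rescue_groups(gs, genomes, annotations, pep_db, config, sp_order)
    })
    gs <- res$gs; pep_db <- res$pep_db; adopted <- res$adopted
  }
  gs <- stage("finalize",
              finalize_universal(gs, config, pep_db, sp_order))

  spec_tab <- NULL
  panel <- NULL
  if (!("specificity" %in% skip) && length(cf$inputs$outgroups) > 0L) {
    spec_tab <- stage("specificity", {
      og_sets <- lapply(
        stats::setNames(names(cf$inputs$outgroups),
                        names(cf$inputs$outgroups)),
        function(sp) read_peptides(cf$inputs$outgroups[[sp]]$path, sp))
      og_levels <- vapply(cf$inputs$outgroups, `[[`, "", "level")
      panel <- outgroup_panel(og_sets, og_levels)
      specificity_table(gs, panel, config)
    })
  }

  associates <- if (!("associates" %in% skip))
    stage("associates", assign_associates(gs, pep_db, config)) else NULL
  supergroups <- if (!("supergroups" %in% skip))
    stage("supergroups", find_supergroups(gs, pep_db, config)) else NULL

  stage("write_outputs", {
    write_group_tables(gs, spec_tab, out_dir, pep_db, config)
    if (!is.null(associates))
      utils::write.table(associates, file.path(out_dir, "associates.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(supergroups)) {
      sg <- data.frame(
        supergroup_id = rep(sprintf("SG%03d", seq_along(supergroups)),
                            vapply(supergroups, length, 0L)),
        group_id = unlist(supergroups) %||% character(0))
      utils::write.table(sg, file.path(out_dir, "supergroups.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    disc <- do.call(rbind, c(lapply(
      gs$groups[order(names(gs$groups))], function(g)
        if (g$status == "discarded")
          data.frame(group_id = g$group_id, reason = g$reason,
                     stringsAsFactors = FALSE)),
      list(make.row.names = FALSE)))
    if (is.null(disc))
      disc <- data.frame(group_id = character(), reason = character())
    utils::write.table(disc, file.path(out_dir, "discarded.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    subs <- do.call(rbind, c(lapply(
      gs$groups[order(names(gs$groups))], function(g) g$substitutions),
      list(make.row.names = FALSE)))
    if (is.null(subs))
      subs <- data.frame(group_id = character(), pass = integer(),
                         species = character(), old_pep = character(),
                         new_pep = character(), delta_R = numeric())
    utils::write.table(subs, file.path(out_dir, "substitutions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(adopted))
      write_rescued(adopted, file.path(out_dir, "rescued.gff3"),
                    file.path(out_dir, "rescued.fasta"), pep_db)
    NULL
  })

  input_files <- unlist(cf$inputs, use.names = FALSE)
  input_files <- vapply(input_files, function(x)
    if (is.list(x)) x$path else x, "")
  manifest <- list(
    package_version = as.character(utils::packageVersion("univgroups")),
    config = unclass(config),
    species = cf$species,
    reference_species = cf$reference_species,
    input_digests = as.list(tools::md5sum(
      input_files[file.exists(input_files)])),
    stage_seconds = t_all,
    n_groups_seeded = length(gs$groups),
    n_groups_universal = length(universal_groups(gs)),
    outputs = sort(list.files(out_dir, recursive = TRUE)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(groups = gs, pep_db = pep_db, specificity = spec_tab,
                 associates = associates, supergroups = supergroups,
                 outgroup_panel = panel, manifest = manifest,
                 out_dir = out_dir))
}

#' Command-line entry point
#'
#' Subcommands: `simulate --seed S --out DIR` (write a synthetic dataset)
#' and `run --config FILE [--out DIR] [--skip stage,...]` (run the
#' pipeline). Returns the exit code: 0 on success, 2 on a config/usage
#' error, 3 on a stage failure.
#'
#' @param args character vector of command-line arguments.
#' @return integer exit code, invisibly.
#' @export
univgroups_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  getopt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) == 0L || i[1] == length(args)) return(default)
    args[i[1] + 1L]
  }
  code <- tryCatch({
    if (length(args) == 0L)
      stopf("usage: univgroups <simulate|run> [options]")
    cmd <- args[1]
    if (cmd == "simulate") {
      out <- getopt("--out")
      if (is.null(out)) stopf("simulate: --out is required")
      seed <- as.integer(getopt("--seed", "1"))
      simulate_dataset(sim_config(seed = seed), out)
      0L
    } else if (cmd == "run") {
      cfgp <- getopt("--config")
      if (is.null(cfgp)) stopf("run: --config is required")
      skip <- getopt("--skip", "")
      skip <- if (nzchar(skip)) strsplit(skip, ",")[[1]] else character(0)
      r <- tryCatch(
        run_pipeline(cfgp, out_dir = getopt("--out"), skip = skip),
        error = function(e) {
          message("stage failure: ", conditionMessage(e)); NULL
        })
      if (is.null(r)) 3L else 0L
    } else stopf("unknown subcommand: %s", cmd)
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    2L
  })
  invisible(code)
}
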