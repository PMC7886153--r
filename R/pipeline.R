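# End-to-end orchestration: curate -> dereplicate -> base composition ->
# windows -> per-window trees -> SuperTRI -> calibration export, with a
# machine-readable manifest. Stages only consume files/objects listed in
# the manifest, so a run is reproducible and each stage re-runnable.

#' Validate a pipeline run configuration
#'
#' A run configuration is a named list (or YAML file) with entries:
#' `alignment` (path) or `alignment_object`; optional `species` /
#' `family` TSV path (columns `taxon`, `species`, `family`); `mask`
#' (list of intervals); `drop_singleton_indels` (logical);
#' `recode` (`"none"`/`"tv"`); `derep_threshold`; `windows_k`;
#' `tree_source` (`"builtin"` or a vector of tree files); `boot_reps`
#' (per-window bootstrap replicates); `supertri` (list: `floor`,
#' `n_reps`, `pp_min`, `sbp_min`, `search`, `n_restarts`);
#' `calibration_sheet` (path) and `calibration_strategy` (`"U"`/`"L"`);
#' `seed`; `out_dir`.
#'
#' @param config named list or YAML file path.
#' @return the validated config with defaults filled in.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  defaults <- list(mask = list(), drop_singleton_indels = TRUE,
                   recode = "none", derep_threshold = 0.01,
                   windows_k = 5L, tree_source = "builtin",
                   boot_reps = 100L,
                   supertri = list(), calibration_sheet = NULL,
                   calibration_strategy = "L", seed = 1L,
                   out_dir = tempfile("mitophylo_run_"))
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  st_def <- list(floor = 0.05, n_reps = 200L, pp_min = 0.95, sbp_min = 95,
                 search = "auto", n_restarts = 2L)
  for (nm in names(st_def)) {
    if (is.null(config$supertri[[nm]])) config$supertri[[nm]] <- st_def[[nm]]
  }
  # [[ avoids partial matching of `alignment` onto `alignment_object`
  if (is.null(config[["alignment"]]) &&
      is.null(config[["alignment_object"]])) {
    stop("config error: no alignment given", call. = FALSE)
  }
  for (f in c(config[["alignment"]], config$species_table,
              config$calibration_sheet,
              if (!identical(config$tree_source, "builtin"))
                config$tree_source)) {
    if (!is.null(f) && !file.exists(f)) {
      stop("config error: file not found: ", f, call. = FALSE)
    }
  }
  config
}

#' Run the full analysis pipeline
#'
#' Executes curation, dereplication, base-composition diagnostics,
#' windowing, per-window tree inference (or import), SuperTRI support
#' aggregation with node classification and conflict detection, and
#' calibration-prior export. All stage outputs are written under
#' `config$out_dir` together with `manifest.tsv` (stage, output, md5
#' checksum, parameters). Rerunning with an identical config reproduces
#' identical checksums.
#'
#' @param config a run configuration (see [validate_config()]).
#' @return list of in-memory stage results: `alignment`, `derep`,
#'   `composition`, `skews`, `windows`, `window_trees`, `mrp`,
#'   `supertree`, `sbp`, `support` (the NodeSupport table with conflicts),
#'   `calibrations`, `manifest`.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  note <- function(stage, path, params = "") {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = stage, output = basename(path),
      md5 = unname(tools::md5sum(path)), params = params,
      stringsAsFactors = FALSE)
  }

  # -- curation ------------------------------------------------------------
  aln <- if (!is.null(config[["alignment_object"]]))
           config[["alignment_object"]]
         else read_alignment(config[["alignment"]])
  if (!is.null(config$species_table)) {
    st <- utils::read.delim(config$species_table, stringsAsFactors = FALSE)
    aln$species <- stats::setNames(st$species, st$taxon)[aln_taxa(aln)]
    if (!is.null(st$family)) {
      aln$family <- stats::setNames(st$family, st$taxon)[aln_taxa(aln)]
    }
  }
  if (length(config$mask)) aln <- mask_regions(aln, config$mask)
  if (isTRUE(config$drop_singleton_indels)) {
    cur <- remove_singleton_indels(aln)
    aln <- cur$alignment
    utils::write.table(cur$report,
                       file.path(config$out_dir, "curation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    note("curate", file.path(config$out_dir, "curation.tsv"))
  }
  if (identical(config$recode, "tv")) aln <- recode_transversions(aln)
  write_alignment(aln, file.path(config$out_dir, "curated.fasta"))
  note("curate", file.path(config$out_dir, "curated.fasta"),
       paste0("recode=", config$recode))

  # -- dereplication and distance screen -----------------------------------
  dm <- p_distance_matrix(aln)
  derep <- NULL
  if (!is.null(aln$species)) {
    derep <- dereplicate(aln, threshold = config$derep_threshold, dm = dm)
    utils::write.table(derep$report,
                       file.path(config$out_dir, "derep.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    note("derep", file.path(config$out_dir, "derep.tsv"),
         paste0("threshold=", config$derep_threshold))
    keep <- derep$kept
    aln$matrix <- aln$matrix[keep, , drop = FALSE]
    aln$species <- aln$species[keep]
    if (!is.null(aln$family)) aln$family <- aln$family[keep]
    dm <- p_distance_matrix(aln)
    screen <- distance_screen(dm, aln$species)
    utils::write.table(screen,
                       file.path(config$out_dir, "distance_screen.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    note("derep", file.path(config$out_dir, "distance_screen.tsv"))
  }

  # -- base composition ----------------------------------------------------
  comp <- sk <- NULL
  pos <- attr(aln, "codon_positions")
  if (is.null(pos)) pos <- rep_len(1:3, aln_length(aln))
  comp <- codon_frequencies(aln, pos)
  sk <- skews(comp)
  utils::write.table(cbind(comp[, 1:13], sk[, -1L]),
                     file.path(config$out_dir, "composition.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  note("basecomp", file.path(config$out_dir, "composition.tsv"))

  # -- windows and per-window trees ----------------------------------------
  ws <- make_windows(aln_length(aln), config$windows_k)
  write_window_table(ws, file.path(config$out_dir, "windows.tsv"))
  note("windows", file.path(config$out_dir, "windows.tsv"),
       paste0("k=", config$windows_k))
  if (identical(config$tree_source, "builtin")) {
    subs <- slice_windows(aln, ws)
    samples <- lapply(seq_along(subs), function(i) {
      s <- bootstrap_trees(subs[[i]], n_reps = config$boot_reps,
                           seed = config$seed + i)
      s$label <- names(subs)[i]
      s
    })
  } else {
    samples <- lapply(config$tree_source, read_trees)
  }
  window_trees <- lapply(samples, function(s)
    ape::consensus(s$trees, p = 0.5))
  write_trees(window_trees,
              file.path(config$out_dir, "window_consensus.nwk"))
  note("windtrees", file.path(config$out_dir, "window_consensus.nwk"),
       paste0("boot=", config$boot_reps))

  # -- SuperTRI ------------------------------------------------------------
  lists <- lapply(samples, bipartition_frequencies,
                  floor = config$supertri$floor)
  mrp <- build_mrp(lists, taxa = sort(aln_taxa(aln)))
  write_mrp(mrp, file.path(config$out_dir, "mrp.nex"))
  note("supertri", file.path(config$out_dir, "mrp.nex"),
       paste0("floor=", config$supertri$floor))
  supertree <- mrp_supertree(mrp, search = config$supertri$search,
                             seed = config$seed,
                             n_restarts = config$supertri$n_restarts)
  boot <- supertri_bootstrap(mrp, n_reps = config$supertri$n_reps,
                             seed = config$seed,
                             search = config$supertri$search,
                             n_restarts = config$supertri$n_restarts)
  # main analysis: whole-alignment NJ bootstrap stands in for the
  # posterior sample
  main <- bootstrap_trees(aln, n_reps = config$boot_reps,
                          seed = config$seed)
  main$label <- "main"
  main_splits <- bipartition_frequencies(main,
                                         floor = config$supertri$floor)
  names(main_splits)[names(main_splits) == "support"] <- "pp"
  support <- node_support_table(main_splits, boot$sbp, window_trees,
                                taxa = sort(aln_taxa(aln)),
                                n_windows = length(window_trees))
  utils::write.table(support,
                     file.path(config$out_dir, "node_support.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  note("supertri", file.path(config$out_dir, "node_support.tsv"),
       paste0("n_reps=", config$supertri$n_reps, ";seed=", config$seed))
  ape::write.tree(supertree, file.path(config$out_dir, "supertree.nwk"))
  ape::write.tree(boot$consensus,
                  file.path(config$out_dir, "supertree_consensus.nwk"))
  note("supertri", file.path(config$out_dir, "supertree.nwk"))

  # -- calibrations --------------------------------------------------------
  calib <- NULL
  if (!is.null(config$calibration_sheet)) {
    calib <- load_calibration_sheet(config$calibration_sheet,
                                    strategy = config$calibration_strategy)
    export_priors(calib, file.path(config$out_dir, "priors.tsv"))
    note("calib", file.path(config$out_dir, "priors.tsv"),
         paste0("strategy=", config$calibration_strategy))
  }

  manifest <- do.call(rbind, manifest)
  utils::write.table(manifest, file.path(config$out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  list(alignment = aln, derep = derep, composition = comp, skews = sk,
       windows = ws, window_trees = window_trees, mrp = mrp,
       supertree = supertree, sbp = boot$sbp, support = support,
       calibrations = calib, manifest = manifest)
}
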