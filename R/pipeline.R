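#' Split one seed into named reproducible sub-seeds
#'
#' A single user-facing integer seed drives every stochastic stage; each
#' stage gets its own derived stream so pool, placement and island draws can
#' be varied independently. Derived seeds stay below 2^31.
#'
#' @param seed integer master seed.
#' @param names character vector naming the streams.
#' @return named integer vector of sub-seeds.
#' @export
split_seed <- function(seed, names = c("pool", "placement", "islands")) {
  set.seed(as.integer(seed))
  setNames(sample.int(.Machine$integer.max, length(names)), names)
}

#' Assemble a pipeline configuration
#'
#' Exactly one input route: either paths to an existing count table (+ areas,
#' optionally a tree), or a simulation block describing a synthetic
#' community. Flags mirror the CLI; values read from a JSON config file are
#' overridden by explicitly supplied arguments.
#'
#' @param table_path,areas_path,tree_path input files (TSV / TSV / Newick).
#' @param simulation list of simulation settings: `n_species`, `sad`,
#'   `total_individuals`, `alpha`, `meanlog`, `sdlog`, `n_samples`,
#'   `sample_area`, `total_area`, `multipliers`, `tree` (logical).
#' @param thresholds a [class_thresholds()].
#' @param n_models,group_sizes island-model parameters.
#' @param nested,within_replacement island-model flags
#'   (see [build_island_models()]).
#' @param A_T total area for the Coleman stage; default = sum of all source
#'   sample areas.
#' @param n_mode `"reads"` or `"incidence"`.
#' @param area_unit unit of the areas input, `"m2"` or `"cm2"`.
#' @param out_dir output directory (created if missing).
#' @param seed master seed.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(table_path = NULL, areas_path = NULL,
                            tree_path = NULL, simulation = NULL,
                            thresholds = class_thresholds(),
                            n_models = 8L, group_sizes = NULL,
                            nested = FALSE, within_replacement = FALSE,
                            A_T = NULL, n_mode = "reads",
                            area_unit = "m2",
                            out_dir = tempfile("passar_run_"), seed = 1L) {
  has_paths <- !is.null(table_path) || !is.null(areas_path)
  if (has_paths && !is.null(simulation))
    passar_error("provide input paths OR a simulation spec, not both",
                 "passar_bad_config")
  if (!has_paths && is.null(simulation))
    passar_error("provide input paths or a simulation spec",
                 "passar_bad_config")
  if (has_paths && (is.null(table_path) || is.null(areas_path)))
    passar_error("both table_path and areas_path are required",
                 "passar_bad_config")
  structure(list(table_path = table_path, areas_path = areas_path,
                 tree_path = tree_path, simulation = simulation,
                 thresholds = thresholds, n_models = as.integer(n_models),
                 group_sizes = group_sizes, nested = nested,
                 within_replacement = within_replacement,
                 A_T = A_T, n_mode = n_mode, area_unit = area_unit,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

sim_defaults <- list(n_species = 5000L, sad = "logseries",
                     total_individuals = 200000L, alpha = NULL,
                     meanlog = 0, sdlog = 1.5,
                     n_samples = 8L, sample_area = 0.36,
                     total_area = NULL, multipliers = 1, tree = FALSE)

#' Cross-check pipeline inputs
#'
#' Reports (without failing) ID mismatches between count table, areas and
#' tree: samples lacking an area, extra areas, table taxa missing from the
#' tree.
#'
#' @param table an [abundance_table()].
#' @param areas a [sample_areas()].
#' @param tree optional `phylo`.
#' @return character vector of diagnostics; empty when fully consistent.
#' @export
validate_inputs <- function(table, areas, tree = NULL) {
  diags <- character(0)
  no_area <- setdiff(rownames(table), names(areas))
  if (length(no_area) > 0L)
    diags <- c(diags, paste0("samples without an area: ",
                             paste(no_area, collapse = ", ")))
  extra <- setdiff(names(areas), rownames(table))
  if (length(extra) > 0L)
    diags <- c(diags, paste0("areas for unknown samples (ignored): ",
                             paste(extra, collapse = ", ")))
  if (!is.null(tree)) {
    lost <- setdiff(colnames(table), tree$tip.label)
    if (length(lost) > 0L)
      diags <- c(diags, paste0(length(lost), " table taxa missing from tree: ",
                               paste(utils::head(lost, 5L), collapse = ", "),
                               if (length(lost) > 5L) ", ..."))
  }
  diags
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full passive-sampling analysis pipeline
#'
#' Simulate-or-load, classify, build island models, fit SARs, compute the
#' class-stratified random-placement comparison, decompose beta diversity
#' (both families) and, when a tree is available, UniFrac matrices. Every
#' intermediate is written as TSV under `config$out_dir` next to a
#' machine-readable `report.json` and a human-readable `summary.txt`. Fully
#' deterministic given `config$seed`.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return a `run_report` list (alpha table, classification counts, SAR
#'   fits + mean slope, Coleman comparison, beta summaries, UniFrac
#'   matrices, provenance), invisibly mirrored on disk.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message("[passar] ", sprintf(...))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- split_seed(config$seed)

  # --- stage: inputs ---------------------------------------------------
  if (!is.null(config$simulation)) {
    sim <- modifyList(sim_defaults, config$simulation)
    say("simulating pool: %d species, %d individuals (%s)",
        sim$n_species, sim$total_individuals, sim$sad)
    pool <- generate_pool(pool_spec(
      n_species = sim$n_species, sad = sim$sad,
      total_individuals = sim$total_individuals, alpha = sim$alpha,
      meanlog = sim$meanlog, sdlog = sim$sdlog, seed = seeds[["pool"]]))
    island_areas <- setNames(rep(sim$sample_area, sim$n_samples),
                             sprintf("tw%d", seq_len(sim$n_samples)))
    total_area <- if (is.null(sim$total_area)) sum(island_areas) else sim$total_area
    placement <- placement_spec(island_areas, total_area,
                                multipliers = sim$multipliers,
                                seed = seeds[["placement"]])
    table <- simulate_passive_sampling(pool, placement)
    # drop species that landed nowhere: the observable table
    table <- abundance_table(unclass(table)[, colSums(table) > 0, drop = FALSE])
    areas <- sample_areas(island_areas, unit = config$area_unit)
    write_tsv(data.frame(taxon_id = pool$taxon_ids, abundance = pool$abundance),
              file.path(config$out_dir, "pool.tsv"))
    tree <- if (isTRUE(sim$tree))
      random_tree(colnames(table), seed = seeds[["placement"]]) else NULL
  } else {
    say("loading %s", config$table_path)
    table <- read_abundance_table(config$table_path)
    areas <- read_sample_areas(config$areas_path, unit = config$area_unit)
    tree <- if (!is.null(config$tree_path)) read_newick(config$tree_path) else NULL
  }
  write_abundance_table(table, file.path(config$out_dir, "table.tsv"))
  write_sample_areas(areas, file.path(config$out_dir, "areas.tsv"))
  if (!is.null(tree)) write_newick(tree, file.path(config$out_dir, "tree.nwk"))

  diags <- validate_inputs(table, areas, tree)
  for (d in diags) say("diagnostic: %s", d)

  # --- stage: alpha + classification ----------------------------------
  alpha <- alpha_diversity(table)
  write_tsv(alpha, file.path(config$out_dir, "alpha.tsv"))
  classification <- classify_abundance(table, config$thresholds)
  write_tsv(data.frame(taxon_id = names(classification),
                       class = as.character(classification)),
            file.path(config$out_dir, "classification.tsv"))
  class_counts <- base::table(classification)
  say("classes: %s", paste(names(class_counts), as.integer(class_counts),
                           sep = "=", collapse = ", "))

  # --- stage: island models + SAR -------------------------------------
  models <- build_island_models(table, areas, n_models = config$n_models,
                                group_sizes = config$group_sizes,
                                seed = seeds[["islands"]],
                                nested = config$nested,
                                within_replacement = config$within_replacement)
  manifest <- group_richness_points(models)
  write_tsv(manifest, file.path(config$out_dir, "islands_manifest.tsv"))
  area_scale <- if (config$area_unit == "m2") 1e4 else 1  # fit SARs in cm2
  sar <- fit_sar_models(models, area_scale = area_scale)
  write_tsv(sar, file.path(config$out_dir, "sar_fits.tsv"))
  zbar <- mean(sar$z)
  say("mean SAR slope over %d models: %.4f", nrow(sar), zbar)

  # --- stage: Coleman --------------------------------------------------
  A_T <- if (is.null(config$A_T)) sum(as.numeric(areas)) else config$A_T
  obs <- observed_class_richness(models, classification)
  pred <- predict_by_class(table, classification,
                           areas = sort(unique(obs$area)), A_T = A_T,
                           n_mode = config$n_mode, observed = obs)
  write_tsv(pred, file.path(config$out_dir, "coleman.tsv"))
  comparisons <- lapply(split(pred, pred$class), function(d) {
    d <- d[!is.na(d$observed), , drop = FALSE]
    if (nrow(d) < 2L) return(NULL)
    cmp <- compare_to_coleman(d$observed, d$expected)
    data.frame(class = d$class[1L], n_areas = nrow(d),
               mean_diff = cmp$mean_diff, sd_diff = cmp$sd_diff,
               t = cmp$t, df = cmp$df, p = cmp$p)
  })
  coleman_stats <- do.call(rbind, comparisons)
  write_tsv(coleman_stats, file.path(config$out_dir, "coleman_stats.tsv"))

  # --- stage: beta diversity ------------------------------------------
  beta <- lapply(c(sorensen = "sorensen", jaccard = "jaccard"), function(f) {
    tr <- beta_triplets(table, f)
    write_tsv(tr, file.path(config$out_dir, paste0("beta_", f, ".tsv")))
    summarize_decomposition(tr)
  })
  for (f in names(beta))
    say("%s replacement contribution: %.1f%%", f,
        beta[[f]]$replacement_contribution_pct)

  unifrac <- NULL
  if (!is.null(tree)) {
    unifrac <- lapply(c(unweighted = "unweighted", weighted = "weighted"),
                      function(metric) {
      d <- unifrac_matrix(table, tree, metric)
      write_tsv(data.frame(sample_id = rownames(d), as.data.frame(d),
                           check.names = FALSE),
                file.path(config$out_dir,
                          paste0("unifrac_", metric, ".tsv")))
      d
    })
  }

  # --- report ----------------------------------------------------------
  report <- list(
    provenance = list(
      package = "passar",
      version = as.character(utils::packageVersion("passar")),
      seed = config$seed, sub_seeds = as.list(seeds),
      n_samples = nrow(table), n_taxa = ncol(table),
      A_T = A_T, n_mode = config$n_mode, diagnostics = diags),
    alpha = alpha,
    class_counts = as.list(class_counts),
    sar_fits = sar, mean_slope = zbar,
    coleman_stats = coleman_stats,
    beta = beta)
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(c(
    sprintf("passar run (seed %d): %d samples x %d taxa", config$seed,
            nrow(table), ncol(table)),
    sprintf("mean SAR slope: %.4f over %d models", zbar, nrow(sar)),
    sprintf("replacement contribution: Sorensen %.1f%%, Jaccard %.1f%%",
            beta$sorensen$replacement_contribution_pct,
            beta$jaccard$replacement_contribution_pct),
    "per-class Coleman comparison (expected - observed):",
    utils::capture.output(print(coleman_stats, row.names = FALSE))),
    file.path(config$out_dir, "summary.txt"))
  report$models <- models
  report$unifrac <- unifrac
  invisible(structure(report, class = "run_report"))
}
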