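#' Pipeline settings
#'
#' Collects every threshold and knob the end-to-end run applies. Seeded
#' stochastic stages (GSEA permutation) refuse to run without a seed.
#'
#' @param contrasts Contrast names to analyze.
#' @param alpha1,alpha2 Per-experiment significance thresholds for the
#'   directional intersection.
#' @param filter_conditions Present-filter conditions (see
#'   [present_filter()]).
#' @param half_rule Present-filter half rule, `"ceil"` or `"floor"`.
#' @param gsea List of GSEA settings: `alpha`, `n_perm`, `metric`, `mode`.
#' @param clustering List: `metric` (`"correlation"`/`"euclidean"`), `k`.
#' @param onoff_mode `"welch"` or `"fisher"` p-values for on/off calls.
#' @param floor Signal floor before log2.
#' @param seed Integer seed for stochastic stages.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(contrasts = CONTRAST_NAMES,
                            alpha1 = 0.05, alpha2 = 0.05,
                            filter_conditions = default_filter_conditions(),
                            half_rule = "ceil",
                            gsea = list(alpha = 0.05, n_perm = 999,
                                        metric = "welch_t", mode = "gene"),
                            clustering = list(metric = "correlation", k = 3L),
                            onoff_mode = "welch",
                            floor = 1,
                            seed = NULL) {
  cfg <- list(contrasts = contrasts, alpha1 = alpha1, alpha2 = alpha2,
              filter_conditions = filter_conditions, half_rule = half_rule,
              gsea = utils::modifyList(
                list(alpha = 0.05, n_perm = 999, metric = "welch_t",
                     mode = "gene"), gsea),
              clustering = utils::modifyList(
                list(metric = "correlation", k = 3L), clustering),
              onoff_mode = onoff_mode, floor = floor, seed = seed)
  structure(cfg, class = "pipeline_config")
}

#' Read pipeline settings (and input paths) from a YAML file
#'
#' Recognized top-level keys: any [pipeline_config()] argument plus
#' `inputs` (paths per experiment: `signals`, `calls`, `samples`,
#' `platform_id`; plus `annotation` and `gmt`, a list of GMT paths) and
#' `out_dir`. Referenced files must exist at validation time.
#'
#' @param path YAML file path.
#' @return A `"pipeline_config"` with attributes `inputs` and `out_dir`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  cfg <- do.call(pipeline_config, raw[intersect(names(raw), known)])
  if (!is.null(raw$inputs)) {
    files <- unlist(lapply(raw$inputs, function(x)
      if (is.list(x)) x[setdiff(names(x), "platform_id")] else x))
    files <- files[!vapply(files, is.null, logical(1L))]
    missing <- files[!file.exists(unlist(files))]
    if (length(missing))
      stop("configured input file not found: ", missing[[1L]], call. = FALSE)
    attr(cfg, "inputs") <- raw$inputs
  }
  attr(cfg, "out_dir") <- raw$out_dir
  cfg
}

#' Run the full replication pipeline
#'
#' Executes filter, differential expression, directional replication with
#' on/off calls, GSEA and array clustering over the two experiments, and
#' writes every result table plus `manifest.json` (config hash, seed,
#' package version, per-stage record counts, file list). Reruns with the
#' same inputs and config are byte-identical.
#'
#' @param exp1,exp2 The two `"expression_experiment"`s (experiment 1 on the
#'   nested platform).
#' @param annotation Probe annotation covering both platforms.
#' @param gene_sets A `"gene_set_collection"` or `NULL` to skip GSEA.
#' @param out_dir Output directory.
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results of every stage:
#'   `filters`, `differential`, `replication` (per contrast), `onoff`,
#'   `gsea`, `trees`, `manifest`.
#' @export
run_pipeline <- function(exp1, exp2, annotation, gene_sets = NULL, out_dir,
                         config = pipeline_config()) {
  if (!is.null(gene_sets) && is.null(config$seed))
    stop("config error: `seed` is mandatory when the GSEA stage is enabled",
         call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  exps <- list(exp1 = exp1, exp2 = exp2)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  filters <- stage("filter", lapply(exps, present_filter,
                                    conditions = config$filter_conditions,
                                    half_rule = config$half_rule))

  shared_platform <- intersect(probe_ids(exp1), probe_ids(exp2))
  runnable <- Filter(function(cn) {
    ct <- make_contrast(cn)
    all(vapply(exps, function(e)
      length(samples_in_groups(e, ct$ref)) >= 2L &&
        length(samples_in_groups(e, ct$test)) >= 2L, logical(1L)))
  }, config$contrasts)

  de <- stage("differential", {
    out <- list()
    for (en in names(exps)) for (cn in runnable) {
      tab <- differential_table(
        exps[[en]], cn,
        alpha = if (en == "exp1") config$alpha1 else config$alpha2,
        probes = filters[[en]]$retained_probe_ids, floor = config$floor)
      tab <- data.frame(experiment = en, tab, stringsAsFactors = FALSE)
      out[[paste(en, cn, sep = ".")]] <- tab
    }
    out
  })

  replication <- stage("replication", {
    lapply(stats::setNames(nm = runnable), function(cn) {
      shared <- intersect(shared_platform,
                          intersect(filters$exp1$retained_probe_ids,
                                    filters$exp2$retained_probe_ids))
      directional_intersection(
        de[[paste("exp1", cn, sep = ".")]],
        de[[paste("exp2", cn, sep = ".")]],
        shared_probes = shared,
        alpha1 = config$alpha1, alpha2 = config$alpha2,
        annotation = annotation)
    })
  })

  onoff <- stage("onoff", {
    do.call(rbind, unlist(recursive = FALSE, lapply(names(exps), function(en)
      lapply(runnable, function(cn) {
        oo <- onoff_calls(exps[[en]], cn,
                          de_records = de[[paste(en, cn, sep = ".")]],
                          mode = config$onoff_mode, annotation = annotation)
        if (nrow(oo)) data.frame(experiment = en, oo,
                                 stringsAsFactors = FALSE)
        else NULL
      }))))
  })

  gsea <- if (is.null(gene_sets)) NULL else
    stage("gsea", gsea_campaign(
      exp1, exp2, gene_sets, annotation, contrasts = runnable,
      alpha = config$gsea$alpha, n_perm = config$gsea$n_perm,
      metric = config$gsea$metric, mode = config$gsea$mode,
      seed = config$seed,
      filter_conditions = config$filter_conditions, floor = config$floor))

  trees <- stage("clustering", lapply(exps, cluster_arrays,
                                      metric = config$clustering$metric,
                                      floor = config$floor))

  files <- write_results_tables(
    list(differential = do.call(rbind, unname(de)),
         replication = replication, onoff = onoff,
         gsea = if (is.null(gsea)) NULL else gsea$results),
    out_dir)
  for (en in names(trees)) {
    p <- file.path(out_dir, paste0("dendrogram_", en, ".nwk"))
    writeLines(as_newick(trees[[en]]), p)
    files <- c(files, p)
    assign_ <- data.frame(sample_id = names(cut_tree(trees[[en]],
                                                     config$clustering$k)),
                          cluster = unname(cut_tree(trees[[en]],
                                                    config$clustering$k)))
    p <- file.path(out_dir, paste0("cluster_assignments_", en, ".tsv"))
    utils::write.table(assign_, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, p)
  }
  p <- file.path(out_dir, "filter_report.json")
  jsonlite::write_json(lapply(filters, function(f)
    list(n_input = f$n_input, n_retained = f$n_retained,
         fraction_retained = f$fraction_retained)),
    p, auto_unbox = TRUE, digits = NA)
  files <- c(files, p)
  p <- file.path(out_dir, "replication_report.json")
  jsonlite::write_json(lapply(replication, function(r)
    r[setdiff(names(r), "shared_records")]), p, auto_unbox = TRUE,
    digits = NA)
  files <- c(files, p)

  manifest <- list(
    package_version = as.character(utils::packageVersion("replicaseq")),
    seed = config$seed,
    config_hash = config_hash(config),
    stages = list(
      filter = lapply(filters, `[[`, "n_retained"),
      differential = vapply(de, nrow, integer(1L)),
      replication = list(
        shared = vapply(replication, `[[`, integer(1L), "n_observed"),
        onoff = if (is.null(onoff)) 0L else nrow(onoff)),
      gsea = if (is.null(gsea)) 0L else nrow(gsea$results),
      clustering = vapply(trees, function(t) length(t$labels), integer(1L))),
    thresholds = list(alpha1 = config$alpha1, alpha2 = config$alpha2,
                      gsea_alpha = config$gsea$alpha,
                      half_rule = config$half_rule),
    files = basename(files))
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  invisible(list(filters = filters, differential = de,
                 replication = replication, onoff = onoff, gsea = gsea,
                 trees = trees, manifest = manifest))
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Write a simulated experiment pair as standard pipeline inputs
#'
#' Emits per-experiment `signals.tsv`, `calls.tsv`, `samples.tsv`, a shared
#' `annotation.tsv`, `genesets.gmt` and `ground_truth.json` under `dir`.
#'
#' @param sim Output of [simulate_experiment_pair()].
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_experiment(sim$exp1, file.path(dir, "exp1"))
  write_experiment(sim$exp2, file.path(dir, "exp2"))
  utils::write.table(sim$annotation, file.path(dir, "annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sim$gene_sets))
    write_gmt(sim$gene_sets, file.path(dir, "genesets.gmt"))
  truth <- sim$truth
  truth$true_log2_effect <- truth$true_log2_effect[truth$true_log2_effect != 0]
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = FALSE, digits = NA)
  invisible(dir)
}
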