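format_error <- function(path, line, msg) {
  stop(sprintf("%s:%s: %s", path, if (is.null(line)) "?" else line, msg),
       call. = FALSE)
}

read_tsv_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) format_error(path, 1L, "expected probe_id plus >=1 sample column")
  ids <- as.character(df[[1L]])
  dup <- which(duplicated(ids))
  if (length(dup))
    format_error(path, dup[1L] + 1L, paste0("duplicate probe id '", ids[dup[1L]], "'"))
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- ids
  m
}

#' Read one experiment from its TSV triplet
#'
#' Expects `signals_path` and `calls_path` to be probe x sample matrices
#' (first column probe id, header row sample ids, tab-separated) and
#' `samples_path` a two-column table `sample_id`, `group` with groups
#' restricted to [GROUP_LABELS]. Shapes, orderings and value domains are
#' validated strictly; any violation raises an error naming file and line.
#'
#' @param signals_path,calls_path,samples_path Paths to the three TSV files.
#' @param platform_id Platform name stored on the experiment.
#' @return An `"expression_experiment"`.
#' @seealso [write_experiment()]
#' @export
read_experiment <- function(signals_path, calls_path, samples_path,
                            platform_id) {
  signal <- read_tsv_matrix(signals_path)
  if (!is.numeric(signal))
    format_error(signals_path, NULL, "non-numeric signal value")
  neg <- which(signal < 0, arr.ind = TRUE)
  if (nrow(neg))
    format_error(signals_path, neg[1L, 1L] + 1L,
                 sprintf("negative signal for probe '%s'",
                         rownames(signal)[neg[1L, 1L]]))
  calls_df <- read_tsv_matrix(calls_path)
  calls <- matrix(as.character(calls_df), nrow(calls_df), ncol(calls_df),
                  dimnames = dimnames(calls_df))
  if (!identical(dim(calls), dim(signal)))
    format_error(calls_path, NULL,
                 sprintf("shape mismatch: calls are %dx%d but signals are %dx%d",
                         nrow(calls), ncol(calls), nrow(signal), ncol(signal)))
  if (!identical(rownames(calls), rownames(signal)))
    format_error(calls_path,
                 which(rownames(calls) != rownames(signal))[1L] + 1L,
                 "probe row order differs from signals file")
  if (!identical(colnames(calls), colnames(signal)))
    format_error(calls_path, 1L, "sample column order differs from signals file")
  bad <- which(!(calls %in% DETECTION_CALLS), arr.ind = FALSE)
  if (length(bad))
    format_error(calls_path, ((bad[1L] - 1L) %% nrow(calls)) + 2L,
                 sprintf("invalid detection call '%s'", calls[bad[1L]]))

  samp <- utils::read.delim(samples_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(samp)))
    format_error(samples_path, 1L, "expected columns sample_id, group")
  bad <- which(!(samp$group %in% GROUP_LABELS))
  if (length(bad))
    format_error(samples_path, bad[1L] + 1L,
                 sprintf("unknown group label '%s'", samp$group[bad[1L]]))
  missing <- setdiff(colnames(signal), samp$sample_id)
  if (length(missing))
    format_error(samples_path, NULL,
                 paste0("no group for sample '", missing[1L], "'"))
  groups <- stats::setNames(samp$group, samp$sample_id)[colnames(signal)]
  expression_experiment(platform_id, signal, calls, groups)
}

#' Write one experiment as its TSV triplet
#'
#' Inverse of [read_experiment()]: writes `signals.tsv`, `calls.tsv` and
#' `samples.tsv` into `dir`. All outputs are UTF-8, tab-separated, LF-ended.
#'
#' @param exp An `"expression_experiment"`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_experiment <- function(exp, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("signals.tsv", "calls.tsv", "samples.tsv"))
  write_matrix_tsv(exp$signal, paths[1L])
  write_matrix_tsv(exp$detection, paths[2L])
  utils::write.table(
    data.frame(sample_id = sample_ids(exp), group = unname(exp$groups)),
    paths[3L], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

write_matrix_tsv <- function(m, path) {
  df <- data.frame(probe_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Construct a gene-set collection
#'
#' @param name Character vector of unique set names.
#' @param description Character vector of set descriptions.
#' @param members List of character vectors of member gene ids (non-empty).
#' @param database Database label per set, one of `early_development`,
#'   `stem_cell`, `custom`.
#' @return A data-frame-backed object of class `"gene_set_collection"` with
#'   columns `name`, `description`, `database` and list-column `members`.
#' @export
gene_set_collection <- function(name, description, members,
                                database = "custom") {
  stopifnot(length(name) == length(members),
            length(description) == length(name))
  dup <- which(duplicated(name))
  if (length(dup))
    stop("duplicate set name: ", name[dup[1L]], call. = FALSE)
  if (any(lengths(members) == 0L))
    stop("gene sets must have >= 1 member", call. = FALSE)
  database <- rep_len(database, length(name))
  bad <- setdiff(unique(database), c("early_development", "stem_cell", "custom"))
  if (length(bad))
    stop("unknown database label: ", bad[1L], call. = FALSE)
  out <- data.frame(name = name, description = description,
                    database = database, stringsAsFactors = FALSE)
  out$members <- lapply(members, as.character)
  class(out) <- c("gene_set_collection", "data.frame")
  out
}

#' Read a GMT gene-set file
#'
#' GMT dialect: one set per line, `name TAB description TAB member TAB
#' member ...`. Members duplicated within a set are deduplicated with a
#' warning; a line with fewer than three fields or a duplicated set name is
#' a format error naming file and line.
#'
#' @param path Path to the GMT file.
#' @param database Database label attached to every set in the file.
#' @return A `"gene_set_collection"`.
#' @export
read_gmt <- function(path, database = "custom") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    format_error(path, short[1L], "GMT line has fewer than 3 fields")
  name <- vapply(fields, `[[`, character(1L), 1L)
  dup <- which(duplicated(name))
  if (length(dup))
    format_error(path, dup[1L], paste0("duplicate set name '", name[dup[1L]], "'"))
  members <- lapply(fields, function(f) f[-(1:2)])
  ndup <- vapply(members, anyDuplicated, integer(1L))
  if (any(ndup > 0L)) {
    warning(sprintf("%s: deduplicated members within %d set(s)",
                    path, sum(ndup > 0L)), call. = FALSE)
    members <- lapply(members, unique)
  }
  gene_set_collection(name = name,
                      description = vapply(fields, `[[`, character(1L), 2L),
                      members = members, database = database)
}

#' Write a gene-set collection as GMT
#' @param collection A `"gene_set_collection"`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(seq_len(nrow(collection)), function(i) {
    paste(c(collection$name[i], collection$description[i],
            collection$members[[i]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a probe annotation table
#'
#' Expects columns `probe_id`, `gene_symbol`, `on_platform_A` (logical or
#' 0/1). Gene symbols may be empty and may be shared by multiple probes.
#'
#' @param path Path to annotation.tsv.
#' @return A data.frame.
#' @export
read_annotation <- function(path) {
  ann <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("probe_id", "gene_symbol", "on_platform_A") %in% names(ann)))
    format_error(path, 1L,
                 "expected columns probe_id, gene_symbol, on_platform_A")
  dup <- which(duplicated(ann$probe_id))
  if (length(dup))
    format_error(path, dup[1L] + 1L,
                 paste0("duplicate probe id '", ann$probe_id[dup[1L]], "'"))
  ann$on_platform_A <- as.logical(ann$on_platform_A)
  ann
}

#' Write the pipeline result tables
#'
#' Emits `differential.tsv` (per-probe Welch records for every contrast and
#' experiment run), `replicated_genes.tsv` (gene symbol plus per-experiment
#' signed fold change and direction), `onoff.tsv` (probe, p-value, On/Off,
#' subgroup contrast) and `gsea.tsv` (set, contrast, per-experiment p,
#' enrichment direction, semicolon-joined leading-edge genes). Row order is
#' deterministic: ascending p, ties broken by id.
#'
#' @param results A named list with any of `differential` (data.frame),
#'   `replication` (a `"replication_report"` or list of them), `onoff`
#'   (data.frame), `gsea` (data.frame as returned in
#'   `gsea_campaign()$results` merged across experiments). Missing elements
#'   yield header-only files.
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
write_results_tables <- function(results, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ok <- dir.exists(out_dir) && file.access(out_dir, 2L) == 0L
  if (!ok) stop("cannot write to directory: ", out_dir, call. = FALSE)

  empty <- function(cols) {
    df <- as.data.frame(stats::setNames(rep(list(character(0L)), length(cols)),
                                        cols))
    df
  }
  order_by <- function(df, pcol, idcol) {
    if (nrow(df)) df[order(df[[pcol]], df[[idcol]]), , drop = FALSE] else df
  }
  wt <- function(df, file) {
    utils::write.table(df, file.path(out_dir, file), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    file.path(out_dir, file)
  }

  de <- results$differential
  if (is.null(de))
    de <- empty(c("experiment", "contrast", "probe_id", "mean_log2_ref",
                  "mean_log2_test", "welch_t", "welch_df", "p_value",
                  "signed_fold", "direction"))
  de <- order_by(de, "p_value", "probe_id")
  p1 <- wt(de, "differential.tsv")

  rep_ <- results$replication
  if (!is.null(rep_) && inherits(rep_, "replication_report"))
    rep_ <- list(rep_)
  shared <- if (is.null(rep_)) NULL else
    do.call(rbind, lapply(rep_, function(r) r$shared_records))
  if (is.null(shared))
    shared <- empty(c("probe_id", "gene_symbol", "contrast", "fold_exp1",
                      "fold_exp2", "p_exp1", "p_exp2", "direction"))
  shared <- order_by(shared, "p_exp1", "probe_id")
  p2 <- wt(shared, "replicated_genes.tsv")

  onoff <- results$onoff
  if (is.null(onoff))
    onoff <- empty(c("probe_id", "gene_symbol", "contrast", "status",
                     "p_value"))
  onoff <- order_by(onoff, "p_value", "probe_id")
  p3 <- wt(onoff, "onoff.tsv")

  gsea <- results$gsea
  if (is.null(gsea))
    gsea <- empty(c("set", "contrast", "experiment", "size_in_universe",
                    "es_peak", "peak_position", "p_value", "enriched_in",
                    "leading_edge"))
  gsea <- order_by(gsea, "p_value", "set")
  p4 <- wt(gsea, "gsea.tsv")

  invisible(c(p1, p2, p3, p4))
}
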