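#' Analytic null probability of a directional two-experiment overlap
#'
#' Two independent experiments each call a null gene significant with
#' probability `alpha1` and `alpha2`; the chance the calls also agree in
#' up/down direction is 1/2, so the joint probability is
#' `alpha1 * alpha2 / 2` (0.00125 at the 0.05/0.05 defaults).
#'
#' @param alpha1,alpha2 Per-experiment significance thresholds in (0, 1].
#' @return The joint probability.
#' @export
joint_null_probability <- function(alpha1 = 0.05, alpha2 = 0.05) {
  stopifnot(alpha1 >= 0, alpha1 <= 1, alpha2 >= 0, alpha2 <= 1)
  alpha1 * alpha2 / 2
}

#' Expected chance overlap between two experiments
#'
#' @param n_common Number of genes tested in both experiments.
#' @param alpha1,alpha2 Per-experiment thresholds.
#' @return `n_common * alpha1 * alpha2 / 2` (unrounded; round for display).
#' @export
expected_overlap <- function(n_common, alpha1 = 0.05, alpha2 = 0.05) {
  n_common * joint_null_probability(alpha1, alpha2)
}

#' Overlap false discovery rate
#'
#' FDR of a replicated gene (or set) list: the overlap expected under the
#' null divided by the overlap observed. Undefined (NA) when nothing was
#' observed.
#'
#' @param expected Expected null overlap count.
#' @param observed Observed overlap count.
#' @return The FDR (may exceed 1 if fewer observed than expected).
#' @export
overlap_fdr <- function(expected, observed) {
  if (observed <= 0) return(NA_real_)
  expected / observed
}

#' Phenotype incidence as a printed percentage
#'
#' Reports `k` affected out of `n` as a percentage rounded to `digits`
#' decimals, the way incidence figures are printed (34 of 127 -> 27).
#'
#' @param k Number affected.
#' @param n Total.
#' @param digits Decimals to keep (default 0).
#' @return The rounded percentage.
#' @export
percent_incidence <- function(k, n, digits = 0) {
  stopifnot(n > 0, k >= 0, k <= n)
  round(100 * k / n, digits)
}

#' Directional intersection of two experiments' gene lists
#'
#' A probe replicates iff it is significant in both experiments
#' (`p1 <= alpha1`, `p2 <= alpha2`) with the same non-null direction of
#' change. The expected chance overlap is analytic
#' (`n_common * alpha1 * alpha2 / 2`) and the replication FDR is
#' expected / observed.
#'
#' @param de1,de2 Differential tables from [differential_table()] for the
#'   same contrast in the two experiments.
#' @param shared_probes Probe ids tested in both experiments (present-
#'   filtered in each and on the shared platform).
#' @param alpha1,alpha2 Per-experiment thresholds in (0, 1].
#' @param annotation Optional annotation data.frame (`probe_id`,
#'   `gene_symbol`) used to attach symbols to the shared records.
#' @return A `"replication_report"` list: `contrast`, `n_common_tested`,
#'   `alpha1`, `alpha2`, `p_joint`, `expected_null`,
#'   `expected_null_rounded`, `n_observed`, `n_down`, `n_up`, `fdr` and
#'   `shared_records` (per-probe paired records).
#' @export
directional_intersection <- function(de1, de2, shared_probes = NULL,
                                     alpha1 = 0.05, alpha2 = 0.05,
                                     annotation = NULL) {
  stopifnot(alpha1 >= 0, alpha1 <= 1, alpha2 >= 0, alpha2 <= 1)
  if (is.null(shared_probes))
    shared_probes <- intersect(de1$probe_id, de2$probe_id)
  if (!length(shared_probes))
    stop("empty shared probe universe", call. = FALSE)
  for (de in list(de1, de2)) {
    missing <- setdiff(shared_probes, de$probe_id)
    if (length(missing))
      stop("differential table does not cover shared probe ", missing[1L],
           call. = FALSE)
  }
  i1 <- de1[match(shared_probes, de1$probe_id), ]
  i2 <- de2[match(shared_probes, de2$probe_id), ]
  dir1 <- ifelse(i1$p_value <= alpha1,
                 ifelse(i1$signed_fold < 0, "down", "up"), "none")
  dir2 <- ifelse(i2$p_value <= alpha2,
                 ifelse(i2$signed_fold < 0, "down", "up"), "none")
  hit <- dir1 != "none" & dir1 == dir2
  n_obs <- sum(hit)
  exp_null <- expected_overlap(length(shared_probes), alpha1, alpha2)

  shared <- data.frame(
    probe_id = shared_probes[hit],
    gene_symbol = rep(NA_character_, sum(hit)),
    contrast = i1$contrast[hit],
    fold_exp1 = i1$signed_fold[hit],
    fold_exp2 = i2$signed_fold[hit],
    p_exp1 = i1$p_value[hit],
    p_exp2 = i2$p_value[hit],
    direction = dir1[hit],
    stringsAsFactors = FALSE)
  if (!is.null(annotation))
    shared$gene_symbol <-
      annotation$gene_symbol[match(shared$probe_id, annotation$probe_id)]
  shared <- shared[order(shared$p_exp1, shared$probe_id), ]
  rownames(shared) <- NULL

  structure(
    list(contrast = if (nrow(i1)) i1$contrast[1L] else NA_character_,
         n_common_tested = length(shared_probes),
         alpha1 = alpha1, alpha2 = alpha2,
         p_joint = joint_null_probability(alpha1, alpha2),
         expected_null = exp_null,
         expected_null_rounded = round(exp_null),
         n_observed = n_obs,
         n_down = sum(dir1[hit] == "down"),
         n_up = sum(dir1[hit] == "up"),
         fdr = overlap_fdr(exp_null, n_obs),
         shared_records = shared),
    class = "replication_report")
}

#' @export
print.replication_report <- function(x, ...) {
  cat(sprintf("replication report (%s):\n", x$contrast))
  cat(sprintf("  %d probes tested in common; p_joint = %g\n",
              x$n_common_tested, x$p_joint))
  cat(sprintf("  expected by chance %.2f (~%d), observed %d (%d down / %d up)\n",
              x$expected_null, x$expected_null_rounded, x$n_observed,
              x$n_down, x$n_up))
  cat(sprintf("  FDR = %s\n",
              if (is.na(x$fdr)) "undefined (nothing observed)"
              else sprintf("%.3f", x$fdr)))
  invisible(x)
}

#' On/off presence calls for one contrast
#'
#' A probe is `off_in_test` when it satisfies the present rule (Present on
#' at least `ceiling(n/2)` arrays) in the reference arm and is Present on
#' zero test-arm arrays; `on_in_test` is the symmetric pattern. The
#' attached p-value is either the Welch p from the matching differential
#' record (`mode = "welch"`) or a Fisher exact test on the Present/Absent
#' counts (`mode = "fisher"`).
#'
#' @param exp An `"expression_experiment"` with detection calls.
#' @param contrast A [make_contrast()] result or name.
#' @param de_records Differential table for the same contrast (required for
#'   `mode = "welch"`).
#' @param mode `"welch"` (default) or `"fisher"`.
#' @param annotation Optional annotation for gene symbols.
#' @return data.frame `probe_id`, `gene_symbol`, `contrast`, `status`,
#'   `p_value`, sorted by p-value.
#' @export
onoff_calls <- function(exp, contrast, de_records = NULL,
                        mode = c("welch", "fisher"), annotation = NULL) {
  mode <- match.arg(mode)
  contrast <- as_contrast(contrast)
  ref <- samples_in_groups(exp, contrast$ref)
  test <- samples_in_groups(exp, contrast$test)
  if (!length(ref) || !length(test))
    stop("contrast arm absent from experiment", call. = FALSE)
  p_ref <- rowSums(exp$detection[, ref, drop = FALSE] == "P")
  p_test <- rowSums(exp$detection[, test, drop = FALSE] == "P")
  need_ref <- ceiling(length(ref) / 2)
  need_test <- ceiling(length(test) / 2)
  off <- p_ref >= need_ref & p_test == 0L
  on <- p_test >= need_test & p_ref == 0L
  idx <- which(off | on)
  if (!length(idx))
    return(data.frame(probe_id = character(0L), gene_symbol = character(0L),
                      contrast = character(0L), status = character(0L),
                      p_value = numeric(0L), stringsAsFactors = FALSE))
  ids <- probe_ids(exp)[idx]
  pval <- if (mode == "welch") {
    if (is.null(de_records))
      stop("mode = \"welch\" needs `de_records` for the same contrast",
           call. = FALSE)
    de_records$p_value[match(ids, de_records$probe_id)]
  } else {
    vapply(idx, function(i) {
      tab <- matrix(c(p_ref[i], length(ref) - p_ref[i],
                      p_test[i], length(test) - p_test[i]), 2L, 2L)
      stats::fisher.test(tab)$p.value
    }, numeric(1L))
  }
  out <- data.frame(
    probe_id = ids,
    gene_symbol = if (is.null(annotation)) NA_character_ else
      annotation$gene_symbol[match(ids, annotation$probe_id)],
    contrast = contrast$name,
    status = ifelse(off[idx], "off_in_test", "on_in_test"),
    p_value = pval,
    stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$probe_id), ]
  rownames(out) <- NULL
  out
}
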