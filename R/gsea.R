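#' Rank genes by association with a contrast
#'
#' Computes a per-probe association metric on log2 signals, oriented so
#' positive values mean higher expression in the reference arm (the
#' controls for the three control-based contrasts), collapses probes to
#' genes by maximum absolute metric, and sorts descending with ties broken
#' by gene id. The resulting list is the GSEA universe for the contrast.
#'
#' @param exp An `"expression_experiment"`.
#' @param contrast A [make_contrast()] result or name.
#' @param annotation Annotation data.frame (`probe_id`, `gene_symbol`)
#'   covering the probes ranked.
#' @param metric `"welch_t"` (default) or `"signal_to_noise"`
#'   ((mean_ref - mean_test) / (sd_ref + sd_test)). Genes with zero
#'   variance in both arms get metric 0 (noted via `message`).
#' @param probes Optional probe universe (e.g. the present-filtered set).
#' @param floor Signal floor for [log_transform()].
#' @return A `"ranked_list"`: `contrast`, `gene_ids` (best-to-worst for
#'   reference-high expression), `scores`, `orientation`, `ref_label`,
#'   `test_label`.
#' @export
rank_genes <- function(exp, contrast, annotation,
                       metric = c("welch_t", "signal_to_noise"),
                       probes = NULL, floor = 1) {
  metric <- match.arg(metric)
  contrast <- as_contrast(contrast)
  ref <- samples_in_groups(exp, contrast$ref)
  test <- samples_in_groups(exp, contrast$test)
  if (length(ref) < 2L || length(test) < 2L)
    stop(sprintf("contrast %s needs >= 2 samples per arm", contrast$name),
         call. = FALSE)
  logm <- log_transform(exp, floor)
  if (!is.null(probes)) logm <- logm[probes, , drop = FALSE]

  score <- if (metric == "welch_t") {
    st <- row_welch(logm, ref, test)
    s <- -st$welch_t                      # positive = higher in reference
    zero <- !is.finite(s) & st$mean_log2_ref == st$mean_log2_test
    if (any(zero)) {
      message(sum(zero), " gene(s) with zero variance in both arms: metric 0")
      s[zero] <- 0
    }
    s[!is.finite(s)] <- sign(s[!is.finite(s)]) * .Machine$double.xmax
    s
  } else {
    xr <- logm[, ref, drop = FALSE]; xt <- logm[, test, drop = FALSE]
    mr <- rowMeans(xr); mt <- rowMeans(xt)
    sr <- sqrt(rowSums((xr - mr)^2) / (length(ref) - 1))
    st_ <- sqrt(rowSums((xt - mt)^2) / (length(test) - 1))
    denom <- sr + st_
    zero <- denom == 0
    if (any(zero))
      message(sum(zero), " gene(s) with zero variance in both arms: metric 0")
    out <- (mr - mt) / ifelse(zero, 1, denom)
    out[zero] <- 0
    out
  }

  gene <- annotation$gene_symbol[match(rownames(logm), annotation$probe_id)]
  if (anyNA(gene))
    stop("annotation does not cover probe ",
         rownames(logm)[which(is.na(gene))[1L]], call. = FALSE)
  # collapse probes -> genes by max |metric|; ties by probe id
  o <- order(gene, -abs(score), rownames(logm))
  first <- !duplicated(gene[o])
  gene_ids <- gene[o][first]
  scores <- score[o][first]
  o2 <- order(-scores, gene_ids)
  structure(
    list(contrast = contrast$name, gene_ids = gene_ids[o2],
         scores = scores[o2], orientation = "forward",
         ref_label = contrast$ref_label, test_label = contrast$test_label),
    class = "ranked_list")
}

#' Flip the orientation of a ranked list
#'
#' Testing enrichment in the other arm of a contrast amounts to reversing
#' the ranking; this returns the exact reverse with negated scores and
#' swapped arm labels.
#'
#' @param ranked A `"ranked_list"`.
#' @return The reversed `"ranked_list"`.
#' @export
reverse_ranking <- function(ranked) {
  structure(
    list(contrast = ranked$contrast,
         gene_ids = rev(ranked$gene_ids),
         scores = rev(-ranked$scores),
         orientation = if (ranked$orientation == "forward") "reverse" else "forward",
         ref_label = ranked$test_label, test_label = ranked$ref_label),
    class = "ranked_list")
}

#' Running-sum enrichment score
#'
#' Unweighted Kolmogorov-Smirnov form: walking down the ranked list, a
#' gene-set member ("hit") increments the running sum by `1/n_hits`, a
#' non-member decrements it by `1/(N - n_hits)`. The enrichment score is
#' the maximum of the running sum (one-sided, top-enrichment only) and the
#' leading edge is the set members at ranks up to that maximum.
#'
#' @param ranked A `"ranked_list"`.
#' @param members Character vector of member gene ids. Members absent from
#'   the universe are dropped with a warning.
#' @return List: `es_profile` (running sum over ranks), `es_peak`,
#'   `peak_position` (first argmax), `leading_edge`, `n_hits`.
#' @export
enrichment_score <- function(ranked, members) {
  hits <- ranked$gene_ids %in% members
  n_hits <- sum(hits)
  n_absent <- length(unique(members)) - n_hits
  if (n_absent > 0L)
    warning(n_absent, " member(s) absent from the ranked universe; dropped",
            call. = FALSE)
  if (n_hits == 0L)
    stop("no gene-set member present in the ranked universe", call. = FALSE)
  N <- length(ranked$gene_ids)
  inc <- if (N == n_hits) rep(1 / n_hits, N)
         else ifelse(hits, 1 / n_hits, -1 / (N - n_hits))
  running <- cumsum(inc)
  peak_pos <- which.max(running)
  list(es_profile = running,
       es_peak = running[peak_pos],
       peak_position = peak_pos,
       leading_edge = ranked$gene_ids[seq_len(peak_pos)][hits[seq_len(peak_pos)]],
       n_hits = n_hits)
}

# ES peak from sorted member rank positions (1-based), without building the
# full profile: the maximum of the running sum always lies at a hit rank.
es_peak_from_ranks <- function(r, N, k) {
  if (k == N) return(1)
  r <- sort.int(r)
  i <- seq_len(k)
  max(i / k - (r - i) / (N - k))
}

#' Permutation p-value for a gene set's enrichment score
#'
#' Compares the observed enrichment-score peak with a null distribution of
#' peaks: `mode = "gene"` draws random member sets of equal size from the
#' ranked universe; `mode = "phenotype"` permutes the group labels of the
#' contrast's arrays and recomputes the ranking (falling back to full
#' enumeration of distinct relabellings when there are fewer than
#' `n_perm`). Sampled modes use `p = (1 + #{null >= observed}) /
#' (1 + n_perm)`; full enumeration uses the exact `#{null >= observed} /
#' n_distinct` (the identity relabelling is included, so p >= 1/n_distinct).
#'
#' @param exp An `"expression_experiment"`.
#' @param contrast A [make_contrast()] result or name.
#' @param members Member gene ids.
#' @param n_perm Number of permutations (>= 100).
#' @param mode `"gene"` (default) or `"phenotype"`.
#' @param seed Integer seed (required: the result must be reproducible).
#' @param annotation,metric,probes,floor Passed to [rank_genes()].
#' @return List: `p_value`, `es_peak`, `peak_position`, `leading_edge`,
#'   `n_perm_used`, `mode`.
#' @export
permutation_pvalue <- function(exp, contrast, members, n_perm = 999,
                               mode = c("gene", "phenotype"), seed,
                               annotation, metric = "welch_t",
                               probes = NULL, floor = 1) {
  mode <- match.arg(mode)
  if (n_perm < 100L) stop("n_perm must be >= 100", call. = FALSE)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  set.seed(seed)
  contrast <- as_contrast(contrast)
  ranked <- rank_genes(exp, contrast, annotation, metric = metric,
                       probes = probes, floor = floor)
  obs <- enrichment_score(ranked, members)
  N <- length(ranked$gene_ids)
  k <- obs$n_hits

  if (mode == "gene") {
    null_peaks <- gene_null_peaks(N, k, n_perm)
    p <- (1 + sum(null_peaks >= obs$es_peak)) / (1 + n_perm)
    n_used <- n_perm
  } else {
    arm_ref <- samples_in_groups(exp, contrast$ref)
    arm_test <- samples_in_groups(exp, contrast$test)
    arms <- c(arm_ref, arm_test)
    n_ref <- length(arm_ref)
    n_distinct <- choose(length(arms), n_ref)
    member_set <- unique(members)
    peak_for <- function(ref_idx) {
      perm_exp <- exp
      g <- perm_exp$groups
      # relabel: chosen arrays take the reference groups, rest the test side
      g[arms] <- contrast$test[1L]
      g[arms[ref_idx]] <- contrast$ref[1L]
      perm_exp$groups <- g
      pr <- rank_genes(perm_exp, contrast, annotation, metric = metric,
                      probes = probes, floor = floor)
      suppressWarnings(enrichment_score(pr, member_set)$es_peak)
    }
    if (n_distinct <= n_perm) {
      combos <- utils::combn(length(arms), n_ref)
      null_peaks <- apply(combos, 2L, peak_for)
      p <- sum(null_peaks >= obs$es_peak) / n_distinct
      n_used <- as.integer(n_distinct)
    } else {
      null_peaks <- vapply(seq_len(n_perm), function(i)
        peak_for(sample.int(length(arms), n_ref)), numeric(1L))
      p <- (1 + sum(null_peaks >= obs$es_peak)) / (1 + n_perm)
      n_used <- n_perm
    }
  }
  list(p_value = p, es_peak = obs$es_peak,
       peak_position = obs$peak_position, leading_edge = obs$leading_edge,
       n_perm_used = n_used, mode = mode)
}

# Null ES peaks for random member sets of size k in a universe of size N.
# The null depends only on (N, k), never on the scores, so campaigns cache
# these draws across sets, contrasts and orientations.
gene_null_peaks <- function(N, k, n_perm) {
  vapply(seq_len(n_perm), function(i)
    es_peak_from_ranks(sample.int(N, k), N, k), numeric(1L))
}

#' Run the full GSEA campaign over both experiments
#'
#' For every gene set, contrast and experiment, computes the one-sided
#' enrichment score in both contrast orientations, assigns each test the
#' orientation with the smaller permutation p-value (its `enriched_in`
#' direction), and summarizes cross-experiment set-level replication: a
#' (set, contrast) pair is shared when `p <= alpha` in both experiments
#' with the same direction. The expected chance-shared count is
#' `n_contrasts x n_sets x alpha^2 / 2` (each set counted once per
#' contrast) and the set-level FDR is expected / observed.
#'
#' @param exp1,exp2 The two experiments.
#' @param collection A `"gene_set_collection"`.
#' @param annotation Annotation covering both platforms.
#' @param contrasts Contrast names to run (default all four). A contrast
#'   missing a group in either experiment is skipped with a warning.
#' @param alpha Set-level significance threshold.
#' @param n_perm Permutations per test.
#' @param metric,mode Passed to the ranking/permutation machinery; gene
#'   mode is the default (phenotype permutation is nearly degenerate at
#'   these group sizes).
#' @param seed Integer seed (required).
#' @param filter_conditions Present-filter conditions defining each
#'   experiment's probe universe.
#' @param floor Signal floor.
#' @return List with `results` (data.frame: one row per set, contrast,
#'   experiment) and `report`, a `"set_replication_report"`
#'   (`n_tests_total`, `alpha`, `expected_shared`,
#'   `expected_shared_rounded`, `n_shared_observed`, `fdr`, `shared_sets`).
#' @export
gsea_campaign <- function(exp1, exp2, collection, annotation,
                          contrasts = CONTRAST_NAMES, alpha = 0.05,
                          n_perm = 999, metric = "welch_t",
                          mode = c("gene", "phenotype"), seed,
                          filter_conditions = default_filter_conditions(),
                          floor = 1) {
  mode <- match.arg(mode)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  set.seed(seed)
  exps <- list(exp1 = exp1, exp2 = exp2)
  universes <- lapply(exps, function(e)
    present_filter(e, filter_conditions)$retained_probe_ids)

  runnable <- vapply(contrasts, function(cn) {
    ct <- make_contrast(cn)
    all(vapply(exps, function(e)
      length(samples_in_groups(e, ct$ref)) >= 2L &&
        length(samples_in_groups(e, ct$test)) >= 2L, logical(1L)))
  }, logical(1L))
  if (any(!runnable))
    warning("skipping contrast(s) missing a group: ",
            paste(contrasts[!runnable], collapse = ", "), call. = FALSE)
  contrasts <- contrasts[runnable]
  if (!length(contrasts)) stop("no runnable contrast", call. = FALSE)

  # Pre-rank once per (experiment, contrast, orientation).
  rankings <- list()
  for (en in names(exps)) for (cn in contrasts) {
    fwd <- rank_genes(exps[[en]], cn, annotation, metric = metric,
                      probes = universes[[en]], floor = floor)
    rankings[[paste(en, cn, "fwd", sep = ".")]] <- fwd
    rankings[[paste(en, cn, "rev", sep = ".")]] <- reverse_ranking(fwd)
  }

  null_cache <- new.env(parent = emptyenv())
  cached_null <- function(N, k) {
    key <- paste(N, k, sep = ":")
    if (is.null(null_cache[[key]]))
      null_cache[[key]] <- gene_null_peaks(N, k, n_perm)
    null_cache[[key]]
  }

  # Phenotype mode: relabelled rankings shared by every set of a contrast.
  perm_rankings <- list()
  if (mode == "phenotype") {
    for (en in names(exps)) for (cn in contrasts) {
      perm_rankings[[paste(en, cn, sep = ".")]] <-
        phenotype_permuted_rankings(exps[[en]], cn, annotation, metric,
                                    universes[[en]], floor, n_perm)
    }
  }

  rows <- vector("list", nrow(collection) * length(contrasts) * 2L)
  ri <- 0L
  for (en in names(exps)) {
    for (cn in contrasts) {
      fwd <- rankings[[paste(en, cn, "fwd", sep = ".")]]
      rev_ <- rankings[[paste(en, cn, "rev", sep = ".")]]
      N <- length(fwd$gene_ids)
      pos_of <- stats::setNames(seq_len(N), fwd$gene_ids)
      for (si in seq_len(nrow(collection))) {
        members <- unique(collection$members[[si]])
        ranks_fwd <- unname(pos_of[members])
        ranks_fwd <- ranks_fwd[!is.na(ranks_fwd)]
        k <- length(ranks_fwd)
        ri <- ri + 1L
        if (k == 0L) {
          rows[[ri]] <- data.frame(
            set = collection$name[si], contrast = cn, experiment = en,
            size_in_universe = 0L, es_peak = NA_real_,
            peak_position = NA_integer_, p_value = NA_real_,
            enriched_in = NA_character_, leading_edge = "",
            stringsAsFactors = FALSE)
          next
        }
        es_fwd <- es_peak_from_ranks(ranks_fwd, N, k)
        ranks_rev <- N + 1L - ranks_fwd
        es_rev <- es_peak_from_ranks(ranks_rev, N, k)
        if (mode == "gene") {
          nulls <- cached_null(N, k)
          p_fwd <- (1 + sum(nulls >= es_fwd)) / (1 + n_perm)
          p_rev <- (1 + sum(nulls >= es_rev)) / (1 + n_perm)
        } else {
          pr <- perm_rankings[[paste(en, cn, sep = ".")]]
          peaks <- vapply(pr$rankings, function(r) {
            rk <- match(members, r$gene_ids)
            rk <- rk[!is.na(rk)]
            c(es_peak_from_ranks(rk, N, length(rk)),
              es_peak_from_ranks(N + 1L - rk, N, length(rk)))
          }, numeric(2L))
          if (pr$exhaustive) {
            p_fwd <- sum(peaks[1L, ] >= es_fwd) / ncol(peaks)
            p_rev <- sum(peaks[2L, ] >= es_rev) / ncol(peaks)
          } else {
            p_fwd <- (1 + sum(peaks[1L, ] >= es_fwd)) / (1 + ncol(peaks))
            p_rev <- (1 + sum(peaks[2L, ] >= es_rev)) / (1 + ncol(peaks))
          }
        }
        use_fwd <- p_fwd <= p_rev
        chosen <- if (use_fwd) fwd else rev_
        es <- suppressWarnings(enrichment_score(chosen, members))
        rows[[ri]] <- data.frame(
          set = collection$name[si], contrast = cn, experiment = en,
          size_in_universe = k,
          es_peak = es$es_peak, peak_position = es$peak_position,
          p_value = if (use_fwd) p_fwd else p_rev,
          enriched_in = chosen$ref_label,
          leading_edge = paste(es$leading_edge, collapse = ";"),
          stringsAsFactors = FALSE)
      }
    }
  }
  results <- do.call(rbind, rows[seq_len(ri)])

  r1 <- results[results$experiment == "exp1", ]
  r2 <- results[results$experiment == "exp2", ]
  key1 <- paste(r1$set, r1$contrast)
  key2 <- paste(r2$set, r2$contrast)
  m <- match(key1, key2)
  shared <- !is.na(r1$p_value) & !is.na(r2$p_value[m]) &
    r1$p_value <= alpha & r2$p_value[m] <= alpha &
    r1$enriched_in == r2$enriched_in[m]
  shared[is.na(shared)] <- FALSE
  n_tests_total <- length(contrasts) * nrow(collection)
  expected <- n_tests_total * alpha^2 / 2
  shared_sets <- data.frame(
    set = r1$set[shared], contrast = r1$contrast[shared],
    enriched_in = r1$enriched_in[shared],
    p_exp1 = r1$p_value[shared], p_exp2 = r2$p_value[m][shared],
    stringsAsFactors = FALSE)
  shared_sets <- shared_sets[order(shared_sets$p_exp1, shared_sets$set), ]
  rownames(shared_sets) <- NULL
  report <- structure(
    list(n_tests_total = n_tests_total, alpha = alpha,
         expected_shared = expected,
         expected_shared_rounded = round(expected),
         n_shared_observed = sum(shared),
         fdr = overlap_fdr(expected, sum(shared)),
         shared_sets = shared_sets),
    class = "set_replication_report")
  list(results = results, report = report)
}

# Relabelled-group rankings for phenotype permutation, enumerated when the
# number of distinct relabellings is below n_perm, sampled otherwise.
phenotype_permuted_rankings <- function(exp, cn, annotation, metric, probes,
                                        floor, n_perm) {
  ct <- make_contrast(cn)
  arm_ref <- samples_in_groups(exp, ct$ref)
  arm_test <- samples_in_groups(exp, ct$test)
  arms <- c(arm_ref, arm_test)
  n_ref <- length(arm_ref)
  n_distinct <- choose(length(arms), n_ref)
  rank_for <- function(ref_idx) {
    pe <- exp
    g <- pe$groups
    g[arms] <- ct$test[1L]
    g[arms[ref_idx]] <- ct$ref[1L]
    pe$groups <- g
    rank_genes(pe, cn, annotation, metric = metric, probes = probes,
               floor = floor)
  }
  if (n_distinct <= n_perm) {
    combos <- utils::combn(length(arms), n_ref)
    list(rankings = lapply(seq_len(ncol(combos)),
                           function(j) rank_for(combos[, j])),
         exhaustive = TRUE)
  } else {
    list(rankings = lapply(seq_len(n_perm), function(i)
      rank_for(sample.int(length(arms), n_ref))), exhaustive = FALSE)
  }
}

#' @export
print.set_replication_report <- function(x, ...) {
  cat(sprintf("set-level replication: %d tests at alpha %.3g\n",
              x$n_tests_total, x$alpha))
  cat(sprintf("  expected shared by chance %.2f (~%d), observed %d\n",
              x$expected_shared, x$expected_shared_rounded,
              x$n_shared_observed))
  cat(sprintf("  FDR = %s\n",
              if (is.na(x$fdr)) "undefined (nothing observed)"
              else sprintf("%.0f%%", 100 * x$fdr)))
  invisible(x)
}
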