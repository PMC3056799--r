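#' Configuration for the paired-experiment simulator
#'
#' Defines the statistical structure of a pair of synthetic microarray
#' experiments that emulate the study design the pipeline targets: two
#' platforms with nested probe universes (platform A a strict subset of
#' platform B), small group sizes, log-normal baseline signals, detection
#' calls correlated with signal, planted down/up-regulated probes shared by
#' both experiments, NTO-specific probes, planted all-present-to-all-absent
#' ("off") probes, and gene sets whose members are coherently shifted.
#'
#' Defaults mirror the study conditions: experiment 1 has 4 controls and 4
#' alcohol-treated arrays (2 NTC + 2 NTO), experiment 2 has 4 controls,
#' 3 NTC and 4 NTO; 606 gene sets split 415/191 across two databases.
#'
#' @param n_probes_platform_B Probes on the larger platform (experiment 2).
#' @param n_probes_platform_A Probes on the smaller platform (experiment 1);
#'   must be strictly fewer than `n_probes_platform_B` and is a strict subset
#'   of its probe ids.
#' @param group_sizes List with elements `exp1` and `exp2`, each a named
#'   integer vector over [GROUP_LABELS]; every group needs >= 2 arrays.
#' @param baseline_log2_mean,baseline_log2_sd Mean and sd of the per-probe
#'   baseline expression on the log2 scale.
#' @param noise_log2_sd Per-array log2 measurement/biological noise sd.
#' @param n_planted_down,n_planted_up Probes down-/up-regulated (by
#'   `planted_log2_effect` log2 units) in every alcohol-treated array, in
#'   both experiments.
#' @param planted_log2_effect Magnitude of the planted log2 effect.
#' @param n_planted_off Probes present in every control array and absent in
#'   every alcohol-treated array.
#' @param n_planted_subgroup Probes down-regulated only in ALC_NTO arrays,
#'   giving the two alcohol phenotypes distinguishable profiles.
#' @param n_gene_sets Number of gene sets emitted (first 415 labelled
#'   `early_development`, remainder `stem_cell`, mirroring the two databases).
#' @param set_size_range Length-2 integer vector, inclusive range of set sizes.
#' @param n_planted_enriched_sets Sets whose members are all shifted down by
#'   `set_shift_log2` in alcohol-treated arrays.
#' @param set_shift_log2 Coherent log2 shift applied to planted-set members.
#' @param detection_threshold_log2 A probe is called Present on an array iff
#'   its log2 signal is at or above this threshold (before flip noise).
#' @param detection_flip_prob Probability that a threshold-derived call is
#'   flipped (P <-> A), modelling borderline-call uncertainty. Planted off
#'   probes are exempt so their presence pattern is exact by construction.
#' @param seed Integer RNG seed; identical seeds give bit-identical output.
#'
#' @return A validated list of class `"simulation_config"`.
#' @seealso [simulate_experiment_pair()], [null_simulation_config()]
#' @export
simulation_config <- function(n_probes_platform_B = 20000L,
                              n_probes_platform_A = 13810L,
                              group_sizes = list(
                                exp1 = c(CONTROL = 4L, ALC_NTC = 2L, ALC_NTO = 2L),
                                exp2 = c(CONTROL = 4L, ALC_NTC = 3L, ALC_NTO = 4L)),
                              baseline_log2_mean = 6.6,
                              baseline_log2_sd = 2.0,
                              noise_log2_sd = 0.25,
                              n_planted_down = 300L,
                              n_planted_up = 200L,
                              planted_log2_effect = 1.0,
                              n_planted_off = 10L,
                              n_planted_subgroup = 150L,
                              n_gene_sets = 606L,
                              set_size_range = c(10L, 50L),
                              n_planted_enriched_sets = 5L,
                              set_shift_log2 = 0.5,
                              detection_threshold_log2 = 6.0,
                              detection_flip_prob = 0.05,
                              seed = 1L) {
  cfg <- list(
    n_probes_platform_B = as.integer(n_probes_platform_B),
    n_probes_platform_A = as.integer(n_probes_platform_A),
    group_sizes = lapply(group_sizes, function(g) {
      g <- vapply(g, as.integer, integer(1L))
      g
    }),
    baseline_log2_mean = baseline_log2_mean,
    baseline_log2_sd = baseline_log2_sd,
    noise_log2_sd = noise_log2_sd,
    n_planted_down = as.integer(n_planted_down),
    n_planted_up = as.integer(n_planted_up),
    planted_log2_effect = planted_log2_effect,
    n_planted_off = as.integer(n_planted_off),
    n_planted_subgroup = as.integer(n_planted_subgroup),
    n_gene_sets = as.integer(n_gene_sets),
    set_size_range = as.integer(set_size_range),
    n_planted_enriched_sets = as.integer(n_planted_enriched_sets),
    set_shift_log2 = set_shift_log2,
    detection_threshold_log2 = detection_threshold_log2,
    detection_flip_prob = detection_flip_prob,
    seed = as.integer(seed))
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  if (cfg$n_probes_platform_A >= cfg$n_probes_platform_B)
    stop("platform A must be a strict subset of platform B ",
         "(n_probes_platform_A < n_probes_platform_B)", call. = FALSE)
  if (cfg$n_probes_platform_A < 1L)
    stop("need at least one platform-A probe", call. = FALSE)
  for (e in c("exp1", "exp2")) {
    g <- cfg$group_sizes[[e]]
    if (!setequal(names(g), GROUP_LABELS))
      stop(e, ": group_sizes must name exactly ",
           paste(GROUP_LABELS, collapse = ", "), call. = FALSE)
    if (any(g < 2L))
      stop(e, ": every group needs >= 2 arrays (Welch test requirement)",
           call. = FALSE)
  }
  if (cfg$baseline_log2_sd <= 0 || cfg$noise_log2_sd <= 0)
    stop("standard deviations must be > 0", call. = FALSE)
  if (cfg$detection_flip_prob < 0 || cfg$detection_flip_prob > 1)
    stop("detection_flip_prob must be in [0, 1]", call. = FALSE)
  counts <- c(cfg$n_planted_down, cfg$n_planted_up, cfg$n_planted_off,
              cfg$n_planted_subgroup, cfg$n_planted_enriched_sets,
              cfg$n_gene_sets)
  if (any(counts < 0L)) stop("planted counts must be >= 0", call. = FALSE)
  if (cfg$n_planted_enriched_sets > cfg$n_gene_sets)
    stop("n_planted_enriched_sets cannot exceed n_gene_sets", call. = FALSE)
  if (length(cfg$set_size_range) != 2L ||
      cfg$set_size_range[1L] > cfg$set_size_range[2L] ||
      cfg$set_size_range[1L] < 1L)
    stop("set_size_range must be an increasing pair of positive counts",
         call. = FALSE)
  max_members <- cfg$n_planted_enriched_sets * cfg$set_size_range[2L]
  if (cfg$n_planted_down + cfg$n_planted_up + cfg$n_planted_off +
      cfg$n_planted_subgroup + max_members > cfg$n_probes_platform_A)
    stop("planted categories exceed the platform-A probe universe",
         call. = FALSE)
  invisible(cfg)
}

#' Null-calibration simulator configuration
#'
#' A configuration with no planted effects, a 4-vs-4 design in both
#' experiments and a high baseline so that nearly the whole shared universe
#' survives the detection filter. Used to check that the per-experiment
#' Welch false-positive rate is alpha and that the directional
#' two-experiment intersection rate matches its analytic value
#' alpha1 * alpha2 / 2; a large tested universe keeps the Monte-Carlo error
#' on those rates small.
#'
#' @param n_shared Number of probes shared by the two platforms (platform A
#'   size; platform B carries 5% extra probes to stay a strict superset).
#' @param seed Integer RNG seed.
#' @return A `"simulation_config"`.
#' @export
null_simulation_config <- function(n_shared = 20000L, seed = 1L) {
  n_shared <- as.integer(n_shared)
  simulation_config(
    n_probes_platform_B = n_shared + max(1L, n_shared %/% 20L),
    n_probes_platform_A = n_shared,
    group_sizes = list(
      exp1 = c(CONTROL = 4L, ALC_NTC = 2L, ALC_NTO = 2L),
      exp2 = c(CONTROL = 4L, ALC_NTC = 2L, ALC_NTO = 2L)),
    baseline_log2_mean = 8, baseline_log2_sd = 1.5,
    detection_threshold_log2 = 5,
    n_planted_down = 0L, n_planted_up = 0L, n_planted_off = 0L,
    n_planted_subgroup = 0L, n_planted_enriched_sets = 0L,
    n_gene_sets = 0L,
    seed = seed)
}

#' Simulate a pair of nested-platform experiments
#'
#' Draws per-probe log2 baselines, plants the configured effects, adds
#' i.i.d. log2 noise per array, exponentiates to the MAS5-style natural
#' scale, and derives detection calls by thresholding the log2 signal with
#' symmetric flip noise. Experiment 1 is restricted to the platform-A
#' probes; experiment 2 carries the full platform-B universe. The same
#' per-probe ground-truth effect drives both experiments.
#'
#' Planted probes (down, up, off, NTO-specific, enriched-set members) are
#' mutually disjoint and live on platform A so replication can recover
#' them; their baselines are forced above the detection threshold because
#' differential expression is only observable for expressed transcripts.
#'
#' @param config A [simulation_config()].
#' @return A list with elements `exp1`, `exp2` (class
#'   `"expression_experiment"`), `annotation` (data.frame: `probe_id`,
#'   `gene_symbol`, `on_platform_A`), `gene_sets` (a gene-set collection as
#'   from [read_gmt()], or `NULL` if `n_gene_sets` is 0) and `truth`, the
#'   ground-truth list (`planted_down_ids`, `planted_up_ids`,
#'   `planted_off_ids`, `planted_subgroup_ids`,
#'   `planted_enriched_set_names`, and the named per-probe
#'   `true_log2_effect` on platform B, oriented test minus control for the
#'   pooled alcohol arm).
#' @export
simulate_experiment_pair <- function(config) {
  if (!inherits(config, "simulation_config"))
    config <- do.call(simulation_config, config)
  validate_simulation_config(config)
  set.seed(config$seed)
  nB <- config$n_probes_platform_B
  nA <- config$n_probes_platform_A

  probe_id <- sprintf("S%06d_at", seq_len(nB))
  gene_symbol <- sprintf("Gene%06d", seq_len(nB))
  on_A <- seq_len(nB) <= nA

  # Disjoint planted categories, all on platform A.
  set_sizes <- if (config$n_planted_enriched_sets > 0L)
    sample(seq(config$set_size_range[1L], config$set_size_range[2L]),
           config$n_planted_enriched_sets, replace = TRUE) else integer(0L)
  n_needed <- config$n_planted_down + config$n_planted_up +
    config$n_planted_off + config$n_planted_subgroup + sum(set_sizes)
  pool <- if (n_needed > 0L) sample.int(nA, n_needed) else integer(0L)
  take <- function(n) {
    out <- pool[seq_len(n)]
    pool <<- pool[-seq_len(n)]
    out
  }
  idx_down <- take(config$n_planted_down)
  idx_up <- take(config$n_planted_up)
  idx_off <- take(config$n_planted_off)
  idx_sub <- take(config$n_planted_subgroup)
  idx_set_members <- lapply(set_sizes, take)

  thr <- config$detection_threshold_log2
  baseline <- stats::rnorm(nB, config$baseline_log2_mean, config$baseline_log2_sd)
  planted <- c(idx_down, idx_up, idx_sub, unlist(idx_set_members))
  baseline[planted] <- pmax(baseline[planted], thr + 1)
  baseline[idx_off] <- pmax(baseline[idx_off], thr + 2)

  eff <- config$planted_log2_effect
  alc_effect <- numeric(nB)            # applied in every alcohol array
  alc_effect[idx_down] <- -eff
  alc_effect[idx_up] <- eff
  for (m in idx_set_members) alc_effect[m] <- alc_effect[m] - config$set_shift_log2
  nto_effect <- numeric(nB)            # additional effect in ALC_NTO arrays
  nto_effect[idx_sub] <- -eff

  gene_sets <- simulate_gene_sets(config, gene_symbol, on_A, idx_set_members,
                                  planted_probe_idx = c(idx_down, idx_up,
                                                        idx_off, idx_sub))

  build <- function(which_exp, platform_id, keep) {
    sizes <- config$group_sizes[[which_exp]]
    groups <- rep(GROUP_LABELS, times = sizes[GROUP_LABELS])
    ids <- sprintf("%s_%s_%d", which_exp, groups,
                   stats::ave(seq_along(groups), groups, FUN = seq_along))
    n_samp <- length(groups)
    log2sig <- matrix(baseline, nB, n_samp) +
      matrix(stats::rnorm(nB * n_samp, 0, config$noise_log2_sd), nB, n_samp)
    is_alc <- groups != "CONTROL"
    log2sig[, is_alc] <- log2sig[, is_alc] + alc_effect
    is_nto <- groups == "ALC_NTO"
    log2sig[, is_nto] <- log2sig[, is_nto] + nto_effect
    if (length(idx_off)) {
      # Present in every control, below threshold in every alcohol array.
      log2sig[idx_off, is_alc] <- (thr - 2) +
        matrix(stats::rnorm(length(idx_off) * sum(is_alc), 0,
                            config$noise_log2_sd),
               length(idx_off), sum(is_alc))
    }
    calls <- matrix(ifelse(log2sig >= thr, "P", "A"), nB, n_samp)
    if (config$detection_flip_prob > 0) {
      flip <- matrix(stats::runif(nB * n_samp) < config$detection_flip_prob,
                     nB, n_samp)
      flip[idx_off, ] <- FALSE
      calls[flip] <- ifelse(calls[flip] == "P", "A", "P")
    }
    dimnames(log2sig) <- dimnames(calls) <- list(probe_id, ids)
    expression_experiment(
      platform_id = platform_id,
      signal = 2^log2sig[keep, , drop = FALSE],
      detection = calls[keep, , drop = FALSE],
      groups = stats::setNames(groups, ids))
  }

  exp1 <- build("exp1", "platform_A", on_A)
  exp2 <- build("exp2", "platform_B", rep(TRUE, nB))

  truth <- list(
    planted_down_ids = probe_id[sort(idx_down)],
    planted_up_ids = probe_id[sort(idx_up)],
    planted_off_ids = probe_id[sort(idx_off)],
    planted_subgroup_ids = probe_id[sort(idx_sub)],
    planted_enriched_set_names = if (length(set_sizes))
      sprintf("PLANTED_SET_%02d", seq_along(set_sizes)) else character(0L),
    true_log2_effect = stats::setNames(alc_effect, probe_id))

  list(exp1 = exp1, exp2 = exp2,
       annotation = data.frame(probe_id = probe_id, gene_symbol = gene_symbol,
                               on_platform_A = on_A,
                               stringsAsFactors = FALSE),
       gene_sets = gene_sets, truth = truth)
}

# Planted sets get the reserved shifted members; null sets draw from the
# whole gene universe (real collections contain affected genes too, and
# excluding them would deplete null sets from the top of the ranking,
# creating spurious opposite-direction enrichment).
simulate_gene_sets <- function(config, gene_symbol, on_A, idx_set_members,
                               planted_probe_idx) {
  if (config$n_gene_sets == 0L) return(NULL)
  n_null <- config$n_gene_sets - config$n_planted_enriched_sets
  null_pool <- seq_along(gene_symbol)
  sets <- vector("list", config$n_gene_sets)
  names_ <- character(config$n_gene_sets)
  k <- 0L
  for (i in seq_along(idx_set_members)) {
    k <- k + 1L
    names_[k] <- sprintf("PLANTED_SET_%02d", i)
    sets[[k]] <- sort(gene_symbol[idx_set_members[[i]]])
  }
  if (n_null > 0L) {
    sizes <- sample(seq(config$set_size_range[1L], config$set_size_range[2L]),
                    n_null, replace = TRUE)
    for (i in seq_len(n_null)) {
      k <- k + 1L
      names_[k] <- sprintf("NULL_SET_%03d", i)
      sets[[k]] <- sort(gene_symbol[sample(null_pool, sizes[i])])
    }
  }
  n_early <- min(415L, config$n_gene_sets)
  gene_set_collection(
    name = names_,
    description = ifelse(grepl("^PLANTED", names_),
                         "planted coherently shifted set", "random set"),
    members = sets,
    database = c(rep("early_development", n_early),
                 rep("stem_cell", config$n_gene_sets - n_early)))
}
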