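CONTRAST_NAMES <- c("CTRL_vs_ALC", "CTRL_vs_NTC", "CTRL_vs_NTO", "NTC_vs_NTO")

#' Define a group contrast
#'
#' The four study contrasts compare controls to the pooled alcohol arm, to
#' each alcohol phenotype separately, and the two phenotypes to each other.
#'
#' @param name One of `CTRL_vs_ALC`, `CTRL_vs_NTC`, `CTRL_vs_NTO`,
#'   `NTC_vs_NTO`.
#' @return A list with `name`, `ref` / `test` group-label sets, and
#'   `ref_label` / `test_label` display labels.
#' @export
make_contrast <- function(name = CONTRAST_NAMES) {
  name <- match.arg(name)
  switch(name,
    CTRL_vs_ALC = list(name = name, ref = "CONTROL",
                       test = c("ALC_NTC", "ALC_NTO"),
                       ref_label = "CONTROL", test_label = "ALC"),
    CTRL_vs_NTC = list(name = name, ref = "CONTROL", test = "ALC_NTC",
                       ref_label = "CONTROL", test_label = "ALC_NTC"),
    CTRL_vs_NTO = list(name = name, ref = "CONTROL", test = "ALC_NTO",
                       ref_label = "CONTROL", test_label = "ALC_NTO"),
    NTC_vs_NTO = list(name = name, ref = "ALC_NTC", test = "ALC_NTO",
                      ref_label = "ALC_NTC", test_label = "ALC_NTO"))
}

as_contrast <- function(x) {
  if (is.character(x)) make_contrast(x) else x
}

#' Log2-transform signals with a floor
#'
#' Every signal `s` becomes `log2(max(s, floor))`; the floor absorbs the
#' zeros MAS5 can produce.
#'
#' @param x An `"expression_experiment"` or a non-negative numeric matrix.
#' @param floor Positive lower bound applied before the log.
#' @return A numeric matrix of log2 signals.
#' @export
log_transform <- function(x, floor = 1) {
  if (floor <= 0) stop("`floor` must be > 0", call. = FALSE)
  m <- if (inherits(x, "expression_experiment")) x$signal else x
  log2(pmax(m, floor))
}

#' Welch's two-sample t-test
#'
#' Thin wrapper over [stats::t.test()] (unequal variances,
#' Welch-Satterthwaite degrees of freedom, two-sided). The degenerate case
#' of zero variance in both groups with equal means returns
#' `t = 0, p = 1`; with unequal means `t = +-Inf` and the smallest
#' representable p.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @return List with elements `t`, `df`, `p` (`t` oriented mean(x) - mean(y)).
#' @export
welch_test <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("welch_test needs >= 2 observations per group", call. = FALSE)
  if (stats::var(x) + stats::var(y) == 0) {
    d <- mean(x) - mean(y)
    df <- length(x) + length(y) - 2
    if (d == 0) return(list(t = 0, df = df, p = 1))
    return(list(t = sign(d) * Inf, df = df, p = .Machine$double.xmin))
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = max(ht$p.value, .Machine$double.xmin))
}

# Vectorized row-wise Welch test on a log-scale matrix. Returns per-row
# statistics oriented mean(test) - mean(ref) so the sign matches the fold
# change convention. Zero-variance rows follow the welch_test() rules.
row_welch <- function(logm, ref_samples, test_samples) {
  xr <- logm[, ref_samples, drop = FALSE]
  xt <- logm[, test_samples, drop = FALSE]
  nr <- length(ref_samples); nt <- length(test_samples)
  mr <- rowMeans(xr); mt <- rowMeans(xt)
  vr <- rowSums((xr - mr)^2) / (nr - 1)
  vt <- rowSums((xt - mt)^2) / (nt - 1)
  se2 <- vr / nr + vt / nt
  d <- mt - mr
  t <- d / sqrt(se2)
  df <- se2^2 / ((vr / nr)^2 / (nr - 1) + (vt / nt)^2 / (nt - 1))
  p <- 2 * stats::pt(-abs(t), df)
  degen <- se2 == 0
  if (any(degen)) {
    t[degen] <- sign(d[degen]) * Inf
    t[degen & d == 0] <- 0
    df[degen] <- nr + nt - 2
    p[degen] <- ifelse(d[degen] == 0, 1, .Machine$double.xmin)
  }
  p <- pmax(p, .Machine$double.xmin)
  data.frame(mean_log2_ref = mr, mean_log2_test = mt, welch_t = t,
             welch_df = df, p_value = p, row.names = rownames(logm))
}

# Map a log2 mean difference (test - ref) to the signed fold convention:
# ratios below 1 are reported as -1/ratio, so |signed_fold| >= 1.
signed_fold_from_log2diff <- function(d) {
  ifelse(d < 0, -(2^(-d)), 2^d)
}

#' Per-probe differential expression table for one contrast
#'
#' Welch's t-test on log2-transformed signals for every (retained) probe,
#' with the signed fold change computed from the difference of group means
#' of log signals (a geometric-mean ratio) and mapped to the signed
#' convention (ratios below 1 reported as -1/ratio). A probe's direction is
#' `down`/`up` only when `p <= alpha`; otherwise `none`.
#'
#' @param exp An `"expression_experiment"`.
#' @param contrast A [make_contrast()] result or contrast name.
#' @param alpha Per-experiment significance threshold (default 0.05).
#' @param probes Optional probe ids to restrict to (e.g. the
#'   present-filtered universe); default all probes.
#' @param floor Signal floor for [log_transform()].
#' @return A data.frame with one row per probe: `probe_id`, `contrast`,
#'   `mean_log2_ref`, `mean_log2_test`, `welch_t` (oriented test - ref),
#'   `welch_df`, `p_value`, `signed_fold`, `direction`.
#' @export
differential_table <- function(exp, contrast, alpha = 0.05, probes = NULL,
                               floor = 1) {
  contrast <- as_contrast(contrast)
  ref <- samples_in_groups(exp, contrast$ref)
  test <- samples_in_groups(exp, contrast$test)
  if (length(ref) < 2L || length(test) < 2L)
    stop(sprintf("contrast %s needs >= 2 samples per arm (got %d vs %d)",
                 contrast$name, length(ref), length(test)), call. = FALSE)
  logm <- log_transform(exp, floor)
  if (!is.null(probes)) {
    missing <- setdiff(probes, rownames(logm))
    if (length(missing))
      stop("probe not on this platform: ", missing[1L], call. = FALSE)
    logm <- logm[probes, , drop = FALSE]
  }
  st <- row_welch(logm, ref, test)
  d <- st$mean_log2_test - st$mean_log2_ref
  sig <- st$p_value <= alpha
  out <- data.frame(
    probe_id = rownames(logm),
    contrast = contrast$name,
    st,
    signed_fold = signed_fold_from_log2diff(d),
    direction = ifelse(!sig, "none", ifelse(d < 0, "down", "up")),
    row.names = NULL, stringsAsFactors = FALSE)
  out
}
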