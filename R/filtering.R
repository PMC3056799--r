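#' Default filter conditions: controls and the pooled alcohol arm
#'
#' @return Named list of group-label sets.
#' @export
default_filter_conditions <- function() {
  list(control = "CONTROL", alcohol = c("ALC_NTC", "ALC_NTO"))
}

#' Per-group filter conditions (one condition per study arm)
#' @return Named list of group-label sets.
#' @export
per_group_conditions <- function() {
  stats::setNames(as.list(GROUP_LABELS), GROUP_LABELS)
}

#' Detection-call ("present") filter
#'
#' A probe set is retained iff, in at least one condition, it is called
#' Present on at least half of that condition's arrays. "At least half"
#' with an odd number of arrays defaults to `count >= ceiling(n/2)` (the
#' strictest reading); `half_rule = "floor"` relaxes it for sensitivity
#' analysis. Marginal ("M") calls count as not-present.
#'
#' @param exp An `"expression_experiment"`.
#' @param conditions Named list of group-label sets; each condition pools
#'   the samples of its groups. Defaults to [default_filter_conditions()].
#' @param half_rule `"ceil"` (default) or `"floor"`.
#' @return A `"filter_result"`: `retained_probe_ids`, `n_input`,
#'   `n_retained`, `fraction_retained`, and `present_counts`, a probe x
#'   condition matrix of Present counts.
#' @export
present_filter <- function(exp, conditions = default_filter_conditions(),
                           half_rule = c("ceil", "floor")) {
  half_rule <- match.arg(half_rule)
  if (!length(conditions)) stop("need >= 1 condition", call. = FALSE)
  if (is.null(names(conditions)) || any(!nzchar(names(conditions))))
    names(conditions) <- vapply(conditions, paste, character(1L),
                                collapse = "+")
  counts <- sapply(conditions, function(labels) {
    s <- samples_in_groups(exp, labels)
    if (!length(s))
      stop("condition {", paste(labels, collapse = ","),
           "} has no samples in this experiment", call. = FALSE)
    rowSums(exp$detection[, s, drop = FALSE] == "P")
  })
  counts <- matrix(counts, nrow = nrow(exp$signal),
                   dimnames = list(probe_ids(exp), names(conditions)))
  n_cond <- vapply(conditions,
                   function(labels) length(samples_in_groups(exp, labels)),
                   integer(1L))
  need <- if (half_rule == "ceil") ceiling(n_cond / 2) else
    pmax(1L, floor(n_cond / 2))
  keep <- rowSums(counts >= rep(need, each = nrow(counts))) > 0L
  structure(
    list(retained_probe_ids = probe_ids(exp)[keep],
         n_input = nrow(exp$signal),
         n_retained = sum(keep),
         fraction_retained = sum(keep) / nrow(exp$signal),
         present_counts = counts,
         half_rule = half_rule,
         condition_sizes = need),
    class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  cat(sprintf("present filter: retained %d / %d probe sets (%.1f%%)\n",
              x$n_retained, x$n_input, 100 * x$fraction_retained))
  invisible(x)
}
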