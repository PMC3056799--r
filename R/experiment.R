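#' @keywords internal
"_PACKAGE"

#' Experimental arm labels
#'
#' The three study arms: vehicle controls, alcohol-treated embryos with a
#' closed neural tube (NTC) and alcohol-treated embryos with an open neural
#' tube (NTO). The pooled alcohol arm is always derived as
#' `ALC_NTC` + `ALC_NTO`, never stored.
#'
#' @format Character vector of length 3.
#' @export
GROUP_LABELS <- c("CONTROL", "ALC_NTC", "ALC_NTO")

DETECTION_CALLS <- c("P", "A", "M")

#' Construct a single-platform expression experiment
#'
#' Bundles a MAS5-style signal matrix (natural scale, probe sets x samples),
#' the matching Present/Absent/Marginal detection-call matrix, and the group
#' assignment of every array. All statistics downstream re-log the signals;
#' storage stays on the natural scale to mirror MAS5 output.
#'
#' @param platform_id Character scalar naming the array platform.
#' @param signal Numeric matrix, probe sets x samples, non-negative, with
#'   probe ids as rownames and sample ids as colnames.
#' @param detection Character matrix of calls in `{"P","A","M"}` with the
#'   same dimensions and dimnames as `signal`.
#' @param groups Named character vector (or factor) mapping every sample id
#'   to one of [GROUP_LABELS].
#'
#' @return An object of class `"expression_experiment"`.
#' @export
expression_experiment <- function(platform_id, signal, detection, groups) {
  stopifnot(is.character(platform_id), length(platform_id) == 1L)
  if (!is.matrix(signal) || !is.numeric(signal))
    stop("`signal` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(signal)) || is.null(colnames(signal)))
    stop("`signal` must carry probe ids as rownames and sample ids as colnames",
         call. = FALSE)
  if (anyDuplicated(rownames(signal)))
    stop("duplicate probe id in signal matrix: ",
         rownames(signal)[duplicated(rownames(signal))][1L], call. = FALSE)
  if (anyDuplicated(colnames(signal)))
    stop("duplicate sample id in signal matrix", call. = FALSE)
  if (any(!is.finite(signal)) || any(signal < 0))
    stop("signals must be finite and non-negative", call. = FALSE)
  if (!is.matrix(detection) || !identical(dim(detection), dim(signal)))
    stop("`detection` must be a matrix with the same shape as `signal`",
         call. = FALSE)
  if (!identical(dimnames(detection), dimnames(signal)))
    stop("`detection` must have identical row/column ordering to `signal`",
         call. = FALSE)
  if (!all(detection %in% DETECTION_CALLS))
    stop("detection calls must be one of P, A, M", call. = FALSE)
  groups <- stats::setNames(as.character(groups), names(groups))
  if (is.null(names(groups)) || !setequal(names(groups), colnames(signal)))
    stop("`groups` must be named by sample id and cover every sample",
         call. = FALSE)
  groups <- groups[colnames(signal)]
  bad <- setdiff(unique(groups), GROUP_LABELS)
  if (length(bad))
    stop("unknown group label: ", paste(bad, collapse = ", "), call. = FALSE)
  structure(
    list(platform_id = platform_id, signal = signal, detection = detection,
         groups = groups),
    class = "expression_experiment")
}

#' @export
print.expression_experiment <- function(x, ...) {
  cat(sprintf("expression_experiment: platform %s\n", x$platform_id))
  cat(sprintf("  %d probe sets x %d samples\n", nrow(x$signal), ncol(x$signal)))
  tab <- table(factor(x$groups, levels = GROUP_LABELS))
  cat("  groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}

probe_ids <- function(exp) rownames(exp$signal)
sample_ids <- function(exp) colnames(exp$signal)

# Sample ids belonging to any of the given group labels.
samples_in_groups <- function(exp, labels) {
  bad <- setdiff(labels, GROUP_LABELS)
  if (length(bad))
    stop("unknown group label: ", paste(bad, collapse = ", "), call. = FALSE)
  sample_ids(exp)[exp$groups %in% labels]
}
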