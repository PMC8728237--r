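#' Reads-per-million tRNA-mapped quantification
#'
#' RPM = 1e6 * C / N, where C is the count of one tsRNA and N the total
#' counts mapped to tRNA in the sample.
#'
#' @param C tsRNA count(s).
#' @param N total tRNA-mapped count(s) of the sample.
#' @return numeric RPM; N = 0 yields 0 with a warning.
#' @export
compute_rpm <- function(C, N) {
  if (any(N < 0) || any(C < 0)) stop("counts must be non-negative")
  if (any(C > N)) stop("tsRNA count C cannot exceed the sample total N")
  out <- 1e6 * C / pmax(N, 1)
  out <- out * as.numeric(N > 0)
  if (any(N == 0)) warning("sample with zero tRNA-mapped counts: RPM set to 0")
  out
}

#' Rank-based inverse-Gaussian normalization to \[-1, 1\]
#'
#' Values are replaced by normal quantiles of their (average-tie) ranks,
#' z_i = qnorm((r_i - 0.5)/m), then divided by the maximum absolute z so the
#' output spans \[-1, 1\] with a zero median for odd, tie-free input. The
#' transform depends only on ranks, so any strictly monotone rescaling of
#' the input (for example, cohort-specific sequencing depth) leaves it
#' unchanged — which is what makes it suitable for pan-cohort pooling.
#'
#' @param values numeric vector, length >= 2, finite.
#' @return numeric vector in \[-1, 1\] (names preserved); an all-constant
#'   input returns zeros with a warning.
#' @export
rank_inverse_gaussian <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values")
  if (any(!is.finite(values))) stop("values must be finite")
  m <- length(values)
  r <- rank(values, ties.method = "average")
  z <- stats::qnorm((r - 0.5) / m)
  mx <- max(abs(z))
  if (mx == 0) {
    warning("all values identical; returning zeros")
    out <- z
  } else {
    out <- z / mx
  }
  names(out) <- names(values)
  out
}

#' Build a tsRNA-by-sample RPM expression matrix from call tables
#'
#' @param call_tables named list of per-sample call data.frames (columns
#'   `name` and `count`, as produced by [tsr_find()]).
#' @param totals optional named numeric of per-sample total tRNA-mapped
#'   counts; defaults to the per-sample sum of call counts.
#' @return numeric matrix (tsRNA x sample) of RPM values.
#' @export
build_expression_matrix <- function(call_tables, totals = NULL) {
  if (is.null(names(call_tables))) {
    names(call_tables) <- paste0("sample", seq_along(call_tables))
  }
  all_names <- sort(unique(unlist(lapply(call_tables, `[[`, "name"))))
  mat <- matrix(0, nrow = length(all_names), ncol = length(call_tables),
                dimnames = list(all_names, names(call_tables)))
  for (s in names(call_tables)) {
    tab <- call_tables[[s]]
    N <- if (!is.null(totals)) totals[[s]] else sum(tab$count)
    if (nrow(tab)) mat[tab$name, s] <- compute_rpm(tab$count, N)
  }
  mat
}

#' Normalize an expression matrix with the rank-based transform
#'
#' Applies [rank_inverse_gaussian()] along one margin of an RPM matrix —
#' by default per tsRNA across samples, the orientation used when comparing
#' one molecule's abundance across a cohort.
#'
#' @param mat numeric matrix (tsRNA x sample).
#' @param margin 1 = per row (per tsRNA), 2 = per column (per sample).
#' @return matrix of the same shape with values in \[-1, 1\].
#' @export
normalize_expression <- function(mat, margin = 1L) {
  out <- apply(mat, margin, rank_inverse_gaussian)
  # apply() returns the transformed vectors as columns; restore orientation
  if (margin == 1L) out <- t(out)
  dimnames(out) <- dimnames(mat)
  out
}

#' Per-group expression summary
#'
#' Plain mean/median RPM per group for a sample sheet, the tabular
#' counterpart of differential-abundance overviews.
#'
#' @param mat RPM matrix (tsRNA x sample).
#' @param groups named character vector mapping sample_id to group label.
#' @return data.frame: tsrna_name, group, mean_rpm, median_rpm.
#' @export
summarize_by_group <- function(mat, groups) {
  groups <- groups[colnames(mat)]
  rows <- list()
  for (g in sort(unique(groups))) {
    sub <- mat[, groups == g, drop = FALSE]
    rows[[g]] <- data.frame(
      tsrna_name = rownames(mat), group = g,
      mean_rpm = rowMeans(sub),
      median_rpm = apply(sub, 1, stats::median),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
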