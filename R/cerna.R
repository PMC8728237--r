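#' Hypergeometric upper-tail probability of shared targets
#'
#' Probability that two regulators sharing `k` or more of their mRNA targets
#' would do so by chance: with `N` mRNAs in the universe, `K` interacting
#' with the miRNA and `n` with the tsRNA, the shared count follows a
#' hypergeometric distribution and the upper tail
#' sum_{i=k}^{min(K,n)} C(K,i) C(N-K,n-i) / C(N,n) is evaluated through the
#' survival function.
#'
#' @param N universe size (all mRNAs).
#' @param K targets of the miRNA.
#' @param n targets of the tsRNA.
#' @param k shared targets.
#' @return P(X >= k); vectorized.
#' @export
hypergeom_upper_tail <- function(N, K, n, k) {
  if (any(K > N) || any(n > N)) stop("K and n cannot exceed the universe N")
  if (any(k < 0) || any(k > pmin(K, n))) stop("require 0 <= k <= min(K, n)")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted P values with cumulative-minimum enforcement, in input
#' order.
#'
#' @param pvalues numeric vector in \[0, 1\].
#' @return adjusted values, same order as input.
#' @export
bh_fdr <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stop("P values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Score tsRNA-miRNA competing-endogenous-RNA pairs and build the network
#'
#' Every (miRNA, tsRNA) pair sharing at least one mRNA target is tested with
#' the hypergeometric upper tail; pairs below the FDR threshold after
#' Benjamini-Hochberg correction become "competes" edges. Pairs sharing no
#' target are not tested (they cannot be significant and would only dilute
#' the FDR correction); their count is reported.
#'
#' @param tsrna_targets data.frame with columns regulator_id (or tsrna_name)
#'   and mrna_id.
#' @param mirna_targets data.frame with columns regulator_id (or mirna_id)
#'   and mrna_id.
#' @param universe_size number of mRNAs in the universe; defaults to the
#'   distinct mRNAs observed in the union of both tables.
#' @param fdr_threshold FDR cutoff for a "competes" edge.
#' @return list with `tests` (mirna_id, tsrna_name, N, K, n, k, pvalue, fdr)
#'   and `network` (list of `nodes` and `edges` data.frames).
#' @export
build_cerna_network <- function(tsrna_targets, mirna_targets,
                                universe_size = NULL, fdr_threshold = 0.05) {
  pick <- function(df, pref) {
    id_col <- intersect(c(pref, "regulator_id"), names(df))[1]
    if (is.na(id_col) || !"mrna_id" %in% names(df)) {
      stop("target table needs regulator and mrna_id columns")
    }
    out <- unique(data.frame(regulator = as.character(df[[id_col]]),
                             mrna = as.character(df$mrna_id),
                             stringsAsFactors = FALSE))
    out[order(out$regulator, out$mrna), ]
  }
  tsr <- pick(tsrna_targets, "tsrna_name")
  mir <- pick(mirna_targets, "mirna_id")
  all_mrnas <- sort(unique(c(tsr$mrna, mir$mrna)))
  N <- if (is.null(universe_size)) length(all_mrnas) else universe_size
  if (N < length(all_mrnas)) {
    stop("universe_size (", N, ") smaller than the ", length(all_mrnas),
         " distinct mRNAs observed")
  }
  ts_sets <- split(tsr$mrna, tsr$regulator)
  mi_sets <- split(mir$mrna, mir$regulator)
  rows <- list()
  n_skipped <- 0L
  for (mi in names(mi_sets)) {
    for (ts in names(ts_sets)) {
      k <- length(intersect(mi_sets[[mi]], ts_sets[[ts]]))
      if (k == 0L) { n_skipped <- n_skipped + 1L; next }
      K <- length(mi_sets[[mi]])
      n <- length(ts_sets[[ts]])
      rows[[length(rows) + 1L]] <- data.frame(
        mirna_id = mi, tsrna_name = ts, N = N, K = K, n = n, k = k,
        pvalue = hypergeom_upper_tail(N, K, n, k),
        stringsAsFactors = FALSE)
    }
  }
  if (n_skipped) {
    message("build_cerna_network: ", n_skipped,
            " pair(s) with no shared target not tested")
  }
  tests <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mirna_id = character(0), tsrna_name = character(0),
               N = integer(0), K = integer(0), n = integer(0),
               k = integer(0), pvalue = numeric(0))
  tests <- tests[order(tests$mirna_id, tests$tsrna_name), , drop = FALSE]
  tests$fdr <- bh_fdr(tests$pvalue)
  rownames(tests) <- NULL
  sig <- tests[tests$fdr < fdr_threshold, , drop = FALSE]
  edges <- rbind(
    data.frame(source = sig$tsrna_name, sink = sig$mirna_id,
               relation = rep("competes", nrow(sig)),
               stringsAsFactors = FALSE),
    data.frame(source = tsr$regulator, sink = tsr$mrna,
               relation = rep("targets", nrow(tsr)),
               stringsAsFactors = FALSE),
    data.frame(source = mir$regulator, sink = mir$mrna,
               relation = rep("targets", nrow(mir)),
               stringsAsFactors = FALSE))
  edges <- edges[order(edges$relation, edges$source, edges$sink), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  nodes <- rbind(
    data.frame(id = sort(unique(tsr$regulator)), type = "tsRNA",
               stringsAsFactors = FALSE),
    data.frame(id = sort(unique(mir$regulator)), type = "miRNA",
               stringsAsFactors = FALSE),
    data.frame(id = all_mrnas, type = "mRNA", stringsAsFactors = FALSE))
  rownames(nodes) <- NULL
  list(tests = tests, network = list(nodes = nodes, edges = edges))
}
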