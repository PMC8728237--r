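#' Binomial P value for positional read enrichment
#'
#' Under an unbiased degradation model a read falls at any of the
#' `L - l + 1` admissible start positions of a transcript with equal
#' probability `p = 1/(L - l + 1)`. The P value of observing `k` or more of
#' the transcript's `n` tags at one position is the upper tail of
#' Binomial(n, p), evaluated through the survival function for numerical
#' stability.
#'
#' @param k tag count at the position of interest.
#' @param n total tags mapped to the transcript.
#' @param L transcript length.
#' @param l read length.
#' @return P(X >= k); vectorized over all arguments.
#' @export
binomial_site_pvalue <- function(k, n, L, l) {
  if (any(L < l)) stop("transcript length L must be >= read length l")
  if (any(l < 1L)) stop("read length l must be >= 1")
  if (any(k < 0L) || any(n < k)) stop("require 0 <= k <= n")
  p <- 1 / (L - l + 1)
  stats::pbinom(k - 1, n, p, lower.tail = FALSE)
}

#' Classify a tsRNA by its cleavage position
#'
#' The six canonical classes are assigned from where the fragment's ends fall
#' on its source: fragments from the 3' trailer of the precursor are tRF-1;
#' on the mature tRNA, fragments anchored at the 5' end (start within the
#' first `s5` bases) are tRNA halves (tiRNA-5) when they end inside the
#' anticodon loop and tRF-5 when they end before it; fragments anchored at
#' the 3' end (end within the last `s3` bases, the CCA tail) are tiRNA-3 when
#' they start inside the anticodon loop and tRF-3 when they start after it;
#' everything else is internal, tRF-i.
#'
#' @param start,end 1-based closed fragment interval on the reference.
#' @param ref a `mature_trna` or `trailer_seq` object.
#' @param s5 width of the 5'-anchor window.
#' @param s3 width of the 3'-anchor window (defaults to the CCA tail).
#' @return one of "tRF-5", "tRF-3", "tRF-i", "tRF-1", "tiRNA-5", "tiRNA-3".
#' @export
classify_tsrna <- function(start, end, ref, s5 = 2L, s3 = 3L) {
  if (inherits(ref, "trailer_seq")) {
    if (start < 1L || end > ref$length || end < start) {
      stop("interval outside trailer reference")
    }
    return("tRF-1")
  }
  L <- ref$L
  if (start < 1L || end > L || end < start) {
    stop("interval outside mature reference")
  }
  loop <- ref$anticodon_loop
  in_loop <- function(p) p >= loop[1] && p <= loop[2]
  if (start <= s5 && in_loop(end)) return("tiRNA-5")
  if (start <= s5 && end < loop[1]) return("tRF-5")
  if (end > L - s3 && in_loop(start)) return("tiRNA-3")
  if (end > L - s3 && start > loop[2]) return("tRF-3")
  "tRF-i"
}

# count-weighted median
weighted_median <- function(x, w) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  cw <- cumsum(w) / sum(w)
  x[which(cw >= 0.5)[1]]
}

type_code <- function(type) {
  c("tRF-5" = "5", "tRF-3" = "3", "tRF-i" = "i", "tRF-1" = "1",
    "tiRNA-5" = "5i", "tiRNA-3" = "3i")[[type]]
}

#' Call tsRNAs from read alignments by positional enrichment
#'
#' For every reference transcript, `n` is its total tag count (collapsed read
#' multiplicities, multi-mapped reads contributing their full count) and `k`
#' at a position is the count of tags whose alignment starts (or, with
#' `count_mode = "end"`, ends) there. The success probability uses a
#' representative read length per transcript (the count-weighted median tag
#' length), so `p = 1/(L - l + 1)` is common to all positions of the
#' transcript; with `length_mode = "per-fragment"` each fragment's own
#' length is used instead. The representative length is the default because
#' `k` pools tags of every length at a position: testing a pooled count
#' against the placement probability of the shortest fragment (the smallest
#' `p`) makes the test anti-conservative on libraries with mixed read
#' lengths. A fragment becomes a candidate when its enrichment P value
#' falls below `p_threshold` and its length lies in the configured range.
#' Identical sequences called on several tRNAs merge into a single call
#' listing all sources; the reported P value is the minimum over sources.
#'
#' @param alignments data.frame from [align_to_trna()].
#' @param reference the reference set the alignments were made against.
#' @param p_threshold binomial P value cutoff.
#' @param min_len,max_len called fragment length range.
#' @param count_mode count tags per start position ("start", default) or per
#'   end position.
#' @param length_mode "representative" (count-weighted median tag length per
#'   transcript, default) or "per-fragment" (each fragment's own length).
#' @param s5,s3 classification anchor windows (see [classify_tsrna()]).
#' @return data.frame of calls: seq, tsrna_type, amino_acid, count, pvalue,
#'   sources (semicolon-joined "gene_id:ref_kind:start-end"), n_sources.
#' @export
call_tsrnas <- function(alignments, reference, p_threshold = 0.01,
                        min_len = 14L, max_len = 45L,
                        count_mode = c("start", "end"),
                        length_mode = c("representative", "per-fragment"),
                        s5 = 2L, s3 = 3L) {
  count_mode <- match.arg(count_mode)
  length_mode <- match.arg(length_mode)
  empty <- data.frame(seq = character(0), tsrna_type = character(0),
                      amino_acid = character(0), count = integer(0),
                      pvalue = numeric(0), sources = character(0),
                      n_sources = integer(0))
  if (!nrow(alignments)) return(empty)
  rt <- ref_table(reference)
  refs <- c(reference$mature, reference$trailers)
  ref_by <- split(seq_along(refs),
                  paste(vapply(refs, `[[`, "", "gene_id"),
                        ifelse(vapply(refs, inherits, TRUE, "trailer_seq"),
                               "trailer", "mature")))
  aln <- alignments
  aln$pos <- if (count_mode == "start") aln$start else aln$end
  aln$tkey <- paste(aln$gene_id, aln$ref_kind)
  frag_rows <- list()
  for (tk in unique(aln$tkey)) {
    sub <- aln[aln$tkey == tk, , drop = FALSE]
    n <- sum(sub$read_count)
    L <- rt$L[match(tk, paste(rt$gene_id, rt$ref_kind))]
    kpos <- tapply(sub$read_count, sub$pos, sum)
    lens <- nchar(sub$read_seq)
    l_rep <- as.integer(round(weighted_median(lens, sub$read_count)))
    for (i in seq_len(nrow(sub))) {
      l <- nchar(sub$read_seq[i])
      if (l < min_len || l > max_len || L < l) next
      l_test <- if (length_mode == "representative") min(l_rep, L) else l
      k <- kpos[[as.character(sub$pos[i])]]
      pv <- binomial_site_pvalue(k, n, L, l_test)
      if (pv >= p_threshold) next
      frag_rows[[length(frag_rows) + 1L]] <- data.frame(
        seq = sub$read_seq[i], gene_id = sub$gene_id[i],
        ref_kind = sub$ref_kind[i], start = sub$start[i], end = sub$end[i],
        count = sub$read_count[i], pvalue = pv, stringsAsFactors = FALSE)
    }
  }
  if (!length(frag_rows)) return(empty)
  fr <- do.call(rbind, frag_rows)
  calls <- lapply(split(fr, fr$seq), function(g) {
    g <- g[order(g$pvalue, g$gene_id, g$ref_kind, g$start), , drop = FALSE]
    types <- vapply(seq_len(nrow(g)), function(i) {
      key <- paste(g$gene_id[i], g$ref_kind[i])
      classify_tsrna(g$start[i], g$end[i],
                     refs[[ref_by[[key]][1]]], s5 = s5, s3 = s3)
    }, character(1))
    aas <- vapply(seq_len(nrow(g)), function(i) {
      key <- paste(g$gene_id[i], g$ref_kind[i])
      r <- refs[[ref_by[[key]][1]]]
      if (is.null(r$amino_acid)) NA_character_ else r$amino_acid
    }, character(1))
    aa_known <- sort(unique(aas[!is.na(aas)]))
    if (!length(aa_known)) {
      # trailer-only call: recover amino acid from the mature mate if present
      mate <- reference$mature[[g$gene_id[1]]]
      aa_known <- if (is.null(mate)) "Xxx" else mate$amino_acid
    }
    if (length(aa_known) > 1L) {
      warning("call ", g$seq[1], " spans amino acids ",
              paste(aa_known, collapse = ","),
              "; using ", aa_known[1])
    }
    data.frame(
      seq = g$seq[1],
      tsrna_type = types[1],
      amino_acid = aa_known[1],
      count = g$count[1],
      pvalue = min(g$pvalue),
      sources = paste(sprintf("%s:%s:%d-%d", g$gene_id, g$ref_kind,
                              g$start, g$end), collapse = ";"),
      n_sources = nrow(g), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, calls)
  out <- out[order(out$seq), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Expand call source strings into a site table
#'
#' Each call lists its sources as "gene_id:ref_kind:start-end" entries; this
#' expands them into one row per (call, source) for positional bookkeeping,
#' e.g. comparing called cleavage sites against a simulation ground truth.
#'
#' @param calls data.frame from [call_tsrnas()].
#' @return data.frame: seq, gene_id, ref_kind, start, end.
#' @export
call_sites <- function(calls) {
  if (!nrow(calls)) {
    return(data.frame(seq = character(0), gene_id = character(0),
                      ref_kind = character(0), start = integer(0),
                      end = integer(0)))
  }
  rows <- lapply(seq_len(nrow(calls)), function(i) {
    parts <- strsplit(strsplit(calls$sources[i], ";", fixed = TRUE)[[1]],
                      ":", fixed = TRUE)
    do.call(rbind, lapply(parts, function(p) {
      iv <- as.integer(strsplit(p[3], "-", fixed = TRUE)[[1]])
      data.frame(seq = calls$seq[i], gene_id = p[1], ref_kind = p[2],
                 start = iv[1], end = iv[2], stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assign stable names to tsRNA calls
#'
#' Names follow the pattern `tsRNA-<amino acid>-<type code>-<serial>` where
#' the type code is 5/3/i/1 for tRFs and 5i/3i for tRNA halves, and the
#' serial is zero-padded and unique within (amino acid, type), assigned in
#' lexicographic order of the fragment sequence so identical inputs always
#' yield identical names.
#'
#' @param calls data.frame from [call_tsrnas()].
#' @return the same data.frame with a `name` column prepended.
#' @export
name_tsrnas <- function(calls) {
  if (!nrow(calls)) {
    calls$name <- character(0)
    return(calls[, c("name", setdiff(names(calls), "name")), drop = FALSE])
  }
  code <- vapply(calls$tsrna_type, type_code, character(1))
  grp <- paste(calls$amino_acid, code, sep = "|")
  serial <- integer(nrow(calls))
  for (g in unique(grp)) {
    idx <- which(grp == g)
    serial[idx][order(calls$seq[idx])] <- seq_along(idx)
  }
  calls$name <- sprintf("tsRNA-%s-%s-%04d", calls$amino_acid, code, serial)
  calls[, c("name", setdiff(names(calls), "name")), drop = FALSE]
}

#' Flag calls present in an experimentally supported whitelist
#'
#' The whitelist collects tsRNAs confirmed by modification-erasing library
#' protocols (e.g. PANDORA-seq); membership is annotation only and never
#' changes which fragments are called.
#'
#' @param calls data.frame of calls.
#' @param whitelist character vector of sequences (T/U spelling free).
#' @return calls with a logical `whitelisted` column.
#' @export
annotate_whitelist <- function(calls, whitelist = character(0)) {
  wl <- if (length(whitelist)) normalize_seq(whitelist) else character(0)
  calls$whitelisted <- calls$seq %in% wl
  calls
}

#' Full tsRNA identification pipeline
#'
#' Collapse reads, apply the exclusion/exogenous filters, align to the
#' mature and trailer references with modification-aware scoring, call
#' positionally enriched fragments with the binomial test, classify, name
#' and annotate whitelist membership.
#'
#' @param reads character vector of read sequences (or collapsed data.frame).
#' @param reference reference set from [build_reference_set()] or
#'   [generate_trna_reference()].
#' @param mod_sites modification-site table or NULL.
#' @param exclusion_refs named character vector of other-RNA references.
#' @param genome named character vector for the exogenous filter (NULL skips).
#' @param whitelist character vector of trusted sequences.
#' @param p_threshold,min_len,max_len,max_edits,min_score,count_mode
#'   tuning parameters passed through to the stages.
#' @param index optional prebuilt alignment index.
#' @return named call table (see [call_tsrnas()], [name_tsrnas()]).
#' @export
tsr_find <- function(reads, reference, mod_sites = NULL,
                     exclusion_refs = NULL, genome = NULL,
                     whitelist = character(0), p_threshold = 0.01,
                     min_len = 14L, max_len = 45L, max_edits = 1L,
                     min_score = -Inf, count_mode = "start",
                     length_mode = "representative", index = NULL) {
  reads <- collapse_reads(reads)
  if (!is.null(exclusion_refs) || !is.null(genome)) {
    reads <- filter_reads(reads, exclusion_refs, genome, max_edits)
  }
  aln <- align_to_trna(reads, reference, mod_sites, max_edits = max_edits,
                       min_score = min_score, min_len = min_len,
                       max_len = max_len, index = index)
  calls <- call_tsrnas(aln, reference, p_threshold = p_threshold,
                       min_len = min_len, max_len = max_len,
                       count_mode = count_mode, length_mode = length_mode)
  annotate_whitelist(name_tsrnas(calls), whitelist)
}
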