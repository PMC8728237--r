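#' Collapse reads to unique sequences with multiplicities
#'
#' @param reads character vector of read sequences (or a data.frame already
#'   carrying seq and count, returned unchanged after normalization).
#' @return data.frame with columns seq, count, sorted by sequence.
#' @export
collapse_reads <- function(reads) {
  if (is.data.frame(reads)) {
    reads$seq <- normalize_seq(reads$seq)
    agg <- stats::aggregate(count ~ seq, data = reads, FUN = sum)
    agg <- agg[order(agg$seq), c("seq", "count")]
    rownames(agg) <- NULL
    return(agg)
  }
  reads <- normalize_seq(reads)
  tab <- table(reads)
  data.frame(seq = names(tab), count = as.integer(tab),
             stringsAsFactors = FALSE)
}

# Flatten a reference set into an alignment table: one row per reference
# sequence (mature tRNAs and trailers).
ref_table <- function(reference) {
  if (!is.null(reference$mature) || !is.null(reference$trailers)) {
    refs <- c(reference$mature, reference$trailers)
  } else {
    refs <- reference
  }
  rows <- lapply(refs, function(r) {
    kind <- if (inherits(r, "trailer_seq")) "trailer" else "mature"
    data.frame(gene_id = r$gene_id, ref_kind = kind, seq = r$seq,
               L = nchar(r$seq), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[nchar(out$seq) > 0L, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build an exact-match index over reference substrings
#'
#' Hash of every reference substring in the read length range; alignment of
#' a perfectly matching read is then a lookup rather than a scan. Build once
#' per reference set and pass to [align_to_trna()] when aligning many
#' libraries against the same references.
#'
#' @param reference reference set (list with `mature` and/or `trailers`, or a
#'   plain list of such objects).
#' @param min_len,max_len read length range indexed.
#' @return an opaque index object.
#' @export
build_alignment_index <- function(reference, min_len = 14L, max_len = 45L) {
  rt <- ref_table(reference)
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(nrow(rt))) {
    s <- rt$seq[i]
    L <- rt$L[i]
    for (len in min_len:min(max_len, L)) {
      for (st in 1:(L - len + 1L)) {
        key <- substr(s, st, st + len - 1L)
        hit <- c(i, st)
        prev <- env[[key]]
        env[[key]] <- if (is.null(prev)) list(hit) else c(prev, list(hit))
      }
    }
  }
  structure(list(env = env, ref_table = rt,
                 min_len = min_len, max_len = max_len),
            class = "tsr_alignment_index")
}

# Ungapped scan: all offsets of `read` on `refseq` with at most max_mm
# mismatches. Returns a list of (start, mismatch positions on reference).
mismatch_scan <- function(read_int, ref_int, max_mm) {
  len <- length(read_int)
  noff <- length(ref_int) - len + 1L
  if (noff < 1L) return(list())
  mm <- integer(noff)
  off <- seq_len(noff)
  for (j in seq_len(len)) {
    mm <- mm + (ref_int[off + j - 1L] != read_int[j])
  }
  keep <- which(mm <= max_mm)
  lapply(keep, function(o) {
    pos <- which(ref_int[o:(o + len - 1L)] != read_int) + o - 1L
    list(start = o, mm_pos = pos)
  })
}

# modification-site lookup environment, keys "gene_id\tposition"
mod_env <- function(mod_sites) {
  env <- new.env(hash = TRUE, parent = emptyenv())
  if (!is.null(mod_sites) && nrow(mod_sites)) {
    for (i in seq_len(nrow(mod_sites))) {
      env[[paste(mod_sites$gene_id[i], mod_sites$position[i], sep = "\t")]] <- TRUE
    }
  }
  env
}

score_placement <- function(n_match, mm_plain, mm_mod, ind_plain, ind_mod) {
  n_match - mm_plain - ind_plain - 0.5 * (mm_mod + ind_mod)
}

#' Align small-RNA reads to tRNA references with modification-aware scoring
#'
#' Exhaustive ungapped offset scan over the mature and trailer references,
#' plus single-indel placements when the edit budget allows and no ungapped
#' placement fits it (a one-indel alignment can tie but never beat an
#' ungapped one under the scoring rule). Scoring follows
#' the modification-aware rule: +1 per matched base, -1 per mismatch or
#' indel at an ordinary position, -0.5 when the mismatch/indel falls on a
#' known modification site (reverse-transcriptase stops and misreads at
#' modified bases are expected, so they are penalized less). For every read
#' all best-scoring placements are kept, so a fragment shared by several
#' isodecoders multi-maps to all of them.
#'
#' @param reads character vector, or data.frame with seq and count columns.
#' @param reference reference set (see [build_reference_set()]).
#' @param mod_sites modification-site data.frame (gene_id, position,
#'   mod_type) on mature coordinates, or NULL.
#' @param max_edits maximum mismatches+indels per placement (at most one
#'   indel is explored).
#' @param min_score minimum alignment score to report.
#' @param min_len,max_len read length range considered.
#' @param index optional prebuilt [build_alignment_index()] object.
#' @return data.frame with one row per reported placement: read_seq,
#'   read_count, gene_id, ref_kind, start, end, n_match, n_mismatch_plain,
#'   n_mismatch_mod, n_indel_plain, n_indel_mod, score.
#' @export
align_to_trna <- function(reads, reference, mod_sites = NULL, max_edits = 1L,
                          min_score = -Inf, min_len = 14L, max_len = 45L,
                          index = NULL) {
  reads <- collapse_reads(reads)
  lens <- nchar(reads$seq)
  reads <- reads[lens >= min_len & lens <= max_len, , drop = FALSE]
  if (is.null(index)) index <- build_alignment_index(reference, min_len, max_len)
  rt <- index$ref_table
  menv <- mod_env(mod_sites)
  ref_ints <- lapply(rt$seq, utf8ToInt)
  is_mod <- function(ref_i, pos) {
    rt$ref_kind[ref_i] == "mature" &&
      !is.null(menv[[paste(rt$gene_id[ref_i], pos, sep = "\t")]])
  }
  out <- vector("list", nrow(reads))
  empty_row <- function() NULL
  for (r in seq_len(nrow(reads))) {
    rs <- reads$seq[r]
    len <- nchar(rs)
    placements <- list()
    hits <- index$env[[rs]]
    if (!is.null(hits)) {
      placements <- lapply(hits, function(h) list(
        ref_i = h[1], start = h[2], end = h[2] + len - 1L,
        n_match = len, mm_plain = 0L, mm_mod = 0L,
        ind_plain = 0L, ind_mod = 0L))
    } else if (max_edits >= 1L) {
      read_int <- utf8ToInt(rs)
      for (i in seq_len(nrow(rt))) {
        for (pl in mismatch_scan(read_int, ref_ints[[i]], max_edits)) {
          mod <- vapply(pl$mm_pos, function(p) is_mod(i, p), logical(1))
          placements[[length(placements) + 1L]] <- list(
            ref_i = i, start = pl$start, end = pl$start + len - 1L,
            n_match = len - length(pl$mm_pos),
            mm_plain = sum(!mod), mm_mod = sum(mod),
            ind_plain = 0L, ind_mod = 0L)
        }
      }
      # single-indel placements are explored only when no ungapped placement
      # fits the budget: a one-indel alignment has one fewer matched base at
      # equal penalty, so it can tie but never beat an ungapped placement
      if (!length(placements)) {
        for (i in seq_len(nrow(rt))) {
          # one read bulge: read carries an extra base relative to reference
          for (del in seq_len(len)) {
            variant <- utf8ToInt(paste0(substr(rs, 1L, del - 1L),
                                        substr(rs, del + 1L, len)))
            for (pl in mismatch_scan(variant, ref_ints[[i]], max_edits - 1L)) {
              ipos <- min(pl$start + del - 1L, pl$start + len - 2L)
              mod <- vapply(pl$mm_pos, function(p) is_mod(i, p), logical(1))
              placements[[length(placements) + 1L]] <- list(
                ref_i = i, start = pl$start, end = pl$start + len - 2L,
                n_match = len - 1L - length(pl$mm_pos),
                mm_plain = sum(!mod), mm_mod = sum(mod),
                ind_plain = as.integer(!is_mod(i, ipos)),
                ind_mod = as.integer(is_mod(i, ipos)))
            }
          }
          # one reference bulge: reference carries an extra (skipped) base
          Lr <- rt$L[i]
          if (Lr >= len + 1L) {
            for (j in seq_len(len - 1L)) {
              for (st in seq_len(Lr - len)) {
                skip <- st + j
                win <- c(ref_ints[[i]][st:(st + j - 1L)],
                         ref_ints[[i]][(skip + 1L):(st + len)])
                mmp <- which(win != read_int)
                if (length(mmp) > max_edits - 1L) next
                ref_mm <- ifelse(mmp <= j, st + mmp - 1L, st + mmp)
                mod <- vapply(ref_mm, function(p) is_mod(i, p), logical(1))
                placements[[length(placements) + 1L]] <- list(
                  ref_i = i, start = st, end = st + len,
                  n_match = len - length(mmp),
                  mm_plain = sum(!mod), mm_mod = sum(mod),
                  ind_plain = as.integer(!is_mod(i, skip)),
                  ind_mod = as.integer(is_mod(i, skip)))
              }
            }
          }
        }
      }
    }
    if (!length(placements)) next
    sc <- vapply(placements, function(p) score_placement(
      p$n_match, p$mm_plain, p$mm_mod, p$ind_plain, p$ind_mod), numeric(1))
    keep <- sc >= min_score & sc == max(sc[sc >= min_score], -Inf)
    if (!any(keep)) next
    placements <- placements[keep]
    sc <- sc[keep]
    # deduplicate identical intervals reached by different routes
    key <- vapply(placements, function(p)
      paste(p$ref_i, p$start, p$end), character(1))
    first <- !duplicated(key)
    placements <- placements[first]
    sc <- sc[first]
    out[[r]] <- data.frame(
      read_seq = rs, read_count = reads$count[r],
      gene_id = rt$gene_id[vapply(placements, `[[`, 0L, "ref_i")],
      ref_kind = rt$ref_kind[vapply(placements, `[[`, 0L, "ref_i")],
      start = vapply(placements, `[[`, 0L, "start"),
      end = vapply(placements, `[[`, 0L, "end"),
      n_match = vapply(placements, `[[`, 0L, "n_match"),
      n_mismatch_plain = vapply(placements, `[[`, 0L, "mm_plain"),
      n_mismatch_mod = vapply(placements, `[[`, 0L, "mm_mod"),
      n_indel_plain = vapply(placements, `[[`, 0L, "ind_plain"),
      n_indel_mod = vapply(placements, `[[`, 0L, "ind_mod"),
      score = sc, stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(data.frame(read_seq = character(0), read_count = integer(0),
                      gene_id = character(0), ref_kind = character(0),
                      start = integer(0), end = integer(0),
                      n_match = integer(0), n_mismatch_plain = integer(0),
                      n_mismatch_mod = integer(0), n_indel_plain = integer(0),
                      n_indel_mod = integer(0), score = numeric(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# does `read` occur within refseq with at most max_mm mismatches (ungapped)?
matches_within <- function(read, refseq, max_mm = 0L) {
  if (nchar(read) > nchar(refseq)) return(FALSE)
  cnt <- Biostrings::countPattern(read, refseq, max.mismatch = max_mm,
                                  fixed = TRUE)
  cnt > 0L
}

#' Filter a read set against exclusion references and the genome
#'
#' Reads matching any exclusion reference (other small RNA classes: rRNA,
#' snoRNA, snRNA, miRNA, mRNA fragments, repeats) within the mismatch budget
#' are discarded; when a genome is supplied, reads with no genomic match on
#' either strand are discarded as exogenous. Removal counts per category are
#' reported via `message()` so the filtering cascade is auditable from the
#' log.
#'
#' @param reads character vector or collapsed data.frame (seq, count).
#' @param exclusion_refs named character vector of sequences to exclude
#'   against (NULL for none).
#' @param genome named character vector of chromosome sequences, or NULL to
#'   skip the exogenous filter.
#' @param max_edits mismatch budget for both checks.
#' @return collapsed data.frame (seq, count) of retained reads.
#' @export
filter_reads <- function(reads, exclusion_refs = NULL, genome = NULL,
                         max_edits = 1L) {
  reads <- collapse_reads(reads)
  n0 <- nrow(reads)
  if (!is.null(exclusion_refs) && length(exclusion_refs)) {
    excl <- vapply(reads$seq, function(s)
      any(vapply(exclusion_refs, function(ref)
        matches_within(s, ref, max_edits), logical(1))), logical(1))
    message("filter_reads: ", sum(excl), "/", n0,
            " unique reads matched exclusion references")
    reads <- reads[!excl, , drop = FALSE]
  }
  if (!is.null(genome) && length(genome)) {
    n1 <- nrow(reads)
    genomic <- vapply(reads$seq, function(s) {
      any(vapply(genome, function(chrom)
        matches_within(s, chrom, max_edits) ||
          matches_within(revcomp(s), chrom, max_edits), logical(1)))
    }, logical(1))
    message("filter_reads: ", sum(!genomic), "/", n1,
            " unique reads removed as exogenous (no genomic match)")
    reads <- reads[genomic, , drop = FALSE]
  }
  rownames(reads) <- NULL
  reads
}
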