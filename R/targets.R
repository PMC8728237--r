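#' Collapse CLIP reads and separate tsRNA tags from target tags
#'
#' Reads are collapsed to unique sequences with multiplicities; reads shorter
#' than `min_len` are discarded. Reads matching a tRNA reference on the sense
#' strand are tsRNA fragments (`is_tsrna = TRUE`); reads matching tRNA only
#' as the reverse complement are antisense artifacts and are removed; the
#' remainder are candidate target-side tags.
#'
#' @param reads character vector or collapsed data.frame (seq, count).
#' @param trna_refs reference set (or named character vector of tRNA
#'   sequences) used for the strand test.
#' @param min_len minimum read length retained.
#' @param max_edits mismatch budget of the strand test.
#' @return data.frame: seq, count, is_tsrna.
#' @export
collapse_and_filter_tags <- function(reads, trna_refs, min_len = 14L,
                                     max_edits = 0L) {
  tags <- collapse_reads(reads)
  tags <- tags[nchar(tags$seq) >= min_len, , drop = FALSE]
  refseqs <- if (is.character(trna_refs)) trna_refs
             else ref_table(trna_refs)$seq
  sense <- vapply(tags$seq, function(s)
    any(vapply(refseqs, function(ref)
      matches_within(s, ref, max_edits), logical(1))), logical(1))
  anti <- !sense & vapply(tags$seq, function(s)
    any(vapply(refseqs, function(ref)
      matches_within(revcomp(s), ref, max_edits), logical(1))), logical(1))
  if (any(anti)) {
    message("collapse_and_filter_tags: ", sum(anti),
            " antisense tag(s) removed")
  }
  tags <- tags[!anti, , drop = FALSE]
  tags$is_tsrna <- sense[!anti]
  rownames(tags) <- NULL
  tags
}

#' Place target-side tags on transcripts and compute coverage
#'
#' @param tags data.frame (seq, count) of target-side tags.
#' @param targets named character vector of target transcript sequences.
#' @return list with `tags` (seq, count, target_id, start, end, strand) and
#'   `coverage` (named list of per-position integer vectors).
#' @export
map_tags_to_targets <- function(tags, targets) {
  placed <- list()
  coverage <- lapply(targets, function(t) integer(nchar(t)))
  for (i in seq_len(nrow(tags))) {
    s <- tags$seq[i]
    for (tid in names(targets)) {
      m <- gregexpr(s, targets[[tid]], fixed = TRUE)[[1]]
      if (m[1] == -1L) next
      for (st in as.integer(m)) {
        en <- st + nchar(s) - 1L
        placed[[length(placed) + 1L]] <- data.frame(
          seq = s, count = tags$count[i], target_id = tid,
          start = st, end = en, strand = "+", stringsAsFactors = FALSE)
        coverage[[tid]][st:en] <- coverage[[tid]][st:en] + tags$count[i]
      }
    }
  }
  tag_df <- if (length(placed)) do.call(rbind, placed) else
    data.frame(seq = character(0), count = integer(0),
               target_id = character(0), start = integer(0),
               end = integer(0), strand = character(0))
  list(tags = tag_df, coverage = coverage)
}

#' Call peaks in a tag-coverage vector by local maxima
#'
#' A summit is a position whose coverage reaches `min_height` and strictly
#' exceeds both flanking values (for a plateau, its leftmost position). The
#' peak interval extends from the summit while coverage stays at or above
#' half the summit height. Peaks are claimed in decreasing height order and
#' trimmed so no two peaks overlap.
#'
#' @param coverage non-negative integer vector.
#' @param min_height minimum summit height.
#' @return data.frame: summit, height, start, end.
#' @export
call_peaks <- function(coverage, min_height = 1L) {
  empty <- data.frame(summit = integer(0), height = numeric(0),
                      start = integer(0), end = integer(0))
  n <- length(coverage)
  if (!n) return(empty)
  r <- rle(as.numeric(coverage))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  prevv <- c(-Inf, r$values[-length(r$values)])
  nextv <- c(r$values[-1], -Inf)
  is_summit <- r$values >= min_height & r$values > prevv & r$values > nextv
  if (!any(is_summit)) return(empty)
  summits <- starts[is_summit]
  heights <- r$values[is_summit]
  ord <- order(-heights, summits)
  claimed <- logical(n)
  rows <- list()
  for (idx in ord) {
    sm <- summits[idx]; h <- heights[idx]
    if (claimed[sm]) next
    half <- h / 2
    lo <- sm
    while (lo > 1L && coverage[lo - 1L] >= half && !claimed[lo - 1L]) lo <- lo - 1L
    hi <- sm
    while (hi < n && coverage[hi + 1L] >= half && !claimed[hi + 1L]) hi <- hi + 1L
    claimed[lo:hi] <- TRUE
    rows[[length(rows) + 1L]] <- data.frame(summit = sm, height = h,
                                            start = lo, end = hi)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$summit), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# base-pair stacking surrogate: GC -3, AU -2, GU wobble -1; NA if not a pair
pair_score <- function(a, b) {
  key <- paste0(a, b)
  sc <- c(GC = -3, CG = -3, AT = -2, TA = -2, GT = -1, TG = -1)[key]
  unname(sc)
}

# lexicographic comparison of duplex outcomes: lower score, then more pairs,
# then leftmost paired target position, then fewer mismatches
better_outcome <- function(a, b) {
  if (a$sc != b$sc) return(a$sc < b$sc)
  if (a$np != b$np) return(a$np > b$np)
  if (a$minj != b$minj) return(a$minj < b$minj)
  a$nm < b$nm
}

#' Seed-anchored tsRNA-target duplex search
#'
#' Finds the best antiparallel duplex between a tsRNA and a target site. The
#' duplex must contain a fully paired, gap-free helix across the tsRNA seed
#' (positions 2-7 by default, a 6-nt anchor); extension to either side may
#' use Watson-Crick or G-U pairs, at most `max_mismatch` interior
#' mismatches, and at most `max_bulge_*` unpaired bases per strand. The
#' surrogate stacking energy scores each pair -3 (GC), -2 (AU) or -1 (GU)
#' and charges +1 per mismatch and per bulged base; a duplex is reported
#' only if its score is at or below `energy_cutoff`, so the default -10
#' demands roughly a 4-6 bp stable helix beyond nothing. Ties are broken by
#' more pairs, then leftmost target position.
#'
#' @param tsrna tsRNA sequence (>= 8 nt).
#' @param target target site sequence.
#' @param max_mismatch maximum interior mismatches.
#' @param max_bulge_tsrna,max_bulge_target maximum bulged bases per strand.
#' @param seed_span integer length-2: first and last seed position on the
#'   tsRNA.
#' @param energy_cutoff report duplexes with score <= this value.
#' @return a `duplex_pairing` object (list: tsrna_seq, target_seq, pair_map
#'   two-column matrix of paired positions, seed_ok, duplex_score,
#'   mismatches, site c(start, end) on target) or NULL when no qualifying
#'   duplex exists.
#' @export
find_duplex <- function(tsrna, target, max_mismatch = 2L,
                        max_bulge_tsrna = 2L, max_bulge_target = 2L,
                        seed_span = c(2L, 7L), energy_cutoff = -10) {
  ts <- strsplit(normalize_seq(tsrna), "", fixed = TRUE)[[1]]
  tg <- strsplit(normalize_seq(target), "", fixed = TRUE)[[1]]
  if (length(ts) < 8L) stop("tsRNA must be at least 8 nt")
  s1 <- seed_span[1]; s2 <- seed_span[2]
  w <- s2 - s1 + 1L
  lts <- length(ts); ltg <- length(tg)
  if (ltg < w) return(NULL)
  best <- NULL
  best_site_start <- Inf
  for (j in seq_len(ltg - w + 1L)) {
    # seed anchor: tsrna s1..s2 pairs antiparallel with target (j+w-1)..j
    seed_sc <- 0
    seed_pairs <- matrix(0L, nrow = w, ncol = 2)
    ok <- TRUE
    for (t in 0:(w - 1L)) {
      ps <- pair_score(ts[s1 + t], tg[j + w - 1L - t])
      if (is.na(ps)) { ok <- FALSE; break }
      seed_sc <- seed_sc + ps
      seed_pairs[t + 1L, ] <- c(s1 + t, j + w - 1L - t)
    }
    if (!ok) next
    memo3 <- new.env(hash = TRUE, parent = emptyenv())
    memo5 <- new.env(hash = TRUE, parent = emptyenv())
    # 3' extension: tsrna i = s2+1.. pairs target j-1 downward
    rec3 <- function(i, mm, bt, bg) {
      key <- paste(i, mm, bt, bg)
      hit <- memo3[[key]]
      if (!is.null(hit)) return(hit)
      res <- list(sc = 0, np = 0L, nm = 0L, minj = Inf, pairs = NULL)
      jj <- j - (i - s2) + bt - bg
      if (i <= lts && jj >= 1L) {
        ps <- pair_score(ts[i], tg[jj])
        if (!is.na(ps)) {
          ch <- rec3(i + 1L, mm, bt, bg)
          cand <- list(sc = ps + ch$sc, np = ch$np + 1L, nm = ch$nm,
                       minj = min(jj, ch$minj),
                       pairs = rbind(c(i, jj), ch$pairs))
          if (better_outcome(cand, res)) res <- cand
        }
        if (mm < max_mismatch) {
          ch <- rec3(i + 1L, mm + 1L, bt, bg)
          cand <- list(sc = 1 + ch$sc, np = ch$np, nm = ch$nm + 1L,
                       minj = ch$minj, pairs = ch$pairs)
          if (better_outcome(cand, res)) res <- cand
        }
      }
      if (i <= lts && bt < max_bulge_tsrna) {
        ch <- rec3(i + 1L, mm, bt + 1L, bg)
        cand <- list(sc = 1 + ch$sc, np = ch$np, nm = ch$nm, minj = ch$minj,
                     pairs = ch$pairs)
        if (better_outcome(cand, res)) res <- cand
      }
      if (jj - 1L >= 1L && bg < max_bulge_target) {
        ch <- rec3(i, mm, bt, bg + 1L)
        cand <- list(sc = 1 + ch$sc, np = ch$np, nm = ch$nm, minj = ch$minj,
                     pairs = ch$pairs)
        if (better_outcome(cand, res)) res <- cand
      }
      memo3[[key]] <- res
      res
    }
    # 5' extension: tsrna i = s1-1..1 pairs target j+w upward; stopping hands
    # the remaining budgets to the 3' side
    rec5 <- function(i, mm, bt, bg) {
      if (i < 1L) return(rec3(s2 + 1L, mm, bt, bg))
      key <- paste(i, mm, bt, bg)
      hit <- memo5[[key]]
      if (!is.null(hit)) return(hit)
      res <- rec3(s2 + 1L, mm, bt, bg)
      jj <- j + w + (s1 - 1L - i) - bt + bg
      if (jj <= ltg) {
        ps <- pair_score(ts[i], tg[jj])
        if (!is.na(ps)) {
          ch <- rec5(i - 1L, mm, bt, bg)
          cand <- list(sc = ps + ch$sc, np = ch$np + 1L, nm = ch$nm,
                       minj = min(jj, ch$minj),
                       pairs = rbind(c(i, jj), ch$pairs))
          if (better_outcome(cand, res)) res <- cand
        }
        if (mm < max_mismatch) {
          ch <- rec5(i - 1L, mm + 1L, bt, bg)
          cand <- list(sc = 1 + ch$sc, np = ch$np, nm = ch$nm + 1L,
                       minj = ch$minj, pairs = ch$pairs)
          if (better_outcome(cand, res)) res <- cand
        }
        if (bg < max_bulge_target) {
          ch <- rec5(i, mm, bt, bg + 1L)
          cand <- list(sc = 1 + ch$sc, np = ch$np, nm = ch$nm,
                       minj = ch$minj, pairs = ch$pairs)
          if (better_outcome(cand, res)) res <- cand
        }
      }
      if (bt < max_bulge_tsrna) {
        ch <- rec5(i - 1L, mm, bt + 1L, bg)
        cand <- list(sc = 1 + ch$sc, np = ch$np, nm = ch$nm, minj = ch$minj,
                     pairs = ch$pairs)
        if (better_outcome(cand, res)) res <- cand
      }
      memo5[[key]] <- res
      res
    }
    ext <- rec5(s1 - 1L, 0L, 0L, 0L)
    cand <- list(sc = seed_sc + ext$sc, np = w + ext$np, nm = ext$nm,
                 pairs = rbind(seed_pairs, ext$pairs))
    site_start <- min(j, ext$minj)
    replace <- is.null(best) || cand$sc < best$sc ||
      (cand$sc == best$sc &&
         (cand$np > best$np ||
            (cand$np == best$np && site_start < best_site_start)))
    if (replace) {
      best <- cand
      best_site_start <- site_start
    }
  }
  if (is.null(best) || best$sc > energy_cutoff) return(NULL)
  pm <- best$pairs[order(best$pairs[, 1]), , drop = FALSE]
  colnames(pm) <- c("tsrna_pos", "target_pos")
  structure(list(tsrna_seq = paste(ts, collapse = ""),
                 target_seq = paste(tg, collapse = ""),
                 pair_map = pm,
                 seed_ok = all(s1:s2 %in% pm[, 1]),
                 duplex_score = best$sc,
                 mismatches = best$nm,
                 site = c(start = min(pm[, 2]), end = max(pm[, 2]))),
            class = "duplex_pairing")
}

#' @export
print.duplex_pairing <- function(x, ...) {
  cat(sprintf("duplex: %d pairs, score %.1f, %d mismatch(es), target %d-%d\n",
              nrow(x$pair_map), x$duplex_score, x$mismatches,
              x$site["start"], x$site["end"]))
  invisible(x)
}

#' Split a chimeric read into tsRNA and target arms
#'
#' Finds the longest prefix and the longest suffix of the read matching any
#' tRNA reference (within the mismatch budget) and takes the longer as the
#' tsRNA arm. The split is reported only when the arm length falls within
#' \[min_tsrna, max_tsrna\] and the unmatched remainder exceeds
#' `min_target - 1` nt.
#'
#' @param read chimeric read sequence.
#' @param trna_refs reference set or named character vector of tRNA
#'   sequences.
#' @param min_tsrna,max_tsrna admissible tsRNA arm length range.
#' @param min_target minimum target arm length.
#' @param max_edits mismatch budget of the arm match; the default 0 keeps
#'   arm boundaries exact (with a budget, a chance match beyond a mismatch
#'   can extend an arm past the true ligation point).
#' @return list (seq, tsrna_arm = c(start, end), target_arm = c(start, end),
#'   source_gene_id) or NULL.
#' @export
split_chimera <- function(read, trna_refs, min_tsrna = 14L, max_tsrna = 40L,
                          min_target = 9L, max_edits = 0L) {
  read <- normalize_seq(read)
  len <- nchar(read)
  rt <- if (is.character(trna_refs)) {
    data.frame(gene_id = names(trna_refs), seq = unname(trna_refs),
               stringsAsFactors = FALSE)
  } else {
    ref_table(trna_refs)
  }
  read_int <- utf8ToInt(read)
  # longest prefix of ri matching somewhere in the references with <= budget
  # mismatches; refs are passed reversed when searching for a suffix arm
  longest_arm <- function(ri, reverse = FALSE) {
    best_len <- 0L; best_gene <- NA_character_
    for (g in seq_len(nrow(rt))) {
      ref_int <- utf8ToInt(rt$seq[g])
      if (reverse) ref_int <- rev(ref_int)
      Lr <- length(ref_int)
      for (st in seq_len(Lr)) {
        span <- min(length(ri), Lr - st + 1L)
        if (span <= best_len) next
        mism <- cumsum(ref_int[st:(st + span - 1L)] != ri[seq_len(span)])
        okl <- which(mism <= max_edits)
        if (length(okl) && max(okl) > best_len) {
          best_len <- max(okl)
          best_gene <- rt$gene_id[g]
        }
      }
    }
    list(len = best_len, gene = best_gene)
  }
  pre <- longest_arm(read_int)
  suf <- longest_arm(rev(read_int), reverse = TRUE)
  use_prefix <- pre$len >= suf$len
  arm_len <- if (use_prefix) pre$len else suf$len
  gene <- if (use_prefix) pre$gene else suf$gene
  rest <- len - arm_len
  if (arm_len < min_tsrna || arm_len > max_tsrna || rest < min_target) {
    return(NULL)
  }
  if (use_prefix) {
    list(seq = read, tsrna_arm = c(1L, arm_len),
         target_arm = c(arm_len + 1L, len), source_gene_id = gene)
  } else {
    list(seq = read, tsrna_arm = c(len - arm_len + 1L, len),
         target_arm = c(1L, len - arm_len), source_gene_id = gene)
  }
}

#' Detect a fake chimera
#'
#' A read is a fake chimera when it aligns contiguously to the genome (either
#' strand, within the edit budget): it is one genomic fragment rather than a
#' ligation product of two molecules.
#'
#' @param read read sequence.
#' @param genome named character vector of chromosome sequences.
#' @param max_edits mismatch budget.
#' @return TRUE when the read maps contiguously.
#' @export
detect_fake_chimera <- function(read, genome, max_edits = 1L) {
  read <- normalize_seq(read)
  any(vapply(genome, function(chrom)
    matches_within(read, chrom, max_edits) ||
      matches_within(revcomp(read), chrom, max_edits), logical(1)))
}

#' Filter interactions by binding-site conservation
#'
#' The mean per-base conservation over the binding site (positions missing
#' from the track count as 0) must exceed `cutoff` for an interaction to be
#' retained; the mean is stored in `conservation_mean`.
#'
#' @param interactions data.frame with target_id, site_start, site_end.
#' @param track per-base track data.frame (target_id, pos, score), e.g. from
#'   [read_conservation_track()] or [simulate_conservation_track()].
#' @param cutoff retention threshold on the mean.
#' @return filtered interactions with conservation_mean added.
#' @export
conservation_filter <- function(interactions, track, cutoff = 0.3) {
  if (!nrow(interactions)) {
    interactions$conservation_mean <- numeric(0)
    return(interactions)
  }
  key <- paste(track$target_id, track$pos)
  means <- vapply(seq_len(nrow(interactions)), function(i) {
    pos <- interactions$site_start[i]:interactions$site_end[i]
    sc <- track$score[match(paste(interactions$target_id[i], pos), key)]
    sc[is.na(sc)] <- 0
    mean(sc)
  }, numeric(1))
  interactions$conservation_mean <- means
  out <- interactions[means > cutoff, , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_interactions <- function() {
  data.frame(tsrna_name = character(0), tsrna_seq = character(0),
             target_id = character(0), site_start = integer(0),
             site_end = integer(0), seed_ok = logical(0),
             duplex_score = numeric(0), mismatches = integer(0),
             evidence = character(0), experiment_id = character(0),
             stringsAsFactors = FALSE)
}

#' Discover tsRNA targets from CLIP tag data
#'
#' Collapses and strand-filters tags, maps target-side tags onto the target
#' transcripts, calls coverage peaks, and pairs every tsRNA with every peak
#' sequence through [find_duplex()]; optionally applies the conservation
#' filter.
#'
#' @param reads CLIP read sequences.
#' @param tsrnas named character vector of tsRNA sequences (names become
#'   tsrna_name).
#' @param trna_refs reference set for the strand filter.
#' @param targets named character vector of target transcripts.
#' @param min_height minimum peak summit height.
#' @param track optional conservation track data.frame.
#' @param conservation_cutoff threshold for the track filter.
#' @param experiment_id label copied to the output.
#' @param ... passed to [find_duplex()].
#' @return interactions data.frame.
#' @export
find_targets_clip <- function(reads, tsrnas, trna_refs, targets,
                              min_height = 2L, track = NULL,
                              conservation_cutoff = 0.3,
                              experiment_id = "clip", ...) {
  tags <- collapse_and_filter_tags(reads, trna_refs)
  mapped <- map_tags_to_targets(tags[!tags$is_tsrna, , drop = FALSE], targets)
  rows <- list()
  for (tid in names(targets)) {
    peaks <- call_peaks(mapped$coverage[[tid]], min_height = min_height)
    for (p in seq_len(nrow(peaks))) {
      site_seq <- substr(targets[[tid]], peaks$start[p], peaks$end[p])
      for (tn in names(tsrnas)) {
        dp <- find_duplex(tsrnas[[tn]], site_seq, ...)
        if (is.null(dp)) next
        rows[[length(rows) + 1L]] <- data.frame(
          tsrna_name = tn, tsrna_seq = normalize_seq(tsrnas[[tn]]),
          target_id = tid,
          site_start = peaks$start[p] + dp$site["start"] - 1L,
          site_end = peaks$start[p] + dp$site["end"] - 1L,
          seed_ok = dp$seed_ok, duplex_score = dp$duplex_score,
          mismatches = dp$mismatches, evidence = "CLIP",
          experiment_id = experiment_id, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty_interactions()
  rownames(out) <- NULL
  if (!is.null(track)) {
    out <- conservation_filter(out, track, conservation_cutoff)
  }
  out
}

#' Discover tsRNA targets from CLASH/CLEAR chimeric reads
#'
#' Removes fake chimeras (reads mapping contiguously to the genome), splits
#' each remaining read into a tsRNA arm and a target arm, and requires a
#' qualifying duplex between the two arms.
#'
#' @param chimeras character vector of chimeric read sequences.
#' @param trna_refs reference set for arm matching.
#' @param genome named character vector for fake-chimera removal (NULL
#'   skips).
#' @param evidence "CLASH" or "CLEAR" label.
#' @param experiment_id label copied to the output.
#' @param max_edits mismatch budget of the genomic fake-chimera check.
#' @param split_edits mismatch budget of the arm split (0 keeps boundaries
#'   exact).
#' @param ... passed to [find_duplex()].
#' @return interactions data.frame; site coordinates are on the target arm
#'   of the read, and tsrna_name is the arm sequence.
#' @export
find_targets_clash <- function(chimeras, trna_refs, genome = NULL,
                               evidence = "CLASH", experiment_id = "clash",
                               max_edits = 1L, split_edits = 0L, ...) {
  chimeras <- normalize_seq(chimeras)
  rows <- list()
  n_fake <- 0L
  for (ci in seq_along(chimeras)) {
    rd <- chimeras[ci]
    if (!is.null(genome) && detect_fake_chimera(rd, genome, max_edits)) {
      n_fake <- n_fake + 1L
      next
    }
    sp <- split_chimera(rd, trna_refs, max_edits = split_edits)
    if (is.null(sp)) next
    ts_seq <- substr(rd, sp$tsrna_arm[1], sp$tsrna_arm[2])
    tg_seq <- substr(rd, sp$target_arm[1], sp$target_arm[2])
    dp <- find_duplex(ts_seq, tg_seq, ...)
    if (is.null(dp)) next
    rows[[length(rows) + 1L]] <- data.frame(
      tsrna_name = ts_seq, tsrna_seq = ts_seq,
      target_id = paste0("chimera_", ci),
      site_start = unname(dp$site["start"]),
      site_end = unname(dp$site["end"]),
      seed_ok = dp$seed_ok, duplex_score = dp$duplex_score,
      mismatches = dp$mismatches, evidence = evidence,
      experiment_id = experiment_id, stringsAsFactors = FALSE)
  }
  if (n_fake) message("find_targets_clash: ", n_fake, " fake chimera(s) removed")
  out <- if (length(rows)) do.call(rbind, rows) else empty_interactions()
  rownames(out) <- NULL
  out
}
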