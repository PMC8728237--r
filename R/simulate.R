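#' Simulation configuration
#'
#' Bundles the knobs of the synthetic-data generators. Defaults describe a
#' small but realistic study: ten tRNA genes of canonical length, uniform
#' degradation background at one tag per position (the exact null of the
#' positional binomial test), and planted fragments specified by the caller.
#'
#' @param seed integer seed; every generator draw flows from it.
#' @param n_trnas number of tRNA genes.
#' @param trna_len_range spliced-length range of the genes (nt).
#' @param planted_tsrnas data.frame (gene_index, start, end, abundance) of
#'   fragments to plant on mature tRNAs, or NULL.
#' @param background_depth uniform degradation background, tags per position.
#' @param n_noise_reads number of random non-tRNA reads.
#' @param mismatch_rate per-base mismatch probability of planted reads
#'   (tripled at modification sites, where reverse transcription misreads).
#' @param mod_sites_per_trna modification sites sampled per gene.
#' @param intron_prob probability a gene carries an intron.
#' @param intron_len_range intron length range (nt).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_trnas = 10L, trna_len_range = c(72L, 90L),
                       planted_tsrnas = NULL, background_depth = 1,
                       n_noise_reads = 0L, mismatch_rate = 0,
                       mod_sites_per_trna = 2L, intron_prob = 0.3,
                       intron_len_range = c(8L, 20L)) {
  stopifnot(background_depth >= 0, mismatch_rate >= 0, mismatch_rate <= 1,
            trna_len_range[1] <= trna_len_range[2])
  if (!is.null(planted_tsrnas) && any(planted_tsrnas$abundance < 1)) {
    stop("planted abundances must be >= 1")
  }
  structure(list(seed = as.integer(seed), n_trnas = as.integer(n_trnas),
                 trna_len_range = trna_len_range,
                 planted_tsrnas = planted_tsrnas,
                 background_depth = background_depth,
                 n_noise_reads = as.integer(n_noise_reads),
                 mismatch_rate = mismatch_rate,
                 mod_sites_per_trna = as.integer(mod_sites_per_trna),
                 intron_prob = intron_prob,
                 intron_len_range = intron_len_range),
            class = "sim_config")
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a synthetic tRNA reference set
#'
#' Random tRNA-like genes with an anticodon embedded mid-sequence, an
#' optional intron inserted just 3' of the anticodon (where real tRNA introns
#' sit), placement on a toy chromosome with >= 60 nt flanks on alternating
#' strands, and sampled modification sites on mature coordinates. Fully
#' reproducible per seed.
#'
#' @param config a [sim_config()].
#' @return list with `genes` (annotation data.frame incl. genomic_seq),
#'   `genome` (named character), `mod_sites` (data.frame) and `reference`
#'   (built mature/trailer set, see [build_reference_set()]).
#' @export
generate_trna_reference <- function(config) {
  set.seed(config$seed)
  lr <- config$trna_len_range
  if (lr[1] < 40L) stop("tRNA length range too small for anticodon placement")
  aas <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His",
           "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp",
           "Tyr", "Val")
  flank <- 60L
  chrom_parts <- character(0)
  pos <- 0L
  rows <- list()
  for (i in seq_len(config$n_trnas)) {
    Ls <- sample(lr[1]:lr[2], 1L)
    spliced <- random_seq(Ls)
    a <- round(Ls * 0.45)
    anticodon <- random_seq(3L)
    substr(spliced, a, a + 2L) <- anticodon
    has_intron <- stats::runif(1) < config$intron_prob
    if (has_intron) {
      ilen <- sample(config$intron_len_range[1]:config$intron_len_range[2], 1L)
      intron <- random_seq(ilen)
      cut <- a + 3L
      unspliced <- paste0(substr(spliced, 1L, cut), intron,
                          substr(spliced, cut + 1L, Ls))
      introns <- sprintf("%d-%d", cut + 1L, cut + ilen)
    } else {
      unspliced <- spliced
      introns <- ""
    }
    strand <- sample(c("+", "-"), 1L)
    left <- random_seq(flank)
    chrom_parts <- c(chrom_parts, left,
                     if (strand == "+") unspliced else revcomp(unspliced))
    start <- pos + flank + 1L
    end <- start + nchar(unspliced) - 1L
    pos <- end
    aa <- sample(aas, 1L)
    rows[[i]] <- data.frame(
      gene_id = sprintf("tRNA-%s-%s-%d-1", aa, anticodon, i),
      amino_acid = aa, anticodon = anticodon, chrom = "chrT",
      start = start, end = end, strand = strand, introns = introns,
      genomic_seq = unspliced, stringsAsFactors = FALSE)
  }
  chrom_parts <- c(chrom_parts, random_seq(flank))
  genome <- c(chrT = paste(chrom_parts, collapse = ""))
  genes <- do.call(rbind, rows)
  reference <- build_reference_set(genes, genome)
  mods <- lapply(seq_len(nrow(genes)), function(i) {
    m <- reference$mature[[genes$gene_id[i]]]
    if (config$mod_sites_per_trna < 1L) return(NULL)
    data.frame(gene_id = m$gene_id,
               position = sort(sample(seq_len(m$L),
                                      min(config$mod_sites_per_trna, m$L))),
               mod_type = sample(c("m1A", "m5C", "m7G", "Y"),
                                 min(config$mod_sites_per_trna, m$L),
                                 replace = TRUE),
               stringsAsFactors = FALSE)
  })
  mods <- mods[!vapply(mods, is.null, logical(1))]
  mod_sites <- if (length(mods)) do.call(rbind, mods) else
    data.frame(gene_id = character(0), position = integer(0),
               mod_type = character(0))
  list(genes = genes, genome = genome, mod_sites = mod_sites,
       reference = reference)
}

mutate_read <- function(seq, rate, mod_pos = integer(0)) {
  if (rate <= 0) return(seq)
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  p <- rep(rate, length(bases))
  p[mod_pos] <- pmin(1, 3 * rate)
  hit <- stats::runif(length(bases)) < p
  if (any(hit)) {
    for (i in which(hit)) {
      bases[i] <- sample(setdiff(c("A", "C", "G", "T"), bases[i]), 1L)
    }
  }
  paste(bases, collapse = "")
}

#' Simulate a small-RNA sequencing library
#'
#' Emits planted tsRNA reads at their stated abundances (with per-base
#' mismatches at `mismatch_rate`, biased toward modification sites), a
#' uniform tRNA-degradation background (for each fragment a length is drawn
#' with a geometric tail and its start is uniform over all admissible
#' positions — the exact null of the positional binomial test) and random
#' non-tRNA noise reads, together with a ground-truth manifest.
#'
#' @param config a [sim_config()].
#' @param ref output of [generate_trna_reference()].
#' @param seed seed for the library draw (defaults to `config$seed`); vary it
#'   to generate replicate libraries over one reference.
#' @param min_len,max_len background fragment length range.
#' @param len_geom_prob geometric-tail parameter of background lengths.
#' @return list with `reads` (character vector, one element per read copy)
#'   and `truth` (list of data.frames: planted, background, noise).
#' @export
simulate_small_rna_library <- function(config, ref, seed = config$seed,
                                       min_len = 14L, max_len = 45L,
                                       len_geom_prob = 0.25) {
  set.seed(seed)
  mature <- ref$reference$mature
  mods_by_gene <- split(ref$mod_sites$position, ref$mod_sites$gene_id)
  reads <- character(0)
  planted_rows <- list()
  if (!is.null(config$planted_tsrnas) && nrow(config$planted_tsrnas)) {
    pt <- config$planted_tsrnas
    for (i in seq_len(nrow(pt))) {
      m <- mature[[pt$gene_index[i]]]
      if (pt$end[i] > m$L) stop("planted fragment outside mature tRNA")
      frag <- substr(m$seq, pt$start[i], pt$end[i])
      mod_pos <- mods_by_gene[[m$gene_id]]
      mod_local <- mod_pos[mod_pos >= pt$start[i] & mod_pos <= pt$end[i]] -
        pt$start[i] + 1L
      copies <- vapply(seq_len(pt$abundance[i]), function(x)
        mutate_read(frag, config$mismatch_rate, mod_local), character(1))
      reads <- c(reads, copies)
      planted_rows[[i]] <- data.frame(
        kind = "planted", gene_id = m$gene_id, start = pt$start[i],
        end = pt$end[i], length = nchar(frag), seq = frag,
        count = pt$abundance[i], stringsAsFactors = FALSE)
    }
  }
  bg_rows <- list()
  if (config$background_depth > 0) {
    for (m in mature) {
      n_pos <- m$L - min_len + 1L
      n_tags <- round(config$background_depth * n_pos)
      if (n_tags < 1L) next
      lens <- pmin(min_len + stats::rgeom(n_tags, len_geom_prob),
                   pmin(max_len, m$L))
      starts <- vapply(lens, function(l)
        sample.int(m$L - l + 1L, 1L), integer(1))
      seqs <- substring(m$seq, starts, starts + lens - 1L)
      reads <- c(reads, seqs)
      bg_rows[[length(bg_rows) + 1L]] <- data.frame(
        kind = "background", gene_id = m$gene_id, start = starts,
        end = starts + lens - 1L, length = lens, seq = seqs, count = 1L,
        stringsAsFactors = FALSE)
    }
  }
  noise_rows <- list()
  if (config$n_noise_reads > 0L) {
    refseqs <- vapply(mature, `[[`, "", "seq")
    for (i in seq_len(config$n_noise_reads)) {
      repeat {
        s <- random_seq(sample(16:35, 1L))
        hit <- any(vapply(refseqs, function(r)
          matches_within(s, r, 1L), logical(1)))
        if (!hit) break
      }
      reads <- c(reads, s)
      noise_rows[[i]] <- data.frame(kind = "noise", gene_id = NA_character_,
                                    start = NA_integer_, end = NA_integer_,
                                    length = nchar(s), seq = s, count = 1L,
                                    stringsAsFactors = FALSE)
    }
  }
  bind <- function(x) if (length(x)) do.call(rbind, x) else
    data.frame(kind = character(0), gene_id = character(0),
               start = integer(0), end = integer(0), length = integer(0),
               seq = character(0), count = integer(0))
  list(reads = reads,
       truth = list(planted = bind(planted_rows),
                    background = bind(bg_rows),
                    noise = bind(noise_rows)))
}

#' Generate target transcripts with embedded tsRNA binding sites
#'
#' Each transcript is random sequence with the reverse complement of one
#' tsRNA embedded at a known position — a perfect-duplex binding site whose
#' coordinates are returned for truth-based checks.
#'
#' @param tsrna_seqs named character vector of tsRNA sequences.
#' @param target_len transcript length (nt).
#' @param seed integer seed.
#' @return list with `targets` (named character) and `sites` (data.frame:
#'   target_id, tsrna_name, start, end).
#' @export
simulate_target_transcripts <- function(tsrna_seqs, target_len = 200L,
                                        seed = 1L) {
  set.seed(seed)
  targets <- character(0)
  sites <- list()
  for (i in seq_along(tsrna_seqs)) {
    site <- revcomp(normalize_seq(tsrna_seqs[[i]]))
    slen <- nchar(site)
    if (target_len < slen + 20L) stop("target_len too small for site")
    at <- sample.int(target_len - slen - 10L, 1L) + 5L
    tg <- random_seq(target_len)
    substr(tg, at, at + slen - 1L) <- site
    tid <- paste0("target_", i)
    targets[tid] <- tg
    sites[[i]] <- data.frame(
      target_id = tid,
      tsrna_name = if (is.null(names(tsrna_seqs))) paste0("tsrna_", i)
                   else names(tsrna_seqs)[i],
      start = at, end = at + slen - 1L, stringsAsFactors = FALSE)
  }
  list(targets = targets, sites = do.call(rbind, sites))
}

#' Simulate CLASH/CLEAR chimeric reads with ground truth
#'
#' Emits true chimeras (a tsRNA arm of 14-40 nt ligated to a random target
#' arm > 8 nt, in both orientations), fake chimeras (contiguous genome
#' fragments), and arm-length boundary cases labelled as rejects in the
#' truth manifest.
#'
#' @param config a [sim_config()] (supplies the seed).
#' @param ref output of [generate_trna_reference()].
#' @param n_true,n_fake,n_boundary how many of each kind.
#' @param seed seed (defaults to `config$seed`).
#' @return list with `reads` (character) and `truth` (data.frame: read_index,
#'   kind, label, gene_id, arm_start, arm_end, target_start, target_end).
#' @export
simulate_chimeras <- function(config, ref, n_true = 10L, n_fake = 10L,
                              n_boundary = 2L, seed = config$seed) {
  set.seed(seed)
  mature <- ref$reference$mature
  genome <- ref$genome
  reads <- character(0)
  rows <- list()
  add <- function(read, kind, label, gene = NA_character_,
                  arm = c(NA_integer_, NA_integer_),
                  tgt = c(NA_integer_, NA_integer_)) {
    reads[[length(reads) + 1L]] <<- read
    rows[[length(rows) + 1L]] <<- data.frame(
      read_index = length(reads), kind = kind, label = label,
      gene_id = gene, arm_start = arm[1], arm_end = arm[2],
      target_start = tgt[1], target_end = tgt[2], stringsAsFactors = FALSE)
  }
  make_arm <- function(arm_len) {
    m <- mature[[sample.int(length(mature), 1L)]]
    st <- sample.int(m$L - arm_len + 1L, 1L)
    list(gene = m$gene_id, seq = substr(m$seq, st, st + arm_len - 1L))
  }
  refseqs <- vapply(mature, `[[`, "", "seq")
  # a junction base that cannot extend the arm match into any reference,
  # so the ligation boundary is unambiguous for an exact splitter
  safe_base <- function(arm_seq, side) {
    for (cand in sample(c("A", "C", "G", "T"))) {
      probe <- if (side == "after") paste0(arm_seq, cand)
               else paste0(cand, arm_seq)
      if (!any(vapply(refseqs, function(r)
        grepl(probe, r, fixed = TRUE), logical(1)))) return(cand)
    }
    stop("no junction-safe base for arm ", arm_seq)
  }
  for (i in seq_len(n_true)) {
    arm_len <- sample(14:40, 1L)
    tgt_len <- sample(9:25, 1L)
    arm <- make_arm(arm_len)
    tgt <- random_seq(tgt_len)
    tsrna_first <- i %% 2L == 1L
    if (tsrna_first) {
      substr(tgt, 1L, 1L) <- safe_base(arm$seq, "after")
    } else {
      substr(tgt, tgt_len, tgt_len) <- safe_base(arm$seq, "before")
    }
    if (tsrna_first) {
      add(paste0(arm$seq, tgt), "true", "accept", arm$gene,
          c(1L, arm_len), c(arm_len + 1L, arm_len + tgt_len))
    } else {
      add(paste0(tgt, arm$seq), "true", "accept", arm$gene,
          c(tgt_len + 1L, tgt_len + arm_len), c(1L, tgt_len))
    }
  }
  glen <- nchar(genome[[1]])
  for (i in seq_len(n_fake)) {
    flen <- sample(28:60, 1L)
    st <- sample.int(glen - flen + 1L, 1L)
    add(substr(genome[[1]], st, st + flen - 1L), "fake", "reject")
  }
  for (i in seq_len(n_boundary)) {
    # target arm of exactly 8 nt: fails the > 8 nt gate
    arm <- make_arm(20L)
    add(paste0(arm$seq, random_seq(8L)), "boundary", "reject", arm$gene,
        c(1L, 20L), c(21L, 28L))
  }
  list(reads = unlist(reads), truth = do.call(rbind, rows))
}

#' Simulate a per-base conservation track
#'
#' Conserved sites receive the `high` score and every other base the `low`
#' score, so a mean-conservation cutoff between the two separates conserved
#' from background sites exactly.
#'
#' @param targets named character vector of target transcripts.
#' @param conserved_sites data.frame (target_id, start, end).
#' @param high,low scores inside and outside conserved sites.
#' @return data.frame: target_id, pos, score.
#' @export
simulate_conservation_track <- function(targets, conserved_sites,
                                        high = 0.6, low = 0.05) {
  rows <- lapply(names(targets), function(tid) {
    n <- nchar(targets[[tid]])
    sc <- rep(low, n)
    cs <- conserved_sites[conserved_sites$target_id == tid, , drop = FALSE]
    for (i in seq_len(nrow(cs))) {
      if (cs$start[i] < 1L || cs$end[i] > n) stop("site outside target")
      sc[cs$start[i]:cs$end[i]] <- high
    }
    data.frame(target_id = tid, pos = seq_len(n), score = sc,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
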