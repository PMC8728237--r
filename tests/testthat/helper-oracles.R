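# Independent oracles used to freeze expected values. These deliberately use
# direct summation / exhaustive enumeration rather than the package's code
# paths.

# direct term-by-term summation of the binomial upper tail in log space
binom_tail_oracle <- function(k, n, L, l) {
  p <- 1 / (L - l + 1)
  if (k <= 0) return(1)
  if (k > n) return(0)
  x <- k:n
  sum(exp(lchoose(n, x) + x * log(p) + (n - x) * log1p(-p)))
}

# exhaustive enumeration of all C(N, n) draws for the hypergeometric tail
hyper_tail_enum <- function(N, K, n, k) {
  if (n == 0) return(as.numeric(k <= 0))
  draws <- utils::combn(N, n)
  overlaps <- colSums(draws <= K)
  mean(overlaps >= k)
}

# brute-force duplex search: enumerates every seed register and every
# interleaving of pair/mismatch/bulge moves, collecting all partial duplexes,
# then applies the same ordering (score, pairs desc, target start asc).
# Returns list(sc, np, site_start) or NULL.
duplex_oracle <- function(tsrna, target, max_mismatch = 2L,
                          max_bulge_tsrna = 2L, max_bulge_target = 2L,
                          seed_span = c(2L, 7L), energy_cutoff = -10) {
  pair_sc <- function(a, b) {
    switch(paste0(a, b),
           GC = -3, CG = -3, AT = -2, TA = -2, GT = -1, TG = -1, NA_real_)
  }
  ts <- strsplit(toupper(chartr("U", "T", tsrna)), "")[[1]]
  tg <- strsplit(toupper(chartr("U", "T", target)), "")[[1]]
  s1 <- seed_span[1]; s2 <- seed_span[2]; w <- s2 - s1 + 1L
  lts <- length(ts); ltg <- length(tg)
  if (ltg < w) return(NULL)
  outcomes <- list()
  for (j in seq_len(ltg - w + 1L)) {
    seed_sc <- 0; ok <- TRUE
    for (t in 0:(w - 1L)) {
      ps <- pair_sc(ts[s1 + t], tg[j + w - 1L - t])
      if (is.na(ps)) { ok <- FALSE; break }
      seed_sc <- seed_sc + ps
    }
    if (!ok) next
    acc <- new.env(parent = emptyenv()); acc$out <- list()
    # right side (3' of seed): i ascending, target descending
    enum_right <- function(i, mm, bt, bg, sc, np, minj) {
      acc$out[[length(acc$out) + 1L]] <- c(sc, np, minj)
      jj <- j - (i - s2) + bt - bg
      if (i <= lts && jj >= 1L) {
        ps <- pair_sc(ts[i], tg[jj])
        if (!is.na(ps)) enum_right(i + 1L, mm, bt, bg, sc + ps, np + 1L,
                                   min(minj, jj))
        if (mm < max_mismatch) enum_right(i + 1L, mm + 1L, bt, bg, sc + 1,
                                          np, minj)
      }
      if (i <= lts && bt < max_bulge_tsrna) {
        enum_right(i + 1L, mm, bt + 1L, bg, sc + 1, np, minj)
      }
      if (jj - 1L >= 1L && bg < max_bulge_target) {
        enum_right(i, mm, bt, bg + 1L, sc + 1, np, minj)
      }
    }
    # left side (5' of seed): i descending, target ascending; on every state
    # hand the remaining budgets to the right side
    enum_left <- function(i, mm, bt, bg, sc, np, minj) {
      enum_right(s2 + 1L, mm, bt, bg, sc, np, minj)
      if (i < 1L) return(invisible())
      jj <- j + w + (s1 - 1L - i) - bt + bg
      if (jj <= ltg) {
        ps <- pair_sc(ts[i], tg[jj])
        if (!is.na(ps)) enum_left(i - 1L, mm, bt, bg, sc + ps, np + 1L, minj)
        if (mm < max_mismatch) enum_left(i - 1L, mm + 1L, bt, bg, sc + 1,
                                         np, minj)
        if (bg < max_bulge_target) enum_left(i, mm, bt, bg + 1L, sc + 1,
                                             np, minj)
      }
      if (bt < max_bulge_tsrna) enum_left(i - 1L, mm, bt + 1L, bg, sc + 1,
                                          np, minj)
    }
    enum_left(s1 - 1L, 0L, 0L, 0L, seed_sc, w, j)
    for (o in acc$out) outcomes[[length(outcomes) + 1L]] <- o
  }
  if (!length(outcomes)) return(NULL)
  m <- do.call(rbind, outcomes)
  ord <- order(m[, 1], -m[, 2], m[, 3])
  best <- m[ord[1], ]
  if (best[1] > energy_cutoff) return(NULL)
  list(sc = best[1], np = best[2], site_start = best[3])
}

# hand-made mature tRNA fixture (bypasses build_mature_trna on purpose)
mk_mature <- function(gene_id, seq, loop, amino_acid = "Ala",
                      anticodon = "CGC") {
  structure(list(gene_id = gene_id, amino_acid = amino_acid,
                 anticodon = anticodon, seq = seq, L = nchar(seq),
                 anticodon_start = loop[1] + 2L,
                 anticodon_loop = as.integer(loop)),
            class = "mature_trna")
}

# deterministic pseudo-random DNA for fixtures
fixture_seq <- function(n, seed = 1L) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
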