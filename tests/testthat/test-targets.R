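test_that("tag collapsing enforces length and strand rules", {
  trna <- c(t1 = fixture_seq(76, seed = 81))
  tag <- substr(trna[[1]], 10, 29)
  anti <- revcomp(substr(trna[[1]], 30, 49))
  other <- fixture_seq(20, seed = 82)
  reads <- c(rep(tag, 5), substr(other, 1, 13), anti, other)
  out <- suppressMessages(collapse_and_filter_tags(reads, trna))
  expect_false(any(out$seq == substr(other, 1, 13)))  # < 14 nt dropped
  expect_false(any(out$seq == anti))                  # antisense removed
  expect_equal(out$count[out$seq == tag], 5L)
  expect_true(out$is_tsrna[out$seq == tag])
  expect_false(out$is_tsrna[out$seq == other])
})

test_that("peak calling finds local maxima with half-height intervals", {
  pk <- call_peaks(c(0, 1, 5, 9, 5, 1), min_height = 2)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$summit, 4L)
  expect_equal(pk$height, 9)
  expect_equal(c(pk$start, pk$end), c(3L, 5L))  # coverage >= 4.5

  expect_equal(nrow(call_peaks(rep(0, 20), min_height = 1)), 0L)

  two <- call_peaks(c(0, 6, 0, 0, 8, 0), min_height = 2)
  expect_equal(two$summit, c(2L, 5L))
})

test_that("peak summits are strict local maxima and peaks never overlap", {
  set.seed(83)
  for (i in 1:20) {
    cov <- rpois(50, 2)
    pk <- call_peaks(cov, min_height = 3)
    for (r in seq_len(nrow(pk))) {
      s <- pk$summit[r]
      if (s > 1) expect_gt(cov[s], cov[s - 1] - 1e-9)
      if (s < 50) expect_true(cov[s] >= cov[s + 1])
      expect_true(pk$start[r] <= s && s <= pk$end[r])
    }
    if (nrow(pk) > 1) {
      expect_true(all(pk$start[-1] > pk$end[-nrow(pk)]))
    }
  }
})

test_that("duplex search handles perfect, empty and over-mutated pairings", {
  gc18 <- "GCGGCCGCGGCCGCGGCC"
  dp <- find_duplex(gc18, revcomp(gc18))
  expect_equal(nrow(dp$pair_map), 18L)
  expect_true(dp$seed_ok)
  expect_lte(dp$duplex_score, -10)
  expect_equal(dp$duplex_score, -18 * 3)

  expect_null(find_duplex(strrep("A", 18), strrep("A", 18)))

  # complement with three interior mismatches: dies at max_mismatch = 2
  at20 <- "ATTAATATTAATATTAATAT"
  tg <- revcomp(at20)
  for (at in c(5, 10, 15)) {
    substr(tg, at, at) <- c(A = "C", C = "A", G = "T", T = "G")[
      substr(tg, at, at)]
  }
  expect_null(find_duplex(at20, tg))
  expect_error(find_duplex("ACGTACG", "ACGTACGT"), "at least 8")
})

test_that("duplex search equals the brute-force oracle on mixed cases", {
  set.seed(84)
  rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
  mutate <- function(s, k) {
    b <- strsplit(s, "")[[1]]
    if (k > 0) {
      for (x in sample(length(b), k)) {
        b[x] <- sample(setdiff(c("A", "C", "G", "T"), b[x]), 1)
      }
    }
    paste(b, collapse = "")
  }
  for (rep in 1:60) {
    if (rep %% 4 == 0) {
      ts <- rand_seq(sample(8:12, 1))
      tg <- mutate(revcomp(ts), sample(0:2, 1))
      mm <- 2L; bt <- 2L; bg <- 2L
    } else {
      ts <- rand_seq(sample(8:25, 1))
      tg <- rand_seq(sample(6:25, 1))
      mm <- sample(0:2, 1); bt <- sample(0:1, 1); bg <- sample(0:1, 1)
    }
    im <- find_duplex(ts, tg, max_mismatch = mm, max_bulge_tsrna = bt,
                      max_bulge_target = bg)
    or <- duplex_oracle(ts, tg, max_mismatch = mm, max_bulge_tsrna = bt,
                        max_bulge_target = bg)
    if (is.null(or)) {
      expect_null(im)
    } else {
      expect_false(is.null(im))
      expect_equal(im$duplex_score, or$sc)
      expect_equal(nrow(im$pair_map), or$np)
      expect_equal(unname(im$site["start"]), or$site_start)
    }
  }
})

test_that("chimera splitting respects the 14-40 nt arm and >8 nt remainder gates", {
  trna <- c(t1 = fixture_seq(76, seed = 85))
  arm20 <- substr(trna[[1]], 5, 24)
  tail15 <- fixture_seq(15, seed = 86)
  # pin the junction bases so the random tail cannot extend the arm match
  substr(tail15, 1, 1) <- setdiff(c("A", "C", "G", "T"),
                                  substr(trna[[1]], 25, 25))[1]
  substr(tail15, 15, 15) <- setdiff(c("A", "C", "G", "T"),
                                    substr(trna[[1]], 4, 4))[1]
  sp <- split_chimera(paste0(arm20, tail15), trna)
  expect_equal(sp$tsrna_arm, c(1L, 20L))
  expect_equal(sp$target_arm, c(21L, 35L))
  expect_equal(sp$source_gene_id, "t1")

  # target-first orientation
  sp2 <- split_chimera(paste0(tail15, arm20), trna)
  expect_equal(sp2$tsrna_arm, c(16L, 35L))
  expect_equal(sp2$target_arm, c(1L, 15L))

  # 8-nt remainder fails the > 8 nt gate
  expect_null(split_chimera(paste0(arm20, substr(tail15, 1, 8)), trna))
  # pure tRNA read: no remainder
  expect_null(split_chimera(substr(trna[[1]], 1, 45), trna))
  # 13-nt arm fails the minimum arm gate
  expect_null(split_chimera(paste0(substr(trna[[1]], 5, 17),
                                   fixture_seq(20, seed = 87)), trna))
})

test_that("fake chimeras are exactly the contiguously mapping reads", {
  genome <- c(chr1 = fixture_seq(500, seed = 88))
  frag <- substr(genome[[1]], 101, 140)
  expect_true(detect_fake_chimera(frag, genome))
  # one mismatch within budget still counts as contiguous
  mut <- frag
  substr(mut, 20, 20) <- c(A = "C", C = "A", G = "T", T = "G")[
    substr(frag, 20, 20)]
  expect_true(detect_fake_chimera(mut, genome, max_edits = 1))
  # ligation of two distant fragments does not map contiguously
  lig <- paste0(substr(genome[[1]], 11, 30), substr(genome[[1]], 401, 420))
  expect_false(detect_fake_chimera(lig, genome))
  # reverse-strand fragments also count
  expect_true(detect_fake_chimera(revcomp(frag), genome))
})

test_that("conservation filter keeps sites whose mean exceeds the cutoff", {
  track <- data.frame(target_id = "tx", pos = 1:30,
                      score = c(rep(0.5, 10), rep(0.1, 10),
                                rep(c(0.6, 0.1), 5)))
  ints <- data.frame(tsrna_name = c("a", "b", "c"), target_id = "tx",
                     site_start = c(1L, 11L, 21L),
                     site_end = c(10L, 20L, 30L))
  out <- conservation_filter(ints, track, cutoff = 0.3)
  # means: 0.5 kept, 0.1 dropped, 0.35 kept
  expect_equal(out$tsrna_name, c("a", "c"))
  expect_equal(out$conservation_mean, c(0.5, 0.35))
})

test_that("the CLIP pipeline recovers a planted binding site", {
  cfg <- sim_config(seed = 19, n_trnas = 3, background_depth = 0)
  ref <- generate_trna_reference(cfg)
  tsrna <- substr(ref$reference$mature[[1]]$seq, 1, 20)
  sim <- simulate_target_transcripts(c(ts1 = tsrna), target_len = 120,
                                     seed = 20)
  # CLIP tags pile up over the binding site
  site <- sim$sites
  tag <- substr(sim$targets[[1]], max(1, site$start - 3), site$end + 3)
  reads <- rep(tag, 10)
  out <- find_targets_clip(reads, c(ts1 = tsrna), ref$reference,
                           sim$targets, min_height = 2)
  expect_equal(nrow(out), 1L)
  expect_true(out$seed_ok)
  expect_lte(out$duplex_score, -10)
  expect_lte(abs(out$site_start - site$start), 1)
})

test_that("the CLASH pipeline splits true chimeras and drops fakes", {
  cfg <- sim_config(seed = 23, n_trnas = 4)
  ref <- generate_trna_reference(cfg)
  ch <- simulate_chimeras(cfg, ref, n_true = 6, n_fake = 6, n_boundary = 2)
  fakes <- ch$truth$kind == "fake"
  flagged <- vapply(ch$reads, detect_fake_chimera, logical(1),
                    genome = ref$genome)
  expect_equal(unname(flagged), fakes)
  # every accepted truth row splits with exact arm boundaries
  for (i in which(ch$truth$label == "accept")) {
    sp <- split_chimera(ch$reads[i], ref$reference)
    expect_false(is.null(sp))
    expect_equal(sp$tsrna_arm,
                 c(ch$truth$arm_start[i], ch$truth$arm_end[i]))
  }
  for (i in which(ch$truth$kind == "boundary")) {
    expect_null(split_chimera(ch$reads[i], ref$reference))
  }
})
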