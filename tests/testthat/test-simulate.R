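test_that("reference generation is bit-reproducible and structurally valid", {
  cfg <- sim_config(seed = 101, n_trnas = 6)
  r1 <- generate_trna_reference(cfg)
  r2 <- generate_trna_reference(cfg)
  expect_identical(r1$genes, r2$genes)
  expect_identical(r1$genome, r2$genome)
  expect_identical(r1$mod_sites, r2$mod_sites)
  for (m in r1$reference$mature) {
    expect_true(endsWith(m$seq, "CCA"))
    expect_true(m$anticodon_loop[1] >= 1 && m$anticodon_loop[2] <= m$L)
  }
  # intron-bearing genes yield matures shorter than unspliced + 3
  with_intron <- nzchar(r1$genes$introns)
  if (any(with_intron)) {
    i <- which(with_intron)[1]
    m <- r1$reference$mature[[r1$genes$gene_id[i]]]
    expect_lt(m$L, nchar(r1$genes$genomic_seq[i]) + 3L)
  }
  # genes sit on the toy chromosome with >= 60 nt flanks
  expect_true(all(r1$genes$start > 60))
  expect_lte(max(r1$genes$end), nchar(r1$genome[[1]]) - 60L)
  expect_error(generate_trna_reference(sim_config(trna_len_range = c(20, 30))),
               "too small")
})

test_that("library simulation is seed-deterministic and truth-complete", {
  cfg <- sim_config(seed = 102, n_trnas = 4, background_depth = 0.5,
                    n_noise_reads = 5,
                    planted_tsrnas = data.frame(gene_index = 1:2,
                                                start = c(1, 10),
                                                end = c(25, 35),
                                                abundance = c(30, 40)))
  ref <- generate_trna_reference(cfg)
  l1 <- simulate_small_rna_library(cfg, ref)
  l2 <- simulate_small_rna_library(cfg, ref)
  expect_identical(l1$reads, l2$reads)
  expect_identical(l1$truth, l2$truth)
  # manifests account for every read
  expect_equal(length(l1$reads),
               sum(l1$truth$planted$count) + nrow(l1$truth$background) +
                 nrow(l1$truth$noise))
  # planted sequences are substrings of their source matures
  for (i in seq_len(nrow(l1$truth$planted))) {
    m <- ref$reference$mature[[l1$truth$planted$gene_id[i]]]
    expect_equal(l1$truth$planted$seq[i],
                 substr(m$seq, l1$truth$planted$start[i],
                        l1$truth$planted$end[i]))
  }
  # noise reads never match a tRNA reference
  for (s in l1$truth$noise$seq) {
    expect_false(any(vapply(ref$reference$mature, function(m)
      grepl(s, m$seq, fixed = TRUE), logical(1))))
  }
  # different library seeds give different draws over the same reference
  l3 <- simulate_small_rna_library(cfg, ref, seed = 103)
  expect_false(identical(l1$reads, l3$reads))
})

test_that("with no background the caller recovers exactly the planted calls", {
  cfg <- sim_config(seed = 104, n_trnas = 4, background_depth = 0,
                    planted_tsrnas = data.frame(gene_index = c(1, 2, 3),
                                                start = c(1, 15, 30),
                                                end = c(28, 34, 52),
                                                abundance = c(20, 20, 20)))
  ref <- generate_trna_reference(cfg)
  lib <- simulate_small_rna_library(cfg, ref)
  calls <- tsr_find(lib$reads, ref$reference)
  expect_equal(nrow(calls), 3L)
  expect_setequal(calls$seq, lib$truth$planted$seq)
})

test_that("planted fragments beat a uniform background at the binomial test", {
  cfg <- sim_config(seed = 105, n_trnas = 5, background_depth = 1,
                    planted_tsrnas = data.frame(gene_index = 1:2,
                                                start = c(5, 1),
                                                end = c(30, 22),
                                                abundance = 500))
  ref <- generate_trna_reference(cfg)
  lib <- simulate_small_rna_library(cfg, ref)
  calls <- tsr_find(lib$reads, ref$reference)
  for (i in 1:2) {
    expect_true(lib$truth$planted$seq[i] %in% calls$seq)
  }
  planted_pv <- calls$pvalue[calls$seq %in% lib$truth$planted$seq]
  expect_true(all(planted_pv < 1e-20))
})

test_that("chimera truth labels agree with the split gates", {
  cfg <- sim_config(seed = 106, n_trnas = 4)
  ref <- generate_trna_reference(cfg)
  ch <- simulate_chimeras(cfg, ref, n_true = 8, n_fake = 5, n_boundary = 3)
  c2 <- simulate_chimeras(cfg, ref, n_true = 8, n_fake = 5, n_boundary = 3)
  expect_identical(ch, c2)
  expect_equal(sum(ch$truth$kind == "true"), 8L)
  for (i in seq_len(nrow(ch$truth))) {
    sp <- split_chimera(ch$reads[i], ref$reference)
    if (ch$truth$label[i] == "accept") {
      expect_false(is.null(sp))
    } else if (ch$truth$kind[i] == "boundary") {
      expect_null(sp)
    }
  }
})

test_that("conservation track separates planted sites at the 0.3 cutoff", {
  targets <- c(tx1 = strrep("ACGT", 30))
  sites <- data.frame(target_id = "tx1", start = 11L, end = 30L)
  track <- simulate_conservation_track(targets, sites)
  expect_equal(mean(track$score[track$pos %in% 11:30]), 0.6)
  expect_equal(mean(track$score[track$pos %in% 31:50]), 0.05)
  # a half-conserved site averages (0.6 + 0.05)/2 = 0.325 and passes
  ints <- data.frame(tsrna_name = "t", target_id = "tx1",
                     site_start = c(1L, 21L, 41L), site_end = c(20L, 40L, 60L))
  out <- conservation_filter(ints, track, cutoff = 0.3)
  expect_equal(out$site_start, c(1L, 21L))
  expect_equal(out$conservation_mean[2], 0.325)
})
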