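test_that("binomial enrichment P value matches direct summation and edge cases", {
  expect_equal(binomial_site_pvalue(0, 25, 76, 18), 1)
  expect_equal(binomial_site_pvalue(10, 10, 20, 20), 1)  # p = 1 degenerate
  # frozen from the log-space summation oracle
  expect_equal(binomial_site_pvalue(5, 50, 76, 18), 0.00157197627580051,
               tolerance = 1e-12)
  for (kk in c(1, 3, 7, 12)) {
    for (dims in list(c(76, 18), c(76, 30), c(90, 14))) {
      expect_equal(binomial_site_pvalue(kk, 15, dims[1], dims[2]),
                   binom_tail_oracle(kk, 15, dims[1], dims[2]),
                   tolerance = 1e-10)
    }
  }
  expect_error(binomial_site_pvalue(1, 5, 10, 20), "must be >=")
})

test_that("enrichment P value is monotone in k and in L", {
  ks <- 0:20
  pv <- binomial_site_pvalue(ks, 20, 76, 18)
  expect_true(all(diff(pv) <= 0))
  Ls <- seq(40, 120, by = 10)
  pvL <- vapply(Ls, function(L) binomial_site_pvalue(4, 30, L, 18),
                numeric(1))
  expect_true(all(diff(pvL) <= 1e-12))
})

test_that("cleavage-position classification follows the six-type rule", {
  m <- mk_mature("tRNA-Ala-CGC-1-1", strrep("A", 76), loop = c(32, 38))
  expect_equal(classify_tsrna(58, 75, m), "tRF-3")
  expect_equal(classify_tsrna(1, 34, m), "tiRNA-5")
  expect_equal(classify_tsrna(20, 40, m), "tRF-i")
  expect_equal(classify_tsrna(1, 25, m), "tRF-5")
  expect_equal(classify_tsrna(35, 76, m), "tiRNA-3")
  tr <- structure(list(gene_id = "tRNA-Ala-CGC-1-1", seq = strrep("A", 50),
                       length = 50L), class = "trailer_seq")
  expect_equal(classify_tsrna(1, 20, tr), "tRF-1")
  expect_error(classify_tsrna(0, 10, m), "outside")
  expect_error(classify_tsrna(70, 80, m), "outside")
})

test_that("every interval on a toy tRNA gets exactly one of the six types", {
  m <- mk_mature("g", strrep("A", 76), loop = c(32, 38))
  types <- c("tRF-5", "tRF-3", "tRF-i", "tiRNA-5", "tiRNA-3")
  for (st in seq(1, 60, by = 3)) {
    for (en in seq(st + 13, 76, by = 4)) {
      ty <- classify_tsrna(st, en, m)
      expect_true(ty %in% types)
    }
  }
})

test_that("all tags at one position give a minimal P value call", {
  ref <- list(mature = list(g = mk_mature("g", fixture_seq(76, seed = 61),
                                          loop = c(32, 38),
                                          amino_acid = "Gly")))
  names(ref$mature) <- "g"
  read <- substr(ref$mature$g$seq, 10, 29)
  aln <- align_to_trna(data.frame(seq = read, count = 40L), ref,
                       max_edits = 0)
  calls <- call_tsrnas(aln, ref)
  expect_equal(nrow(calls), 1L)
  expect_lt(calls$pvalue, 1e-30)
})

test_that("uniformly spread single tags are never called", {
  # 20 tags, one per distinct position: k = 1, P(X>=1) = 0.2896 >> 0.01
  ref <- list(mature = list(g = mk_mature("g", fixture_seq(76, seed = 62),
                                          loop = c(32, 38))))
  names(ref$mature) <- "g"
  reads <- vapply(seq(1, 58, by = 3), function(s)
    substr(ref$mature$g$seq, s, s + 17), character(1))
  aln <- align_to_trna(reads, ref, max_edits = 0)
  calls <- call_tsrnas(aln, ref)
  expect_equal(nrow(calls), 0L)
})

test_that("a planted fragment is called against uniform background", {
  cfg <- sim_config(seed = 17, n_trnas = 4, background_depth = 1,
                    planted_tsrnas = data.frame(gene_index = 1, start = 1,
                                                end = 30, abundance = 500))
  ref <- generate_trna_reference(cfg)
  lib <- simulate_small_rna_library(cfg, ref)
  aln <- align_to_trna(lib$reads, ref$reference, max_edits = 0)
  calls <- call_tsrnas(aln, ref$reference)
  planted_gene <- ref$genes$gene_id[1]
  sites <- unique(do.call(rbind, lapply(strsplit(calls$sources, ";"),
    function(s) do.call(rbind, lapply(s, function(x) {
      parts <- strsplit(x, ":")[[1]]
      iv <- as.integer(strsplit(parts[3], "-")[[1]])
      data.frame(gene_id = parts[1], start = iv[1])
    })))))
  expect_true(any(sites$gene_id == planted_gene & sites$start == 1))
  # no site called anywhere else
  expect_true(all(sites$gene_id == planted_gene & sites$start == 1))
})

test_that("the Ala 3'-fragment worked example merges isodecoders under one name", {
  frag <- "TCCCCGGCATCTCCACCA"
  mk76 <- function(id) {
    s <- fixture_seq(76, seed = 63)
    substr(s, 58, 75) <- frag
    mk_mature(id, s, loop = c(32, 38), amino_acid = "Ala", anticodon = "CGC")
  }
  ref <- list(mature = list("tRNA-Ala-CGC-1-1" = mk76("tRNA-Ala-CGC-1-1"),
                            "tRNA-Ala-CGC-2-1" = mk76("tRNA-Ala-CGC-2-1")))
  aln <- align_to_trna(data.frame(seq = frag, count = 60L), ref,
                       max_edits = 0)
  calls <- name_tsrnas(call_tsrnas(aln, ref))
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$tsrna_type, "tRF-3")
  expect_equal(calls$amino_acid, "Ala")
  expect_match(calls$name, "^tsRNA-Ala-3-\\d{4}$")
  expect_equal(calls$n_sources, 2L)
  expect_true(grepl("tRNA-Ala-CGC-1-1", calls$sources) &&
                grepl("tRNA-Ala-CGC-2-1", calls$sources))
})

test_that("names are unique per type and deterministic by sequence order", {
  calls <- data.frame(
    seq = c("CCCCACGTACGTACGTAA", "AAAAACGTACGTACGTAA", "GGGGACGTACGTACGTAA"),
    tsrna_type = c("tRF-5", "tRF-5", "tiRNA-3"),
    amino_acid = "Gly", count = 1L, pvalue = 1e-5,
    sources = "x", n_sources = 1L, stringsAsFactors = FALSE)
  named <- name_tsrnas(calls)
  expect_equal(named$name[named$seq == "AAAAACGTACGTACGTAA"],
               "tsRNA-Gly-5-0001")
  expect_equal(named$name[named$seq == "CCCCACGTACGTACGTAA"],
               "tsRNA-Gly-5-0002")
  expect_equal(named$name[named$tsrna_type == "tiRNA-3"],
               "tsRNA-Gly-3i-0001")
  expect_equal(anyDuplicated(named$name), 0L)
})

test_that("whitelist annotation matches across U/T spellings and is annotation-only", {
  calls <- data.frame(seq = c("ACGTACGTACGTAT", "GGGGACGTACGTAA"),
                      stringsAsFactors = FALSE)
  out <- annotate_whitelist(calls, whitelist = c("ACGUACGUACGUAU"))
  expect_equal(out$whitelisted, c(TRUE, FALSE))
  out2 <- annotate_whitelist(calls, whitelist = character(0))
  expect_false(any(out2$whitelisted))
  expect_equal(nrow(out2), 2L)
})
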