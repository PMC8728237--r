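# tsrkit

Identification, quantification and target analysis of tRNA-derived small
RNAs (tsRNAs) from small RNA-seq, CLIP and CLASH/CLEAR data.

## The problem

Reads mapping to tRNAs dominate many small RNA-seq libraries, but most of
them are degradation fragments, not the regulated cleavage products
(tRF-5/-3/-i/-1 and the tiRNA halves) that carry biology. Tools that report
every tRNA-mapping read as a tsRNA emit thousands of candidates with very
low precision. `tsrkit` is for analysts who want a short, statistically
defended candidate list instead: it tests each cleavage position against a
uniform-degradation null, and only positions with significantly recurrent
read starts become calls.

## The statistics at the core

For a transcript of length *L* carrying *n* tags, a fragment of length *l*
placed at random starts at any of *L − l + 1* positions with probability
*p = 1/(L − l + 1)*. A position holding *k* tag starts is scored with the
exact binomial upper tail

P(X ≥ k) = Σₓ₌ₖⁿ C(n, x) pˣ (1 − p)ⁿ⁻ˣ,

and positions with P < 0.01 are called, classified by cleavage ends
relative to the anticodon loop and the CCA tail, and named
`tsRNA-<amino acid>-<type>-<serial>`. Alignment is modification-aware
(+1 match; −1 mismatch/indel; −0.5 at known modification sites, where
reverse transcriptase misreads are expected). Downstream, expression is
RPM = 10⁶·C/N over tRNA-mapped counts with a rank-based inverse-Gaussian
cohort normalization onto [−1, 1]; tsRNA–mRNA binding sites come from CLIP
peak pileups or CLASH chimera splitting plus a seed-anchored (positions
2–7) duplex search; and tsRNA–miRNA competing-endogenous-RNA pairs are
scored with the hypergeometric upper tail over shared targets at
FDR < 0.05. The methods vignette
(`vignettes/tsrkit-methods.Rmd`) derives and defends each choice.

## Worked example

Everything below is synthetic and seeded, so it reproduces exactly. Two
tsRNAs are planted (120 and 80 copies) on a 5-gene reference over a
uniform degradation background of one tag per position:

```r
library(tsrkit)
cfg <- sim_config(seed = 42, n_trnas = 5, background_depth = 1,
                  planted_tsrnas = data.frame(gene_index = c(1, 2),
                                              start = c(1, 40),
                                              end = c(30, 58),
                                              abundance = c(120, 80)))
ref   <- generate_trna_reference(cfg)
lib   <- simulate_small_rna_library(cfg, ref)   # 573 reads
calls <- tsr_find(lib$reads, ref$reference, mod_sites = ref$mod_sites)
calls[, c("name", "tsrna_type", "count", "pvalue", "sources")]
```

```
             name tsrna_type count        pvalue                       sources
 tsRNA-Thr-5-0002      tRF-5   120 6.430859e-162  tRNA-Thr-GAT-1-1:mature:1-30
 tsRNA-Thr-5-0001      tRF-5     1 6.430859e-162  tRNA-Thr-GAT-1-1:mature:1-25
 tsRNA-Leu-i-0006      tRF-i    80 8.016101e-108 tRNA-Leu-GTG-2-1:mature:40-58
 tsRNA-Leu-i-0001      tRF-i     2  6.193606e-03 tRNA-Leu-GTG-2-1:mature:45-58
 tsRNA-Gln-i-0001      tRF-i     1  3.777791e-03 tRNA-Gln-ACC-4-1:mature:19-36
 ...                                             (14 calls in total)
```

Reading this: the two planted fragments are recovered with overwhelming
evidence (counts 120 and 80, P ≈ 10⁻¹⁶², 10⁻¹⁰⁸). The single-count calls at
the same start positions are background fragments that *share a planted
start* — the test is positional, so any fragment starting at a proven
cleavage site is significant — and the entries near P ≈ 4–6 × 10⁻³ are the
handful of borderline background sites expected from ~300 positional tests
at the 0.01 threshold. Candidate lists should be read ranked by P value;
the call table's `count` column makes the planted molecules unmistakable.

Quantification then turns call tables into an RPM matrix:

```r
rpm <- build_expression_matrix(list(sampleA = calls))
rpm["tsRNA-Thr-5-0002", ]   # 558139.5  (= 1e6 * 120 / 215)
normalize_expression(rpm)   # rank-based inverse-Gaussian, [-1, 1]
```

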