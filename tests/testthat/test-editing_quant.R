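test_that("editing extent follows the strand-aware edited/total convention", {
  # forward strand: edited = T, total = C + T
  obs <- editing_extent(c(A = 1, C = 20, G = 0, T = 413))
  expect_equal(obs$edited, 413)
  expect_equal(obs$total, 433)
  expect_equal(obs$extent, 413 / 433, tolerance = 1e-12)
  expect_true(obs$defined)

  # reverse-strand transcript: reference G, edited reads carry A
  rev <- editing_extent(c(A = 10, C = 3, G = 90, T = 2), strand = "-")
  expect_equal(c(rev$edited, rev$total), c(10, 100))

  # all-bases denominator includes the noise bases
  expect_equal(editing_extent(c(A = 1, C = 20, G = 0, T = 413),
                              denominator = "all")$total, 434)

  # no informative reads: flagged undefined, not an error
  none <- editing_extent(c(A = 0, C = 0, G = 0, T = 0))
  expect_false(none$defined)
  expect_true(is.na(none$extent))

  expect_error(editing_observation(5, 3), "edited <= total")
})

test_that("published edited/total pairs reproduce their printed percentages", {
  counts <- utils::read.delim(system.file("extdata",
                                          "mito_editing_site_counts.tsv",
                                          package = "ppredit"),
                              comment.char = "#")
  wt <- editing_observation(counts$wt_edited[counts$site_id == "nad1-493"],
                            counts$wt_total[counts$site_id == "nad1-493"])
  expect_equal(round(100 * wt$extent, 2), 95.38)
  mut <- editing_observation(counts$mut_edited[counts$site_id == "ccmFN2-356"],
                             counts$mut_total[counts$site_id == "ccmFN2-356"])
  expect_equal(100 * mut$extent, 0)
})

test_that("the exact Fisher test matches enumeration, is symmetric and null-calibrated", {
  o <- function(e, t) list(edited = e, total = t)
  # [[5,0],[0,5]]: 2 of the 252 equally weighted ... hand value 2/252
  expect_equal(fisher_differential(o(5, 5), o(0, 5)), 2 / 252,
               tolerance = 1e-12)
  # identical groups: no association
  expect_equal(fisher_differential(o(3, 10), o(3, 10)), 1, tolerance = 1e-12)
  # group order is irrelevant
  expect_equal(fisher_differential(o(7, 20), o(2, 15)),
               fisher_differential(o(2, 15), o(7, 20)), tolerance = 1e-14)
  expect_error(fisher_differential(o(0, 0), o(1, 2)), "total > 0")

  # random tables against the binomial-coefficient enumeration oracle and
  # against the reference implementation in stats
  set.seed(7)
  for (i in 1:200) {
    t1 <- sample(1:150, 1); t2 <- sample(1:150, 1)
    e1 <- sample(0:t1, 1); e2 <- sample(0:t2, 1)
    p <- fisher_differential(o(e1, t1), o(e2, t2))
    p_or <- fisher_enum_oracle(e1, t1 - e1, e2, t2 - e2)
    expect_equal(p, min(1, p_or), tolerance = 1e-10)
    if (i <= 40) {
      p_ref <- stats::fisher.test(matrix(c(e1, t1 - e1, e2, t2 - e2), 2,
                                         byrow = TRUE))$p.value
      expect_equal(p, p_ref, tolerance = 1e-7)
    }
  }

  # type-I calibration under equal binomial rates (the exact test is mildly
  # conservative, so the observed rate sits at or just under the nominal 5%)
  cfg <- generator_config(seed = 101, n_lost_sites = 0, n_stable_sites = 1000)
  cm <- simulate_count_matrices(cfg)
  d <- call_differential_sites(cm$matrix_a, cm$matrix_b, delta_min = 0)
  expect_equal(nrow(d), 1000L)
  expect_gt(mean(d$p_raw <= 0.05), 0.025)
  expect_lt(mean(d$p_raw <= 0.05), 0.075)

  # family-wise error with Hochberg adjustment: families of null sites
  # reject anywhere in at most ~5% of replicates
  set.seed(11)
  fam <- vapply(1:60, function(i) {
    cfgf <- generator_config(seed = 5000 + i, n_lost_sites = 0,
                             n_stable_sites = 25,
                             coverage_range = c(100L, 300L))
    cmf <- simulate_count_matrices(cfgf)
    any(call_differential_sites(cmf$matrix_a, cmf$matrix_b,
                                delta_min = 0)$p_adj <= 0.05)
  }, logical(1))
  expect_lte(mean(fam), 0.12)

  # power regime: extents 0.90 vs 0.05 at totals >= 40 give p << 1e-6
  for (t in c(40, 60, 100)) {
    p <- fisher_differential(o(round(0.9 * t), t), o(round(0.05 * t), t))
    expect_lt(p, 1e-6)
  }
})

test_that("Hochberg adjustment matches the step-up definition", {
  expect_equal(adjust_pvalues(0.037), 0.037)                 # m = 1
  expect_equal(adjust_pvalues(c(0.01, 0.04, 0.03)), c(0.03, 0.04, 0.04))
  expect_equal(adjust_pvalues(rep(1, 5)), rep(1, 5))
  expect_error(adjust_pvalues(c(0.5, 1.2)), "\\[0,1\\]")

  set.seed(31)
  for (i in 1:200) {
    p <- stats::runif(sample(1:40, 1))^sample(1:3, 1)
    adj <- adjust_pvalues(p)
    expect_equal(adj, hochberg_oracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(diff(adj[order(p)]) >= -1e-15))  # monotone in sorted order
  }
})

test_that("pseudocounted odds ratios stay finite and antisymmetric", {
  o <- function(e, t) list(edited = e, total = t)
  expect_equal(odds_ratio(o(0, 10), o(10, 10)),
               (0.5 * 0.5) / (10.5 * 10.5), tolerance = 1e-12)
  expect_equal(odds_ratio(o(4, 10), o(4, 10)), 1)
  a <- o(7, 30); b <- o(2, 25)
  expect_equal(odds_ratio(a, b), 1 / odds_ratio(b, a), tolerance = 1e-12)
})

test_that("count ingestion preserves rows and sums duplicates with a warning", {
  df <- data.frame(position = c(10L, 20L, 30L), ref = c("C", "G", "C"),
                   strand = c("+", "-", "+"),
                   A = c(0L, 5L, 1L), C = c(90L, 0L, 40L),
                   G = c(0L, 95L, 0L), T = c(10L, 0L, 60L))
  m <- count_from_pileup(df)
  expect_s3_class(m, "site_count_matrix")
  expect_equal(nrow(m), 3L)
  expect_equal(m$T[m$position == 10], 10L)

  dup <- rbind(df, df[1, ])
  expect_warning(m2 <- count_from_pileup(dup), "summed")
  pre_summed <- df; pre_summed[1, c("A", "C", "G", "T")] <-
    2 * df[1, c("A", "C", "G", "T")]
  expect_equal(as.data.frame(m2), as.data.frame(count_from_pileup(pre_summed)))

  tsv <- tempfile(fileext = ".tsv")
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(as.data.frame(count_from_pileup(tsv))$C, df$C)
})

test_that("the alignment adapter counts bases with known read composition", {
  dir <- withr::local_tempdir()
  refseq <- "ACGTACGCATGCATGCATGC"   # position 8 is a C
  ref <- file.path(dir, "ref.fa")
  writeLines(c(">chrM", refseq), ref)

  # 100 five-base reads over positions 6-10; 90 carry T at position 8
  reads <- c(rep("CGTAT", 90), rep("CGCAT", 10))
  sam <- file.path(dir, "aln.sam")
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               "@SQ\tSN:chrM\tLN:20",
               sprintf("r%03d\t0\tchrM\t6\t60\t5M\t*\t0\t0\t%s\tIIIII",
                       seq_along(reads), reads)), sam)
  m <- count_from_alignments(sam, ref)
  row8 <- m[m$position == 8, ]
  expect_equal(row8$ref, "C")
  expect_equal(c(row8$C, row8$T), c(10, 90))
  expect_equal(m$C[m$position == 6], 100)
  expect_equal(unname(attr(m, "filters")["min_mapq"]), 10)

  # a contig absent from the reference is a hard error
  ref2 <- file.path(dir, "other.fa")
  writeLines(c(">chr1", refseq), ref2)
  expect_error(count_from_alignments(sam, ref2), "contig")
})

test_that("differential calling recovers planted losses and skips uncovered sites", {
  cfg <- generator_config(seed = 77, n_lost_sites = 4, n_stable_sites = 6,
                          coverage_range = c(500L, 500L))
  cm <- simulate_count_matrices(cfg)
  d <- call_differential_sites(cm$matrix_a, cm$matrix_b)
  lost_called <- d$position[d$call == "lost"]
  lost_truth <- cm$truth$position[cm$truth$class == "lost"]
  expect_setequal(lost_called, lost_truth)

  # identical matrices: nothing is significant
  d0 <- call_differential_sites(cm$matrix_a, cm$matrix_a)
  expect_equal(sum(d0$significant), 0L)
  expect_true(all(abs(d0$p_raw - 1) < 1e-12))

  # a site present in only one matrix is silently outside the shared set;
  # a shared site below min_total is skipped with a message
  a <- data.frame(position = c(1L, 2L, 3L), ref = "C", strand = "+",
                  A = 0L, C = c(50L, 50L, 4L), G = 0L, T = c(50L, 50L, 3L))
  b <- data.frame(position = c(1L, 2L, 3L), ref = "C", strand = "+",
                  A = 0L, C = c(95L, 50L, 2L), G = 0L, T = c(5L, 50L, 1L))
  expect_message(d1 <- call_differential_sites(a, b[b$position != 2, ]),
                 "skipped")
  expect_false(2 %in% d1$position)
  expect_equal(attr(d1, "skipped"), 3L)

  expect_error(call_differential_sites(a, transform(a, position = position + 10)),
               "share no positions")
  bad_ref <- a; bad_ref$ref[1] <- "G"
  expect_error(call_differential_sites(a, bad_ref), "mismatch")
})

test_that("codon effects reproduce the annotated amino-acid transitions", {
  eff <- codon_effect("CGT", 1)
  expect_equal(eff[c("ref_codon", "ref_aa", "edited_codon", "edited_aa")],
               list(ref_codon = "CGT", ref_aa = "R",
                    edited_codon = "TGT", edited_aa = "C"))
  expect_false(eff$synonymous)

  expect_equal(codon_effect("TCG", 2)$edited_aa, "L")     # S -> L
  expect_equal(codon_effect("TCA", 2)$edited_aa, "L")     # S -> L
  expect_equal(codon_effect("CGC", 1)$edited_aa, "C")     # R -> C

  # third-position edit that keeps the amino acid
  syn <- codon_effect("GGC", 3)
  expect_true(syn$synonymous)
  expect_equal(syn$ref_aa, syn$edited_aa)

  # edits inside a longer in-frame CDS pick the right codon
  eff2 <- codon_effect("ATGCGTTAA", 4)
  expect_equal(eff2$ref_codon, "CGT")
  expect_equal(eff2$edited_aa, "C")

  expect_error(codon_effect("ATG", 1), "not C")
  expect_error(codon_effect("ATGC", 9), "outside")
})
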