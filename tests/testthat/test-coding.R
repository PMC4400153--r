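test_that("translate_codon follows the standard genetic code", {
  expect_equal(translate_codon(c("GGG", "GAG")), c("G", "E"))
  expect_equal(translate_codon("ATG"), "M")
  expect_equal(translate_codon(c("AAC", "ACC")), c("N", "T"))
  expect_equal(translate_codon(c("taa", "TGA", "Tag")), c("*", "*", "*"))
  expect_error(translate_codon("ANG"), "position 1")
  expect_error(translate_codon(c("ATG", "AT")), "position 2")
})

test_that("a plus-strand substitution is annotated in the published dialect", {
  # codon 74 = GGG, middle base G->A: gGg/gAg, G74E
  codons <- c(rep("ATG", 73), "GGG", rep("AAA", 6))
  toy <- toy_gene(codons)
  pos <- toy$start + 73 * 3 + 1  # middle base of codon 74
  eff <- classify_snp_effect("chr1", pos, "G", "A", toy$models, toy$reference)
  expect_equal(eff$effect, "nonsynonymous")
  expect_equal(eff$codon_change, "gGg/gAg")
  expect_equal(eff$protein_change, "G74E")
  expect_equal(eff$gene_id, "g1")
})

test_that("third-position wobble changes are synonymous", {
  toy <- toy_gene(c("ATG", "GGA", "TAA"))
  pos <- toy$start + 5  # third base of codon 2: GGA -> GGG
  eff <- classify_snp_effect("chr1", pos, "A", "G", toy$models, toy$reference)
  expect_equal(eff$effect, "synonymous")
  expect_equal(eff$protein_change, "G2G")
})

test_that("positions outside any CDS are noncoding", {
  toy <- toy_gene(c("ATG", "TAA"))
  eff <- classify_snp_effect("chr1", 5, "N", "A", toy$models, toy$reference)
  expect_equal(eff$effect, "noncoding")
  expect_true(is.na(eff$gene_id))
})

test_that("classifier agrees with the whole-protein translation oracle over all codons", {
  # one gene carrying all 64 codons; every single-base substitution of
  # every codon position must agree with translating the full protein
  bases <- c("A", "C", "G", "T")
  all_codons <- apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")
  for (strand in c("+", "-")) {
    toy <- toy_gene(all_codons, strand = strand, chrom_length = 500)
    for (pos in seq(toy$start, toy$end)) {
      ref <- substr(as.character(toy$reference[[1]]), pos, pos)
      for (alt in setdiff(bases, ref)) {
        got <- classify_snp_effect("chr1", pos, ref, alt, toy$models,
                                   toy$reference)$effect
        want <- oracle_effect("chr1", pos, alt, toy$models, toy$reference)
        expect_equal(got, want,
                     info = sprintf("strand %s pos %d %s>%s", strand, pos, ref, alt))
      }
    }
  }
})

test_that("classification is strand-consistent", {
  # the same protein on the minus strand yields identical protein changes
  codons <- c("ATG", "GGG", "CAT", "TAA")
  plus <- toy_gene(codons, strand = "+")
  minus <- toy_gene(codons, strand = "-")
  # middle base of codon 2 (G->A: G2E): locate it on each strand
  pos_plus <- plus$start + 4
  pos_minus <- minus$end - 4
  ref_m <- substr(as.character(minus$reference[[1]]), pos_minus, pos_minus)
  eff_p <- classify_snp_effect("chr1", pos_plus, "G", "A",
                               plus$models, plus$reference)
  eff_m <- classify_snp_effect("chr1", pos_minus, ref_m, "T",
                               minus$models, minus$reference)
  expect_equal(eff_p$protein_change, eff_m$protein_change)
  expect_equal(eff_p$codon_change, eff_m$codon_change)
})

test_that("fixed-difference detection honours the threshold logic", {
  tab <- tibble::tibble(
    chrom = "X", pos = 1:5, ref = "A", alt = "G",
    af_a = c(1.00, 0.96, 0.96, 0.03, 0.50),
    af_b = c(0.00, 0.02, 0.30, 0.98, 0.50)
  )
  hits <- find_fixed_differences(tab, "a", "b", fix_threshold = 0.95)
  expect_equal(hits$pos, c(1, 2, 4))
  # allele assignment follows which pool is fixed for alt
  expect_equal(hits$allele_a, c("G", "G", "A"))
  expect_equal(hits$allele_b, c("A", "A", "G"))
  strict <- find_fixed_differences(tab, "a", "b", fix_threshold = 1)
  expect_equal(strict$pos, 1)
  expect_error(find_fixed_differences(tab, "a", "b", fix_threshold = 0.4),
               "fix_threshold")
  expect_error(find_fixed_differences(tab, "a", "zz"), "not found")
})

test_that("site membership is pool-order invariant (only labels swap)", {
  tab <- tibble::tibble(chrom = "X", pos = 1:4, ref = "A", alt = "G",
                        af_a = c(1, 0, 0.97, 0.5),
                        af_b = c(0, 1, 0.01, 0.5))
  ab <- find_fixed_differences(tab, "a", "b")
  ba <- find_fixed_differences(tab, "b", "a")
  expect_equal(ab$pos, ba$pos)
  expect_equal(ab$allele_a, ba$allele_b)
  expect_equal(ab$allele_b, ba$allele_a)
})

test_that("conservation status respects both thresholds exactly", {
  diffs <- tibble::tibble(chrom = "X", pos = 1:4,
                          m_allele = "A", s_allele = "G")
  field <- tibble::tibble(
    chrom = "X", pos = 1:4, ref = "A", alt = "G",
    af_field_M = c(0.00, 0.06, 0.02, 0.02),  # M-allele freq = 1 - af
    af_field_S = c(1.00, 1.00, 0.85, 0.50)
  )
  res <- conservation_filter(diffs, field)
  expect_equal(res$calls$status,
               c("conserved_high", "not_conserved", "conserved_mid",
                 "not_conserved"))
  # boundary: field M frequency 0.94 can never be conserved_high
  b <- conservation_filter(
    tibble::tibble(chrom = "X", pos = 1, m_allele = "A", s_allele = "G"),
    tibble::tibble(chrom = "X", pos = 1, ref = "A", alt = "G",
                   af_field_M = 0.06, af_field_S = 1))
  expect_equal(b$calls$status, "not_conserved")
  # all field pools fixed for the matching alleles: everything conserved
  allfix <- conservation_filter(
    diffs, dplyr::mutate(field, af_field_M = 0, af_field_S = 1))
  expect_true(all(allfix$calls$status == "conserved_high"))
})

test_that("conservation counts are monotone in the thresholds", {
  set.seed(81)
  n <- 60
  diffs <- tibble::tibble(chrom = "X", pos = seq_len(n),
                          m_allele = "A", s_allele = "G")
  field <- tibble::tibble(chrom = "X", pos = seq_len(n), ref = "A", alt = "G",
                          af_field_M = runif(n, 0, 0.2),
                          af_field_S = runif(n, 0.5, 1))
  n_high <- function(thr) {
    sum(conservation_filter(diffs, field, thr_hi = thr)$calls$status ==
          "conserved_high")
  }
  highs <- vapply(c(0.8, 0.9, 0.95, 0.99), n_high, numeric(1))
  expect_true(all(diff(highs) <= 0))
})

test_that("missing field sites are reported separately, and onset is the minimum", {
  diffs <- tibble::tibble(chrom = "X", pos = c(10, 20, 30),
                          m_allele = "A", s_allele = "G")
  field <- tibble::tibble(chrom = "X", pos = c(10, 30), ref = "A", alt = "G",
                          af_field_M = 0, af_field_S = 1)
  res <- conservation_filter(diffs, field)
  expect_equal(res$missing$pos, 20)
  expect_equal(res$onset, 10)
})

test_that("planted synthetic dataset is recovered exactly", {
  set.seed(82)
  ds <- synthetic_coding_dataset()
  diffs <- find_fixed_differences(ds$strain_sites, "RbMM", "RbSS",
                                  fix_threshold = 0.95)
  expect_equal(nrow(diffs), nrow(ds$truth))
  ann <- annotate_effects(diffs, ds$models, ds$reference)
  expect_true(all(ann$effect == "nonsynonymous"))
  res <- conservation_filter(ann, ds$field_sites)
  hi <- res$calls[res$calls$status == "conserved_high", ]
  want <- ds$truth[ds$truth$planted_status == "conserved_high", ]
  expect_equal(sort(hi$pos), sort(want$pos))
  expect_equal(nrow(res$genes), 12)
  expect_equal(sum(res$genes$n_conserved_high), 20)
  expect_equal(res$onset, min(want$pos))
})
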