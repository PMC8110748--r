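test_that("substitution classes collapse strands over all 12 ordered pairs", {
  expected <- c(GA = "GC>AT", CT = "GC>AT", AG = "AT>GC", TC = "AT>GC",
                GT = "GC>TA", CA = "GC>TA", GC = "GC>CG", CG = "GC>CG",
                AT = "AT>TA", TA = "AT>TA", AC = "AT>CG", TG = "AT>CG")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (key in names(expected)) {
    ref <- substr(key, 1, 1); alt <- substr(key, 2, 2)
    expect_identical(substitution_class(ref, alt), unname(expected[key]))
    # strand involution: complementing both bases keeps the class
    expect_identical(substitution_class(comp[ref], comp[alt]),
                     substitution_class(ref, alt))
  }
  expect_true(is_canonical_ems("G", "A"))
  expect_true(is_canonical_ems("C", "T"))
  expect_false(is_canonical_ems("A", "G"))
  expect_false(is_canonical_ems("G", "T"))
  expect_error(substitution_class("N", "A"), "ACGT")
  expect_error(substitution_class("A", "A"), "differ")
})

test_that("effects follow the gene model: UTR, splice window, intron, codons", {
  ref <- two_exon_reference("+")
  expect_identical(predict_effect(ref, 3, "G", "A")$category, "utr")  # flank
  expect_identical(predict_effect(ref, 8, "A", "G")$category, "utr")  # 5'UTR
  expect_identical(predict_effect(ref, 38, "T", "C")$category, "utr") # 3'UTR
  # intron runs 18..27; the two bases at each boundary are splice
  expect_identical(predict_effect(ref, 18, "G", "A")$category, "splice")
  expect_identical(predict_effect(ref, 19, "T", "C")$category, "splice")
  expect_identical(predict_effect(ref, 26, "A", "T")$category, "splice")
  expect_identical(predict_effect(ref, 27, "G", "C")$category, "splice")
  expect_identical(predict_effect(ref, 20, "A", "C")$category, "intron")
  expect_identical(predict_effect(ref, 25, "A", "G")$category, "intron")
  # codon 2 (TAT, Tyr) at amplicon 14-16
  e <- predict_effect(ref, 16, "T", "A")     # TAT -> TAA
  expect_identical(e$category, "truncation")
  expect_identical(e$aa_change, "Y2*")
  e <- predict_effect(ref, 16, "T", "C")     # TAT -> TAC, still Tyr
  expect_identical(e$category, "silent")
  e <- predict_effect(ref, 14, "T", "G")     # TAT -> GAT
  expect_identical(e$category, "missense")
  expect_identical(e$aa_change, "Y2D")
  # codon 3 (GAT) spans the splice junction: second base is amplicon 28
  e <- predict_effect(ref, 28, "A", "T")
  expect_identical(e$aa_change, "D3V")
  expect_identical(e$codon_ref, "GAT")
  expect_identical(e$codon_alt, "GTT")
  expect_error(predict_effect(ref, 16, "G", "A"), "mismatch")
  # start-loss is outside the reporting categories: missense plus warning
  expect_warning(e <- predict_effect(ref, 12, "T", "C"), "start-loss")
  expect_identical(e$aa_change, "M1T")
})

test_that("reverse-complemented amplicon with flipped strand gives identical effects", {
  fwd <- two_exon_reference("+")
  rev <- two_exon_reference("-")
  L <- nchar(fwd$sequence)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  cases <- list(c(16, "T", "A"), c(16, "T", "C"), c(14, "T", "G"),
                c(28, "A", "T"), c(19, "T", "C"), c(22, "A", "G"),
                c(8, "A", "G"))
  for (cs in cases) {
    pos <- as.integer(cs[1])
    ef <- predict_effect(fwd, pos, cs[2], cs[3])
    er <- predict_effect(rev, L - pos + 1L, comp[[cs[2]]], comp[[cs[3]]])
    expect_identical(unclass(er), unclass(ef))
  }
})

test_that("severity applies the BLOSUM62 >= 0 rule and the categorical overrides", {
  mk <- function(aa_ref, aa_alt)
    structure(list(category = "missense", aa_ref = aa_ref, aa_alt = aa_alt),
              class = "effect")
  expect_identical(severity(mk("D", "N")), "NSM")  # BLOSUM62 +1
  expect_identical(severity(mk("A", "T")), "NSM")  # BLOSUM62 0: boundary
  expect_identical(severity(mk("S", "F")), "PSM")  # BLOSUM62 -2
  expect_identical(severity(structure(list(category = "truncation",
                                           aa_ref = "Q", aa_alt = "*"),
                                      class = "effect")), "PSM")
  expect_identical(severity(structure(list(category = "splice", aa_ref = NA,
                                           aa_alt = NA), class = "effect")),
                   "PSM")
  expect_true(is.na(severity(structure(list(category = "silent",
                                            aa_ref = "L", aa_alt = "L"),
                                       class = "effect"))))
  expect_error(severity(mk("O", "F")), "unknown residue")
})

test_that("annotation fills effect, severity and canonicity per candidate", {
  ref <- two_exon_reference("+")
  cand <- data.frame(
    target_id = "toy", position = c(16L, 14L, 22L), ref = "T",
    alt = c("A", "G", "G"), set = 0L, individual = 1L, zygosity = "het",
    f_score = 10, confidence_class = "high")
  cand$ref <- c("T", "T", "A")
  ann <- annotate_candidates(cand, list(toy = ref))
  expect_identical(ann$effect, c("truncation", "missense", "intron"))
  expect_identical(ann$severity, c("PSM", "PSM", NA))
  expect_identical(ann$canonical, c(FALSE, FALSE, FALSE))
  expect_identical(ann$substitution, c("AT>TA", "AT>CG", "AT>GC"))
})
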