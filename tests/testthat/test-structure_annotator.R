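test_that("annotate_element recovers planted features at divergence 0", {
  for (seed in c(2, 9, 27)) {
    el <- make_element(fix_hine_spec(), seed = seed)
    tr <- el$truth
    ann <- annotate_element(el$seq, hine_mo_profile("consensus"))
    expect_identical(ann$structure_type, "HINE")
    expect_identical(c(ann$subtir5$start, ann$subtir5$end), tr$subtir5)
    expect_identical(c(ann$subtir3$start, ann$subtir3$end), tr$subtir3)
    expect_identical(c(ann$palindrome3$start, ann$palindrome3$end),
                     tr$palindrome3)
    expect_true(ann$evidence$subtir_architecture)
    expect_gte(ann$evidence$subtir_pair_identity, 0.9)
  }
})

test_that("a Helentron element classifies via its Rep ORF", {
  el <- make_element(fix_helentron_spec(), seed = 5)
  ann <- annotate_element(el$seq, hine_mo_profile("consensus"))
  expect_identical(ann$structure_type, "Helentron")
  expect_identical(ann$rep_call$classification, "Helentron")
  expect_true(nrow(ann$orfs) >= 1L)
})

test_that("short input is unclassified with a reason", {
  ann <- annotate_element(strrep("ACGT", 20), hine_mo_profile())
  expect_identical(ann$structure_type, "unclassified")
  expect_identical(ann$evidence$reason, "too short")
})

test_that("helitron termini checks follow the IUPAC expansion", {
  seq <- paste0("TC", strrep("ACG", 60), "CTAG")
  hel <- detect_helitron_termini(seq, helitron_profile())
  expect_true(hel$pass5)
  expect_true(hel$pass3)   # CTAG is inside CTRR
  seq2 <- paste0("TC", strrep("ACG", 60), "CTTT")
  expect_false(detect_helitron_termini(seq2, helitron_profile())$pass3)
  # planted 20-nt palindrome 11 bp from the 3' end is found
  el <- make_element(element_spec("canonical_Helitron", embed_rep_orf = FALSE),
                     seed = 8)
  expect_true(detect_helitron_termini(el$seq, helitron_profile())$pass_pal)
})

mk_ev <- function(subtir = FALSE, heli = FALSE, coding = FALSE,
                  tir = FALSE, pal5 = FALSE, pal3 = FALSE) {
  ann <- list(evidence = list(too_short = FALSE,
                              subtir_architecture = subtir,
                              helitron_termini = heli, coding = coding,
                              terminal_tir = tir, palindrome5_found = pal5,
                              palindrome3_found = pal3))
  class(ann) <- "element_annotation"
  ann
}

test_that("classify_structure implements the decision table", {
  expect_identical(classify_structure(mk_ev(subtir = TRUE, coding = TRUE),
                                      "Helentron"), "Helentron")
  expect_identical(classify_structure(mk_ev(subtir = TRUE, coding = FALSE),
                                      "indeterminate"), "HINE")
  expect_identical(classify_structure(mk_ev(subtir = TRUE, coding = TRUE),
                                      "indeterminate"), "unclassified")
  expect_identical(classify_structure(mk_ev(heli = TRUE, coding = TRUE),
                                      "Helitron"), "canonical_Helitron")
  expect_identical(classify_structure(mk_ev(heli = TRUE, coding = TRUE),
                                      "Helentron"), "proto_Helentron")
  # endonuclease evidence vetoes the intermediate call
  expect_identical(classify_structure(mk_ev(heli = TRUE, coding = TRUE),
                                      "Helentron",
                                      domain_calls = data.frame(
                                        domain = "AP endonuclease")),
                   "unclassified")
  # both architectures -> contradictory -> unclassified
  expect_identical(classify_structure(mk_ev(subtir = TRUE, heli = TRUE),
                                      "Helentron"), "unclassified")
  # terminal TIRs + palindromes at both ends + Rep without endonuclease
  expect_identical(classify_structure(mk_ev(coding = TRUE, tir = TRUE,
                                            pal5 = TRUE, pal3 = TRUE),
                                      "Helentron"), "Helitron2_like")
  expect_identical(classify_structure(mk_ev(), NULL), "unclassified")
})

test_that("random sequence is almost never called (false-positive bound)", {
  profile <- hine_mo_profile("consensus")
  withr::with_seed(101, {
    calls <- vapply(1:100, function(i) {
      seq <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
                   collapse = "")
      annotate_element(seq, profile, check_coding = FALSE)$structure_type
    }, character(1))
  })
  expect_lte(sum(calls != "unclassified"), 5L)
})

test_that("annotate_element is a pure function", {
  el <- make_element(fix_hine_spec(), seed = 14)
  a <- annotate_element(el$seq, hine_mo_profile())
  set.seed(99)
  b <- annotate_element(el$seq, hine_mo_profile())
  expect_identical(a[names(a) != "orfs"], b[names(b) != "orfs"])
})

test_that("DINE-1 style non-palindromic subTIRs are found as an IR pair", {
  withr::with_seed(55, {
    sub <- helentronscan:::rand_dna(13)         # generic, non-palindromic
    pad5 <- helentronscan:::rand_dna_noT(3)
    body <- helentronscan:::rand_dna(250)
    # short IR nested at the subTIR, right arm 10 bp downstream
    ir_arm <- helentronscan:::rand_dna(4)
    # keep the spacer from extending the planted subTIR pair by chance
    spacer <- paste0(helentronscan:::non_pairing_base(
      substr(pad5, nchar(pad5), nchar(pad5))),
      helentronscan:::rand_dna(19))
    parm <- helentronscan:::rand_dna(3)
    pal <- paste0(parm, "AA", revcomp(parm))
    pad3 <- helentronscan:::rand_dna_noT(12)
    seq <- paste0(pad5, sub, ir_arm, helentronscan:::rand_dna(10),
                  revcomp(ir_arm), body, revcomp(sub),
                  spacer, pal, pad3)
  })
  prof <- dine1_profile()
  ann <- annotate_element(seq, prof, check_coding = FALSE)
  expect_false(is.null(ann$subtir5))
  expect_false(is.null(ann$subtir3))
  expect_identical(ann$subtir5$seq, sub)
  expect_identical(ann$subtir3$seq, revcomp(sub))
  expect_gte(ann$evidence$subtir_pair_identity, 0.9)
})

test_that("scan_genome recovers planted copies with exact boundaries", {
  sim <- fix_small_sim(seed = 61, n_elements = 2, n_copies = 3,
                       bg_len = 80000, dup_fraction = 0, divergence = 0)
  anns <- scan_genome(sim$genome, hine_mo_profile("genomic"))
  ins <- sim$truth$insertions
  found <- vapply(seq_len(nrow(ins)), function(k) {
    any(vapply(anns, function(a) {
      a$element$seqid == ins$seqid[k] &&
        abs(a$element$start - ins$start[k]) <= 2L &&
        abs(a$element$end - ins$end[k]) <= 2L &&
        a$element$strand == ins$strand[k]
    }, logical(1)))
  }, logical(1))
  expect_true(all(found))
})

test_that("scan_genome is strand-covariant", {
  sim <- fix_small_sim(seed = 71, n_elements = 1, n_copies = 3,
                       bg_len = 50000, dup_fraction = 0, divergence = 0)
  fwd <- scan_genome(sim$genome, hine_mo_profile("genomic"))
  rc <- scan_genome(stats::setNames(revcomp(sim$genome[[1]]), "chr1"),
                    hine_mo_profile("genomic"))
  expect_identical(length(fwd), length(rc))
  n <- nchar(sim$genome[[1]])
  fwd_iv <- sort(vapply(fwd, function(a) a$element$start, integer(1)))
  rc_iv <- sort(vapply(rc, function(a) n - a$element$end, integer(1)))
  expect_identical(fwd_iv, rc_iv)
  expect_identical(sort(vapply(fwd, function(a) a$element$strand, character(1))),
                   sort(ifelse(vapply(rc, function(a) a$element$strand,
                                      character(1)) == "+", "-", "+")))
})

test_that("seeded scans find the same planted copies", {
  sim <- fix_small_sim(seed = 81, n_elements = 1, n_copies = 3,
                       bg_len = 50000, dup_fraction = 0, divergence = 0)
  seeds <- sim$truth$elements[[1]]$subtir
  anns <- scan_genome(sim$genome, hine_mo_profile("genomic"), seeds = seeds)
  expect_identical(length(anns), 3L)
})

test_that("an element-free genome draws at most one false call per Mbp", {
  n_calls <- 0L
  for (seed in 1:2) {
    bg <- generate_background(1e6, 0.45, seed = 900 + seed)
    n_calls <- n_calls + length(scan_genome(c(chr = bg),
                                            hine_mo_profile("consensus")))
  }
  expect_lte(n_calls, 2L)
})
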