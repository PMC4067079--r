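test_that("locate_rep_motif2 matches the printed pattern exactly", {
  hit <- locate_rep_motif2(fix_protein_with("VELQARGSPHIH"))
  expect_identical(hit$matched, "VELQARGSPHIH")
  expect_identical(hit$diag2, "S")
  hit2 <- locate_rep_motif2(fix_protein_with("IEDQTRGLPHAH"))
  expect_identical(hit2$diag2, "L")
  # A at the S/L position violates the pattern
  expect_null(locate_rep_motif2(fix_protein_with("VELQARGAPHIH")))
  # leftmost match is returned, all matches listed
  two <- locate_rep_motif2(paste0(fix_protein_with("VELQARGSPHIH", seed = 2),
                                  fix_protein_with("IEDQTRGLPHAH", seed = 3)))
  expect_identical(two$diag2, "S")
  expect_identical(nrow(two$all_matches), 2L)
})

test_that("classify_rep implements the S/L dichotomy", {
  expect_identical(classify_rep(fix_protein_with("VELQARGSPHIH"))$classification,
                   "Helentron")
  expect_identical(classify_rep(fix_protein_with("IEDQTRGLPHAH"))$classification,
                   "Helitron")
  expect_identical(classify_rep("MKKK")$classification, "indeterminate")
  # every pattern match yields S or L by construction
  call <- classify_rep(fix_protein_with("VELQARGSPHIH"))
  expect_true(call$diag2_residue %in% c("S", "L"))
})

test_that("classify_rep is invariant to residues outside the motif", {
  a <- classify_rep(fix_protein_with("VELQARGSPHIH", seed = 10))
  b <- classify_rep(fix_protein_with("VELQARGSPHIH", seed = 20))
  expect_identical(a$classification, b$classification)
  expect_identical(a$diag2_residue, b$diag2_residue)
})

test_that("the secondary diagnostic is evidence-only", {
  p <- paste0("AAAA", "FWR", "AAA", "VELQARGSPHIH", "AAAA")
  call <- classify_rep(p, diag1_offset = -6L)
  expect_identical(call$classification, "Helentron")
  expect_identical(call$diag1_residues, "FWR")
  expect_match(call$evidence, "matches")
  # a failing diag1 never overrides diag2
  p2 <- paste0("AAAA", "AAA", "AAA", "VELQARGSPHIH", "AAAA")
  call2 <- classify_rep(p2, diag1_offset = -6L)
  expect_identical(call2$classification, "Helentron")
})

test_that("shuffled proteins are essentially never called (small null)", {
  base <- fix_protein_with("VELQARGSPHIH", n_flank = 150)
  withr::with_seed(17, {
    false_calls <- sum(vapply(1:100, function(i) {
      shuf <- paste(sample(strsplit(base, "")[[1]]), collapse = "")
      classify_rep(shuf)$classification != "indeterminate"
    }, logical(1)))
  })
  expect_lte(false_calls, 1L)
})

test_that("find_orfs translates simple cases and maps both strands", {
  orfs <- find_orfs("ATGAAATAA", min_aa = 2)
  expect_identical(nrow(orfs), 1L)
  expect_identical(orfs$aa_seq, "MK")
  expect_identical(orfs$frame, 1L)
  expect_identical(c(orfs$start, orfs$end), c(0L, 6L))

  rc <- find_orfs(revcomp("ATGAAATAA"), min_aa = 2)
  expect_identical(nrow(rc), 1L)
  expect_identical(rc$aa_seq, "MK")
  expect_identical(rc$strand, "-")
  expect_identical(c(rc$start, rc$end), c(3L, 9L))  # mirrored interval

  stops <- paste(rep("TAA", 30), collapse = "")
  expect_identical(nrow(find_orfs(stops, min_aa = 2)), 0L)
})

test_that("find_orfs never loses an ORF embedded in random UTRs", {
  orf_nt <- helentronscan:::make_rep_orf(120L)
  withr::with_seed(31, {
    for (i in 1:5) {
      utr5 <- paste(sample(c("A", "C", "G", "T"), 151, replace = TRUE), collapse = "")
      utr3 <- paste(sample(c("A", "C", "G", "T"), 97, replace = TRUE), collapse = "")
      seq <- paste0(utr5, orf_nt, utr3)
      found <- find_orfs(seq, min_aa = 100)
      expect_true(any(grepl("VELQARGSPHIH", found$aa_seq)))
      rc_found <- find_orfs(revcomp(seq), min_aa = 100)
      expect_true(any(grepl("VELQARGSPHIH", rc_found$aa_seq)))
    }
  })
})

test_that("scan_element_proteins summarises coding capacity", {
  el <- make_element(fix_helentron_spec(), seed = 3)
  sp <- scan_element_proteins(el$seq)
  expect_identical(sp$rep_call$classification, "Helentron")
  expect_false(sp$non_coding)
  expect_gte(sp$coding_summary$n_rep, 1L)

  hine <- make_element(fix_hine_spec(), seed = 4)
  sp2 <- scan_element_proteins(hine$seq)
  expect_true(sp2$non_coding)
  expect_identical(sp2$rep_call$classification, "indeterminate")
})

test_that("adjacent split ORFs are merged and flagged, not repaired", {
  aas <- setdiff(unique(Biostrings::GENETIC_CODE), c("*", "M"))
  withr::with_seed(8, {
    aa1 <- paste0("M", paste(sample(aas, 120, replace = TRUE), collapse = ""), "VE")
    aa2 <- paste0("QARGSPHIH", paste(sample(aas, 120, replace = TRUE), collapse = ""))
  })
  # a stop splits the Rep frame; the second segment restarts at M
  nt <- paste0(helentronscan:::aa_to_nt(aa1), "TAA",
               helentronscan:::aa_to_nt(paste0("M", aa2)), "TAA")
  sp <- scan_element_proteins(nt, min_aa_accessory = 100L)
  expect_identical(sp$rep_call$classification, "Helentron")
  expect_true(sp$coding_summary$putative_corrected)
  expect_match(sp$rep_call$evidence, "putative corrected")
})
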