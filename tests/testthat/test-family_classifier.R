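test_that("shared_subtir_length is a longest-common-substring over both orientations", {
  expect_identical(shared_subtir_length("AAACGCGTTTAGC", "TAACGCGTTTAGG"), 11L)
  expect_identical(shared_subtir_length(strrep("GATC", 3), strrep("GATC", 3)), 12L)
  expect_identical(shared_subtir_length("AAAA", "CCCC"), 0L)
  # orientation maximum: revcomp of b scores too
  expect_identical(shared_subtir_length("ACGTACGTACGT", revcomp("ACGTACGTACGT")),
                   12L)
  # symmetry
  withr::with_seed(3, {
    for (i in 1:10) {
      a <- helentronscan:::rand_dna(13); b <- helentronscan:::rand_dna(14)
      expect_identical(shared_subtir_length(a, b), shared_subtir_length(b, a))
    }
  })
})

test_that("family assignment is single-linkage at the 11 bp threshold", {
  core <- "GGATCCGTACG"                 # 11 bp shared block
  subtirs <- list(A = paste0("AA", core), B = paste0(core, "TT"),
                  C = paste0("C", core, "G"))
  # A~B and B~C share >= 11 bp; single linkage puts all three together
  fam <- assign_families(subtirs)
  expect_identical(length(unique(fam$family)), 1L)
  # exactly 10 bp shared stays apart
  ten <- substr(core, 1, 10)
  fam2 <- assign_families(list(A = paste0("AAA", ten), B = paste0(ten, "CCC")))
  expect_identical(shared_subtir_length(paste0("AAA", ten), paste0(ten, "CCC")), 10L)
  expect_identical(length(unique(fam2$family)), 2L)
  # elements without a subTIR are excluded and reported
  fam3 <- assign_families(list(A = "ACGTACGTACGTA", B = character(0)))
  expect_identical(attr(fam3, "excluded"), "B")
})

test_that("family partition and numbering are permutation-invariant", {
  withr::with_seed(12, {
    subtirs <- c(lapply(1:3, function(i) paste0("AA", "GGATCCGTACG",
                                                helentronscan:::rand_dna(2))),
                 lapply(1:2, function(i) paste0("CC", "TTTACCCGGGA",
                                                helentronscan:::rand_dna(2))))
    names(subtirs) <- paste0("el", 1:5)
  })
  fam <- assign_families(subtirs)
  perm <- sample(names(subtirs))
  fam_p <- assign_families(subtirs[perm])
  m <- merge(fam, fam_p, by = "element_id")
  expect_identical(m$family.x, m$family.y)
  # larger family gets number 1
  expect_identical(sort(table(fam$family), decreasing = TRUE)[[1]], 3L)
  expect_identical(unname(fam$family[fam$element_id == "el1"]), 1L)
})

test_that("three_prime_identity matches counting on substitution-only pairs", {
  withr::with_seed(77, {
    a <- helentronscan:::rand_dna(80)
    expect_identical(three_prime_identity(a, a), 1)
    # 12 scattered substitutions in the last 60 bp -> exactly 48/60
    tail60 <- substr(a, 21, 80)
    chars <- strsplit(tail60, "")[[1]]
    pos <- seq(3, 58, by = 5)[1:12]
    for (p in pos) chars[p] <- setdiff(c("A", "C", "G", "T"), chars[p])[1]
    b <- paste0(substr(a, 1, 20), paste(chars, collapse = ""))
    expect_equal(three_prime_identity(a, b), 0.80)
    # one fewer match fails the 0.80 subfamily threshold
    chars[29] <- setdiff(c("A", "C", "G", "T"), chars[29])[1]
    b13 <- paste0(substr(a, 1, 20), paste(chars, collapse = ""))
    expect_lt(three_prime_identity(a, b13), 0.80)
  })
  expect_error(three_prime_identity("ACGT", "ACGT", window = 60), "at least")
})

test_that("alignment scores agree with an independent DP oracle", {
  withr::with_seed(31, {
    for (i in 1:8) {
      a <- helentronscan:::rand_dna(40)
      b <- if (i %% 2) helentronscan:::mutate_seq(a, 0.15)
           else helentronscan:::rand_dna(40)
      got <- helentronscan:::nw_align_strings(a, b)$score
      expect_equal(got, oracle_global_score(a, b))
    }
  })
})

test_that("gap columns count against identity by default", {
  a <- strrep("ACGTTGCA", 8)
  b <- paste0(substr(a, 1, 30), substr(a, 32, 64), "G")   # one deletion
  incl <- three_prime_identity(a, b, gap_inclusive = TRUE)
  excl <- three_prime_identity(a, b, gap_inclusive = FALSE)
  expect_lt(incl, excl)
})

test_that("subfamily letters and partitions follow the 80%/60bp rule", {
  withr::with_seed(91, {
    base <- helentronscan:::rand_dna(120)
    near <- paste0(helentronscan:::rand_dna(120 - 60), {
      tail <- strsplit(substr(base, 61, 120), "")[[1]]
      pos <- seq(2, 57, by = 5)[1:11]     # 11 subs -> 49/60 = 0.817
      for (p in pos) tail[p] <- setdiff(c("A", "C", "G", "T"), tail[p])[1]
      paste(tail, collapse = "")
    })
    far <- helentronscan:::rand_dna(120)
  })
  seqs <- c(A = base, B = near, C = far)
  fam <- data.frame(element_id = c("A", "B", "C"), family = 1L)
  sub <- assign_subfamilies(seqs, fam)
  expect_identical(sub$subfamily[sub$element_id == "A"],
                   sub$subfamily[sub$element_id == "B"])
  expect_false(sub$subfamily[sub$element_id == "C"] ==
                 sub$subfamily[sub$element_id == "A"])
  # singleton family gets subfamily A; letters continue AA after Z
  expect_identical(helentronscan:::subfamily_letters(c(1, 26, 27, 28)),
                   c("A", "Z", "AA", "AB"))
})

test_that("designed cohorts are recovered with Rand index 1", {
  # two designed families (distinct subTIRs), divergent 3' tiers
  withr::with_seed(7, {
    armA <- helentronscan:::rand_dna(6); armB <- helentronscan:::rand_dna(6)
    subA <- paste0(armA, "G", revcomp(armA))
    subB <- paste0(armB, "C", revcomp(armB))
  })
  elsA <- lapply(1:3, function(i)
    make_element(fix_hine_spec(subtir_seq = subA), seed = 500 + i))
  elsB <- lapply(1:2, function(i)
    make_element(fix_hine_spec(subtir_seq = subB), seed = 600 + i))
  seqs <- vapply(c(elsA, elsB), `[[`, character(1), "seq")
  names(seqs) <- paste0("el", 1:5)
  subtirs <- lapply(c(elsA, elsB), function(e) e$truth$subtir)
  names(subtirs) <- names(seqs)
  fam <- assign_families(subtirs)
  design <- c(1, 1, 1, 2, 2)
  expect_identical(rand_index(fam$family, design), 1)
})

test_that("deletion-derivative linking follows the identity thresholds", {
  el <- make_element(fix_helentron_spec(), seed = 19)
  der <- make_deletion_derivative(el, 120L, 120L)
  # 5% diverged derivative still links with end identities around 0.95
  withr::with_seed(3, mut <- helentronscan:::mutate_seq(der$seq, 0.05))
  link <- link_deletion_derivative(el$seq, mut)
  expect_true(link$link)
  expect_gt(link$identity_5p, 0.88)
  expect_lt(link$identity_5p, 1)
  # unrelated sequence does not link
  withr::with_seed(4, unrel <- helentronscan:::rand_dna(300))
  expect_false(link_deletion_derivative(el$seq, unrel)$link)
  expect_error(link_deletion_derivative("ACGT", "ACGTACGT"), "at least as long")
})

test_that("name_element reproduces the published naming scheme", {
  expect_identical(name_element("Mo", list(family = 1, subfamily = "A",
                                           variant_index = 1,
                                           autonomous = FALSE), "HINE"),
                   "HINE-Mo-1A.1")
  expect_identical(name_element("Cq", list(family = 32, subfamily = "A",
                                           autonomous = TRUE), "Helentron"),
                   "Helentron-Cq-32A")
  expect_identical(name_element("Pi", list(), "proto-Helentron"),
                   "proto-Helentron-Pi")
})

test_that("classification is invariant under reverse complement", {
  withr::with_seed(23, {
    subtirs <- list(a = "GGATCCGTACGAA", b = "TGGATCCGTACGA",
                    c = "TTTACCCGGGATT")
  })
  fam <- assign_families(subtirs)
  fam_rc <- assign_families(lapply(subtirs, revcomp))
  m <- merge(fam, fam_rc, by = "element_id")
  expect_identical(m$family.x, m$family.y)
})
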