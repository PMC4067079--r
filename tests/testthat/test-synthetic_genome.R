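test_that("generate_background is deterministic and honours GC", {
  a <- generate_background(10000, 0.5, seed = 1)
  b <- generate_background(10000, 0.5, seed = 1)
  expect_identical(a, b)
  expect_false(identical(a, generate_background(10000, 0.5, seed = 2)))
  g <- generate_background(100000, 0.3, seed = 3)
  gc <- mean(strsplit(g, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc - 0.3), 0.02)
  expect_error(generate_background(0), "positive")
  expect_error(generate_background(10, gc = 1.2), "gc")
})

test_that("make_element plants features at the recorded coordinates", {
  for (seed in 1:5) {
    el <- make_element(fix_hine_spec(), seed = seed)
    tr <- el$truth
    expect_identical(nchar(el$seq), tr$core_len)
    expect_identical(substr0(el$seq, tr$subtir5[1], tr$subtir5[2]), tr$subtir)
    expect_identical(substr0(el$seq, tr$subtir3[1], tr$subtir3[2]), tr$subtir)
    expect_true(is_self_palindromic(tr$subtir) ||
                  nchar(tr$subtir) %% 2L == 1L)
    pal <- substr0(el$seq, tr$palindrome3[1], tr$palindrome3[2])
    arm <- substr(pal, 1, tr$pal3_arm)
    expect_identical(substr(pal, nchar(pal) - tr$pal3_arm + 1, nchar(pal)),
                     revcomp(arm))
    # offsets honour the spec windows
    expect_identical(tr$subtir5[1], 3L)
    expect_identical(tr$core_len - tr$subtir3[2], 48L)
    expect_identical(tr$core_len - tr$palindrome3[2], 20L)
  }
})

test_that("element_spec validates windows and divergence", {
  expect_error(element_spec("HINE", subtir_len = 11), "subtir_len")
  expect_error(element_spec("HINE", divergence = 0.5), "divergence")
  expect_error(element_spec("HINE", pal3_arm = 6, pal3_loop = 0), "span")
})

test_that("Helitron-type elements carry the canonical termini", {
  el <- make_element(element_spec("canonical_Helitron", embed_rep_orf = FALSE),
                     seed = 2)
  expect_identical(substr(el$seq, 1, 2), "TC")
  expect_match(substr(el$seq, nchar(el$seq) - 3, nchar(el$seq)), "CT[AG][AG]")
  hel <- detect_helitron_termini(el$seq, helitron_profile())
  expect_true(hel$pass5 && hel$pass3 && hel$pass_pal)
  # 16-20 nt palindrome ending 11 bp from the 3' end
  expect_identical(nchar(el$seq) - el$truth$palindrome3[2], 11L)

  proto <- make_element(element_spec("proto_Helentron", embed_rep_orf = FALSE),
                        seed = 3)
  expect_identical(substr(proto$seq, 1, 2), "TT")
  expect_identical(substr(proto$seq, nchar(proto$seq) - 3, nchar(proto$seq)),
                   "CTAG")
  # CTAG is contained in the IUPAC expansion of CTRR
  expect_true(detect_helitron_termini(proto$seq, helitron_profile())$pass3)
})

test_that("planting is deterministic and conserves sequence", {
  simA <- fix_small_sim(seed = 21)
  simB <- fix_small_sim(seed = 21)
  expect_identical(simA$genome, simB$genome)
  expect_identical(simA$truth$insertions, simB$truth$insertions)
  # genome length = background + inserted + duplicated windows + spacers
  ins_len <- sum(simA$truth$insertions$end - simA$truth$insertions$start)
  dup_len <- sum(simA$truth$empty_sites$end - simA$truth$empty_sites$start)
  n_dup <- nrow(simA$truth$empty_sites)
  expect_identical(nchar(simA$genome[[1]]),
                   60000L + ins_len + dup_len + 100L * n_dup)
})

test_that("recorded truth matches the emitted genome exactly", {
  sim <- fix_small_sim(seed = 33, divergence = 0)
  g <- sim$genome[[1]]
  ins <- sim$truth$insertions
  for (k in seq_len(nrow(ins))) {
    eseq <- substr0(g, ins$start[k], ins$end[k])
    if (ins$strand[k] == "-") eseq <- revcomp(eseq)
    # recorded T runs match the emitted sequence
    expect_identical(helentronscan:::t_run_at(eseq, 0L), ins$left_t_run[k])
    expect_identical(helentronscan:::t_run_before(eseq, nchar(eseq)),
                     ins$right_t_run[k])
    # at divergence 0 the core equals the designed element
    core <- substr0(eseq, ins$left_t_run[k], nchar(eseq) - ins$right_t_run[k])
    el <- sim$truth$elements[[as.integer(sub("element", "", ins$element_id[k]))]]
    tr_sub <- el$subtir
    expect_identical(substr0(core, el$subtir5[1], el$subtir5[2]), tr_sub)
    # host contributes exactly one T on each side (isolated TT target)
    left_host <- substr0(g, ins$start[k] - 2L, ins$start[k])
    right_host <- substr0(g, ins$end[k], ins$end[k] + 2L)
    if (ins$strand[k] == "+") {
      expect_match(left_host, "[^T]T$")
      expect_match(right_host, "^T[^T]")
    } else {
      expect_match(left_host, "[^A]A$")
      expect_match(right_host, "^A[^A]")
    }
  }
})

test_that("adding copies never perturbs earlier copies", {
  bg <- generate_background(60000, 0.5, seed = 5)
  els <- list(make_element(fix_hine_spec(), seed = 7))
  sim3 <- plant_insertions(bg, els, n_copies = 3, dup_fraction = 0, seed = 9)
  sim5 <- plant_insertions(bg, els, n_copies = 5, dup_fraction = 0, seed = 9)
  a <- sim3$truth$insertions[order(sim3$truth$insertions$copy_id), ]
  b <- sim5$truth$insertions[match(a$copy_id, sim5$truth$insertions$copy_id), ]
  expect_identical(a$site, b$site)
  expect_identical(a$strand, b$strand)
  expect_identical(a$left_t_run, b$left_t_run)
  expect_identical(a$divergence, b$divergence)
})

test_that("truth serialization round-trips", {
  sim <- fix_small_sim(seed = 41, n_elements = 1, n_copies = 2)
  prefix <- withr::local_tempfile()
  write_truth(sim$truth, prefix)
  back <- read_truth(paste0(prefix, ".truth.json"))
  expect_identical(back$insertions$start, sim$truth$insertions$start)
  expect_identical(back$insertions$copy_id, sim$truth$insertions$copy_id)
  expect_identical(back$empty_sites$start, sim$truth$empty_sites$start)
  bed <- readLines(paste0(prefix, ".truth.bed"))
  expect_identical(length(bed), nrow(sim$truth$insertions))
})

test_that("deletion derivatives keep the termini and drop the interior", {
  el <- make_element(fix_helentron_spec(), seed = 13)
  keep5 <- el$truth$subtir5[2] + 60L
  keep3 <- el$truth$core_len - el$truth$subtir3[1] + 10L
  der <- make_deletion_derivative(el, keep5, keep3)
  expect_lt(nchar(der$seq), nchar(el$seq))
  expect_identical(substr0(der$seq, der$truth$subtir5[1], der$truth$subtir5[2]),
                   el$truth$subtir)
  expect_identical(substr0(der$seq, der$truth$subtir3[1], der$truth$subtir3[2]),
                   el$truth$subtir)
  link <- link_deletion_derivative(el$seq, der$seq)
  expect_true(link$link)
  expect_identical(link$identity_5p, 1)
  expect_identical(link$identity_3p, 1)
  expect_error(make_deletion_derivative(el, 5L, keep3), "too small")
})
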