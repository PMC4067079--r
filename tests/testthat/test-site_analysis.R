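test_that("build_chimeric_query concatenates the two flanks", {
  genome <- c(chr = paste0("AAAA", strrep("G", 30), "CCCC"))
  el <- ginterval("chr", 4, 34)
  q <- build_chimeric_query(genome, el, flank = 4)
  expect_identical(as.character(q), "AAAACCCC")
  expect_identical(attr(q, "junction_offset"), 4L)
  expect_error(build_chimeric_query(genome, ginterval("chr", 2, 34), flank = 4),
               "insufficient flank")
  expect_error(empty_site_params(flank = 10), ">= 20")
})

make_dup_genome <- function(seed = 5, n = 20000, flank = 50, paralog_div = 0) {
  withr::with_seed(seed, {
    bg <- helentronscan:::rand_dna(n)
    site <- 8000L
    locus <- substr(bg, site - flank + 1, site + flank)        # pre-insertion
    paralog <- helentronscan:::mutate_seq(locus, paralog_div)
    elem <- helentronscan:::rand_dna(400)
    genome <- paste0(substr(bg, 1, site), elem,
                     substr(bg, site + 1, n), "GG", paralog)
  })
  list(genome = c(chr = genome), element = ginterval("chr", site, site + 400),
       paralog_start = n + 400 + 2, flank = flank)
}

test_that("find_empty_sites recovers an exact duplicated pre-insertion locus", {
  fx <- make_dup_genome()
  q <- build_chimeric_query(fx$genome, fx$element, fx$flank)
  hits <- find_empty_sites(q, fx$genome, empty_site_params(),
                           insertion = fx$element)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$identity, 1)
  expect_identical(hits$coverage, 1)
  expect_identical(hits$start, as.integer(fx$paralog_start))
  expect_identical(hits$junction_offset, 50L)
})

test_that("identity thresholds gate divergent paralogs", {
  fx <- make_dup_genome(seed = 8, paralog_div = 0.15)
  q <- build_chimeric_query(fx$genome, fx$element, fx$flank)
  strict <- find_empty_sites(q, fx$genome, empty_site_params(),
                             insertion = fx$element)
  expect_identical(nrow(strict), 0L)
  loose <- find_empty_sites(q, fx$genome,
                            empty_site_params(min_identity = 0.80,
                                              min_coverage = 0.80),
                            insertion = fx$element)
  expect_identical(nrow(loose), 1L)
})

test_that("hit sets equal the Waterman-Eggert oracle", {
  withr::with_seed(44, {
    for (i in 1:4) {
      sim <- fix_small_sim(seed = 200 + i, n_elements = 1, n_copies = 2,
                           bg_len = 20000, dup_fraction = 1, divergence = 0)
      ins <- sim$truth$insertions[1, ]
      iv <- ginterval(ins$seqid, ins$start, ins$end, ins$strand)
      q <- build_chimeric_query(sim$genome, iv, 50)
      params <- empty_site_params()
      got <- find_empty_sites(q, sim$genome, params, insertion = iv)
      exp <- oracle_empty_sites(q, sim$genome, params, insertion = iv)
      expect_identical(site_key(got), site_key(exp))
      expect_gte(nrow(got), 1L)
    }
  })
})

test_that("find_empty_sites is strand-covariant", {
  fx <- make_dup_genome(seed = 9)
  q <- build_chimeric_query(fx$genome, fx$element, fx$flank)
  fwd <- find_empty_sites(q, fx$genome, empty_site_params(),
                          insertion = fx$element)
  n <- nchar(fx$genome[[1]])
  rc_genome <- c(chr = revcomp(fx$genome[[1]]))
  rc_iv <- ginterval("chr", n - fx$element$end, n - fx$element$start, "-")
  rc <- find_empty_sites(q, rc_genome, empty_site_params(), insertion = rc_iv)
  expect_identical(nrow(fwd), nrow(rc))
  expect_identical(sort(n - rc$end), sort(fwd$start))
  expect_identical(fwd$identity, rc$identity)
})

test_that("target-site reports recover planted runs, TT and no TSD", {
  sim <- fix_small_sim(seed = 55, n_elements = 1, n_copies = 3,
                       bg_len = 30000, dup_fraction = 1, divergence = 0)
  ins <- sim$truth$insertions
  for (k in seq_len(nrow(ins))) {
    iv <- ginterval(ins$seqid[k], ins$start[k], ins$end[k], ins$strand[k])
    q <- build_chimeric_query(sim$genome, iv, 50)
    hits <- find_empty_sites(q, sim$genome, empty_site_params(), insertion = iv)
    rep <- analyze_target_site(sim$genome, iv,
                               empty = hits[1, , drop = FALSE])
    expect_identical(rep$left_t_run, ins$left_t_run[k])
    expect_identical(rep$right_t_run, ins$right_t_run[k])
    expect_true(rep$tt_at_insertion)
    expect_identical(rep$tsd, NA_character_)
  }
})

test_that("a planted class-2-style TSD is detected and validated", {
  bg <- generate_background(30000, 0.5, seed = 66)
  el <- make_element(fix_hine_spec(), seed = 67)
  sim <- plant_insertions(bg, list(el), n_copies = 2, dup_fraction = 1,
                          seed = 66, tsd_len = 8L, random_strand = FALSE)
  ins <- sim$truth$insertions
  for (k in seq_len(nrow(ins))) {
    iv <- ginterval(ins$seqid[k], ins$start[k], ins$end[k], ins$strand[k])
    q <- build_chimeric_query(sim$genome, iv, 50)
    hits <- find_empty_sites(q, sim$genome,
                             empty_site_params(min_coverage = 0.85),
                             insertion = iv)
    rep <- analyze_target_site(sim$genome, iv,
                               empty = hits[1, , drop = FALSE])
    expect_identical(nchar(rep$tsd), 8L)
    expect_true(rep$tsd_validated)
  }
})

test_that("Helitron insertions sit between A and T without a TSD", {
  bg <- generate_background(30000, 0.5, seed = 77)
  el <- make_element(element_spec("canonical_Helitron", embed_rep_orf = FALSE,
                                  body_len = 600), seed = 78)
  sim <- plant_insertions(bg, list(el), n_copies = 2, dup_fraction = 1,
                          seed = 77, random_strand = FALSE)
  ins <- sim$truth$insertions
  for (k in seq_len(nrow(ins))) {
    iv <- ginterval(ins$seqid[k], ins$start[k], ins$end[k], ins$strand[k])
    q <- build_chimeric_query(sim$genome, iv, 50)
    hits <- find_empty_sites(q, sim$genome, empty_site_params(), insertion = iv)
    rep <- analyze_target_site(sim$genome, iv,
                               empty = hits[1, , drop = FALSE])
    expect_true(rep$at_insertion)
    expect_identical(rep$tsd, NA_character_)
  }
})

test_that("canonicalize_boundaries grows, shrinks and round-trips", {
  el <- ginterval("chr", 100, 200)
  rep <- list(left_t_run = 3L, right_t_run = 2L)
  excl <- canonicalize_boundaries(el, rep, "exclusive", current = "inclusive")
  expect_identical(c(excl$start, excl$end), c(103L, 198L))
  back <- canonicalize_boundaries(excl, rep, "inclusive", current = "exclusive")
  expect_identical(c(back$start, back$end), c(100L, 200L))
  # zero runs: all policies identical
  z <- list(left_t_run = 0L, right_t_run = 0L)
  expect_identical(canonicalize_boundaries(el, z, "exclusive"), el)
  expect_error(canonicalize_boundaries(el, rep, "split"), "ambiguous")
})
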