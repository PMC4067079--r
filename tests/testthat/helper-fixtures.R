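# shared fixture builders (everything generated in code, no stored data)

fix_hine_spec <- function(...) {
  element_spec(kind = "HINE", subtir_len = 13L, subtir5_offset = 3L,
               subtir3_offset = 48L, pal3_arm = 4L, pal3_loop = 2L,
               pal3_offset = 20L, body_len = 300L, ...)
}

fix_helentron_spec <- function(...) {
  element_spec(kind = "Helentron", subtir_len = 14L, subtir5_offset = 3L,
               subtir3_offset = 50L, pal3_arm = 4L, pal3_loop = 1L,
               pal3_offset = 15L, body_len = 400L, ...)
}

fix_small_sim <- function(seed = 11L, n_elements = 2L, n_copies = 3L,
                          bg_len = 60000L, dup_fraction = 1,
                          divergence = 0, random_strand = TRUE) {
  bg <- generate_background(bg_len, 0.5, seed = seed)
  els <- lapply(seq_len(n_elements), function(i)
    make_element(fix_hine_spec(divergence = divergence),
                 seed = seed + 100L * i))
  plant_insertions(bg, els, n_copies = n_copies, dup_fraction = dup_fraction,
                   seed = seed, random_strand = random_strand)
}

# protein carrying a motif instantiation inside a random background
fix_protein_with <- function(core, seed = 1L, n_flank = 80L) {
  aas <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], character(0))
  withr::with_seed(seed, paste0(
    paste(sample(aas, n_flank, replace = TRUE), collapse = ""),
    core,
    paste(sample(aas, n_flank, replace = TRUE), collapse = "")))
}
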