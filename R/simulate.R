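#' Specification of a synthetic element
#'
#' Describes one planted element: architecture windows (matching the
#' HINE/Helentron profile by default), body length, optional
#' microsatellite and embedded Rep ORF, and the per-copy divergence
#' ceiling.  Copies drawn from this spec receive a substitution rate
#' uniform on `[0, divergence]` ("copies insert over time").
#'
#' @param kind one of `"HINE"`, `"Helentron"`, `"canonical_Helitron"`,
#'   `"proto_Helentron"`.
#' @param subtir_len subTIR length (bp, 12-15; even lengths are perfect
#'   palindromes, odd lengths carry a 1-bp loop).
#' @param subtir5_offset bp between the 5' terminus and the subTIR.
#' @param subtir3_offset bp between the 3' subTIR end and the 3' terminus.
#' @param pal3_arm,pal3_loop 3' palindrome arm and loop (total span 5-10).
#' @param pal3_offset bp between the palindrome end and the 3' terminus.
#' @param body_len random body length (bp) excluding any embedded ORF.
#' @param microsat `NULL` or `list(unit=, copies=)`.
#' @param embed_rep_orf embed an ORF carrying the Helentron motif-2
#'   instantiation (`VELQARGSPHIH`).
#' @param rep_aa_len length of the embedded Rep ORF in amino acids.
#' @param subtir_seq optional explicit subTIR sequence (palindromic
#'   designs only), used to build cohorts with designed subTIR sharing.
#' @param divergence per-copy substitution-rate ceiling in `[0, 0.3]`.
#' @return an `element_spec` list.
#' @export
element_spec <- function(kind = c("HINE", "Helentron", "canonical_Helitron",
                                  "proto_Helentron"),
                         subtir_len = 13L, subtir5_offset = 3L,
                         subtir3_offset = 48L, pal3_arm = 4L, pal3_loop = 2L,
                         pal3_offset = 20L, body_len = NULL, microsat = NULL,
                         embed_rep_orf = NULL, rep_aa_len = 350L,
                         subtir_seq = NULL, divergence = 0.05) {
  kind <- match.arg(kind)
  if (is.null(embed_rep_orf)) embed_rep_orf <- kind %in% c("Helentron")
  if (is.null(body_len)) {
    body_len <- switch(kind, HINE = 300L, Helentron = 400L,
                       canonical_Helitron = 1500L, proto_Helentron = 1500L)
  }
  if (divergence < 0 || divergence > 0.3) {
    stop("divergence must be in [0, 0.3]", call. = FALSE)
  }
  if (kind %in% c("HINE", "Helentron")) {
    stopifnot(subtir_len >= 12L, subtir_len <= 15L,
              subtir5_offset >= 2L, subtir5_offset <= 4L,
              subtir3_offset >= 38L, subtir3_offset <= 60L,
              pal3_offset >= 8L, pal3_offset <= 35L)
    span <- 2L * pal3_arm + pal3_loop
    stopifnot(span >= 5L, span <= 10L)
    stopifnot(subtir3_offset - span - pal3_offset >= 0L)
  }
  if (!is.null(subtir_seq)) {
    stopifnot(nchar(subtir_seq) == subtir_len)
  }
  out <- list(kind = kind, subtir_len = as.integer(subtir_len),
              subtir5_offset = as.integer(subtir5_offset),
              subtir3_offset = as.integer(subtir3_offset),
              pal3_arm = as.integer(pal3_arm), pal3_loop = as.integer(pal3_loop),
              pal3_offset = as.integer(pal3_offset),
              body_len = as.integer(body_len), microsat = microsat,
              embed_rep_orf = isTRUE(embed_rep_orf),
              rep_aa_len = as.integer(rep_aa_len),
              subtir_seq = subtir_seq, divergence = divergence)
  class(out) <- "element_spec"
  out
}

#' Random background genome
#'
#' I.i.d. bases at the stated GC content; deterministic for a fixed seed.
#'
#' @param length genome length in bp (> 0).
#' @param gc GC fraction in (0, 1).
#' @param seed RNG seed.
#' @return a DNA string.
#' @export
generate_background <- function(length, gc = 0.5, seed = NULL) {
  if (length <= 0L) stop("length must be positive", call. = FALSE)
  if (gc <= 0 || gc >= 1) stop("gc must be in (0, 1)", call. = FALSE)
  run_seeded(seed, rand_dna(length, gc))
}

# reverse-translate an amino-acid string using one fixed codon per residue
aa_to_nt <- function(aa) {
  gc <- Biostrings::GENETIC_CODE
  codon_of <- vapply(unique(gc), function(a) names(gc)[gc == a][1], character(1))
  names(codon_of) <- unique(gc)
  paste(codon_of[strsplit(aa, "")[[1]]], collapse = "")
}

make_rep_orf <- function(aa_len = 350L) {
  aas <- setdiff(unique(Biostrings::GENETIC_CODE), "*")
  aas <- setdiff(aas, "M")   # avoid extra internal methionines upstream noise
  motif <- "VELQARGSPHIH"
  pre <- paste(sample(aas, max(0L, aa_len %/% 2L), replace = TRUE), collapse = "")
  post <- paste(sample(aas, max(0L, aa_len - nchar(pre) - nchar(motif) - 1L),
                       replace = TRUE), collapse = "")
  aa <- paste0("M", pre, motif, post)
  paste0(aa_to_nt(aa), "TAA")
}

# force `pos` (1-based) of chars to a base that is neither `avoid_comp`'s
# complement nor in `forbid`
non_pairing_base <- function(partner, forbid = character(0)) {
  compl <- c(A = "T", C = "G", G = "C", T = "A")
  choices <- setdiff(c("A", "C", "G", "T"), c(compl[[partner]], forbid))
  sample(choices, 1L)
}

#' Build one synthetic element and its feature truth
#'
#' Assembles 5' pad + palindromic subTIR + body (optional microsatellite
#' and embedded Rep ORF) + subTIR copy + spacer + 3' hairpin + 3' pad,
#' honouring all spec offsets.  Bases adjacent to planted stems are
#' constrained so the stems cannot extend by chance, and the terminal
#' pads avoid T so the boundary T runs added at insertion time stay
#' identifiable.  Helitron-type kinds get the canonical termini instead
#' (5' TC / 3' CTRR, or 5' TT / 3' CTAG, with a 16-20 nt palindrome
#' ending 11 bp from the 3' end).
#'
#' @param spec an [element_spec()].
#' @param seed RNG seed.
#' @return list with `seq` (the element core, boundary T runs excluded)
#'   and `truth` (0-based feature coordinates within `seq`).
#' @export
make_element <- function(spec, seed = NULL) {
  run_seeded(seed, {
    if (spec$kind %in% c("HINE", "Helentron")) {
      pad5 <- rand_dna_noT(spec$subtir5_offset)
      arm_len <- spec$subtir_len %/% 2L
      loop_len <- spec$subtir_len %% 2L
      if (!is.null(spec$subtir_seq)) {
        subtir <- spec$subtir_seq
        arm <- substr(subtir, 1L, arm_len)
      } else {
        arm <- rand_dna(arm_len)
        subtir <- paste0(arm, rand_dna(loop_len), revcomp(arm))
      }
      body <- rand_dna(spec$body_len)
      orf_rng <- NULL
      if (spec$embed_rep_orf) {
        orf <- make_rep_orf(spec$rep_aa_len)
        half <- nchar(body) %/% 2L
        body <- paste0(substr(body, 1L, half), orf,
                       substr(body, half + 1L, nchar(body)))
        orf_rng <- c(half, half + nchar(orf))   # body-local, adjusted below
      }
      if (!is.null(spec$microsat)) {
        ms <- paste(rep(spec$microsat$unit, spec$microsat$copies), collapse = "")
        body <- paste0(ms, body)
        if (!is.null(orf_rng)) orf_rng <- orf_rng + nchar(ms)
      }
      pal_span <- 2L * spec$pal3_arm + spec$pal3_loop
      spacer_len <- spec$subtir3_offset - pal_span - spec$pal3_offset
      spacer <- rand_dna_ac(spacer_len)
      pad3 <- rand_dna_ac(spec$pal3_offset)
      parm <- rand_dna(spec$pal3_arm)
      ploop <- rand_dna(spec$pal3_loop)
      # keep the planted loop from pairing inward
      if (spec$pal3_loop >= 2L) {
        l1 <- substr(ploop, 1L, 1L)
        substr(ploop, spec$pal3_loop, spec$pal3_loop) <- non_pairing_base(l1)
      }
      pal <- paste0(parm, ploop, revcomp(parm))
      # block outward stem extension at every planted stem junction
      if (nchar(body) > 0L && nchar(pad5) > 0L) {
        substr(body, 1L, 1L) <-
          non_pairing_base(substr(pad5, nchar(pad5), nchar(pad5)))
      }
      left_of_sub3 <- substr(body, nchar(body), nchar(body))
      if (spacer_len > 0L) {
        substr(spacer, 1L, 1L) <-
          non_pairing_base(left_of_sub3, forbid = c("G", "T"))
      }
      core <- paste0(pad5, subtir, body, subtir, spacer, pal, pad3)
      s5 <- nchar(pad5)
      s3 <- nchar(pad5) + nchar(subtir) + nchar(body)
      ps <- s3 + nchar(subtir) + spacer_len
      truth <- list(kind = spec$kind, subtir = subtir,
                    subtir5 = c(s5, s5 + nchar(subtir)),
                    subtir3 = c(s3, s3 + nchar(subtir)),
                    palindrome3 = c(ps, ps + pal_span),
                    pal3_arm = spec$pal3_arm, pal3_loop = spec$pal3_loop,
                    orf = if (is.null(orf_rng)) NULL else
                      orf_rng + nchar(pad5) + nchar(subtir),
                    core_len = nchar(core), spec = spec)
      list(seq = core, truth = truth)
    } else {
      m5 <- if (spec$kind == "canonical_Helitron") "TC" else "TT"
      m3 <- if (spec$kind == "canonical_Helitron")
        paste0("CT", paste(sample(c("A", "G"), 2, replace = TRUE), collapse = ""))
      else "CTAG"
      body <- rand_dna(spec$body_len)
      orf_rng <- NULL
      if (spec$embed_rep_orf) {
        orf <- make_rep_orf(spec$rep_aa_len)
        half <- nchar(body) %/% 2L
        body <- paste0(substr(body, 1L, half), orf,
                       substr(body, half + 1L, nchar(body)))
        orf_rng <- c(half, half + nchar(orf))
      }
      parm <- rand_dna(9L); ploop <- rand_dna(2L)
      l1 <- substr(ploop, 1L, 1L)
      substr(ploop, 2L, 2L) <- non_pairing_base(l1)
      pal <- paste0(parm, ploop, revcomp(parm))      # 20 nt
      spacer <- rand_dna(7L)                          # pal ends 11 bp from 3' end
      if (nchar(body) > 0L) {
        substr(body, nchar(body), nchar(body)) <-
          non_pairing_base(substr(spacer, 1L, 1L))
      }
      core <- paste0(m5, body, pal, spacer, m3)
      ps <- nchar(m5) + nchar(body)
      truth <- list(kind = spec$kind, subtir = NA_character_,
                    motif5 = m5, motif3 = m3,
                    palindrome3 = c(ps, ps + nchar(pal)),
                    orf = if (is.null(orf_rng)) NULL else orf_rng + nchar(m5),
                    core_len = nchar(core), spec = spec)
      list(seq = core, truth = truth)
    }
  })
}

#' Excise the internal segment of an element (deletion derivative)
#'
#' Keeps `keep_5p` bp of the 5' end and `keep_3p` bp of the 3' end; the
#' keep windows must cover the structural features (subTIRs and 3'
#' hairpin).
#'
#' @param element output of [make_element()] (list with `seq`, `truth`).
#' @param keep_5p,keep_3p bp retained at each end.
#' @return list with `seq` and updated `truth`.
#' @export
make_deletion_derivative <- function(element, keep_5p, keep_3p) {
  tr <- element$truth
  n <- nchar(element$seq)
  if (keep_5p + keep_3p >= n) stop("keep windows cover the whole element",
                                   call. = FALSE)
  if (keep_5p < tr$subtir5[2] || keep_3p < n - tr$subtir3[1]) {
    stop("keep windows too small: structural features not covered",
         call. = FALSE)
  }
  shift <- n - keep_5p - keep_3p
  seq <- paste0(substr(element$seq, 1L, keep_5p),
                substr(element$seq, n - keep_3p + 1L, n))
  tr$subtir3 <- tr$subtir3 - shift
  tr$palindrome3 <- tr$palindrome3 - shift
  tr$orf <- NULL
  tr$core_len <- nchar(seq)
  tr$kind <- "HINE"
  tr$spec$kind <- "HINE"
  tr$spec$embed_rep_orf <- FALSE
  list(seq = seq, truth = tr)
}

isolated_dinuc_sites <- function(bg, base) {
  chars <- strsplit(bg, "")[[1]]
  n <- length(chars)
  is_b <- chars == base
  ok <- is_b[-n] & is_b[-1L]                      # positions p: bg[p]==bg[p+1]==base
  p <- which(ok)
  p <- p[p >= 2L & p <= n - 2L]
  p <- p[chars[p - 1L] != base & chars[p + 2L] != base]
  p - 1L                                          # 0-based position of first base
}

mimics_tsd <- function(bg, junction, max_tsd = 20L) {
  # junction: 0-based position where the element will be inserted
  for (k in 2L:max_tsd) {
    if (junction - k < 0L || junction + k > nchar(bg)) next
    lk <- substr0(bg, junction - k, junction)
    rk <- substr0(bg, junction, junction + k)
    if (lk == rk) return(TRUE)
  }
  FALSE
}

#' Plant element copies into a background genome
#'
#' For each copy a target site is drawn: an isolated TT dinucleotide for
#' rolling-circle kinds (an isolated AA for minus-strand copies), or an
#' A|T junction for Helitron kinds.  Sites whose pre-existing flanking
#' repeats would mimic a target-site duplication are rejected, so the
#' generator's "no TSD" ground truth is decidable.  With probability
#' `dup_fraction` the pre-insertion locus is first duplicated (appended
#' after the genome with random spacers), creating a paralogous empty
#' site.  Rolling-circle copies receive 2-5 extra T nucleotides at each
#' terminus (after per-copy substitution at a rate uniform on
#' `[0, divergence]`), and the recorded T runs are re-measured on the
#' emitted sequence.  Each copy consumes its own derived RNG stream, so
#' adding copies never perturbs earlier ones.  `tsd_len > 0` switches to
#' a class-2-style negative control that duplicates the `tsd_len`-bp
#' target at both ends.
#'
#' @param background background genome string.
#' @param elements list of [make_element()] outputs.
#' @param n_copies copies per element (scalar or vector).
#' @param dup_fraction fraction of copies with a duplicated pre-insertion
#'   locus.
#' @param seed RNG seed.
#' @param genome_id name of the output sequence.
#' @param spacing minimum distance between insertion sites (bp).
#' @param flank_margin minimum distance of any site from the contig ends.
#' @param random_strand plant copies on both strands.
#' @param tsd_len TSD length for the class-2-style control mode (0 = off).
#' @param dup_window bp of pre-insertion context duplicated on each side
#'   of the junction for empty sites.
#' @return list with `genome` (named character) and `truth`
#'   (`synthetic_truth`: `insertions`, `empty_sites`, `elements`, `seed`).
#' @export
plant_insertions <- function(background, elements, n_copies = 1L,
                             dup_fraction = 0, seed = NULL,
                             genome_id = "chr1", spacing = 200L,
                             flank_margin = 120L, random_strand = TRUE,
                             tsd_len = 0L, dup_window = 80L) {
  if (length(n_copies) == 1L) n_copies <- rep(n_copies, length(elements))
  stopifnot(length(n_copies) == length(elements))
  total <- sum(n_copies)
  el_idx <- rep(seq_along(elements), n_copies)
  bg_chars <- strsplit(background, "")[[1]]
  sites_tt <- isolated_dinuc_sites(background, "T")
  sites_aa <- isolated_dinuc_sites(background, "A")
  sites_at <- which(bg_chars == "A")
  sites_at <- sites_at[sites_at < length(bg_chars)]
  sites_at <- (sites_at - 1L)[bg_chars[sites_at + 1L] == "T"]

  # each copy draws its site, strand, divergence and boundary Ts from its
  # own derived stream, so adding copies never perturbs earlier ones
  plan <- list(el_idx = el_idx, strands = character(total),
               dup = logical(total), site = integer(total))
  inserts <- vector("list", total)
  runs <- matrix(0L, total, 2L)
  rates <- numeric(total)
  chosen <- integer(0)
  for (c_i in seq_len(total)) {
    el <- elements[[el_idx[c_i]]]
    rc_kind <- el$truth$kind %in% c("HINE", "Helentron")
    res <- run_seeded(if (is.null(seed)) NULL else child_seed(seed, c_i), {
      strand <- if (random_strand) sample(c("+", "-"), 1L) else "+"
      dup <- stats::runif(1L) < dup_fraction
      pool <- if (!rc_kind) sites_at
              else if (strand == "+") sites_tt else sites_aa
      pool <- pool[pool >= flank_margin &
                   pool <= nchar(background) - flank_margin]
      pool <- sample(pool)
      picked <- NA_integer_
      for (p in pool) {
        junction <- p + 1L
        if (length(chosen) && min(abs(chosen - p)) < spacing) next
        if (tsd_len == 0L && mimics_tsd(background, junction)) next
        picked <- p
        break
      }
      if (is.na(picked)) stop("not enough eligible target sites", call. = FALSE)
      rate <- stats::runif(1L, 0, el$truth$spec$divergence)
      core <- mutate_seq(el$seq, rate)
      if (rc_kind && tsd_len == 0L) {
        r5 <- sample(2:5, 1L); r3 <- sample(2:5, 1L)
        ins <- paste0(strrep("T", r5), core, strrep("T", r3))
      } else {
        ins <- core
      }
      list(strand = strand, dup = dup, site = picked, rate = rate,
           runs = c(t_run_at(ins, 0L), t_run_before(ins, nchar(ins))),
           ins = if (strand == "-") revcomp(ins) else ins)
    })
    plan$strands[c_i] <- res$strand
    plan$dup[c_i] <- res$dup
    plan$site[c_i] <- res$site
    rates[c_i] <- res$rate
    runs[c_i, ] <- res$runs
    inserts[[c_i]] <- res$ins
    chosen <- c(chosen, res$site)
  }

  ord <- order(plan$site)
  n_bg <- nchar(background)
  pieces <- character(0)
  ins_rows <- list()
  emp_rows <- list()
  prev <- 0L
  offset <- 0L
  for (c_i in ord) {
    p <- plan$site[c_i]
    junction <- p + 1L
    el <- elements[[plan$el_idx[c_i]]]
    rc_kind <- el$truth$kind %in% c("HINE", "Helentron")
    dup_this <- plan$dup[c_i]
    lead <- if (tsd_len > 0L)
      substr0(background, junction, junction + tsd_len) else ""
    pieces <- c(pieces, substr0(background, prev, junction), lead,
                inserts[[c_i]])
    start_f <- junction + offset + nchar(lead)
    end_f <- start_f + nchar(inserts[[c_i]])
    offset <- offset + nchar(inserts[[c_i]]) + nchar(lead)
    prev <- junction
    lr <- runs[c_i, 1L]; rr <- runs[c_i, 2L]
    ins_rows[[length(ins_rows) + 1L]] <- data.frame(
      copy_id = sprintf("copy%03d", c_i),
      element_id = sprintf("element%d", plan$el_idx[c_i]),
      kind = el$truth$kind, seqid = genome_id,
      start = start_f, end = end_f, strand = plan$strands[c_i],
      left_t_run = lr, right_t_run = rr,
      divergence = rates[c_i], dup = dup_this, site = p,
      stringsAsFactors = FALSE)
  }
  pieces <- c(pieces, substr0(background, prev, n_bg))
  genome <- paste(pieces, collapse = "")
  # append duplicated pre-insertion loci (empty sites) with random spacers
  app <- run_seeded(if (is.null(seed)) NULL else child_seed(seed, total + 1L), {
    tail_pieces <- character(0)
    pos <- nchar(genome)
    rows <- list()
    for (k in seq_along(ins_rows)) {
      r <- ins_rows[[k]]
      if (!r$dup) next
      w_s <- max(0L, r$site + 1L - dup_window)
      w_e <- min(n_bg, r$site + 1L + dup_window)
      dup_seq <- substr0(background, w_s, w_e)
      sp <- rand_dna(100L)
      tail_pieces <- c(tail_pieces, sp, dup_seq)
      pos <- pos + nchar(sp)
      rows[[length(rows) + 1L]] <- data.frame(
        copy_id = r$copy_id, seqid = genome_id,
        start = pos, end = pos + nchar(dup_seq),
        junction_offset = (r$site + 1L) - w_s, stringsAsFactors = FALSE)
      pos <- pos + nchar(dup_seq)
    }
    list(tail = paste(tail_pieces, collapse = ""), rows = rows)
  })
  genome <- paste0(genome, app$tail)
  insertions <- do.call(rbind, ins_rows)
  empty_sites <- if (length(app$rows)) do.call(rbind, app$rows) else
    data.frame(copy_id = character(0), seqid = character(0),
               start = integer(0), end = integer(0),
               junction_offset = integer(0), stringsAsFactors = FALSE)
  genome_vec <- stats::setNames(genome, genome_id)
  truth <- list(genome_id = genome_id, seed = seed,
                insertions = insertions, empty_sites = empty_sites,
                elements = lapply(elements, `[[`, "truth"))
  class(truth) <- "synthetic_truth"
  list(genome = genome_vec, truth = truth)
}

#' Serialize synthetic-genome truth to JSON and BED
#'
#' @param truth a `synthetic_truth`.
#' @param prefix output path prefix (writes `<prefix>.truth.json` and
#'   `<prefix>.truth.bed`).
#' @return invisibly, the JSON path.
#' @export
write_truth <- function(truth, prefix) {
  json_path <- paste0(prefix, ".truth.json")
  bed_path <- paste0(prefix, ".truth.bed")
  payload <- list(genome_id = truth$genome_id, seed = truth$seed,
                  insertions = truth$insertions,
                  empty_sites = truth$empty_sites)
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  tab <- truth$insertions
  writeLines(paste(tab$seqid, tab$start, tab$end, tab$copy_id, 0, tab$strand,
                   sep = "\t"), bed_path)
  invisible(json_path)
}

#' Read serialized truth back
#'
#' @param json_path path written by [write_truth()].
#' @return a `synthetic_truth` (without the per-element feature lists).
#' @export
read_truth <- function(json_path) {
  payload <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  truth <- list(genome_id = payload$genome_id, seed = payload$seed,
                insertions = as.data.frame(payload$insertions),
                empty_sites = as.data.frame(payload$empty_sites))
  class(truth) <- "synthetic_truth"
  truth
}
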