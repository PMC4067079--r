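#' Structure profiles
#'
#' A structure profile holds the positional windows used to recognise an
#' element architecture: subTIR length and offsets from both termini, the
#' 3' palindrome (stem-loop) length and offset, the optional DINE-1 short
#' IR, and canonical-Helitron terminal motifs.  All windows are inclusive
#' hard ranges, each extendable by `slack` bp.
#'
#' Shipped presets:
#' * `hine_mo_profile()` — the HINE/Helentron architecture: 12-15 bp
#'   palindromic subTIRs 2-4 bp from the 5' terminus and 38-60 bp from
#'   the 3' terminus, plus a 5-10 bp palindrome 8-35 bp from the 3' end.
#'   `strictness = "consensus"` (default) allows no stem mismatches and
#'   requires >= 0.90 identity between the two subTIRs;
#'   `strictness = "genomic"` tolerates the divergence of genomic copies
#'   (2 arm mismatches, >= 0.80 pair identity, 3' palindrome optional for
#'   reporting, and the subTIR must recur in at least 2 copies).
#' * `dine1_profile()` — Drosophila DINE-1: 13 bp non-palindromic
#'   subTIRs plus a short IR 3-22 bp from the 5' subTIR.
#' * `helitron_profile()` — canonical Helitron termini (5' TC, 3' CTRR,
#'   16-20 nt palindrome ~11 bp from the 3' end).
#' * `proto_helentron_profile()` — Helitron-like termini of the
#'   Helitron/Helentron intermediate (5' TT, 3' CTAG).
#'
#' @param name profile name.
#' @param subtir_len_range,subtir5_offset_range,subtir3_offset_range
#'   subTIR length and offset windows (bp; offsets measured from the
#'   nearest terminus to the subTIR start at the 5' end, and to the
#'   subTIR end at the 3' end).
#' @param palindrome3_len_range,palindrome3_offset_range 3' palindrome
#'   total span and end-offset windows (bp from the 3' terminus).
#' @param require_palindromic_subtir if `TRUE` subTIRs are located as
#'   self-palindromic hairpins; otherwise as an inverted-repeat pair
#'   between the two termini (DINE-1 style).
#' @param require_palindrome3 whether a missing 3' palindrome disqualifies
#'   a candidate during genome scans (annotation-level typing always
#'   requires it for the HINE/Helentron call).
#' @param ir_gap_range optional gap window for the DINE-1 short IR.
#' @param helitron_5p_motifs,helitron_3p_motifs terminal motif strings
#'   (IUPAC codes allowed).
#' @param helitron_pal_len_range,helitron_pal_offset_range Helitron
#'   subterminal palindrome span and 3'-end offset windows.
#' @param subtir_pair_min_identity minimum identity between the 5' and 3'
#'   subTIR (best of direct and reverse-complement orientation).
#' @param subtir_max_mismatch,pal3_max_mismatch arm mismatch tolerances.
#' @param pair_mm_budget cap on the summed arm mismatches of a candidate
#'   subTIR pair during genome scans.
#' @param min_element_len,max_element_len element length bounds (bp).
#' @param slack window slack in bp applied to every positional range.
#' @param min_subtir_copies minimum number of scan calls sharing a subTIR
#'   (>= 0.85 identity) for a call to be retained.
#' @return a `structure_profile` list.
#' @export
structure_profile <- function(name = "custom",
                              subtir_len_range = c(12L, 15L),
                              subtir5_offset_range = c(2L, 4L),
                              subtir3_offset_range = c(38L, 60L),
                              palindrome3_len_range = c(5L, 10L),
                              palindrome3_offset_range = c(8L, 35L),
                              require_palindromic_subtir = TRUE,
                              require_palindrome3 = TRUE,
                              ir_gap_range = NULL,
                              helitron_5p_motifs = c("TC", "TT"),
                              helitron_3p_motifs = "CTRR",
                              helitron_pal_len_range = c(16L, 20L),
                              helitron_pal_offset_range = c(8L, 14L),
                              subtir_pair_min_identity = 0.90,
                              subtir_max_mismatch = 0L,
                              pal3_max_mismatch = 0L,
                              pair_mm_budget = 0L,
                              min_element_len = 150L,
                              max_element_len = 20000L,
                              slack = 3L,
                              min_subtir_copies = 1L) {
  ranges <- list(subtir_len_range, subtir5_offset_range, subtir3_offset_range,
                 palindrome3_len_range, palindrome3_offset_range)
  for (r in ranges) {
    if (length(r) != 2L || any(r < 0) || r[2] < r[1]) {
      stop("profile ranges must be non-empty, non-negative [min,max]", call. = FALSE)
    }
  }
  out <- list(name = name,
              subtir_len_range = as.integer(subtir_len_range),
              subtir5_offset_range = as.integer(subtir5_offset_range),
              subtir3_offset_range = as.integer(subtir3_offset_range),
              palindrome3_len_range = as.integer(palindrome3_len_range),
              palindrome3_offset_range = as.integer(palindrome3_offset_range),
              require_palindromic_subtir = isTRUE(require_palindromic_subtir),
              require_palindrome3 = isTRUE(require_palindrome3),
              ir_gap_range = if (is.null(ir_gap_range)) NULL else as.integer(ir_gap_range),
              helitron_5p_motifs = helitron_5p_motifs,
              helitron_3p_motifs = helitron_3p_motifs,
              helitron_pal_len_range = as.integer(helitron_pal_len_range),
              helitron_pal_offset_range = as.integer(helitron_pal_offset_range),
              subtir_pair_min_identity = subtir_pair_min_identity,
              subtir_max_mismatch = as.integer(subtir_max_mismatch),
              pal3_max_mismatch = as.integer(pal3_max_mismatch),
              pair_mm_budget = as.integer(pair_mm_budget),
              min_element_len = as.integer(min_element_len),
              max_element_len = as.integer(max_element_len),
              slack = as.integer(slack),
              min_subtir_copies = as.integer(min_subtir_copies))
  class(out) <- "structure_profile"
  out
}

#' @rdname structure_profile
#' @param strictness `"consensus"` for curated consensus sequences,
#'   `"genomic"` for divergent genomic copies.
#' @export
hine_mo_profile <- function(strictness = c("consensus", "genomic")) {
  strictness <- match.arg(strictness)
  if (strictness == "consensus") {
    structure_profile(name = "hine-mo")
  } else {
    structure_profile(name = "hine-mo-genomic",
                      subtir_pair_min_identity = 0.80,
                      require_palindrome3 = FALSE,
                      subtir_max_mismatch = 2L, pal3_max_mismatch = 1L,
                      pair_mm_budget = 4L, min_subtir_copies = 2L)
  }
}

#' @rdname structure_profile
#' @export
dine1_profile <- function() {
  structure_profile(name = "dine-1",
                    subtir_len_range = c(13L, 13L),
                    require_palindromic_subtir = FALSE,
                    ir_gap_range = c(3L, 22L))
}

#' @rdname structure_profile
#' @export
helitron_profile <- function() {
  structure_profile(name = "helitron",
                    helitron_5p_motifs = "TC", helitron_3p_motifs = "CTRR")
}

#' @rdname structure_profile
#' @export
proto_helentron_profile <- function() {
  structure_profile(name = "proto-helentron",
                    helitron_5p_motifs = "TT", helitron_3p_motifs = "CTAG")
}

#' @export
print.structure_profile <- function(x, ...) {
  cat("<structure_profile>", x$name, "\n")
  cat("  subTIR", paste(x$subtir_len_range, collapse = "-"), "bp;",
      "5' offset", paste(x$subtir5_offset_range, collapse = "-"),
      "; 3' offset", paste(x$subtir3_offset_range, collapse = "-"), "\n")
  cat("  3' palindrome", paste(x$palindrome3_len_range, collapse = "-"),
      "bp at", paste(x$palindrome3_offset_range, collapse = "-"),
      "bp from 3' end\n")
  invisible(x)
}

pick_best_hairpin <- function(df) {
  if (nrow(df) == 0L) return(NULL)
  df <- df[order(-df$arm_len, df$mismatches, df$offset), , drop = FALSE]
  as.list(df[1L, , drop = FALSE])
}

hairpin_feature <- function(hit) {
  if (is.null(hit)) return(NULL)
  span <- 2L * hit$arm_len + hit$loop_len
  list(start = hit$offset, end = hit$offset + span, seq = hit$seq,
       arm_len = hit$arm_len, loop_len = hit$loop_len,
       mismatches = hit$mismatches)
}

subtir_pair_identity <- function(a, b) {
  max(slide_identity_cpp(a, b), slide_identity_cpp(a, revcomp(b)))
}

# DINE-1-style subTIR search: a left segment in the 5' window whose
# reverse complement recurs (<= max_mismatch) with its end in the 3' window
find_ir_subtirs <- function(seq, profile) {
  n <- nchar(seq); sl <- profile$slack
  lr <- profile$subtir_len_range
  w5 <- c(max(0L, profile$subtir5_offset_range[1] - sl),
          profile$subtir5_offset_range[2] + sl)
  w3 <- c(max(0L, n - profile$subtir3_offset_range[2] - sl),
          n - profile$subtir3_offset_range[1] + sl)
  best <- NULL
  for (len in seq(lr[2], lr[1])) {
    for (s5 in seq(w5[1], w5[2])) {
      if (s5 + len > n) next
      left <- substr0(seq, s5, s5 + len)
      target <- revcomp(left)
      for (e3 in seq(w3[1], min(w3[2], n))) {
        s3 <- e3 - len
        if (s3 <= s5 + len) next
        right <- substr0(seq, s3, e3)
        mm <- sum(strsplit(right, "")[[1]] != strsplit(target, "")[[1]])
        if (mm <= profile$subtir_max_mismatch) {
          cand <- list(s5 = s5, e5 = s5 + len, s3 = s3, e3 = e3,
                       len = len, mm = mm)
          if (is.null(best) || len > best$len ||
              (len == best$len && mm < best$mm)) best <- cand
        }
      }
    }
  }
  best
}

# longest run of a 1-6 bp unit repeated >= 4 times (reported, not used in typing)
find_microsat <- function(seq) {
  m <- gregexpr("([ACGT]{1,6})\\1{3,}", seq, perl = TRUE)[[1]]
  if (m[1] == -1L) return(NULL)
  len <- attr(m, "match.length")
  k <- which.max(len)
  if (len[k] < 12L) return(NULL)
  list(start = m[k] - 1L, end = m[k] - 1L + len[k],
       seq = substr(seq, m[k], m[k] + len[k] - 1L))
}

#' Check canonical-Helitron terminal signatures
#'
#' Reports whether the sequence starts with a 5' terminal motif (TC, or
#' profile variants such as TT), ends with a 3' motif matched against its
#' IUPAC expansion (CTRR admits CTAG), and carries a 16-20 nt palindrome
#' ending about 11 bp from the 3' end (window configurable).
#'
#' @param seq DNA string.
#' @param profile a [structure_profile()].
#' @return list with `motif5`, `motif3` (matched motif or `NA`),
#'   `palindrome` (hairpin feature or `NULL`) and logical `pass5`,
#'   `pass3`, `pass_pal`.
#' @export
detect_helitron_termini <- function(seq, profile = helitron_profile()) {
  assert_dna(seq)
  n <- nchar(seq); sl <- profile$slack
  m5 <- NA_character_
  for (m in profile$helitron_5p_motifs) {
    if (grepl(paste0("^", iupac_to_regex(m)), seq)) { m5 <- m; break }
  }
  m3 <- NA_character_
  for (m in profile$helitron_3p_motifs) {
    if (grepl(paste0(iupac_to_regex(m), "$"), seq)) { m3 <- m; break }
  }
  plr <- profile$helitron_pal_len_range
  pal <- NULL
  if (n >= plr[1]) {
    pals <- find_palindromes(seq, min_arm = floor(plr[1] / 2),
                             max_arm = ceiling(plr[2] / 2),
                             min_loop = 0L, max_loop = 4L,
                             max_mismatch = profile$pal3_max_mismatch)
    span <- 2L * pals$arm_len + pals$loop_len
    dist3 <- n - (pals$offset + span)
    keep <- span >= plr[1] & span <= plr[2] &
      dist3 >= profile$helitron_pal_offset_range[1] - sl &
      dist3 <= profile$helitron_pal_offset_range[2] + sl
    pal <- hairpin_feature(pick_best_hairpin(pals[keep, , drop = FALSE]))
  }
  list(motif5 = m5, motif3 = m3, palindrome = pal,
       pass5 = !is.na(m5), pass3 = !is.na(m3), pass_pal = !is.null(pal))
}

#' Annotate the structural architecture of one element sequence
#'
#' Locates the 5' and 3' subTIRs, the 3' palindrome, the optional DINE-1
#' short IR and microsatellite runs within the positional windows of a
#' [structure_profile()], checks canonical-Helitron termini, scans for
#' ORFs and the Rep motif-2 signature, and emits a structure-type call
#' via [classify_structure()].  Feature ties are broken by longer arm,
#' fewer mismatches, then smaller offset.  Coordinates in the returned
#' annotation are 0-based half-open, relative to `seq` plus `offset`.
#'
#' @param seq element DNA sequence (boundaries at the sequence ends).
#' @param profile a [structure_profile()].
#' @param id,seqid identifiers for the annotation.
#' @param offset coordinate shift applied to all reported intervals.
#' @param strand reported strand.
#' @param check_coding run the ORF/Rep scan (set `FALSE` to skip).
#' @param min_aa_rep,min_aa_accessory ORF length thresholds (aa) for a
#'   putative Rep/Helicase and for accessory ORFs.
#' @param domain_calls optional data frame of externally computed domain
#'   calls with a `domain` column (hook for endonuclease evidence).
#' @return an `element_annotation` list: element interval, features,
#'   `orfs`, `rep_call`, `structure_type` and an `evidence` list of
#'   named window checks.
#' @export
annotate_element <- function(seq, profile = hine_mo_profile(),
                             id = "query", seqid = id, offset = 0L,
                             strand = "+", check_coding = TRUE,
                             min_aa_rep = 300L, min_aa_accessory = 100L,
                             domain_calls = NULL) {
  assert_dna(seq)
  n <- nchar(seq)
  sl <- profile$slack
  ev <- list()
  ann <- list(id = id, structure_type = "unclassified", evidence = ev,
              subtir5 = NULL, subtir3 = NULL, palindrome3 = NULL,
              palindrome5 = NULL, ir = NULL, microsat = NULL,
              orfs = NULL, rep_call = NULL, score = NA_real_,
              element = ginterval(seqid, offset, offset + n, strand))
  if (n < profile$min_element_len) {
    ann$evidence <- list(too_short = TRUE, reason = "too short")
    class(ann) <- "element_annotation"
    return(ann)
  }
  ev$too_short <- FALSE

  lr <- profile$subtir_len_range
  if (profile$require_palindromic_subtir) {
    smm <- profile$subtir_max_mismatch
    cands <- hairpins_multi(seq, min_arm = floor(lr[1] / 2),
                              max_arm = ceiling(lr[2] / 2) + smm,
                              min_loop = 0L, max_loop = 1L,
                              max_mismatch = smm)
    span <- 2L * cands$arm_len + cands$loop_len
    cands <- cands[span >= lr[1] & span <= lr[2] + 2L * smm, , drop = FALSE]
    span <- 2L * cands$arm_len + cands$loop_len
    in5 <- cands$offset >= max(0L, profile$subtir5_offset_range[1] - sl) &
      cands$offset <= profile$subtir5_offset_range[2] + sl
    dist3 <- n - (cands$offset + span)
    in3 <- dist3 >= profile$subtir3_offset_range[1] - sl &
      dist3 <= profile$subtir3_offset_range[2] + sl
    c5 <- cands[in5, , drop = FALSE]
    c3 <- cands[in3, , drop = FALSE]
    if (nrow(c5) && nrow(c3)) {
      # choose the 5'/3' pair jointly: the two subTIRs are copies of one
      # another, so cross-end agreement outranks individual stem length
      cap <- ceiling(lr[2] / 2)
      best <- NULL; best_score <- -Inf
      for (a in seq_len(nrow(c5))) {
        for (b in seq_len(nrow(c3))) {
          id <- subtir_pair_identity(c5$seq[a], c3$seq[b])
          sc <- 12 * id +
            (min(c5$arm_len[a], cap) - c5$mismatches[a]) +
            (min(c3$arm_len[b], cap) - c3$mismatches[b])
          if (sc > best_score) { best_score <- sc; best <- c(a, b) }
        }
      }
      ann$subtir5 <- hairpin_feature(as.list(c5[best[1], , drop = FALSE]))
      ann$subtir3 <- hairpin_feature(as.list(c3[best[2], , drop = FALSE]))
    } else {
      ann$subtir5 <- hairpin_feature(pick_best_hairpin(c5))
      ann$subtir3 <- hairpin_feature(pick_best_hairpin(c3))
    }
  } else {
    hit <- find_ir_subtirs(seq, profile)
    if (!is.null(hit)) {
      ann$subtir5 <- list(start = hit$s5, end = hit$e5,
                          seq = substr0(seq, hit$s5, hit$e5),
                          arm_len = hit$len, loop_len = NA_integer_,
                          mismatches = hit$mm)
      ann$subtir3 <- list(start = hit$s3, end = hit$e3,
                          seq = substr0(seq, hit$s3, hit$e3),
                          arm_len = hit$len, loop_len = NA_integer_,
                          mismatches = hit$mm)
    }
  }
  ev$subtir5_found <- !is.null(ann$subtir5)
  ev$subtir3_found <- !is.null(ann$subtir3)

  plr <- profile$palindrome3_len_range
  pals <- hairpins_multi(seq, min_arm = max(2L, floor(plr[1] / 2)),
                           max_arm = ceiling(plr[2] / 2),
                           min_loop = 0L, max_loop = max(0L, plr[2] - 4L),
                           max_mismatch = profile$pal3_max_mismatch)
  pspan <- 2L * pals$arm_len + pals$loop_len
  pals <- pals[pspan >= plr[1] & pspan <= plr[2], , drop = FALSE]
  pspan <- 2L * pals$arm_len + pals$loop_len
  pdist3 <- n - (pals$offset + pspan)
  in_p3 <- pdist3 >= profile$palindrome3_offset_range[1] - sl &
    pdist3 <= profile$palindrome3_offset_range[2] + sl
  ann$palindrome3 <- hairpin_feature(pick_best_hairpin(pals[in_p3, , drop = FALSE]))
  ev$palindrome3_found <- !is.null(ann$palindrome3)
  # 5' palindrome (Helitron2-style architectures carry one near each end)
  in_p5 <- pals$offset <= profile$palindrome3_offset_range[2] + sl
  ann$palindrome5 <- hairpin_feature(pick_best_hairpin(pals[in_p5, , drop = FALSE]))

  if (ev$subtir5_found && ev$subtir3_found) {
    ev$subtir_pair_identity <- subtir_pair_identity(ann$subtir5$seq, ann$subtir3$seq)
    ev$subtir_pair_pass <- ev$subtir_pair_identity >= profile$subtir_pair_min_identity
  } else {
    ev$subtir_pair_identity <- NA_real_
    ev$subtir_pair_pass <- FALSE
  }
  ev$subtir_architecture <- ev$subtir5_found && ev$subtir3_found &&
    ev$palindrome3_found && ev$subtir_pair_pass

  if (!is.null(profile$ir_gap_range) && ev$subtir5_found) {
    to <- min(n, ann$subtir5$end + profile$ir_gap_range[2] + 15L)
    win <- substr0(seq, ann$subtir5$start, to)
    irs <- find_inverted_repeat_pairs(win, min_arm = 3L,
                                      min_gap = profile$ir_gap_range[1],
                                      max_gap = profile$ir_gap_range[2],
                                      max_mismatch = 0L, max_arm = 12L)
    if (nrow(irs)) {
      irs <- irs[order(-irs$arm_len, irs$left_start), , drop = FALSE]
      ann$ir <- list(start = ann$subtir5$start + irs$left_start[1],
                     end = ann$subtir5$start + irs$right_end[1],
                     arm_len = irs$arm_len[1], gap = irs$gap[1],
                     mismatches = irs$mismatches[1])
    }
  }
  ev$ir_found <- !is.null(ann$ir)

  ann$microsat <- find_microsat(seq)

  hel <- detect_helitron_termini(seq, profile)
  ev$helitron_5p <- hel$pass5
  ev$helitron_3p <- hel$pass3
  ev$helitron_palindrome <- hel$pass_pal
  ev$helitron_termini <- hel$pass5 && hel$pass3
  ann$helitron <- hel

  # terminal inverted repeats (Helitron2-style check)
  win_len <- min(40L, n %/% 2L)
  lcs <- lcs_length(substr0(seq, 0L, win_len),
                    revcomp(substr0(seq, n - win_len, n)))
  ev$terminal_tir <- lcs >= 10L
  ev$palindrome5_found <- !is.null(ann$palindrome5)

  if (check_coding) {
    sp <- scan_element_proteins(seq, min_aa_rep = min_aa_rep,
                                min_aa_accessory = min_aa_accessory)
    ann$orfs <- sp$orfs
    ann$rep_call <- sp$rep_call
    ev$coding <- !sp$non_coding
    ev$rep_class <- sp$rep_call$classification %||% "indeterminate"
  } else {
    ev$coding <- NA
    ev$rep_class <- NA_character_
  }

  ann$evidence <- ev
  ann$structure_type <- classify_structure(ann, ann$rep_call,
                                           domain_calls = domain_calls)
  # offset features to absolute coordinates
  shift <- function(f) {
    if (is.null(f)) return(NULL)
    f$start <- f$start + offset; f$end <- f$end + offset; f
  }
  for (nm in c("subtir5", "subtir3", "palindrome3", "palindrome5", "ir", "microsat")) {
    ann[[nm]] <- shift(ann[[nm]])
  }
  if (!is.null(ann$orfs) && nrow(ann$orfs)) {
    ann$orfs$start <- ann$orfs$start + offset
    ann$orfs$end <- ann$orfs$end + offset
  }
  class(ann) <- "element_annotation"
  ann
}

#' Structure-type decision table
#'
#' Combines the architectural evidence of an annotation with a Rep
#' protein call: subTIR architecture with a Helentron-class Rep is a
#' `Helentron`; subTIR architecture without coding capacity is a `HINE`;
#' canonical Helitron termini with a Helitron-class Rep is a
#' `canonical_Helitron`; Helitron termini with a Helentron-class Rep (and
#' no endonuclease evidence) is a `proto_Helentron`; terminal inverted
#' repeats with palindromes at both ends and a Rep lacking endonuclease
#' evidence is `Helitron2_like`; contradictory or insufficient evidence
#' yields `unclassified` (both evidence sets are retained).
#'
#' @param annotation an `element_annotation`.
#' @param rep_call a Rep classification (list with `$classification`, a
#'   string, or `NULL`).
#' @param domain_calls optional external domain-call table (`domain`
#'   column); presence of an endonuclease entry vetoes `proto_Helentron`.
#' @return one of `"HINE"`, `"Helentron"`, `"canonical_Helitron"`,
#'   `"proto_Helentron"`, `"Helitron2_like"`, `"unclassified"`.
#' @export
classify_structure <- function(annotation, rep_call = NULL, domain_calls = NULL) {
  ev <- annotation$evidence
  if (isTRUE(ev$too_short)) return("unclassified")
  rep_class <- if (is.character(rep_call)) rep_call
               else rep_call$classification %||% "indeterminate"
  has_endo <- !is.null(domain_calls) &&
    any(grepl("endonuclease", domain_calls$domain, ignore.case = TRUE))
  subtir_ok <- isTRUE(ev$subtir_architecture)
  heli_ok <- isTRUE(ev$helitron_termini)
  if (subtir_ok && heli_ok) return("unclassified")
  if (subtir_ok) {
    if (rep_class == "Helentron") return("Helentron")
    if (!isTRUE(ev$coding)) return("HINE")
    return("unclassified")
  }
  if (heli_ok) {
    if (rep_class == "Helitron") return("canonical_Helitron")
    if (rep_class == "Helentron" && !has_endo) return("proto_Helentron")
    return("unclassified")
  }
  if (isTRUE(ev$terminal_tir) && isTRUE(ev$palindrome5_found) &&
      isTRUE(ev$palindrome3_found) && isTRUE(ev$coding) &&
      rep_class != "indeterminate" && !has_endo) {
    return("Helitron2_like")
  }
  "unclassified"
}

#' @export
print.element_annotation <- function(x, ...) {
  iv <- x$element
  cat(sprintf("<element_annotation> %s  %s:%d-%d(%s)  type=%s\n",
              x$id, iv$seqid, iv$start, iv$end, iv$strand, x$structure_type))
  feat <- function(nm) if (!is.null(x[[nm]]))
    cat(sprintf("  %-13s %d-%d %s\n", nm, x[[nm]]$start, x[[nm]]$end,
                x[[nm]]$seq %||% ""))
  for (nm in c("subtir5", "subtir3", "palindrome3", "ir", "microsat")) feat(nm)
  if (!is.null(x$orfs)) cat("  ORFs:", nrow(x$orfs), "\n")
  invisible(x)
}
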