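REP_MOTIF2_PATTERN <- "[VI]E.Q.RG[SL][PL]H.H"

translate_frame <- function(seq, frame_offset) {
  n <- nchar(seq)
  usable <- n - frame_offset
  usable <- usable - usable %% 3L
  if (usable < 3L) return("")
  sub <- substr(seq, frame_offset + 1L, frame_offset + usable)
  as.character(suppressWarnings(
    Biostrings::translate(Biostrings::DNAString(sub),
                          if.fuzzy.codon = "solve")))
}

#' Find open reading frames in all six frames
#'
#' An ORF is the longest stop-to-stop segment beginning at the first ATG
#' (set `require_atg = FALSE` for bare stop-to-stop segments).  Reported
#' nucleotide intervals are 0-based half-open on the forward strand and
#' cover the coding residues (the terminating stop codon is excluded).
#'
#' @param seq DNA string.
#' @param min_aa minimum ORF length in amino acids.
#' @param require_atg require the ORF to start at a methionine.
#' @return data frame with columns `frame` (1,2,3,-1,-2,-3), `strand`,
#'   `start`, `end`, `length_aa`, `aa_seq`, sorted by descending length.
#' @export
find_orfs <- function(seq, min_aa = 100L, require_atg = TRUE) {
  assert_dna(seq)
  n <- nchar(seq)
  rows <- list()
  scan_strand <- function(s, strand) {
    for (f in 0:2) {
      aa <- translate_frame(s, f)
      if (!nzchar(aa)) next
      # stop-to-stop segments as (aa start, aa end) 1-based inclusive
      stops <- c(0L, which(strsplit(aa, "")[[1]] == "*"), nchar(aa) + 1L)
      for (k in seq_len(length(stops) - 1L)) {
        seg_start <- stops[k] + 1L
        seg_end <- stops[k + 1L] - 1L
        if (seg_end < seg_start) next
        seg <- substr(aa, seg_start, seg_end)
        if (require_atg) {
          mpos <- regexpr("M", seg, fixed = TRUE)
          if (mpos == -1L) next
          seg_start <- seg_start + as.integer(mpos) - 1L
          seg <- substr(aa, seg_start, seg_end)
        }
        len <- nchar(seg)
        if (len < min_aa) next
        nuc_s <- f + (seg_start - 1L) * 3L      # 0-based on this strand
        nuc_e <- f + seg_end * 3L
        if (strand == "+") {
          start <- nuc_s; end <- nuc_e; frame <- f + 1L
        } else {
          start <- n - nuc_e; end <- n - nuc_s; frame <- -(f + 1L)
        }
        rows[[length(rows) + 1L]] <<- data.frame(
          frame = frame, strand = strand, start = start, end = end,
          length_aa = len, aa_seq = seg, stringsAsFactors = FALSE)
      }
    }
  }
  scan_strand(seq, "+")
  scan_strand(revcomp(seq), "-")
  if (!length(rows)) {
    return(data.frame(frame = integer(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      length_aa = integer(0), aa_seq = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$length_aa, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Locate the Rep motif-2 signature in a protein
#'
#' Matches the 12-position rolling-circle initiator block
#' `(V/I)ExQxRG(S/L)(P/L)HxH` (`x` = any residue).  The leftmost match is
#' returned; all matches are listed.
#'
#' @param protein amino-acid string.
#' @return `NULL` if absent, else a list with `start`, `end` (1-based
#'   inclusive protein coordinates), `matched`, `diag2` (the S/L residue
#'   between the G and the P/L) and `all_matches` (data frame).
#' @export
locate_rep_motif2 <- function(protein) {
  stopifnot(is.character(protein), length(protein) == 1L)
  protein <- toupper(protein)
  m <- gregexpr(REP_MOTIF2_PATTERN, protein, perl = TRUE)[[1]]
  if (m[1] == -1L) return(NULL)
  len <- attr(m, "match.length")
  matched <- substring(protein, m, m + len - 1L)
  all_matches <- data.frame(start = as.integer(m),
                            end = as.integer(m) + len - 1L,
                            matched = matched, stringsAsFactors = FALSE)
  list(start = all_matches$start[1], end = all_matches$end[1],
       matched = all_matches$matched[1],
       diag2 = substr(all_matches$matched[1], 8L, 8L),
       all_matches = all_matches)
}

#' Classify a Rep protein as Helentron-type or Helitron-type
#'
#' The residue between the conserved G and the P/L of motif 2 is the
#' primary diagnostic: S calls Helentron, L calls Helitron.  The
#' secondary three-residue diagnostic (F/Y, w/l/y/k, R) near the motif is
#' positionally ambiguous in the source data; it is checked only when
#' `diag1_offset` is supplied (residues at `motif start + diag1_offset`)
#' and is recorded as corroborating evidence, never overriding the
#' primary call.  No motif yields `indeterminate`.
#'
#' @param protein amino-acid string.
#' @param diag1_offset optional integer offset of the secondary
#'   diagnostic triplet relative to the motif start (disabled by default).
#' @return a `rep_motif_call` list: `classification`
#'   (`Helentron`/`Helitron`/`indeterminate`), `motif_span`, `matched`,
#'   `diag2_residue`, `diag1_residues`, `evidence`.
#' @export
classify_rep <- function(protein, diag1_offset = NULL) {
  hit <- locate_rep_motif2(protein)
  if (is.null(hit)) {
    out <- list(classification = "indeterminate", motif_span = NULL,
                matched = NA_character_, diag2_residue = NA_character_,
                diag1_residues = NA_character_, evidence = "no motif-2 match")
    class(out) <- "rep_motif_call"
    return(out)
  }
  diag2 <- hit$diag2
  cls <- if (diag2 == "S") "Helentron" else if (diag2 == "L") "Helitron"
         else "indeterminate"
  diag1 <- NA_character_
  ev <- sprintf("motif 2 at %d-%d", hit$start, hit$end)
  if (!is.null(diag1_offset)) {
    pos <- hit$start + as.integer(diag1_offset)
    diag1 <- toupper(substr(protein, pos, pos + 2L))
    ok <- grepl("^[FY][WLYK]R$", diag1)
    ev <- paste0(ev, "; diag1 '", diag1, "' ",
                 if (ok) "matches" else "does not match", " [FY][WLYK]R")
  }
  out <- list(classification = cls, motif_span = c(hit$start, hit$end),
              matched = hit$matched, diag2_residue = diag2,
              diag1_residues = diag1, evidence = ev)
  class(out) <- "rep_motif_call"
  out
}

#' Scan an element's coding capacity and Rep signature
#'
#' Runs [find_orfs()] and [classify_rep()] on every ORF translation.  The
#' element-level Rep call is the first determinate call in descending ORF
#' length order.  When no single ORF carries the motif, translations of
#' adjacent same-strand ORF pairs (gap <= `merge_gap` nt) are also
#' tested and, on a hit, flagged as a putative frameshift/stop-corrected
#' ORF rather than silently repaired.
#'
#' @param seq element DNA sequence.
#' @param min_aa_rep ORF length (aa) counted as a putative Rep/Helicase.
#' @param min_aa_accessory ORF length (aa) counted as an accessory ORF;
#'   an element with no ORF at this threshold is non-coding
#'   (HINE-compatible).
#' @param merge_gap maximum nucleotide gap for the merged-ORF check.
#' @return list with `orfs`, `rep_call`, `coding_summary`
#'   (`n_rep`, `n_accessory`, `putative_corrected`) and `non_coding`.
#' @export
scan_element_proteins <- function(seq, min_aa_rep = 300L,
                                  min_aa_accessory = 100L,
                                  merge_gap = 100L) {
  orfs <- find_orfs(seq, min_aa = min_aa_accessory)
  rep_call <- NULL
  corrected <- FALSE
  for (k in seq_len(nrow(orfs))) {
    cl <- classify_rep(orfs$aa_seq[k])
    if (cl$classification != "indeterminate") { rep_call <- cl; break }
  }
  if (is.null(rep_call) && nrow(orfs) >= 2L) {
    byp <- orfs[order(orfs$start), , drop = FALSE]
    for (ka in seq_len(nrow(byp) - 1L)) {
      for (kb in seq(ka + 1L, nrow(byp))) {
        a <- byp[ka, ]; b <- byp[kb, ]
        gap <- b$start - a$end
        if (a$strand != b$strand || gap > merge_gap || gap < -30L) next
        pair_aa <- if (a$strand == "+") c(a$aa_seq, b$aa_seq)
                   else c(b$aa_seq, a$aa_seq)
        cl <- classify_rep(paste0(pair_aa[1], pair_aa[2]))
        if (cl$classification != "indeterminate") {
          cl$evidence <- paste(cl$evidence, "(putative corrected ORF: merged",
                               "adjacent same-strand ORFs)")
          rep_call <- cl; corrected <- TRUE; break
        }
      }
      if (corrected) break
    }
  }
  if (is.null(rep_call)) {
    rep_call <- classify_rep("")   # indeterminate placeholder
  }
  list(orfs = orfs, rep_call = rep_call,
       coding_summary = list(n_rep = sum(orfs$length_aa >= min_aa_rep),
                             n_accessory = nrow(orfs),
                             putative_corrected = corrected),
       non_coding = nrow(orfs) == 0L)
}
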