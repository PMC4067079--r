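scan_candidates <- function(subject, profile, seeds = NULL) {
  lr <- profile$subtir_len_range
  if (!is.null(seeds)) {
    rows <- list()
    subj <- Biostrings::DNAString(subject)
    for (seed in unique(c(seeds, revcomp(seeds)))) {
      m <- Biostrings::matchPattern(Biostrings::DNAString(seed), subj,
                                    max.mismatch = profile$subtir_max_mismatch)
      if (!length(m)) next
      st <- IRanges::start(m) - 1L
      for (k in seq_along(st)) {
        hit <- as.character(m[[k]])
        mm <- sum(strsplit(hit, "")[[1]] != strsplit(seed, "")[[1]])
        rows[[length(rows) + 1L]] <- data.frame(
          start = st[k], end = st[k] + nchar(seed), mm = mm, seq = hit,
          stringsAsFactors = FALSE)
      }
    }
    if (!length(rows)) {
      return(data.frame(start = integer(0), end = integer(0), mm = integer(0),
                        seq = character(0), stringsAsFactors = FALSE))
    }
    out <- do.call(rbind, rows)
    out <- out[!duplicated(out[, c("start", "end")]), , drop = FALSE]
  } else {
    # allow the arm cap and span ceiling to exceed the profile by the
    # mismatch budget: chance-matched outer pairs can inflate a planted
    # stem beyond its designed span before trimming
    mm <- profile$subtir_max_mismatch
    h <- hairpins_multi(subject, min_arm = floor(lr[1] / 2),
                          max_arm = ceiling(lr[2] / 2) + mm,
                          min_loop = 0L, max_loop = 1L,
                          max_mismatch = mm)
    span <- 2L * h$arm_len + h$loop_len
    h <- h[span >= lr[1] & span <= lr[2] + 2L * mm, , drop = FALSE]
    out <- data.frame(start = h$offset,
                      end = h$offset + 2L * h$arm_len + h$loop_len,
                      mm = h$mismatches, seq = h$seq, stringsAsFactors = FALSE)
  }
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# evaluate candidate subTIR pairs on one strand; returns local-coordinate
# candidate calls (inclusive boundary convention, host T excluded)
eval_strand <- function(subject, profile, seeds = NULL) {
  n <- nchar(subject)
  sl <- profile$slack
  off5 <- profile$subtir5_offset_range
  off3 <- profile$subtir3_offset_range
  poff <- profile$palindrome3_offset_range
  plr <- profile$palindrome3_len_range
  empty_out <- data.frame(start = integer(0), end = integer(0),
                          score = numeric(0), subtir5_start = integer(0),
                          subtir5_end = integer(0), subtir = character(0),
                          pair_identity = numeric(0), stringsAsFactors = FALSE)
  cands <- scan_candidates(subject, profile, seeds)
  if (nrow(cands) < 2L) return(empty_out)
  min_span <- max(24L, profile$min_element_len - off5[2] - off3[2] - 10L)
  pairs <- pair_candidates_cpp(cands$start, cands$end, cands$mm,
                               cands$seq, revcomp(cands$seq),
                               min_span, profile$max_element_len,
                               profile$subtir_pair_min_identity,
                               profile$pair_mm_budget)
  if (nrow(pairs) == 0L) return(empty_out)
  pals <- hairpins_multi(subject, min_arm = max(3L, floor(plr[1] / 2)),
                           max_arm = ceiling(plr[2] / 2),
                           min_loop = 0L, max_loop = max(0L, plr[2] - 6L),
                           max_mismatch = profile$pal3_max_mismatch)
  pspan <- 2L * pals$arm_len + pals$loop_len
  pals <- pals[pspan >= plr[1] & pspan <= plr[2], , drop = FALSE]
  pal_start <- pals$offset
  pal_end <- pals$offset + 2L * pals$arm_len + pals$loop_len
  pal_q <- pals$arm_len - pals$mismatches
  pord <- order(pal_end)
  pal_start <- pal_start[pord]; pal_end <- pal_end[pord]; pal_q <- pal_q[pord]
  tts <- tt_positions(subject)

  # pair evaluation (palindrome + TT boundary windows, scoring) is the
  # hot path and runs in C++; see eval_pairs_cpp for the scoring notes
  df <- eval_pairs_cpp(subject,
                       cands$start, cands$end, cands$mm,
                       pairs$i, pairs$j, pairs$pair_identity,
                       pal_start, pal_end, pal_q, tts,
                       off5[1], off5[2], off3[1], off3[2],
                       poff[1], poff[2], sl,
                       profile$require_palindrome3,
                       profile$min_element_len, profile$max_element_len,
                       ceiling(profile$subtir_len_range[2] / 2),
                       ceiling(profile$palindrome3_len_range[2] / 2))
  if (nrow(df) == 0L) return(empty_out)
  df$subtir <- cands$seq[df$sub_idx]
  df$sub_idx <- NULL
  df
}

# Palindromic subTIRs read as hairpins on both strands, so a genuine
# call and its shifted opposite-strand "mirror" can score almost equally.
# Copies of one family share orientation-specific interior sequence, so
# the family majority decides: members whose head aligns to the
# reference better in reverse complement are re-derived on the other
# strand, exactly as a curator would orient copies against a consensus.
resolve_orientation <- function(all, genome, profile) {
  n_rows <- nrow(all)
  if (n_rows < 2L) return(all)
  seq_of <- function(k) {
    s <- substr0(genome[[all$seqid[k]]], all$start[k], all$end[k])
    if (all$strand[k] == "-") s <- revcomp(s)
    s
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  aln_score <- function(a, b) {
    Biostrings::score(Biostrings::pairwiseAlignment(
      a, b, type = "local", substitutionMatrix = mat,
      gapOpening = 2, gapExtension = 1))
  }
  # single-linkage subTIR clusters among accepted calls
  comp <- seq_len(n_rows)
  for (i in seq_len(n_rows - 1L)) {
    for (j in seq(i + 1L, n_rows)) {
      idd <- max(slide_identity_cpp(all$subtir[i], all$subtir[j]),
                 slide_identity_cpp(all$subtir[i], revcomp(all$subtir[j])))
      if (idd >= 0.85) comp[comp == comp[j]] <- comp[i]
    }
  }
  for (cl in unique(comp)) {
    idx <- which(comp == cl)
    if (length(idx) < 2L) next
    ref <- idx[which.max(all$score[idx])]
    ref_seq <- seq_of(ref)
    for (k in setdiff(idx, ref)) {
      h <- seq_of(k)
      if (aln_score(revcomp(h), ref_seq) < aln_score(h, ref_seq) + 5) next
      # mirror-flipped: re-derive the call on the opposite strand
      sid <- all$seqid[k]
      n_seq <- nchar(genome[[sid]])
      r_s <- max(0L, all$start[k] - 120L)
      r_e <- min(n_seq, all$end[k] + 120L)
      region <- substr0(genome[[sid]], r_s, r_e)
      new_strand <- if (all$strand[k] == "+") "-" else "+"
      subject <- if (new_strand == "+") region else revcomp(region)
      rows2 <- eval_strand(subject, profile)
      if (!nrow(rows2)) next
      if (new_strand == "+") {
        rows2$fs <- r_s + rows2$start; rows2$fe <- r_s + rows2$end
      } else {
        w <- nchar(region)
        rows2$fs <- r_s + (w - rows2$end); rows2$fe <- r_s + (w - rows2$start)
      }
      ov <- pmin(rows2$fe, all$end[k]) - pmax(rows2$fs, all$start[k])
      rows2 <- rows2[ov > 0.5 * (all$end[k] - all$start[k]), , drop = FALSE]
      if (!nrow(rows2)) next
      best <- rows2[which.max(rows2$score), , drop = FALSE]
      all$start[k] <- best$fs; all$end[k] <- best$fe
      all$strand[k] <- new_strand
      all$subtir[k] <- best$subtir
    }
  }
  all
}

# drop calls for which an (almost) equally scoring call shares one
# boundary but is substantially shorter: chimeric pairings of subTIRs
# from two neighbouring copies of a family lose to the parsimonious
# per-copy interpretation (neighbourhood lookups on sorted boundaries)
suppress_chimeras <- function(df, slack = 2.5, min_shorter = 100L) {
  n <- nrow(df)
  if (n < 2L) return(df)
  drop <- logical(n)
  key <- paste(df$seqid, df$strand)
  so <- order(df$start); eo <- order(df$end)
  s_sorted <- df$start[so]; e_sorted <- df$end[eo]
  for (k in seq_len(n)) {
    lo <- findInterval(df$start[k] - 4L, s_sorted) + 1L
    hi <- findInterval(df$start[k] + 3L, s_sorted)
    cand <- if (hi >= lo) so[lo:hi] else integer(0)
    lo2 <- findInterval(df$end[k] - 4L, e_sorted) + 1L
    hi2 <- findInterval(df$end[k] + 3L, e_sorted)
    cand2 <- if (hi2 >= lo2) eo[lo2:hi2] else integer(0)
    near <- unique(c(cand, cand2))
    near <- near[near != k & key[near] == key[k]]
    if (!length(near)) next
    hit <- (abs(df$start[near] - df$start[k]) <= 3L &
              df$end[near] <= df$end[k] - min_shorter) |
      (abs(df$end[near] - df$end[k]) <= 3L &
         df$start[near] >= df$start[k] + min_shorter)
    if (any(hit & df$score[near] >= df$score[k] - slack)) drop[k] <- TRUE
  }
  df[!drop, , drop = FALSE]
}

greedy_nonoverlap <- function(df) {
  df <- df[order(-df$score, df$seqid, df$start, df$strand), , drop = FALSE]
  keep <- logical(nrow(df))
  for (sid in unique(df$seqid)) {
    idx <- which(df$seqid == sid)
    keep[idx] <- as.logical(greedy_select_cpp(df$start[idx], df$end[idx]))
  }
  df[keep, , drop = FALSE]
}

# Second pass: copies whose subTIR diverged past the hairpin/pair
# thresholds are rescued by re-scanning with the subTIRs of the families
# discovered in pass one as seeds (relaxed cross-end identity, tighter
# span window around the family's typical length).  A rescue call
# replaces overlapping pass-one calls only when the family it is
# anchored to has more copy support than they do.
rescue_with_family_seeds <- function(all, genome, profile) {
  n_rows <- nrow(all)
  if (n_rows < 2L) return(all)
  comp <- seq_len(n_rows)
  for (i in seq_len(n_rows - 1L)) {
    for (j in seq(i + 1L, n_rows)) {
      idd <- max(slide_identity_cpp(all$subtir[i], all$subtir[j]),
                 slide_identity_cpp(all$subtir[i], revcomp(all$subtir[j])))
      if (idd >= 0.85) comp[comp == comp[j]] <- comp[i]
    }
  }
  fams <- list()
  for (cl in unique(comp)) {
    idx <- which(comp == cl)
    if (length(idx) < 2L) next
    fams[[length(fams) + 1L]] <- list(
      seed = all$subtir[idx[which.max(all$score[idx])]],
      size = length(idx),
      span = stats::median(all$end[idx] - all$start[idx]))
  }
  if (!length(fams)) return(all)
  seeds <- vapply(fams, `[[`, character(1), "seed")
  spans <- vapply(fams, `[[`, numeric(1), "span")
  sizes <- vapply(fams, `[[`, numeric(1), "size")
  rp <- profile
  rp$subtir_max_mismatch <- 3L
  rp$subtir_pair_min_identity <- 0.60
  # one heavily diverged subTIR is rescuable, two is indistinguishable
  # from chance seed matches
  rp$pair_mm_budget <- 5L
  rp$min_element_len <- as.integer(0.8 * min(spans))
  rp$max_element_len <- as.integer(1.25 * max(spans))
  rescue_rows <- list()
  for (sid in names(genome)) {
    n_seq <- nchar(genome[[sid]])
    for (strand in c("+", "-")) {
      subject <- if (strand == "+") genome[[sid]] else revcomp(genome[[sid]])
      df <- eval_strand(subject, rp, seeds = seeds)
      if (!nrow(df)) next
      if (strand == "+") {
        df$fstart <- df$start; df$fend <- df$end
      } else {
        df$fstart <- n_seq - df$end; df$fend <- n_seq - df$start
      }
      df$seqid <- sid; df$strand <- strand
      rescue_rows[[length(rescue_rows) + 1L]] <- df
    }
  }
  if (!length(rescue_rows)) return(all)
  res <- do.call(rbind, rescue_rows)
  # assign each rescue row to its best-matching family and require the
  # family's typical span
  fam_of <- vapply(seq_len(nrow(res)), function(k) {
    ids <- vapply(seeds, function(sd)
      max(slide_identity_cpp(res$subtir[k], sd),
          slide_identity_cpp(res$subtir[k], revcomp(sd))), numeric(1))
    which.max(ids)
  }, integer(1))
  span_ok <- abs((res$fend - res$fstart) - spans[fam_of]) <=
    pmax(20, 0.15 * spans[fam_of])
  res <- res[span_ok, , drop = FALSE]
  fam_of <- fam_of[span_ok]
  res$fam_size <- sizes[fam_of]
  res$start <- res$fstart; res$end <- res$fend
  res <- res[order(-res$score), , drop = FALSE]
  res <- res[!duplicated(res[, c("seqid", "strand", "start", "end")]), ,
             drop = FALSE]
  keep_res <- rep(TRUE, nrow(res))
  for (k in seq_len(nrow(res))) {
    ov <- which(all$seqid == res$seqid[k] &
                  all$start < res$end[k] & all$end > res$start[k])
    if (!length(ov)) next
    same_fam <- vapply(ov, function(o)
      max(slide_identity_cpp(all$subtir[o], res$subtir[k]),
          slide_identity_cpp(all$subtir[o], revcomp(res$subtir[k]))) >= 0.85,
      logical(1))
    if (any(same_fam)) { keep_res[k] <- FALSE; next }
    if (all(all$support[ov] < res$fam_size[k])) {
      all <- all[-ov, , drop = FALSE]
    } else {
      keep_res[k] <- FALSE
    }
  }
  res <- res[keep_res, , drop = FALSE]
  if (nrow(res)) {
    # rescue rows may overlap each other; resolve greedily
    res <- greedy_nonoverlap(res)
    res$support <- res$fam_size
    common <- intersect(names(all), names(res))
    all <- rbind(all[, common, drop = FALSE], res[, common, drop = FALSE])
  }
  all
}

#' Scan a genome for subTIR/stem-loop element architectures
#'
#' Hairpin candidates matching the profile's subTIR windows are paired
#' within the element length bounds (subTIR identity, mismatch budget),
#' anchored by the 3' palindrome and the terminal TT boundary signals,
#' scored, and resolved greedily into non-overlapping calls; both strands
#' are scanned and each accepted call is re-annotated with
#' [annotate_element()].  Boundary convention: terminal T runs belong to
#' the element, the host TT target contributes one T per side.  With
#' `profile$min_subtir_copies > 1`, calls whose subTIR does not recur in
#' that many calls genome-wide are dropped (interspersed-repeat
#' evidence).  Output order is deterministic (seqid, then start).
#'
#' @param genome named character vector of sequences (see [read_fasta()]).
#' @param profile a [structure_profile()]; use
#'   `hine_mo_profile("genomic")` for divergent genomic copies.
#' @param seeds optional character vector of known subTIR sequences used
#'   to seed candidates instead of the exhaustive hairpin search.
#' @param check_coding run the ORF/Rep scan on each call.
#' @return list of `element_annotation` objects with per-call scan
#'   metadata in `$scan`.
#' @export
scan_genome <- function(genome, profile = hine_mo_profile("genomic"),
                        seeds = NULL, check_coding = TRUE) {
  if (length(genome) == 0L) stop("empty genome", call. = FALSE)
  if (is.null(names(genome))) names(genome) <- paste0("seq", seq_along(genome))
  calls <- list()
  for (sid in names(genome)) {
    seq <- genome[[sid]]
    n <- nchar(seq)
    for (strand in c("+", "-")) {
      subject <- if (strand == "+") seq else revcomp(seq)
      df <- eval_strand(subject, profile, seeds)
      if (!nrow(df)) next
      if (strand == "+") {
        df$fstart <- df$start; df$fend <- df$end
      } else {
        df$fstart <- n - df$end; df$fend <- n - df$start
      }
      df$seqid <- sid; df$strand <- strand
      calls[[length(calls) + 1L]] <- df
    }
  }
  if (!length(calls)) return(list())
  all <- do.call(rbind, calls)
  all$start <- all$fstart; all$end <- all$fend
  # collapse duplicate intervals (several candidate pairs can imply the
  # same boundaries), keeping the best-scoring interpretation
  all <- all[order(-all$score), , drop = FALSE]
  all <- all[!duplicated(all[, c("seqid", "strand", "start", "end")]), ,
             drop = FALSE]
  # family-level length support: genuine copies of one element recur at
  # a consistent span, chimeric cross-copy pairings do not
  support <- length_support_cpp(all$subtir, revcomp(all$subtir),
                                all$start, all$end,
                                match(all$seqid, unique(all$seqid)), 0.85)
  all$score <- all$score + 2 * pmin(support - 1L, 2L)
  all$support <- support
  drop <- contained_chimera_cpp(all$start, all$end, all$score,
                                all$subtir, revcomp(all$subtir),
                                match(all$seqid, unique(all$seqid)),
                                0.85, 3.0, 100L)
  all <- all[!drop, , drop = FALSE]
  all <- suppress_chimeras(all)
  all <- greedy_nonoverlap(all)
  if (profile$min_subtir_copies > 1L && nrow(all) > 0L) {
    # interspersed-repeat evidence: the subTIR must recur at a similar
    # span in at least min_subtir_copies disjoint calls
    all <- all[all$support >= profile$min_subtir_copies, , drop = FALSE]
  }
  if (!nrow(all)) return(list())
  all <- resolve_orientation(all, genome, profile)
  if (is.null(seeds) && profile$min_subtir_copies > 1L) {
    all <- rescue_with_family_seeds(all, genome, profile)
  }
  all <- all[order(all$seqid, all$start), , drop = FALSE]
  out <- vector("list", nrow(all))
  for (k in seq_len(nrow(all))) {
    sid <- all$seqid[k]; fs <- all$start[k]; fe <- all$end[k]
    strand <- all$strand[k]
    eseq <- substr0(genome[[sid]], fs, fe)
    if (strand == "-") eseq <- revcomp(eseq)
    id <- sprintf("%s_%d_%d%s", sid, fs, fe, ifelse(strand == "+", "", "_rc"))
    ann <- annotate_element(eseq, profile, id = id, seqid = sid,
                            offset = 0L, strand = strand,
                            check_coding = check_coding)
    # map features from element-local to forward genome coordinates
    remap <- function(f) {
      if (is.null(f)) return(NULL)
      if (strand == "+") { f$start <- f$start + fs; f$end <- f$end + fs }
      else { tmp <- f$start; f$start <- fe - f$end; f$end <- fe - tmp }
      f
    }
    for (nm in c("subtir5", "subtir3", "palindrome3", "palindrome5",
                 "ir", "microsat")) ann[[nm]] <- remap(ann[[nm]])
    if (!is.null(ann$orfs) && nrow(ann$orfs)) {
      if (strand == "+") {
        ann$orfs$start <- ann$orfs$start + fs
        ann$orfs$end <- ann$orfs$end + fs
      } else {
        tmp <- ann$orfs$start
        ann$orfs$start <- fe - ann$orfs$end
        ann$orfs$end <- fe - tmp
        ann$orfs$strand <- ifelse(ann$orfs$strand == "+", "-", "+")
      }
    }
    ann$element <- ginterval(sid, fs, fe, strand)
    ann$score <- all$score[k]
    ann$scan <- list(score = all$score[k], subtir = all$subtir[k],
                     pair_identity = all$pair_identity[k])
    out[[k]] <- ann
  }
  out
}
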