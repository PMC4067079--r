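#' Empty-site search parameters
#'
#' A paralogous empty site is a locus matching the chimeric
#' upstream+downstream flank query with at least `min_identity` identity
#' over at least `min_coverage` of the query.
#'
#' @param flank bp of flanking sequence on each side of the element.
#' @param min_identity minimum alignment identity (gap columns count as
#'   errors).
#' @param min_coverage minimum aligned-query-span / query-length.
#' @return an `empty_site_params` list.
#' @export
empty_site_params <- function(flank = 50L, min_identity = 0.90,
                              min_coverage = 0.90) {
  if (flank < 20L) stop("flank must be >= 20 bp", call. = FALSE)
  stopifnot(min_identity > 0, min_identity <= 1,
            min_coverage > 0, min_coverage <= 1)
  out <- list(flank = as.integer(flank), min_identity = min_identity,
              min_coverage = min_coverage)
  class(out) <- "empty_site_params"
  out
}

get_seq <- function(genome, seqid) {
  if (is.character(genome) && length(genome) == 1L && is.null(names(genome))) {
    return(genome)
  }
  s <- genome[[seqid]]
  if (is.null(s)) stop("sequence not found in genome: ", seqid, call. = FALSE)
  s
}

#' Build the chimeric empty-site query for an element
#'
#' Concatenates `flank` bp upstream and `flank` bp downstream of the
#' element; a perfect match elsewhere in the genome is a pre-insertion
#' (empty) paralogous site.  The junction between the two flanks sits at
#' offset `flank` (attribute `junction_offset`).
#'
#' @param genome named character vector of sequences (or one sequence).
#' @param element one-row [ginterval()] locating the element.
#' @param flank bp of flank on each side.
#' @return the chimeric query string with attribute `junction_offset`.
#' @export
build_chimeric_query <- function(genome, element, flank = 50L) {
  seq <- get_seq(genome, element$seqid[1])
  s <- element$start[1]; e <- element$end[1]; n <- nchar(seq)
  if (s - flank < 0L || e + flank > n) {
    stop("insufficient flank: element within ", flank,
         " bp of a contig edge", call. = FALSE)
  }
  q <- paste0(substr0(seq, s - flank, s), substr0(seq, e, e + flank))
  attr(q, "junction_offset") <- as.integer(flank)
  q
}

local_alignment_stats <- function(query, subject) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(query, subject, type = "local",
                                       substitutionMatrix = mat,
                                       gapOpening = 2, gapExtension = 1)
  pat <- Biostrings::pattern(aln); sub <- Biostrings::subject(aln)
  pa <- strsplit(as.character(pat), "")[[1]]
  sa <- strsplit(as.character(sub), "")[[1]]
  matches <- sum(pa == sa & pa != "-")
  cols <- length(pa)
  # subject offset of the column aligned to the last base of the first
  # query flank (junction mapping)
  list(score = Biostrings::score(aln), matches = matches, cols = cols,
       q_start = IRanges::start(pat) - 1L, q_end = IRanges::end(pat),
       s_start = IRanges::start(sub) - 1L, s_end = IRanges::end(sub),
       pattern = pa, subject_aln = sa)
}

cluster_positions <- function(pos, gap) {
  if (!length(pos)) return(list())
  pos <- sort(pos)
  breaks <- c(0L, which(diff(pos) > gap), length(pos))
  lapply(seq_len(length(breaks) - 1L), function(k)
    pos[(breaks[k] + 1L):breaks[k + 1L]])
}

#' Find paralogous empty sites for a chimeric flank query
#'
#' Seed-and-extend search of the query against both strands of the
#' genome: exact 8-mer seeds are clustered and each cluster window is
#' realigned locally (match +1, mismatch -1, gap open -2, gap extend -1).
#' Hits are kept when identity (matches / alignment columns) reaches
#' `min_identity` and the aligned query span reaches
#' `min_coverage * nchar(query)`.  The insertion locus itself and any
#' `mask` intervals (e.g. other annotated copies of the same family) are
#' excluded.  Hits are sorted by descending identity.
#'
#' @param query chimeric query from [build_chimeric_query()].
#' @param genome named character vector of sequences.
#' @param params an [empty_site_params()].
#' @param insertion optional [ginterval()] of the insertion locus to mask.
#' @param mask optional data frame of intervals (`seqid`, `start`, `end`)
#'   to exclude.
#' @return data frame (`seqid`, `start`, `end`, `strand`, `identity`,
#'   `coverage`, `score`, `junction_offset`), 0-based half-open forward
#'   coordinates.
#' @export
find_empty_sites <- function(query, genome, params = empty_site_params(),
                             insertion = NULL, mask = NULL) {
  qlen <- nchar(query)
  hits <- list()
  if (is.null(names(genome))) names(genome) <- paste0("seq", seq_along(genome))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  flank <- attr(query, "junction_offset") %||% (qlen %/% 2L)
  for (seqid in names(genome)) {
    n <- nchar(genome[[seqid]])
    for (strand in c("+", "-")) {
      subject <- if (strand == "+") genome[[seqid]] else revcomp(genome[[seqid]])
      # 9-mer exact seeds: any hit at >=90% identity over >=90% of the
      # query contains an exact run of at least 9 bases (pigeonhole)
      seeds <- kmer_seed_positions_cpp(query, subject, 9L)
      clusters <- cluster_positions(seeds, qlen)
      if (!length(clusters)) next
      w_start <- vapply(clusters, function(cl) max(0L, min(cl) - qlen - 20L),
                        integer(1))
      w_end <- vapply(clusters, function(cl)
        min(n, max(cl) + 9L + qlen + 20L), integer(1))
      windows <- substring(subject, w_start + 1L, w_end)
      # one vectorised alignment call over all cluster windows
      alns <- Biostrings::pairwiseAlignment(
        Biostrings::DNAStringSet(rep(query, length(windows))),
        Biostrings::DNAStringSet(windows),
        type = "local", substitutionMatrix = mat,
        gapOpening = 2, gapExtension = 1)
      pat <- Biostrings::pattern(alns); sub <- Biostrings::subject(alns)
      pa_all <- as.character(pat); sa_all <- as.character(sub)
      q_start <- IRanges::start(pat) - 1L; q_end <- IRanges::end(pat)
      s_start <- IRanges::start(sub) - 1L; s_end <- IRanges::end(sub)
      scores <- Biostrings::score(alns)
      for (w in seq_along(windows)) {
        pa <- strsplit(pa_all[w], "")[[1]]
        sa <- strsplit(sa_all[w], "")[[1]]
        matches <- sum(pa == sa & pa != "-")
        cols <- length(pa)
        identity <- if (cols > 0L) matches / cols else 0
        coverage <- (q_end[w] - q_start[w]) / qlen
        if (identity < params$min_identity || coverage < params$min_coverage) next
        s0 <- w_start[w] + s_start[w]; e0 <- w_start[w] + s_end[w]
        # junction: subject bases consumed up to the query flank boundary
        qi <- q_start[w]; si <- 0L
        for (k in seq_along(pa)) {
          if (qi >= flank) break
          if (pa[k] != "-") qi <- qi + 1L
          if (sa[k] != "-") si <- si + 1L
        }
        if (strand == "+") {
          fs <- s0; fe <- e0; junction <- si
        } else {
          fs <- n - e0; fe <- n - s0; junction <- (e0 - s0) - si
        }
        hits[[length(hits) + 1L]] <- data.frame(
          seqid = seqid, start = fs, end = fe, strand = strand,
          identity = identity, coverage = coverage, score = scores[w],
          junction_offset = junction, stringsAsFactors = FALSE)
      }
    }
  }
  empty <- data.frame(seqid = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      identity = numeric(0), coverage = numeric(0),
                      score = numeric(0), junction_offset = integer(0),
                      stringsAsFactors = FALSE)
  if (!length(hits)) return(empty)
  out <- do.call(rbind, hits)
  out <- out[!duplicated(out[, c("seqid", "start", "end", "strand")]), , drop = FALSE]
  overlaps <- function(df, iv) {
    df$seqid == iv$seqid[1] & df$start < iv$end[1] & df$end > iv$start[1]
  }
  if (!is.null(insertion)) out <- out[!overlaps(out, insertion), , drop = FALSE]
  if (!is.null(mask) && nrow(mask)) {
    for (k in seq_len(nrow(mask))) {
      out <- out[!overlaps(out, mask[k, , drop = FALSE]), , drop = FALSE]
    }
  }
  out <- out[order(-out$identity, out$seqid, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("empty_site_hits", "data.frame")
  out
}

#' Target-site report for one insertion
#'
#' Measures the contiguous T runs immediately inside the element
#' boundaries (on the element strand), tests whether the reconstructed
#' pre-insertion site carries a TT spanning the junction, scans for a
#' target-site duplication (identical k-mers immediately flanking both
#' ends, k in `min_tsd..max_tsd`), and reports the Helitron-style A|T
#' junction.  When an empty-site hit is supplied, a TSD candidate is
#' validated against the pre-insertion locus: the candidate is a real
#' duplication only if removing one copy reconstructs the empty site
#' better than the plain flank concatenation does — coincidental flanking
#' repeats that pre-date the insertion are thereby rejected, which is how
#' the absence of target-site modification is established.
#'
#' @param genome named character vector of sequences.
#' @param element one-row [ginterval()] (boundary convention: terminal T
#'   runs belong to the element).
#' @param empty optional one-row empty-site hit from [find_empty_sites()].
#' @param max_tsd,min_tsd TSD scan range in bp.
#' @return a `target_site_report` list: `left_t_run`, `right_t_run`,
#'   `tt_at_insertion`, `tsd` (`NA` if none), `tsd_validated`,
#'   `at_insertion`.
#' @export
analyze_target_site <- function(genome, element, empty = NULL,
                                max_tsd = 20L, min_tsd = 2L) {
  seq <- get_seq(genome, element$seqid[1])
  n <- nchar(seq)
  if (element$strand[1] == "-") {
    seq <- revcomp(seq)
    s <- n - element$end[1]; e <- n - element$start[1]
  } else {
    s <- element$start[1]; e <- element$end[1]
  }
  left_run <- t_run_at(seq, s)
  right_run <- t_run_before(seq, e)
  lf <- substr0(seq, max(0L, s - 60L), s)       # host flank, element strand
  rf <- substr0(seq, e, min(n, e + 60L))
  tt <- nchar(lf) >= 1L && nchar(rf) >= 1L &&
    substr(lf, nchar(lf), nchar(lf)) == "T" && substr(rf, 1L, 1L) == "T"
  at <- nchar(lf) >= 1L && nchar(rf) >= 1L &&
    substr(lf, nchar(lf), nchar(lf)) == "A" && substr(rf, 1L, 1L) == "T"

  empty_seq <- NULL
  if (!is.null(empty) && nrow(empty) >= 1L) {
    es <- get_seq(genome, empty$seqid[1])
    empty_seq <- substr0(es, empty$start[1], empty$end[1])
    if (empty$strand[1] == "-") empty_seq <- revcomp(empty_seq)
  }
  tsd <- NA_character_
  validated <- NA
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  aln_score <- function(a, b) {
    Biostrings::score(Biostrings::pairwiseAlignment(
      a, b, type = "local", substitutionMatrix = mat,
      gapOpening = 2, gapExtension = 1))
  }
  k_hi <- min(max_tsd, nchar(lf), nchar(rf))
  for (k in (if (k_hi >= min_tsd) seq(k_hi, min_tsd) else integer(0))) {
    lk <- substr(lf, nchar(lf) - k + 1L, nchar(lf))
    rk <- substr(rf, 1L, k)
    if (lk != rk || grepl("N", lk, fixed = TRUE)) next
    if (is.null(empty_seq)) { tsd <- lk; validated <- FALSE; break }
    plain <- paste0(lf, rf)
    dedup <- paste0(lf, substr(rf, k + 1L, nchar(rf)))
    if (aln_score(dedup, empty_seq) > aln_score(plain, empty_seq)) {
      tsd <- lk; validated <- TRUE; break
    }
    # candidate repeat pre-dates the insertion: not a TSD; stop scanning
    break
  }
  out <- list(left_t_run = left_run, right_t_run = right_run,
              tt_at_insertion = tt, tsd = tsd, tsd_validated = validated,
              at_insertion = at)
  class(out) <- "target_site_report"
  out
}

#' Canonicalize element boundaries with respect to terminal T runs
#'
#' The boundary T nucleotides of these elements cannot be attributed
#' unambiguously to element or host, so two conventions are supported:
#' `inclusive` assigns all contiguous boundary Ts of the report to the
#' element, `exclusive` assigns them to the host.  A `split` policy is
#' deliberately unsupported (the attribution is genuinely ambiguous).
#'
#' @param element one-row [ginterval()].
#' @param report a `target_site_report` for the element.
#' @param policy `"inclusive"` (default) or `"exclusive"`; `"split"`
#'   raises an error.
#' @param current the convention `element` is currently expressed in.
#' @return the re-canonicalized interval.
#' @export
canonicalize_boundaries <- function(element, report,
                                    policy = c("inclusive", "exclusive", "split"),
                                    current = c("inclusive", "exclusive")) {
  policy <- match.arg(policy)
  current <- match.arg(current)
  if (policy == "split") {
    stop("policy 'split' is unsupported: the distribution of boundary Ts ",
         "between element and host is genuinely ambiguous", call. = FALSE)
  }
  if (policy == current) return(element)
  l <- report$left_t_run; r <- report$right_t_run
  sgn <- if (policy == "inclusive") -1L else 1L   # inclusive grows the interval
  out <- element
  if (out$strand[1] == "+") {
    out$start <- out$start + sgn * l
    out$end <- out$end - sgn * r
  } else {
    out$start <- out$start + sgn * r
    out$end <- out$end - sgn * l
  }
  out
}
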