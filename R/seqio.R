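#' Genomic intervals
#'
#' All coordinates inside the package are 0-based half-open
#' (`start` inclusive, `end` exclusive); conversion to the 1-based
#' inclusive GFF3 convention happens only at serialization.
#'
#' @param seqid sequence identifier(s).
#' @param start 0-based inclusive start offset(s).
#' @param end 0-based exclusive end offset(s).
#' @param strand `"+"` or `"-"`.
#' @return a `genomic_interval` data frame.
#' @export
ginterval <- function(seqid, start, end, strand = "+") {
  start <- as.integer(start); end <- as.integer(end)
  if (any(start < 0L) || any(end <= start)) {
    stop("invalid interval: need 0 <= start < end", call. = FALSE)
  }
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'", call. = FALSE)
  out <- data.frame(seqid = as.character(seqid), start = start, end = end,
                    strand = strand, stringsAsFactors = FALSE)
  class(out) <- c("genomic_interval", "data.frame")
  out
}

validate_interval <- function(iv, seqlens) {
  if (is.null(seqlens)) return(invisible(TRUE))
  for (k in seq_len(nrow(iv))) {
    len <- seqlens[[iv$seqid[k]]]
    if (is.null(len) || is.na(len)) {
      stop("interval on unknown sequence: ", iv$seqid[k], call. = FALSE)
    }
    if (iv$end[k] > len) {
      stop(sprintf("interval %s:%d-%d outside sequence bounds (length %d)",
                   iv$seqid[k], iv$start[k], iv$end[k], len), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Read a FASTA file into a normalized sequence set
#'
#' Sequences are uppercased on ingest.  For DNA, `U` is converted to `T`
#' and IUPAC ambiguity codes other than `N` are mapped to `N` with a
#' warning.  Empty sequences and residues outside the alphabet are
#' rejected.
#'
#' @param path path to a FASTA file.
#' @param alphabet `"dna"` or `"protein"`.
#' @return a named character vector of sequences (names are the first
#'   whitespace-delimited token of each header) with attribute
#'   `alphabet`, class `seq_set`.
#' @export
read_fasta <- function(path, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  first_content <- which(nzchar(trimws(lines)))[1]
  if (is.na(first_content) || !startsWith(trimws(lines[first_content]), ">")) {
    stop(sprintf("malformed FASTA %s: no header at line %d",
                 path, if (is.na(first_content)) 1L else first_content),
         call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs))) {
    stop("empty sequence in record: ", ids[!nzchar(seqs)][1], call. = FALSE)
  }
  if (alphabet == "dna") {
    seqs <- chartr("U", "T", seqs)
    ambig <- grepl("[RYSWKMBDHV]", seqs)
    if (any(ambig)) {
      warning(sprintf("mapped IUPAC ambiguity codes to N in %d record(s): %s",
                      sum(ambig), paste(ids[ambig], collapse = ", ")),
              call. = FALSE)
      seqs <- gsub("[RYSWKMBDHV]", "N", seqs)
    }
    bad <- grepl("[^ACGTN]", seqs)
    if (any(bad)) {
      stop("illegal residue in DNA record: ", ids[bad][1], call. = FALSE)
    }
  } else {
    bad <- grepl("[^A-Z*]", seqs)
    if (any(bad)) {
      stop("illegal residue in protein record: ", ids[bad][1], call. = FALSE)
    }
  }
  names(seqs) <- ids
  attr(seqs, "alphabet") <- alphabet
  class(seqs) <- c("seq_set", class(seqs))
  seqs
}

#' Write sequences to FASTA
#'
#' @param x named character vector of sequences.
#' @param path output path.
#' @param width line wrap width.
#' @return invisibly, `path`.
#' @export
write_fasta <- function(x, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(x)) {
    writeLines(paste0(">", names(x)[i]), con)
    s <- x[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

annotation_rows <- function(annotations) {
  rows <- list()
  for (ann in annotations) {
    iv <- ann$element
    eid <- ann$id
    rows[[length(rows) + 1L]] <- data.frame(
      seqid = iv$seqid, start = iv$start, end = iv$end, strand = iv$strand,
      type = "element", id = eid, parent = NA_character_,
      structure_type = ann$structure_type, score = ann$score %||% NA_real_,
      stringsAsFactors = FALSE)
    sub <- function(feat, type) {
      if (is.null(feat)) return(NULL)
      data.frame(seqid = iv$seqid, start = feat$start, end = feat$end,
                 strand = iv$strand, type = type,
                 id = paste0(eid, ":", type), parent = eid,
                 structure_type = NA_character_, score = NA_real_,
                 stringsAsFactors = FALSE)
    }
    rows <- c(rows, Filter(Negate(is.null), list(
      sub(ann$subtir5, "subTIR_5p"), sub(ann$subtir3, "subTIR_3p"),
      sub(ann$palindrome3, "palindrome_3p"), sub(ann$ir, "IR"),
      sub(ann$microsat, "microsat"))))
    if (!is.null(ann$orfs) && nrow(ann$orfs) > 0L) {
      for (k in seq_len(nrow(ann$orfs))) {
        rows[[length(rows) + 1L]] <- data.frame(
          seqid = iv$seqid, start = ann$orfs$start[k], end = ann$orfs$end[k],
          strand = ann$orfs$strand[k], type = "ORF",
          id = paste0(eid, ":ORF", k), parent = eid,
          structure_type = NA_character_, score = NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(seqid = character(0), start = integer(0), end = integer(0),
                      strand = character(0), type = character(0), id = character(0),
                      parent = character(0), structure_type = character(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Write element annotations to GFF3, BED or TSV
#'
#' GFF3 output is 1-based inclusive; BED output is 0-based half-open.
#' Subfeatures (`subTIR_5p`, `subTIR_3p`, `palindrome_3p`, `IR`, `ORF`)
#' carry a `Parent` attribute pointing at their element row.
#'
#' @param annotations list of `element_annotation` objects.
#' @param path output file.
#' @param format one of `"gff3"`, `"bed"`, `"tsv"`.
#' @param source source tag for the GFF3 column 2.
#' @param seqlens optional named vector of sequence lengths; if given,
#'   intervals outside bounds raise an error.
#' @return invisibly, `path`.
#' @export
write_annotations <- function(annotations, path,
                              format = c("gff3", "bed", "tsv"),
                              source = "helentronscan", seqlens = NULL) {
  format <- match.arg(format)
  tab <- annotation_rows(annotations)
  if (nrow(tab) > 0L && !is.null(seqlens)) {
    validate_interval(ginterval(tab$seqid, tab$start, tab$end, tab$strand), seqlens)
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "gff3") {
    writeLines("##gff-version 3", con)
    if (nrow(tab)) {
      attrs <- ifelse(is.na(tab$parent),
                      paste0("ID=", tab$id,
                             ifelse(is.na(tab$structure_type), "",
                                    paste0(";structure_type=", tab$structure_type))),
                      paste0("ID=", tab$id, ";Parent=", tab$parent))
      writeLines(paste(tab$seqid, source, tab$type,
                       tab$start + 1L, tab$end,
                       ifelse(is.na(tab$score), ".", format(tab$score, digits = 4)),
                       tab$strand, ".", attrs, sep = "\t"), con)
    }
  } else if (format == "bed") {
    writeLines(paste0("track name=", source), con)
    if (nrow(tab)) {
      sc <- ifelse(is.na(tab$score), 0, pmin(1000, round(tab$score * 10)))
      writeLines(paste(tab$seqid, tab$start, tab$end, tab$id, sc, tab$strand,
                       sep = "\t"), con)
    }
  } else {
    utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
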