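#' Classification parameters
#'
#' Families are defined by shared subTIR identity (longest common
#' substring of at least `family_min_shared_subtir` bp, best orientation),
#' subfamilies by at least `subfamily_min_identity` global-alignment
#' identity over the last `subfamily_window` bp of the 3' end (which
#' covers the 3' subTIR and stem-loop).
#'
#' @param family_min_shared_subtir bp of identical subTIR sequence
#'   required for family co-membership.
#' @param subfamily_min_identity minimum 3'-end identity fraction.
#' @param subfamily_window bp of 3'-terminal sequence compared.
#' @param gap_inclusive whether gap columns count in the identity
#'   denominator (the conservative default).
#' @return a `classification_params` list.
#' @export
classification_params <- function(family_min_shared_subtir = 11L,
                                  subfamily_min_identity = 0.80,
                                  subfamily_window = 60L,
                                  gap_inclusive = TRUE) {
  stopifnot(subfamily_min_identity > 0, subfamily_min_identity <= 1,
            subfamily_window >= 15L)
  out <- list(family_min_shared_subtir = as.integer(family_min_shared_subtir),
              subfamily_min_identity = subfamily_min_identity,
              subfamily_window = as.integer(subfamily_window),
              gap_inclusive = isTRUE(gap_inclusive))
  class(out) <- "classification_params"
  out
}

# longest common substring length (dynamic programme over suffix matches)
lcs_length <- function(a, b) {
  na <- nchar(a); nb <- nchar(b)
  if (na == 0L || nb == 0L) return(0L)
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  prev <- integer(nb); best <- 0L
  for (i in seq_len(na)) {
    cur <- integer(nb)
    hit <- which(y == x[i])
    for (j in hit) cur[j] <- (if (j > 1L) prev[j - 1L] else 0L) + 1L
    best <- max(best, if (length(hit)) max(cur[hit]) else 0L)
    prev <- cur
  }
  best
}

#' Longest identical subTIR stretch between two elements
#'
#' Length of the longest common substring of the two subTIRs, computed
#' over both orientations (the maximum of the forward and the
#' reverse-complement comparison), since subTIRs are palindromic in some
#' families but not all.
#'
#' @param a,b subTIR strings.
#' @return shared length in bp.
#' @export
shared_subtir_length <- function(a, b) {
  stopifnot(nzchar(a), nzchar(b))
  max(lcs_length(a, b), lcs_length(a, revcomp(b)))
}

uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}
uf_union <- function(parent, i, j) {
  ri <- uf_find(parent, i); rj <- uf_find(parent, j)
  if (ri != rj) parent[ri] <- rj
  parent
}

single_linkage <- function(n, edges) {
  parent <- uf_new(n)
  if (nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      parent <- uf_union(parent, edges$i[k], edges$j[k])
    }
  }
  vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
}

#' Partition elements into families by shared subTIRs
#'
#' Single-linkage closure over the relation "shared subTIR length >=
#' threshold" (the relation is not transitive, so the closure is the
#' weakest consistent reading and is reported as such).  Family numbers
#' are assigned by descending family size, ties broken by the
#' lexicographically smallest subTIR in the family, making the partition
#' invariant under input reordering.
#'
#' @param subtirs named list; each entry is the character vector of an
#'   element's detected subTIR sequences (5' and/or 3').  Elements with
#'   no subTIR are excluded and reported in the `excluded` attribute.
#' @param params a [classification_params()].
#' @return data frame (`element_id`, `family`) with attribute `excluded`.
#' @export
assign_families <- function(subtirs, params = classification_params()) {
  ids <- names(subtirs)
  if (is.null(ids)) stop("subtirs must be a named list", call. = FALSE)
  keep <- vapply(subtirs, function(x) length(x) > 0L && any(nzchar(x)),
                 logical(1))
  excluded <- ids[!keep]
  ids <- ids[keep]; subtirs <- subtirs[keep]
  # canonical processing order, so the partition is permutation-invariant
  ord <- order(ids)
  ids <- ids[ord]; subtirs <- subtirs[ord]
  n <- length(ids)
  ei <- integer(0); ej <- integer(0)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        shared <- max(outer(subtirs[[i]], subtirs[[j]],
                            Vectorize(shared_subtir_length)))
        if (shared >= params$family_min_shared_subtir) {
          ei <- c(ei, i); ej <- c(ej, j)
        }
      }
    }
  }
  comp <- single_linkage(n, data.frame(i = ei, j = ej))
  groups <- split(seq_len(n), comp)
  size <- vapply(groups, length, integer(1))
  min_subtir <- vapply(groups, function(g)
    min(unlist(subtirs[g])), character(1))
  ord_fam <- order(-size, min_subtir)
  fam_of_group <- integer(length(groups))
  fam_of_group[ord_fam] <- seq_along(groups)
  fam <- fam_of_group[match(comp, as.integer(names(groups)))]
  out <- data.frame(element_id = ids, family = fam, stringsAsFactors = FALSE)
  attr(out, "excluded") <- excluded
  out
}

nw_align_strings <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                       substitutionMatrix = mat,
                                       gapOpening = 2, gapExtension = 1)
  list(a = as.character(Biostrings::pattern(aln)),
       b = as.character(Biostrings::subject(aln)),
       score = Biostrings::score(aln))
}

alignment_identity <- function(a_aln, b_aln, gap_inclusive = TRUE) {
  x <- strsplit(a_aln, "")[[1]]; y <- strsplit(b_aln, "")[[1]]
  matches <- sum(x == y & x != "-")
  cols <- if (gap_inclusive) length(x) else sum(x != "-" & y != "-")
  matches / cols
}

#' 3'-terminal identity between two elements
#'
#' Global alignment (match +1, mismatch -1, gap open -2, gap extend -1)
#' of the last `window` bases of each sequence; identity is
#' matches / alignment columns, with gap columns counting against
#' identity unless `gap_inclusive = FALSE`.
#'
#' @param a,b DNA strings, each at least `window` long.
#' @param window bp of 3' sequence compared.
#' @param gap_inclusive include gap columns in the denominator.
#' @return identity fraction in `[0, 1]`.
#' @export
three_prime_identity <- function(a, b, window = 60L, gap_inclusive = TRUE) {
  if (nchar(a) < window || nchar(b) < window) {
    stop("both sequences must be at least `window` long", call. = FALSE)
  }
  ta <- substr(a, nchar(a) - window + 1L, nchar(a))
  tb <- substr(b, nchar(b) - window + 1L, nchar(b))
  aln <- nw_align_strings(ta, tb)
  alignment_identity(aln$a, aln$b, gap_inclusive)
}

subfamily_letters <- function(k) {
  # A..Z, then AA, AB, ...
  vapply(k, function(i) {
    out <- ""
    while (i > 0L) {
      rem <- (i - 1L) %% 26L
      out <- paste0(LETTERS[rem + 1L], out)
      i <- (i - 1L) %/% 26L
    }
    out
  }, character(1))
}

#' Partition family members into subfamilies by 3'-end identity
#'
#' Single-linkage within each family at `subfamily_min_identity` over the
#' last `subfamily_window` bp.  Letters A, B, ... are assigned by
#' descending subfamily size, ties by smallest element id; beyond 26
#' subfamilies the labels continue AA, AB, ...
#'
#' @param seqs named character vector of element sequences.
#' @param families data frame from [assign_families()].
#' @param params a [classification_params()].
#' @return data frame (`element_id`, `family`, `subfamily`).
#' @export
assign_subfamilies <- function(seqs, families, params = classification_params()) {
  out <- families
  out$subfamily <- NA_character_
  for (f in unique(families$family)) {
    ids <- sort(families$element_id[families$family == f])
    n <- length(ids)
    ei <- integer(0); ej <- integer(0)
    if (n > 1L) {
      for (i in seq_len(n - 1L)) {
        for (j in seq(i + 1L, n)) {
          idt <- three_prime_identity(seqs[[ids[i]]], seqs[[ids[j]]],
                                      window = params$subfamily_window,
                                      gap_inclusive = params$gap_inclusive)
          if (idt >= params$subfamily_min_identity) {
            ei <- c(ei, i); ej <- c(ej, j)
          }
        }
      }
    }
    comp <- single_linkage(n, data.frame(i = ei, j = ej))
    groups <- split(ids, comp)
    size <- vapply(groups, length, integer(1))
    min_id <- vapply(groups, min, character(1))
    ord <- order(-size, min_id)
    letter_of_group <- character(length(groups))
    letter_of_group[ord] <- subfamily_letters(seq_along(groups))
    for (g in seq_along(groups)) {
      out$subfamily[out$element_id %in% groups[[g]]] <- letter_of_group[g]
    }
  }
  out
}

#' Test whether a candidate is a deletion derivative of an autonomous element
#'
#' Aligns the candidate's 5' and 3' terminal windows (default 200 bp)
#' locally against the autonomous element and reports per-end identities;
#' the elements are linked when both ends reach `min_identity` (default
#' 0.84, the low end of the observed HINE/Helentron identity range).
#'
#' @param autonomous,candidate DNA strings,
#'   `nchar(autonomous) >= nchar(candidate)`.
#' @param min_identity per-end identity required for a link.
#' @param end_window bp of each candidate terminus aligned.
#' @return list with `link`, `identity_5p`, `identity_3p`,
#'   `overall_identity`.
#' @export
link_deletion_derivative <- function(autonomous, candidate,
                                     min_identity = 0.84, end_window = 200L) {
  if (nchar(autonomous) < nchar(candidate)) {
    stop("autonomous element must be at least as long as the candidate",
         call. = FALSE)
  }
  w <- min(end_window, nchar(candidate) %/% 2L)
  # a short derivative's terminal window can straddle the deletion
  # junction, so identity is taken over the aligned span; a minimum
  # anchor length keeps spurious short high-identity cores from linking
  anchor <- min(w, 50L)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  end_identity <- function(window_seq) {
    aln <- Biostrings::pairwiseAlignment(window_seq, autonomous,
                                         type = "local",
                                         substitutionMatrix = mat,
                                         gapOpening = 2, gapExtension = 1)
    pa <- as.character(Biostrings::pattern(aln))
    sa <- as.character(Biostrings::subject(aln))
    x <- strsplit(pa, "")[[1]]; y <- strsplit(sa, "")[[1]]
    list(matches = sum(x == y & x != "-"), cols = length(x))
  }
  e5 <- end_identity(substr(candidate, 1L, w))
  e3 <- end_identity(substr(candidate, nchar(candidate) - w + 1L, nchar(candidate)))
  id5 <- if (e5$cols) e5$matches / e5$cols else 0
  id3 <- if (e3$cols) e3$matches / e3$cols else 0
  list(link = id5 >= min_identity && id3 >= min_identity &&
         e5$cols >= anchor && e3$cols >= anchor,
       identity_5p = id5, identity_3p = id3,
       overall_identity = (e5$matches + e3$matches) /
         max(1L, e5$cols + e3$cols))
}

#' Build the canonical element name
#'
#' Autonomous elements are `Helentron-<sp>-<family><subfamily>`,
#' non-autonomous partners `HINE-<sp>-<family><subfamily>.<variant>`, and
#' Helitron/Helentron intermediates `proto-Helentron-<sp>`.
#'
#' @param species_code short species abbreviation (e.g. `"Mo"`).
#' @param assignment list or one-row data frame with `family`,
#'   `subfamily`, `variant_index`, `autonomous`.
#' @param kind `"Helentron"`, `"HINE"` or `"proto-Helentron"`.
#' @return the name string.
#' @export
name_element <- function(species_code, assignment,
                         kind = c("Helentron", "HINE", "proto-Helentron")) {
  kind <- match.arg(kind)
  if (kind == "proto-Helentron") {
    return(paste0("proto-Helentron-", species_code))
  }
  base <- paste0(species_code, "-", assignment$family, assignment$subfamily)
  if (kind == "Helentron") {
    paste0("Helentron-", base)
  } else {
    paste0("HINE-", base, ".", assignment$variant_index %||% 1L)
  }
}

#' Full family/subfamily classification of a set of elements
#'
#' Convenience wrapper running [assign_families()],
#' [assign_subfamilies()], variant numbering of non-autonomous members
#' (by element id within each subfamily) and [name_element()].
#'
#' @param seqs named character vector of element sequences.
#' @param subtirs named list of subTIR strings per element.
#' @param autonomous named logical vector (coding elements).
#' @param species_code species abbreviation used in names.
#' @param params a [classification_params()].
#' @return data frame (`element_id`, `family`, `subfamily`,
#'   `variant_index`, `autonomous`, `name`), with excluded elements in
#'   the `excluded` attribute.
#' @export
classify_elements <- function(seqs, subtirs, autonomous, species_code = "Xx",
                              params = classification_params()) {
  fam <- assign_families(subtirs, params)
  sub <- assign_subfamilies(seqs, fam, params)
  sub$autonomous <- as.logical(autonomous[sub$element_id])
  sub$variant_index <- NA_integer_
  for (key in unique(paste(sub$family, sub$subfamily))) {
    rows <- which(paste(sub$family, sub$subfamily) == key & !sub$autonomous)
    rows <- rows[order(sub$element_id[rows])]
    sub$variant_index[rows] <- seq_along(rows)
  }
  sub$name <- vapply(seq_len(nrow(sub)), function(k) {
    name_element(species_code, sub[k, ],
                 kind = if (sub$autonomous[k]) "Helentron" else "HINE")
  }, character(1))
  attr(sub, "excluded") <- attr(fam, "excluded")
  sub
}
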