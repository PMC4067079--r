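#' @useDynLib helentronscan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over the {A,C,G,T,N} alphabet.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  as.character(revcomp_cpp(x))
}

# evaluate expr under a fixed RNG state, restoring the caller's stream
run_seeded <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# derive a child seed from a base seed; keeps results below 2^31
child_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + i * 104729) %% 2147483647)
}

assert_dna <- function(seq, what = "sequence") {
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) {
    stop(sprintf("%s contains non-DNA characters (expected A/C/G/T/N)", what),
         call. = FALSE)
  }
  invisible(TRUE)
}

# expand an IUPAC nucleotide pattern (e.g. CTRR) into a regex character class
iupac_to_regex <- function(pattern) {
  map <- c(A = "A", C = "C", G = "G", T = "T", U = "T",
           R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]",
           K = "[GT]", M = "[AC]", B = "[CGT]", D = "[AGT]",
           H = "[ACT]", V = "[ACG]", N = "[ACGT]")
  chars <- strsplit(toupper(pattern), "")[[1]]
  unknown <- setdiff(chars, names(map))
  if (length(unknown)) stop("unknown IUPAC code: ", paste(unknown, collapse = ","))
  paste0(map[chars], collapse = "")
}

# random DNA string at a given GC content
rand_dna <- function(n, gc = 0.5, alphabet = c("A", "C", "G", "T")) {
  if (n <= 0) return("")
  prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(alphabet, n, replace = TRUE, prob = prob), collapse = "")
}

# random DNA avoiding T (used for element pads where the boundary T runs
# must stay identifiable)
rand_dna_noT <- function(n) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G"), n, replace = TRUE), collapse = "")
}

# random DNA over {A,C}: contains no T (boundary identifiability) and can
# host no hairpin (A/T and C/G pairs are impossible), so the 3'-terminal
# spacer and pad cannot spawn decoy stem-loops
rand_dna_ac <- function(n) {
  if (n <= 0) return("")
  paste(sample(c("A", "C"), n, replace = TRUE), collapse = "")
}

# substitute bases at a per-site rate; substitutions always change the base
mutate_seq <- function(seq, rate) {
  if (rate <= 0 || nchar(seq) == 0L) return(seq)
  chars <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(chars)) < rate & chars %in% c("A", "C", "G", "T"))
  for (i in hit) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

# 0-based positions i such that seq[i..i+1] == "TT"
tt_positions <- function(seq) {
  chars <- charToRaw(seq)
  tt <- chars == charToRaw("T")
  n <- length(tt)
  if (n < 2L) return(integer(0))
  which(tt[-n] & tt[-1L]) - 1L
}

# length of the contiguous T run ending just before 0-based position pos
t_run_before <- function(seq, pos) {
  run <- 0L
  while (pos - run - 1L >= 0L &&
         substr(seq, pos - run, pos - run) == "T") run <- run + 1L
  run
}

# length of the contiguous T run starting at 0-based position pos
t_run_at <- function(seq, pos) {
  n <- nchar(seq)
  run <- 0L
  while (pos + run < n &&
         substr(seq, pos + run + 1L, pos + run + 1L) == "T") run <- run + 1L
  run
}

# 0-based half-open substring
substr0 <- function(seq, start, end) substr(seq, start + 1L, end)
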