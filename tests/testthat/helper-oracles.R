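# Independent brute-force oracles, kept deliberately separate from the
# package's implementations.

.ocomp <- c(A = "T", C = "G", G = "C", T = "A")

# enumerate every (offset, arm, loop) triple, then keep the maximal ones:
# a triple is maximal when neither the outward extension (o-1, a+1, l)
# nor the inward extension (o, a+1, l-2) is valid
oracle_palindromes <- function(seq, min_arm, max_arm, min_loop, max_loop,
                               max_mm) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  pair_match <- function(i, j) {
    ci <- chars[i + 1L]
    !is.na(.ocomp[ci]) && !is.na(chars[j + 1L]) &&
      identical(unname(.ocomp[ci]), chars[j + 1L])
  }
  mm_of <- function(o, a, l) {
    sum(vapply(seq_len(a) - 1L, function(k)
      !pair_match(o + k, o + 2L * a + l - 1L - k), logical(1)))
  }
  valid <- function(o, a, l) {
    if (o < 0L || a < min_arm || a > max_arm || l < min_loop || l > max_loop)
      return(FALSE)
    if (o + 2L * a + l > n) return(FALSE)
    mm_of(o, a, l) <= max_mm
  }
  rows <- list()
  for (o in 0:(n - 1L)) {
    for (l in min_loop:max_loop) {
      for (a in min_arm:max_arm) {
        if (o + 2L * a + l > n) next
        mm <- mm_of(o, a, l)
        if (mm > max_mm) next
        if (valid(o - 1L, a + 1L, l)) next
        if (valid(o, a + 1L, l - 2L)) next
        rows[[length(rows) + 1L]] <- c(o, a, l, mm)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(offset = integer(0), arm_len = integer(0),
                      loop_len = integer(0), mismatches = integer(0)))
  }
  df <- as.data.frame(do.call(rbind, rows))
  names(df) <- c("offset", "arm_len", "loop_len", "mismatches")
  df[order(df$offset, -df$arm_len, df$loop_len), , drop = FALSE]
}

hit_key <- function(df) {
  if (nrow(df) == 0L) return(character(0))
  sort(paste(df$offset, df$arm_len, df$loop_len, df$mismatches, sep = ":"))
}

ir_key <- function(df) {
  if (nrow(df) == 0L) return(character(0))
  sort(paste(df$left_start, df$arm_len, df$gap, df$mismatches, sep = ":"))
}

# plain-R global alignment score oracle (Gotoh affine: match +1,
# mismatch -1, gap of length k costs 2 + k).  Identity itself is only
# asserted on constructed cases where the optimal alignment is unique;
# on random pairs ties between optima can carry different match counts.
oracle_global_score <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  NEG <- -1e9
  go <- 2; ge <- 1
  H <- matrix(NEG, n + 1, m + 1); E <- H; F <- H
  H[1, 1] <- 0
  for (j in seq_len(m)) {
    E[1, j + 1] <- max(H[1, j] - go - ge, E[1, j] - ge)
    H[1, j + 1] <- E[1, j + 1]
  }
  for (i in seq_len(n)) {
    F[i + 1, 1] <- max(H[i, 1] - go - ge, F[i, 1] - ge)
    H[i + 1, 1] <- F[i + 1, 1]
    for (j in seq_len(m)) {
      E[i + 1, j + 1] <- max(H[i + 1, j] - go - ge, E[i + 1, j] - ge)
      F[i + 1, j + 1] <- max(H[i, j + 1] - go - ge, F[i, j + 1] - ge)
      d <- H[i, j] + if (x[i] == y[j]) 1 else -1
      H[i + 1, j + 1] <- max(d, E[i + 1, j + 1], F[i + 1, j + 1])
    }
  }
  H[n + 1, m + 1]
}

# exhaustive empty-site oracle: Waterman-Eggert all-hits DP over the full
# genome on both strands, then the printed identity/coverage filters
oracle_empty_sites <- function(query, genome, params, insertion = NULL) {
  qlen <- nchar(query)
  rows <- list()
  for (seqid in names(genome)) {
    n <- nchar(genome[[seqid]])
    for (strand in c("+", "-")) {
      subject <- if (strand == "+") genome[[seqid]] else revcomp(genome[[seqid]])
      we <- helentronscan:::waterman_eggert_cpp(query, subject, 1, -1, 2, 1,
                                                min_score = 40, max_hits = 25L)
      if (!nrow(we)) next
      identity <- we$matches / we$columns
      coverage <- (we$q_end - we$q_start) / qlen
      keep <- identity >= params$min_identity & coverage >= params$min_coverage
      we <- we[keep, , drop = FALSE]
      if (!nrow(we)) next
      fs <- if (strand == "+") we$s_start else n - we$s_end
      fe <- if (strand == "+") we$s_end else n - we$s_start
      rows[[length(rows) + 1L]] <- data.frame(
        seqid = seqid, start = fs, end = fe, strand = strand,
        identity = identity[keep], coverage = coverage[keep],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(seqid = character(0), start = integer(0),
                      end = integer(0), strand = character(0)))
  }
  out <- do.call(rbind, rows)
  if (!is.null(insertion)) {
    drop <- out$seqid == insertion$seqid[1] &
      out$start < insertion$end[1] & out$end > insertion$start[1]
    out <- out[!drop, , drop = FALSE]
  }
  out
}

site_key <- function(df) {
  if (nrow(df) == 0L) return(character(0))
  sort(paste(df$seqid, df$start, df$end, df$strand, sep = ":"))
}

rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  mean(same_a == same_b)
}

# vectorised form of the same enumeration (needed at acceptance scale);
# identical definition, computed with the recurrence
# mm(o, a, l) = mismatch(outer pair) + mm(o+1, a-1, l)
oracle_palindromes_fast <- function(seq, min_arm, max_arm, min_loop,
                                    max_loop, max_mm) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  comp <- c(A = "T", C = "G", G = "C", T = "A")[chars]
  mm_store <- list()     # mm_store[[l]][[a]] = mm vector over offsets 0..n-1
  for (l in min_loop:max_loop) {
    mm_a <- rep(0L, n + 2L)
    store_a <- list()
    for (a in 1:(max_arm)) {
      D <- 2L * a + l - 1L
      mis <- rep(TRUE, n)
      o_idx <- seq_len(n - D)
      if (length(o_idx)) {
        mis[o_idx] <- is.na(comp[o_idx]) | comp[o_idx] != chars[o_idx + D]
      }
      mm_new <- rep(NA_integer_, n)
      inner <- c(mm_a[2:(n + 1L)])
      mm_new <- as.integer(mis) + ifelse(is.na(inner), 0L, inner)
      mm_new[seq_len(n) + D > n] <- NA_integer_
      store_a[[a]] <- mm_new
      mm_a <- c(mm_new, NA_integer_, NA_integer_)
    }
    mm_store[[as.character(l)]] <- store_a
  }
  valid <- function(o, a, l) {
    # o 0-based vector; returns logical
    if (a < min_arm || a > max_arm || l < min_loop || l > max_loop)
      return(rep(FALSE, length(o)))
    mm <- rep(NA_integer_, length(o))
    pos <- o + 1L
    sel <- pos >= 1L & pos <= n
    mm[sel] <- mm_store[[as.character(l)]][[a]][pos[sel]]
    o >= 0L & (o + 2L * a + l) <= n & !is.na(mm) & mm <= max_mm
  }
  rows <- list()
  for (l in min_loop:max_loop) {
    for (a in min_arm:max_arm) {
      o <- 0:(n - 1L)
      keep <- valid(o, a, l) & !valid(o - 1L, a + 1L, l) &
        !valid(o, a + 1L, l - 2L)
      if (any(keep)) {
        mm <- mm_store[[as.character(l)]][[a]][o[keep] + 1L]
        rows[[length(rows) + 1L]] <- data.frame(
          offset = o[keep], arm_len = a, loop_len = l, mismatches = mm)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(offset = integer(0), arm_len = integer(0),
                      loop_len = integer(0), mismatches = integer(0)))
  }
  df <- do.call(rbind, rows)
  df[order(df$offset, -df$arm_len, df$loop_len), , drop = FALSE]
}
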