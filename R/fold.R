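# Self-contained RNA secondary-structure scoring: base-pair-maximisation
# folding, dinucleotide-preserving shuffle significance, and miRNA:target
# duplex alignment. These replace the heavyweight thermodynamic folders for
# the purposes of the curation criteria, which are randomization tests and
# pairing-geometry checks rather than energy estimates.

# Run code with a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Fold an RNA sequence by nested base-pair maximisation
#'
#' Computes a maximum set of nested \{A:U, G:C, G:U\} base pairs subject to a
#' minimum hairpin-loop size, by the classic Nussinov dynamic program, and
#' returns one optimal structure. The traceback is deterministic: at each
#' position the 5'-most optimal pairing partner is taken, so identical inputs
#' give identical structures.
#'
#' @param seq RNA sequence (character scalar; `T` accepted and read as `U`).
#' @param min_loop Minimum number of unpaired nucleotides enclosed by a pair
#'   (default 3, the standard steric minimum).
#' @return An object of class `rna_fold`: a list with `seq`, `structure`
#'   (dot-bracket), `pair_count` and `pair_table` (1-based partner indices,
#'   `NA` when unpaired).
#' @export
#' @examples
#' fold_nussinov("GGGAAACCC")$structure
fold_nussinov <- function(seq, min_loop = 3L) {
  seq <- normalize_rna(seq)
  chars <- seq_chars(seq)
  n <- length(chars)
  if (n < 1L) stop("empty sequence")
  if (min_loop < 0L) stop("min_loop must be >= 0")

  pairable <- outer(chars, chars, is_fold_pair)
  N <- matrix(0L, n, n)
  val <- function(i, j) if (i > j) 0L else N[i, j]

  if (n >= min_loop + 2L) {
    for (span in (min_loop + 1L):(n - 1L)) {
      for (i in seq_len(n - span)) {
        j <- i + span
        best <- N[i + 1L, j]
        ks <- (i + min_loop + 1L):j
        ks <- ks[pairable[i, ks]]
        if (length(ks) > 0L) {
          left <- ifelse(ks - 1L >= i + 1L, N[cbind(i + 1L, ks - 1L)], 0L)
          right <- ifelse(ks + 1L <= j, N[cbind(pmin(ks + 1L, j), j)], 0L)
          right[ks + 1L > j] <- 0L
          best <- max(best, 1L + left + right)
        }
        N[i, j] <- best
      }
    }
  }

  # traceback: prefer "i unpaired", then the smallest optimal partner k
  pt <- rep(NA_integer_, n)
  stack <- list(c(1L, n))
  while (length(stack) > 0L) {
    ij <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- ij[1L]; j <- ij[2L]
    if (i >= j || j - i <= min_loop) next
    if (N[i, j] == N[i + 1L, j]) {
      stack[[length(stack) + 1L]] <- c(i + 1L, j)
      next
    }
    for (k in (i + min_loop + 1L):j) {
      if (!pairable[i, k]) next
      inner <- val(i + 1L, k - 1L)
      outer_ <- val(k + 1L, j)
      if (N[i, j] == 1L + inner + outer_) {
        pt[i] <- k; pt[k] <- i
        stack[[length(stack) + 1L]] <- c(i + 1L, k - 1L)
        stack[[length(stack) + 1L]] <- c(k + 1L, j)
        break
      }
    }
  }

  structure(
    list(seq = seq,
         structure = pairs_to_dotbracket(pt),
         pair_count = sum(!is.na(pt)) %/% 2L,
         pair_table = pt),
    class = "rna_fold"
  )
}

#' @export
print.rna_fold <- function(x, ...) {
  cat(x$seq, "\n", x$structure, "\n", sep = "")
  cat(x$pair_count, "base pairs\n")
  invisible(x)
}

#' Shuffle a sequence preserving mono- or dinucleotide composition
#'
#' Order 1 is a uniform permutation of the letters. Order 2 is an
#' Altschul-Erickson Eulerian-path shuffle: the shuffled sequence has exactly
#' the dinucleotide (and hence mononucleotide) counts of the input, with the
#' same first and last letters.
#'
#' @param seq RNA sequence (>= 3 nt for order 2).
#' @param order 1 or 2.
#' @return A shuffled sequence (character scalar). Uses the current RNG
#'   stream; seed externally (e.g. via [shuffle_pvalue()]).
#' @export
shuffle_sequence <- function(seq, order = 2L) {
  seq <- normalize_rna(seq)
  chars <- seq_chars(seq)
  n <- length(chars)
  if (order == 1L) {
    return(paste(sample(chars), collapse = ""))
  }
  if (n < 3L) stop("sequence too short to dinucleotide-shuffle (< 3 nt)")
  verts <- unique(chars)
  if (length(verts) == 1L) return(seq)

  from <- chars[-n]
  to <- chars[-1L]
  last_v <- chars[n]
  edge_idx <- split(seq_along(to), from)   # outgoing edge indices per vertex

  # choose, per non-terminal vertex, a random final edge; accept when the
  # chosen final edges form an arborescence into the terminal vertex
  need <- setdiff(names(edge_idx), last_v)
  repeat {
    last_edge <- vapply(need, function(v) {
      ids <- edge_idx[[v]]
      if (length(ids) == 1L) ids else sample(ids, 1L)
    }, integer(1L))
    nxt <- setNames(to[last_edge], need)
    ok <- TRUE
    for (v in need) {
      cur <- v
      steps <- 0L
      while (cur != last_v) {
        if (!cur %in% need || steps > length(verts)) { ok <- FALSE; break }
        cur <- nxt[[cur]]
        steps <- steps + 1L
      }
      if (!ok) break
    }
    if (ok) break
  }

  ordered <- lapply(names(edge_idx), function(v) {
    ids <- edge_idx[[v]]
    if (v %in% need) {
      rest <- setdiff(ids, last_edge[[v]])
      if (length(rest) > 1L) rest <- sample(rest)
      c(rest, last_edge[[v]])
    } else {
      if (length(ids) > 1L) sample(ids) else ids
    }
  })
  names(ordered) <- names(edge_idx)

  # walk the Eulerian path from the original first letter
  ptr <- setNames(rep(1L, length(ordered)), names(ordered))
  out <- character(n)
  out[1L] <- chars[1L]
  cur <- chars[1L]
  for (i in 2:n) {
    e <- ordered[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    cur <- to[e]
    out[i] <- cur
  }
  paste(out, collapse = "")
}

#' Randomisation p-value for folding strength
#'
#' Compares the base-pair count of a sequence's optimal fold against folds of
#' composition-preserving shuffles, in the manner of randfold. The p-value is
#' the add-one estimator `(1 + ties-or-better) / (n_shuffles + 1)`, so it can
#' never be exactly zero.
#'
#' @param seq RNA sequence.
#' @param n_shuffles Number of shuffles (default 99).
#' @param shuffle_order 1 (mononucleotide) or 2 (dinucleotide-preserving,
#'   default).
#' @param seed Integer seed for the shuffle stream.
#' @param min_loop Passed to [fold_nussinov()].
#' @param fold_fun Optional plug-in folding backend: a function
#'   `f(seq)` returning a list with at least `pair_count` (or an `energy`
#'   field, negated into a comparable score). Defaults to [fold_nussinov()].
#' @return A single numeric p-value in `[1/(n_shuffles+1), 1]`.
#' @export
shuffle_pvalue <- function(seq, n_shuffles = 99L, shuffle_order = 2L,
                           seed = 1L, min_loop = 3L, fold_fun = NULL) {
  stopifnot(n_shuffles >= 1L)
  seq <- normalize_rna(seq)
  if (nchar(seq) < 3L) stop("sequence too short to shuffle (< 3 nt)")
  score_of <- function(s) {
    if (is.null(fold_fun)) {
      fold_nussinov(s, min_loop = min_loop)$pair_count
    } else {
      res <- fold_fun(s)
      if (!is.null(res$pair_count)) res$pair_count else -res$energy
    }
  }
  observed <- score_of(seq)
  with_seed(seed, {
    hits <- 0L
    for (b in seq_len(n_shuffles)) {
      sh <- shuffle_sequence(seq, order = shuffle_order)
      if (score_of(sh) >= observed) hits <- hits + 1L
    }
    (1 + hits) / (n_shuffles + 1)
  })
}

#' Duplex alignment scoring parameters
#'
#' @param wc Score for a Watson-Crick pair (default +2).
#' @param gu Score for a G:U wobble pair (default +1).
#' @param mismatch Score for two opposed, non-pairing nucleotides (default -1).
#' @param gap_open Cost of the first nucleotide of a bulge (default -3).
#' @param gap_extend Cost of each further bulged nucleotide (default -2).
#' @return A named list of class `duplex_params`.
#' @export
duplex_params <- function(wc = 2, gu = 1, mismatch = -1,
                          gap_open = -3, gap_extend = -2) {
  structure(list(wc = wc, gu = gu, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "duplex_params")
}

#' Align a miRNA against a target window as an antiparallel duplex
#'
#' Finds the optimal antiparallel hybrid of a miRNA and a candidate target
#' window under simple per-pair scores with affine bulge penalties
#' (a semi-global dynamic program: terminal overhangs on either strand are
#' free). Every miRNA position is assigned a state: `paired_wc`, `paired_gu`,
#' `mismatch`, `bulged` (opposite a gap), or `unpaired_end` (terminal
#' overhang).
#'
#' @param mirna miRNA sequence, 5' to 3'.
#' @param window Target window on the transcript sense strand, 5' to 3'.
#'   Typically within 3 nt of the miRNA length.
#' @param params A [duplex_params()] object.
#' @return An object of class `mirna_duplex`: list with `mirna`, `window`,
#'   `score`, `states` (character vector, one per miRNA position),
#'   `target_span` (1-based inclusive interval on `window` covered by the
#'   duplex).
#' @export
#' @examples
#' duplex_align("ACGUACGU", revcomp_rna("ACGUACGU"))$states
duplex_align <- function(mirna, window, params = duplex_params()) {
  mirna <- normalize_rna(mirna)
  window <- normalize_rna(window)
  m <- seq_chars(mirna)
  w <- rev(seq_chars(window))    # antiparallel: miRNA pos 1 faces window 3' end
  Lm <- length(m); Lw <- length(w)
  if (Lm == 0L || Lw == 0L) stop("empty input to duplex_align")

  pair_score <- function(a, b) {
    if (is_wc_pair(a, b)) params$wc
    else if ((a == "G" && b == "U") || (a == "U" && b == "G")) params$gu
    else params$mismatch
  }
  S <- matrix(0, Lm, Lw)
  for (i in seq_len(Lm)) for (j in seq_len(Lw)) S[i, j] <- pair_score(m[i], w[j])

  NEG <- -1e9
  M <- matrix(NEG, Lm + 1L, Lw + 1L)  # ends with m[i] opposed to w[j]
  X <- matrix(NEG, Lm + 1L, Lw + 1L)  # ends with m[i] bulged (gap in window)
  Y <- matrix(NEG, Lm + 1L, Lw + 1L)  # ends with w[j] bulged (gap in miRNA)
  M[1L, ] <- 0; M[, 1L] <- 0          # free leading overhangs
  for (i in seq_len(Lm)) {
    for (j in seq_len(Lw)) {
      M[i + 1L, j + 1L] <- S[i, j] + max(M[i, j], X[i, j], Y[i, j])
      X[i + 1L, j + 1L] <- max(M[i, j + 1L] + params$gap_open,
                               X[i, j + 1L] + params$gap_extend)
      Y[i + 1L, j + 1L] <- max(M[i + 1L, j] + params$gap_open,
                               Y[i + 1L, j] + params$gap_extend)
    }
  }

  # free trailing overhangs: best M cell on the last row or column
  ends <- rbind(cbind(Lm + 1L, seq_len(Lw + 1L)),
                cbind(seq_len(Lm), Lw + 1L))
  end_scores <- M[ends]
  best <- which.max(end_scores)
  score <- end_scores[best]
  ei <- ends[best, 1L]; ej <- ends[best, 2L]

  states <- rep("unpaired_end", Lm)
  j_touched <- integer(0)
  target_bulges <- 0L
  i <- ei; j <- ej; state <- "M"
  while (i > 1L && j > 1L) {
    if (state == "M") {
      if (M[i, j] == 0 && (i == 1L || j == 1L)) break
      a <- m[i - 1L]; b <- w[j - 1L]
      states[i - 1L] <- if (is_wc_pair(a, b)) "paired_wc"
        else if ((a == "G" && b == "U") || (a == "U" && b == "G")) "paired_gu"
        else "mismatch"
      j_touched <- c(j_touched, j - 1L)
      prev <- M[i, j] - S[i - 1L, j - 1L]
      state <- if (isTRUE(all.equal(prev, M[i - 1L, j - 1L]))) "M"
        else if (isTRUE(all.equal(prev, X[i - 1L, j - 1L]))) "X"
        else "Y"
      i <- i - 1L; j <- j - 1L
    } else if (state == "X") {
      states[i - 1L] <- "bulged"
      state <- if (isTRUE(all.equal(X[i, j], M[i - 1L, j] + params$gap_open))) "M" else "X"
      i <- i - 1L
    } else {
      j_touched <- c(j_touched, j - 1L)
      target_bulges <- target_bulges + 1L   # internal window nt opposite a gap
      state <- if (isTRUE(all.equal(Y[i, j], M[i, j - 1L] + params$gap_open))) "M" else "Y"
      j <- j - 1L
    }
  }

  span <- if (length(j_touched) > 0L) {
    # reversed-window indices back to original window coordinates
    range(Lw - j_touched + 1L)
  } else {
    c(NA_integer_, NA_integer_)
  }

  structure(
    list(mirna = mirna, window = window, score = score,
         states = states, target_span = span,
         target_bulges = target_bulges),
    class = "mirna_duplex"
  )
}

#' @export
print.mirna_duplex <- function(x, ...) {
  cat("miRNA:target duplex, score ", x$score, "\n", sep = "")
  cat(x$mirna, "\n", sep = "")
  glyph <- c(paired_wc = "|", paired_gu = ":", mismatch = ".",
             bulged = "-", unpaired_end = " ")
  cat(paste(glyph[x$states], collapse = ""), "\n", sep = "")
  invisible(x)
}
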