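# Bona fide miRNA curation: precursor duplex geometry, read-stack 5'
# homogeneity, the six-criterion evaluation, blacklist filtering, and
# homology-based detection for species without genome assemblies.

#' Curation thresholds for bona fide miRNA calls
#'
#' Defaults encode the standard structural and read-support criteria for
#' animal miRNA annotation as applied to cnidarians: an upstream discovery
#' score of at least 10, an exact 2-nt star 3' overhang, at least 90% of
#' mature-arm reads sharing one 5' position, at least 16 mature/star base
#' pairs, at least 10 reads, and a significant randomisation p-value for the
#' precursor fold. Terminal-loop-size and star-strand-consistency
#' requirements are deliberately not applied (cnidarian precursors do not
#' follow them); the switches exist for completeness.
#'
#' @param min_score Minimum upstream (e.g. miRDeep2) score; candidates
#'   without a score skip this criterion.
#' @param overhang_nt Required star 3' overhang in nt (exact).
#' @param min_five_prime_consistency Minimum modal 5'-start fraction.
#' @param min_mature_star_pairs Minimum mature/star base pairs.
#' @param min_reads Minimum mature-arm read count.
#' @param fold_alpha Significance level for [shuffle_pvalue()].
#' @param mature_reads_only Count only reads overlapping the mature arm
#'   toward `min_reads`? (default TRUE; set FALSE to count the whole stack.)
#' @param overhang_anchor_scan How far (nt) to scan inward for the first
#'   paired mature 5' nucleotide when the terminus frays (default 2).
#' @param require_loop_size,require_star_consistency Disabled relaxed
#'   criteria (defaults FALSE); when enabled, `min_loop_size` applies.
#' @param min_loop_size Terminal loop threshold used only if
#'   `require_loop_size`.
#' @return A list of class `curation_thresholds`.
#' @export
curation_thresholds <- function(min_score = 10, overhang_nt = 2L,
                                min_five_prime_consistency = 0.90,
                                min_mature_star_pairs = 16L,
                                min_reads = 10L, fold_alpha = 0.05,
                                mature_reads_only = TRUE,
                                overhang_anchor_scan = 2L,
                                require_loop_size = FALSE,
                                require_star_consistency = FALSE,
                                min_loop_size = 8L) {
  structure(list(min_score = min_score, overhang_nt = as.integer(overhang_nt),
                 min_five_prime_consistency = min_five_prime_consistency,
                 min_mature_star_pairs = as.integer(min_mature_star_pairs),
                 min_reads = as.integer(min_reads), fold_alpha = fold_alpha,
                 mature_reads_only = mature_reads_only,
                 overhang_anchor_scan = as.integer(overhang_anchor_scan),
                 require_loop_size = require_loop_size,
                 require_star_consistency = require_star_consistency,
                 min_loop_size = as.integer(min_loop_size)),
            class = "curation_thresholds")
}

# fold (or parse) the structure attached to a candidate row
candidate_fold <- function(candidate, min_loop = 3L) {
  db <- candidate$structure[1L]
  if (!is.null(db) && !is.na(db) && nzchar(db)) {
    pt <- parse_dotbracket(db)
    structure(list(seq = candidate$precursor[1L], structure = db,
                   pair_count = sum(!is.na(pt)) %/% 2L, pair_table = pt),
              class = "rna_fold")
  } else {
    fold_nussinov(candidate$precursor[1L], min_loop = min_loop)
  }
}

#' Measure the mature/star duplex geometry of a folded precursor
#'
#' From a candidate's fold, counts the base pairs joining a mature position
#' to a star position, and measures the star 3' overhang: the number of
#' star-strand 3'-terminal nucleotides beyond the pairing partner of the
#' first paired mature 5' nucleotide. When the mature 5' terminus itself is
#' unpaired (real hairpins fray), the anchor advances inward by up to
#' `anchor_scan` nucleotides to the first paired mature position.
#'
#' @param candidate A one-row candidate tibble (see [make_hairpin()] for the
#'   columns).
#' @param fold An `rna_fold` object covering the precursor; computed from the
#'   candidate's structure (or sequence) if omitted.
#' @param anchor_scan Fraying tolerance in nt (default 2).
#' @return A list with `star_3p_overhang` (integer, `NA` if no mature-star
#'   pairs exist) and `mature_star_pairs` (integer).
#' @export
duplex_geometry <- function(candidate, fold = NULL, anchor_scan = 2L) {
  if (is.null(fold)) fold <- candidate_fold(candidate)
  pt <- fold$pair_table
  m0 <- candidate$mature_start[1L]; m1 <- candidate$mature_end[1L]
  s0 <- candidate$star_start[1L]; s1 <- candidate$star_end[1L]
  mature_pos <- m0:m1
  partners <- pt[mature_pos]
  in_star <- !is.na(partners) & partners >= s0 & partners <= s1
  n_pairs <- sum(in_star)
  if (n_pairs == 0L) {
    return(list(star_3p_overhang = NA_integer_, mature_star_pairs = 0L))
  }
  # anchor: first paired mature 5' nucleotide, scanning <= anchor_scan inward
  anchor <- NA_integer_
  for (d in 0:anchor_scan) {
    i <- which(mature_pos == m0 + d)
    if (length(i) == 1L && in_star[i]) { anchor <- i; break }
  }
  if (is.na(anchor)) anchor <- which(in_star)[1L]
  partner <- partners[anchor]
  list(star_3p_overhang = as.integer(s1 - partner),
       mature_star_pairs = as.integer(n_pairs))
}

#' 5'-end consistency of a read stack
#'
#' Fraction of mature-arm reads that start at the modal 5' position, the
#' signature of precise Drosha/Dicer processing. Only reads overlapping the
#' mature arm are considered. Ties at the mode are broken toward the
#' annotated mature start, else toward the smaller coordinate.
#'
#' @param stack Read-stack tibble (`start`, `length`, `count`).
#' @param mature_start 1-based mature 5' position on the precursor.
#' @param mature_end 1-based mature 3' position (reads overlapping
#'   `[mature_start, mature_end]` count; default `mature_start` + 21).
#' @return A list with `consistency` (fraction in `[0, 1]`), `modal_start`
#'   and `n_reads` (total mature-arm read count).
#' @export
five_prime_consistency <- function(stack, mature_start,
                                   mature_end = mature_start + 21L) {
  if (nrow(stack) == 0L || sum(stack$count) == 0L) stop("empty read stack")
  ov <- stack$start <= mature_end & (stack$start + stack$length - 1L) >= mature_start
  sub <- stack[ov, , drop = FALSE]
  if (nrow(sub) == 0L) {
    return(list(consistency = 0, modal_start = NA_integer_, n_reads = 0L))
  }
  per_start <- tapply(sub$count, sub$start, sum)
  starts <- as.integer(names(per_start))
  best <- which(per_start == max(per_start))
  modal <- if (mature_start %in% starts[best]) mature_start else min(starts[best])
  list(consistency = unname(per_start[as.character(modal)] / sum(per_start)),
       modal_start = modal,
       n_reads = as.integer(sum(per_start)))
}

#' Evaluate one precursor candidate against the curation criteria
#'
#' Applies, in order: upstream score, star 3' overhang, 5'-end read
#' consistency, mature/star complementarity, read depth, and fold
#' significance. All criteria are evaluated even after the first failure so
#' the audit table lists every reason; `bona_fide` is the conjunction of the
#' enabled criteria. A candidate without an upstream score skips that
#' criterion.
#'
#' @param candidate One-row candidate tibble.
#' @param stack Read-stack tibble for this candidate.
#' @param thresholds A [curation_thresholds()] object.
#' @param n_shuffles Shuffles for [shuffle_pvalue()] (default 99).
#' @param seed Seed for the shuffle stream.
#' @return A one-row tibble: measured values (`score`, `star_3p_overhang`,
#'   `five_prime`, `mature_star_pairs`, `n_reads`, `fold_pvalue`), the
#'   per-criterion logicals (`pass_*`), `bona_fide` and a comma-separated
#'   `failure_reasons` string.
#' @export
evaluate_candidate <- function(candidate, stack,
                               thresholds = curation_thresholds(),
                               n_shuffles = 99L, seed = 1L) {
  th <- thresholds
  fold <- candidate_fold(candidate)
  geom <- duplex_geometry(candidate, fold,
                          anchor_scan = th$overhang_anchor_scan)
  fp <- five_prime_consistency(stack, candidate$mature_start[1L],
                               candidate$mature_end[1L])
  n_reads <- if (th$mature_reads_only) fp$n_reads else sum(stack$count)
  pval <- shuffle_pvalue(candidate$precursor[1L], n_shuffles = n_shuffles,
                         seed = seed)
  score <- candidate$score[1L]

  pass <- c(
    score = if (is.na(score)) NA else score >= th$min_score,
    overhang = !is.na(geom$star_3p_overhang) &&
      geom$star_3p_overhang == th$overhang_nt,
    five_prime = fp$consistency >= th$min_five_prime_consistency,
    complementarity = geom$mature_star_pairs >= th$min_mature_star_pairs,
    min_reads = n_reads >= th$min_reads,
    fold_pvalue = pval < th$fold_alpha
  )
  enabled <- !is.na(pass)
  bona_fide <- all(pass[enabled])
  reasons <- names(pass)[which(enabled & !pass)]

  tibble::tibble(
    id = candidate$id[1L],
    species = candidate$species[1L],
    score = score,
    star_3p_overhang = geom$star_3p_overhang,
    five_prime = fp$consistency,
    mature_star_pairs = geom$mature_star_pairs,
    n_reads = n_reads,
    fold_pvalue = pval,
    pass_score = pass[["score"]],
    pass_overhang = pass[["overhang"]],
    pass_five_prime = pass[["five_prime"]],
    pass_complementarity = pass[["complementarity"]],
    pass_min_reads = pass[["min_reads"]],
    pass_fold_pvalue = pass[["fold_pvalue"]],
    bona_fide = bona_fide,
    failure_reasons = paste(reasons, collapse = ",")
  )
}

#' Curate a table of precursor candidates
#'
#' Vectorised [evaluate_candidate()]: one audit row per candidate, the shape
#' of a supplementary curation table (one column per criterion, measured
#' values alongside).
#'
#' @param candidates Candidate tibble (one row per candidate).
#' @param stacks Read-stack tibble with an `id` column linking to candidates.
#' @param thresholds,n_shuffles,seed Passed to [evaluate_candidate()]; each
#'   candidate's shuffle stream is offset by its row index so candidates are
#'   independent but the table is reproducible.
#' @return An audit tibble of class `mirna_audit`.
#' @export
curate_mirnas <- function(candidates, stacks,
                          thresholds = curation_thresholds(),
                          n_shuffles = 99L, seed = 1L) {
  rows <- purrr::map(seq_len(nrow(candidates)), function(r) {
    cand <- candidates[r, , drop = FALSE]
    st <- stacks[stacks$id == cand$id, , drop = FALSE]
    evaluate_candidate(cand, st, thresholds,
                       n_shuffles = n_shuffles, seed = seed + r)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("mirna_audit", class(out))
  out
}

#' Remove candidates matching tRNA/rRNA/symbiont blacklists
#'
#' A candidate is removed when its mature sequence occurs as a substring of
#' any blacklist sequence, on either strand, with at most `max_mismatch`
#' mismatches (default 0 — exact matching, the conservative desk-scale
#' equivalent of mapping candidates to the contaminant references). The first
#' matching blacklist is recorded as the removal source.
#'
#' @param candidates Candidate tibble carrying a `mature` column, or any
#'   tibble with `id` and `mature` (use [candidate_mature()] to derive it).
#' @param blacklists Named list of tibbles with columns `id`, `seq` (e.g.
#'   `list(tRNA = ..., rRNA = ..., symbiont = ...)`); may be empty.
#' @param max_mismatch Allowed mismatches (default 0).
#' @return A list with `kept` and `removed` (the latter with a `source`
#'   column); their union is the input.
#' @export
blacklist_filter <- function(candidates, blacklists = list(),
                             max_mismatch = 0L) {
  if (nrow(candidates) == 0L || length(blacklists) == 0L) {
    removed <- candidates[0, , drop = FALSE]
    removed$source <- character(0)
    return(list(kept = candidates, removed = removed))
  }
  mat <- candidate_mature(candidates)
  source <- rep(NA_character_, nrow(candidates))
  for (bl_name in names(blacklists)) {
    bl <- blacklists[[bl_name]]
    if (is.null(bl) || nrow(bl) == 0L) next
    targets <- c(normalize_rna(bl$seq), revcomp_rna(bl$seq))
    for (r in which(is.na(source))) {
      pat <- mat[r]
      hit <- if (max_mismatch == 0L) {
        any(vapply(targets, function(s) grepl(pat, s, fixed = TRUE),
                   logical(1L)))
      } else {
        any(vapply(targets, function(s) {
          length(Biostrings::matchPattern(
            chartr("U", "T", pat), chartr("U", "T", s),
            max.mismatch = max_mismatch)) > 0L
        }, logical(1L)))
      }
      if (hit) source[r] <- bl_name
    }
  }
  removed <- candidates[!is.na(source), , drop = FALSE]
  removed$source <- source[!is.na(source)]
  list(kept = candidates[is.na(source), , drop = FALSE], removed = removed)
}

#' Extract mature sequences from a candidate table
#'
#' @param candidates Candidate tibble; if a `mature` column exists it is
#'   used, otherwise the mature is cut from `precursor` by its interval.
#' @return Character vector of mature sequences.
#' @export
candidate_mature <- function(candidates) {
  if ("mature" %in% names(candidates)) {
    return(normalize_rna(candidates$mature))
  }
  substring(candidates$precursor, candidates$mature_start,
            candidates$mature_end)
}

#' Detect conserved miRNAs by read support on known matures
#'
#' For species without genome assemblies, reads are assigned to known mature
#' miRNAs by lenient alignment: a read supports a mature when it matches with
#' at most `max_mismatch` mismatches and its 5'/3' ends are each within
#' `max_shift` nt of the mature's ends. Each read is assigned to at most one
#' mature (fewest mismatches, then fewest total end shift, then lexicographic
#' id). A mature is detected when its summed supporting counts reach
#' `min_reads`.
#'
#' @param reads Tibble with columns `seq`, `count`.
#' @param known_matures Tibble with columns `id`, `seq`.
#' @param min_reads Detection threshold (default 10).
#' @param max_shift Maximum 5'/3' end offset in nt (default 2).
#' @param max_mismatch Maximum mismatches in the overlap (default 1).
#' @return A tibble (`id`, `count`, `detected`), one row per known mature.
#' @export
quantify_known <- function(reads, known_matures, min_reads = 10L,
                           max_shift = 2L, max_mismatch = 1L) {
  stopifnot(nrow(known_matures) > 0L)
  mat_seqs <- normalize_rna(known_matures$seq)
  counts <- setNames(rep(0L, nrow(known_matures)), known_matures$id)

  # best feasible placement of `read` against `mature`; NULL if none
  best_fit <- function(read, mature) {
    rc <- seq_chars(read); mc <- seq_chars(mature)
    nr <- length(rc); nm <- length(mc)
    best <- NULL
    for (shift in -max_shift:max_shift) {
      # read position i sits over mature position i + shift
      i0 <- max(1L, 1L - shift); i1 <- min(nr, nm - shift)
      if (i1 < i0) next
      d5 <- abs(shift)
      d3 <- abs((nr + shift) - nm)
      if (d5 > max_shift || d3 > max_shift) next
      mism <- sum(rc[i0:i1] != mc[(i0:i1) + shift])
      if (mism > max_mismatch) next
      cand <- c(mism = mism, shifts = d5 + d3)
      if (is.null(best) || cand[["mism"]] < best[["mism"]] ||
          (cand[["mism"]] == best[["mism"]] &&
           cand[["shifts"]] < best[["shifts"]])) {
        best <- cand
      }
    }
    best
  }

  ord <- order(known_matures$id)  # lexicographic tie-break
  for (r in seq_len(nrow(reads))) {
    read <- normalize_rna(reads$seq[r])
    winner <- NULL; winner_fit <- NULL
    for (m in ord) {
      fit <- best_fit(read, mat_seqs[m])
      if (is.null(fit)) next
      if (is.null(winner_fit) || fit[["mism"]] < winner_fit[["mism"]] ||
          (fit[["mism"]] == winner_fit[["mism"]] &&
           fit[["shifts"]] < winner_fit[["shifts"]])) {
        winner <- m; winner_fit <- fit
      }
    }
    if (!is.null(winner)) {
      counts[winner] <- counts[winner] + reads$count[r]
    }
  }
  tibble::tibble(id = known_matures$id,
                 count = as.integer(unname(counts[known_matures$id])),
                 detected = unname(counts[known_matures$id]) >= min_reads)
}
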