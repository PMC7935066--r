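# Target-site discovery by near-perfect antisense complementarity, in the
# style of a small-RNA read mapper run with plant-like stringency, followed
# by duplex-level validation of candidate sites.

#' Mapper rule set for target-site discovery
#'
#' The five parameters governing site discovery, with defaults matching the
#' stringent plant-like rules used for cnidarian slicing targets
#' (`-c -s 11 -S 2 -m 2 -n 1` in mapper notation):
#' the miRNA 5' nucleotide need not match the target (`free_5prime`), an
#' 11-nt seed, at most 2 mismatches in the seed, at most 2 mismatches
#' downstream of the seed, and the miRNA's last nucleotide may be unpaired.
#'
#' The seed window is miRNA positions 1..`seed_len`, with position 1 exempt
#' under `free_5prime` (so positions 2..`seed_len` are charged to the seed
#' budget). G:U wobbles count as mismatches at scan stage — the behaviour of
#' a nucleotide-space read mapper — and as pairs at validation stage
#' (thermodynamic pairing); both are configurable.
#'
#' @param free_5prime miRNA position 1 exempt from matching? (default TRUE)
#' @param seed_len Seed length in nt (default 11).
#' @param seed_mismatch_max Mismatch budget in the seed (default 2).
#' @param tail_mismatch_max Mismatch budget downstream of the seed
#'   (default 2).
#' @param unpaired_3prime Number of 3'-terminal miRNA nucleotides exempt from
#'   matching (default 1).
#' @param gu_is_match_scan G:U counts as a match during scanning?
#'   (default FALSE)
#' @param gu_is_match_validation G:U counts as a pair during duplex
#'   validation? (default TRUE)
#' @return A list of class `target_rules`.
#' @export
target_rules <- function(free_5prime = TRUE, seed_len = 11L,
                         seed_mismatch_max = 2L, tail_mismatch_max = 2L,
                         unpaired_3prime = 1L,
                         gu_is_match_scan = FALSE,
                         gu_is_match_validation = TRUE) {
  stopifnot(seed_len >= 1L, seed_mismatch_max >= 0L,
            tail_mismatch_max >= 0L, unpaired_3prime >= 0L)
  structure(list(free_5prime = free_5prime,
                 seed_len = as.integer(seed_len),
                 seed_mismatch_max = as.integer(seed_mismatch_max),
                 tail_mismatch_max = as.integer(tail_mismatch_max),
                 unpaired_3prime = as.integer(unpaired_3prime),
                 gu_is_match_scan = gu_is_match_scan,
                 gu_is_match_validation = gu_is_match_validation),
            class = "target_rules")
}

#' Scan one transcript for antisense target sites of one miRNA
#'
#' Slides the miRNA along the transcript in antiparallel orientation (miRNA
#' position 1, the 5' nucleotide, faces the 3'-most nucleotide of each
#' window) and emits every window whose per-region mismatch counts are within
#' the rule budgets. Matching is ungapped Watson-Crick (G:U is a mismatch
#' unless `gu_is_match_scan`); mismatches at position 1 are recorded but not
#' charged when `free_5prime`; the `unpaired_3prime` terminal positions are
#' recorded but never charged.
#'
#' @param mirna miRNA sequence, 5' to 3'.
#' @param transcript Transcript sequence (sense strand), 5' to 3'.
#' @param rules A [target_rules()] object.
#' @return A tibble of sites sorted by transcript position: `start`, `end`
#'   (1-based inclusive; `end` pairs miRNA position 1), `seed_mm`, `tail_mm`,
#'   `pos1_mismatch`, `last_nt_unpaired`, `validated` (`NA` until
#'   [validate_site()]).
#' @export
scan_transcript <- function(mirna, transcript, rules = target_rules()) {
  mirna <- normalize_rna(mirna)
  transcript <- normalize_rna(transcript)
  L <- nchar(mirna)
  n <- nchar(transcript)
  if (L <= rules$seed_len) stop("miRNA not longer than the seed length")
  if (L < rules$seed_len + rules$unpaired_3prime + 1L) {
    stop("miRNA shorter than seed_len + unpaired_3prime + 1")
  }
  empty <- tibble::tibble(start = integer(0), end = integer(0),
                          seed_mm = integer(0), tail_mm = integer(0),
                          pos1_mismatch = logical(0),
                          last_nt_unpaired = logical(0),
                          validated = logical(0))
  if (n < L) return(empty)

  tchars <- seq_chars(transcript)
  mchars <- seq_chars(mirna)
  n_off <- n - L + 1L

  # match[o, i]: does miRNA position i pair the opposing transcript nt of the
  # window starting at offset o? Opposing coordinate: o + L - i.
  mm <- matrix(FALSE, n_off, L)
  for (i in seq_len(L)) {
    tt <- tchars[(L - i + 1L):(L - i + n_off)]
    ok <- WC_PARTNER[mchars[i]] == tt
    if (rules$gu_is_match_scan) {
      ok <- ok | (mchars[i] == "G" & tt == "U") | (mchars[i] == "U" & tt == "G")
    }
    mm[, i] <- !ok
  }

  region <- mirna_regions(L, rules)
  seed_cols <- which(region == "seed")
  tail_cols <- which(region == "tail")
  seed_mm <- if (length(seed_cols)) rowSums(mm[, seed_cols, drop = FALSE]) else 0L
  tail_mm <- if (length(tail_cols)) rowSums(mm[, tail_cols, drop = FALSE]) else 0L
  pos1_cost <- if (rules$free_5prime) 0L else as.integer(mm[, 1L])
  seed_total <- seed_mm + pos1_cost

  keep <- seed_total <= rules$seed_mismatch_max &
    tail_mm <= rules$tail_mismatch_max
  if (!any(keep)) return(empty)

  off <- which(keep)
  last_cols <- which(region == "last")
  tibble::tibble(
    start = off,
    end = off + L - 1L,
    seed_mm = as.integer(seed_total[off]),
    tail_mm = as.integer(tail_mm[off]),
    pos1_mismatch = mm[off, 1L],
    last_nt_unpaired = if (length(last_cols))
      rowSums(mm[off, last_cols, drop = FALSE]) > 0L else FALSE,
    validated = NA
  )
}

#' Scan many miRNAs against many transcripts
#'
#' Tidy wrapper over [scan_transcript()]: every (miRNA, transcript) pair is
#' scanned and the sites are stacked, sorted by transcript id, coordinate and
#' miRNA id. Overlapping sites are all reported; downstream degradome
#' evidence disambiguates.
#'
#' @param mirnas Tibble with columns `id`, `seq` (e.g. from
#'   [read_rna_fasta()]).
#' @param transcripts Tibble with columns `id`, `seq`.
#' @param rules A [target_rules()] object.
#' @return A site tibble with `mirna_id` and `transcript_id` prepended.
#' @export
scan_targets <- function(mirnas, transcripts, rules = target_rules()) {
  combos <- tidyr::expand_grid(mi = seq_len(nrow(mirnas)),
                               tx = seq_len(nrow(transcripts)))
  res <- purrr::pmap(combos, function(mi, tx) {
    sites <- scan_transcript(mirnas$seq[mi], transcripts$seq[tx], rules)
    if (nrow(sites) == 0L) return(NULL)
    dplyr::mutate(sites, mirna_id = mirnas$id[mi],
                  transcript_id = transcripts$id[tx], .before = 1L)
  })
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0L) {
    return(tibble::tibble(mirna_id = character(0), transcript_id = character(0),
                          start = integer(0), end = integer(0),
                          seed_mm = integer(0), tail_mm = integer(0),
                          pos1_mismatch = logical(0),
                          last_nt_unpaired = logical(0),
                          validated = logical(0)))
  }
  dplyr::arrange(out, .data$transcript_id, .data$start, .data$mirna_id)
}

#' Validate a candidate site with a duplex alignment
#'
#' Runs [duplex_align()] on the site window extended by 3 nt on each side
#' (clamped to the transcript) and re-checks the rule budgets on the duplex
#' states: G:U wobbles count as pairs (configurable), mismatch/bulge states
#' are charged to their miRNA regions (position 1 exempt under
#' `free_5prime`; the `unpaired_3prime` terminal positions exempt), at most
#' one bulge is tolerated in total, and miRNA positions 9-12 — the region
#' opposing the slicer catalytic centre — must all be paired.
#'
#' @param mirna miRNA sequence.
#' @param site_start,site_end 1-based inclusive site interval on the
#'   transcript (`site_end` pairs miRNA position 1).
#' @param transcript Transcript sequence.
#' @param rules A [target_rules()] object.
#' @param params A [duplex_params()] object.
#' @param flank Window extension in nt (default 3).
#' @param max_bulges Total bulge tolerance (default 1).
#' @param central Positions that must be paired (default 9:12).
#' @return A list with `validated` (logical), `duplex` (the `mirna_duplex`),
#'   and the per-region charge counts `seed_mm`, `tail_mm`, `n_bulges`.
#' @export
validate_site <- function(mirna, site_start, site_end, transcript,
                          rules = target_rules(), params = duplex_params(),
                          flank = 3L, max_bulges = 1L, central = 9:12) {
  mirna <- normalize_rna(mirna)
  transcript <- normalize_rna(transcript)
  L <- nchar(mirna)
  lo <- max(1L, site_start - flank)
  hi <- min(nchar(transcript), site_end + flank)
  window <- substr(transcript, lo, hi)
  dx <- duplex_align(mirna, window, params)

  paired_states <- c("paired_wc",
                     if (rules$gu_is_match_validation) "paired_gu")
  charge <- !(dx$states %in% paired_states)  # mismatch/bulge/unpaired charges
  region <- mirna_regions(L, rules)
  exempt <- region == "last" | (rules$free_5prime & region == "pos1")
  seed_mm <- sum(charge & region %in% c("seed", if (!rules$free_5prime) "pos1") &
                   !exempt)
  tail_mm <- sum(charge & region == "tail")
  n_bulges <- sum(dx$states == "bulged") + dx$target_bulges
  central <- central[central <= L]
  central_ok <- all(dx$states[central] %in% paired_states)

  validated <- seed_mm <= rules$seed_mismatch_max &&
    tail_mm <= rules$tail_mismatch_max &&
    n_bulges <= max_bulges &&
    central_ok
  list(validated = validated, duplex = dx,
       seed_mm = seed_mm, tail_mm = tail_mm, n_bulges = n_bulges,
       central_ok = central_ok)
}

#' Validate every site in a site table
#'
#' @param sites A site tibble from [scan_targets()] (or candidate homolog
#'   windows with the same columns).
#' @param mirnas Tibble with columns `id`, `seq`.
#' @param transcripts Tibble with columns `id`, `seq`.
#' @param rules,params,... Passed to [validate_site()].
#' @return `sites` with `validated` filled in and `duplex_score` appended.
#' @export
validate_sites <- function(sites, mirnas, transcripts,
                           rules = target_rules(), params = duplex_params(),
                           ...) {
  if (nrow(sites) == 0L) {
    return(dplyr::mutate(sites, duplex_score = numeric(0)))
  }
  mi_seq <- setNames(mirnas$seq, mirnas$id)
  tx_seq <- setNames(transcripts$seq, transcripts$id)
  res <- purrr::map(seq_len(nrow(sites)), function(r) {
    validate_site(mi_seq[[sites$mirna_id[r]]],
                  sites$start[r], sites$end[r],
                  tx_seq[[sites$transcript_id[r]]],
                  rules = rules, params = params, ...)
  })
  dplyr::mutate(sites,
                validated = purrr::map_lgl(res, "validated"),
                duplex_score = purrr::map_dbl(res, ~ .x$duplex$score))
}
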