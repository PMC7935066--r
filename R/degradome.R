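# Degradome (PARE) verification of predicted target sites. A degradome
# read's 5' end marks an endonucleolytic cleavage position; a site is
# verified when a read's 5' end sits exactly at the transcript nucleotide
# pairing miRNA position 10 — the 5' end of the 3' fragment left by
# Argonaute-mediated slicing between target positions opposite miRNA
# nucleotides 10 and 11.

#' Cleavage rule for degradome verification
#'
#' @param offset_nt The miRNA position whose pairing transcript nucleotide
#'   the supporting read's 5' end must hit (default 10, the slicer geometry).
#' @param require_exact Must the read 5' end hit the coordinate exactly?
#'   (default TRUE; FALSE tolerates +/- 1 nt, for sensitivity analysis only.)
#' @param min_supporting_reads Reads required to call a site verified
#'   (default 1).
#' @return A list of class `cleavage_rule`.
#' @export
cleavage_rule <- function(offset_nt = 10L, require_exact = TRUE,
                          min_supporting_reads = 1L) {
  stopifnot(offset_nt >= 1L, min_supporting_reads >= 1L)
  structure(list(offset_nt = as.integer(offset_nt),
                 require_exact = require_exact,
                 min_supporting_reads = as.integer(min_supporting_reads)),
            class = "cleavage_rule")
}

#' Map a degradome read's 5' end onto a transcript
#'
#' Returns every 1-based start coordinate at which the read matches the
#' transcript sense strand with at most `max_mismatch` mismatches. The
#' unique-best (ambiguity) policy is applied by the caller;
#' [map_degradome()] drops multi-mapping reads.
#'
#' @param read Read sequence (>= 10 nt).
#' @param transcript Transcript sequence.
#' @param max_mismatch Allowed mismatches (default 0).
#' @return Integer vector of 1-based start coordinates (possibly empty).
#' @export
map_read_5p <- function(read, transcript, max_mismatch = 0L) {
  read <- normalize_rna(read)
  transcript <- normalize_rna(transcript)
  if (nchar(read) < 10L) stop("read shorter than 10 nt")
  hits <- Biostrings::matchPattern(chartr("U", "T", read),
                                   chartr("U", "T", transcript),
                                   max.mismatch = max_mismatch)
  as.integer(BiocGenerics::start(hits))
}

#' Map a degradome read table across a transcriptome
#'
#' Maps every read against every transcript and keeps only reads with a
#' single best location over the whole transcriptome (ambiguous reads are
#' conservatively discarded before counting).
#'
#' @param reads Tibble with columns `read_id`, `seq`.
#' @param transcripts Tibble with columns `id`, `seq`.
#' @param max_mismatch Allowed mismatches (default 0).
#' @return A tibble (`read_id`, `transcript_id`, `pos5p`), one row per
#'   uniquely mapped read.
#' @export
map_degradome <- function(reads, transcripts, max_mismatch = 0L) {
  hits <- purrr::map(seq_len(nrow(reads)), function(r) {
    per_tx <- purrr::map(seq_len(nrow(transcripts)), function(t) {
      pos <- map_read_5p(reads$seq[r], transcripts$seq[t], max_mismatch)
      if (length(pos) == 0L) return(NULL)
      tibble::tibble(read_id = reads$read_id[r],
                     transcript_id = transcripts$id[t], pos5p = pos)
    })
    out <- dplyr::bind_rows(per_tx)
    if (nrow(out) == 1L) out else NULL   # drop unmapped and ambiguous
  })
  out <- dplyr::bind_rows(hits)
  if (nrow(out) == 0L) {
    return(tibble::tibble(read_id = character(0), transcript_id = character(0),
                          pos5p = integer(0)))
  }
  out
}

#' Verify target sites with degradome cleavage evidence
#'
#' For each site, the supported cleavage coordinate is the transcript
#' nucleotide pairing miRNA position `offset_nt`: with `end` the 1-based
#' coordinate pairing miRNA position 1, that is `end - (offset_nt - 1)`. A
#' mapped read supports the site when its 5' end equals that coordinate
#' (exactly, under `require_exact`); the site is verified when the number of
#' distinct supporting read positions' total count reaches
#' `min_supporting_reads`.
#'
#' @param sites Site tibble (needs `transcript_id`, `start`, `end`).
#' @param read_positions Mapped-read tibble from [map_degradome()]
#'   (`transcript_id`, `pos5p`).
#' @param rule A [cleavage_rule()] object.
#' @return `sites` with `cleavage_pos`, `n_supporting` and `verified`
#'   appended.
#' @export
verify_sites <- function(sites, read_positions, rule = cleavage_rule()) {
  if (nrow(sites) == 0L) {
    return(dplyr::mutate(sites, cleavage_pos = integer(0),
                         n_supporting = integer(0), verified = logical(0)))
  }
  cleave <- sites$end - (rule$offset_nt - 1L)
  n_sup <- purrr::map_int(seq_len(nrow(sites)), function(r) {
    pos <- read_positions$pos5p[
      read_positions$transcript_id == sites$transcript_id[r]]
    if (rule$require_exact) {
      sum(pos == cleave[r])
    } else {
      sum(abs(pos - cleave[r]) <= 1L)
    }
  })
  dplyr::mutate(sites,
                cleavage_pos = as.integer(cleave),
                n_supporting = n_sup,
                verified = n_sup >= rule$min_supporting_reads)
}
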