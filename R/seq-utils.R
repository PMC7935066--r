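# Sequence primitives shared by every module. All internal sequence handling
# is RNA over {A,C,G,U}; T is accepted on input and mapped to U.

RNA_LETTERS <- c("A", "C", "G", "U")

# Pairing relations. Watson-Crick only (mapper semantics) vs. WC + G:U wobble
# (thermodynamic semantics, used in folding and duplex validation).
WC_PARTNER <- c(A = "U", C = "G", G = "C", U = "A")

#' Normalise a nucleotide sequence to uppercase RNA
#'
#' Accepts DNA or RNA input in either case; `T` is mapped to `U`. Any other
#' letter is an error: the pipeline's matching rules are only defined over
#' the four unambiguous bases.
#'
#' @param seq Character vector of sequences.
#' @return Character vector of uppercase RNA sequences.
#' @export
#' @examples
#' normalize_rna("acgt")
normalize_rna <- function(seq) {
  out <- chartr("tT", "uU", seq)
  out <- toupper(out)
  bad <- grepl("[^ACGU]", out)
  if (any(bad)) {
    stop("non-RNA letters in sequence(s): ",
         paste(utils::head(which(bad), 3L), collapse = ", "))
  }
  out
}

#' Reverse complement of an RNA sequence
#'
#' @param seq Character vector of RNA (or DNA) sequences.
#' @return Character vector of reverse-complemented RNA sequences.
#' @export
#' @examples
#' revcomp_rna("AAGCU")
revcomp_rna <- function(seq) {
  seq <- normalize_rna(seq)
  vapply(seq, function(s) {
    chars <- rev(strsplit(s, "", fixed = TRUE)[[1L]])
    paste(WC_PARTNER[chars], collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

# split to character vector
seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1L]]

# TRUE when a:b is a Watson-Crick pair
is_wc_pair <- function(a, b) WC_PARTNER[a] == b

# TRUE when a:b is WC or G:U wobble
is_fold_pair <- function(a, b) {
  (WC_PARTNER[a] == b) | (a == "G" & b == "U") | (a == "U" & b == "G")
}

#' Read sequences from a FASTA file as a tibble
#'
#' Thin wrapper over [Biostrings::readBStringSet()]; sequences are normalised
#' to RNA (`T` mapped to `U`).
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` (first whitespace-delimited token of the
#'   header) and `seq`.
#' @export
read_rna_fasta <- function(path) {
  set <- tryCatch(Biostrings::readBStringSet(path), error = function(e) {
    stop("failed to parse FASTA file '", path, "': ", conditionMessage(e),
         call. = FALSE)
  })
  ids <- sub("\\s.*$", "", names(set))
  tibble::tibble(id = ids, seq = normalize_rna(as.character(set)))
}

#' Write sequences to a FASTA file
#'
#' @param x A data frame with columns `id` and `seq`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rna_fasta <- function(x, path) {
  stopifnot(all(c("id", "seq") %in% names(x)))
  lines <- as.vector(rbind(paste0(">", x$id), x$seq))
  writeLines(lines, path)
  invisible(path)
}

#' Parse a dot-bracket secondary structure
#'
#' @param db Dot-bracket string (`(`, `)`, `.` only).
#' @return Integer pair table: `pt[i]` is the 1-based partner of position `i`,
#'   or `NA` when unpaired.
#' @export
#' @examples
#' parse_dotbracket("(((...)))")
parse_dotbracket <- function(db) {
  chars <- seq_chars(db)
  if (!all(chars %in% c("(", ")", "."))) stop("invalid dot-bracket characters")
  n <- length(chars)
  pt <- rep(NA_integer_, n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (length(stack) == 0L) stop("unbalanced dot-bracket string")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j
      pt[j] <- i
    }
  }
  if (length(stack) > 0L) stop("unbalanced dot-bracket string")
  pt
}

# pair table -> dot-bracket
pairs_to_dotbracket <- function(pt) {
  out <- rep(".", length(pt))
  paired <- which(!is.na(pt))
  out[paired[pt[paired] > paired]] <- "("
  out[paired[pt[paired] < paired]] <- ")"
  paste(out, collapse = "")
}
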