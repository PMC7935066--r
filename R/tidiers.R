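# broom-style tidiers for the package's result objects.

#' Tidy an RNA fold into per-position rows
#'
#' @param x An `rna_fold` from [fold_nussinov()].
#' @param ... Unused.
#' @return A tibble (`position`, `letter`, `partner`, `paired`).
#' @export
tidy.rna_fold <- function(x, ...) {
  chars <- seq_chars(x$seq)
  tibble::tibble(position = seq_along(chars), letter = chars,
                 partner = x$pair_table,
                 paired = !is.na(x$pair_table))
}

#' @rdname tidy.rna_fold
#' @return For `glance()`: a one-row tibble (`length`, `pair_count`,
#'   `structure`).
#' @export
glance.rna_fold <- function(x, ...) {
  tibble::tibble(length = nchar(x$seq), pair_count = x$pair_count,
                 structure = x$structure)
}

#' Tidy a miRNA:target duplex into per-position states
#'
#' @param x A `mirna_duplex` from [duplex_align()].
#' @param ... Unused.
#' @return A tibble (`position`, `letter`, `state`).
#' @export
tidy.mirna_duplex <- function(x, ...) {
  tibble::tibble(position = seq_along(x$states),
                 letter = seq_chars(x$mirna),
                 state = x$states)
}

#' @rdname tidy.mirna_duplex
#' @export
glance.mirna_duplex <- function(x, ...) {
  tab <- table(factor(x$states, levels = c("paired_wc", "paired_gu",
                                           "mismatch", "bulged",
                                           "unpaired_end")))
  tibble::tibble(score = x$score,
                 n_wc = as.integer(tab[["paired_wc"]]),
                 n_gu = as.integer(tab[["paired_gu"]]),
                 n_mismatch = as.integer(tab[["mismatch"]]),
                 n_bulged = as.integer(tab[["bulged"]]),
                 n_unpaired_end = as.integer(tab[["unpaired_end"]]))
}

#' Tidy a position frequency matrix
#'
#' @param x A `mirna_pfm` from [position_bias()].
#' @param ... Unused.
#' @return A long tibble (`position`, `letter`, `freq`, `information`,
#'   `coverage`).
#' @export
tidy.mirna_pfm <- function(x, ...) {
  L <- ncol(x$freq)
  tibble::tibble(
    position = rep(seq_len(L), each = 4L),
    letter = rep(RNA_LETTERS, L),
    freq = as.vector(x$freq),
    information = rep(x$information, each = 4L),
    coverage = rep(as.integer(x$coverage), each = 4L)
  )
}

#' @rdname tidy.mirna_pfm
#' @export
glance.mirna_pfm <- function(x, ...) {
  tibble::tibble(n_positions = ncol(x$freq),
                 mean_information = mean(x$information),
                 max_information = max(x$information),
                 max_information_position = which.max(x$information))
}

#' Tidy a Dollo reconstruction into per-node rows
#'
#' @param x A `dollo_recon` from [dollo_reconstruct()].
#' @param ... Unused.
#' @return A tibble (`node`, `node_label`, `n_gains`, `n_losses`,
#'   `n_present`), one row per tree node.
#' @export
tidy.dollo_recon <- function(x, ...) {
  gains <- dplyr::count(x$gains, .data$node, name = "n_gains")
  losses <- dplyr::count(x$losses, .data$node, name = "n_losses")
  out <- dplyr::left_join(x$shared, gains, by = "node")
  out <- dplyr::left_join(out, losses, by = "node")
  dplyr::mutate(out,
                n_gains = dplyr::coalesce(.data$n_gains, 0L),
                n_losses = dplyr::coalesce(.data$n_losses, 0L))
}

#' @rdname tidy.dollo_recon
#' @export
glance.dollo_recon <- function(x, ...) {
  tibble::tibble(n_families = length(x$families),
                 total_gains = nrow(x$gains),
                 total_losses = nrow(x$losses))
}

#' Tidy an ungapped mature-miRNA alignment
#'
#' @param x A `mirna_alignment` from [align_orthologs()].
#' @param ... Unused.
#' @return A tibble (`name`, `offset`, `identity`, `seq`).
#' @export
tidy.mirna_alignment <- function(x, ...) {
  tibble::tibble(name = names(x$seqs), offset = unname(x$offsets),
                 identity = unname(x$identity), seq = unname(x$seqs))
}

#' Summarise a curation audit table
#'
#' @param x A `mirna_audit` from [curate_mirnas()].
#' @param ... Unused.
#' @return A one-row tibble: candidate and bona fide counts plus
#'   per-criterion failure counts.
#' @export
glance.mirna_audit <- function(x, ...) {
  crit <- grep("^pass_", names(x), value = TRUE)
  fails <- vapply(crit, function(cn) sum(!x[[cn]], na.rm = TRUE), integer(1L))
  names(fails) <- sub("^pass_", "fail_", crit)
  dplyr::bind_cols(
    tibble::tibble(n_candidates = nrow(x),
                   n_bona_fide = sum(x$bona_fide)),
    tibble::as_tibble_row(as.list(fails))
  )
}
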