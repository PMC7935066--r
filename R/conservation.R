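# Cross-species layer: reciprocal-best-hit orthology, category I/II/III
# target classification, site-region and site-location annotation,
# substitution counting over ortholog alignments, position bias statistics,
# Dollo parsimony gain/loss reconstruction and miRNA turnover rates.

rna_to_dna_set <- function(seqs, ids) {
  x <- Biostrings::DNAStringSet(chartr("Uu", "Tt", seqs))
  names(x) <- ids
  x
}

#' Alignment scoring for orthology detection
#'
#' @param match,mismatch Substitution scores (defaults +2 / -1).
#' @param gap_open,gap_extend Gap penalties, given as positive costs
#'   (defaults 5 and 2, the convention of [Biostrings::pairwiseAlignment()]).
#' @return A list of class `rbh_scoring`.
#' @export
rbh_scoring <- function(match = 2, mismatch = -1, gap_open = 5,
                        gap_extend = 2) {
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "rbh_scoring")
}

# |A| x |B| local-alignment score matrix
local_score_matrix <- function(seqs_a, seqs_b, scoring) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = scoring$match, mismatch = scoring$mismatch, baseOnly = TRUE)
  a_set <- rna_to_dna_set(seqs_a, seq_along(seqs_a))
  out <- matrix(0, length(seqs_a), length(seqs_b))
  for (j in seq_along(seqs_b)) {
    out[, j] <- Biostrings::pairwiseAlignment(
      a_set, chartr("Uu", "Tt", seqs_b[j]), type = "local",
      substitutionMatrix = mat, gapOpening = scoring$gap_open,
      gapExtension = scoring$gap_extend, scoreOnly = TRUE)
  }
  out
}

#' Reciprocal best hits between two transcript sets
#'
#' Scores every cross-species pair by local alignment, takes the best hit
#' per query in each direction (ties broken toward the lexicographically
#' smaller id, and recorded), and marks pairs whose bests agree both ways as
#' reciprocal — the standard operational proxy for orthology.
#'
#' @param transcriptome_a,transcriptome_b Tibbles with columns `id`, `seq`.
#' @param scoring An [rbh_scoring()] object.
#' @param hits Optional precomputed tabular hits (columns `id_a`, `id_b`,
#'   `score_ab`, `score_ba`), e.g. from an external aligner run in both
#'   directions; when supplied, alignment is skipped.
#' @return A tibble (`id_a`, `id_b`, `score_ab`, `score_ba`, `reciprocal`,
#'   `tie`), one row per id_a with its best hit.
#' @export
reciprocal_best_hits <- function(transcriptome_a, transcriptome_b,
                                 scoring = rbh_scoring(), hits = NULL) {
  stopifnot(nrow(transcriptome_a) > 0L, nrow(transcriptome_b) > 0L)
  ids_a <- transcriptome_a$id
  ids_b <- transcriptome_b$id
  if (is.null(hits)) {
    S <- local_score_matrix(transcriptome_a$seq, transcriptome_b$seq, scoring)
  } else {
    S <- matrix(NA_real_, length(ids_a), length(ids_b),
                dimnames = list(ids_a, ids_b))
    S[cbind(match(hits$id_a, ids_a), match(hits$id_b, ids_b))] <- hits$score_ab
    S[is.na(S)] <- -Inf
  }
  ord_a <- order(ids_a)
  ord_b <- order(ids_b)

  best_of_row <- function(i) {
    v <- S[i, ]
    cand <- which(v == max(v))
    list(j = cand[order(ids_b[cand])][1L], tie = length(cand) > 1L)
  }
  best_of_col <- function(j) {
    v <- S[, j]
    cand <- which(v == max(v))
    cand[order(ids_a[cand])][1L]
  }
  rows <- purrr::map(seq_along(ids_a), function(i) {
    br <- best_of_row(i)
    j <- br$j
    bc <- best_of_col(j)
    tibble::tibble(id_a = ids_a[i], id_b = ids_b[j],
                   score_ab = S[i, j], score_ba = S[bc, j],
                   reciprocal = bc == i, tie = br$tie)
  })
  dplyr::bind_rows(rows)
}

#' Project a coordinate from one transcript onto an ortholog
#'
#' Globally aligns the two transcripts and walks the alignment to find the
#' partner coordinate; positions opposite a gap project to the nearest
#' aligned position to the left.
#'
#' @param transcript_a,transcript_b Sequences.
#' @param pos 1-based coordinate(s) on `transcript_a`.
#' @param scoring An [rbh_scoring()] object.
#' @param min_score Alignment-score floor; below it the pair is declared
#'   unalignable and `NA` is returned.
#' @return Integer vector of projected 1-based coordinates on
#'   `transcript_b` (`NA` when unalignable).
#' @export
project_coordinate <- function(transcript_a, transcript_b, pos,
                               scoring = rbh_scoring(), min_score = 0) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = scoring$match, mismatch = scoring$mismatch, baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    chartr("Uu", "Tt", transcript_a), chartr("Uu", "Tt", transcript_b),
    type = "global", substitutionMatrix = mat,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
  if (Biostrings::score(aln) < min_score) return(rep(NA_integer_, length(pos)))
  pa <- seq_chars(as.character(Biostrings::alignedPattern(aln)))
  pb <- seq_chars(as.character(Biostrings::alignedSubject(aln)))
  ia <- cumsum(pa != "-")
  ib <- cumsum(pb != "-")
  vapply(pos, function(p) {
    cols <- which(ia == p & pa != "-")
    if (length(cols) == 0L) return(NA_integer_)
    col <- cols[1L]
    b <- ib[col]
    if (b == 0L) 1L else as.integer(b)
  }, integer(1L))
}

#' Classify conservation of verified miRNA-target pairs across species
#'
#' For each verified reference (miRNA, target) pair with a reciprocal
#' homolog in the other species:
#' * **I** (conserved) — the same miRNA family is present in the other
#'   repertoire and has a validated site on the homolog;
#' * **II** (shared) — a different miRNA has a validated site on the homolog
#'   and the reference miRNA family is absent from the other repertoire;
#' * **III** — a candidate site exists on the homolog but failed duplex
#'   validation;
#' * **none** otherwise (including targets without a reciprocal homolog,
#'   with reason `no_homolog`).
#'
#' @param reference_records Tibble of verified reference pairs: columns
#'   `mirna` (family label), `transcript_id`.
#' @param rbh Tibble from [reciprocal_best_hits()] with `id_a` = reference
#'   transcripts; only `reciprocal` rows are used.
#' @param other_sites Site tibble on the other species' transcripts with
#'   columns `mirna` (family), `transcript_id`, `validated` — validated and
#'   failed candidates both (failed candidates are category III feedstock).
#' @param other_repertoire Character vector of miRNA family labels detected
#'   in the other species.
#' @return A tibble (`mirna`, `transcript_id`, `homolog_id`, `category`,
#'   `reason`), one row per reference record; `category` is a factor over
#'   I/II/III/none.
#' @export
classify_conservation <- function(reference_records, rbh, other_sites,
                                  other_repertoire) {
  rbh_ok <- rbh[rbh$reciprocal, , drop = FALSE]
  homolog_of <- setNames(rbh_ok$id_b, rbh_ok$id_a)
  rows <- purrr::map(seq_len(nrow(reference_records)), function(r) {
    fam <- reference_records$mirna[r]
    tx <- reference_records$transcript_id[r]
    hom <- homolog_of[tx]
    if (is.na(hom)) {
      return(tibble::tibble(mirna = fam, transcript_id = tx,
                            homolog_id = NA_character_,
                            category = "none", reason = "no_homolog"))
    }
    on_hom <- other_sites[other_sites$transcript_id == hom, , drop = FALSE]
    same_valid <- any(on_hom$validated & on_hom$mirna == fam &
                        fam %in% other_repertoire)
    other_valid <- any(on_hom$validated & on_hom$mirna != fam)
    any_candidate <- nrow(on_hom) > 0L
    category <- if (same_valid) "I"
      else if (other_valid && !(fam %in% other_repertoire)) "II"
      else if (any_candidate) "III"
      else "none"
    tibble::tibble(mirna = fam, transcript_id = tx, homolog_id = unname(hom),
                   category = category, reason = NA_character_)
  })
  out <- dplyr::bind_rows(rows)
  out$category <- factor(out$category, levels = c("I", "II", "III", "none"))
  out
}

#' Annotate the transcript region of a target site
#'
#' @param site_start,site_end 1-based inclusive site interval.
#' @param cds_start,cds_end 1-based inclusive CDS interval on the same
#'   transcript (`NA` allowed).
#' @return `"5'UTR"` (site entirely upstream of the CDS), `"3'UTR"` (site
#'   entirely downstream), `"CDS"` (any overlap — coding-sequence constraint
#'   is the biologically meaningful case), or `"unknown"` when the CDS is
#'   unannotated. Vectorised.
#' @export
annotate_site_region <- function(site_start, site_end, cds_start, cds_end) {
  dplyr::case_when(
    is.na(cds_start) | is.na(cds_end) ~ "unknown",
    site_end < cds_start ~ "5'UTR",
    site_start > cds_end ~ "3'UTR",
    TRUE ~ "CDS"
  )
}

#' Is a target site's location conserved between orthologs?
#'
#' TRUE when the two sites sit in the same transcript region and the
#' midpoint of the reference site, projected through a global alignment of
#' the two transcripts, lies within `tolerance` nucleotides of the other
#' site's midpoint — i.e. the binding site keeps its location, with the
#' projection absorbing indels elsewhere in the transcript.
#'
#' @param site_a,site_b Lists/rows with `start`, `end` (1-based inclusive).
#' @param transcript_a,transcript_b The (RBH-partner) transcript sequences.
#' @param region_a,region_b Region labels (see [annotate_site_region()]);
#'   pass `"unknown"` for both to skip the region check.
#' @param tolerance Midpoint distance tolerance in nt (default 30).
#' @param scoring,min_score Passed to [project_coordinate()].
#' @return A list with `conserved` (logical) and `reason`.
#' @export
site_location_conserved <- function(site_a, site_b, transcript_a,
                                    transcript_b,
                                    region_a = "unknown",
                                    region_b = "unknown",
                                    tolerance = 30L,
                                    scoring = rbh_scoring(),
                                    min_score = 0) {
  if (!identical(region_a, region_b)) {
    return(list(conserved = FALSE, reason = "region_mismatch"))
  }
  mid_a <- (site_a$start + site_a$end) %/% 2L
  mid_b <- (site_b$start + site_b$end) %/% 2L
  proj <- project_coordinate(transcript_a, transcript_b, mid_a,
                             scoring = scoring, min_score = min_score)
  if (is.na(proj)) {
    return(list(conserved = FALSE, reason = "unalignable"))
  }
  list(conserved = abs(proj - mid_b) <= tolerance, reason = NA_character_)
}

#' Ungapped offset alignment of orthologous mature miRNAs
#'
#' Assigns every sequence the integer 5'-end offset (within
#' `[-max_offset, max_offset]`) that maximises identity with the reference
#' sequence over their overlap — enough to expose the characteristic 1-nt
#' shifts between homologous matures without a full gapped alignment.
#'
#' @param matures Named character vector of mature sequences (>= 2).
#' @param reference Name (or index) of the reference sequence (default the
#'   first).
#' @param max_offset Maximum |offset| in nt (default 2).
#' @return An object of class `mirna_alignment`: list with `seqs`, `offsets`
#'   (named integer vector; offset o means the sequence's position 1 sits at
#'   reference position 1 + o), `identity` (fraction vs reference over the
#'   overlap).
#' @export
align_orthologs <- function(matures, reference = 1L, max_offset = 2L) {
  stopifnot(length(matures) >= 2L)
  matures <- normalize_rna(matures)
  if (is.null(names(matures))) {
    names(matures) <- paste0("seq", seq_along(matures))
  }
  ref <- matures[[reference]]
  rc <- seq_chars(ref)
  offs <- integer(length(matures))
  idents <- numeric(length(matures))
  for (k in seq_along(matures)) {
    sc <- seq_chars(matures[[k]])
    best_off <- 0L; best_ident <- -1
    for (o in -max_offset:max_offset) {
      # sequence position i sits at reference position i + o
      i0 <- max(1L, 1L - o); i1 <- min(length(sc), length(rc) - o)
      if (i1 < i0) next
      ident <- mean(sc[i0:i1] == rc[(i0:i1) + o])
      if (ident > best_ident ||
          (ident == best_ident && abs(o) < abs(best_off))) {
        best_ident <- ident; best_off <- o
      }
    }
    offs[k] <- best_off; idents[k] <- best_ident
  }
  names(offs) <- names(matures); names(idents) <- names(matures)
  structure(list(seqs = matures, offsets = offs, identity = idents,
                 reference = names(matures)[[if (is.numeric(reference))
                   reference else match(reference, names(matures))]]),
            class = "mirna_alignment")
}

# matrix of aligned columns (reference coordinates); NA outside a sequence
alignment_matrix <- function(alignment) {
  seqs <- alignment$seqs; offs <- alignment$offsets
  lens <- nchar(seqs)
  span <- range(c(1L + offs, lens + offs))
  ncol <- span[2L] - span[1L] + 1L
  mat <- matrix(NA_character_, length(seqs), ncol)
  for (k in seq_along(seqs)) {
    sc <- seq_chars(seqs[[k]])
    cols <- (seq_along(sc) + offs[k]) - span[1L] + 1L
    mat[k, cols] <- sc
  }
  rownames(mat) <- names(seqs)
  mat
}

#' Count substitutions over an ortholog alignment
#'
#' Two counting conventions are provided because neither is canonical:
#' `distinct_minus_one` counts, per column, the number of distinct
#' nucleotides minus one (the minimum number of changes under a star
#' phylogeny); `non_modal_count` counts the sequences differing from the
#' plurality nucleotide. Only columns covered by every sequence are counted.
#'
#' @param alignment A `mirna_alignment` from [align_orthologs()], or a list
#'   of such (multi-family input: totals are summed over families).
#' @param mode `"distinct_minus_one"` (default) or `"non_modal_count"`.
#' @return A tibble (`position`, `substitutions`) with attribute `total`;
#'   for multi-family input positions are per-family columns stacked with a
#'   `family` column and `total` is the grand total.
#' @export
count_substitutions <- function(alignment,
                                mode = c("distinct_minus_one",
                                         "non_modal_count")) {
  mode <- match.arg(mode)
  if (inherits(alignment, "mirna_alignment")) {
    mat <- alignment_matrix(alignment)
    full <- colSums(is.na(mat)) == 0L
    counts <- apply(mat[, full, drop = FALSE], 2L, function(col) {
      if (mode == "distinct_minus_one") length(unique(col)) - 1L
      else sum(col != names(which.max(table(col)))[1L])
    })
    out <- tibble::tibble(position = which(full),
                          substitutions = as.integer(counts))
    attr(out, "total") <- sum(counts)
    return(out)
  }
  # list of alignments: one family per element
  parts <- purrr::imap(alignment, function(a, nm) {
    p <- count_substitutions(a, mode = mode)
    dplyr::mutate(p, family = as.character(nm), .before = 1L)
  })
  out <- dplyr::bind_rows(parts)
  attr(out, "total") <- sum(out$substitutions)
  out
}

#' Per-position nucleotide frequencies and information content
#'
#' Builds a position frequency matrix over \{A,C,G,U\} from a set of mature
#' sequences (ragged 3' ends allowed: each column is normalised by its
#' coverage) and the per-column information content `2 - H` in bits, the
#' quantity a sequence logo displays. An invariant column carries 2 bits; a
#' uniform column 0.
#'
#' @param matures Character vector of mature sequences.
#' @return An object of class `mirna_pfm`: list with `freq` (4 x L matrix,
#'   columns sum to 1), `coverage` (sequences covering each position) and
#'   `information` (bits per position).
#' @export
position_bias <- function(matures) {
  stopifnot(length(matures) >= 1L)
  matures <- normalize_rna(matures)
  L <- max(nchar(matures))
  counts <- matrix(0L, 4L, L, dimnames = list(RNA_LETTERS, NULL))
  for (s in matures) {
    sc <- seq_chars(s)
    for (i in seq_along(sc)) counts[sc[i], i] <- counts[sc[i], i] + 1L
  }
  coverage <- colSums(counts)
  freq <- sweep(counts, 2L, pmax(coverage, 1L), "/")
  info <- apply(freq, 2L, function(p) {
    p <- p[p > 0]
    2 - sum(-p * log2(p))
  })
  structure(list(freq = freq, coverage = coverage, information = info),
            class = "mirna_pfm")
}

#' Dollo parsimony reconstruction of miRNA gains and losses
#'
#' Under Dollo parsimony each miRNA family is gained exactly once — at the
#' most recent common ancestor of the species possessing it — and may be
#' lost repeatedly. A family is present at an internal node when the node
#' lies within the gain clade and at least one of its descendants possesses
#' the family; losses are the edges where presence ends.
#'
#' @param presence Logical/0-1 matrix, rows = miRNA families, columns =
#'   species (the shape of a presence/absence supplementary table), or a
#'   data frame of the same shape.
#' @param tree A rooted `phylo` tree (e.g. [ape::read.tree()]) whose tip
#'   labels cover the matrix columns.
#' @return An object of class `dollo_recon`: list with `gains` (tibble
#'   `family`, `node`, `node_label`), `losses` (tibble `family`, `node`,
#'   `node_label` — the child end of each loss edge), `shared` (tibble
#'   `node`, `node_label`, `n_present` for every node), and `tree`. Families
#'   absent everywhere are skipped with a warning.
#' @export
dollo_reconstruct <- function(presence, tree) {
  presence <- as.matrix(presence)
  mode(presence) <- "logical"
  if (!all(colnames(presence) %in% tree$tip.label)) {
    stop("presence matrix has species missing from the tree")
  }
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  node_label <- c(tree$tip.label,
                  if (!is.null(tree$node.label) &&
                      length(tree$node.label) == tree$Nnode &&
                      all(nzchar(tree$node.label))) tree$node.label
                  else paste0("node_", (n_tip + 1L):n_node))

  # tip sets per node
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  tips_below <- vector("list", n_node)
  for (i in seq_len(n_tip)) tips_below[[i]] <- i
  fill <- function(node) {
    if (!is.null(tips_below[[node]])) return(tips_below[[node]])
    res <- unlist(lapply(kids[[as.character(node)]], fill))
    tips_below[[node]] <<- res
    res
  }
  root <- setdiff(tree$edge[, 1L], tree$edge[, 2L])[1L]
  fill(root)
  ancestors <- function(node) {
    out <- node
    repeat {
      parent <- tree$edge[tree$edge[, 2L] == node, 1L]
      if (length(parent) == 0L) break
      out <- c(out, parent)
      node <- parent
    }
    out
  }

  empty <- rownames(presence)[rowSums(presence) == 0L]
  if (length(empty) > 0L) {
    warning("families absent from every species skipped: ",
            paste(empty, collapse = ", "))
    presence <- presence[rowSums(presence) > 0L, , drop = FALSE]
  }

  gains <- list(); losses <- list()
  present_at <- matrix(FALSE, nrow(presence), n_node)
  for (f in seq_len(nrow(presence))) {
    tips <- match(colnames(presence)[presence[f, ]], tree$tip.label)
    gain <- if (length(tips) == 1L) tips else ape::getMRCA(tree, tips)
    clade <- c(gain,
               if (gain > n_tip) unlist(lapply(
                 setdiff(seq_len(n_node), gain),
                 function(nd) if (gain %in% ancestors(nd)) nd else NULL)))
    clade <- unique(clade)
    has_possessor <- vapply(clade, function(nd)
      any(tips_below[[nd]] %in% tips), logical(1L))
    present <- clade[has_possessor]
    present_at[f, present] <- TRUE
    gains[[length(gains) + 1L]] <-
      tibble::tibble(family = rownames(presence)[f], node = as.integer(gain),
                     node_label = node_label[gain])
    # loss edges: parent present, child in clade, child absent
    loss_children <- tree$edge[
      present_at[f, tree$edge[, 1L]] &
        tree$edge[, 2L] %in% clade &
        !present_at[f, tree$edge[, 2L]], 2L]
    if (length(loss_children) > 0L) {
      losses[[length(losses) + 1L]] <-
        tibble::tibble(family = rownames(presence)[f],
                       node = as.integer(loss_children),
                       node_label = node_label[loss_children])
    }
  }
  shared <- tibble::tibble(
    node = seq_len(n_node),
    node_label = node_label,
    n_present = as.integer(colSums(present_at))
  )
  structure(list(gains = dplyr::bind_rows(gains),
                 losses = dplyr::bind_rows(losses),
                 shared = shared, tree = tree,
                 families = rownames(presence)),
            class = "dollo_recon")
}

#' miRNA turnover rate between two repertoires
#'
#' The number of miRNA families private to either repertoire (gains plus
#' losses since the split), divided by the divergence-time window, in
#' families per million years. The window bounds map inversely:
#' the older divergence bound gives the lower rate.
#'
#' @param repertoire_a,repertoire_b Character vectors of miRNA family
#'   labels.
#' @param t_min,t_max Divergence window in Myr (`0 < t_min <= t_max`).
#' @param per_lineage Divide by 2 to express the rate per lineage rather
#'   than over both branches jointly? (default FALSE)
#' @return A one-row tibble: `d` (symmetric difference), `rate_low`
#'   (`d / t_max`), `rate_high` (`d / t_min`).
#' @export
turnover_rate <- function(repertoire_a, repertoire_b, t_min, t_max,
                          per_lineage = FALSE) {
  stopifnot(t_min > 0, t_max >= t_min)
  d <- length(setdiff(repertoire_a, repertoire_b)) +
    length(setdiff(repertoire_b, repertoire_a))
  div <- if (per_lineage) 2 else 1
  tibble::tibble(d = as.integer(d),
                 rate_low = d / t_max / div,
                 rate_high = d / t_min / div)
}
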