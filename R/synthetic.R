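# Synthetic-data generators. Every input the pipeline consumes can be
# generated here with ground truth known by construction: hairpin precursors
# with configurable duplex overhangs, read stacks with a tunable 5'-homogeneity
# fraction, transcriptomes with target sites planted at specified per-region
# mismatch budgets, degradome reads marking planted cleavage positions,
# ortholog transcript pairs, and mature-miRNA families with known per-position
# substitution counts. All generators are deterministic given `seed`.
#
# Coordinates in all generator outputs are 1-based inclusive, the package-wide
# human-facing convention (0-based half-open appears only in BED export).

# a letter that forms neither a WC nor a G:U pair with anything in `avoid`
pick_nonpairing <- function(avoid) {
  partners <- function(a) switch(a, A = "U", C = "G", G = c("C", "U"),
                                 U = c("A", "G"))
  banned <- unique(unlist(lapply(avoid, partners)))
  ok <- setdiff(RNA_LETTERS, banned)
  if (length(ok) == 0L) "A" else ok[1L]
}

# a letter that pairs (WC or GU) with none of `against` and differs from `not`
mismatch_letter <- function(mirna_nt, not) {
  partners <- switch(mirna_nt, A = "U", C = "G", G = c("C", "U"),
                     U = c("A", "G"))
  ok <- setdiff(RNA_LETTERS, c(partners, not))
  ok[1L]
}

#' Generate a random RNA sequence
#'
#' @param n Length in nucleotides.
#' @param seed Integer seed.
#' @param first Optional fixed first letter (e.g. `"U"` for a miRNA-like
#'   5' bias).
#' @return A character scalar.
#' @export
random_rna <- function(n, seed, first = NULL) {
  with_seed(seed, {
    chars <- sample(RNA_LETTERS, n, replace = TRUE)
    if (!is.null(first)) chars[1L] <- first
    paste(chars, collapse = "")
  })
}

#' Construct a hairpin precursor with a prescribed duplex geometry
#'
#' Builds a precursor as 5' arm (the mature strand), a terminal loop, and a
#' 3' arm (the star strand) that is the reverse complement of the first
#' `length(mature) - star_3p_overhang` mature nucleotides followed by
#' `star_3p_overhang` non-pairing tail nucleotides. By construction,
#' [duplex_geometry()] on the recorded structure reports exactly
#' `star_3p_overhang` nucleotides of star 3' overhang and
#' `length(mature) - star_3p_overhang` mature/star base pairs — the geometry
#' the Drosha/Dicer 2-nt-overhang criterion inspects. Loop and tail letters
#' are chosen not to pair with the flanking mature letters so that folding
#' the sequence de novo recovers the same geometry.
#'
#' @param mature Mature miRNA sequence (>= 16 nt).
#' @param loop_len Terminal loop length (>= 3 nt).
#' @param star_3p_overhang Star-strand 3' overhang in nt (0 = blunt).
#' @param seed Integer seed.
#' @param id Candidate id.
#' @param species Species label.
#' @return A one-row candidate tibble (columns `id`, `species`, `precursor`,
#'   `structure`, `mature_start`, `mature_end`, `star_start`, `star_end`,
#'   `score`), coordinates 1-based inclusive on the precursor.
#' @export
make_hairpin <- function(mature, loop_len = 8L, star_3p_overhang = 2L,
                         seed = 1L, id = "hairpin-1", species = "synthetic") {
  mature <- normalize_rna(mature)
  m <- nchar(mature)
  if (m < 16L) stop("mature must be >= 16 nt")
  if (loop_len < 3L) stop("loop_len < 3: hairpin would be unfoldable")
  if (star_3p_overhang < 0L || star_3p_overhang >= m) {
    stop("star_3p_overhang must be in [0, mature length)")
  }
  k <- as.integer(star_3p_overhang)
  mc <- seq_chars(mature)
  star_core <- revcomp_rna(substr(mature, 1L, m - k))
  loop_letter <- pick_nonpairing(mc[max(1L, m - k - 1L):(m - k)])
  tail_letter <- pick_nonpairing(mc[1L:min(m, 2L)])
  precursor <- paste0(mature, strrep(loop_letter, loop_len),
                      star_core, strrep(tail_letter, k))
  n <- nchar(precursor)

  pt <- rep(NA_integer_, n)
  for (i in seq_len(m - k)) {
    partner <- m + loop_len + (m - k) - i + 1L
    pt[i] <- partner
    pt[partner] <- i
  }

  tibble::tibble(
    id = id, species = species,
    precursor = precursor,
    structure = pairs_to_dotbracket(pt),
    mature_start = 1L, mature_end = m,
    star_start = m + loop_len + 1L, star_end = n,
    score = NA_real_
  )
}

#' Simulate a small-RNA read stack over a precursor
#'
#' `round(n_reads * five_prime_fraction)` reads (round-half-up) start at the
#' mature 5' position; the remainder start at positions shifted by one or two
#' nucleotides in either direction, drawn uniformly. This emulates the 5'-end
#' homogeneity that Drosha/Dicer processing imposes on genuine miRNA loci and
#' that the 90% 5'-consistency criterion measures.
#'
#' @param candidate A one-row candidate tibble (see [make_hairpin()]).
#' @param n_reads Total read count (>= 1).
#' @param five_prime_fraction Fraction of reads starting exactly at the mature
#'   5' position, in `[0, 1]`.
#' @param seed Integer seed.
#' @return A read-stack tibble (`id`, `start`, `length`, `count`), `start`
#'   1-based on the precursor; counts sum to `n_reads`.
#' @export
make_read_stack <- function(candidate, n_reads, five_prime_fraction,
                            seed = 1L) {
  stopifnot(n_reads >= 1L,
            five_prime_fraction >= 0, five_prime_fraction <= 1)
  mstart <- candidate$mature_start[1L]
  mlen <- candidate$mature_end[1L] - mstart + 1L
  n_major <- as.integer(floor(n_reads * five_prime_fraction + 0.5))
  n_major <- min(n_major, n_reads)
  n_minor <- n_reads - n_major
  starts <- with_seed(seed, {
    shifts <- if (n_minor > 0L) sample(c(-2L, -1L, 1L, 2L), n_minor,
                                       replace = TRUE) else integer(0)
    # a shift running off the precursor 5' end is mirrored, so shifted reads
    # never collapse onto the mature start
    mstart + ifelse(mstart + shifts < 1L, -shifts, shifts)
  })
  all_starts <- c(rep(mstart, n_major), starts)
  agg <- table(all_starts)
  tibble::tibble(
    id = candidate$id[1L],
    start = as.integer(names(agg)),
    length = mlen,
    count = as.integer(agg)
  )
}

# region of each miRNA position under a rule set: "pos1", "seed", "tail",
# "last" (the 3'-terminal unpaired_3prime positions)
mirna_regions <- function(mirna_len, rules) {
  region <- rep("tail", mirna_len)
  region[1L] <- "pos1"
  if (rules$seed_len >= 2L) region[2:min(rules$seed_len, mirna_len)] <- "seed"
  if (rules$unpaired_3prime > 0L) {
    region[(mirna_len - rules$unpaired_3prime + 1L):mirna_len] <- "last"
  }
  region
}

#' Plant a miRNA target site into a transcript
#'
#' Overwrites the interval `[position, position + length(mirna) - 1]` with the
#' reverse complement of the miRNA and then injects exactly the requested
#' number of mismatches into each rule region (`pos1`, `seed`, `tail`,
#' `last`), at seeded random positions within the region. Injected mismatch
#' letters pair with the miRNA under neither Watson-Crick nor G:U rules, so
#' the planted mismatch counts are exact under both the scan-stage and
#' validation-stage semantics.
#'
#' @param transcript Transcript sequence.
#' @param mirna miRNA sequence.
#' @param mismatch_spec Named list/vector with any of `seed`, `tail`, `pos1`,
#'   `last` giving mismatch counts per region (absent = 0).
#' @param position 1-based start of the site on the transcript.
#' @param seed Integer seed.
#' @param rules A [target_rules()] object defining the region layout.
#' @param existing Optional tibble of previously planted sites (`start`,
#'   `end`); overlap is an error, keeping planted truth unambiguous.
#' @return A list with `transcript` (modified sequence) and `truth` (one-row
#'   tibble: `start`, `end`, `seed_mm`, `tail_mm`, `pos1_mm`, `last_mm`).
#' @export
plant_target_site <- function(transcript, mirna, mismatch_spec = list(),
                              position, seed = 1L, rules = target_rules(),
                              existing = NULL) {
  transcript <- normalize_rna(transcript)
  mirna <- normalize_rna(mirna)
  L <- nchar(mirna)
  if (position < 1L || position + L - 1L > nchar(transcript)) {
    stop("site does not fit inside the transcript")
  }
  if (!is.null(existing) && nrow(existing) > 0L) {
    if (any(position <= existing$end & position + L - 1L >= existing$start)) {
      stop("planted site overlaps a previously planted site")
    }
  }
  spec <- list(seed = 0L, tail = 0L, pos1 = 0L, last = 0L)
  spec[names(mismatch_spec)] <- mismatch_spec

  region <- mirna_regions(L, rules)
  tchars <- seq_chars(transcript)
  mchars <- seq_chars(mirna)
  site <- seq_chars(revcomp_rna(mirna))      # perfect complement, 5'->3'
  # transcript offset within site for miRNA position i: L - i + 1
  with_seed(seed, {
    for (reg in c("pos1", "seed", "tail", "last")) {
      k <- spec[[reg]]
      if (k == 0L) next
      pos_in_mirna <- which(region == reg)
      if (k > length(pos_in_mirna)) {
        stop("mismatch_spec asks for more mismatches than region '", reg,
             "' has positions")
      }
      chosen <- if (length(pos_in_mirna) == 1L) pos_in_mirna else
        sample(pos_in_mirna, k)
      chosen <- chosen[seq_len(k)]
      for (i in chosen) {
        off <- L - i + 1L
        site[off] <- mismatch_letter(mchars[i], not = site[off])
      }
    }
  })
  tchars[position:(position + L - 1L)] <- site
  list(
    transcript = paste(tchars, collapse = ""),
    truth = tibble::tibble(
      start = as.integer(position), end = as.integer(position + L - 1L),
      seed_mm = as.integer(spec$seed), tail_mm = as.integer(spec$tail),
      pos1_mm = as.integer(spec$pos1), last_mm = as.integer(spec$last)
    )
  )
}

#' Simulate degradome reads for a target site
#'
#' Signal reads are exact transcript substrings whose 5' ends sit at the
#' coordinate pairing miRNA position 10 of the site — the 5' end of the 3'
#' cleavage fragment left by Argonaute-mediated slicing. Noise reads start at
#' seeded uniform positions.
#'
#' @param transcript Transcript sequence.
#' @param site_start,site_end 1-based inclusive site interval (`site_end` is
#'   the transcript coordinate pairing miRNA position 1).
#' @param n_signal,n_noise Read counts.
#' @param read_len Read length in nt.
#' @param seed Integer seed.
#' @param offset_nt Slicer offset (default 10; see [cleavage_rule()]).
#' @return A list with `reads` (tibble `read_id`, `seq`) and `truth` (the
#'   1-based cleavage coordinate).
#' @export
make_degradome_reads <- function(transcript, site_start, site_end,
                                 n_signal, n_noise, read_len = 20L,
                                 seed = 1L, offset_nt = 10L) {
  transcript <- normalize_rna(transcript)
  tlen <- nchar(transcript)
  cleave <- site_end - (offset_nt - 1L)
  if (n_signal > 0L && cleave + read_len - 1L > tlen) {
    stop("read_len exceeds the distance from the cleavage position to the 3' end")
  }
  noise_starts <- with_seed(seed, {
    if (n_noise > 0L) sample.int(tlen - read_len + 1L, n_noise, replace = TRUE)
    else integer(0)
  })
  starts <- c(rep(cleave, n_signal), noise_starts)
  reads <- tibble::tibble(
    read_id = sprintf("read_%03d", seq_along(starts)),
    seq = substring(transcript, starts, starts + read_len - 1L)
  )
  list(reads = reads, truth = as.integer(cleave))
}

#' Evolve an ortholog copy of a transcript
#'
#' Applies i.i.d. per-site substitutions and indels. Planted sites are
#' shielded from substitutions when `preserve_site = TRUE`; indels are never
#' placed inside planted sites (so planted mismatch truth stays countable by
#' position).
#'
#' @param transcript Transcript sequence.
#' @param substitution_rate,indel_rate Per-site probabilities in `[0, 1]`.
#' @param sites Optional tibble of planted-site intervals (`start`, `end`,
#'   1-based inclusive).
#' @param preserve_site Shield planted sites from substitutions?
#' @param seed Integer seed.
#' @return A list with `seq` (the ortholog sequence) and `map` (integer
#'   vector: `map[i]` is the new 1-based coordinate of original position `i`,
#'   `NA` if deleted).
#' @export
make_ortholog_transcript <- function(transcript, substitution_rate = 0.05,
                                     indel_rate = 0, sites = NULL,
                                     preserve_site = TRUE, seed = 1L) {
  stopifnot(substitution_rate >= 0, substitution_rate <= 1,
            indel_rate >= 0, indel_rate <= 1)
  transcript <- normalize_rna(transcript)
  chars <- seq_chars(transcript)
  n <- length(chars)
  in_site <- rep(FALSE, n)
  if (!is.null(sites) && nrow(sites) > 0L) {
    for (r in seq_len(nrow(sites))) {
      in_site[sites$start[r]:sites$end[r]] <- TRUE
    }
  }
  with_seed(seed, {
    sub_ok <- if (preserve_site) !in_site else rep(TRUE, n)
    do_sub <- sub_ok & runif(n) < substitution_rate
    for (i in which(do_sub)) {
      chars[i] <- sample(setdiff(RNA_LETTERS, chars[i]), 1L)
    }
    # indels, outside sites always
    pieces <- vector("list", n)
    for (i in seq_len(n)) pieces[[i]] <- chars[i]
    if (indel_rate > 0) {
      do_indel <- !in_site & runif(n) < indel_rate
      for (i in which(do_indel)) {
        if (runif(1) < 0.5) {
          pieces[[i]] <- character(0)                       # deletion
        } else {
          pieces[[i]] <- c(sample(RNA_LETTERS, 1L), chars[i]) # insertion before
        }
      }
    }
    lens <- lengths(pieces)
    ends <- cumsum(lens)
    map <- ifelse(lens == 0L, NA_integer_, ends)  # position of original nt
    list(seq = paste(unlist(pieces), collapse = ""), map = as.integer(map))
  })
}

#' Evolve a family of orthologous mature miRNAs with known substitutions
#'
#' Starting from one reference mature, produces `n_species` homologues in
#' which a prescribed total number of substitutions is distributed at seeded
#' random (position, species) slots — never in the reference. The per-position
#' substitution counts are returned as ground truth for
#' [count_substitutions()].
#'
#' @param mature Reference mature sequence.
#' @param n_species Number of homologues (including the reference).
#' @param n_substitutions Total substitutions to inject.
#' @param seed Integer seed.
#' @return A list with `seqs` (named character vector, reference first) and
#'   `truth_per_position` (integer vector of injected substitution counts).
#' @export
make_mature_family <- function(mature, n_species, n_substitutions, seed = 1L) {
  mature <- normalize_rna(mature)
  L <- nchar(mature)
  stopifnot(n_species >= 2L,
            n_substitutions <= (n_species - 1L) * L)
  mat <- matrix(rep(seq_chars(mature), n_species), nrow = n_species,
                byrow = TRUE)
  truth <- integer(L)
  with_seed(seed, {
    slots <- expand.grid(sp = 2:n_species, pos = seq_len(L))
    take <- slots[sample.int(nrow(slots), n_substitutions), , drop = FALSE]
    for (r in seq_len(nrow(take))) {
      sp <- take$sp[r]; pos <- take$pos[r]
      mat[sp, pos] <- sample(setdiff(RNA_LETTERS, mat[sp, pos]), 1L)
      truth[pos] <- truth[pos] + 1L
    }
  })
  seqs <- apply(mat, 1L, paste, collapse = "")
  names(seqs) <- c("reference", paste0("species_", 2:n_species))
  list(seqs = seqs, truth_per_position = truth)
}

#' Generate a full two-or-more-species scenario with planted conservation
#'
#' Emits per-species miRNA repertoires, transcriptomes, reference degradome
#' reads and a truth table such that running the whole pipeline (curation is
#' bypassed: matures are given) reproduces `category_plan` for every
#' non-reference species:
#' * category I — the homolog carries the same miRNA's intact site and the
#'   miRNA is in the second repertoire (a conserved target);
#' * category II — the homolog carries a valid site of a species-specific
#'   miRNA while the reference miRNA is withheld from the second repertoire
#'   (a shared target);
#' * category III — the reference miRNA is present but the homologous site is
#'   degraded beyond the duplex rules (3 seed + 3 tail mismatches).
#'
#' @param n_species Number of species; species 1 is the reference.
#' @param n_targets Number of reference targets; must equal
#'   `length(category_plan)`.
#' @param category_plan Character vector over `c("I", "II", "III")`.
#' @param seed Integer seed.
#' @param transcript_length Transcript length in nt.
#' @param n_decoys Untargeted decoy transcripts per species.
#' @param substitution_rate Background substitution rate applied to ortholog
#'   transcripts outside planted sites.
#' @param indel_rate Background indel rate (outside sites).
#' @param rules A [target_rules()] object.
#' @param mirna_len Mature miRNA length.
#' @param n_signal Degradome signal reads per reference site.
#' @param read_len Degradome read length.
#' @return A list with tibbles `mirnas` (`species`, `id`, `family`, `seq`),
#'   `transcripts` (`species`, `id`, `seq`), `degradome` (reference reads:
#'   `read_id`, `transcript_id`, `seq`), `sites_truth` (planted reference
#'   sites) and `truth` (`species`, `ref_transcript`, `homolog`, `mirna`,
#'   `category`).
#' @export
make_species_scenario <- function(n_species = 2L, n_targets = 3L,
                                  category_plan = c("I", "II", "III"),
                                  seed = 1L, transcript_length = 300L,
                                  n_decoys = 3L, substitution_rate = 0,
                                  indel_rate = 0, rules = target_rules(),
                                  mirna_len = 22L, n_signal = 3L,
                                  read_len = 20L) {
  stopifnot(length(category_plan) == n_targets,
            all(category_plan %in% c("I", "II", "III")),
            n_species >= 2L)
  species <- c("ref", if (n_species > 2L)
    paste0("sp", 2:(n_species - 1L)) else character(0), "sp_other")
  species <- species[seq_len(n_species)]
  ref <- species[1L]

  mirnas <- list(); transcripts <- list(); degradome <- list()
  truth <- list(); sites_truth <- list()
  site_pos <- transcript_length - mirna_len - read_len - 20L  # room for 3' fragment

  for (t in seq_len(n_targets)) {
    fam <- sprintf("mir-%d", 1000L + t)
    mat <- random_rna(mirna_len, seed = seed * 1000L + t, first = "U")
    mirnas[[length(mirnas) + 1L]] <-
      tibble::tibble(species = ref, id = paste0(fam, "_", ref),
                     family = fam, seq = mat)

    tx_id <- sprintf("%s_tx%02d", ref, t)
    base <- random_rna(transcript_length, seed = seed * 2000L + t)
    planted <- plant_target_site(base, mat, list(), position = site_pos,
                                 seed = seed * 3000L + t, rules = rules)
    transcripts[[length(transcripts) + 1L]] <-
      tibble::tibble(species = ref, id = tx_id, seq = planted$transcript)
    sites_truth[[length(sites_truth) + 1L]] <-
      dplyr::mutate(planted$truth, transcript_id = tx_id, mirna = fam,
                    .before = 1L)

    dg <- make_degradome_reads(planted$transcript,
                               site_start = planted$truth$start,
                               site_end = planted$truth$end,
                               n_signal = n_signal, n_noise = 0L,
                               read_len = read_len, seed = seed * 4000L + t)
    degradome[[length(degradome) + 1L]] <-
      dplyr::mutate(dg$reads,
                    read_id = paste0(tx_id, "_", .data$read_id),
                    transcript_id = tx_id, .after = "read_id")

    for (s in species[-1L]) {
      cat_t <- category_plan[t]
      s_idx <- match(s, species)
      orth <- make_ortholog_transcript(
        planted$transcript, substitution_rate = substitution_rate,
        indel_rate = indel_rate,
        sites = planted$truth[, c("start", "end")],
        preserve_site = TRUE,
        seed = seed * 5000L + t * 10L + s_idx)
      oseq <- orth$seq
      o_start <- orth$map[planted$truth$start]
      o_end <- o_start + mirna_len - 1L
      homolog_id <- sprintf("%s_tx%02d", s, t)
      if (cat_t == "I") {
        mirnas[[length(mirnas) + 1L]] <-
          tibble::tibble(species = s, id = paste0(fam, "_", s),
                         family = fam, seq = mat)
      } else if (cat_t == "II") {
        fam2 <- sprintf("mir-%d", 2000L + t)
        mat2 <- random_rna(mirna_len, seed = seed * 6000L + t * 10L + s_idx,
                           first = "U")
        # plant the species-specific miRNA's site elsewhere on the homolog
        pos2 <- 20L
        replant <- plant_target_site(oseq, mat2, list(), position = pos2,
                                     seed = seed * 7000L + t * 10L + s_idx,
                                     rules = rules,
                                     existing = tibble::tibble(start = o_start,
                                                               end = o_end))
        oseq <- replant$transcript
        mirnas[[length(mirnas) + 1L]] <-
          tibble::tibble(species = s, id = paste0(fam2, "_", s),
                         family = fam2, seq = mat2)
      } else { # III: same miRNA present, site degraded beyond the rule budgets
        degraded <- plant_target_site(
          oseq, mat, list(seed = 3L, tail = 3L), position = o_start,
          seed = seed * 8000L + t * 10L + s_idx, rules = rules)
        oseq <- degraded$transcript
        mirnas[[length(mirnas) + 1L]] <-
          tibble::tibble(species = s, id = paste0(fam, "_", s),
                         family = fam, seq = mat)
      }
      transcripts[[length(transcripts) + 1L]] <-
        tibble::tibble(species = s, id = homolog_id, seq = oseq)
      truth[[length(truth) + 1L]] <-
        tibble::tibble(species = s, ref_transcript = tx_id,
                       homolog = homolog_id, mirna = fam, category = cat_t)
    }
  }

  # decoys: unrelated sequences in every species
  for (s in species) {
    for (d in seq_len(n_decoys)) {
      s_idx <- match(s, species)
      transcripts[[length(transcripts) + 1L]] <- tibble::tibble(
        species = s, id = sprintf("%s_decoy%02d", s, d),
        seq = random_rna(transcript_length,
                         seed = seed * 9000L + s_idx * 100L + d))
    }
  }

  list(
    mirnas = dplyr::bind_rows(mirnas),
    transcripts = dplyr::bind_rows(transcripts),
    degradome = dplyr::bind_rows(degradome),
    sites_truth = dplyr::bind_rows(sites_truth),
    truth = dplyr::bind_rows(truth)
  )
}
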