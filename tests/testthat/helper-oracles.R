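# Independent oracles and fixture builders. These are written from the rule
# definitions directly, without reusing the package's scanning/folding code
# paths, so they can stand as cross-checks.

# --- naive per-offset mismatch counter (target-scan oracle) -----------------
# Loops over every window and miRNA position explicitly; Watson-Crick only.
naive_scan <- function(mirna, transcript, seed_len = 11, seed_max = 2,
                       tail_max = 2, unpaired_3p = 1, free_5p = TRUE) {
  comp <- c(A = "U", U = "A", G = "C", C = "G")
  mi <- strsplit(mirna, "")[[1]]
  tx <- strsplit(transcript, "")[[1]]
  L <- length(mi)
  hits <- list()
  for (start in seq_len(length(tx) - L + 1)) {
    seed_mm <- 0; tail_mm <- 0
    for (i in seq_len(L)) {
      opposite <- tx[start + L - i]
      match <- comp[[mi[i]]] == opposite
      if (i == 1) {
        if (!free_5p && !match) seed_mm <- seed_mm + 1
      } else if (i <= seed_len) {
        if (!match) seed_mm <- seed_mm + 1
      } else if (i > L - unpaired_3p) {
        # exempt
      } else {
        if (!match) tail_mm <- tail_mm + 1
      }
    }
    if (seed_mm <= seed_max && tail_mm <= tail_max) {
      hits[[length(hits) + 1]] <- c(start = start, seed_mm = seed_mm,
                                    tail_mm = tail_mm)
    }
  }
  if (length(hits) == 0) {
    return(data.frame(start = integer(0), seed_mm = integer(0),
                      tail_mm = integer(0)))
  }
  as.data.frame(do.call(rbind, hits))
}

# --- exhaustive nested-structure enumeration (folding oracle) ---------------
# Enumerates every nested pairing explicitly and returns the maximum pair
# count. Feasible for sequences up to ~12 nt.
brute_max_pairs <- function(seq, min_loop = 3) {
  ok <- function(a, b) {
    (a == "A" && b == "U") || (a == "U" && b == "A") ||
      (a == "G" && b == "C") || (a == "C" && b == "G") ||
      (a == "G" && b == "U") || (a == "U" && b == "G")
  }
  chars <- strsplit(seq, "")[[1]]
  memo <- new.env()
  best <- function(i, j) {
    if (j - i <= min_loop) return(0)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    # enumerate: position j unpaired, or paired with any k
    res <- best(i, j - 1)
    for (k in i:(j - min_loop - 1)) {
      if (ok(chars[k], chars[j])) {
        left <- if (k - 1 >= i) best(i, k - 1) else 0
        res <- max(res, 1 + left + best(k + 1, j - 1))
      }
    }
    memo[[key]] <- res
    res
  }
  best(1, length(chars))
}

# dinucleotide count table of a sequence, as a sorted named vector
dinuc_counts <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  if (length(chars) < 2) return(table(character(0)))
  di <- paste0(chars[-length(chars)], chars[-1])
  sort(table(di))
}

# --- factorial curation fixture --------------------------------------------
# Builds a candidate + read stack in which each of the six criteria passes or
# fails independently, by direct construction (structure supplied as an input
# dot-bracket; sequence chosen separately to control fold significance).
#
# Geometry: mature = positions 1..21, star arm mirrors it; `pairs` mature
# positions are paired; the star 3' end extends `overhang` nt beyond the
# partner of mature position 1.
grid_candidate <- function(pass_score, pass_overhang, pass_five_prime,
                           pass_complementarity, pass_reads,
                           pass_fold, id = "grid") {
  m <- 21
  loop <- 8
  pairs <- if (pass_complementarity) 16 else 15
  overhang <- if (pass_overhang) 2 else 0
  # star: revcomp of mature[1..pairs] plus overhang tail
  star_len <- pairs + overhang
  n <- m + loop + star_len
  pt <- rep(NA_integer_, n)
  for (i in seq_len(pairs)) {
    partner <- m + loop + pairs - i + 1
    pt[i] <- partner
    pt[partner] <- i
  }
  db <- rep(".", n)
  db[!is.na(pt) & pt > seq_len(n)] <- "("
  db[!is.na(pt) & pt < seq_len(n)] <- ")"
  structure_str <- paste(db, collapse = "")

  seq <- if (pass_fold) {
    # a genuine random-armed hairpin folds far better than its dinucleotide
    # shuffles (a homopolymer-block stem would shuffle onto itself)
    half <- (n - loop) %/% 2
    arm <- random_rna(half, seed = 11)
    paste0(arm, strrep("A", loop), revcomp_rna(arm),
           strrep("A", n - loop - 2 * half))
  } else {
    strrep("A", n)   # homopolymer: every shuffle identical, p = 1
  }

  cand <- tibble::tibble(
    id = id, species = "grid", precursor = seq,
    structure = structure_str,
    mature_start = 1L, mature_end = as.integer(m),
    star_start = as.integer(m + loop + 1), star_end = as.integer(n),
    score = if (pass_score) 12 else 5
  )
  # reads: modal-start count a, off-by-one count b
  ab <- if (pass_reads && pass_five_prime) c(9L, 1L)
  else if (pass_reads && !pass_five_prime) c(5L, 5L)
  else if (!pass_reads && pass_five_prime) c(9L, 0L)
  else c(5L, 4L)
  stack <- tibble::tibble(
    id = id,
    start = if (ab[2] > 0) c(1L, 2L) else 1L,
    length = 21L,
    count = if (ab[2] > 0) ab else ab[1]
  )
  list(candidate = cand, stack = stack)
}

# 3-species scenario helper used across conservation tests
plan_scenario <- function(plan, seed, ...) {
  make_species_scenario(n_species = 2, n_targets = length(plan),
                        category_plan = plan, seed = seed, ...)
}

# run the cross-species comparison for a scenario and return categories in
# truth order
scenario_categories <- function(sc, rules = target_rules()) {
  ref_tx <- sc$transcripts[sc$transcripts$species == "ref", c("id", "seq")]
  oth <- setdiff(unique(sc$transcripts$species), "ref")
  out <- list()
  for (s in oth) {
    oth_tx <- sc$transcripts[sc$transcripts$species == s, c("id", "seq")]
    ref_mir <- sc$mirnas[sc$mirnas$species == "ref", c("family", "seq")]
    oth_mir <- sc$mirnas[sc$mirnas$species == s, c("family", "seq")]
    ref_records <- sc$sites_truth[, c("mirna", "transcript_id", "start", "end")]
    cmp <- compare_species(ref_records, ref_mir, ref_tx, oth_mir, oth_tx,
                           rules = rules)
    cls <- cmp$classification
    truth_s <- sc$truth[sc$truth$species == s, ]
    got <- cls$category[match(truth_s$ref_transcript, cls$transcript_id)]
    out[[s]] <- as.character(got)
  }
  unlist(out, use.names = FALSE)
}
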