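test_that("five_prime_consistency counts mature-arm reads and breaks ties", {
  stack <- tibble::tibble(id = "c", start = c(10L, 12L), length = 22L,
                          count = c(18L, 2L))
  expect_equal(five_prime_consistency(stack, 10L)$consistency, 0.9)

  one <- tibble::tibble(id = "c", start = 10L, length = 22L, count = 7L)
  expect_equal(five_prime_consistency(one, 10L)$consistency, 1.0)

  # tie: prefer the annotated mature start
  tie <- tibble::tibble(id = "c", start = c(10L, 11L), length = 22L,
                        count = c(5L, 5L))
  fp <- five_prime_consistency(tie, 11L)
  expect_equal(fp$modal_start, 11L)
  expect_equal(fp$consistency, 0.5)
  # tie without the mature start among the modes: smaller coordinate
  fp2 <- five_prime_consistency(tie, 30L)
  expect_equal(fp2$modal_start, 10L)

  # reads outside the mature arm are ignored
  far <- tibble::tibble(id = "c", start = c(10L, 200L), length = 22L,
                        count = c(5L, 50L))
  expect_equal(five_prime_consistency(far, 10L)$n_reads, 5L)

  expect_error(five_prime_consistency(far[0, ], 10L), "empty")
})

test_that("evaluate_candidate applies every criterion and records reasons", {
  fix <- grid_candidate(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE)
  ev <- evaluate_candidate(fix$candidate, fix$stack, n_shuffles = 49,
                           seed = 1)
  expect_true(ev$bona_fide)
  expect_equal(ev$failure_reasons, "")

  # boundary: reads = 9 vs 10
  lo <- grid_candidate(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE)
  ev9 <- evaluate_candidate(lo$candidate, lo$stack, n_shuffles = 49, seed = 1)
  expect_false(ev9$bona_fide)
  expect_equal(ev9$n_reads, 9L)
  expect_match(ev9$failure_reasons, "min_reads")

  # boundary: mature/star pairs = 15 vs 16
  mp <- grid_candidate(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE)
  ev15 <- evaluate_candidate(mp$candidate, mp$stack, n_shuffles = 49,
                             seed = 1)
  expect_false(ev15$bona_fide)
  expect_equal(ev15$mature_star_pairs, 15L)
  expect_match(ev15$failure_reasons, "complementarity")

  # all failures are listed, not just the first
  allf <- grid_candidate(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE)
  evf <- evaluate_candidate(allf$candidate, allf$stack, n_shuffles = 49,
                            seed = 1)
  expect_false(evf$bona_fide)
  expect_setequal(strsplit(evf$failure_reasons, ",")[[1]],
                  c("score", "overhang", "five_prime", "complementarity",
                    "min_reads", "fold_pvalue"))

  # a candidate without an upstream score skips that criterion
  ns <- grid_candidate(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE)
  ns$candidate$score <- NA_real_
  evna <- evaluate_candidate(ns$candidate, ns$stack, n_shuffles = 49,
                             seed = 1)
  expect_true(is.na(evna$pass_score))
  expect_true(evna$bona_fide)
})

test_that("overhang anchor advances past a frayed mature 5' terminus", {
  # 12-nt toy: mature 1..4 with position 1 unpaired, loop 5..8, star 9..12;
  # pairs 2:11, 3:10, 4:9 leave star position 12 beyond the anchor partner
  db <- ".(((....)))."
  cand <- tibble::tibble(id = "toy", species = "t", precursor = strrep("A", 12),
                         structure = db, mature_start = 1L, mature_end = 4L,
                         star_start = 9L, star_end = 12L, score = NA_real_)
  g <- duplex_geometry(cand)
  # anchor advances to mature position 2 (partner star 11); star nt 12 is
  # beyond it
  expect_equal(g$star_3p_overhang, 1L)
  expect_equal(g$mature_star_pairs, 3L)
})

test_that("blacklist_filter removes both-strand substring matches", {
  cands <- tibble::tibble(
    id = c("a", "b", "c"),
    mature = c("UGAGGUAGUAGGUUGUAUAGUU",  # sits inside the tRNA below
               "ACGUACGUACGUACGUACGUAC",  # clean
               "UUUGGGCCCAAAUUUGGGCCCA")  # revcomp sits in the symbiont seq
  )
  trna <- tibble::tibble(id = "tRNA-1",
                         seq = paste0("GGG", cands$mature[1], "CCC"))
  symb <- tibble::tibble(id = "symb-scaffold",
                         seq = paste0("AA", revcomp_rna(cands$mature[3]), "GG"))
  res <- blacklist_filter(cands, list(tRNA = trna, symbiont = symb))
  expect_equal(sort(res$removed$id), c("a", "c"))
  expect_equal(res$removed$source[res$removed$id == "a"], "tRNA")
  expect_equal(res$removed$source[res$removed$id == "c"], "symbiont")
  expect_equal(res$kept$id, "b")
  # partition: union is the input, no overlap
  expect_setequal(c(res$kept$id, res$removed$id), cands$id)
})

test_that("quantify_known detects matures at the read threshold", {
  known <- tibble::tibble(id = c("mir-2025", "mir-100"),
                          seq = c(random_rna(22, 71, first = "U"),
                                  random_rna(22, 72, first = "U")))
  exact12 <- tibble::tibble(seq = known$seq[1], count = 12L)
  res <- quantify_known(exact12, known)
  expect_true(res$detected[res$id == "mir-2025"])
  expect_equal(res$count[res$id == "mir-2025"], 12L)

  exact9 <- tibble::tibble(seq = known$seq[1], count = 9L)
  expect_false(quantify_known(exact9, known)$detected[1])

  # two mismatches exceed the budget and contribute nothing
  mm2 <- strsplit(known$seq[1], "")[[1]]
  mm2[5] <- setdiff(c("A", "C", "G", "U"), mm2[5])[1]
  mm2[9] <- setdiff(c("A", "C", "G", "U"), mm2[9])[1]
  res2 <- quantify_known(tibble::tibble(seq = paste(mm2, collapse = ""),
                                        count = 50L), known)
  expect_equal(res2$count[res2$id == "mir-2025"], 0L)

  # conservation of read mass: totals never exceed input counts
  mix <- tibble::tibble(seq = c(known$seq, random_rna(22, 73)),
                        count = c(6L, 7L, 100L))
  res3 <- quantify_known(mix, known)
  expect_lte(sum(res3$count), sum(mix$count))
})

test_that("curate_mirnas produces a tidy audit with a summary", {
  fixtures <- list(grid_candidate(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, id = "x1"),
                   grid_candidate(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, id = "x2"))
  cands <- dplyr::bind_rows(lapply(fixtures, `[[`, "candidate"))
  stacks <- dplyr::bind_rows(lapply(fixtures, `[[`, "stack"))
  audit <- curate_mirnas(cands, stacks, n_shuffles = 49, seed = 1)
  expect_s3_class(audit, "mirna_audit")
  expect_equal(audit$bona_fide, c(TRUE, FALSE))
  g <- glance(audit)
  expect_equal(g$n_candidates, 2L)
  expect_equal(g$n_bona_fide, 1L)
  expect_equal(g$fail_overhang, 1L)
  expect_s3_class(autoplot(audit), "ggplot")
})
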