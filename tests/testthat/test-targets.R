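test_that("scan_transcript finds exact antisense matches and obeys -c / -n", {
  mi <- random_rna(22, 21, first = "U")
  flank5 <- random_rna(30, 22)
  flank3 <- random_rna(30, 23)
  tx <- paste0(flank5, revcomp_rna(mi), flank3)

  hits <- scan_transcript(mi, tx)
  exact <- hits[hits$start == 31, ]
  expect_equal(nrow(exact), 1L)
  expect_equal(exact$seed_mm, 0L)
  expect_equal(exact$tail_mm, 0L)
  expect_equal(exact$end, 52L)

  # mutate the transcript nt opposite miRNA position 1 (the window 3' end)
  tchars <- strsplit(tx, "")[[1]]
  tchars[52] <- mismatch_nt <- setdiff(c("A", "C", "G", "U"),
                                       c(tchars[52],
                                         chartr("ACGU", "UGCA",
                                                substr(mi, 1, 1))))[1]
  tx1 <- paste(tchars, collapse = "")
  h1 <- scan_transcript(mi, tx1)
  expect_true(31 %in% h1$start)
  expect_true(h1$pos1_mismatch[h1$start == 31])
  expect_equal(h1$seed_mm[h1$start == 31], 0L)

  # without the free-5prime rule the same mismatch is charged
  h1c <- scan_transcript(mi, tx1, target_rules(free_5prime = FALSE))
  expect_equal(h1c$seed_mm[h1c$start == 31], 1L)

  # three mismatches inside positions 2-11 suppress the site
  pl <- plant_target_site(tx, mi, list(seed = 3), position = 31, seed = 4)
  expect_false(31 %in% scan_transcript(mi, pl$transcript)$start)
})

test_that("scan_transcript agrees with an independent naive counter", {
  for (s in 1:30) {
    mi <- random_rna(sample(20:24, 1), seed = s)
    tx <- random_rna(250, seed = s + 1000)
    got <- scan_transcript(mi, tx)
    want <- naive_scan(mi, tx)
    expect_equal(got$start, want$start, info = s)
    expect_equal(got$seed_mm, as.integer(want$seed_mm), info = s)
    expect_equal(got$tail_mm, as.integer(want$tail_mm), info = s)
  }
})

test_that("relaxing any budget never removes an emitted site", {
  base <- target_rules()
  for (s in 1:10) {
    mi <- random_rna(22, seed = s + 60)
    tx <- random_rna(300, seed = s + 70)
    sites0 <- scan_transcript(mi, tx, base)$start
    relaxed <- list(
      target_rules(seed_mismatch_max = 3),
      target_rules(tail_mismatch_max = 3),
      target_rules(unpaired_3prime = 2)
    )
    for (r in relaxed) {
      expect_true(all(sites0 %in% scan_transcript(mi, tx, r)$start), info = s)
    }
  }
})

test_that("GU handling differs between scan and validation stages", {
  mi <- "UGAGGUAGUAGGUUGUAUAGUU"
  win <- strsplit(revcomp_rna(mi), "")[[1]]
  # place U opposite miRNA G at position 4 (a G:U wobble)
  win[nchar(mi) - 4 + 1] <- "U"
  tx <- paste0(random_rna(30, 81), paste(win, collapse = ""),
               random_rna(30, 82))
  # scan: wobble is a (seed) mismatch
  h <- scan_transcript(mi, tx)
  expect_equal(h$seed_mm[h$start == 31], 1L)
  # validation: wobble is a pair, site validates cleanly
  v <- validate_site(mi, 31, 52, tx)
  expect_true(v$validated)
  expect_equal(v$seed_mm, 0L)
})

test_that("validate_site enforces budgets, bulges and central pairing", {
  mi <- random_rna(22, 91, first = "U")
  tx0 <- random_rna(150, 92)

  ok <- plant_target_site(tx0, mi, list(), position = 60, seed = 1)
  expect_true(validate_site(mi, 60, 81, ok$transcript)$validated)

  bad <- plant_target_site(tx0, mi, list(seed = 3), position = 60, seed = 2)
  expect_false(validate_site(mi, 60, 81, bad$transcript)$validated)

  # deleting the target nt opposite miRNA position 10 forces a central bulge
  site <- revcomp_rna(mi)
  gap10 <- paste0(substr(site, 1, 12), substr(site, 14, 22))
  txb <- paste0(random_rna(40, 93), gap10, random_rna(40, 94))
  vb <- validate_site(mi, 41, 41 + 20, txb)
  expect_false(vb$validated)
})

test_that("scan_targets stacks and orders multi-sequence scans", {
  mirnas <- tibble::tibble(id = c("mirB", "mirA"),
                           seq = c(random_rna(22, 95), random_rna(22, 96)))
  tx <- tibble::tibble(
    id = c("tx2", "tx1"),
    seq = c(paste0(random_rna(20, 97), revcomp_rna(mirnas$seq[1]),
                   random_rna(20, 98)),
            paste0(random_rna(50, 99), revcomp_rna(mirnas$seq[2]),
                   random_rna(10, 100))))
  sites <- scan_targets(mirnas, tx)
  expect_true(all(c("mirA", "mirB") %in% sites$mirna_id))
  expect_equal(sites$transcript_id, sort(sites$transcript_id))
  val <- validate_sites(sites, mirnas, tx)
  expect_true(all(val$validated[val$seed_mm == 0 & val$tail_mm == 0]))
})
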