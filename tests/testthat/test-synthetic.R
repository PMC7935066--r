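test_that("generators are byte-identical under a fixed seed", {
  expect_identical(make_hairpin(random_rna(21, 5), seed = 9),
                   make_hairpin(random_rna(21, 5), seed = 9))
  h <- make_hairpin(random_rna(21, 5), seed = 9)
  expect_identical(make_read_stack(h, 50, 0.9, seed = 2),
                   make_read_stack(h, 50, 0.9, seed = 2))
  tx <- random_rna(200, 8)
  mi <- random_rna(22, 9)
  expect_identical(plant_target_site(tx, mi, list(seed = 2), 50, seed = 4),
                   plant_target_site(tx, mi, list(seed = 2), 50, seed = 4))
  expect_identical(make_species_scenario(seed = 3),
                   make_species_scenario(seed = 3))
})

test_that("make_hairpin realises the requested duplex geometry", {
  mat <- random_rna(21, 7, first = "U")
  h2 <- make_hairpin(mat, loop_len = 8, star_3p_overhang = 2, seed = 7)
  g2 <- duplex_geometry(h2, fold_nussinov(h2$precursor))
  expect_equal(g2$star_3p_overhang, 2L)
  expect_equal(g2$mature_star_pairs, 19L)

  h0 <- make_hairpin(mat, loop_len = 8, star_3p_overhang = 0, seed = 7)
  g0 <- duplex_geometry(h0, fold_nussinov(h0$precursor))
  expect_equal(g0$star_3p_overhang, 0L)
  expect_equal(g0$mature_star_pairs, 21L)

  # 16-nt mature with a 2-nt overhang has only 14 pairs: below the
  # complementarity criterion. The recorded structure carries exactly the
  # constructed geometry; a de novo refold can realise the same pair count
  # with a different (equally optimal) pairing, but never reaches 16
  # mature/star pairs
  h16 <- make_hairpin(random_rna(16, 1, first = "U"), loop_len = 8,
                      star_3p_overhang = 2, seed = 1)
  g16 <- duplex_geometry(h16)
  expect_equal(g16$mature_star_pairs, 14L)
  expect_equal(g16$star_3p_overhang, 2L)
  g16f <- duplex_geometry(h16, fold_nussinov(h16$precursor))
  expect_lt(g16f$mature_star_pairs, 16L)

  expect_error(make_hairpin(random_rna(21, 1), loop_len = 2), "unfoldable")
  expect_error(make_hairpin("ACGTX"), "non-RNA")
})

test_that("read stacks honour the 5'-homogeneity fraction and read count", {
  h <- make_hairpin(random_rna(21, 5), seed = 9)
  st <- make_read_stack(h, 20, 0.9, seed = 1)
  expect_equal(sum(st$count), 20L)
  expect_equal(st$count[st$start == h$mature_start], 18L)
  fp <- five_prime_consistency(st, h$mature_start, h$mature_end)
  expect_equal(fp$consistency, 0.9)

  st10 <- make_read_stack(h, 10, 1.0, seed = 1)
  expect_equal(sum(st10$count), 10L)
  expect_equal(five_prime_consistency(st10, h$mature_start)$consistency, 1.0)

  st9 <- make_read_stack(h, 9, 1.0, seed = 1)
  expect_equal(sum(st9$count), 9L)
})

test_that("planted sites carry exactly the requested mismatches", {
  mi <- random_rna(22, 31, first = "U")
  tx <- random_rna(150, 32)

  perfect <- plant_target_site(tx, mi, list(), position = 40, seed = 1)
  hit <- scan_transcript(mi, perfect$transcript)
  expect_equal(nrow(hit[hit$start == 40, ]), 1L)
  expect_equal(hit$seed_mm[hit$start == 40], 0L)
  expect_equal(hit$tail_mm[hit$start == 40], 0L)

  over <- plant_target_site(tx, mi, list(seed = 3), position = 40, seed = 2)
  expect_false(40 %in% scan_transcript(mi, over$transcript)$start)

  lastnt <- plant_target_site(tx, mi, list(last = 1), position = 40, seed = 3)
  h3 <- scan_transcript(mi, lastnt$transcript)
  expect_true(40 %in% h3$start)
  expect_true(h3$last_nt_unpaired[h3$start == 40])

  expect_error(
    plant_target_site(tx, mi, list(), position = 45, seed = 1,
                      existing = tibble::tibble(start = 40L, end = 61L)),
    "overlaps")
})

test_that("degradome read generation marks the slicer coordinate", {
  mi <- random_rna(22, 41, first = "U")
  tx <- random_rna(300, 42)
  pl <- plant_target_site(tx, mi, list(), position = 100, seed = 1)
  dg <- make_degradome_reads(pl$transcript, 100, 121, n_signal = 5,
                             n_noise = 3, read_len = 20, seed = 2)
  expect_equal(nrow(dg$reads), 8L)
  expect_equal(dg$truth, 121L - 9L)
  # signal reads are exact substrings starting at the cleavage coordinate
  expect_equal(substr(pl$transcript, dg$truth, dg$truth + 19),
               dg$reads$seq[1])
})

test_that("ortholog evolution respects rates, site shielding and mapping", {
  tx <- random_rna(200, 51)
  id0 <- make_ortholog_transcript(tx, 0, 0, seed = 1)
  expect_identical(id0$seq, tx)
  expect_identical(id0$map, seq_len(200L))

  sites <- tibble::tibble(start = 50L, end = 71L)
  ev <- make_ortholog_transcript(tx, 0.2, 0.05, sites = sites,
                                 preserve_site = TRUE, seed = 7)
  expect_identical(substr(ev$seq, ev$map[50], ev$map[50] + 21),
                   substr(tx, 50, 71))
  # mapping is monotone over surviving positions
  surv <- ev$map[!is.na(ev$map)]
  expect_true(all(diff(surv) > 0))
})

test_that("mature families carry their substitution truth", {
  fam <- make_mature_family(random_rna(22, 61, first = "U"), n_species = 8,
                            n_substitutions = 12, seed = 5)
  aln <- align_orthologs(fam$seqs, max_offset = 0)
  prof <- count_substitutions(aln, mode = "non_modal_count")
  expect_equal(attr(prof, "total"), 12L)
  expect_equal(prof$substitutions, fam$truth_per_position)
})

test_that("species scenarios reproduce their planted category plan", {
  sc <- make_species_scenario(n_species = 2, n_targets = 3,
                              category_plan = c("I", "II", "III"), seed = 42)
  expect_equal(scenario_categories(sc), c("I", "II", "III"))
  # category II fixtures withhold the reference miRNA from the other species
  ii <- sc$truth[sc$truth$category == "II", ]
  oth_fams <- sc$mirnas$family[sc$mirnas$species != "ref"]
  expect_false(any(ii$mirna %in% oth_fams))
})
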