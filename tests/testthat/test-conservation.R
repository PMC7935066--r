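test_that("reciprocal_best_hits pairs identical transcriptomes identically", {
  tx <- tibble::tibble(id = c("t1", "t2", "t3"),
                       seq = c(random_rna(200, 1), random_rna(200, 2),
                               random_rna(200, 3)))
  rbh <- reciprocal_best_hits(tx, tx)
  expect_true(all(rbh$reciprocal))
  expect_equal(rbh$id_a, rbh$id_b)
})

test_that("non-agreeing bests are not reciprocal", {
  # B1 is identical to A2; A1 is a slightly mutated copy of B1.
  a2 <- random_rna(200, 5)
  a1 <- make_ortholog_transcript(a2, 0.05, 0, seed = 2)$seq
  txa <- tibble::tibble(id = c("A1", "A2"), seq = c(a1, a2))
  txb <- tibble::tibble(id = c("B1", "Bdecoy"),
                        seq = c(a2, random_rna(200, 6)))
  rbh <- reciprocal_best_hits(txa, txb)
  expect_false(rbh$reciprocal[rbh$id_a == "A1"])
  expect_true(rbh$reciprocal[rbh$id_a == "A2"])
})

test_that("RBH recovers diverged orthologs among decoys and is symmetric", {
  orths <- sapply(1:4, function(i) random_rna(300, 100 + i))
  txa <- tibble::tibble(id = paste0("A", 1:4), seq = orths)
  txb <- tibble::tibble(
    id = paste0("B", 1:4),
    seq = sapply(1:4, function(i)
      make_ortholog_transcript(orths[i], 0.05, 0.01, seed = 200 + i)$seq))
  decoys_b <- tibble::tibble(id = paste0("D", 1:6),
                             seq = sapply(1:6, function(i)
                               random_rna(300, 300 + i)))
  txb_all <- dplyr::bind_rows(txb, decoys_b)
  rbh <- reciprocal_best_hits(txa, txb_all)
  expect_true(all(rbh$reciprocal))
  expect_equal(rbh$id_b, paste0("B", 1:4))

  # symmetry: swapping the transcriptomes transposes the reciprocal pairs
  rbh_rev <- reciprocal_best_hits(txb_all, txa)
  fwd <- paste(rbh$id_a, rbh$id_b)[rbh$reciprocal]
  rev_ <- paste(rbh_rev$id_b, rbh_rev$id_a)[rbh_rev$reciprocal]
  expect_setequal(fwd, rev_)
})

test_that("classification reproduces planted categories and partitions", {
  sc <- plan_scenario(c("I", "II", "III"), seed = 7)
  got <- scenario_categories(sc)
  expect_equal(got, c("I", "II", "III"))

  # every reference record maps to exactly one category
  ref_tx <- sc$transcripts[sc$transcripts$species == "ref", c("id", "seq")]
  oth_tx <- sc$transcripts[sc$transcripts$species != "ref", c("id", "seq")]
  cmp <- compare_species(
    sc$sites_truth[, c("mirna", "transcript_id", "start", "end")],
    sc$mirnas[sc$mirnas$species == "ref", c("family", "seq")], ref_tx,
    sc$mirnas[sc$mirnas$species != "ref", c("family", "seq")], oth_tx)
  expect_equal(nrow(cmp$classification), 3L)
  expect_false(any(is.na(cmp$classification$category)))

  # a reference target without an RBH homolog is category none/no_homolog
  lone <- tibble::tibble(mirna = "mir-x", transcript_id = "ghost",
                         start = 10L, end = 31L)
  cls <- classify_conservation(
    lone, tibble::tibble(id_a = character(0), id_b = character(0),
                         score_ab = numeric(0), score_ba = numeric(0),
                         reciprocal = logical(0), tie = logical(0)),
    tibble::tibble(mirna = character(0), transcript_id = character(0),
                   validated = logical(0)),
    other_repertoire = character(0))
  expect_equal(as.character(cls$category), "none")
  expect_equal(cls$reason, "no_homolog")
})

test_that("site regions annotate by the any-overlap CDS rule", {
  expect_equal(annotate_site_region(50, 72, 100, 400), "5'UTR")
  expect_equal(annotate_site_region(150, 172, 100, 400), "CDS")
  expect_equal(annotate_site_region(390, 412, 100, 400), "CDS")
  expect_equal(annotate_site_region(450, 472, 100, 400), "3'UTR")
  expect_equal(annotate_site_region(50, 72, NA, NA), "unknown")
})

test_that("site location conservation projects through indels", {
  tx <- random_rna(400, 41)
  site <- list(start = 200L, end = 221L)
  same <- site_location_conserved(site, site, tx, tx, "CDS", "CDS")
  expect_true(same$conserved)

  # a 5-nt deletion upstream shifts coordinates; projection absorbs it
  tx_del <- paste0(substr(tx, 1, 50), substr(tx, 56, 400))
  site_b <- list(start = 195L, end = 216L)
  shifted <- site_location_conserved(site, site_b, tx, tx_del, "CDS", "CDS")
  expect_true(shifted$conserved)

  # same region but far apart fails the tolerance
  far <- site_location_conserved(site, list(start = 30L, end = 51L),
                                 tx, tx, "CDS", "CDS")
  expect_false(far$conserved)
  # region mismatch fails outright
  reg <- site_location_conserved(site, site, tx, tx, "CDS", "3'UTR")
  expect_equal(reg$reason, "region_mismatch")
})

test_that("align_orthologs finds integer shifts and count_substitutions counts", {
  ref <- random_rna(22, 51)
  shifted <- paste0("G", substr(ref, 1, 21))   # 1-nt 5' shift
  aln <- align_orthologs(c(ref = ref, shifted = shifted))
  expect_equal(unname(aln$offsets), c(0L, -1L))
  expect_equal(unname(aln$identity[2]), 1.0)

  idem <- align_orthologs(c(a = ref, b = ref, c = ref))
  expect_true(all(idem$offsets == 0L))

  cols <- align_orthologs(c(x = "AAG", y = "AAG", z = "AGG"), max_offset = 0)
  prof_d <- count_substitutions(cols, mode = "distinct_minus_one")
  prof_n <- count_substitutions(cols, mode = "non_modal_count")
  # columns: {A,A,A} -> 0; {A,A,G} -> 1 (both modes); {G,G,G} -> 0
  expect_equal(prof_d$substitutions, c(0L, 1L, 0L))
  expect_equal(prof_n$substitutions, c(0L, 1L, 0L))

  cols2 <- align_orthologs(c(w = "AA", x = "AA", y = "AG", z = "AG"),
                           max_offset = 0)
  expect_equal(count_substitutions(cols2)$substitutions[2], 1L)
  expect_equal(count_substitutions(cols2,
                                   mode = "non_modal_count")$substitutions[2],
               2L)

  # permutation invariance of totals
  perm <- align_orthologs(c(z = "AG", w = "AA", y = "AG", x = "AA"),
                          max_offset = 0)
  expect_equal(attr(count_substitutions(perm), "total"),
               attr(count_substitutions(cols2), "total"))
})

test_that("position_bias yields logo frequencies and information content", {
  pfm <- position_bias(c("UAAA", "UAGA", "UACA", "UAUA"))
  expect_equal(unname(pfm$freq["U", 1]), 1.0)
  expect_equal(pfm$information[1], 2)
  expect_equal(pfm$information[3], 0)          # uniform column
  expect_true(all(abs(colSums(pfm$freq) - 1) < 1e-12))

  three_one <- position_bias(c("U", "U", "U", "A"))
  expect_equal(three_one$information[1], 2 - (-0.75 * log2(0.75)
                                              - 0.25 * log2(0.25)),
               tolerance = 1e-12)

  # ragged 3' ends: trailing columns are normalised by coverage
  rag <- position_bias(c("UA", "UAG"))
  expect_equal(unname(rag$coverage), c(2L, 2L, 1L))
  expect_equal(unname(rag$freq["G", 3]), 1.0)
  expect_s3_class(autoplot(pfm), "ggplot")
})

test_that("Dollo reconstruction places gains at MRCAs and counts losses", {
  tree <- ape::read.tree(text = "((A,B),C);")
  pres <- rbind(
    `mir-ab` = c(A = 1, B = 1, C = 0),
    `mir-ac` = c(A = 1, B = 0, C = 1),
    `mir-all` = c(A = 1, B = 1, C = 1)
  )
  rec <- dollo_reconstruct(pres, tree)
  mrca_ab <- ape::getMRCA(tree, c("A", "B"))
  root <- ape::getMRCA(tree, c("A", "C"))

  expect_equal(rec$gains$node[rec$gains$family == "mir-ab"], mrca_ab)
  expect_equal(rec$gains$node[rec$gains$family == "mir-ac"], root)
  expect_equal(rec$gains$node[rec$gains$family == "mir-all"], root)
  # mir-ac is lost on B's terminal edge; nothing else is lost
  expect_equal(rec$losses$family, "mir-ac")
  expect_equal(rec$losses$node_label, "B")
  # shared counts: root carries mir-ac + mir-all; MRCA(A,B) all three
  shared <- setNames(rec$shared$n_present, rec$shared$node)
  expect_equal(unname(shared[as.character(root)]), 2L)
  expect_equal(unname(shared[as.character(mrca_ab)]), 3L)
  # Dollo constraint: one gain per family
  expect_equal(nrow(rec$gains), nrow(pres))
  expect_equal(anyDuplicated(rec$gains$family), 0L)

  expect_warning(
    dollo_reconstruct(rbind(pres, `mir-none` = c(A = 0, B = 0, C = 0)), tree),
    "absent")
  td <- tidy(rec)
  expect_equal(sum(td$n_gains), 3L)
  expect_equal(sum(td$n_losses), 1L)
})

test_that("turnover_rate arithmetic matches the divergence window", {
  r <- turnover_rate(paste0("m", 1:30), paste0("m", 8:30), 16.2, 35.3)
  expect_equal(r$d, 7L)
  a <- turnover_rate(c(paste0("a", 1:12), paste0("s", 1:10)),
                     c(paste0("b", 1:11), paste0("s", 1:10)), 16.2, 35.3)
  expect_equal(a$d, 23L)
  expect_equal(round(a$rate_low, 3), 0.652)
  expect_equal(round(a$rate_high, 3), 1.420)

  same <- turnover_rate(c("x", "y"), c("x", "y"), 10, 20)
  expect_equal(c(same$rate_low, same$rate_high), c(0, 0))
  ten <- turnover_rate(paste0("m", 1:10), character(0), 10, 10)
  expect_equal(c(ten$rate_low, ten$rate_high), c(1, 1))
  half <- turnover_rate(paste0("m", 1:10), character(0), 10, 10,
                        per_lineage = TRUE)
  expect_equal(half$rate_high, 0.5)
})
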