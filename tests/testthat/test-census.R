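test_that("census counts proteins per genome and category", {
  gm <- setNames(c("g1", "g1", "g1"), c("p1", "p2", "p3"))
  cm <- census(setNames(rep("AI", 3), c("p1", "p2", "p3")), gm)
  expect_identical(unname(cm["g1", "AI"]), 3L)
  expect_identical(unname(attr(cm, "presence")["g1", "AI"]), 1L)
  # empty categories appear as all-zero columns
  cm2 <- census(setNames("AI", "p1"), setNames("g1", "p1"),
                categories = c("AI", "AII"))
  expect_identical(unname(cm2[, "AII"]), 0L)
  expect_error(census(setNames("AI", "p9"), gm), "not mapped")
})

test_that("census equals the simulation truth tally", {
  fam <- fixture_family()
  tr <- fam$truth
  gm <- setNames(tr$species_id, tr$seq_id)
  cm <- census(setNames(tr$subfamily, tr$seq_id), gm)
  for (i in seq_len(nrow(tr))) {
    expect_identical(
      unname(cm[tr$species_id[i], tr$subfamily[i]]),
      sum(tr$species_id == tr$species_id[i] &
            tr$subfamily == tr$subfamily[i]))
  }
  expect_identical(sum(cm), nrow(tr))
})

test_that("co-occurrence regions partition the genomes", {
  # 8 genomes covering all 2^3 membership patterns
  pats <- expand.grid(A = 0:1, B = 0:1, C = 0:1)
  rows <- list(); gm <- character(0)
  k <- 0
  for (i in seq_len(nrow(pats))) {
    g <- paste0("g", i)
    for (cat in c("A", "B", "C")) {
      if (pats[i, cat] == 1) {
        k <- k + 1
        rows[[k]] <- data.frame(seq_id = paste0("p", k), category = cat)
        gm[paste0("p", k)] <- g
      }
    }
  }
  asn <- do.call(rbind, rows)
  cm <- census(asn, gm, categories = c("A", "B", "C"))
  # genome g1 (no protein at all) is absent from the census matrix;
  # the 7 non-empty patterns each occur once
  vn <- cooccurrence(cm, c("A", "B", "C"))
  expect_identical(sum(vn), nrow(cm))
  expect_true(all(vn[names(vn) != "none"] == 1L))
  # two categories, all genomes with both
  cm2 <- census(data.frame(seq_id = c("q1", "q2"),
                           category = c("A", "B")),
                c(q1 = "g", q2 = "g"))
  v2 <- cooccurrence(cm2, c("A", "B"))
  expect_identical(unname(v2[["A&B"]]), 1L)
  expect_identical(sum(v2), 1L)
})

test_that("taxonomic breakdown reports genome and taxon counts", {
  nodes <- data.frame(tax_id = 1:3, parent_id = c(1, 1, 1),
                      rank = c("no rank", "phylum", "phylum"),
                      name = c("root", "P1", "P2"))
  lm <- c(g1 = 2L, g2 = 2L, g3 = 2L, g4 = 3L)
  tax <- taxonomy_table(nodes, lm)
  asn <- data.frame(seq_id = paste0("p", 1:4), category = "AI")
  gm <- setNames(paste0("g", 1:4), paste0("p", 1:4))
  cm <- census(asn, gm)
  bd <- taxonomic_breakdown(cm, tax, "phylum")
  expect_identical(bd$summary$n_genomes, 4L)
  expect_identical(bd$summary$n_taxa, 2L)
  fr <- setNames(bd$by_taxon$fraction, bd$by_taxon$taxon)
  expect_equal(unname(fr[c("P1", "P2")]), c(0.75, 0.25))
  # marginal consistency with census presence sums
  expect_identical(bd$summary$n_genomes,
                   sum(attr(cm, "presence")[, "AI"]))
})

test_that("region extraction maps reference coordinates through gaps", {
  aln <- c(ref = "ABCDEFGHIJ", o = "QRSTUVWXYZ")
  names(aln) <- c("ref", "o")
  aln[] <- c("ACDEFGHIKL", "MNPQRSTVWY")
  r1 <- extract_region(aln, "ref", c(5, 10))
  expect_identical(attr(r1, "columns"), 5:10)
  # two gaps before reference position 5 shift the columns
  aln2 <- c(ref = "AC--DEFGHIKL", o = "MNPQRSTVWYAC")
  r2 <- extract_region(aln2, "ref", c(5, 10))
  expect_identical(attr(r2, "columns"), 7:12)
  # reading the reference row of the slice reproduces its residues
  ref_sub <- gsub("-", "", r2[["ref"]])
  expect_identical(ref_sub, substr(gsub("-", "", aln2[["ref"]]), 5, 10))
  expect_error(extract_region(aln2, "ref", c(5, 60)), "exceeds")
})

test_that("taxon split is disjoint and exhaustive", {
  st <- sim_species_tree(6, 0.2, seed = 3)
  tx <- sim_taxonomy(st$tree)
  tax <- taxonomy_table(tx$taxonomy, tx$leaf_map)
  rows <- setNames(replicate(6, random_peptide(10)), st$tree$tip.label)
  sp <- split_by_taxon(rows, tax, "Prokaryota")
  expect_identical(sum(sp$counts), 6L)
  expect_setequal(c(names(sp$in_group), names(sp$out_group)),
                  names(rows))
})

test_that("logo frequencies sum to one and match entropy arithmetic", {
  lg1 <- logo(c(s = "CPC"))
  expect_true(all(abs(colSums(lg1$freq) - 1) < 1e-12))
  expect_identical(logo_consensus(lg1), "CPC")
  # column with C:2, S:2 of 4 rows
  sub <- c(a = "C", b = "C", c = "S", d = "S")
  lgf <- logo(sub)
  expect_equal(unname(lgf$freq["C", 1]), 0.5)
  lgi <- logo(sub, mode = "information")
  expect_equal(unname(lgi$information[1]), log2(20) - 1,
               tolerance = 1e-12)
  expect_equal(unname(lgi$height["C", 1]), 0.5 * (log2(20) - 1),
               tolerance = 1e-12)
  # gap mass keeps columns summing to 1
  lgg <- logo(c(a = "C-", b = "CC"))
  expect_true(all(abs(colSums(lgg$freq) - 1) < 1e-12))
  expect_equal(unname(lgg$freq["-", 2]), 0.5)
})
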