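test_that("six-frame translation follows the standard code", {
  fr <- translate_six_frames("ATGGCT")
  expect_identical(unname(fr[["+1"]]), "MA")
  # frame -1 of s equals frame +1 of the reverse complement
  s <- "ATGGCTTACCGA"
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(s)))
  expect_identical(translate_six_frames(s)[["-1"]],
                   translate_six_frames(rc)[["+1"]])
  # N renders X, stops render *
  expect_identical(unname(translate_six_frames("TAANNN")[["+1"]]), "*X")
})

test_that("error-free fragments translate back to their source protein", {
  fam <- fixture_family()
  tr <- fam$truth
  ids <- tr$seq_id[tr$subfamily == "IB2"][1:2]
  cds <- back_translate(fam$sequences[ids], seed = 2)
  ests <- fragment_to_ests(cds, mean_fragments_per_gene = 3,
                           fragment_length_distribution = c(240, 0),
                           error_rate = 0, seed = 5)
  for (i in seq_len(nrow(ests$truth))) {
    tt <- ests$truth[i, ]
    fr <- translate_six_frames(ests$ests[[tt$fragment_id]])
    src <- fam$sequences[[tt$source_gene]]
    frame_name <- paste0("+", tt$frame)
    # offset in the protein of the first full codon of this fragment
    aa_start <- (tt$start + (3 - tt$frame) %% 3 - 1) %/% 3 + 1
    pep <- gsub("\\*", "", fr[[if (tt$frame == 1) "+1" else
      c("+3", "+2")[tt$frame - 1]]])
    expect_true(grepl(pep, src, fixed = TRUE))
  }
})

test_that("fragment recruitment enforces its thresholds", {
  fam <- fixture_family()
  aln <- masked_alignment(fam$sequences)
  prof <- build_profile(aln$rows)
  prof <- calibrate_evalues(prof, simulate_background(500, c(150, 20),
                                                      seed = 6))
  member <- fam$sequences[[1]]
  frag <- substr(member, 40, 105)       # 66 residues
  r <- recruit_fragment(prof, c(`+1` = frag), min_bits = 20,
                        min_match_states = 50, fragment_id = "f1")
  expect_false(isTRUE(r$rejected))
  expect_gte(length(r$matched_states), 50)
  r2 <- recruit_fragment(prof, c(`+1` = frag), min_bits = 20,
                         min_match_states = 80)
  expect_true(r2$rejected)
  expect_identical(r2$reason, "too partial")
  set.seed(3)
  r3 <- recruit_fragment(prof, c(`+1` = random_peptide(66)),
                         min_bits = 20, min_match_states = 50)
  expect_true(r3$rejected)
  expect_identical(r3$reason, "below min_bits")
})

test_that("contig merging joins agreeing overlaps, keeps paralogs apart", {
  fam <- fixture_family()
  aln <- masked_alignment(fam$sequences)
  prof <- build_profile(aln$rows)
  gene <- fam$sequences[[1]]
  fa <- recruit_fragment(prof, c(`+1` = substr(gene, 1, 90)),
                         min_bits = 10, min_match_states = 30,
                         fragment_id = "fa")
  fb <- recruit_fragment(prof, c(`+1` = substr(gene, 60, 150)),
                         min_bits = 10, min_match_states = 30,
                         fragment_id = "fb")
  merged <- merge_gene_fragments(list(fa, fb), min_overlap_columns = 10)
  expect_length(merged, 1L)
  expect_setequal(merged[[1]]$members, c("fa", "fb"))
  expect_setequal(merged[[1]]$matched_states,
                  union(fa$matched_states, fb$matched_states))
  # a diverged paralog over the same columns stays separate
  tr <- fam$truth
  par_gene <- fam$sequences[[tr$seq_id[tr$subfamily == "IB4"][1]]]
  fc <- recruit_fragment(prof, c(`+1` = substr(par_gene, 60, 150)),
                         min_bits = 10, min_match_states = 30,
                         fragment_id = "fc")
  merged2 <- merge_gene_fragments(list(fa, fc),
                                  min_overlap_columns = 10,
                                  max_overlap_mismatch = 0.05)
  expect_length(merged2, 2L)
  # single fragment passes through
  expect_length(merge_gene_fragments(list(fa)), 1L)
})

test_that("orthology margin splits ortholog, paralog, ambiguous", {
  fam <- fixture_family()
  tr <- fam$truth
  orth <- fam$sequences[tr$seq_id[tr$subfamily == "IB2"]]
  para <- fam$sequences[tr$seq_id[tr$subfamily == "IB1"]]
  frag_o <- substr(orth[[1]], 30, 120)
  expect_identical(orthology_filter(frag_o, orth[-1], para),
                   "ortholog")
  frag_p <- substr(para[[1]], 30, 120)
  expect_identical(orthology_filter(frag_p, orth[-1], para[-1]),
                   "paralog")
  # a sequence present in both panels is ambiguous by construction
  shared <- orth[[1]]
  expect_identical(
    orthology_filter(substr(shared, 20, 140),
                     c(orth[1], orth[2]), c(orth[1], para[1])),
    "ambiguous")
  expect_error(orthology_filter(frag_o, character(0), para),
               "non-empty")
})

test_that("alignment augmentation is column-faithful and non-invasive", {
  fam <- fixture_family()
  aln <- masked_alignment(fam$sequences)
  prof <- build_profile(aln$rows)
  gene <- fam$sequences[[3]]
  # full-length exact copy reproduces the source row
  full <- recruit_fragment(prof, c(`+1` = gene), min_bits = 10,
                           min_match_states = 50, fragment_id = "copy")
  full$verdict <- "ortholog"
  aug <- insert_into_alignment(aln, full)
  expect_length(aug$rows, length(aln$rows) + 1L)
  expect_identical(nchar(aug$rows[["copy"]]),
                   nchar(aln$rows[[1]]))
  expect_identical(unname(aug$rows[["copy"]]),
                   unname(aln$rows[[3]]))
  # pre-existing rows bytewise unchanged
  expect_identical(aug$rows[names(aln$rows)], aln$rows)
  # partial fragment is gapped outside its matched span
  part <- recruit_fragment(prof, c(`+1` = substr(gene, 30, 100)),
                           min_bits = 10, min_match_states = 30,
                           fragment_id = "part")
  part$verdict <- "ortholog"
  aug2 <- insert_into_alignment(aln, part)
  row <- strsplit(aug2$rows[["part"]], "")[[1]]
  span <- range(part$alignment_columns)
  expect_true(all(row[seq_len(span[1] - 1)] == "-"))
  expect_true(all(row[seq(span[2] + 1, length(row))] == "-"))
  # verdict gate
  part$verdict <- "paralog"
  expect_error(insert_into_alignment(aln, part), "ortholog")
})
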