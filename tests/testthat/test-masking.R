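test_that("insertion-column rule keeps exactly-threshold columns", {
  aln <- c(a = "ACD-EF", b = "AC-DEF", c = "A--DEF", d = "A--DEF")
  # col 3: occupancy 0.25 -> dropped; col 2: 0.50 -> kept
  r <- drop_insertion_columns(aln)
  expect_identical(r$index_map, c(1L, 2L, 4L, 5L, 6L))
  expect_identical(r$column_status[3L], "dropped-insertion")
  # documented switch for the other reading
  r2 <- drop_insertion_columns(aln, keep_at_threshold = FALSE)
  expect_false(2L %in% r2$index_map)
  # gapless alignment unchanged; idempotence
  g <- c(a = "ACDEF", b = "ACDEF")
  expect_identical(drop_insertion_columns(g)$index_map, 1:5)
  expect_identical(drop_insertion_columns(r)$index_map, r$index_map)
})

test_that("partial-sequence removal uses a strict missing threshold", {
  aln <- c(x = strrep("A", 100),
           y = paste0(strrep("A", 49), strrep("-", 51)),
           z = paste0(strrep("A", 50), strrep("-", 50)))
  r <- drop_partial_sequences(aln)
  expect_identical(r$removed_rows, "y")
  expect_setequal(names(r$rows), c("x", "z"))
  # full-length rows untouched; reapplication stable
  expect_identical(drop_partial_sequences(r)$removed_rows, "y")
})

test_that("pairwise alignment matches the affine-gap DP oracle", {
  pa <- align_progressive(c(q = "ACDEFG", s = "ACEFG"))
  expect_identical(unname(pa$rows["q"]), "ACDEFG")
  expect_identical(unname(pa$rows["s"]), "AC-EFG")
  # independent oracle: Biostrings' exact global aligner
  ref <- Biostrings::pairwiseAlignment(
    Biostrings::AAString("ACDEFG"), Biostrings::AAString("ACEFG"),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 1)
  expect_equal(attr(pa, "score"), Biostrings::score(ref))
  set.seed(3)
  for (i in 1:10) {
    a <- random_peptide(sample(6:30, 1)); b <- random_peptide(sample(6:30, 1))
    pa <- align_progressive(c(x = a, y = b))
    ref <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 1)
    expect_equal(attr(pa, "score"), Biostrings::score(ref))
  }
})

test_that("identical and zero-divergence sequences align without gaps", {
  two <- c(a = "MKLVWPQR", b = "MKLVWPQR")
  pa <- align_progressive(two)
  expect_false(any(grepl("-", pa$rows, fixed = TRUE)))
  st <- sim_species_tree(4, depth = 0.2, seed = 2)$tree
  st$edge.length[] <- 0
  fam <- simulate_family(sim_config(st, root_sequence_length = 40,
                                    ancestral_divergence = 0, seed = 6))
  al <- align_progressive(fam$sequences)
  expect_false(any(grepl("-", al$rows, fixed = TRUE)))
  expect_error(align_progressive(c(a = "AC1DE", b = "ACDE")), "illegal")
})

test_that("block selection reproduces a hand-traced 20-column fixture", {
  # 4 rows; conserved count > 2 (i.e. >= 3), flank count >= 4.
  # identity per column (designed):
  #  1:4 2:3 3:4 4:3 | 5-13: nine nonconserved (identity 1) |
  #  14:3 15:4 16:4 17:3 18:1 19:3 20:4
  col <- function(ident) switch(as.character(ident),
    "4" = c("A", "A", "A", "A"), "3" = c("A", "A", "A", "C"),
    "1" = c("A", "C", "D", "E"))
  ident <- c(4, 3, 4, 3, rep(1, 9), 3, 4, 4, 3, 1, 3, 4)
  m <- do.call(cbind, lapply(ident, col))
  aln <- apply(m, 1, paste0, collapse = "")
  names(aln) <- paste0("r", 1:4)
  preset <- block_preset("medium", max_contiguous_nonconserved = 8,
                         min_block_length = 3)
  r <- select_blocks(aln, preset)
  # hand trace: the 9-long nonconserved run 5..13 is rejected;
  # block 1..4 trims to flank columns 1..3; block 14..20 trims to
  # 15..20 (col 14 is not flank-conserved); both meet min length 3.
  expect_identical(r$index_map, c(1L, 2L, 3L, 15L, 16L, 17L, 18L,
                                  19L, 20L))
  # fully conserved alignment keeps everything as one block
  same <- c(a = strrep("ACDEFGHIKL", 2), b = strrep("ACDEFGHIKL", 2),
            c = strrep("ACDEFGHIKL", 2))
  expect_identical(select_blocks(same, "medium")$index_map, 1:20)
  expect_error(block_preset("medium", min_flank_fraction = 0.3),
               "invariant")
})

test_that("preset kept-column sets nest: strict within medium within loose", {
  set.seed(17)
  for (i in 1:50) {
    n <- sample(4:10, 1); L <- sample(20:60, 1)
    m <- matrix(sample(c("A", "C", "D", "E", "F", "-"), n * L, TRUE,
                       prob = c(.28, .28, .14, .14, .06, .10)), n, L)
    a <- apply(m, 1, paste0, collapse = "")
    names(a) <- paste0("s", seq_len(n))
    ks <- select_blocks(a, "strict")$index_map
    km <- select_blocks(a, "medium")$index_map
    kl <- select_blocks(a, "loose")$index_map
    expect_true(all(ks %in% km))
    expect_true(all(km %in% kl))
  }
})

test_that("mask provenance is complete and order-preserving", {
  aln <- c(a = "AC--DEFGHI", b = "ACD-DEFGHI", c = "AC--DEF-HI",
           d = "ACD-DEFGHI")
  r <- select_blocks(drop_insertion_columns(aln),
                     block_preset("loose", min_block_length = 2))
  expect_identical(length(r$column_status), 10L)
  expect_identical(sum(r$column_status == "kept"), length(r$index_map))
  expect_true(all(diff(r$index_map) > 0))
  # rows never reordered
  expect_identical(names(r$rows), names(aln))
  f <- tempfile()
  write_mask_tsv(r, f)
  tab <- read.table(f, header = TRUE, sep = "\t")
  expect_identical(nrow(tab), 10L)
})
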