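make_panel <- function() {
  reference_panel(
    c("prok_Me1", "prok_Me2"),
    c("MKLCPCLLVAGAVWTTRRLKDEHGGFWQNAYT",
      "MKLSPCIIGDEWQNNPPRRSTVYKLMHEDAFC"),
    c("Me+", "Me2+"), c("IB-1", "IB-2"))
}

test_that("best-hit labels transfer from the top local alignment", {
  panel <- make_panel()
  # identity -> self labels
  r <- best_hit_label(panel$sequence[1], panel, min_score = 10)
  expect_identical(r$specificity, "Me+")
  expect_identical(r$hit_id, "prok_Me1")
  # two substitutions keep the label
  q <- sub("TT", "TS", panel$sequence[1])
  q <- sub("GG", "GA", q)
  r2 <- best_hit_label(q, panel, min_score = 10)
  expect_identical(r2$specificity, "Me+")
  expect_identical(r2$class, "IB-1")
  # random decoy stays unassigned at 50 bits
  set.seed(8)
  rd <- best_hit_label(random_peptide(30), panel, min_score = 50)
  expect_identical(rd$specificity, "unassigned")
  expect_error(best_hit_label("MKL", panel[0, ]), "empty")
})

test_that("panel FASTA descriptions carry both labels", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">r1 label=Me+ class=IB-1", "MKLCPCAVWTT",
               ">r2 label=Me2+ class=IB-2", "MKLSPCGDEWQ"), f)
  p <- read_reference_panel(f)
  expect_identical(p$specificity, c("Me+", "Me2+"))
  expect_identical(p$class, c("IB-1", "IB-2"))
})

test_that("motif calls read the reference-anchored columns", {
  aln <- c(ref = "MK-CPCDE", x = "MKLSPCDE", y = "MKLAPCDE",
           z = "MK--PCDE", w = "MKLCPHDE")
  mc <- call_tm6_motif(aln, "ref", 3)
  got <- setNames(mc$trigram, mc$leaf_id)
  expect_identical(unname(got[c("ref", "x", "y", "z", "w")]),
                   c("CPC", "SPC", "APC", "unresolved", "CPH"))
  cls <- setNames(mc$class, mc$leaf_id)
  expect_identical(unname(cls[c("ref", "x", "y", "w")]),
                   c("CPx", "SPC", "APC", "CPx"))
  expect_error(call_tm6_motif(aln, "zz", 3), "absent")
  expect_error(call_tm6_motif(aln, "ref", 7), "exceed")
})

test_that("motif calls match simulation truth on invariant columns", {
  fam <- fixture_family()
  tr <- fam$truth
  aln <- masked_alignment(fam$sequences)   # no indels simulated
  mc <- call_tm6_motif(aln, tr$seq_id[1], tr$motif_start[1])
  got <- mc$trigram[match(tr$seq_id, mc$leaf_id)]
  expect_identical(got, tr$motif)
})

test_that("taxonomy annotation labels nodes with shared ancestors", {
  st <- sim_species_tree(6, depth = 0.2, seed = 14)
  tx <- sim_taxonomy(st$tree)
  tax <- taxonomy_table(tx$taxonomy, tx$leaf_map)
  tr <- annotate_tree(st$tree, tax)
  nt <- ape::Ntip(st$tree)
  # every leaf got its species name; root is the shared root taxon
  expect_identical(tr$node_data$taxon_name[seq_len(nt)],
                   st$tree$tip.label)
  expect_identical(tr$node_data$taxon_name[nt + 1L], "root")
  # the two root children carry their own domains
  kids <- st$tree$edge[st$tree$edge[, 1] == nt + 1L, 2]
  kids <- kids[kids > nt]
  for (k in kids)
    expect_true(tr$node_data$taxon_rank[k] %in%
                  c("superkingdom", "phylum", "species"))
  # unmapped leaf warns and is kept as unknown
  phy2 <- st$tree
  phy2$tip.label[1] <- "alien"
  expect_warning(tr2 <- annotate_tree(phy2, tax), "unknown")
  expect_identical(tr2$node_data$taxon_name[1], "unknown")
})

test_that("clade collapsing preserves leaf counts and paraphyly", {
  st <- sim_species_tree(8, depth = 0.3, seed = 4)
  tx <- sim_taxonomy(st$tree)
  tax <- taxonomy_table(tx$taxonomy, tx$leaf_map)
  tr <- annotate_tree(st$tree, tax)
  col <- collapse_clades(tr, "phylum")
  nt2 <- ape::Ntip(col$phylo)
  counts <- col$node_data$leaf_count[seq_len(nt2)]
  expect_identical(sum(counts), ape::Ntip(st$tree))
  # collapsing below all annotations leaves the tree unchanged
  col2 <- collapse_clades(tr, "species")
  expect_identical(topology_distance(col2, st$tree), 0L)
  expect_error(collapse_clades(tr, "genus"), "absent")
  # forced paraphyly: one taxon split across two clades gives two
  # collapsed tips with the same name
  nodes <- data.frame(
    tax_id = 1:4, parent_id = c(1, 1, 1, 1),
    rank = c("no rank", "phylum", "phylum", "phylum"),
    name = c("root", "P1", "P2", "P1"))
  nodes$tax_id <- c(1L, 2L, 3L, 4L)
  lm <- c(a = 2L, b = 2L, c = 3L, d = 4L, e = 4L)
  tax2 <- taxonomy_table(nodes, lm)
  phy <- ape::read.tree(text = "((a:1,b:1):1,(c:1,(d:1,e:1):1):1);")
  # P1 = {a,b} and {d,e}: two clades, same phylum
  nodes$name[4] <- "P1"
  tr2 <- annotate_tree(phy, tax2)
  cc <- collapse_clades(tr2, "phylum")
  expect_identical(sort(cc$phylo$tip.label), c("P1", "P1", "c"))
})

test_that("subgroup assignment follows nested anchor clades", {
  t6 <- import_tree(
    "(((HMA2:1,(HMA3:1,HMA4:1):1):1,(x1:1,x2:1):1):1,(HMA1:1,y1:1):1);")
  asg <- assign_subgroups(t6, list(`IB-2` = c("HMA2", "HMA3", "HMA4"),
                                   `IB-4` = "HMA1"))
  a <- asg$assignments
  expect_identical(unname(a[c("HMA2", "HMA3", "HMA4")]), rep("IB-2", 3))
  expect_identical(unname(a[["HMA1"]]), "IB-4")
  expect_identical(unname(a[["x1"]]), "unassigned")
  expect_true(all(asg$monophyletic))
  # an anchor clade spanning the whole tree only claims the leftovers
  asg2 <- assign_subgroups(t6, list(small = c("HMA2", "HMA4"),
                                    wide = c("x1", "y1")))
  expect_identical(unname(asg2$assignments[["HMA3"]]), "small")
  expect_identical(unname(asg2$assignments[["x2"]]), "wide")
  expect_false(asg2$monophyletic[["wide"]])
  expect_error(assign_subgroups(t6, list(a = "HMA2", b = "HMA2")),
               "disjoint")
  expect_error(assign_subgroups(t6, list(a = "nope")), "absent")
})

test_that("assignments are invariant to rerooting inside another clade", {
  fam <- fixture_family()
  tr <- fam$truth
  aln <- masked_alignment(fam$sequences)
  mod <- substitution_model("LG", gamma_shape = 1)
  nj <- build_nj(ml_distance_matrix(aln, mod))
  rooted <- root_with_outgroup(nj, tr$seq_id[tr$subfamily == "OUT"])
  anchors <- fixture_anchors(fam, c("IB2", "IB4"))
  names(anchors) <- c("IB-2", "IB-4")
  a1 <- assign_subgroups(rooted, anchors)$assignments
  # reroot on a leaf inside the IB-2 clade: IB-4 assignments unchanged
  inside <- tr$seq_id[tr$subfamily == "IB2"][1]
  rr <- ape::root(ape::unroot(rooted$phylo), outgroup = inside,
                  resolve.root = TRUE)
  a2 <- assign_subgroups(annotated_tree(rr, rooted = TRUE),
                         anchors["IB-4"])$assignments
  ib4 <- names(a1)[a1 == "IB-4"]
  expect_identical(sort(names(a2)[a2 == "IB-4"]), sort(ib4))
})
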