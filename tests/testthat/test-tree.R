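test_that("ML distance matches the 20-state equal-rates closed form", {
  mod <- substitution_model("Poisson", frequencies = "uniform",
                            gamma_shape = Inf)
  expect_equal(ml_pairwise_distance("ARNDC", "ARNDC", mod), 0)
  for (nm in c(10, 20, 30)) {
    a <- strrep("A", 80)
    b <- paste0(strrep("A", 80 - nm), strrep("C", nm))
    p <- nm / 80
    expect_equal(ml_pairwise_distance(a, b, mod),
                 -(19 / 20) * log(1 - 20 * p / 19), tolerance = 1e-6)
  }
  expect_error(ml_pairwise_distance("A--", "-A-", mod), "no shared")
})

test_that("the 1-D optimiser agrees with a grid-search oracle", {
  mod <- substitution_model("LG", gamma_shape = 1, k = 4)
  set.seed(23)
  st <- sim_species_tree(2, depth = 0.3, seed = 3)$tree
  for (i in 1:10) {
    cfg <- sim_config(st, root_sequence_length = 120, seed = 100 + i,
                      ancestral_divergence = 0)
    fam <- simulate_family(cfg)
    a <- fam$sequences[[1]]; b <- fam$sequences[[2]]
    d <- ml_pairwise_distance(a, b, mod)
    # independent oracle: dense grid on the same likelihood
    ia <- match(strsplit(a, "")[[1]], AA20)
    ib <- match(strsplit(b, "")[[1]], AA20)
    nll <- function(t) {
      P <- matrix(0, 20, 20)
      for (r in mod$rates)
        P <- P + mod$U %*% (exp(mod$eval * r * t) * mod$Uinv)
      P <- P / length(mod$rates)
      -sum(log(pmax(P[cbind(ia, ib)], 1e-300)))
    }
    grid <- seq(0.001, 2, by = 0.001)
    best <- grid[which.min(vapply(grid, nll, numeric(1)))]
    expect_lt(abs(d - best), 0.0011)
  }
})

test_that("in-package distances agree with phangorn's ML distances", {
  mod <- substitution_model("LG", gamma_shape = 0.8, k = 4)
  set.seed(4)
  a <- random_peptide(60); b <- random_peptide(60)
  b <- paste0(substr(a, 1, 50), substr(b, 51, 60))
  d1 <- ml_pairwise_distance(a, b, mod)
  pd <- phangorn::phyDat(rbind(x = strsplit(a, "")[[1]],
                               y = strsplit(b, "")[[1]]), type = "AA")
  d2 <- as.numeric(phangorn::dist.ml(pd, model = "LG", k = 4,
                                     shape = 0.8))
  expect_equal(d1, d2, tolerance = 1e-3)
})

test_that("neighbor joining solves 3 taxa exactly and rejects bad input", {
  D <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- build_nj(D)$phylo
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(bl[c("a", "b", "c")]), c(2, 3, 7))
  expect_error(build_nj(D[1:2, 1:2]), "at least 3")
  Dn <- D; Dn[1, 2] <- NA
  expect_error(build_nj(Dn), "NA")
  Ds <- D; Ds[1, 2] <- 6
  expect_error(build_nj(Ds), "symmetric")
})

test_that("neighbor joining recovers additive trees exactly", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(6:12, 1)
    tr <- ape::rtree(n)
    D <- stats::cophenetic(tr)
    nj <- build_nj(D)
    expect_identical(topology_distance(nj, tr), 0L)
    # branch lengths reproduce the additive metric
    expect_lt(max(abs(stats::cophenetic(nj$phylo)[rownames(D),
                                                  colnames(D)] - D)),
              1e-9)
    # cross-check against ape's NJ on the same matrix
    expect_identical(
      phangorn::RF.dist(ape::unroot(nj$phylo),
                        ape::unroot(ape::nj(D))), 0L)
  }
})

test_that("tied distance matrices resolve deterministically", {
  D <- matrix(1, 5, 5); diag(D) <- 0
  dimnames(D) <- list(letters[1:5], letters[1:5])
  t1 <- build_nj(D); t2 <- build_nj(D)
  expect_identical(ape::write.tree(t1$phylo), ape::write.tree(t2$phylo))
})

test_that("bootstrap gives full support to a clean signal and is seeded", {
  # perfectly tree-like signal, repeated 50 times: two split columns
  # ((A,B),(C,D)) plus one private column per leaf
  block <- c(A = "AACAAA", B = "AAACAA", C = "DDAACA", D = "DDAAAC")
  aln <- vapply(block, strrep, character(1), 50)
  mod <- substitution_model("Poisson", frequencies = "uniform",
                            gamma_shape = Inf)
  bt <- bootstrap_support(aln, mod, n_replicates = 30, seed = 5)
  expect_true(all(bt$bipartition_support == 100))
  expect_identical(bt$n_replicates_kept, 30L)
  bt2 <- bootstrap_support(aln, mod, n_replicates = 30, seed = 5)
  expect_identical(bt$bipartition_support, bt2$bipartition_support)
  # no replicates -> supports flagged absent
  bt0 <- bootstrap_support(aln, mod, n_replicates = 0, seed = 5)
  expect_true(all(is.na(bt0$support)))
  expect_error(bootstrap_support(aln[1:3], mod), "at least 4")
})

test_that("outgroup rooting places the root as specified", {
  t0 <- import_tree("((A:1,B:1):1,(C:1,D:1):1);")
  r1 <- root_with_outgroup(t0, "A")
  expect_true(r1$rooted)
  expect_true(ape::is.monophyletic(r1$phylo, c("B", "C", "D")))
  r2 <- root_with_outgroup(t0, c("C", "D"))
  expect_true(ape::is.monophyletic(r2$phylo, c("A", "B")))
  expect_true(ape::is.monophyletic(r2$phylo, c("C", "D")))
  # rooting never changes the unrooted bipartition set
  expect_identical(topology_distance(r2, t0), 0L)
  expect_error(root_with_outgroup(t0, c("A", "B", "C", "D")), "all")
  expect_error(root_with_outgroup(t0, "nope"), "absent")
  expect_warning(root_with_outgroup(t0, c("A", "C")),
                 "not monophyletic")
})

test_that("ladderization is deterministic, stable, topology-preserving", {
  set.seed(12)
  for (i in 1:10) {
    tr <- ape::rtree(20)
    l1 <- ladderize_tree(tr)
    l2 <- ladderize_tree(l1)
    expect_identical(l1$edge, l2$edge)
    expect_identical(topology_distance(tr, l1), 0L)
  }
  # mirrored input converges to the same edge order
  tr <- ape::read.tree(text = "((a:1,(b:1,c:1):1):1,d:1);")
  mr <- ape::read.tree(text = "(d:1,((c:1,b:1):1,a:1):1);")
  expect_identical(ape::write.tree(ladderize_tree(tr)),
                   ape::write.tree(ladderize_tree(mr)))
})

test_that("tree import detects support kinds and resolves NEXUS", {
  t1 <- import_tree("(A:1,(B:1,C:1)0.82:1);")
  expect_identical(t1$support_kind, "pp")
  expect_equal(t1$support[2], 0.82)
  t2 <- import_tree("(A:1,(B:1,C:1)97:1);")
  expect_identical(t2$support_kind, "bootstrap")
  # round trip preserves bipartitions and branch lengths
  set.seed(2)
  tr <- ape::rtree(10)
  f <- tempfile()
  ape::write.tree(tr, f)
  ti <- import_tree(f)
  expect_identical(topology_distance(ti, tr), 0L)
  expect_equal(sort(ti$phylo$edge.length), sort(tr$edge.length),
               tolerance = 1e-9)
  # NEXUS with translate table
  nx <- c("#NEXUS", "begin trees;", "translate", "1 Alpha,", "2 Beta,",
          "3 Gamma;", "tree t = [&U] (1:1,(2:1,3:1):1);", "end;")
  fn <- tempfile(); writeLines(nx, fn)
  t3 <- import_tree(fn)
  expect_setequal(t3$phylo$tip.label, c("Alpha", "Beta", "Gamma"))
  expect_error(import_tree("(A:1,(B:1,C:1"), "parse error")
})

test_that("annotated NEXUS round-trips node metadata", {
  t1 <- import_tree("((A:1,B:1)90:1,(C:1,D:1)80:1);")
  t1$node_data$taxon_name <- c("a", "b", "c", "d", NA, "cladeX",
                               "cladeY")
  t1$node_data$motif <- c("CPC", "CPC", "SPC", "APC", rep(NA, 3))
  f <- tempfile(fileext = ".nex")
  write_annotated_nexus(t1, f)
  t2 <- import_tree(f)
  expect_identical(topology_distance(t1, t2), 0L)
  nd2 <- t2$node_data
  tips2 <- t2$phylo$tip.label
  expect_identical(nd2$motif[match(c("A", "B", "C", "D"), tips2)],
                   c("CPC", "CPC", "SPC", "APC"))
  expect_identical(nd2$taxon_name[match("A", tips2)], "a")
})
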