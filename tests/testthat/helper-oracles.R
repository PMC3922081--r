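# Independent oracles and shared fixtures.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Exhaustive enumeration of all local alignment paths of a sequence
# through a profile (entry into any match state, exit from any match
# state, flanks free).  Independent of the package's DP code: walks the
# state graph recursively and returns every complete path score.
enum_path_scores <- function(profile, seq) {
  chars <- strsplit(toupper(seq), "")[[1L]]
  L <- length(chars)
  M <- profile$match_state_count
  S <- log2(sweep(profile$match_emission, 2L, profile$background, "/"))
  idx <- match(chars, AA20)
  tr <- profile$trans
  entry <- -log2(M)
  scores <- numeric(0)
  rec <- function(i, k, state, sc) {
    if (state == "M") scores <<- c(scores, sc)       # may exit here
    if (state %in% c("M", "I")) {
      if (state == "M" && k < M) rec(i, k + 1L, "D", sc + tr$MD[k])
      if (i < L) {
        if (state == "M" && k < M) rec(i + 1L, k, "I", sc + tr$MI[k])
        if (state == "I") rec(i + 1L, k, "I", sc + tr$II[k])
        if (k < M) {
          t1 <- if (state == "M") tr$MM[k] else tr$IM[k]
          rec(i + 1L, k + 1L, "M", sc + t1 + S[k + 1L, idx[i + 1L]])
        }
      }
    } else {                                         # D
      if (k < M) {
        rec(i, k + 1L, "D", sc + tr$DD[k])
        if (i < L) rec(i + 1L, k + 1L, "M",
                       sc + tr$DM[k] + S[k + 1L, idx[i + 1L]])
      }
    }
  }
  for (s in seq_len(L)) for (k0 in seq_len(M))
    rec(s, k0, "M", entry + S[k0, idx[s]])
  scores
}

random_small_profile <- function(M = NULL, nseq = NULL) {
  if (is.null(M)) M <- sample(2:4, 1L)
  if (is.null(nseq)) nseq <- sample(3:6, 1L)
  aln <- vapply(seq_len(nseq), function(i)
    paste0(sample(AA20[1:8], M, replace = TRUE), collapse = ""),
    character(1L))
  names(aln) <- paste0("s", seq_len(nseq))
  build_profile(aln)
}

random_peptide <- function(L, alphabet = AA20) {
  paste0(sample(alphabet, L, replace = TRUE), collapse = "")
}

# ---- shared synthetic-family fixture (computed once per test run) ----
.fixture_cache <- new.env()

# Study conditions: 6 species (coalescent tree, depth 0.25
# substitutions/site), five ancient subfamilies = one outgroup + the
# four target subgroups, a chloroplast-like paralog pair (IB1/IB1cp,
# both CPC) mirroring a nested ancestral duplication, SPC motif on IB4,
# moderate within-subfamily duplication/loss.
fixture_family <- function() {
  if (!is.null(.fixture_cache$family)) return(.fixture_cache$family)
  st <- sim_species_tree(6, depth = 0.25, seed = 21)$tree
  cfg <- sim_config(st, duplication_rate = 0.05, loss_rate = 0.02,
                    root_sequence_length = 180,
                    motif_spec = c(OUT = "CPC", IB1 = "CPC",
                                   IB1cp = "CPC", IB2 = "CPC",
                                   IB4 = "SPC"),
                    ancestral_divergence = 0.5, seed = 33)
  fam <- simulate_family(cfg)
  fam$species_tree <- st
  fam$config <- cfg
  .fixture_cache$family <- fam
  fam
}

# anchors: up to 3 subfamily members from species chosen greedily for
# maximal spread on the species tree (reference proteins are picked
# from diverse organisms)
fixture_anchors <- function(fam, subfamilies) {
  tr <- fam$truth
  spd <- stats::cophenetic(fam$species_tree)
  anchor_of <- function(sf, k = 3L) {
    ids <- tr$seq_id[tr$subfamily == sf]
    sps <- tr$species_id[tr$subfamily == sf]
    keep <- !duplicated(sps)
    ids <- ids[keep]; sps <- sps[keep]
    if (length(ids) <= k) return(ids)
    sel <- which.max(rowSums(spd[sps, sps]))
    while (length(sel) < k) {
      rest <- setdiff(seq_along(sps), sel)
      add <- rest[which.max(vapply(rest, function(r)
        min(spd[sps[r], sps[sel]]), numeric(1L)))]
      sel <- c(sel, add)
    }
    ids[sel]
  }
  setNames(lapply(subfamilies, anchor_of), subfamilies)
}

fixture_recipe <- function() {
  if (!is.null(.fixture_cache$recipe)) return(.fixture_cache$recipe)
  fam <- fixture_family()
  tr <- fam$truth
  anchors <- fixture_anchors(fam, c("IB1", "IB1cp", "IB2", "IB4"))
  names(anchors) <- c("IB-1", "IB-1-chloroplast", "IB-2", "IB-4")
  res <- run_metal_subtree_recipe(pipeline_config(
    family_sequences = fam$sequences,
    anchors = anchors,
    outgroup = tr$seq_id[tr$subfamily == "OUT"],
    motif_reference = list(id = tr$seq_id[tr$subfamily == "IB2"][1L],
                           position = tr$motif_start[1L]),
    bootstrap_n = 100L, seed = 99L))
  res$anchors <- anchors
  .fixture_cache$recipe <- res
  res
}

# truth subgroup labels in recipe naming
fixture_truth_subgroups <- function(fam) {
  tr <- fam$truth
  map <- c(OUT = "OUT", IB1 = "IB-1", IB1cp = "IB-1-chloroplast",
           IB2 = "IB-2", IB4 = "IB-4")
  setNames(unname(map[tr$subfamily]), tr$seq_id)
}
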