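#' Annotated tree container
#'
#' An `ape` phylo plus per-node support values, a support kind tag
#' (bootstrap percentages on \[0,100\] or imported posterior
#' probabilities on \[0,1\]), per-node metadata (taxonomy, specificity,
#' motif, collapse information) and a rootedness flag.  Bipartition
#' supports are additionally kept keyed by canonical tip-set so they
#' survive rerooting.
#'
#' @param phylo an ape phylo.
#' @param support numeric vector over internal nodes (length `Nnode`).
#' @param support_kind `"none"`, `"bootstrap"` or `"pp"`.
#' @param node_data data frame keyed by node number (column `node`).
#' @param rooted logical.
#' @return object of class `annotated_tree`.
#' @export
annotated_tree <- function(phylo, support = NULL,
                           support_kind = "none", node_data = NULL,
                           rooted = ape::is.rooted(phylo)) {
  nt <- ape::Ntip(phylo)
  if (is.null(support)) support <- rep(NA_real_, phylo$Nnode)
  if (!all(is.na(support))) {
    ok <- support[!is.na(support)]
    if (support_kind == "bootstrap" && any(ok < 0 | ok > 100))
      stop("bootstrap supports must lie in [0, 100]")
    if (support_kind == "pp" && any(ok < 0 | ok > 1))
      stop("posterior probabilities must lie in [0, 1]")
  }
  if (is.null(node_data))
    node_data <- data.frame(node = seq_len(nt + phylo$Nnode),
                            label = c(phylo$tip.label,
                                      rep(NA_character_, phylo$Nnode)),
                            stringsAsFactors = FALSE)
  structure(list(phylo = phylo, support = support,
                 support_kind = support_kind, node_data = node_data,
                 bipartition_support = NULL, rooted = rooted),
            class = "annotated_tree")
}

#' @export
print.annotated_tree <- function(x, ...) {
  cat("annotated_tree:", ape::Ntip(x$phylo), "tips,",
      x$phylo$Nnode, "internal nodes;",
      if (x$rooted) "rooted;" else "unrooted;",
      "support:", x$support_kind, "\n")
  invisible(x)
}

as_phylo <- function(tree) {
  if (inherits(tree, "annotated_tree")) tree$phylo else tree
}

#' Maximum-likelihood pairwise distance
#'
#' Optimizes the independent-sites likelihood of two aligned sequences
#' over the branch length t >= 0 under a reversible amino-acid model
#' with discrete-gamma rate mixing; gap columns are pairwise-deleted.
#'
#' @param seq_a,seq_b aligned sequences (equal length).
#' @param model a [substitution_model()].
#' @param t_max saturation cap (default 10 substitutions/site; capped
#'   distances raise a warning).
#' @return the ML distance (substitutions/site).
#' @export
ml_pairwise_distance <- function(seq_a, seq_b, model, t_max = 10) {
  a <- seq_chars(toupper(seq_a)); b <- seq_chars(toupper(seq_b))
  if (length(a) != length(b)) stop("sequences must be aligned")
  ia <- aa_index(a); ib <- aa_index(b)
  use <- !is.na(ia) & !is.na(ib)
  if (!any(use)) stop("undefined distance: no shared non-gap columns")
  key <- (ia[use] - 1L) * 20L + ib[use]
  cnt <- tabulate(key, 400L)
  nz <- which(cnt > 0L)
  if (all((nz - 1L) %/% 20L + 1L == (nz - 1L) %% 20L + 1L)) return(0)
  nll <- function(t) {
    P <- matrix(0, 20L, 20L)
    for (r in model$rates) P <- P + model_pmat(model, r * t)
    P <- P / length(model$rates)
    -sum(cnt[nz] * log(pmax(t(P)[nz], 1e-300)))
  }
  opt <- optimize(nll, c(1e-9, t_max), tol = 1e-8)
  t_hat <- opt$minimum
  if (t_hat > t_max * 0.995) {
    warning("saturated pair: distance capped at t_max = ", t_max)
    return(t_max)
  }
  # optimize() never evaluates the boundary; snap near-zero optima
  if (t_hat < 5e-8 || nll(1e-9) <= opt$objective) t_hat <- 0
  t_hat
}

#' Pairwise ML distance matrix of an alignment
#'
#' @param aln alignment (named character vector or `masked_alignment`).
#' @param model a [substitution_model()].
#' @param t_max saturation cap passed to [ml_pairwise_distance()].
#' @return symmetric distance matrix with sequence names.
#' @export
ml_distance_matrix <- function(aln, model, t_max = 10) {
  if (inherits(aln, "masked_alignment")) aln <- aln$rows
  n <- length(aln)
  D <- matrix(0, n, n, dimnames = list(names(aln), names(aln)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    D[i, j] <- D[j, i] <- ml_pairwise_distance(aln[[i]], aln[[j]],
                                               model, t_max)
  D
}

#' Neighbor joining with deterministic tie-breaking
#'
#' Canonical neighbor joining; among tied minimal Q entries the pair
#' with the lowest (row, column) index is chosen, and negative branch
#' lengths are clamped to zero.
#'
#' @param distance_matrix symmetric matrix with zero diagonal and
#'   dimnames (>= 3 taxa).
#' @return `annotated_tree` (unrooted; trifurcating root).
#' @export
build_nj <- function(distance_matrix) {
  D <- as.matrix(distance_matrix)
  if (any(is.na(D)) || any(!is.finite(D)))
    stop("distance matrix contains NA/NaN/Inf entries")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix is not symmetric")
  if (any(abs(diag(D)) > 1e-12)) stop("diagonal must be zero")
  n <- nrow(D)
  if (n < 3L) stop("need at least 3 taxa")
  labs <- rownames(D)
  if (is.null(labs)) labs <- paste0("t", seq_len(n))
  nodes <- labs                       # newick fragment per active node
  repeat {
    n <- nrow(D)
    if (n == 3L) break
    R <- rowSums(D)
    Q <- (n - 2) * D - outer(R, R, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin < 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    cand <- cand[order(cand[, 1L], cand[, 2L]), , drop = FALSE]
    i <- cand[1L, 1L]; j <- cand[1L, 2L]
    li <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (n - 2))
    lj <- D[i, j] - li
    li <- max(li, 0); lj <- max(lj, 0)
    new_node <- paste0("(", nodes[i], ":", fmt_bl(li), ",",
                       nodes[j], ":", fmt_bl(lj), ")")
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    nodes <- c(nodes[keep], new_node)
    D <- D2
  }
  l1 <- max(0, (D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  l2 <- max(0, (D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  l3 <- max(0, (D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  nwk <- paste0("(", nodes[1], ":", fmt_bl(l1), ",",
                nodes[2], ":", fmt_bl(l2), ",",
                nodes[3], ":", fmt_bl(l3), ");")
  annotated_tree(ape::read.tree(text = nwk), rooted = FALSE)
}

# canonical bipartition keys of the internal edges of a phylo
tree_bipartition_keys <- function(phy) {
  nt <- ape::Ntip(phy)
  if (phy$Nnode < 2L) return(character(0))
  pp <- ape::prop.part(phy)
  all_tips <- sort(phy$tip.label)
  keys <- character(0)
  for (i in 2:length(pp)) {            # 1 = root clade (all tips)
    side <- sort(phy$tip.label[pp[[i]]])
    if (length(side) <= 1L || length(side) >= nt - 1L) next
    if (all_tips[1L] %in% side) side <- setdiff(all_tips, side)
    keys[length(keys) + 1L] <- paste(sort(side), collapse = "|")
    names(keys)[length(keys)] <- as.character(nt + i)
  }
  keys
}

bipartition_key <- function(phy, tips) {
  all_tips <- sort(phy$tip.label)
  side <- sort(tips)
  if (all_tips[1L] %in% side) side <- setdiff(all_tips, side)
  paste(sort(side), collapse = "|")
}

#' Nonparametric bootstrap support for an NJ tree
#'
#' Resamples alignment columns with replacement, rebuilds the tree per
#' replicate with [ml_distance_matrix()] + [build_nj()], and reports for
#' each internal bipartition of the point-estimate tree the percentage
#' of replicates containing it.  Replicates with an undefined pairwise
#' distance are dropped and counted.
#'
#' @param alignment alignment (>= 4 taxa).
#' @param model a [substitution_model()].
#' @param n_replicates number of pseudo-replicates (default 100).
#' @param seed integer seed; replicate r uses `seed + r`.
#' @param t_max saturation cap for distances.
#' @return `annotated_tree` with `support` (percent, NA when
#'   `n_replicates = 0`), `bipartition_support` keyed by canonical tip
#'   set, and attribute fields `n_replicates_kept`, `n_dropped`.
#' @export
bootstrap_support <- function(alignment, model, n_replicates = 100L,
                              seed = 1L, t_max = 10) {
  if (inherits(alignment, "masked_alignment")) alignment <- alignment$rows
  if (length(alignment) < 4L) stop("need at least 4 taxa")
  m <- aln_matrix(alignment)
  point <- build_nj(ml_distance_matrix(alignment, model, t_max))
  phy <- point$phylo
  keys <- tree_bipartition_keys(phy)
  counts <- setNames(rep(0L, length(keys)), keys)
  kept <- 0L; dropped <- 0L
  for (r in seq_len(n_replicates)) {
    set.seed(seed + r)
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    rep_aln <- matrix_aln(m[, cols, drop = FALSE])
    Dr <- tryCatch(suppressWarnings(
      ml_distance_matrix(rep_aln, model, t_max)),
      error = function(e) NULL)
    if (is.null(Dr)) { dropped <- dropped + 1L; next }
    rep_tree <- suppressWarnings(build_nj(Dr))
    kept <- kept + 1L
    rep_keys <- tree_bipartition_keys(rep_tree$phylo)
    hit <- keys %in% rep_keys
    counts[hit] <- counts[hit] + 1L
  }
  support <- rep(NA_real_, phy$Nnode)
  bip <- NULL
  if (kept > 0L) {
    pct <- 100 * counts / kept
    bip <- setNames(as.numeric(pct), keys)
    node_of <- as.integer(names(keys))
    support[node_of - ape::Ntip(phy)] <- pct
  }
  out <- annotated_tree(phy, support = support,
                        support_kind = if (kept > 0L) "bootstrap"
                                       else "none",
                        rooted = FALSE)
  out$bipartition_support <- bip
  out$n_replicates_kept <- kept
  out$n_dropped <- dropped
  out
}

#' Support of the bipartition separating a tip set
#'
#' @param tree result of [bootstrap_support()].
#' @param tips tip labels of one side of the split.
#' @return support percentage, or `NA` when the split is not an
#'   internal edge of the point tree.
#' @export
split_support <- function(tree, tips) {
  key <- bipartition_key(as_phylo(tree), tips)
  sup <- tree$bipartition_support
  if (is.null(sup) || !key %in% names(sup)) return(NA_real_)
  unname(sup[key])
}

#' Root a tree on an outgroup
#'
#' The root is placed on the branch subtending the smallest clade
#' containing all outgroup taxa.  When the outgroup is not
#' monophyletic in the unrooted tree, the branch maximizing
#' outgroup/ingroup separation is used and a warning is emitted.
#'
#' @param tree `annotated_tree` or phylo.
#' @param outgroup_taxa non-empty character vector of tip labels.
#' @return rooted `annotated_tree` (bipartition supports carried over).
#' @export
root_with_outgroup <- function(tree, outgroup_taxa) {
  phy <- as_phylo(tree)
  if (length(outgroup_taxa) == 0L) stop("outgroup must be non-empty")
  if (!all(outgroup_taxa %in% phy$tip.label))
    stop("outgroup taxa absent from tree: ",
         paste(setdiff(outgroup_taxa, phy$tip.label), collapse = ", "))
  if (setequal(outgroup_taxa, phy$tip.label))
    stop("outgroup cannot contain all taxa")
  nt <- ape::Ntip(phy)
  pp <- ape::prop.part(phy)
  clades <- c(lapply(seq_len(nt), function(i) phy$tip.label[i]),
              lapply(pp, function(ix) phy$tip.label[ix]))
  mono <- any(vapply(clades, function(cl)
    setequal(cl, outgroup_taxa) ||
      setequal(setdiff(phy$tip.label, cl), outgroup_taxa), logical(1L)))
  if (mono) {
    rooted <- ape::root(phy, outgroup = outgroup_taxa,
                        resolve.root = TRUE)
  } else {
    warning("outgroup is not monophyletic; rooting on the branch ",
            "maximizing outgroup/ingroup separation")
    best <- NULL; best_score <- -Inf
    for (e in seq_len(nrow(phy$edge))) {
      child <- phy$edge[e, 2L]
      side <- if (child <= nt) phy$tip.label[child]
              else phy$tip.label[pp[[child - nt]]]
      inn <- setdiff(phy$tip.label, outgroup_taxa)
      sc <- max(length(intersect(side, outgroup_taxa)) +
                  length(setdiff(inn, side)),
                length(setdiff(outgroup_taxa, side)) +
                  length(intersect(side, inn)))
      if (sc > best_score) { best_score <- sc; best <- child }
    }
    rooted <- if (best <= nt)
      ape::root(phy, outgroup = phy$tip.label[best], resolve.root = TRUE)
    else ape::root(phy, node = best, resolve.root = TRUE)
  }
  out <- annotated_tree(rooted, rooted = TRUE,
                        support_kind = if (inherits(tree,
                                                    "annotated_tree"))
                          tree$support_kind else "none")
  if (inherits(tree, "annotated_tree"))
    out$bipartition_support <- tree$bipartition_support
  out
}

#' Ladderize a tree deterministically
#'
#' Children of every node are sorted by descendant-leaf count (ties by
#' lexicographically smallest descendant label); only the edge order
#' changes, so node numbers, metadata, and the bipartition set are
#' untouched.  The operation is a fixed point under reapplication.
#'
#' @param tree `annotated_tree` or phylo.
#' @param direction `"ascending"` (small clades first) or
#'   `"descending"`.
#' @return same class as the input, reordered.
#' @export
ladderize_tree <- function(tree, direction = c("ascending",
                                               "descending")) {
  direction <- match.arg(direction)
  phy <- as_phylo(tree)
  nt <- ape::Ntip(phy)
  children <- split(seq_len(nrow(phy$edge)), phy$edge[, 1L])
  nlv <- integer(nt + phy$Nnode); minl <- character(nt + phy$Nnode)
  info <- function(node) {
    if (node <= nt) { nlv[node] <<- 1L; minl[node] <<- phy$tip.label[node]
      return() }
    for (e in children[[as.character(node)]]) info(phy$edge[e, 2L])
    ch <- phy$edge[children[[as.character(node)]], 2L]
    nlv[node] <<- sum(nlv[ch]); minl[node] <<- min(minl[ch])
  }
  root <- nt + 1L
  info(root)
  new_order <- integer(0)
  walk <- function(node) {
    if (node <= nt) return()
    ee <- children[[as.character(node)]]
    ch <- phy$edge[ee, 2L]
    o <- order(nlv[ch], minl[ch])
    if (direction == "descending") o <- order(-nlv[ch], minl[ch])
    for (e in ee[o]) {
      new_order[length(new_order) + 1L] <<- e
      walk(phy$edge[e, 2L])
    }
  }
  walk(root)
  phy$edge <- phy$edge[new_order, ]
  if (!is.null(phy$edge.length))
    phy$edge.length <- phy$edge.length[new_order]
  attr(phy, "order") <- "cladewise"
  if (inherits(tree, "annotated_tree")) { tree$phylo <- phy; tree }
  else phy
}

#' Robinson-Foulds distance between two trees
#'
#' Thin wrapper over [phangorn::RF.dist()] for topology comparison.
#'
#' @param a,b trees (`annotated_tree` or phylo).
#' @return the RF distance (integer).
#' @export
topology_distance <- function(a, b) {
  phangorn::RF.dist(ape::unroot(as_phylo(a)), ape::unroot(as_phylo(b)))
}
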