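#' Configuration for gene-family simulation
#'
#' Describes the generative scenario the pipeline assumes: a species tree
#' (branch lengths in substitutions/site), a set of subfamilies created by
#' ancestral duplications of one root gene, within-subfamily gene
#' duplication and loss as a birth-death walk down the species tree, and
#' a clade-specific tripeptide motif (e.g. CPC vs SPC vs APC) held
#' invariant at an anchored column within each subfamily.
#'
#' @param species_tree an `ape` phylo with branch lengths
#'   (substitutions/site) and tip labels used as species ids.
#' @param duplication_rate,loss_rate birth-death event rates per unit
#'   branch length (>= 0).
#' @param root_sequence_length protein length of the ancestral gene.
#' @param motif_spec named character vector mapping each subfamily label
#'   to a 3-residue motif, e.g. `c(IB1 = "CPC", IB4 = "SPC")`.
#' @param motif_anchor 1-based column where the motif starts
#'   (within `[1, root_sequence_length - 2]`).
#' @param ancestral_divergence branch length separating subfamily root
#'   sequences (the depth of the ancestral duplications).
#' @param model substitution model name (see [substitution_model()]).
#' @param gamma_shape gamma shape for among-site rate variation.
#' @param seed integer seed; all stages derive from it.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(species_tree, duplication_rate = 0, loss_rate = 0,
                       root_sequence_length = 200L,
                       motif_spec = c(IB1 = "CPC"),
                       motif_anchor = NULL,
                       ancestral_divergence = 0.6,
                       model = "LG", gamma_shape = 1, seed = 1L) {
  stopifnot(inherits(species_tree, "phylo"),
            duplication_rate >= 0, loss_rate >= 0,
            root_sequence_length >= 10L,
            all(nchar(motif_spec) == 3L),
            !anyDuplicated(names(motif_spec)),
            gamma_shape > 0)
  if (is.null(motif_anchor))
    motif_anchor <- max(1L, round(root_sequence_length * 0.6))
  if (motif_anchor < 1L || motif_anchor > root_sequence_length - 2L)
    stop("motif_anchor must lie in [1, root_sequence_length - 2]")
  structure(
    list(species_tree = species_tree,
         duplication_rate = duplication_rate, loss_rate = loss_rate,
         root_sequence_length = as.integer(root_sequence_length),
         motif_spec = motif_spec, motif_anchor = as.integer(motif_anchor),
         ancestral_divergence = ancestral_divergence,
         model = model, gamma_shape = gamma_shape,
         seed = as.integer(seed)),
    class = "sim_config")
}

#' Simulate a gene family with known truth
#'
#' One ancestral gene duplicates into the configured subfamilies at depth
#' `ancestral_divergence`; each subfamily then evolves down the species
#' tree under a continuous-time birth-death duplication/loss walk (events
#' Poisson in branch length).  Sequences evolve site-wise under the named
#' empirical model with discrete-gamma (k = 4) rate heterogeneity; the
#' subfamily motif is written over the anchored columns after simulation
#' so truth labels are exact.
#'
#' @param config a [sim_config()].
#' @return list with `sequences` (named character vector),
#'   `truth` (class `family_truth`: data frame with one row per emitted
#'   sequence: `seq_id`, `species_id`, `subfamily`, `motif`,
#'   `motif_start`), `gene_tree` (ape phylo; duplication nodes labelled
#'   `"D"`), and `empty` flag (all lineages lost).
#' @export
simulate_family <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  model <- substitution_model(config$model, gamma_shape = config$gamma_shape,
                              k = 4L)
  L <- config$root_sequence_length
  site_rates <- model$rates[sample.int(model$k, L, replace = TRUE)]

  sf <- names(config$motif_spec)
  root_seq <- sample(AA_ORDER, L, replace = TRUE, prob = model$freq)

  # subfamily radiation: caterpillar over subfamily labels
  sf_seqs <- list(root = root_seq)
  depth <- config$ancestral_divergence
  if (length(sf) == 1L) {
    sf_seqs[[sf]] <- evolve_seq(root_seq, depth, site_rates, model)
  } else {
    cur <- root_seq
    for (i in seq_along(sf)) {
      sf_seqs[[sf[i]]] <- evolve_seq(cur, depth, site_rates, model)
      if (i < length(sf)) cur <- evolve_seq(cur, depth / length(sf),
                                            site_rates, model)
    }
  }

  sp_tree <- config$species_tree
  records <- list(); seqs <- list(); sub_newicks <- character(0)
  for (s in sf) {
    gt <- bd_gene_tree(sp_tree, config$duplication_rate, config$loss_rate,
                       subfamily = s)
    if (is.null(gt)) next
    phy <- ape::read.tree(text = paste0(gt$newick, ";"))
    leaf_seqs <- evolve_along_tree(phy, sf_seqs[[s]], site_rates, model)
    # enforce invariant motif columns within the subfamily
    motif <- seq_chars(config$motif_spec[[s]])
    a <- config$motif_anchor
    for (id in names(leaf_seqs)) leaf_seqs[[id]][a:(a + 2L)] <- motif
    seqs <- c(seqs, lapply(leaf_seqs, paste0, collapse = ""))
    records[[s]] <- data.frame(
      seq_id = names(leaf_seqs),
      species_id = gt$species[names(leaf_seqs)],
      subfamily = s,
      motif = config$motif_spec[[s]],
      motif_start = a,
      stringsAsFactors = FALSE)
    sub_newicks <- c(sub_newicks, gt$newick)
  }

  if (length(seqs) == 0L) {
    return(list(sequences = character(0),
                truth = empty_truth(), gene_tree = NULL, empty = TRUE))
  }
  truth <- do.call(rbind, records)
  rownames(truth) <- NULL
  class(truth) <- c("family_truth", class(truth))

  # join subfamily trees with the caterpillar shape used for the
  # radiation: (sf1:d, (sf2:d, (sf3:d, ...):d/S):d/S)
  gene_tree <- if (length(sub_newicks) == 1L) {
    ape::read.tree(text = paste0(sub_newicks, ";"))
  } else {
    S <- length(sub_newicks)
    d <- config$ancestral_divergence
    step <- d / S
    nwk <- paste0(sub_newicks[S], ":", fmt_bl(d + step))
    for (i in rev(seq_len(S - 1L))) {
      nwk <- paste0("(", sub_newicks[i], ":", fmt_bl(d), ",", nwk, ")D")
      if (i > 1L) nwk <- paste0(nwk, ":", fmt_bl(step))
    }
    ape::read.tree(text = paste0(nwk, ";"))
  }
  list(sequences = unlist(seqs), truth = truth, gene_tree = gene_tree,
       empty = FALSE)
}

empty_truth <- function() {
  t <- data.frame(seq_id = character(0), species_id = character(0),
                  subfamily = character(0), motif = character(0),
                  motif_start = integer(0), stringsAsFactors = FALSE)
  class(t) <- c("family_truth", class(t))
  t
}

# birth-death walk of one gene lineage down the species tree.
# Returns NULL when every lineage is lost, else a newick subtree string
# (no ";") and a leaf -> species map.  Duplication nodes carry label "D".
# Internal results are (str = subtree without top branch length,
# pl = branch length accumulated below the caller's attachment point).
bd_gene_tree <- function(sp_tree, dup, loss, subfamily) {
  env <- new.env()
  env$counter <- 0L
  env$species <- character(0)
  nt <- ape::Ntip(sp_tree)
  root <- nt + 1L
  kids <- function(node) sp_tree$edge[sp_tree$edge[, 1L] == node, 2L]
  blen <- function(node) sp_tree$edge.length[sp_tree$edge[, 2L] == node]
  total <- dup + loss

  # lineage entering the branch above `node` with t_left to traverse
  walk <- function(node, t_left) {
    e <- if (total > 0) stats::rexp(1L, total) else Inf
    if (e >= t_left) {
      r <- at_node(node)
      if (is.null(r)) return(NULL)
      return(list(str = r$str, pl = r$pl + t_left))
    }
    if (stats::runif(1L) < loss / total) return(NULL)       # loss event
    a <- walk(node, t_left - e)                             # duplication
    b <- walk(node, t_left - e)
    if (is.null(a) && is.null(b)) return(NULL)
    if (is.null(a)) return(list(str = b$str, pl = b$pl + e))
    if (is.null(b)) return(list(str = a$str, pl = a$pl + e))
    list(str = paste0("(", a$str, ":", fmt_bl(a$pl), ",",
                      b$str, ":", fmt_bl(b$pl), ")D"),
         pl = e)
  }

  # lineage arriving at `node` (its branch fully traversed)
  at_node <- function(node) {
    ch <- kids(node)
    if (length(ch) == 0L) {                                 # species leaf
      env$counter <- env$counter + 1L
      sp <- sp_tree$tip.label[node]
      id <- paste0(sp, "_", subfamily, "_g", env$counter)
      env$species[id] <- sp
      return(list(str = id, pl = 0))
    }
    parts <- list()
    for (c1 in ch) {
      r <- walk(c1, blen(c1))
      if (!is.null(r)) parts[[length(parts) + 1L]] <- r
    }
    if (length(parts) == 0L) return(NULL)
    if (length(parts) == 1L) return(parts[[1L]])            # pass-through
    list(str = paste0("(", paste0(vapply(parts, function(r)
      paste0(r$str, ":", fmt_bl(r$pl)), character(1L)),
      collapse = ","), ")"), pl = 0)
  }

  res <- at_node(root)
  if (is.null(res)) return(NULL)
  nwk <- if (grepl("[(,]", res$str)) res$str
         else paste0("(", res$str, ":", fmt_bl(res$pl), ")")
  list(newick = nwk, species = env$species)
}

fmt_bl <- function(x) sprintf("%.10g", x)

# evolve a residue vector over branch length t (site-specific rates)
evolve_seq <- function(chars, t, site_rates, model) {
  if (t <= 0) return(chars)
  out <- chars
  idx <- aa_index(chars)
  for (r in unique(site_rates)) {
    P <- model_pmat(model, r * t)
    sites <- which(site_rates == r)
    for (a in unique(idx[sites])) {
      ss <- sites[idx[sites] == a]
      out[ss] <- sample(AA_ORDER, length(ss), replace = TRUE, prob = P[a, ])
    }
  }
  out
}

# evolve a root sequence down an ape phylo; returns list of residue
# vectors keyed by tip label
evolve_along_tree <- function(phy, root_seq, site_rates, model) {
  nt <- ape::Ntip(phy)
  nn <- nt + phy$Nnode
  seqs <- vector("list", nn)
  root <- nt + 1L
  seqs[[root]] <- root_seq
  ord <- ape::reorder.phylo(phy, "cladewise")
  for (i in seq_len(nrow(ord$edge))) {
    par <- ord$edge[i, 1L]; ch <- ord$edge[i, 2L]
    seqs[[ch]] <- evolve_seq(seqs[[par]], ord$edge.length[i],
                             site_rates, model)
  }
  out <- seqs[seq_len(nt)]
  names(out) <- phy$tip.label
  out
}

#' Simulate decoy (non-family) background proteins
#'
#' i.i.d. sequences with lengths drawn from a normal distribution and
#' residues drawn from the given frequencies; used for E-value
#' calibration and threshold-breakdown tests.
#'
#' @param n number of sequences (>= 0).
#' @param length_distribution numeric `c(mean, sd)` of sequence length.
#' @param residue_frequencies 20-vector summing to 1 (order
#'   ARNDCQEGHILKMFPSTWYV); default uniform.
#' @param seed integer seed.
#' @return named character vector (`decoy1`, `decoy2`, ...).
#' @export
simulate_background <- function(n, length_distribution = c(120, 20),
                                residue_frequencies = rep(1 / 20, 20),
                                seed = 1L) {
  stopifnot(n >= 0, length(residue_frequencies) == 20L)
  if (abs(sum(residue_frequencies) - 1) > 1e-9)
    stop("residue_frequencies must sum to 1")
  if (n == 0L) return(setNames(character(0), character(0)))
  set.seed(seed)
  lens <- pmax(10L, round(rnorm(n, length_distribution[1L],
                                length_distribution[2L])))
  out <- vapply(lens, function(L)
    paste0(sample(AA_ORDER, L, replace = TRUE, prob = residue_frequencies),
           collapse = ""), character(1L))
  names(out) <- paste0("decoy", seq_len(n))
  out
}

#' Back-translate proteins to CDS with uniform synonymous codons
#'
#' @param proteins named character vector of protein sequences.
#' @param seed integer seed.
#' @return named character vector of nucleotide CDS (stop codon appended).
#' @export
back_translate <- function(proteins, seed = 1L) {
  set.seed(seed)
  gc <- Biostrings::GENETIC_CODE
  by_aa <- split(names(gc), gc)
  out <- vapply(proteins, function(p) {
    aas <- seq_chars(p)
    cods <- vapply(aas, function(a) {
      ch <- by_aa[[a]]
      if (is.null(ch)) stop("cannot back-translate residue: ", a)
      ch[sample.int(length(ch), 1L)]
    }, character(1L))
    paste0(c(cods, "TAA"), collapse = "")
  }, character(1L))
  names(out) <- names(proteins)
  out
}

#' Fragment CDS sequences into error-prone EST reads
#'
#' Fragments are drawn from the sense strand at random offsets (the
#' reading frame follows from the offset), with point errors applied at
#' `error_rate` per base.  A truth mapping records the source gene, frame
#' and coordinates of every fragment.
#'
#' @param gene_cds named character vector of CDS (length a multiple of 3).
#' @param mean_fragments_per_gene Poisson mean of fragments per gene.
#' @param fragment_length_distribution numeric `c(mean, sd)` in nt.
#' @param error_rate per-base substitution probability.
#' @param seed integer seed.
#' @return list with `ests` (named nucleotide vector) and `truth`
#'   (data frame: `fragment_id`, `source_gene`, `frame`, `start`, `end`,
#'   `truncated`, `n_errors`).
#' @export
fragment_to_ests <- function(gene_cds, mean_fragments_per_gene = 2,
                             fragment_length_distribution = c(300, 60),
                             error_rate = 0.01, seed = 1L) {
  stopifnot(all(nchar(gene_cds) %% 3L == 0L), error_rate >= 0,
            error_rate < 1)
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  ests <- character(0); rows <- list(); k <- 0L
  for (g in names(gene_cds)) {
    cds <- gene_cds[[g]]
    Lg <- nchar(cds)
    nf <- rpois(1L, mean_fragments_per_gene)
    for (j in seq_len(nf)) {
      k <- k + 1L
      fl <- max(30L, round(rnorm(1L, fragment_length_distribution[1L],
                                 fragment_length_distribution[2L])))
      truncated <- fl > Lg
      fl <- min(fl, Lg)
      start <- sample.int(Lg - fl + 1L, 1L)
      frag <- seq_chars(substr(cds, start, start + fl - 1L))
      nerr <- rbinom(1L, fl, error_rate)
      if (nerr > 0L) {
        pos <- sample.int(fl, nerr)
        frag[pos] <- vapply(frag[pos], function(b)
          sample(setdiff(bases, b), 1L), character(1L))
      }
      id <- paste0("est", k, "_", g)
      ests[id] <- paste0(frag, collapse = "")
      rows[[k]] <- data.frame(
        fragment_id = id, source_gene = g,
        frame = ((start - 1L) %% 3L) + 1L,
        start = start, end = start + fl - 1L,
        truncated = truncated, n_errors = nerr,
        stringsAsFactors = FALSE)
    }
  }
  truth <- if (length(rows)) do.call(rbind, rows) else
    data.frame(fragment_id = character(0), source_gene = character(0),
               frame = integer(0), start = integer(0), end = integer(0),
               truncated = logical(0), n_errors = integer(0))
  list(ests = ests, truth = truth)
}

#' Simulated species tree and mock taxonomy
#'
#' Draws a random coalescent species tree rescaled to a given depth, and
#' derives a four-rank mock taxonomy (root / domain / phylum / species)
#' from its topology: the two root clades become the domains and the
#' next-level clades the phyla.
#'
#' @param n_species number of species.
#' @param depth root-to-tip height in substitutions/site.
#' @param seed integer seed.
#' @return list `tree` (phylo, tips `sp1..spN`) used by [sim_config()].
#' @export
sim_species_tree <- function(n_species, depth = 0.3, seed = 1L) {
  set.seed(seed)
  tr <- ape::rcoal(n_species, tip.label = paste0("sp", seq_len(n_species)))
  h <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length * depth / h
  list(tree = tr)
}

#' @rdname sim_species_tree
#' @param species_tree a phylo from which to derive the taxonomy.
#' @return for `sim_taxonomy()`: list `taxonomy` (data frame with
#'   `tax_id`, `parent_id`, `rank`, `name`) and `leaf_map` (named vector
#'   species -> tax_id).
#' @export
sim_taxonomy <- function(species_tree) {
  tr <- species_tree
  nt <- ape::Ntip(tr)
  root <- nt + 1L
  kids <- function(node) tr$edge[tr$edge[, 1L] == node, 2L]
  tips_under <- function(node) {
    if (node <= nt) return(node)
    unlist(lapply(kids(node), tips_under))
  }
  rows <- list(
    data.frame(tax_id = 1L, parent_id = 1L, rank = "no rank",
               name = "root", stringsAsFactors = FALSE))
  leaf_map <- integer(0)
  nid <- 1L
  domains <- kids(root)
  dom_names <- c("Prokaryota", "Eukaryota")
  for (di in seq_along(domains)) {
    nid <- nid + 1L; dom_id <- nid
    rows[[length(rows) + 1L]] <- data.frame(
      tax_id = dom_id, parent_id = 1L, rank = "superkingdom",
      name = dom_names[min(di, 2L)], stringsAsFactors = FALSE)
    phyla <- kids(domains[di])
    if (length(phyla) == 0L) phyla <- domains[di]  # domain is a single tip
    for (pi in seq_along(phyla)) {
      nid <- nid + 1L; ph_id <- nid
      rows[[length(rows) + 1L]] <- data.frame(
        tax_id = ph_id, parent_id = dom_id, rank = "phylum",
        name = paste0(dom_names[min(di, 2L)], "_phylum", pi),
        stringsAsFactors = FALSE)
      for (tip in tips_under(phyla[pi])) {
        nid <- nid + 1L
        sp <- tr$tip.label[tip]
        rows[[length(rows) + 1L]] <- data.frame(
          tax_id = nid, parent_id = ph_id, rank = "species",
          name = sp, stringsAsFactors = FALSE)
        leaf_map[sp] <- nid
      }
    }
  }
  list(taxonomy = do.call(rbind, rows), leaf_map = leaf_map)
}

#' Write simulation truth to plain-text files
#'
#' @param fam result of [simulate_family()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_truth <- function(fam, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(fam$sequences, file.path(dir, "family.fasta"))
  write.table(fam$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(fam$gene_tree))
    ape::write.tree(fam$gene_tree, file.path(dir, "gene_tree.nwk"))
  invisible(dir)
}
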