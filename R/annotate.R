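#' Reference panel of annotated pump sequences
#'
#' Labeled sequences anchoring substrate-specificity transfer and
#' subgroup definitions (e.g. Me+ / Me2+ specificities, classes IB-1,
#' IB-2, IB-4, IB-1-chloroplast).
#'
#' @param ids unique sequence ids.
#' @param sequences protein sequences.
#' @param specificity substrate specificity labels (e.g. `"Me+"`,
#'   `"Me2+"`, `"Ca"`, `"Na/K"`, `"H"`).
#' @param class class labels (e.g. `"IB-1"`, `"IB-2"`, `"IB-4"`).
#' @param organism optional source organism.
#' @return data frame of class `reference_panel`.
#' @export
reference_panel <- function(ids, sequences, specificity, class,
                            organism = NA_character_) {
  if (anyDuplicated(ids)) stop("panel ids must be unique")
  if (any(is.na(specificity)) || any(is.na(class)))
    stop("every panel record needs both labels")
  out <- data.frame(id = ids, sequence = toupper(sequences),
                    specificity = specificity, class = class,
                    organism = organism, stringsAsFactors = FALSE)
  base::class(out) <- c("reference_panel", base::class(out))
  out
}

#' Read a labeled reference panel from FASTA
#'
#' Labels are read from the description line, e.g.
#' `>AtHMA4 label=Me2+ class=IB-2`.
#'
#' @param path FASTA path.
#' @return `reference_panel`.
#' @export
read_reference_panel <- function(path) {
  set <- Biostrings::readBStringSet(path)
  full <- names(set)
  ids <- sub("\\s.*$", "", full)
  get_tag <- function(tag) {
    m <- regmatches(full, regexpr(paste0(tag, "=[^ ]+"), full))
    out <- rep(NA_character_, length(full))
    hit <- grepl(paste0(tag, "="), full)
    out[hit] <- sub(paste0(tag, "="), "", m)
    out
  }
  reference_panel(ids, as.character(set), get_tag("label"),
                  get_tag("class"), get_tag("organism"))
}

# BLAST-style bit score from a raw local-alignment score
# (gapped BLOSUM62 11/1 constants)
blast_bits <- function(raw, lambda = 0.267, K = 0.041) {
  (lambda * raw - log(K)) / log(2)
}

#' Transfer labels from the best local-alignment hit
#'
#' Aligns the query against every panel record with exact local
#' alignment (BLOSUM62, affine gaps 11/1) and transfers the labels of
#' the top scorer; ties break by longer aligned span, then
#' lexicographic id.
#'
#' @param query protein sequence.
#' @param panel a [reference_panel()].
#' @param min_score minimum bit score for a transfer (default 50); below
#'   it the query is `"unassigned"`.
#' @return list with `specificity`, `class`, `score` (bits), `hit_id`.
#' @export
best_hit_label <- function(query, panel, min_score = 50) {
  if (nrow(panel) == 0L) stop("panel is empty")
  q <- Biostrings::AAString(gsub("[^A-Z]", "", toupper(query)))
  raw <- numeric(nrow(panel)); span <- integer(nrow(panel))
  for (i in seq_len(nrow(panel))) {
    al <- Biostrings::pairwiseAlignment(
      q, Biostrings::AAString(panel$sequence[i]), type = "local",
      substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1)
    raw[i] <- Biostrings::score(al)
    span[i] <- Biostrings::nchar(al)
  }
  bits <- blast_bits(raw)
  o <- order(-bits, -span, panel$id)
  top <- o[1L]
  if (bits[top] < min_score)
    return(list(specificity = "unassigned", class = "unassigned",
                score = bits[top], hit_id = NA_character_))
  list(specificity = panel$specificity[top], class = panel$class[top],
       score = bits[top], hit_id = panel$id[top])
}

#' Label every sequence of a set by best panel hit
#'
#' @param queries named character vector.
#' @param panel a [reference_panel()].
#' @param min_score minimum bit score.
#' @return data frame (`seq_id`, `specificity`, `class`, `score`,
#'   `hit_id`).
#' @export
label_sequences <- function(queries, panel, min_score = 50) {
  rows <- lapply(names(queries), function(id) {
    r <- best_hit_label(queries[[id]], panel, min_score)
    data.frame(seq_id = id, specificity = r$specificity,
               class = r$class, score = r$score, hit_id = r$hit_id,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read metal-binding motif calls at reference-anchored columns
#'
#' The three alignment columns carrying the reference protein's motif
#' (e.g. the CPC of an AtHMA4-like anchor in the sixth transmembrane
#' helix) are read for every row.  Rows with a gap in any of the three
#' columns are `"unresolved"`.  The class follows the trigram: `CP*`
#' becomes `CPx`, `SPC` and `APC` their own classes, anything else
#' `other`.
#'
#' @param alignment alignment or `masked_alignment`.
#' @param reference_id row id of the anchor sequence.
#' @param motif_columns the motif positions in the anchor's UNGAPPED
#'   1-based coordinates (3 consecutive positions; give the first or
#'   all three).
#' @return data frame of class `motif_calls` (`leaf_id`, `trigram`,
#'   `class`, `col1`, `col2`, `col3` in current alignment columns).
#' @export
call_tm6_motif <- function(alignment, reference_id, motif_columns) {
  if (inherits(alignment, "masked_alignment")) alignment <- alignment$rows
  if (!reference_id %in% names(alignment))
    stop("reference leaf absent from alignment: ", reference_id)
  if (length(motif_columns) == 1L)
    motif_columns <- motif_columns + 0:2
  stopifnot(length(motif_columns) == 3L)
  refc <- seq_chars(alignment[[reference_id]])
  ungapped <- cumsum(!is_gap(refc))
  cols <- vapply(motif_columns, function(p) {
    hit <- which(ungapped == p & !is_gap(refc))
    if (length(hit) == 0L) NA_integer_ else hit[1L]
  }, integer(1L))
  if (any(is.na(cols)))
    stop("motif positions exceed the reference's ungapped length")
  if (any(is_gap(refc[cols])))
    stop("reference motif columns are gapped")
  m <- aln_matrix(alignment)
  tri <- apply(m[, cols, drop = FALSE], 1L, paste0, collapse = "")
  unresolved <- apply(m[, cols, drop = FALSE], 1L,
                      function(x) any(is_gap(x)))
  tri[unresolved] <- "unresolved"
  cls <- ifelse(unresolved, "unresolved",
                ifelse(substr(tri, 1L, 2L) == "CP", "CPx",
                       ifelse(tri == "SPC", "SPC",
                              ifelse(tri == "APC", "APC", "other"))))
  out <- data.frame(leaf_id = names(alignment), trigram = unname(tri),
                    class = unname(cls), col1 = cols[1L], col2 = cols[2L],
                    col3 = cols[3L], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  base::class(out) <- c("motif_calls", base::class(out))
  out
}

#' Taxonomy table
#'
#' @param nodes data frame with columns `tax_id`, `parent_id`, `rank`,
#'   `name` (single root: a node whose parent is itself).
#' @param leaf_map named integer vector mapping leaf/genome ids to tax
#'   ids.
#' @return object of class `taxonomy_table`.
#' @export
taxonomy_table <- function(nodes, leaf_map) {
  req <- c("tax_id", "parent_id", "rank", "name")
  if (!all(req %in% names(nodes))) stop("taxonomy needs columns: ",
                                        paste(req, collapse = ", "))
  roots <- nodes$tax_id[nodes$tax_id == nodes$parent_id]
  if (length(roots) != 1L) stop("taxonomy must have a single root")
  parent <- setNames(nodes$parent_id, nodes$tax_id)
  for (id in leaf_map) {
    seen <- integer(0); cur <- id
    repeat {
      if (!as.character(cur) %in% names(parent))
        stop("leaf tax id ", id, " does not resolve to the root")
      if (cur %in% seen) stop("taxonomy parent links contain a cycle")
      seen <- c(seen, cur)
      nxt <- parent[[as.character(cur)]]
      if (nxt == cur) break
      cur <- nxt
    }
  }
  structure(list(nodes = nodes, leaf_map = leaf_map,
                 root = roots), class = "taxonomy_table")
}

#' Read a taxonomy from a 4-column TSV or NCBI-style dumps
#'
#' @param path TSV with header `tax_id parent_id rank name`.
#' @param leaf_map named vector mapping leaves to tax ids (or a
#'   2-column TSV path `leaf_id tax_id`).
#' @return `taxonomy_table`.
#' @export
read_taxonomy <- function(path, leaf_map) {
  nodes <- read.table(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
  if (is.character(leaf_map) && length(leaf_map) == 1L &&
      file.exists(leaf_map)) {
    lm <- read.table(leaf_map, sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE)
    leaf_map <- setNames(lm[[2L]], lm[[1L]])
  }
  taxonomy_table(nodes, leaf_map)
}

#' @rdname read_taxonomy
#' @param nodes_dmp,names_dmp NCBI `nodes.dmp` / `names.dmp` paths
#'   (pipe-delimited dumps; scientific names only).
#' @export
read_taxonomy_ncbi <- function(nodes_dmp, names_dmp, leaf_map) {
  nd <- read.table(nodes_dmp, sep = "|", strip.white = TRUE,
                   stringsAsFactors = FALSE, quote = "")
  nm <- read.table(names_dmp, sep = "|", strip.white = TRUE,
                   stringsAsFactors = FALSE, quote = "")
  nm <- nm[nm[[4L]] == "scientific name", ]
  nodes <- data.frame(tax_id = nd[[1L]], parent_id = nd[[2L]],
                      rank = nd[[3L]],
                      name = nm[[2L]][match(nd[[1L]], nm[[1L]])],
                      stringsAsFactors = FALSE)
  taxonomy_table(nodes, leaf_map)
}

# path of tax ids from root down to `id`
tax_path <- function(tax, id) {
  parent <- setNames(tax$nodes$parent_id, tax$nodes$tax_id)
  path <- integer(0); cur <- id
  repeat {
    path <- c(cur, path)
    nxt <- parent[[as.character(cur)]]
    if (nxt == cur) break
    cur <- nxt
  }
  path
}

tax_field <- function(tax, id, field) {
  tax$nodes[[field]][match(id, tax$nodes$tax_id)]
}

#' Annotate a tree with taxonomy, specificity and motif metadata
#'
#' Leaves carry their taxonomic lineage, substrate specificity and
#' motif call; every internal node is annotated with the lowest common
#' ancestor taxon of its descendant leaves.  Leaves missing from the
#' taxonomy map are annotated `"unknown"` with a warning, never dropped.
#'
#' @param tree `annotated_tree` or phylo.
#' @param taxonomy a [taxonomy_table()]; leaf labels (or their species
#'   prefix before `"_"`) must appear in its `leaf_map`.
#' @param labels optional specificity data frame from
#'   [label_sequences()] or named vector leaf -> label.
#' @param motifs optional [call_tm6_motif()] result.
#' @return `annotated_tree` with `node_data` columns `taxon_id`,
#'   `taxon_rank`, `taxon_name`, `specificity`, `motif`.
#' @export
annotate_tree <- function(tree, taxonomy, labels = NULL, motifs = NULL) {
  tr <- if (inherits(tree, "annotated_tree")) tree
        else annotated_tree(tree)
  phy <- tr$phylo
  nt <- ape::Ntip(phy)
  leaf_species <- function(lab) {
    if (lab %in% names(taxonomy$leaf_map)) return(lab)
    sp <- sub("_.*$", "", lab)
    if (sp %in% names(taxonomy$leaf_map)) return(sp)
    NA_character_
  }
  tax_id <- rep(NA_integer_, nt + phy$Nnode)
  for (i in seq_len(nt)) {
    sp <- leaf_species(phy$tip.label[i])
    if (is.na(sp)) {
      warning("leaf not in taxonomy, annotated as unknown: ",
              phy$tip.label[i])
    } else tax_id[i] <- taxonomy$leaf_map[[sp]]
  }
  paths <- lapply(seq_len(nt), function(i)
    if (is.na(tax_id[i])) integer(0) else tax_path(taxonomy, tax_id[i]))
  # LCA per internal node
  pp <- ape::prop.part(phy)
  for (j in seq_along(pp)) {
    node <- nt + j
    lp <- paths[pp[[j]]]
    lp <- lp[vapply(lp, length, integer(1L)) > 0L]
    if (length(lp) == 0L) next
    shared <- Reduce(function(a, b) a[seq_len(min(length(a), length(b)))][
      a[seq_len(min(length(a), length(b)))] ==
        b[seq_len(min(length(a), length(b)))]], lp)
    if (length(shared)) tax_id[node] <- shared[length(shared)]
  }
  nd <- tr$node_data
  nd$taxon_id <- tax_id
  nd$taxon_rank <- tax_field(taxonomy, tax_id, "rank")
  nd$taxon_name <- tax_field(taxonomy, tax_id, "name")
  nd$taxon_name[seq_len(nt)][is.na(nd$taxon_name[seq_len(nt)])] <-
    "unknown"
  if (!is.null(labels)) {
    lv <- if (is.data.frame(labels))
      setNames(labels$specificity, labels$seq_id) else labels
    nd$specificity <- NA_character_
    nd$specificity[seq_len(nt)] <- unname(lv[phy$tip.label])
  }
  if (!is.null(motifs)) {
    mv <- setNames(motifs$trigram, motifs$leaf_id)
    nd$motif <- NA_character_
    nd$motif[seq_len(nt)] <- unname(mv[phy$tip.label])
  }
  tr$node_data <- nd
  tr$taxonomy <- taxonomy
  tr
}

#' Collapse taxon-homogeneous clades at a rank
#'
#' Every maximal clade (two or more leaves) whose leaves all share one
#' taxon at the given rank is replaced by a single pendant node named
#' for that taxon; the pendant branch length is the incoming branch
#' plus the clade's maximum depth, and the leaf count is recorded.
#' Non-monophyletic taxa yield several collapsed nodes with the same
#' name.
#'
#' @param tree an annotated `annotated_tree` (see [annotate_tree()]).
#' @param rank taxonomy rank at which to collapse (e.g. `"phylum"`).
#' @return `annotated_tree`; collapsed tips carry `leaf_count` in
#'   `node_data`.
#' @export
collapse_clades <- function(tree, rank) {
  stopifnot(inherits(tree, "annotated_tree"))
  if (is.null(tree$taxonomy)) stop("tree is not taxonomy-annotated")
  tax <- tree$taxonomy
  if (!rank %in% tax$nodes$rank)
    stop("rank absent from taxonomy: ", rank)
  phy <- tree$phylo
  nt <- ape::Ntip(phy)
  # taxon at `rank` per leaf, from the leaf's root path
  leaf_taxon <- vapply(seq_len(nt), function(i) {
    tid <- tree$node_data$taxon_id[i]
    if (is.na(tid)) return(NA_character_)
    path <- tax_path(tax, tid)
    at <- path[tax_field(tax, path, "rank") == rank]
    if (length(at)) tax_field(tax, at[1L], "name") else NA_character_
  }, character(1L))

  children <- split(seq_len(nrow(phy$edge)), phy$edge[, 1L])
  # collapsed pendant labels temporarily carry their leaf count as a
  # "@@n" suffix, stripped after parsing (a maximal homogeneous clade
  # is detected when its parent emits it as a pendant)
  rec <- function(node, blen) {
    if (node <= nt)
      return(list(nwk = paste0(phy$tip.label[node], ":", fmt_bl(blen)),
                  taxa = leaf_taxon[node], n = 1L, depth = 0))
    ee <- children[[as.character(node)]]
    parts <- lapply(ee, function(e)
      rec(phy$edge[e, 2L], phy$edge.length[e]))
    taxa <- unique(unlist(lapply(parts, `[[`, "taxa")))
    n <- sum(vapply(parts, `[[`, integer(1L), "n"))
    depth <- max(vapply(seq_along(parts), function(i)
      phy$edge.length[ee[i]] + parts[[i]]$depth, numeric(1L)))
    if (length(taxa) == 1L && !is.na(taxa)) {
      return(list(nwk = paste0(taxa, "@@", n, ":",
                               fmt_bl(blen + depth)),
                  taxa = taxa, n = n, depth = depth))
    }
    list(nwk = paste0("(", paste(vapply(parts, `[[`, character(1L),
                                        "nwk"), collapse = ","),
                      "):", fmt_bl(blen)),
         taxa = taxa, n = n, depth = depth)
  }
  root <- nt + 1L
  res <- rec(root, 0)
  nwk <- sub(":[0-9.eE+-]+$", "", res$nwk)
  if (!grepl("^\\(", nwk)) nwk <- paste0("(", res$nwk, ")")
  phy2 <- ape::read.tree(text = paste0(nwk, ";"))
  lc <- rep(1L, ape::Ntip(phy2))
  tagged <- grepl("@@", phy2$tip.label, fixed = TRUE)
  lc[tagged] <- as.integer(sub("^.*@@", "", phy2$tip.label[tagged]))
  phy2$tip.label <- sub("@@.*$", "", phy2$tip.label)
  out <- annotated_tree(phy2, rooted = tree$rooted)
  out$node_data$label <- c(phy2$tip.label,
                           rep(NA_character_, phy2$Nnode))
  out$node_data$leaf_count <- c(lc, rep(NA_integer_, phy2$Nnode))
  out$collapse_rank <- rank
  out
}

#' Assign leaves to subgroups anchored on reference proteins
#'
#' Each subgroup is the smallest clade of the rooted tree containing
#' all of its anchor leaves; every leaf is assigned to the smallest
#' anchor clade containing it (nested anchor clades claim their leaves
#' first), remaining leaves are `"unassigned"`.  A per-subgroup
#' monophyly verdict reports whether the anchor clade contains only
#' leaves assigned to that subgroup (a nested foreign subgroup clade
#' makes the enclosing subgroup paraphyletic, verdict `FALSE`).
#'
#' @param rooted_tree rooted `annotated_tree` or phylo.
#' @param anchors named list: subgroup -> character vector of anchor
#'   leaf ids (disjoint across subgroups).
#' @return list of class `subgroup_assignment`: `assignments` (named
#'   vector leaf -> subgroup), `anchors`, `monophyletic` (named
#'   logical), `clade_leaves` (list).
#' @export
assign_subgroups <- function(rooted_tree, anchors) {
  phy <- as_phylo(rooted_tree)
  nt <- ape::Ntip(phy)
  all_anchor <- unlist(anchors)
  if (anyDuplicated(all_anchor))
    stop("anchor sets must be disjoint across subgroups")
  missing <- setdiff(all_anchor, phy$tip.label)
  if (length(missing))
    stop("anchor leaves absent from tree: ",
         paste(missing, collapse = ", "))
  clade <- lapply(anchors, function(a) {
    if (length(a) == 1L) return(a)
    mrca <- ape::getMRCA(phy, a)
    phy$tip.label[phangorn::Descendants(phy, mrca, "tips")[[1L]]]
  })
  keys <- vapply(clade, function(x)
    paste(sort(x), collapse = "|"), character(1L))
  if (anyDuplicated(keys))
    stop("two subgroups have identical anchor clades: indistinguishable")
  ord <- names(anchors)[order(vapply(clade, length, integer(1L)))]
  assignments <- setNames(rep("unassigned", nt), phy$tip.label)
  for (g in rev(ord))            # largest first, smaller overwrite
    assignments[clade[[g]]] <- g
  mono <- vapply(names(anchors), function(g)
    all(assignments[clade[[g]]] == g), logical(1L))
  structure(list(assignments = assignments, anchors = anchors,
                 monophyletic = mono, clade_leaves = clade),
            class = "subgroup_assignment")
}

#' @export
print.subgroup_assignment <- function(x, ...) {
  tab <- table(x$assignments)
  cat("subgroup_assignment:\n")
  for (g in names(tab))
    cat("  ", g, ": ", tab[[g]],
        if (g %in% names(x$monophyletic))
          paste0(" (monophyletic: ", x$monophyletic[[g]], ")"),
        "\n", sep = "")
  invisible(x)
}
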