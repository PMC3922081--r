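#' Per-genome category census
#'
#' Counts proteins of each category (architecture, subgroup, or motif
#' class) per genome and derives binary presence.
#'
#' @param assignments data frame with one row per protein; must contain
#'   the protein id column `seq_id` and a category column (default
#'   `category`), or a named vector protein -> category.
#' @param genome_map named vector protein id -> genome id (every
#'   protein must be mapped).
#' @param category_col name of the category column.
#' @param categories optional full category set (empty categories then
#'   appear as all-zero columns).
#' @return matrix of class `presence_absence` (genomes x categories,
#'   integer counts); `attr(, "presence")` is the binary version.
#' @export
census <- function(assignments, genome_map, category_col = "category",
                   categories = NULL) {
  if (!is.data.frame(assignments))
    assignments <- data.frame(seq_id = names(assignments),
                              category = unname(assignments),
                              stringsAsFactors = FALSE)
  if (!category_col %in% names(assignments))
    stop("no category column '", category_col, "'")
  unmapped <- setdiff(assignments$seq_id, names(genome_map))
  if (length(unmapped))
    stop("proteins not mapped to a genome: ",
         paste(unmapped, collapse = ", "))
  genomes <- sort(unique(unname(genome_map[assignments$seq_id])))
  cats <- categories %||% sort(unique(assignments[[category_col]]))
  m <- matrix(0L, length(genomes), length(cats),
              dimnames = list(genomes, cats))
  for (i in seq_len(nrow(assignments))) {
    g <- genome_map[[assignments$seq_id[i]]]
    cc <- assignments[[category_col]][i]
    if (cc %in% cats) m[g, cc] <- m[g, cc] + 1L
  }
  attr(m, "presence") <- (m >= 1L) * 1L
  class(m) <- c("presence_absence", class(m))
  m
}

#' Genome co-occurrence (Venn) counts
#'
#' Counts genomes in each membership region of 2 or 3 chosen
#' categories; regions plus `"none"` always sum to the genome count.
#'
#' @param matrix a [census()] result.
#' @param categories 2 or 3 category (column) names.
#' @return named integer vector of region counts (names like
#'   `"A&B"`, `"A_only"`, `"none"`).
#' @export
cooccurrence <- function(matrix, categories) {
  stopifnot(length(categories) %in% c(2L, 3L))
  if (!all(categories %in% colnames(matrix)))
    stop("unknown categories: ",
         paste(setdiff(categories, colnames(matrix)), collapse = ", "))
  pres <- (unclass(matrix)[, categories, drop = FALSE] >= 1L)
  k <- length(categories)
  patterns <- expand.grid(rep(list(c(TRUE, FALSE)), k))[, k:1,
                                                        drop = FALSE]
  names(patterns) <- categories
  out <- integer(nrow(patterns))
  nm <- character(nrow(patterns))
  for (i in seq_len(nrow(patterns))) {
    pat <- unlist(patterns[i, ])
    out[i] <- sum(apply(pres, 1L, function(r) all(r == pat)))
    nm[i] <- if (!any(pat)) "none" else
      paste(categories[pat], collapse = "&")
  }
  setNames(out, nm)
}

#' Taxonomic breakdown of a census at a rank
#'
#' For each category: the number of genomes containing it, the number
#' of distinct taxa at the rank containing it, and per-taxon genome
#' counts with relative fractions.  Genomes without the rank are
#' counted under `"unranked"` with a warning.
#'
#' @param matrix a [census()] result (rows = genome ids present in the
#'   taxonomy's `leaf_map`).
#' @param taxonomy a [taxonomy_table()].
#' @param rank rank name (e.g. `"phylum"`).
#' @return list: `summary` (category, n_genomes, n_taxa) and `by_taxon`
#'   (category, taxon, n_genomes, fraction).
#' @export
taxonomic_breakdown <- function(matrix, taxonomy, rank) {
  pres <- attr(matrix, "presence")
  genomes <- rownames(matrix)
  taxon_of <- vapply(genomes, function(g) {
    if (!g %in% names(taxonomy$leaf_map)) return(NA_character_)
    path <- tax_path(taxonomy, taxonomy$leaf_map[[g]])
    at <- path[tax_field(taxonomy, path, "rank") == rank]
    if (length(at)) tax_field(taxonomy, at[1L], "name")
    else NA_character_
  }, character(1L))
  if (any(is.na(taxon_of))) {
    warning(sum(is.na(taxon_of)), " genome(s) without rank '", rank,
            "' counted as unranked")
    taxon_of[is.na(taxon_of)] <- "unranked"
  }
  summ <- list(); byt <- list()
  for (cc in colnames(matrix)) {
    has <- genomes[pres[, cc] == 1L]
    tx <- taxon_of[has]
    tab <- table(tx)
    summ[[cc]] <- data.frame(category = cc, n_genomes = length(has),
                             n_taxa = length(tab),
                             stringsAsFactors = FALSE)
    if (length(tab))
      byt[[cc]] <- data.frame(category = cc, taxon = names(tab),
                              n_genomes = as.integer(tab),
                              fraction = as.numeric(tab) / length(has),
                              stringsAsFactors = FALSE)
  }
  list(summary = do.call(rbind, c(summ, list(make.row.names = FALSE))),
       by_taxon = if (length(byt))
         do.call(rbind, c(byt, list(make.row.names = FALSE))) else NULL)
}

#' Extract an alignment region by reference-protein coordinates
#'
#' Maps an interval in the reference row's ungapped 1-based coordinates
#' to alignment columns and slices those columns for all rows; column
#' labels carry the reference numbering.
#'
#' @param alignment alignment or `masked_alignment`.
#' @param reference_id reference row id.
#' @param reference_interval `c(start, end)` in the reference's
#'   ungapped coordinates.
#' @return named character vector (sub-alignment) with attribute
#'   `ref_numbering` (reference coordinate per column; NA on columns
#'   gapped in the reference).
#' @export
extract_region <- function(alignment, reference_id, reference_interval) {
  if (inherits(alignment, "masked_alignment")) alignment <- alignment$rows
  if (!reference_id %in% names(alignment))
    stop("reference row absent: ", reference_id)
  refc <- seq_chars(alignment[[reference_id]])
  ungapped <- cumsum(!is_gap(refc))
  if (reference_interval[2L] > max(ungapped) ||
      reference_interval[1L] < 1L)
    stop("interval exceeds reference ungapped length")
  first <- which(ungapped == reference_interval[1L] & !is_gap(refc))[1L]
  last <- which(ungapped == reference_interval[2L] & !is_gap(refc))[1L]
  cols <- first:last
  m <- aln_matrix(alignment)[, cols, drop = FALSE]
  out <- matrix_aln(m)
  attr(out, "ref_numbering") <- ifelse(is_gap(refc[cols]), NA_integer_,
                                       ungapped[cols])
  attr(out, "columns") <- cols
  out
}

#' Split alignment rows by taxonomic membership
#'
#' @param sub_alignment named character vector.
#' @param taxonomy a [taxonomy_table()].
#' @param in_group_taxon name of the in-group taxon (any rank), e.g.
#'   `"Viridiplantae"`.
#' @return list `in_group`, `out_group` (disjoint, exhaustive) and
#'   `counts`.
#' @export
split_by_taxon <- function(sub_alignment, taxonomy, in_group_taxon) {
  ids <- names(sub_alignment)
  in_grp <- vapply(ids, function(id) {
    key <- if (id %in% names(taxonomy$leaf_map)) id
           else sub("_.*$", "", id)
    if (!key %in% names(taxonomy$leaf_map))
      stop("row not mapped to taxonomy: ", id)
    path <- tax_path(taxonomy, taxonomy$leaf_map[[key]])
    in_group_taxon %in% tax_field(taxonomy, path, "name")
  }, logical(1L))
  list(in_group = sub_alignment[in_grp],
       out_group = sub_alignment[!in_grp],
       counts = c(in_group = sum(in_grp), out_group = sum(!in_grp)))
}

#' Sequence-logo matrix of a sub-alignment
#'
#' Frequency mode (the default): letter height = residue frequency per
#' column (gap mass tracked separately; residue + gap frequencies sum
#' to 1).  Information mode: column information
#' `R = log2(20) - H(column)` with gaps excluded from the entropy and
#' no small-sample correction; letter height = frequency x R.
#'
#' @param sub_alignment named character vector (possibly from
#'   [extract_region()], whose reference numbering is propagated).
#' @param mode `"frequency"` or `"information"`.
#' @return object of class `logo_matrix`: list with `freq` (21 x L:
#'   20 residues + `"-"`), `height` (20 x L), `information`
#'   (per column, information mode), `n_sequences`, `ref_numbering`.
#' @export
logo <- function(sub_alignment, mode = c("frequency", "information")) {
  mode <- match.arg(mode)
  if (length(sub_alignment) == 0L) stop("empty sub-alignment")
  m <- aln_matrix(sub_alignment)
  L <- ncol(m); n <- nrow(m)
  freq <- matrix(0, 21L, L, dimnames = list(c(AA_ORDER, "-"), NULL))
  for (j in seq_len(L)) {
    col <- m[, j]
    col[is_gap(col)] <- "-"
    col[!col %in% c(AA_ORDER, "-")] <- "-"   # ambiguity -> gap mass
    tab <- table(factor(col, levels = c(AA_ORDER, "-")))
    freq[, j] <- as.numeric(tab) / n
  }
  info <- rep(NA_real_, L)
  height <- freq[seq_len(20L), , drop = FALSE]
  if (mode == "information") {
    for (j in seq_len(L)) {
      p <- freq[seq_len(20L), j]
      if (sum(p) > 0) {
        q <- p / sum(p)
        H <- -sum(q[q > 0] * log2(q[q > 0]))
        info[j] <- log2(20) - H
        height[, j] <- q * info[j]
      } else info[j] <- 0
    }
  }
  structure(list(freq = freq, height = height, information = info,
                 mode = mode, n_sequences = n,
                 ref_numbering = attr(sub_alignment, "ref_numbering")),
            class = "logo_matrix")
}

#' Consensus trigram of a 3-column logo
#'
#' @param lg a `logo_matrix` over exactly 3 columns.
#' @return the majority-residue trigram.
#' @export
logo_consensus <- function(lg) {
  paste0(apply(lg$freq[seq_len(20L), , drop = FALSE], 2L, function(p)
    AA_ORDER[which.max(p)]), collapse = "")
}

#' Write a logo matrix as TSV
#'
#' @param lg a `logo_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_logo_tsv <- function(lg, path) {
  df <- data.frame(column = seq_len(ncol(lg$freq)),
                   ref_position = lg$ref_numbering %||%
                     seq_len(ncol(lg$freq)),
                   t(lg$freq), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
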