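#' Masked alignment container
#'
#' Wraps an alignment together with per-column keep/drop provenance.
#' `rows` always holds the currently kept columns; `column_status` is a
#' character vector over the ORIGINAL columns (`kept`,
#' `dropped-insertion`, `dropped-block`, `dropped-gap`), and `index_map`
#' maps kept-column index -> original column (1-based, strictly
#' increasing).
#'
#' @param aln named character vector of aligned sequences, or an
#'   existing `masked_alignment` (returned unchanged).
#' @return object of class `masked_alignment`.
#' @export
masked_alignment <- function(aln) {
  if (inherits(aln, "masked_alignment")) return(aln)
  L <- unique(nchar(aln))
  if (length(L) != 1L) stop("alignment rows have unequal lengths")
  structure(list(rows = aln,
                 column_status = rep("kept", L),
                 index_map = seq_len(L),
                 preset = NA_character_,
                 removed_rows = character(0)),
            class = "masked_alignment")
}

#' @export
print.masked_alignment <- function(x, ...) {
  cat("masked_alignment:", length(x$rows), "sequences x",
      length(x$index_map), "kept /", length(x$column_status),
      "original columns",
      if (!is.na(x$preset)) paste0("(preset ", x$preset, ")"), "\n")
  invisible(x)
}

# apply a drop decision over CURRENT columns, updating provenance
mask_drop <- function(ma, drop_current, reason) {
  keep <- !drop_current
  m <- aln_matrix(ma$rows)
  ma$column_status[ma$index_map[drop_current]] <- reason
  ma$index_map <- ma$index_map[keep]
  ma$rows <- matrix_aln(m[, keep, drop = FALSE])
  ma
}

#' Remove insertion columns by residue occupancy
#'
#' Columns held by fewer than `occupancy_threshold` of the sequences
#' (i.e. positions created by insertions in a minority of the rows) are
#' discarded.  A column at exactly the threshold is kept (the strict
#' reading of "insertions in less than 50%"); set
#' `keep_at_threshold = FALSE` for the other convention.
#'
#' @param aln alignment or `masked_alignment`.
#' @param occupancy_threshold minimum kept residue occupancy (default 0.5).
#' @param keep_at_threshold whether occupancy exactly at the threshold
#'   is kept (default `TRUE`).
#' @return `masked_alignment`; idempotent.
#' @export
drop_insertion_columns <- function(aln, occupancy_threshold = 0.5,
                                   keep_at_threshold = TRUE) {
  ma <- masked_alignment(aln)
  m <- aln_matrix(ma$rows)
  if (ncol(m) == 0L) return(ma)
  occ <- colMeans(!is_gap(m))
  drop <- if (keep_at_threshold) occ < occupancy_threshold
          else occ <= occupancy_threshold
  mask_drop(ma, drop, "dropped-insertion")
}

#' Conserved-block selection presets
#'
#' Named parameter families for [select_blocks()].  The presets are
#' ordered so that the kept-column sets nest:
#' strict \eqn{\subseteq} medium \eqn{\subseteq} loose.
#'
#' @param name `"loose"`, `"medium"` or `"strict"`, or pass the
#'   parameters explicitly.
#' @param min_conserved_fraction a column is conserved when its majority
#'   residue count strictly exceeds this fraction of the rows.
#' @param min_flank_fraction a column is highly conserved (eligible as a
#'   block flank) when the count reaches `ceiling(n * fraction)`.
#' @param max_contiguous_nonconserved longest tolerated run of
#'   nonconserved columns inside a block.
#' @param min_block_length minimum length of a kept block after
#'   flank trimming.
#' @param allowed_gap_rule `"none"` (no gaps tolerated), `"half"`
#'   (gaps in at most half of the rows) or `"all"`.
#' @return object of class `block_preset`.
#' @export
block_preset <- function(name = c("medium", "loose", "strict"),
                         min_conserved_fraction = NULL,
                         min_flank_fraction = NULL,
                         max_contiguous_nonconserved = NULL,
                         min_block_length = NULL,
                         allowed_gap_rule = NULL) {
  name <- match.arg(name)
  def <- switch(name,
    loose  = list(0.50, 0.50, 10L, 5L, "half"),
    medium = list(0.50, 0.85, 8L, 10L, "none"),
    strict = list(0.60, 0.90, 6L, 10L, "none"))
  p <- list(name = name,
            min_conserved_fraction =
              min_conserved_fraction %||% def[[1L]],
            min_flank_fraction = min_flank_fraction %||% def[[2L]],
            max_contiguous_nonconserved =
              max_contiguous_nonconserved %||% def[[3L]],
            min_block_length = min_block_length %||% def[[4L]],
            allowed_gap_rule = allowed_gap_rule %||% def[[5L]])
  if (!(p$min_conserved_fraction >= 0.5 &&
        p$min_conserved_fraction <= p$min_flank_fraction &&
        p$min_flank_fraction <= 1))
    stop("preset invariant violated: need 0.5 <= conserved <= flank <= 1")
  if (p$min_block_length < 2L)
    stop("preset invariant violated: min_block_length >= 2")
  class(p) <- "block_preset"
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Select reliably aligned blocks
#'
#' Conservation filtering in the style of block-selection programs:
#' each column is classified from the frequency of its most common
#' residue (gaps excluded from the numerator, included in the
#' denominator) as nonconserved, conserved, or highly conserved; runs of
#' more than `max_contiguous_nonconserved` nonconserved columns are
#' rejected; surviving blocks are trimmed to highly-conserved
#' boundaries; blocks shorter than `min_block_length` are rejected; and
#' columns violating the preset gap rule are removed.
#'
#' @param aln alignment or `masked_alignment` (already
#'   insertion-filtered).
#' @param preset a [block_preset()] or preset name.
#' @return `masked_alignment` with `preset` recorded.
#' @export
select_blocks <- function(aln, preset = "medium") {
  if (is.character(preset)) preset <- block_preset(preset)
  stopifnot(inherits(preset, "block_preset"))
  ma <- masked_alignment(aln)
  m <- aln_matrix(ma$rows)
  n <- nrow(m); L <- ncol(m)
  if (L == 0L) return(ma)

  ident <- integer(L); gaps <- integer(L)
  for (j in seq_len(L)) {
    col <- m[, j]
    g <- is_gap(col)
    gaps[j] <- sum(g)
    ident[j] <- if (all(g)) 0L else max(table(col[!g]))
  }
  cons_cnt <- floor(n * preset$min_conserved_fraction) + 1L
  flank_cnt <- max(ceiling(n * preset$min_flank_fraction), cons_cnt)
  gap_viol <- switch(preset$allowed_gap_rule,
                     none = gaps > 0L,
                     half = gaps > n / 2,
                     all = rep(FALSE, L))
  status <- ifelse(gap_viol | ident < cons_cnt, "NC",
                   ifelse(ident >= flank_cnt, "HC", "C"))

  keep <- rep(TRUE, L)
  # 1. reject long nonconserved runs
  r <- rle(status == "NC")
  ends <- cumsum(r$lengths)
  for (i in seq_along(r$lengths)) {
    if (r$values[i] && r$lengths[i] > preset$max_contiguous_nonconserved)
      keep[(ends[i] - r$lengths[i] + 1L):ends[i]] <- FALSE
  }
  # 2. trim each remaining block to highly-conserved boundaries
  #    and 3. drop short blocks
  kr <- rle(keep)
  kends <- cumsum(kr$lengths)
  for (i in seq_along(kr$lengths)) {
    if (!kr$values[i]) next
    b <- (kends[i] - kr$lengths[i] + 1L):kends[i]
    hc <- b[status[b] == "HC"]
    if (length(hc) == 0L) { keep[b] <- FALSE; next }
    trimmed <- min(hc):max(hc)
    keep[setdiff(b, trimmed)] <- FALSE
    if (length(trimmed) < preset$min_block_length) keep[trimmed] <- FALSE
  }
  # 4. gap rule inside kept blocks
  keep[gap_viol] <- FALSE

  ma <- mask_drop(ma, !keep, "dropped-block")
  ma$preset <- preset$name
  ma
}

#' Remove partial sequences
#'
#' Rows with strictly more than `missing_threshold` missing characters
#' relative to the longest row (the one with the most non-gap
#' characters) are discarded; removals are recorded in `removed_rows`.
#'
#' @param aln alignment or `masked_alignment`.
#' @param missing_threshold maximum tolerated missing fraction
#'   (default 0.5; removal requires missing > threshold, strictly).
#' @return `masked_alignment`.
#' @export
drop_partial_sequences <- function(aln, missing_threshold = 0.5) {
  ma <- masked_alignment(aln)
  m <- aln_matrix(ma$rows)
  if (nrow(m) == 0L) return(ma)
  nongap <- rowSums(!is_gap(m))
  longest <- max(nongap)
  drop <- nongap < (1 - missing_threshold) * longest
  ma$removed_rows <- c(ma$removed_rows, names(ma$rows)[drop])
  ma$rows <- ma$rows[!drop]
  ma
}

#' Progressive multiple alignment (built-in fallback aligner)
#'
#' Average-linkage guide tree on 3-mer distances, then profile-profile
#' global alignment with affine gap costs (a gap of length g costs
#' `gap_open + g * gap_extend`) under BLOSUM62 column-average scoring.
#' Deterministic; intended for desk-scale inputs — external aligners can
#' be imported instead.
#'
#' @param sequences named character vector (>= 2 protein sequences).
#' @param gap_open,gap_extend affine gap penalties (positive costs).
#' @return `masked_alignment` with all columns kept; rows in input order.
#' @export
align_progressive <- function(sequences, gap_open = 10, gap_extend = 1) {
  if (length(sequences) < 2L) stop("need at least 2 sequences")
  bad <- vapply(sequences, function(s)
    any(!seq_chars(toupper(s)) %in% c(AA_ORDER, "B", "Z", "J",
                                      "X", "U", "O", "*")),
    logical(1L))
  if (any(bad))
    stop("illegal characters in sequence(s): ",
         paste(names(sequences)[bad], collapse = ", "))
  sequences <- toupper(sequences)
  data(list = "BLOSUM62", package = "Biostrings",
       envir = environment())
  sm <- get("BLOSUM62", envir = environment())

  n <- length(sequences)
  if (n == 2L) {
    prof <- profile_align(aln_matrix(sequences[1L]),
                          aln_matrix(sequences[2L]),
                          sm, gap_open, gap_extend)
    out <- matrix_aln(prof)
    ma <- masked_alignment(out[names(sequences)])
    attr(ma, "score") <- attr(prof, "score")
    return(ma)
  }
  D <- kmer_distance(sequences, k = 3L)
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  profiles <- lapply(sequences, function(s) {
    m <- matrix(seq_chars(s), nrow = 1L)
    m
  })
  for (i in seq_along(profiles))
    rownames(profiles[[i]]) <- names(sequences)[i]
  merged <- vector("list", n - 1L)
  for (s in seq_len(n - 1L)) {
    pick <- function(x) if (x < 0) profiles[[-x]] else merged[[x]]
    merged[[s]] <- profile_align(pick(hc$merge[s, 1L]),
                                 pick(hc$merge[s, 2L]),
                                 sm, gap_open, gap_extend)
  }
  final <- merged[[n - 1L]]
  out <- matrix_aln(final)[names(sequences)]
  masked_alignment(out)
}

kmer_distance <- function(sequences, k = 3L) {
  kmers <- lapply(sequences, function(s) {
    ch <- seq_chars(s)
    if (length(ch) < k) return(character(0))
    unique(vapply(seq_len(length(ch) - k + 1L), function(i)
      paste0(ch[i:(i + k - 1L)], collapse = ""), character(1L)))
  })
  n <- length(sequences)
  D <- matrix(0, n, n, dimnames = list(names(sequences), names(sequences)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    shared <- length(intersect(kmers[[i]], kmers[[j]]))
    denom <- max(1L, min(length(kmers[[i]]), length(kmers[[j]])))
    D[i, j] <- D[j, i] <- 1 - shared / denom
  }
  D
}

# column-average BLOSUM score matrix between two profiles: mean
# substitution score over residue pairs per column pair (gaps excluded;
# all-gap column pairs score 0)
profile_score_matrix <- function(sm, A, B) {
  sm20 <- sm[AA_ORDER, AA_ORDER]
  count_cols <- function(P) {
    C <- matrix(0, 20L, ncol(P))
    for (a in seq_len(20L)) C[a, ] <- colSums(P == AA_ORDER[a])
    C
  }
  Ca <- count_cols(A); Cb <- count_cols(B)
  na <- colSums(Ca); nb <- colSums(Cb)
  num <- t(Ca) %*% sm20 %*% Cb
  den <- outer(na, nb)
  S <- num
  S[den > 0] <- num[den > 0] / den[den > 0]
  S[den == 0] <- 0
  S
}

# global profile-profile alignment, affine gaps (Gotoh), deterministic
# traceback preference: diagonal, then gap-in-B, then gap-in-A
profile_align <- function(A, B, sm, gap_open, gap_extend) {
  la <- ncol(A); lb <- ncol(B)
  S <- profile_score_matrix(sm, A, B)
  NEG <- -1e9
  Mm <- matrix(NEG, la + 1L, lb + 1L)
  Xx <- matrix(NEG, la + 1L, lb + 1L)   # gap in B (consume A)
  Yy <- matrix(NEG, la + 1L, lb + 1L)   # gap in A (consume B)
  Mm[1L, 1L] <- 0
  Xx[seq_len(la) + 1L, 1L] <- -gap_open - seq_len(la) * gap_extend
  Yy[1L, seq_len(lb) + 1L] <- -gap_open - seq_len(lb) * gap_extend
  jj <- seq_len(lb)
  for (i in seq_len(la)) {
    prevM <- Mm[i, ]; prevX <- Xx[i, ]; prevY <- Yy[i, ]
    best <- pmax(prevM, pmax(prevX, prevY))[jj]
    Mrow <- c(Mm[i + 1L, 1L], best + S[i, ])
    Xrow <- c(Xx[i + 1L, 1L],
              pmax(prevM[jj + 1L] - gap_open - gap_extend,
                   prevX[jj + 1L] - gap_extend))
    # Y scan along the row: Y[j] = max(M[j-1]-go-ge, Y[j-1]-ge)
    y <- cummax(c(Yy[i + 1L, 1L] + 0,
                  Mrow[jj] - gap_open + gap_extend * (jj - 1L)))
    Yrow <- c(Yy[i + 1L, 1L], y[jj + 1L] - gap_extend * jj)
    Mm[i + 1L, ] <- Mrow; Xx[i + 1L, ] <- Xrow; Yy[i + 1L, ] <- Yrow
  }
  # traceback
  i <- la; j <- lb
  final_score <- max(Mm[la + 1L, lb + 1L], Xx[la + 1L, lb + 1L],
                     Yy[la + 1L, lb + 1L])
  state <- which.max(c(Mm[la + 1L, lb + 1L], Xx[la + 1L, lb + 1L],
                       Yy[la + 1L, lb + 1L]))
  opsA <- integer(0); opsB <- integer(0)   # 1 = consume, 0 = gap
  tol <- 1e-9
  while (i > 0L || j > 0L) {
    if (state == 1L && i > 0L && j > 0L) {
      opsA <- c(1L, opsA); opsB <- c(1L, opsB)
      prev <- Mm[i + 1L, j + 1L] - S[i, j]
      i <- i - 1L; j <- j - 1L
      state <- if (abs(Mm[i + 1L, j + 1L] - prev) < tol) 1L
               else if (abs(Xx[i + 1L, j + 1L] - prev) < tol) 2L else 3L
    } else if (state == 2L || (j == 0L && i > 0L)) {
      opsA <- c(1L, opsA); opsB <- c(0L, opsB)
      prev <- Xx[i + 1L, j + 1L]
      state <- if (i > 1L || j > 0L) {
        if (abs(Mm[i, j + 1L] - gap_open - gap_extend - prev) < tol) 1L
        else 2L
      } else 1L
      i <- i - 1L
    } else {
      opsA <- c(0L, opsA); opsB <- c(1L, opsB)
      prev <- Yy[i + 1L, j + 1L]
      state <- if (j > 1L || i > 0L) {
        if (abs(Mm[i + 1L, j] - gap_open - gap_extend - prev) < tol) 1L
        else 3L
      } else 1L
      j <- j - 1L
    }
  }
  Lout <- length(opsA)
  out <- matrix("-", nrow(A) + nrow(B), Lout)
  rownames(out) <- c(rownames(A), rownames(B))
  ia <- 0L; ib <- 0L
  for (cidx in seq_len(Lout)) {
    if (opsA[cidx] == 1L) { ia <- ia + 1L; out[seq_len(nrow(A)), cidx] <-
      A[, ia] }
    if (opsB[cidx] == 1L) { ib <- ib + 1L
      out[nrow(A) + seq_len(nrow(B)), cidx] <- B[, ib] }
  }
  attr(out, "score") <- final_score
  out
}

#' Write column mask provenance as TSV
#'
#' @param ma a `masked_alignment`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask_tsv <- function(ma, path) {
  write.table(data.frame(column = seq_along(ma$column_status),
                         status = ma$column_status),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
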