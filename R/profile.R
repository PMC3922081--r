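#' Build a profile HMM from a seed alignment
#'
#' Columns whose residue occupancy is at least `occupancy_threshold`
#' become match states; all other columns are treated as insertions
#' (emitting background).  Match emissions are weighted residue counts
#' plus background-proportional pseudocounts; state transitions are
#' estimated from the per-row paths through the alignment under a weak
#' prior favouring match continuation.
#'
#' @param seed_alignment named character vector of aligned sequences
#'   (uniform length; gaps `-` or `.`).
#' @param occupancy_threshold fraction of rows that must hold a residue
#'   for a column to become a match state (default 0.5).
#' @param pseudocount_weight total weight of the background-proportional
#'   emission pseudocount per match state.
#' @param background optional 20-vector of background residue
#'   frequencies; default: observed alignment frequencies, smoothed.
#' @return object of class `profile_hmm`; notably `match_state_count`,
#'   `match_columns` (original alignment columns of the match states)
#'   and, after [calibrate_evalues()], Gumbel parameters `mu`, `lambda`.
#' @export
build_profile <- function(seed_alignment, occupancy_threshold = 0.5,
                          pseudocount_weight = 1, background = NULL) {
  m <- aln_matrix(seed_alignment)
  n <- nrow(m); L <- ncol(m)
  if (n == 0L || L == 0L) stop("empty seed alignment")
  resid <- !is_gap(m)
  occ <- colMeans(resid)
  match_cols <- which(occ >= occupancy_threshold)
  M <- length(match_cols)
  if (M == 0L) stop("no match states: every column is below the ",
                    "occupancy threshold")

  if (is.null(background)) {
    cnt <- table(factor(m[resid & m %in% AA_ORDER], levels = AA_ORDER))
    background <- (as.numeric(cnt) + 1) / (sum(cnt) + 20)
  }
  background <- background / sum(background)

  em <- matrix(0, M, 20L, dimnames = list(NULL, AA_ORDER))
  for (j in seq_len(M)) {
    col <- m[, match_cols[j]]
    cnt <- table(factor(col[col %in% AA_ORDER], levels = AA_ORDER))
    p <- as.numeric(cnt) + pseudocount_weight * background
    em[j, ] <- p / sum(p)
  }

  tr <- estimate_transitions(m, match_cols)

  structure(
    list(match_state_count = M, match_columns = match_cols,
         alignment_length = L,
         match_emission = em, insert_emission = background,
         background = background,
         match_score = log2(sweep(em, 2L, background, "/")),
         trans = tr, occupancy_threshold = occupancy_threshold,
         mu = NULL, lambda = NULL, calib_n = NULL),
    class = "profile_hmm")
}

# per-state transition log2-probabilities from row paths.
# Supported topology: M->M/I/D, I->I/M, D->D/M (I<->D folded into the
# nearest supported move).  Weak prior: continuation 1.0, gap moves 0.125.
estimate_transitions <- function(m, match_cols) {
  M <- length(match_cols)
  pr_main <- 1; pr_gap <- 0.125
  cMM <- rep(pr_main, max(M - 1L, 1L)); cMI <- rep(pr_gap, max(M - 1L, 1L))
  cMD <- rep(pr_gap, max(M - 1L, 1L)); cII <- rep(pr_gap, max(M - 1L, 1L))
  cIM <- rep(pr_main, max(M - 1L, 1L)); cDD <- rep(pr_gap, max(M - 1L, 1L))
  cDM <- rep(pr_main, max(M - 1L, 1L))
  is_match <- logical(ncol(m)); is_match[match_cols] <- TRUE
  for (r in seq_len(nrow(m))) {
    row <- m[r, ]
    state <- "none"; k <- 0L
    for (j in seq_len(ncol(m))) {
      if (is_match[j]) {
        new <- if (is_gap(row[j])) "D" else "M"
        if (k >= 1L && k < M) {
          key <- paste0(state, new)
          switch(key,
                 MM = cMM[k] <- cMM[k] + 1,
                 MD = cMD[k] <- cMD[k] + 1,
                 IM = cIM[k] <- cIM[k] + 1,
                 ID = cMD[k] <- cMD[k] + 1,   # folded
                 DM = cDM[k] <- cDM[k] + 1,
                 DD = cDD[k] <- cDD[k] + 1)
        }
        state <- new; k <- k + 1L
      } else if (!is_gap(row[j])) {
        if (k >= 1L && k < M) {
          if (state == "M") cMI[k] <- cMI[k] + 1
          else if (state == "I") cII[k] <- cII[k] + 1
          # D -> I folded into D -> D (no-op on counts)
          state <- "I"
        }
      }
    }
  }
  mt <- cMM + cMI + cMD
  it <- cII + cIM
  dt <- cDD + cDM
  list(MM = log2(cMM / mt), MI = log2(cMI / mt), MD = log2(cMD / mt),
       II = log2(cII / it), IM = log2(cIM / it),
       DD = log2(cDD / dt), DM = log2(cDM / dt))
}

# per-residue match log-odds (bits) for one sequence, incl. ambiguity
# codes scored as background-weighted averages over their residue sets
match_score_matrix <- function(profile, chars) {
  L <- length(chars)
  M <- profile$match_state_count
  S <- matrix(0, L, M)
  idx <- aa_index(chars)
  known <- !is.na(idx)
  if (any(known)) S[known, ] <- t(profile$match_score[, idx[known],
                                                      drop = FALSE])
  if (any(!known)) {
    amb_sets <- list(B = c("N", "D"), Z = c("Q", "E"), J = c("I", "L"),
                     X = AA_ORDER, U = AA_ORDER, O = AA_ORDER)
    for (i in which(!known)) {
      set <- amb_sets[[chars[i]]]
      if (is.null(set)) set <- AA_ORDER
      w <- profile$background[match(set, AA_ORDER)]
      w <- w / sum(w)
      num <- profile$match_emission[, match(set, AA_ORDER),
                                    drop = FALSE] %*% w
      den <- sum(profile$background[match(set, AA_ORDER)] * w)
      S[i, ] <- log2(as.numeric(num) / den)
    }
  }
  S
}

# log2(2^a + 2^b) elementwise, -Inf-safe
log2add <- function(a, b) {
  m <- pmax(a, b)
  r <- m + log2(2^(a - m) + 2^(b - m))
  r[is.infinite(m) & m < 0] <- -Inf
  r
}

# running log2-sum-exp of a vector (single-offset variant)
log2cumsumexp <- function(v) {
  if (all(!is.finite(v))) return(rep(-Inf, length(v)))
  m <- max(v[is.finite(v)])
  m + log2(cumsum(2^(v - m)))
}

#' Score a sequence against a profile HMM
#'
#' Computes the local-alignment Viterbi and Forward log-odds scores (in
#' bits) of a protein sequence under the profile, relative to the
#' background model.  Local semantics: uniform `1/M` entry into any
#' match state, free exit from any match state, flanking residues scored
#' as background (0 bits), insert emissions equal to background.
#'
#' @param profile a [build_profile()] result.
#' @param seq protein sequence (character scalar).
#' @param traceback if `TRUE`, also return the Viterbi state path.
#' @param forward if `FALSE`, skip the Forward recursion
#'   (`forward_bits` is `NA`); Viterbi-only scoring is what calibration
#'   and screening use.
#' @return list with `viterbi_bits`, `forward_bits`, and (if requested)
#'   `path`: data frame of emitted positions (`pos`, `state` M/I,
#'   `match_state`).
#' @export
score_sequence <- function(profile, seq, traceback = FALSE,
                           forward = TRUE) {
  chars <- seq_chars(toupper(seq))
  chars <- chars[!is_gap(chars)]
  M <- profile$match_state_count
  L <- length(chars)
  entry <- -log2(M)
  if (L == 0L) {
    # defined score of the all-delete path
    s <- entry + if (M > 1L) sum(profile$trans$DD) else 0
    return(list(viterbi_bits = s, forward_bits = s,
                path = if (traceback) data.frame(pos = integer(0),
                                                 state = character(0),
                                                 match_state = integer(0))))
  }
  S <- match_score_matrix(profile, chars)
  tr <- profile$trans

  VM <- matrix(-Inf, L, M); VI <- matrix(-Inf, L, M)
  VD <- matrix(-Inf, L, M)
  FM <- matrix(-Inf, L, M); FI <- matrix(-Inf, L, M)
  FD <- matrix(-Inf, L, M)

  VM[, 1L] <- S[, 1L] + entry
  if (forward) FM[, 1L] <- S[, 1L] + entry
  if (L > 1L && M > 1L) {
    ii <- seq_len(L)
    VI[, 1L] <- c(-Inf, (tr$MI[1L] + (ii[-1L] - 2L) * tr$II[1L]) +
                    cummax(VM[-L, 1L] - (ii[-L] - 1L) * tr$II[1L]))
    if (forward)
      FI[, 1L] <- c(-Inf, (tr$MI[1L] + (ii[-1L] - 2L) * tr$II[1L]) +
                      log2cumsumexp(FM[-L, 1L] - (ii[-L] - 1L) *
                                      tr$II[1L]))
  }
  if (M > 1L) for (k in 2L:M) {
    km <- k - 1L
    VD[, k] <- pmax(VM[, km] + tr$MD[km], VD[, km] + tr$DD[km])
    prevVM <- c(-Inf, VM[-L, km]); prevVI <- c(-Inf, VI[-L, km])
    prevVD <- c(-Inf, VD[-L, km])
    VM[, k] <- S[, k] + pmax(entry,
                             pmax(prevVM + tr$MM[km],
                                  pmax(prevVI + tr$IM[km],
                                       prevVD + tr$DM[km])))
    if (forward) {
      FD[, k] <- log2add(FM[, km] + tr$MD[km], FD[, km] + tr$DD[km])
      prevFM <- c(-Inf, FM[-L, km]); prevFI <- c(-Inf, FI[-L, km])
      prevFD <- c(-Inf, FD[-L, km])
      FM[, k] <- S[, k] +
        log2add(log2add(rep(entry, L), prevFM + tr$MM[km]),
                log2add(prevFI + tr$IM[km], prevFD + tr$DM[km]))
    }
    if (k < M && L > 1L) {
      ii <- seq_len(L)
      VI[, k] <- c(-Inf, (tr$MI[k] + (ii[-1L] - 2L) * tr$II[k]) +
                     cummax(VM[-L, k] - (ii[-L] - 1L) * tr$II[k]))
      if (forward)
        FI[, k] <- c(-Inf, (tr$MI[k] + (ii[-1L] - 2L) * tr$II[k]) +
                       log2cumsumexp(FM[-L, k] - (ii[-L] - 1L) *
                                       tr$II[k]))
    }
  }

  vit <- max(VM)
  fwd <- NA_real_
  if (forward) {
    m0 <- max(FM)
    fwd <- m0 + log2(sum(2^(FM - m0)))
  }

  out <- list(viterbi_bits = vit, forward_bits = fwd)
  if (traceback)
    out$path <- viterbi_traceback(profile, chars, S, VM, VI, VD)
  out
}

# reconstruct the Viterbi path from the filled DP matrices
viterbi_traceback <- function(profile, chars, S, VM, VI, VD) {
  tr <- profile$trans
  M <- profile$match_state_count
  L <- length(chars)
  entry <- -log2(M)
  best <- which(VM == max(VM), arr.ind = TRUE)
  best <- best[order(best[, 1L], best[, 2L]), , drop = FALSE][1L, ]
  i <- best[[1L]]; k <- best[[2L]]
  tol <- 1e-9
  rows <- list()
  state <- "M"
  repeat {
    if (state == "M") {
      rows[[length(rows) + 1L]] <-
        data.frame(pos = i, state = "M", match_state = k)
      target <- VM[i, k] - S[i, k]
      if (i == 1L || k == 1L || abs(target - entry) < tol) {
        if (k > 1L && i > 1L) {
          # prefer an extension over a fresh entry only if one matches
          cand <- c(M = VM[i - 1L, k - 1L] + tr$MM[k - 1L],
                    I = VI[i - 1L, k - 1L] + tr$IM[k - 1L],
                    D = VD[i - 1L, k - 1L] + tr$DM[k - 1L])
          hit <- names(cand)[abs(cand - target) < tol]
          if (length(hit)) { state <- hit[1L]; i <- i - 1L; k <- k - 1L
                             next }
        }
        break                                   # fresh entry
      }
      cand <- c(M = VM[i - 1L, k - 1L] + tr$MM[k - 1L],
                I = VI[i - 1L, k - 1L] + tr$IM[k - 1L],
                D = VD[i - 1L, k - 1L] + tr$DM[k - 1L])
      hit <- names(cand)[abs(cand - target) < tol]
      if (!length(hit)) break
      state <- hit[1L]; i <- i - 1L; k <- k - 1L
    } else if (state == "I") {
      rows[[length(rows) + 1L]] <-
        data.frame(pos = i, state = "I", match_state = k)
      target <- VI[i, k]
      if (abs(VM[i - 1L, k] + tr$MI[k] - target) < tol) state <- "M"
      else state <- "I"
      i <- i - 1L
    } else {                                    # D
      target <- VD[i, k]
      if (abs(VM[i, k - 1L] + tr$MD[k - 1L] - target) < tol) state <- "M"
      else state <- "D"
      k <- k - 1L
    }
  }
  path <- do.call(rbind, rev(rows))
  rownames(path) <- NULL
  path
}

# maximum-likelihood Gumbel (max-domain) fit
fit_gumbel <- function(x) {
  if (stats::sd(x) < 1e-12)
    stop("calibration failure: degenerate decoy score variance")
  xc <- x - mean(x)
  g <- function(lam) {
    v <- -lam * xc
    w <- exp(v - max(v))               # overflow-safe weights
    1 / lam + sum(xc * w) / sum(w)
  }
  lam <- uniroot(g, c(1e-3 / stats::sd(x), 1e3 / stats::sd(x)),
                 tol = 1e-10)$root
  mu <- mean(x) - log(mean(exp(-lam * xc))) / lam
  list(mu = mu, lambda = lam)
}

#' Calibrate profile E-values on decoy scores
#'
#' Scores the decoys with the profile, fits a Gumbel
#' (extreme-value) distribution to the Viterbi bit scores by maximum
#' likelihood, and stores the location `mu` and scale `lambda` so that
#' `E(s) = n * P(S >= s)` under the fit.
#'
#' @param profile a [build_profile()] result.
#' @param decoys named character vector of decoy protein sequences
#'   (at least 500), or a numeric vector of pre-computed bit scores.
#' @param database_size `n` used when reporting E-values; defaults to
#'   the number of decoys.
#' @return the profile with `mu`, `lambda`, `calib_n` filled in.
#' @export
calibrate_evalues <- function(profile, decoys, database_size = NULL) {
  if (is.numeric(decoys)) {
    scores <- decoys
  } else {
    if (length(decoys) < 500L)
      stop("calibration requires at least 500 decoys")
    scores <- vapply(decoys, function(s)
      score_sequence(profile, s, forward = FALSE)$viterbi_bits,
      numeric(1L))
  }
  if (length(scores) < 500L)
    stop("calibration requires at least 500 decoy scores")
  fit <- fit_gumbel(scores)
  profile$mu <- fit$mu
  profile$lambda <- fit$lambda
  profile$calib_n <- if (is.null(database_size)) length(scores)
                     else database_size
  profile
}

#' E-value of a bit score under a calibrated profile
#'
#' @param profile calibrated profile.
#' @param bits numeric bit score(s).
#' @param n database size; default the calibration `n`.
#' @return numeric E-value(s): `n * (1 - exp(-exp(-lambda (s - mu))))`.
#' @export
evalue <- function(profile, bits, n = NULL) {
  if (is.null(profile$lambda)) stop("profile is not calibrated")
  if (is.null(n)) n <- profile$calib_n
  n * (-expm1(-exp(-profile$lambda * (bits - profile$mu))))
}

#' Detect the empirical E-value breakdown separating family from noise
#'
#' Finds the largest gap between consecutive sorted log10 E-values.  If
#' the gap spans at least `min_gap_orders` orders of magnitude the
#' threshold is the geometric midpoint of the two flanking E-values;
#' otherwise no threshold is reported.  Ties in gap size resolve toward
#' the smaller (more stringent) threshold; E-values of exactly 0 are
#' clamped to the smallest positive double.
#'
#' @param hits a `hit_table` (or any data frame with an `evalue` column),
#'   or a numeric vector of E-values.
#' @param min_gap_orders minimum gap, in log10 units (default 3).
#' @return list with `threshold` and `gap_orders`, or `NULL`.
#' @export
detect_threshold_break <- function(hits, min_gap_orders = 3) {
  ev <- if (is.numeric(hits)) hits else hits$evalue
  ev <- ev[is.finite(ev)]
  ev[ev <= 0] <- .Machine$double.xmin
  if (length(ev) < 2L) stop("need at least 2 hits with finite E-values")
  le <- sort(log10(ev))
  gaps <- diff(le)
  if (max(gaps) <= 0) return(NULL)            # all E-values identical
  g <- which(gaps == max(gaps))[1L]           # earliest = smallest mid
  if (gaps[g] < min_gap_orders) return(NULL)
  list(threshold = 10^((le[g] + le[g + 1L]) / 2),
       gap_orders = gaps[g])
}

#' Screen proteomes with a calibrated profile
#'
#' Scores every sequence of every proteome and reports the ones with
#' E-value at or below the cutoff, together with the aligned span on the
#' query (first and last residue emitted by a match state).
#'
#' @param profile calibrated profile.
#' @param proteomes either a character vector of FASTA paths (names used
#'   as proteome ids, default the base file name) or a named list of
#'   named sequence vectors.
#' @param evalue_cutoff maximum E-value of a reported hit.
#' @return `hit_table` data frame (`seq_id`, `proteome_id`, `bits`,
#'   `evalue`, `qstart`, `qend`) sorted by ascending E-value.
#' @export
screen_proteomes <- function(profile, proteomes, evalue_cutoff) {
  if (is.null(profile$lambda)) stop("profile is not calibrated")
  if (is.character(proteomes)) {
    ids <- if (is.null(names(proteomes)))
      sub("\\.[^.]*$", "", basename(proteomes)) else names(proteomes)
    seqsets <- vector("list", length(proteomes))
    names(seqsets) <- ids
    for (i in seq_along(proteomes)) {
      seqsets[[i]] <- tryCatch(read_fasta(proteomes[i]), error = function(e) {
        warning("skipping unreadable FASTA '", proteomes[i], "': ",
                conditionMessage(e))
        character(0)
      })
    }
  } else seqsets <- proteomes
  rows <- list()
  for (pid in names(seqsets)) {
    seqs <- seqsets[[pid]]
    for (sid in names(seqs)) {
      sc <- score_sequence(profile, seqs[[sid]], forward = FALSE)
      ev <- evalue(profile, sc$viterbi_bits)
      if (ev <= evalue_cutoff) {
        tb <- score_sequence(profile, seqs[[sid]], traceback = TRUE,
                             forward = FALSE)$path
        emitted <- tb$pos[tb$state == "M"]
        rows[[length(rows) + 1L]] <- data.frame(
          seq_id = sid, proteome_id = pid, bits = sc$viterbi_bits,
          evalue = ev,
          qstart = if (length(emitted)) min(emitted) else NA_integer_,
          qend = if (length(emitted)) max(emitted) else NA_integer_,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(seq_id = character(0), proteome_id = character(0),
               bits = numeric(0), evalue = numeric(0),
               qstart = integer(0), qend = integer(0))
  out <- out[order(out$evalue, out$seq_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("hit_table", class(out))
  out
}

#' Write / read a profile as a versioned plain-text file
#'
#' @param profile a `profile_hmm`.
#' @param path file path.
#' @return `path` (write) or the profile (read).
#' @export
write_profile <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cat("metalphylo-profile 1\n", file = con)
  cat("M", profile$match_state_count, "\n", file = con)
  cat("match_columns", profile$match_columns, "\n", file = con)
  cat("alignment_length", profile$alignment_length, "\n", file = con)
  cat("occupancy_threshold", profile$occupancy_threshold, "\n", file = con)
  cat("background", format(profile$background, digits = 17), "\n",
      file = con)
  for (nm in names(profile$trans))
    cat(paste0("t", nm), format(profile$trans[[nm]], digits = 17), "\n",
        file = con)
  cat("calibration",
      if (is.null(profile$mu)) "none" else
        paste(format(c(profile$mu, profile$lambda), digits = 17),
              profile$calib_n), "\n", file = con)
  cat("emissions\n", file = con)
  utils::write.table(format(profile$match_emission, digits = 17),
                     con, quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1L], "metalphylo-profile"))
    stop("not a metalphylo profile file")
  kv <- function(key) {
    ln <- lines[startsWith(lines, paste0(key, " "))][1L]
    strsplit(sub(paste0("^", key, " "), "", ln), " +")[[1L]]
  }
  M <- as.integer(kv("M"))
  emi_at <- which(lines == "emissions")
  em <- do.call(rbind, lapply(lines[(emi_at + 1L):(emi_at + M)],
                              function(l) as.numeric(strsplit(trimws(l),
                                                              " +")[[1L]])))
  colnames(em) <- AA_ORDER
  bg <- as.numeric(kv("background"))
  trn <- lapply(c("MM", "MI", "MD", "II", "IM", "DD", "DM"),
                function(nm) as.numeric(kv(paste0("t", nm))))
  names(trn) <- c("MM", "MI", "MD", "II", "IM", "DD", "DM")
  cal <- kv("calibration")
  p <- structure(
    list(match_state_count = M,
         match_columns = as.integer(kv("match_columns")),
         alignment_length = as.integer(kv("alignment_length")),
         match_emission = em, insert_emission = bg, background = bg,
         match_score = log2(sweep(em, 2L, bg, "/")),
         trans = trn,
         occupancy_threshold = as.numeric(kv("occupancy_threshold")),
         mu = NULL, lambda = NULL, calib_n = NULL),
    class = "profile_hmm")
  if (!identical(cal[1L], "none")) {
    p$mu <- as.numeric(cal[1L]); p$lambda <- as.numeric(cal[2L])
    p$calib_n <- as.numeric(cal[3L])
  }
  p
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat("profile_hmm with", x$match_state_count, "match states",
      "(seed alignment length", paste0(x$alignment_length, ")"),
      if (!is.null(x$lambda))
        sprintf("| calibrated: mu = %.3f, lambda = %.3f", x$mu, x$lambda)
      else "| uncalibrated", "\n")
  invisible(x)
}
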