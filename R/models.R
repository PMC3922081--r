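#' Amino-acid substitution model
#'
#' Builds a general time-reversible 20-state model from a named empirical
#' exchangeability matrix (taken from the model tables shipped with
#' phangorn) or from explicit rates, with optional empirical ("+F")
#' stationary frequencies and discrete-gamma rate heterogeneity with
#' `k` equal-probability categories (each category rate is the mean of
#' its quantile interval, normalised to overall mean 1).
#'
#' @param name model name, e.g. `"LG"`, `"WAG"`, `"JTT"`, or `"Poisson"`
#'   for the equal-rates model.
#' @param frequencies `NULL` for model frequencies, `"uniform"`, or a
#'   numeric 20-vector summing to 1 (empirical "+F" use).
#' @param gamma_shape shape alpha of the gamma rate distribution
#'   (> 0); `Inf` disables rate heterogeneity.
#' @param k number of discrete gamma categories.
#' @return object of class `substitution_model` with the scaled rate
#'   matrix `Q` (rows sum to 0, mean rate 1), its eigendecomposition,
#'   stationary frequencies `freq` and category rates `rates`.
#' @export
substitution_model <- function(name = "LG", frequencies = NULL,
                               gamma_shape = Inf, k = 4L) {
  stopifnot(gamma_shape > 0, k >= 1L)
  if (identical(name, "Poisson")) {
    ex <- matrix(1, 20L, 20L)
    bf <- rep(1 / 20, 20L)
  } else {
    tmp <- tryCatch(get(paste0(".", name), environment(phangorn::pml)),
                    error = function(e)
                      stop("unknown substitution model: ", name))
    ex <- matrix(0, 20L, 20L)
    ex[lower.tri(ex)] <- tmp$Q
    ex <- ex + t(ex)
    bf <- as.numeric(tmp$bf)
  }
  if (!is.null(frequencies)) {
    bf <- if (identical(frequencies, "uniform")) rep(1 / 20, 20L)
          else as.numeric(frequencies)
  }
  if (abs(sum(bf) - 1) > 1e-6) stop("frequencies must sum to 1")
  bf <- bf / sum(bf)

  Q <- ex %*% diag(bf)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(bf * diag(Q))          # mean substitution rate
  Q <- Q / mu                        # branch lengths in subs/site

  # symmetric similarity transform for a stable eigendecomposition
  sp <- sqrt(bf)
  S <- diag(sp) %*% Q %*% diag(1 / sp)
  eig <- eigen((S + t(S)) / 2, symmetric = TRUE)
  U <- diag(1 / sp) %*% eig$vectors
  Uinv <- t(eig$vectors) %*% diag(sp)

  rates <- discrete_gamma_rates(gamma_shape, k)
  structure(
    list(name = name, Q = Q, freq = bf, eval = eig$values,
         U = U, Uinv = Uinv, gamma_shape = gamma_shape, k = k,
         rates = rates),
    class = "substitution_model")
}

# mean-of-quantile-interval discrete gamma (mean-1 parameterisation)
discrete_gamma_rates <- function(shape, k) {
  if (!is.finite(shape) || k == 1L) return(rep(1, k))
  b <- stats::qgamma(seq(0, 1, length.out = k + 1L), shape, rate = shape)
  r <- k * (stats::pgamma(b[-1L], shape + 1, rate = shape) -
              stats::pgamma(b[-(k + 1L)], shape + 1, rate = shape))
  r / mean(r)
}

# transition probability matrix P(t) for one rate category
model_pmat <- function(model, t) {
  P <- model$U %*% (exp(model$eval * t) * model$Uinv)
  P[P < 0] <- 0
  P / rowSums(P)
}

#' @export
print.substitution_model <- function(x, ...) {
  cat("substitution_model:", x$name,
      if (is.finite(x$gamma_shape))
        sprintf("+G%d (alpha = %.3g)", x$k, x$gamma_shape) else "",
      "\n")
  invisible(x)
}
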