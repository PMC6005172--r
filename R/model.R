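#' Amino-acid substitution model
#'
#' Builds a time-reversible 20-state substitution model from a symmetric
#' exchangeability matrix and stationary frequencies. The default is the
#' Poisson model (all exchangeabilities equal, uniform frequencies), which is
#' cheap and adequate for desk-scale simulation studies; any published
#' exchangeability table (WAG, LG, ...) can be plugged in via
#' `exchangeabilities` or [read_exchangeability_matrix()].
#'
#' The rate matrix is `Q = S %*% diag(pi)` with the diagonal set so rows sum
#' to zero, then rescaled so the expected substitution rate at stationarity
#' is 1 (branch lengths are expected substitutions per site). Optional
#' among-site rate heterogeneity uses the discrete-gamma approximation with
#' `n_rate_categories` equal-probability categories represented by their
#' category means.
#'
#' @param exchangeabilities symmetric non-negative 20x20 matrix (diagonal
#'   ignored), or `NULL` for the Poisson model.
#' @param frequencies stationary frequencies over the 20 amino acids
#'   (alphabetical one-letter order); `NULL` means uniform.
#' @param gamma_shape positive shape of the gamma rate distribution, or
#'   `NULL` for rate homogeneity.
#' @param n_rate_categories number of discrete gamma categories (ignored
#'   when `gamma_shape` is `NULL`).
#' @return an object of class `aa_model`.
#' @export
#' @examples
#' m <- substitution_model()
#' m_gamma <- substitution_model(gamma_shape = 0.8, n_rate_categories = 4)
substitution_model <- function(exchangeabilities = NULL, frequencies = NULL,
                               gamma_shape = NULL, n_rate_categories = 4L) {
  n <- 20L
  if (is.null(exchangeabilities)) {
    S <- matrix(1, n, n)
  } else {
    S <- as.matrix(exchangeabilities)
    stopifnot(all(dim(S) == c(n, n)))
    if (max(abs(S - t(S))) > 1e-8) stop("exchangeability matrix must be symmetric")
    if (any(S[upper.tri(S)] < 0)) stop("exchangeabilities must be non-negative")
  }
  diag(S) <- 0
  if (is.null(frequencies)) {
    pi <- rep(1 / n, n)
  } else {
    pi <- as.numeric(frequencies)
    stopifnot(length(pi) == n)
    if (any(pi <= 0)) stop("frequencies must be strictly positive")
    if (abs(sum(pi) - 1) > 1e-8) stop("frequencies must sum to 1")
    pi <- pi / sum(pi)
  }
  Q <- S %*% diag(pi)
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q <- Q / mu
  # symmetrize for a stable eigendecomposition: B = D^(1/2) Q D^(-1/2)
  sp <- sqrt(pi)
  B <- diag(sp) %*% Q %*% diag(1 / sp)
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  V <- diag(1 / sp) %*% eig$vectors
  Vinv <- t(eig$vectors) %*% diag(sp)

  if (is.null(gamma_shape)) {
    rates <- 1
  } else {
    stopifnot(gamma_shape > 0, n_rate_categories >= 1)
    rates <- discrete_gamma_rates(gamma_shape, as.integer(n_rate_categories))
  }
  structure(
    list(exchangeabilities = S, frequencies = pi, Q = Q,
         lambda = eig$values, V = V, Vinv = Vinv,
         gamma_shape = gamma_shape, rates = rates),
    class = "aa_model"
  )
}

# category means of k equal-probability slices of Gamma(shape, rate = shape)
discrete_gamma_rates <- function(shape, k) {
  if (k == 1L) return(1)
  b <- qgamma(seq(0, 1, length.out = k + 1), shape = shape, rate = shape)
  r <- k * (pgamma(b[-1], shape = shape + 1, rate = shape) -
              pgamma(b[-(k + 1)], shape = shape + 1, rate = shape))
  r / mean(r) * 1 # guard round-off; mean is 1 analytically
}

#' @export
print.aa_model <- function(x, ...) {
  kind <- if (all(x$exchangeabilities[upper.tri(x$exchangeabilities)] ==
                    x$exchangeabilities[1, 2])) "Poisson (equal exchangeabilities)"
          else "custom exchangeabilities"
  cat("<aa_model> ", kind, "\n", sep = "")
  cat("  frequencies: ",
      if (max(abs(x$frequencies - 1 / 20)) < 1e-12) "uniform" else "non-uniform",
      "\n", sep = "")
  if (is.null(x$gamma_shape)) {
    cat("  rates: homogeneous\n")
  } else {
    cat("  rates: discrete gamma, shape ", format(x$gamma_shape),
        ", ", length(x$rates), " categories\n", sep = "")
  }
  invisible(x)
}

#' Transition probability matrix P(t)
#'
#' @param model an [substitution_model()] object.
#' @param t branch length (expected substitutions per site).
#' @param rate rate multiplier (e.g. a gamma category rate).
#' @return 20x20 row-stochastic matrix.
#' @export
transition_probabilities <- function(model, t, rate = 1) {
  stopifnot(inherits(model, "aa_model"), t >= 0)
  P <- model$V %*% diag(exp(model$lambda * rate * t)) %*% model$Vinv
  P[P < 0] <- 0
  P
}

#' Read an exchangeability matrix from a whitespace-delimited file
#'
#' Accepts either a full 20x20 matrix or the 19-row lower triangle used by
#' common rate-matrix distributions (one row per amino acid from the second
#' onward). Entries follow the alphabetical one-letter amino-acid order.
#'
#' @param path file path.
#' @return symmetric 20x20 numeric matrix.
#' @export
read_exchangeability_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  vals <- lapply(lines, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  if (length(vals) == 20 && all(lengths(vals) == 20)) {
    S <- do.call(rbind, vals)
  } else if (length(vals) >= 19 && all(lengths(vals)[1:19] == 1:19)) {
    S <- matrix(0, 20, 20)
    for (i in 1:19) S[i + 1, seq_len(i)] <- vals[[i]]
    S <- S + t(S)
  } else {
    stop("expected a 20x20 matrix or a 19-row lower triangle in ", path)
  }
  if (any(is.na(S))) stop("non-numeric entries in ", path)
  dimnames(S) <- list(AA_STATES, AA_STATES)
  S
}
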