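#' SOWH parametric bootstrap topology test
#'
#' Tests the hypothesis that a leaf group (typically all metazoans plus the
#' query gene) is monophyletic, against the unconstrained maximum-likelihood
#' tree — the topology test used to confirm HGT candidates against the
#' metazoan-constraint tree. The observed statistic is
#' `delta = lnL(unconstrained ML) - lnL(constrained ML)`. Its null
#' distribution is obtained by simulating `n_reps` alignments on the
#' constrained tree (with its optimized branch lengths) and re-analysing
#' each replicate identically. The p-value uses the add-one correction
#' `(1 + #{delta* >= delta}) / (n_reps + 1)`.
#'
#' @inheritParams ml_search
#' @param group leaf labels of the constrained clade (the query is added
#'   automatically).
#' @param query label of the query leaf.
#' @param n_reps number of parametric replicates.
#' @param seed integer seed; results are reproducible for a fixed seed.
#' @return an object of class `sowh_test` with elements `delta_observed`,
#'   `null_deltas`, `p_value`, `n_replicates`, `best_tree`,
#'   `constrained_tree`.
#' @export
sowh_test <- function(aln, group, query, model, n_reps = 99L, seed = 1L,
                      control = ml_control(refine_k = 3L, tol = 1e-3)) {
  aln <- as_alignment(aln)
  stopifnot(n_reps >= 1)
  cset <- union(group, query)
  bad <- setdiff(cset, names(aln))
  if (length(bad)) stop("constraint leaves absent from alignment: ",
                        paste(bad, collapse = ", "))
  fit <- dual_fit(aln, model, cset, control)
  delta <- attr(fit$u, "loglik") - attr(fit$c, "loglik")
  n_rep_sites <- n_sites(aln)
  seeds <- derive_seeds(seed, n_reps)
  null_deltas <- vapply(seq_len(n_reps), function(i) {
    sim <- simulate_alignment(fit$c, model, n_rep_sites, seeds[i])
    f <- dual_fit(sim, model, cset, control, cache = fit$cache)
    attr(f$u, "loglik") - attr(f$c, "loglik")
  }, 0)
  p <- (1 + sum(null_deltas >= delta)) / (n_reps + 1)
  structure(
    list(delta_observed = delta, null_deltas = null_deltas, p_value = p,
         n_replicates = n_reps, best_tree = fit$u, constrained_tree = fit$c,
         group = group, query = query),
    class = "sowh_test"
  )
}

# unconstrained + constrained ML fits; the constrained optimum is also an
# unconstrained candidate, so lnL_u is floored at lnL_c (delta >= 0).
dual_fit <- function(aln, model, cset, control, cache = NULL) {
  tips <- if (!is.null(cache)) cache$tips else names(aln)
  ed <- engine_data(aln, model, tips = tips)
  if (length(ed$tips) <= 7) {
    if (is.null(cache)) {
      cache <- list(tips = tips,
                    u = new.env(parent = emptyenv()),
                    c = new.env(parent = emptyenv()))
      cache$u$structs <-
        make_structs(constrained_topologies(names(aln), NULL), tips)
      cache$c$structs <-
        make_structs(constrained_topologies(names(aln), cset), tips)
    }
    fit_u <- ml_exhaustive(ed, NULL, control, env = cache$u)
    fit_c <- ml_exhaustive(ed, NULL, control, env = cache$c)
  } else {
    fit_u <- ml_nni(ed, aln, NULL, control, start = cache$start_u)
    fit_c <- ml_nni(ed, aln, cset, control, start = cache$start_c)
    if (is.null(cache))
      cache <- list(tips = tips, start_u = fit_u, start_c = fit_c)
  }
  if (attr(fit_c, "loglik") > attr(fit_u, "loglik")) fit_u <- fit_c
  list(u = fit_u, c = fit_c, cache = cache)
}

#' @export
print.sowh_test <- function(x, ...) {
  cat("SOWH parametric bootstrap test\n")
  cat("  delta (lnL_ML - lnL_constrained): ",
      format(x$delta_observed, digits = 6), "\n", sep = "")
  cat("  replicates: ", x$n_replicates, "\n", sep = "")
  cat("  p-value: ", format(x$p_value, digits = 4), "\n", sep = "")
  invisible(x)
}

#' RELL bootstrap proportions
#'
#' Resampling of estimated log-likelihoods: each replicate draws
#' `ceiling(scale * n_sites)` site indices with replacement, sums the
#' per-site log-likelihoods of every tree over the draw, and awards the
#' replicate to the highest-scoring tree (ties split equally). The returned
#' win proportions sum to one.
#'
#' @param mat per-site log-likelihood matrix (trees x sites), e.g. from
#'   [site_loglik_matrix()].
#' @param scale resampling scale factor (1 = ordinary bootstrap).
#' @param n_rep number of replicates.
#' @param seed integer seed.
#' @return named numeric vector of bootstrap proportions per tree.
#' @export
rell_bootstrap <- function(mat, scale = 1, n_rep = 1000L, seed = 1L) {
  mat <- as.matrix(mat)
  if (!length(mat) || nrow(mat) < 1 || ncol(mat) < 1)
    stop("empty site log-likelihood matrix")
  stopifnot(scale > 0, n_rep >= 1)
  m <- ncol(mat)
  msamp <- ceiling(scale * m)
  ntree <- nrow(mat)
  wins <- numeric(ntree)
  with_seed(seed, {
    done <- 0L
    while (done < n_rep) {
      block <- min(2000L, n_rep - done)
      counts <- rmultinom(block, msamp, rep(1 / m, m))
      totals <- mat %*% counts
      mx <- apply(totals, 2, max)
      ismax <- sweep(totals, 2, mx, ">=")
      wins <- wins + rowSums(sweep(ismax, 2, colSums(ismax), "/"))
      done <- done + block
    }
  })
  out <- wins / n_rep
  names(out) <- rownames(mat)
  out
}

#' Approximately unbiased (AU) topology test
#'
#' Computes the AU p-value of a focal tree from multiscale RELL bootstrap
#' proportions: at each scale `r` the focal tree's bootstrap proportion
#' `BP_r` is transformed to `z_r = qnorm(1 - BP_r)` and the signed distance
#' `d` and curvature `c` are estimated by weighted least squares from
#' `z_r ~ d*sqrt(r) + c/sqrt(r)` (binomial-variance weights); then
#' `p_AU = 1 - pnorm(d - c)`. Proportions are clamped to
#' `[1/(2 n_rep), 1 - 1/(2 n_rep)]`; if the focal tree wins (or loses) at
#' every scale the p-value degenerates to 1 (or 0) and is flagged.
#'
#' @param mat per-site log-likelihood matrix (trees x sites) with row names.
#' @param focal row name of the tree under test (for HGT confirmation, the
#'   metazoan-constraint tree).
#' @param scales resampling scale factors (at least 2).
#' @param n_rep RELL replicates per scale.
#' @param seed integer seed.
#' @return an object of class `au_test` with `p_value`, `d`, `c`,
#'   `bp_per_scale`, `degenerate`.
#' @export
au_test <- function(mat, focal, scales = seq(0.5, 1.4, by = 0.1),
                    n_rep = 10000L, seed = 1L) {
  mat <- as.matrix(mat)
  if (is.null(rownames(mat)) || !focal %in% rownames(mat))
    stop("focal tree not found among matrix rows")
  if (nrow(mat) < 2) stop("need at least 2 trees")
  if (length(scales) < 2) stop("need at least 2 scales")
  seeds <- derive_seeds(seed, length(scales))
  bp <- vapply(seq_along(scales), function(i)
    rell_bootstrap(mat, scales[i], n_rep, seeds[i])[focal], 0)
  names(bp) <- paste0("scale_", format(scales))
  lo <- 1 / (2 * n_rep); hi <- 1 - lo
  degenerate <- FALSE
  # scales where the focal tree essentially always or never wins carry no
  # usable curvature information: the z-transform saturates at the clamp
  # boundary there. Fit on the informative scales; with fewer than two,
  # the p-value degenerates to the saturated side.
  informative <- bp > lo & bp < hi
  if (sum(informative) < 2) {
    degenerate <- TRUE
    if (sum(bp <= lo) >= sum(bp >= hi)) {
      p <- 0
      d <- Inf; cc <- 0
    } else {
      p <- 1
      d <- -Inf; cc <- 0
    }
  } else {
    bpc <- pmin(pmax(bp[informative], lo), hi)
    sc_i <- scales[informative]
    z <- qnorm(1 - bpc)
    X <- cbind(sqrt(sc_i), 1 / sqrt(sc_i))
    w <- n_rep * dnorm(z)^2 / (bpc * (1 - bpc))
    XtW <- t(X * w)
    beta <- solve(XtW %*% X, XtW %*% z)
    d <- beta[1]; cc <- beta[2]
    p <- 1 - pnorm(d - cc)
  }
  structure(
    list(p_value = unname(p), d = unname(d), c = unname(cc),
         bp_per_scale = bp, n_rep = n_rep, scales = scales, focal = focal,
         degenerate = degenerate),
    class = "au_test"
  )
}

#' @export
print.au_test <- function(x, ...) {
  cat("AU test (multiscale RELL)\n")
  cat("  focal tree: ", x$focal, "\n", sep = "")
  cat("  d = ", format(x$d, digits = 4), ", c = ", format(x$c, digits = 4),
      if (x$degenerate) "  [degenerate]" else "", "\n", sep = "")
  cat("  p-value: ", format(x$p_value, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Combined HGT confirmation decision
#'
#' A candidate is confirmed when the SOWH test and both AU runs (bootstrap
#' suboptimal set and manually shuffled suboptimal set) are significant at
#' `alpha`, boundary inclusive (`p <= alpha`).
#'
#' @param sowh_p,au_p_bootstrap,au_p_manual p-values (vectorized).
#' @param alpha significance level.
#' @return tibble with the three p-values and a `confirmed` flag.
#' @export
#' @examples
#' combined_decision(0.001, 0.021, 0.002)$confirmed # TRUE
combined_decision <- function(sowh_p, au_p_bootstrap, au_p_manual,
                              alpha = 0.05) {
  ps <- c(sowh_p, au_p_bootstrap, au_p_manual)
  if (any(!is.finite(ps)) || any(ps < 0) || any(ps > 1))
    stop("p-values must lie in [0, 1]")
  tibble::tibble(
    sowh_p = sowh_p,
    au_p_bootstrap = au_p_bootstrap,
    au_p_manual = au_p_manual,
    alpha = alpha,
    confirmed = sowh_p <= alpha & au_p_bootstrap <= alpha &
      au_p_manual <= alpha
  )
}

#' Likelihood proportions for tree-set visualization
#'
#' Normalizes log-likelihood scores of the best tree, the constraint tree,
#' and a suboptimal-tree set by the suboptimal mean, so different genes'
#' tree sets become comparable on one axis (the violin-plot summary of how
#' far the constraint tree sits from the bootstrap cloud).
#'
#' @param lnl_best log-likelihood of the unconstrained best tree.
#' @param lnl_constrained log-likelihood of the constraint tree.
#' @param lnl_suboptimal log-likelihoods of the suboptimal trees (non-empty).
#' @return long tibble with columns `tree`, `type`, `loglik`, `proportion`.
#' @export
likelihood_proportions <- function(lnl_best, lnl_constrained,
                                   lnl_suboptimal) {
  if (!length(lnl_suboptimal)) stop("suboptimal set must be non-empty")
  msub <- mean(lnl_suboptimal)
  if (msub == 0) stop("mean suboptimal log-likelihood is zero")
  tibble::tibble(
    tree = c("best", "constrained",
             paste0("suboptimal_", seq_along(lnl_suboptimal))),
    type = c("best", "constrained", rep("suboptimal", length(lnl_suboptimal))),
    loglik = c(lnl_best, lnl_constrained, lnl_suboptimal),
    proportion = .data$loglik / msub
  )
}

## broom-style accessors -------------------------------------------------

#' Tidy and glance methods for test objects
#'
#' @param x a `sowh_test` or `au_test` object.
#' @param ... unused.
#' @return a one-row tibble.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
tidy.sowh_test <- function(x, ...) {
  tibble::tibble(test = "SOWH", statistic = x$delta_observed,
                 p_value = x$p_value, n_replicates = x$n_replicates)
}

#' @rdname tidy
#' @export
tidy.au_test <- function(x, ...) {
  tibble::tibble(test = "AU", focal = x$focal, d = x$d, c = x$c,
                 p_value = x$p_value, degenerate = x$degenerate)
}

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")

#' @rdname tidy
#' @export
glance.sowh_test <- function(x, ...) {
  tibble::tibble(
    loglik_best = attr(x$best_tree, "loglik"),
    loglik_constrained = attr(x$constrained_tree, "loglik"),
    delta = x$delta_observed, p_value = x$p_value,
    n_replicates = x$n_replicates
  )
}

#' @rdname tidy
#' @export
glance.au_test <- function(x, ...) {
  tibble::tibble(p_value = x$p_value, d = x$d, c = x$c,
                 n_scales = length(x$scales), n_rep = x$n_rep,
                 degenerate = x$degenerate)
}
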