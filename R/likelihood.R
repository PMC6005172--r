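#' Per-site log-likelihoods on a fixed tree
#'
#' Computes the log-likelihood of every alignment column on a branch-length-
#' bearing tree under a reversible amino-acid model, by the pruning
#' algorithm. Gaps and unknown residues are treated as fully ambiguous
#' (partial vector of ones). With discrete-gamma rates the site likelihood
#' is the equal-weight average over categories.
#'
#' @param tree a `phylo` object with branch lengths; its leaves must all
#'   have sequences in `aln`.
#' @param aln an alignment coercible by [as_alignment()].
#' @param model an [substitution_model()] object.
#' @return numeric vector of per-site log-likelihoods.
#' @export
#' @examples
#' tr <- read_newick("((A:0.2,B:0.2):0.1,(C:0.2,D:0.2):0.1);")
#' aln <- as_alignment(c(A = "AC", B = "AC", C = "AD", D = "AD"))
#' site_log_likelihoods(tr, aln, substitution_model())
site_log_likelihoods <- function(tree, aln, model) {
  aln <- as_alignment(aln)
  ed <- engine_data(aln, model, tips = if (inherits(tree, "phylo"))
    tree$tip.label else names(aln))
  if (!inherits(tree, "phylo") || length(tree$tip.label) == 1) {
    # single-leaf degenerate case: likelihood is the stationary frequency
    lab <- if (inherits(tree, "phylo")) tree$tip.label else names(aln)[1]
    codes <- aln_codes(aln, lab)[, 1]
    return(ifelse(codes < 20, log(model$frequencies[codes + 1]), 0))
  }
  per_pat <- site_loglik_patterns(tree, ed)
  per_pat[ed$index]
}

#' Total log-likelihood of a tree
#' @inheritParams site_log_likelihoods
#' @return scalar log-likelihood.
#' @export
tree_log_likelihood <- function(tree, aln, model) {
  sum(site_log_likelihoods(tree, aln, model))
}

#' Optimize branch lengths on a fixed topology
#'
#' Iteratively re-estimates every branch length by Newton steps on its
#' profile likelihood (all other branches held fixed), sweeping the tree
#' until the total log-likelihood improves by less than `tol` or `max_pass`
#' sweeps have run. Lengths are clamped to `[1e-8, 20]`.
#'
#' @inheritParams site_log_likelihoods
#' @param tol convergence tolerance in log-likelihood units.
#' @param max_pass maximum number of sweeps.
#' @return the tree with optimized `edge.length` and attributes `loglik`
#'   and `converged`.
#' @export
optimize_branch_lengths <- function(tree, aln, model, tol = 1e-6,
                                    max_pass = 20L) {
  aln <- as_alignment(aln)
  ed <- engine_data(aln, model, tips = tree$tip.label)
  fit_tree(tree, ed, tol = tol, max_pass = max_pass)
}

#' Maximum-likelihood tree search
#'
#' For up to 7 leaves the search enumerates every unrooted topology
#' (optionally restricted to those where `constraint` is monophyletic),
#' screens them by likelihood at a common data-scaled starting branch
#' length, and fully optimizes the top-ranking candidates. For larger trees
#' it hill-climbs by nearest-neighbour interchange (NNI) from a
#' distance-based (neighbour-joining) starting tree, rejecting moves that
#' break the constraint. Deterministic given its inputs.
#'
#' @inheritParams site_log_likelihoods
#' @param aln alignment of at least 3 sequences.
#' @param constraint leaf labels forced to be monophyletic, or `NULL`.
#' @param control list of search settings, see [ml_control()].
#' @return the best tree found, with attribute `loglik`.
#' @export
ml_search <- function(aln, model, constraint = NULL, control = ml_control()) {
  aln <- as_alignment(aln)
  if (length(aln) < 3) stop("need at least 3 sequences")
  if (!is.null(constraint)) {
    bad <- setdiff(constraint, names(aln))
    if (length(bad)) stop("constraint leaves absent from alignment: ",
                          paste(bad, collapse = ", "))
  }
  ed <- engine_data(aln, model, tips = names(aln))
  if (length(aln) <= 7) {
    topos <- constrained_topologies(names(aln), constraint)
    ml_exhaustive(ed, topos, control)
  } else {
    ml_nni(ed, aln, constraint, control)
  }
}

#' Search settings for [ml_search()]
#'
#' @param refine_k number of screened topologies to optimize fully in the
#'   exhaustive search.
#' @param tol final branch-length optimization tolerance (log units).
#' @param quick_tol looser tolerance used when ranking NNI neighbours and
#'   screening candidates.
#' @param quick_pass sweep cap for quick fits.
#' @param max_rounds cap on NNI improvement rounds.
#' @return a list of settings.
#' @export
ml_control <- function(refine_k = 5L, tol = 1e-6, quick_tol = 1e-3,
                       quick_pass = 4L, max_rounds = 50L) {
  list(refine_k = refine_k, tol = tol, quick_tol = quick_tol,
       quick_pass = quick_pass, max_rounds = max_rounds)
}

#' Simulate an alignment along a tree
#'
#' Draws the root state of each site from the model's stationary
#' frequencies, then evolves states down every branch by sampling from the
#' transition probabilities; with discrete-gamma rates a category is drawn
#' per site. The parametric replicates of the SOWH test and the synthetic
#' scenario generator are built on this.
#'
#' @inheritParams site_log_likelihoods
#' @param n_sites number of independent sites to simulate.
#' @param seed integer seed; the same seed reproduces the same alignment.
#' @return an `aa_alignment` over the tree's leaves.
#' @export
simulate_alignment <- function(tree, model, n_sites, seed) {
  stopifnot(n_sites >= 1)
  tree <- validate_tree(tree)
  with_seed(seed, {
    post <- ape::reorder.phylo(tree, "postorder")
    ntip <- length(post$tip.label)
    nnode <- ntip + post$Nnode
    root <- post$edge[nrow(post$edge), 1]
    states <- matrix(NA_integer_, nnode, n_sites)
    states[root, ] <- sample.int(20L, n_sites, replace = TRUE,
                                 prob = model$frequencies)
    ncat <- length(model$rates)
    cat_of_site <- if (ncat > 1) sample.int(ncat, n_sites, replace = TRUE)
                   else rep(1L, n_sites)
    for (e in rev(seq_len(nrow(post$edge)))) {
      p <- post$edge[e, 1]; ch <- post$edge[e, 2]
      t <- post$edge.length[e]
      for (c in seq_len(ncat)) {
        idx <- which(cat_of_site == c)
        if (!length(idx)) next
        P <- transition_probabilities(model, t, model$rates[c])
        ps <- states[p, idx]
        out <- integer(length(idx))
        for (i in unique(ps)) {
          sel <- ps == i
          out[sel] <- sample.int(20L, sum(sel), replace = TRUE, prob = P[i, ])
        }
        states[ch, idx] <- out
      }
    }
    seqs <- vapply(seq_len(ntip), function(i)
      paste0(AA_STATES[states[i, ]], collapse = ""), "")
    as_alignment(setNames(seqs, post$tip.label))
  })
}

#' Per-site log-likelihood matrix over a set of trees
#'
#' Rows are trees, columns are alignment sites: the input consumed by RELL
#' resampling and the AU test. Branch lengths can be re-optimized per tree
#' first (the default), matching how per-site likelihood files are produced
#' by ML programs.
#'
#' @param trees named list of `phylo` objects sharing the alignment's leaves.
#' @inheritParams site_log_likelihoods
#' @param optimize re-optimize branch lengths per tree before evaluating?
#' @return numeric matrix with one named row per tree.
#' @export
site_loglik_matrix <- function(trees, aln, model, optimize = TRUE) {
  aln <- as_alignment(aln)
  if (is.null(names(trees)))
    names(trees) <- paste0("tree", seq_along(trees))
  ed <- engine_data(aln, model, tips = trees[[1]]$tip.label)
  rows <- lapply(trees, function(tr) {
    if (optimize || is.null(tr$edge.length))
      tr <- fit_tree(tr, ed, tol = 1e-4, max_pass = 10L)
    site_loglik_patterns(tr, ed)[ed$index]
  })
  do.call(rbind, rows)
}

#' @rdname site_loglik_matrix
#' @param mat matrix as returned by `site_loglik_matrix`.
#' @param path TSV path (tree label, then one column per site).
#' @export
write_site_logliks <- function(mat, path) {
  df <- data.frame(tree = rownames(mat), mat, check.names = FALSE)
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}

#' @rdname site_loglik_matrix
#' @export
read_site_logliks <- function(path) {
  df <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE)
  mat <- as.matrix(df[, -1])
  if (!is.numeric(mat)) stop("non-numeric site log-likelihoods in ", path)
  rownames(mat) <- as.character(df[[1]])
  colnames(mat) <- NULL
  mat
}

#' Nonparametric bootstrap trees
#'
#' Resamples alignment columns with replacement and re-runs a (quick) ML
#' search per replicate, yielding the suboptimal-tree sets used by the AU
#' test. Use [dedupe_trees()] to drop topological duplicates.
#'
#' @inheritParams ml_search
#' @param n number of bootstrap replicates.
#' @param seed integer seed.
#' @param start optional tree used to seed each replicate search.
#' @return list of `phylo` trees of length `n`.
#' @export
bootstrap_trees <- function(aln, model, n, seed, constraint = NULL,
                            control = ml_control(refine_k = 2L, tol = 1e-3,
                                                 max_rounds = 8L),
                            start = NULL) {
  aln <- as_alignment(aln)
  m <- n_sites(aln)
  seeds <- derive_seeds(seed, n)
  chars <- lapply(unclass(aln), function(s) strsplit(s, "")[[1]])
  lapply(seq_len(n), function(i) {
    idx <- with_seed(seeds[i], sample.int(m, m, replace = TRUE))
    seqs <- vapply(chars, function(s) paste0(s[idx], collapse = ""), "")
    rep_aln <- as_alignment(seqs)
    if (length(rep_aln) > 7 && !is.null(start)) {
      ed <- engine_data(rep_aln, model, tips = names(rep_aln))
      ml_nni(ed, rep_aln, constraint, control, start = start)
    } else {
      ml_search(rep_aln, model, constraint = constraint, control = control)
    }
  })
}

## ------------------------------------------------------------------
## internals

engine_data <- function(aln, model, tips) {
  codes <- aln_codes(aln, tips)
  cp <- compress_patterns(codes)
  ed <- list(tips = tips, patterns = cp$patterns, weights = cp$weights,
             index = cp$index, model = model, nsite = nrow(codes))
  ed$t0 <- init_branch_length(ed)
  ed
}

# postorder 0-based edge structures for the C++ core
tree_cpp <- function(tree, ed) {
  perm <- match(tree$tip.label, ed$tips)
  if (anyNA(perm)) stop("tree leaves missing from alignment")
  post <- ape::reorder.phylo(tree, "postorder")
  if (is.null(post$edge.length)) post$edge.length <- rep(0.1, nrow(post$edge))
  list(edge = post$edge - 1L, elen = pmax(post$edge.length, 0),
       ntip = length(post$tip.label),
       nnode = length(post$tip.label) + post$Nnode,
       tipstate = ed$patterns[, perm, drop = FALSE], post = post)
}

site_loglik_patterns <- function(tree, ed) {
  tc <- tree_cpp(tree, ed)
  m <- ed$model
  cpp_site_loglik(tc$edge, tc$elen, tc$ntip, tc$nnode, tc$tipstate,
                  m$lambda, m$V, m$Vinv, m$frequencies, m$rates)
}

# branch-length optimization returning the tree (cladewise) with loglik attr
fit_tree <- function(tree, ed, tol = 1e-6, max_pass = 20L, init = NULL,
                     fallback = TRUE) {
  tc <- tree_cpp(tree, ed)
  if (!is.null(init)) tc$elen <- rep(init, length(tc$elen))
  m <- ed$model
  res <- cpp_optimize_blens(tc$edge, tc$elen, tc$ntip, tc$nnode, tc$tipstate,
                            ed$weights, m$lambda, m$V, m$Vinv, m$frequencies,
                            m$rates, tol, as.integer(max_pass), 1e-8, 20,
                            fallback)
  if (!is.finite(res$loglik)) stop("non-finite likelihood during optimization")
  out <- tc$post
  out$edge.length <- as.numeric(res$elen)
  out <- ape::reorder.phylo(out, "cladewise")
  attr(out, "loglik") <- res$loglik
  attr(out, "converged") <- res$converged
  out
}

score_topology <- function(tree, ed, t0) {
  tc <- tree_cpp(tree, ed)
  m <- ed$model
  lnl <- cpp_site_loglik(tc$edge, rep(t0, length(tc$elen)), tc$ntip, tc$nnode,
                         tc$tipstate, m$lambda, m$V, m$Vinv, m$frequencies,
                         m$rates)
  sum(ed$weights * lnl)
}

# all unrooted topologies on the given labels, by recursive edge insertion
topology_cache <- new.env(parent = emptyenv())

enumerate_topologies <- function(labels) {
  labels <- sort(labels)
  n <- length(labels)
  stopifnot(n >= 3, n <= 8)
  key <- as.character(n)
  if (is.null(topology_cache[[key]])) {
    nest <- list(list("L1", "L2", "L3"))
    if (n > 3) for (k in 4:n) {
      nxt <- list()
      for (tr in nest) nxt <- c(nxt, insert_leaf_everywhere(tr, paste0("L", k)))
      nest <- nxt
    }
    topology_cache[[key]] <- vapply(nest, nested_newick, "")
  }
  tmpl <- topology_cache[[key]]
  lapply(tmpl, function(s) {
    tr <- ape::read.tree(text = s)
    tr$tip.label <- labels[as.integer(sub("^L", "", tr$tip.label))]
    tr
  })
}

insert_leaf_everywhere <- function(tr, x) {
  res <- list()
  for (i in seq_along(tr)) {
    t2 <- tr; t2[[i]] <- list(tr[[i]], x)
    res <- c(res, list(t2))
    if (is.list(tr[[i]])) {
      for (sub in insert_into(tr[[i]], x)) {
        t2 <- tr; t2[[i]] <- sub
        res <- c(res, list(t2))
      }
    }
  }
  res
}

insert_into <- function(node, x) {
  res <- list()
  for (i in 1:2) {
    t2 <- node; t2[[i]] <- list(node[[i]], x)
    res <- c(res, list(t2))
    if (is.list(node[[i]])) {
      for (sub in insert_into(node[[i]], x)) {
        t2 <- node; t2[[i]] <- sub
        res <- c(res, list(t2))
      }
    }
  }
  res
}

nested_newick <- function(node) {
  s <- function(x) if (is.list(x)) paste0("(", paste(vapply(x, s, ""),
                                                     collapse = ","), ")") else x
  paste0(s(node), ";")
}

constrained_topologies <- function(labels, constraint) {
  topos <- enumerate_topologies(labels)
  if (is.null(constraint)) return(topos)
  constraint <- unique(constraint)
  if (length(constraint) <= 1 || length(constraint) >= length(labels) - 1)
    return(topos)
  keep <- vapply(topos, is_monophyletic, TRUE, group = constraint)
  if (!any(keep)) stop("no topology satisfies the constraint")
  topos[keep]
}

# renumber a tree's tips so tip i is ed$tips[i]; lets every topology share
# one tip-state matrix in the C++ core
renumber_tips <- function(tree, tips) {
  map <- match(tree$tip.label, tips)
  E <- tree$edge
  tl <- E[, 2] <= length(tips)
  E[tl, 2] <- map[E[tl, 2]]
  tree$edge <- E
  tree$tip.label <- tips
  tree
}

make_structs <- function(topos, tips) {
  lapply(topos, function(tr) {
    post <- ape::reorder.phylo(renumber_tips(tr, tips), "postorder")
    list(post = post, edge = post$edge - 1L,
         nnode = length(tips) + post$Nnode)
  })
}

fit_struct <- function(st, ed, tol, max_pass = 20L, init = NULL,
                       fallback = TRUE) {
  m <- ed$model
  elen <- if (!is.null(init)) rep(init, nrow(st$edge))
          else if (!is.null(st$post$edge.length)) pmax(st$post$edge.length, 0)
          else rep(0.1, nrow(st$edge))
  res <- cpp_optimize_blens(st$edge, elen, length(ed$tips), st$nnode,
                            ed$patterns, ed$weights, m$lambda, m$V, m$Vinv,
                            m$frequencies, m$rates, tol,
                            as.integer(max_pass), 1e-8, 20, fallback)
  if (!is.finite(res$loglik)) stop("non-finite likelihood during optimization")
  out <- st$post
  out$edge.length <- as.numeric(res$elen)
  out <- ape::reorder.phylo(out, "cladewise")
  attr(out, "loglik") <- res$loglik
  attr(out, "converged") <- res$converged
  attr(out, "elen_post") <- as.numeric(res$elen)
  out
}

# `env`, when given, holds `env$structs` whose per-topology branch lengths
# are updated after each fit -- warm starts for the repeated searches of the
# SOWH replicates (same topologies, similar data)
ml_exhaustive <- function(ed, topos, control, structs = NULL, env = NULL) {
  t0 <- ed$t0
  if (!is.null(env)) structs <- env$structs
  if (is.null(structs)) structs <- make_structs(topos, ed$tips)
  sel <- seq_along(structs)
  if (length(structs) > max(control$refine_k, 10L)) {
    m <- ed$model
    sc <- cpp_screen_topologies(lapply(structs, `[[`, "edge"),
                                vapply(structs, `[[`, 0, "nnode"), t0,
                                length(ed$tips), ed$patterns, ed$weights,
                                m$lambda, m$V, m$Vinv, m$frequencies,
                                m$rates)
    ord <- order(sc, decreasing = TRUE)
    sel <- ord[seq_len(min(control$refine_k, length(structs)))]
  }
  quick_tol <- max(control$quick_tol, control$tol)
  fits <- vector("list", length(sel))
  for (j in seq_along(sel)) {
    st <- structs[[sel[j]]]
    init <- if (is.null(st$post$edge.length)) t0 else NULL
    fits[[j]] <- fit_struct(st, ed, tol = quick_tol, max_pass = 12L,
                            init = init)
    if (!is.null(env)) {
      env$structs[[sel[j]]]$post$edge.length <-
        attr(fits[[j]], "elen_post")
    }
  }
  lls <- vapply(fits, attr, 0, "loglik")
  best <- fits[[which.max(lls)]]
  if (control$tol < quick_tol) best <- fit_tree(best, ed, tol = control$tol)
  best
}

init_branch_length <- function(ed) {
  D <- distance_matrix_codes(ed$patterns, ed$weights)
  max(0.02, mean(D[upper.tri(D)]) / 4)
}

# Poisson-corrected pairwise distances from coded patterns
distance_matrix_codes <- function(patterns, weights) {
  ntax <- ncol(patterns)
  D <- matrix(0, ntax, ntax)
  for (i in seq_len(ntax - 1)) for (j in (i + 1):ntax) {
    ok <- patterns[, i] < 20L & patterns[, j] < 20L
    tot <- sum(weights[ok])
    p <- if (tot > 0) sum(weights[ok & (patterns[, i] != patterns[, j])]) / tot
         else 0
    arg <- 1 - 20 * p / 19
    d <- if (arg <= exp(-20 / 19 * 5)) 5 else -(19 / 20) * log(arg)
    D[i, j] <- D[j, i] <- d
  }
  D
}

nj_start_tree <- function(aln, ed, constraint = NULL) {
  D <- distance_matrix_codes(aln_codes(aln, ed$tips),
                             rep(1, n_sites(aln)))
  dimnames(D) <- list(ed$tips, ed$tips)
  build <- function(labs) {
    if (length(labs) == 1) return(paste0(labs, ":0.1"))
    if (length(labs) == 2) {
      d <- max(D[labs[1], labs[2]] / 2, 0.01)
      return(paste0("(", labs[1], ":", d, ",", labs[2], ":", d, "):0.1"))
    }
    hc <- stats::hclust(stats::as.dist(D[labs, labs]), method = "average")
    nwk <- ape::write.tree(ape::as.phylo(hc))
    sub(";$", ":0.1", nwk)
  }
  if (is.null(constraint) || length(constraint) <= 1 ||
      length(constraint) >= length(ed$tips) - 1) {
    tr <- ape::nj(stats::as.dist(D))
    tr$edge.length <- pmax(tr$edge.length, 1e-4)
    return(ape::unroot(tr))
  }
  other <- setdiff(ed$tips, constraint)
  nwk <- paste0("(", build(sort(constraint)), ",", build(sort(other)), ");")
  tr <- ape::unroot(ape::read.tree(text = nwk))
  tr$edge.length <- pmax(tr$edge.length, 1e-4)
  tr
}

nni_neighbors <- function(tree) {
  tree <- ape::reorder.phylo(ape::unroot(tree), "cladewise")
  ntip <- length(tree$tip.label)
  E <- tree$edge
  root <- ntip + 1L
  res <- list()
  for (er in which(E[, 2] > ntip)) {
    p <- E[er, 1]; ch <- E[er, 2]
    kids <- E[E[, 1] == ch, 2]
    sibs <- setdiff(E[E[, 1] == p, 2], ch)
    if (p == root && length(sibs) >= 2) {
      for (y in sibs[1:2]) res <- c(res, list(swap_subtrees(tree, kids[1], y)))
    } else if (length(sibs) >= 1) {
      y <- sibs[1]
      res <- c(res, list(swap_subtrees(tree, kids[1], y),
                         swap_subtrees(tree, kids[2], y)))
    }
  }
  res[!vapply(res, is.null, TRUE)]
}

swap_subtrees <- function(tree, x, y) {
  E <- tree$edge
  rx <- match(x, E[, 2]); ry <- match(y, E[, 2])
  if (is.na(rx) || is.na(ry)) return(NULL)
  px <- E[rx, 1]; py <- E[ry, 1]
  E[rx, 1] <- py; E[ry, 1] <- px
  t2 <- tree
  t2$edge <- E
  tryCatch(ape::reorder.phylo(t2, "cladewise"), error = function(e) NULL)
}

# NNI hill climb: neighbours are ranked by likelihood at their carried-over
# branch lengths (no optimization), and only the top-ranked few are fully
# optimized -- the standard lazy strategy.
ml_nni <- function(ed, aln, constraint, control, start = NULL) {
  if (is.null(start)) start <- nj_start_tree(aln, ed, constraint)
  best <- fit_tree(start, ed, tol = control$tol)
  for (round in seq_len(control$max_rounds)) {
    nbrs <- nni_neighbors(best)
    if (!is.null(constraint) && length(constraint) > 1 &&
        length(constraint) < length(ed$tips) - 1) {
      nbrs <- Filter(function(t) is_monophyletic(t, constraint), nbrs)
    }
    if (!length(nbrs)) break
    sc <- vapply(nbrs, function(t)
      sum(ed$weights * site_loglik_patterns(t, ed)), 0)
    improved <- FALSE
    for (j in order(sc, decreasing = TRUE)[seq_len(min(3L, length(nbrs)))]) {
      cand <- fit_tree(nbrs[[j]], ed, tol = control$tol)
      if (attr(cand, "loglik") > attr(best, "loglik") + 1e-6) {
        best <- cand
        improved <- TRUE
        break
      }
    }
    if (!improved) break
  }
  best
}
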