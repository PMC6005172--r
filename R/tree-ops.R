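#' Read and write Newick trees
#'
#' Thin wrappers over ape's Newick parser that add the validation this
#' package relies on: unique leaf labels and non-negative branch lengths.
#' Trees are handled as unrooted throughout; rooted input is accepted and
#' interpreted by its unrooted topology.
#'
#' @param text a Newick string (or a file path for `read_newick_file`).
#' @return an [ape::phylo] object.
#' @export
#' @examples
#' tr <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
read_newick <- function(text) {
  tr <- ape::read.tree(text = text)
  if (is.null(tr)) stop("could not parse Newick string")
  validate_tree(tr)
}

#' @rdname read_newick
#' @param path file path containing one or more Newick trees.
#' @export
read_newick_file <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse Newick file: ", path)
  if (inherits(tr, "multiPhylo")) lapply(tr, validate_tree) else validate_tree(tr)
}

#' @rdname read_newick
#' @param tree a `phylo` object.
#' @export
write_newick <- function(tree) {
  ape::write.tree(tree)
}

validate_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    stop("negative branch lengths")
  tree
}

# leaf sets below every edge (child side), as index vectors into tip.label
edge_leafsets <- function(tree) {
  ntip <- length(tree$tip.label)
  post <- ape::reorder.phylo(tree, "postorder")
  sets <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) sets[[i]] <- i
  for (e in seq_len(nrow(post$edge))) {
    p <- post$edge[e, 1]; ch <- post$edge[e, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  lapply(seq_len(nrow(tree$edge)), function(e) sort(sets[[tree$edge[e, 2]]]))
}

#' Bipartitions of an unrooted tree
#'
#' Every edge of an unrooted tree splits the leaves in two; the set of
#' nontrivial splits identifies the topology. Splits are returned in a
#' canonical form (the side not containing the alphabetically first leaf),
#' as sorted label vectors.
#'
#' @param tree a `phylo` object.
#' @param trivial include trivial (single-leaf) splits?
#' @return list of character vectors.
#' @export
tree_splits <- function(tree, trivial = FALSE) {
  tree <- validate_tree(tree)
  labs <- sort(tree$tip.label)
  anchor <- labs[1]
  ntip <- length(tree$tip.label)
  sets <- edge_leafsets(tree)
  out <- list()
  for (s in sets) {
    if (length(s) == 0 || length(s) == ntip) next
    side <- sort(tree$tip.label[s])
    if (anchor %in% side) side <- setdiff(labs, side)
    if (!trivial && (length(side) <= 1 || length(side) >= ntip - 1)) next
    out[[length(out) + 1]] <- side
  }
  unique(out)
}

splits_signature <- function(tree) {
  sp <- tree_splits(tree, trivial = FALSE)
  paste(sort(vapply(sp, paste0, "", collapse = "|")), collapse = ";")
}

#' Test monophyly of a leaf group on an unrooted tree
#'
#' A group is monophyletic when some edge of the unrooted tree separates
#' exactly that group from all other leaves. Groups of size 1 or covering
#' all leaves are monophyletic by definition. By unrooted symmetry,
#' `is_monophyletic(tree, g)` equals `is_monophyletic(tree, complement(g))`.
#'
#' @param tree a `phylo` object.
#' @param group character vector of leaf labels.
#' @return logical flag.
#' @export
is_monophyletic <- function(tree, group) {
  tree <- validate_tree(tree)
  group <- unique(group)
  if (length(group) == 0) stop("group must be non-empty")
  unknown <- setdiff(group, tree$tip.label)
  if (length(unknown))
    stop("unknown leaves in group: ", paste(unknown, collapse = ", "))
  ntip <- length(tree$tip.label)
  k <- length(group)
  if (k == 1 || k == ntip) return(TRUE)
  target <- paste0(sort(group), collapse = "|")
  comp <- paste0(sort(setdiff(tree$tip.label, group)), collapse = "|")
  for (s in edge_leafsets(tree)) {
    side <- paste0(sort(tree$tip.label[s]), collapse = "|")
    if (identical(side, target) || identical(side, comp)) return(TRUE)
  }
  FALSE
}

#' Prune up to `max_prune` leaves to restore monophyly
#'
#' Emulates the contaminant-pruning rule used when screening gene trees: a
#' handful of sequences (database contaminants) may disrupt an otherwise
#' clean animal clade, so the smallest set of at most `max_prune` group
#' members whose removal makes the remaining group monophyletic is deleted.
#' Leaves in `protected` (the query, typically) are never removed. Subsets
#' are tried by increasing size and, within a size, in lexicographic label
#' order, making the result deterministic.
#'
#' @param tree a `phylo` object.
#' @param group leaf labels that should form a clade.
#' @param protected leaf labels that may never be pruned.
#' @param max_prune maximum number of removable leaves to delete (default 2,
#'   the screening rule this package implements).
#' @return list with `tree` (pruned), `removed` (labels), `success` flag.
#' @export
prune_to_monophyly <- function(tree, group, protected = character(),
                               max_prune = 2L) {
  tree <- validate_tree(tree)
  group <- unique(group)
  unknown <- setdiff(group, tree$tip.label)
  if (length(unknown))
    stop("unknown leaves in group: ", paste(unknown, collapse = ", "))
  removable <- sort(setdiff(group, protected))
  for (k in 0:max_prune) {
    if (k > length(removable)) break
    subsets <- if (k == 0) list(character()) else
      apply(combn(removable, k), 2, identity, simplify = FALSE)
    for (rem in subsets) {
      keep_group <- setdiff(group, rem)
      pruned <- if (length(rem)) ape::drop.tip(tree, rem) else tree
      ok <- length(keep_group) <= 1 ||
        is_monophyletic(pruned, keep_group)
      if (ok) {
        return(list(tree = pruned, removed = rem, success = TRUE))
      }
    }
  }
  list(tree = tree, removed = character(), success = FALSE)
}

#' Remove topologically duplicate trees
#'
#' Keeps the first representative of each unrooted topology; identity is
#' equality of nontrivial bipartition sets (branch lengths and rootings are
#' ignored). Used to verify that bootstrap suboptimal-tree sets contain no
#' duplicates before feeding them to the AU test.
#'
#' @param trees list of `phylo` objects (or a `multiPhylo`) over one leaf set.
#' @return list of unique trees.
#' @export
dedupe_trees <- function(trees) {
  trees <- lapply(trees, validate_tree)
  if (length(trees) <= 1) return(trees)
  ref <- sort(trees[[1]]$tip.label)
  for (t in trees[-1])
    if (!identical(sort(t$tip.label), ref)) stop("trees have differing leaf sets")
  sig <- vapply(trees, splits_signature, "")
  trees[!duplicated(sig)]
}

# clades (node ids, tips included, root excluded) with at most max_size leaves
small_clades <- function(tree, max_size = 3L) {
  ntip <- length(tree$tip.label)
  sets <- edge_leafsets(tree)
  nodes <- tree$edge[, 2]
  keep <- vapply(sets, length, 0L) <= max_size
  list(nodes = nodes[keep], leafsets = sets[keep])
}

#' Generate suboptimal trees by shuffling clades of three
#'
#' Builds deliberately suboptimal topologies for topology-test reference
#' sets: three disjoint clades of at most three leaves each are chosen at
#' random and their attachment points are exchanged cyclically. Output trees
#' are deduplicated against each other and against the input topology.
#' Deterministic for a fixed seed.
#'
#' @param tree a `phylo` object (ideally >= 9 leaves; smaller trees yield
#'   whatever rearrangements exist, with a warning).
#' @param n_trees number of distinct shuffled trees requested.
#' @param seed integer seed.
#' @return list of `phylo` objects (possibly fewer than `n_trees` if tree
#'   space is exhausted).
#' @export
shuffle_clades_of_three <- function(tree, n_trees, seed) {
  tree <- validate_tree(tree)
  if (n_trees <= 0) stop("n_trees must be positive")
  if (length(tree$tip.label) < 9)
    warning("tree has fewer than 9 leaves; shuffle space is limited")
  cl <- small_clades(tree, 3L)
  out <- list()
  seen <- splits_signature(tree)
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(.restore_seed(old), add = TRUE)
  attempts <- 0L
  max_attempts <- 200L * n_trees
  while (length(out) < n_trees && attempts < max_attempts) {
    attempts <- attempts + 1L
    if (length(cl$nodes) < 3) break
    pick <- sample(length(cl$nodes), 3)
    sets <- cl$leafsets[pick]
    if (length(unique(unlist(sets))) != length(unlist(sets))) next
    shuffled <- cyclic_exchange(tree, cl$nodes[pick])
    if (is.null(shuffled)) next
    sig <- splits_signature(shuffled)
    if (sig %in% seen) next
    seen <- c(seen, sig)
    out[[length(out) + 1]] <- shuffled
  }
  out
}

# cyclically exchange the attachment points of three disjoint clades
cyclic_exchange <- function(tree, nodes) {
  E <- tree$edge
  rows <- match(nodes, E[, 2])
  if (any(is.na(rows))) return(NULL)
  E2 <- E
  E2[rows[1], 2] <- nodes[2]
  E2[rows[2], 2] <- nodes[3]
  E2[rows[3], 2] <- nodes[1]
  t2 <- tree
  t2$edge <- E2
  t2 <- tryCatch(ape::reorder.phylo(t2, "cladewise"), error = function(e) NULL)
  if (is.null(t2)) return(NULL)
  tryCatch(validate_tree(t2), error = function(e) NULL)
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
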