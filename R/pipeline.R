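#' Run the HGT detection-and-confirmation pipeline for one query gene
#'
#' Orchestrates the full screen: alien-index scoring, the animal-hit
#' branching rule, gene-tree inference with contaminant pruning, the SOWH
#' test and two AU runs (deduplicated bootstrap trees and clade-shuffled
#' trees as suboptimal sets), the combined decision, the close-relative
#' screen, and optional expression / splice-site annexes. Every stage uses
#' the package's exported functions; all randomness derives from one seed.
#'
#' Inputs can be given either as an [simulate_hgt_scenario()] object
#' (`scenario`) or as explicit components (`similarity`, `taxon_map`,
#' `alignment`, `query`).
#'
#' @param scenario an `hgt_scenario`, or `NULL` when passing components.
#' @param similarity similarity tibble ([read_similarity_table()] shape).
#' @param taxon_map taxon map ([read_taxon_map()] shape).
#' @param alignment alignment containing the query and its selected taxa.
#' @param query query gene / leaf id.
#' @param self_phylum phylum excluded from scoring (the query organism's).
#' @param model substitution model for tree inference and tests.
#' @param ai_threshold candidate threshold on the alien index (strict `>`).
#' @param evalue_cutoff hit cutoff for the branching and screens.
#' @param max_prune contaminant-pruning allowance (leaves).
#' @param alpha significance level of the combined decision (inclusive).
#' @param n_bootstrap bootstrap suboptimal trees for the first AU run.
#' @param n_shuffled clade-shuffled suboptimal trees for the second AU run.
#' @param sowh_reps SOWH parametric replicates.
#' @param au_rell RELL replicates per AU scale.
#' @param seed master seed.
#' @param control [ml_control()] search settings.
#' @param expression optional `expression_matrix` (raw counts) for the
#'   developmental-expression annex.
#' @param gene_models,genome optional gene models + genome for the
#'   splice-site annex.
#' @return an object of class `hgt_report`; `tidy()` gives the one-row
#'   per-gene summary.
#' @export
run_hgt_pipeline <- function(scenario = NULL, similarity = NULL,
                             taxon_map = NULL, alignment = NULL,
                             query = NULL, self_phylum = "Ctenophora",
                             model = substitution_model(),
                             ai_threshold = 45, evalue_cutoff = 0.1,
                             max_prune = 2L, alpha = 0.05,
                             n_bootstrap = 100L, n_shuffled = 100L,
                             sowh_reps = 99L, au_rell = 10000L, seed = 1L,
                             control = ml_control(refine_k = 4L, tol = 1e-3),
                             expression = NULL,
                             gene_models = NULL, genome = NULL) {
  if (!is.null(scenario)) {
    stopifnot(inherits(scenario, "hgt_scenario"))
    similarity <- simulate_similarity_table(scenario)
    taxon_map <- scenario$taxon_map
    alignment <- scenario$alignment
    query <- scenario$query
    model <- scenario$model
  }
  if (is.null(similarity) || is.null(taxon_map) || is.null(query))
    stop("provide either a scenario or similarity + taxon_map + query")
  taxon_map <- as_taxon_map(taxon_map)
  seeds <- derive_seeds(seed, 5)
  log <- character()
  note <- function(...) log <<- c(log, paste0(...))

  scored <- score_alien_index(similarity, taxon_map, self_phylum,
                              ai_threshold)
  srow <- scored[scored$gene == query, ]
  if (!nrow(srow)) stop("query ", query, " absent from similarity table")
  note("alien index ", signif(srow$alien_index, 4), "; candidate = ",
       srow$candidate)

  details <- list(scored = scored)
  branch <- NA_character_
  removed <- character()
  sowh_p <- au_boot_p <- au_man_p <- NA_real_
  confirmed <- FALSE
  close_relative <- NA

  run_tests <- FALSE
  if (!srow$candidate) {
    branch <- "NOT_CANDIDATE"
    note("below the alien-index threshold; stopping")
  } else {
    # hit counts at the cutoff, after self-phylum exclusion
    h <- dplyr::inner_join(similarity, taxon_map, by = "subject")
    h <- h[h$evalue <= evalue_cutoff & h$phylum != self_phylum &
             h$query == query, ]
    n_a <- sum(h$class == "metazoan")
    n_na <- sum(h$class != "metazoan")
    branch <- classify_candidate(n_a, n_na)
    note("animal hits: ", n_a, ", non-animal hits: ", n_na,
         " -> ", branch)
    if (branch == "NO_ANIMAL_HITS_HGT") {
      confirmed <- TRUE
    } else if (branch == "PHYLO_TEST") {
      run_tests <- TRUE
    }
  }

  if (run_tests) {
    if (is.null(alignment)) stop("PHYLO_TEST branch needs an alignment")
    aln <- as_alignment(alignment)
    cls <- setNames(taxon_map$class, taxon_map$subject)
    group <- intersect(names(aln)[cls[names(aln)] == "metazoan"],
                       setdiff(names(aln), query))
    tree <- ml_search(aln, model, control = control)
    pr <- prune_animal_clade(tree, group, query, max_prune)
    removed <- pr$removed
    if (!pr$success) {
      branch <- "ANIMALS_NOT_MONOPHYLETIC_DISCARD"
      note("animal clade not recoverable by pruning <= ", max_prune,
           " leaves; discarded")
    } else {
      if (length(removed)) {
        note("pruned putative contaminant(s): ",
             paste(removed, collapse = ", "))
        aln <- as_alignment(unclass(aln)[setdiff(names(aln), removed)])
        group <- setdiff(group, removed)
        tree <- ml_search(aln, model, control = control)
      }
      if (is_monophyletic(tree, union(group, query))) {
        branch <- "VERTICAL_RULED_OUT"
        note("query groups with the animal clade; ruled out as HGT")
      } else {
        sowh <- sowh_test(aln, group, query, model, n_reps = sowh_reps,
                          seed = seeds[1], control = control)
        sowh_p <- sowh$p_value
        boots <- dedupe_trees(bootstrap_trees(aln, model, n_bootstrap,
                                              seed = seeds[2]))
        names(boots) <- paste0("boot", seq_along(boots))
        shuf <- suppressWarnings(
          shuffle_clades_of_three(sowh$best_tree, n_shuffled, seeds[3]))
        names(shuf) <- if (length(shuf)) paste0("shuffle", seq_along(shuf))
                       else character()
        base <- list(constrained = sowh$constrained_tree,
                     best = sowh$best_tree)
        mat_boot <- site_loglik_matrix(c(base, boots), aln, model)
        au_boot <- au_test(mat_boot, "constrained", n_rep = au_rell,
                           seed = seeds[4])
        au_boot_p <- au_boot$p_value
        if (length(shuf)) {
          mat_man <- site_loglik_matrix(c(base, shuf), aln, model)
          au_man <- au_test(mat_man, "constrained", n_rep = au_rell,
                            seed = seeds[5])
          au_man_p <- au_man$p_value
          details$au_manual <- au_man
        } else {
          note("no clade-shuffled trees available; manual AU run skipped")
        }
        confirmed <- sowh_p <= alpha && au_boot_p <= alpha &&
          (is.na(au_man_p) || au_man_p <= alpha)
        sub_lnl <- rowSums(mat_boot[-(1:2), , drop = FALSE])
        details$proportions <- likelihood_proportions(
          sum(mat_boot["best", ]), sum(mat_boot["constrained", ]), sub_lnl)
        details$sowh <- sowh
        details$au_bootstrap <- au_boot
        details$trees <- list(best = sowh$best_tree,
                              constrained = sowh$constrained_tree)
        note("SOWH p = ", signif(sowh_p, 3), "; AU (bootstrap) p = ",
             signif(au_boot_p, 3), "; AU (shuffled) p = ",
             signif(au_man_p, 3))
      }
    }
  }

  if (isTRUE(confirmed)) {
    close_relative <- screen_close_relatives(
      similarity[similarity$query == query, ], taxon_map,
      evalue_cutoff = evalue_cutoff)
    if (close_relative) {
      confirmed <- FALSE
      note("top hit is a close protistan relative of animals; removed")
    }
  }

  expr_score <- NA_real_
  expr_flag <- NA
  if (!is.null(expression) && query %in% rownames(expression$counts)) {
    nm <- if (expression$normalized) expression
          else normalize_per_million(expression)
    es <- developmental_expression_score(nm, query)
    expr_score <- es$score
    expr_flag <- es$expressed
    details$expression <- es
  }

  n_introns <- NA_integer_
  n_canonical <- NA_integer_
  if (!is.null(gene_models) && !is.null(genome) &&
      query %in% gene_models$gene) {
    rep_g <- splice_report(gene_models[gene_models$gene == query, ], genome)
    n_introns <- nrow(rep_g)
    n_canonical <- sum(rep_g$canonical)
    details$splice <- rep_g
  }

  summary <- tibble::tibble(
    gene = query,
    alien_index = srow$alien_index,
    hgt_index = srow$hgt_index,
    candidate = srow$candidate,
    branch = branch,
    n_pruned = length(removed),
    sowh_p = sowh_p,
    au_p_bootstrap = au_boot_p,
    au_p_manual = au_man_p,
    close_relative = close_relative,
    confirmed = confirmed,
    expression_score = expr_score,
    expressed = expr_flag,
    n_introns = n_introns,
    n_canonical_introns = n_canonical
  )
  structure(list(summary = summary, details = details, log = log,
                 seed = seed),
            class = "hgt_report")
}

# The "main animal clade" can legitimately contain the query (vertical
# inheritance) or exclude it (transfer), so contaminant pruning tries both
# readings and keeps the smaller removal set: non-query animal leaves that
# cannot be reconciled with either clade are the putative contaminants.
prune_animal_clade <- function(tree, group, query, max_prune) {
  pr_out <- prune_to_monophyly(tree, group, protected = query,
                               max_prune = max_prune)
  pr_in <- prune_to_monophyly(tree, union(group, query), protected = query,
                              max_prune = max_prune)
  if (pr_out$success && (!pr_in$success ||
                          length(pr_out$removed) <= length(pr_in$removed)))
    return(pr_out)
  pr_in
}

#' @export
print.hgt_report <- function(x, ...) {
  s <- x$summary
  cat("<hgt_report> gene ", s$gene, "\n", sep = "")
  cat("  alien index ", signif(s$alien_index, 4), " (candidate: ",
      s$candidate, ")\n", sep = "")
  cat("  branch: ", s$branch, "\n", sep = "")
  if (!is.na(s$sowh_p))
    cat("  SOWH p = ", signif(s$sowh_p, 3), "; AU p (bootstrap/manual) = ",
        signif(s$au_p_bootstrap, 3), " / ", signif(s$au_p_manual, 3),
        "\n", sep = "")
  cat("  confirmed HGT: ", s$confirmed, "\n", sep = "")
  invisible(x)
}

#' @rdname tidy
#' @export
tidy.hgt_report <- function(x, ...) x$summary

#' @rdname tidy
#' @export
glance.hgt_report <- function(x, ...) {
  dplyr::select(x$summary, "gene", "branch", "confirmed")
}

#' Write an `hgt_report` to disk
#'
#' Writes the one-row summary as TSV and the full record (summary, stage
#' log, p-values) as JSON next to it.
#'
#' @param report an `hgt_report`.
#' @param path base path; `.tsv` and `.json` are appended.
#' @export
write_hgt_report <- function(report, path) {
  readr::write_tsv(report$summary, paste0(path, ".tsv"))
  jsonlite::write_json(
    list(summary = report$summary, log = report$log, seed = report$seed),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
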