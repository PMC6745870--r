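# End-to-end runners for the five sensitivity experiments: taxon count (Q1),
# sampling strategy (Q2), clade restriction (Q3), pruned vs re-estimated
# trees (Q4), and phylogram vs chronogram branch lengths (Q5).  Results are
# long-format data frames (one row per community x size x replicate x
# metric) plus per-cell summaries, ready for plotting without bespoke
# parsing.

# Shared subsampling engine for Q1/Q2: draw subsets, restrict the analysis
# to them, recompute SES per community, classify.  For MPD/MNTD the
# restriction uses the full tree's patristic matrix (provably equal to
# re-pruning, see the package tests); PD re-prunes the tree.
run_subset_strategy <- function(tree, comm, sizes, n_reps, strategy,
                                taxonomy = NULL, quota_method =
                                  "largest_remainder",
                                n_null = 999, metric = "MPD", alpha = 0.05,
                                seed = 1, min_taxa = 2) {
  stopifnot(length(metric) == 1L, !is.unsorted(sizes, strictly = TRUE))
  comm <- as_community_matrix(comm)
  pool <- sort(tree$tip.label)
  d <- if (metric %in% c("MPD", "MNTD")) patristic_matrix(tree)[pool, pool]
  out <- list()
  for (si in seq_along(sizes)) {
    subs <- switch(strategy,
      random = random_subset(pool, sizes[si], n_reps,
                             seed = child_seed(seed, 1000 + si)),
      family_proportional = family_proportional_subset(
        pool, taxonomy, sizes[si], n_reps,
        seed = child_seed(seed, 1000 + si), method = quota_method),
      stop("unknown strategy: ", strategy))
    for (r in seq_len(n_reps)) {
      keep <- subs[[r]]
      ses_seed <- child_seed(seed, si * 1e5 + r)
      res <- if (metric == "PD") {
        ses_phylodiv(comm, tree = prune_to_taxa(tree, keep), metric = metric,
                     n_reps = n_null, seed = ses_seed, alpha = alpha,
                     min_taxa = min_taxa)
      } else {
        ses_phylodiv(comm, dist = d[keep, keep], metric = metric,
                     n_reps = n_null, seed = ses_seed, alpha = alpha,
                     min_taxa = min_taxa)
      }
      res$strategy <- strategy
      res$size <- sizes[si]
      res$realized_size <- length(keep)
      res$replicate <- r
      out[[length(out) + 1L]] <- res
    }
  }
  do.call(rbind, out)
}

# Pattern-class proportions per group of a long results data frame.
experiment_proportions <- function(results, by = c("site", "size")) {
  stopifnot(all(by %in% names(results)), "pattern" %in% names(results))
  key <- interaction(results[by], drop = TRUE, lex.order = TRUE)
  rows <- lapply(split(seq_len(nrow(results)), key), function(ix) {
    pats <- results$pattern[ix]
    props <- if (all(is.na(pats))) {
      structure(c(NA_real_, NA_real_, NA_real_), n = 0L,
                n_na = length(pats),
                names = c("clustered", "overdispersed", "random"))
    } else {
      proportions_table(pats)
    }
    cbind(results[ix[1L], by, drop = FALSE],
          data.frame(clustered = props[["clustered"]],
                     overdispersed = props[["overdispersed"]],
                     random = props[["random"]],
                     n = attr(props, "n"), n_na = attr(props, "n_na")))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Q1: effect of taxon count on detected phylogenetic patterns
#'
#' Draws uniform random subsets of the regional pool at each target size,
#' restricts the analysis to each subset (communities lose their unsampled
#' species), recomputes SES per community, classifies the pattern, and
#' summarizes per community x size the proportions of replicates classified
#' clustered / overdispersed / random.
#'
#' @param tree Regional phylogeny (`phylo`).
#' @param comm Community matrix (sites x species 0/1).
#' @param sizes Strictly increasing subset sizes.
#' @param n_reps Replicates per size (default 50).
#' @param n_null Null replicates per SES (default 999).
#' @param metric One of `"MPD"`, `"MNTD"`, `"PD"` (default `"MPD"`, whose
#'   SES is -NRI).
#' @param alpha Two-tailed significance level.
#' @param seed Master seed; the whole run is reproducible from it.
#' @param min_taxa Minimum post-restriction community size analysed.
#' @return A list: `results` (long data frame) and `proportions`
#'   (per community x size).
#' @export
run_q1 <- function(tree, comm, sizes = c(25, 50, 100, 150), n_reps = 50,
                   n_null = 999, metric = "MPD", alpha = 0.05, seed = 1,
                   min_taxa = 2) {
  results <- run_subset_strategy(tree, comm, sizes, n_reps, "random",
                                 n_null = n_null, metric = metric,
                                 alpha = alpha, seed = seed,
                                 min_taxa = min_taxa)
  list(results = results,
       proportions = experiment_proportions(results, c("site", "size")))
}

#' Q2: random versus family-proportional taxon sampling
#'
#' Runs the Q1 design twice on matched sizes and seeds: once with uniform
#' random subsets and once with subsets sampled within families
#' proportionally to family richness in the complete pool.  Family-
#' proportional realized sizes may undershoot the targets (see
#' [family_quotas()]); they are recorded per replicate.
#'
#' @inheritParams run_q1
#' @param taxonomy Taxonomy data frame covering the pool.
#' @param quota_method Quota rounding rule, see [family_quotas()].
#' @return A list: `results` (long data frame with a `strategy` column) and
#'   `proportions` (per strategy x community x size).
#' @export
run_q2 <- function(tree, comm, taxonomy, sizes = c(25, 50, 100, 150),
                   n_reps = 50, n_null = 999, metric = "MPD", alpha = 0.05,
                   seed = 1, min_taxa = 2,
                   quota_method = "largest_remainder") {
  res_r <- run_subset_strategy(tree, comm, sizes, n_reps, "random",
                               n_null = n_null, metric = metric,
                               alpha = alpha, seed = seed,
                               min_taxa = min_taxa)
  res_f <- run_subset_strategy(tree, comm, sizes, n_reps,
                               "family_proportional", taxonomy = taxonomy,
                               quota_method = quota_method, n_null = n_null,
                               metric = metric, alpha = alpha, seed = seed,
                               min_taxa = min_taxa)
  results <- rbind(res_r, res_f)
  list(results = results,
       proportions = experiment_proportions(results,
                                            c("strategy", "site", "size")))
}

#' Q3: clade-restricted analyses versus the complete dataset
#'
#' For each clade, prunes the regional tree and the communities to the
#' clade's members, recomputes SES and pattern per community, and classifies
#' agreement with the complete-dataset pattern into the five-way
#' match/mismatch taxonomy of [compare_patterns()].  Communities with fewer
#' than `min_taxa` clade members are `NA`.
#'
#' @inheritParams run_q2
#' @param clades Character vector of clade ids resolvable in `taxonomy`
#'   (families or higher clades).
#' @return A list: `full` (complete-dataset SES results), `clades` (named
#'   list of per-clade SES results), and `match_matrix` (communities x
#'   clades character matrix of categories).
#' @export
run_q3 <- function(tree, comm, taxonomy, clades, n_null = 999,
                   metric = "MPD", alpha = 0.05, seed = 1, min_taxa = 2) {
  stopifnot(length(metric) == 1L, length(clades) > 0L)
  comm <- as_community_matrix(comm)
  pool <- sort(tree$tip.label)
  d <- if (metric %in% c("MPD", "MNTD")) patristic_matrix(tree)[pool, pool]
  full <- ses_phylodiv(comm, tree = tree, metric = metric, n_reps = n_null,
                       seed = child_seed(seed, 0), alpha = alpha,
                       min_taxa = min_taxa)
  clade_res <- list()
  match_matrix <- matrix(NA_character_, nrow(comm), length(clades),
                         dimnames = list(rownames(comm), clades))
  for (ci in seq_along(clades)) {
    members <- clade_subset(pool, taxonomy, clades[ci])
    if (length(members) < 2L) {
      stop("clade '", clades[ci], "' has fewer than 2 members in the pool")
    }
    res <- if (metric == "PD") {
      ses_phylodiv(comm, tree = prune_to_taxa(tree, members),
                   metric = metric, n_reps = n_null,
                   seed = child_seed(seed, ci), alpha = alpha,
                   min_taxa = min_taxa)
    } else {
      ses_phylodiv(comm, dist = d[members, members], metric = metric,
                   n_reps = n_null, seed = child_seed(seed, ci),
                   alpha = alpha, min_taxa = min_taxa)
    }
    clade_res[[clades[ci]]] <- res
    match_matrix[, ci] <- compare_patterns(res$pattern, full$pattern)
  }
  list(full = full, clades = clade_res, match_matrix = match_matrix)
}

#' Q4: pruned versus independently re-estimated trees
#'
#' For each random subset replicate, computes SES per community on (a) the
#' tree pruned from the regional phylogeny and (b) an alternative tree for
#' the same taxa, supplied by `tree_provider` or emulated by jittering the
#' pruned tree ([perturb_tree()], the default reconstruction-error
#' emulator).  Differences are tested per community x size with a paired
#' two-sided Wilcoxon signed-rank test on the replicate-aligned SES pairs.
#'
#' @inheritParams run_q1
#' @param tree_provider Optional `function(pruned_tree, size, replicate)`
#'   returning the alternative `phylo` on the same tip set (e.g. a loader of
#'   user-supplied per-replicate trees).
#' @param n_nni,tau Emulator knobs when `tree_provider` is `NULL`: number of
#'   random NNI moves and lognormal sd of branch noise.
#' @param test `"wilcoxon"` (default) or `"t"`.
#' @return A list: `pairs` (long data frame with `ses_pruned`,
#'   `ses_alternative`, both patterns) and `tests` (per community x size:
#'   realized pair count, statistic, p-value).
#' @export
run_q4 <- function(tree, comm, sizes = c(25, 50, 100, 150), n_reps = 30,
                   n_null = 999, metric = "MPD", alpha = 0.05, seed = 1,
                   min_taxa = 2, tree_provider = NULL, n_nni = 5, tau = 0.2,
                   test = "wilcoxon") {
  stopifnot(length(metric) == 1L)
  comm <- as_community_matrix(comm)
  pool <- sort(tree$tip.label)
  provider <- tree_provider
  if (is.null(provider)) {
    provider <- function(pruned, size, replicate) {
      perturb_tree(pruned, n_nni = n_nni, tau = tau,
                   seed = child_seed(seed, 7e6 + size * 1e3 + replicate))
    }
  }
  out <- list()
  for (si in seq_along(sizes)) {
    subs <- random_subset(pool, sizes[si], n_reps,
                          seed = child_seed(seed, 1000 + si))
    for (r in seq_len(n_reps)) {
      pruned <- prune_to_taxa(tree, subs[[r]])
      alt <- provider(pruned, sizes[si], r)
      if (!setequal(alt$tip.label, pruned$tip.label)) {
        stop("replicate alignment failure: alternative tree tips differ ",
             "(size ", sizes[si], ", replicate ", r, ")")
      }
      ses_seed <- child_seed(seed, si * 1e5 + r)
      res_a <- ses_phylodiv(comm, tree = pruned, metric = metric,
                            n_reps = n_null, seed = ses_seed, alpha = alpha,
                            min_taxa = min_taxa)
      res_b <- ses_phylodiv(comm, tree = alt, metric = metric,
                            n_reps = n_null, seed = ses_seed, alpha = alpha,
                            min_taxa = min_taxa)
      out[[length(out) + 1L]] <- data.frame(
        size = sizes[si], replicate = r, site = res_a$site,
        metric = res_a$metric, n_taxa = res_a$n_taxa,
        ses_pruned = res_a$ses, pattern_pruned = res_a$pattern,
        ses_alternative = res_b$ses, pattern_alternative = res_b$pattern,
        stringsAsFactors = FALSE)
    }
  }
  pairs <- do.call(rbind, out)
  list(pairs = pairs,
       tests = paired_cell_tests(pairs, "ses_pruned", "ses_alternative",
                                 test))
}

#' Q5: phylograms versus chronograms
#'
#' Prunes a chronogram and a phylogram on the same topology to matched
#' random subsets and compares replicate-aligned SES per community, with
#' paired tests and side-by-side pattern proportions per tree type.  When no
#' phylogram is supplied one is derived from the chronogram with lognormal
#' branch-rate heterogeneity `sigma` ([derive_phylogram()]).
#'
#' @inheritParams run_q4
#' @param chronogram Ultrametric regional phylogeny.
#' @param phylogram Phylogeny on the identical topology with
#'   non-clock branch lengths, or `NULL` to derive one.
#' @param sigma Rate heterogeneity used when deriving the phylogram.
#' @return A list: `pairs` (long data frame with `ses_phylogram`,
#'   `ses_chronogram`, both patterns), `tests` (paired per community x
#'   size), and `proportions` (per tree type x community x size).
#' @export
run_q5 <- function(chronogram, comm, phylogram = NULL, sigma = 1,
                   sizes = c(25, 50, 100, 150), n_reps = 30, n_null = 999,
                   metric = "MPD", alpha = 0.05, seed = 1, min_taxa = 2,
                   test = "wilcoxon") {
  stopifnot(length(metric) == 1L)
  comm <- as_community_matrix(comm)
  if (is.null(phylogram)) {
    phylogram <- derive_phylogram(chronogram, sigma,
                                  seed = child_seed(seed, 99))
  }
  if (!setequal(chronogram$tip.label, phylogram$tip.label) ||
      !ape::all.equal.phylo(chronogram, phylogram,
                            use.edge.length = FALSE)) {
    stop("topology mismatch between chronogram and phylogram")
  }
  pool <- sort(chronogram$tip.label)
  out <- list()
  for (si in seq_along(sizes)) {
    subs <- random_subset(pool, sizes[si], n_reps,
                          seed = child_seed(seed, 1000 + si))
    for (r in seq_len(n_reps)) {
      keep <- subs[[r]]
      ses_seed <- child_seed(seed, si * 1e5 + r)
      res_p <- ses_phylodiv(comm, tree = prune_to_taxa(phylogram, keep),
                            metric = metric, n_reps = n_null,
                            seed = ses_seed, alpha = alpha,
                            min_taxa = min_taxa)
      res_c <- ses_phylodiv(comm, tree = prune_to_taxa(chronogram, keep),
                            metric = metric, n_reps = n_null,
                            seed = ses_seed, alpha = alpha,
                            min_taxa = min_taxa)
      out[[length(out) + 1L]] <- data.frame(
        size = sizes[si], replicate = r, site = res_p$site,
        metric = res_p$metric, n_taxa = res_p$n_taxa,
        ses_phylogram = res_p$ses, pattern_phylogram = res_p$pattern,
        ses_chronogram = res_c$ses, pattern_chronogram = res_c$pattern,
        stringsAsFactors = FALSE)
    }
  }
  pairs <- do.call(rbind, out)
  long <- rbind(
    data.frame(tree = "phylogram", site = pairs$site, size = pairs$size,
               pattern = pairs$pattern_phylogram, stringsAsFactors = FALSE),
    data.frame(tree = "chronogram", site = pairs$site, size = pairs$size,
               pattern = pairs$pattern_chronogram, stringsAsFactors = FALSE))
  list(pairs = pairs,
       tests = paired_cell_tests(pairs, "ses_phylogram", "ses_chronogram",
                                 test),
       proportions = experiment_proportions(long, c("tree", "site", "size")))
}

# Paired tests per community x size cell of a wide pairs data frame;
# cells with fewer than 5 complete pairs are reported with NA statistics and
# their realized pair count.
paired_cell_tests <- function(pairs, col_a, col_b, method = "wilcoxon") {
  key <- interaction(pairs$site, pairs$size, drop = TRUE, lex.order = TRUE)
  rows <- lapply(split(seq_len(nrow(pairs)), key), function(ix) {
    a <- pairs[[col_a]][ix]
    b <- pairs[[col_b]][ix]
    n_ok <- sum(is.finite(a) & is.finite(b))
    base <- data.frame(site = pairs$site[ix[1L]], size = pairs$size[ix[1L]],
                       n_pairs = n_ok, stringsAsFactors = FALSE)
    if (n_ok < 5L) {
      return(cbind(base, statistic = NA_real_, p_value = NA_real_,
                   degenerate = NA))
    }
    ht <- paired_method_test(a, b, method = method)
    cbind(base, statistic = ht$statistic, p_value = ht$p_value,
          degenerate = ht$degenerate)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
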