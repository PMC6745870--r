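# Phylodiversity metrics and their standardized effect sizes under a
# tip-label randomization null.  These are authored here (not delegated to
# picante) because the null, the rank-p convention, and the degenerate-case
# handling are the package's core, pinned by oracle and calibration tests.

#' Faith's phylogenetic diversity
#'
#' Sum of branch lengths of the minimal subtree spanning the community's
#' tips.  With `include_root = TRUE` (default, matching the behaviour of the
#' tools this package is calibrated against) the path from the community's
#' MRCA up to the tree root is included, so a single-species community has a
#' positive PD equal to its root-to-tip path.
#'
#' @param tree A rooted `phylo` object with branch lengths.
#' @param community Character vector of tip labels.
#' @param include_root Include the MRCA-to-root path? Default `TRUE`.
#' @return The PD value (numeric scalar).
#' @export
faith_pd <- function(tree, community, include_root = TRUE) {
  community <- unique(as.character(community))
  if (!length(community)) stop("empty community")
  unknown <- setdiff(community, tree$tip.label)
  if (length(unknown)) {
    stop("unknown species: ", paste(utils::head(unknown, 5), collapse = ", "))
  }
  if (!include_root && length(community) < 2L) {
    stop("PD without the root path needs at least 2 species")
  }
  idx <- matrix(match(community, tree$tip.label), nrow = 1)
  pd_engine(tree, idx, include_root = include_root)
}

# Vectorized PD over replicate tip-index sets: `idx` is a reps x k matrix of
# tip indices.  Counts selected descendants below every edge in one postorder
# sweep shared across replicates.
pd_engine <- function(tree, idx, include_root = TRUE) {
  po <- stats::reorder(tree, "postorder")
  e <- po$edge
  len <- po$edge.length
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  R <- nrow(idx)
  k <- ncol(idx)
  cnt <- matrix(0, nnode, R)
  cnt[cbind(as.vector(t(idx)), rep(seq_len(R), each = k))] <- 1
  for (j in seq_len(nrow(e))) {
    cnt[e[j, 1L], ] <- cnt[e[j, 1L], ] + cnt[e[j, 2L], ]
  }
  below <- cnt[e[, 2L], , drop = FALSE]
  inc <- below > 0
  if (!include_root) inc <- inc & below < k
  as.vector(colSums(inc * len))
}

#' Mean pairwise distance (MPD)
#'
#' Unweighted mean patristic distance over all unordered pairs of community
#' members.  Its standardized effect size is the negative of Webb's net
#' relatedness index (NRI).
#'
#' @param dist Symmetric patristic distance matrix with tip labels as
#'   dimnames (see [patristic_matrix()]).
#' @param community Character vector of at least 2 tip labels.
#' @return Numeric scalar.
#' @export
mpd <- function(dist, community) {
  sub <- community_submatrix(dist, community)
  k <- nrow(sub)
  sum(sub) / (k * (k - 1))
}

#' Mean nearest taxon distance (MNTD)
#'
#' Mean over community members of the patristic distance to their nearest
#' co-occurring relative.  Its standardized effect size is the negative of
#' Webb's nearest taxon index (NTI).
#'
#' @inheritParams mpd
#' @return Numeric scalar.
#' @export
mntd <- function(dist, community) {
  sub <- community_submatrix(dist, community)
  diag(sub) <- Inf
  mean(apply(sub, 1L, min))
}

community_submatrix <- function(dist, community) {
  community <- unique(as.character(community))
  if (length(community) < 2L) stop("need at least 2 species")
  unknown <- setdiff(community, rownames(dist))
  if (length(unknown)) {
    stop("unknown species: ", paste(utils::head(unknown, 5), collapse = ", "))
  }
  dist[community, community, drop = FALSE]
}

#' Standardized effect sizes of phylodiversity under a tip-shuffle null
#'
#' For every site (row) of a community matrix, computes the observed metric
#' and a null distribution obtained by randomizing the positions of taxa at
#' the tips of the regional phylogeny, keeping the topology, branch lengths,
#' and taxon list fixed ("taxa.labels" style).  For one fixed community this
#' is equivalent to re-drawing, per replicate, the same number of tips
#' uniformly without replacement from the regional pool.  Then
#' `ses = (obs - mean(null)) / sd(null)` (sd with denominator R - 1) and
#' `rank_p = (#\{null <= obs\} + 1) / (R + 1)` (ties counted as `<=`,
#' conservative for clustering claims; tie detection uses a `1e-9` relative
#' tolerance so ranks are stable under global branch rescaling).
#'
#' Species present in the community but absent from the (sub)phylogeny are
#' dropped before computation and `n_taxa` records the post-drop count;
#' communities falling below `min_taxa`, and degenerate nulls (`sd = 0`,
#' e.g. a community equal to the full pool), yield pattern `NA` rather than
#' infinite SES.
#'
#' @param comm Community matrix (sites x species, 0/1; see
#'   [as_community_matrix()]) or a single character vector of species.
#' @param tree Regional phylogeny (`phylo`).  Required for `"PD"`; optional
#'   for `"MPD"`/`"MNTD"` when `dist` is given.
#' @param dist Patristic distance matrix; computed from `tree` when missing.
#' @param metric Character vector among `"PD"`, `"MPD"`, `"MNTD"`.
#' @param n_reps Number of null replicates R (default 999).
#' @param seed Master seed; per-site child seeds are derived from it, so a
#'   site's null draws do not depend on which other sites are present.  All
#'   requested metrics for a site share the same null draws.
#' @param alpha Two-tailed significance level for pattern classification.
#' @param include_root Passed to [faith_pd()].
#' @param min_taxa Minimum community size analysed (default 2).
#' @return A data frame with one row per site x metric: `site`, `metric`,
#'   `n_taxa`, `observed`, `null_mean`, `null_sd`, `ses`, `rank_p`,
#'   `pattern`.
#' @examples
#' tr <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
#' ses_phylodiv(c("A", "B"), tree = tr, metric = "MPD", n_reps = 99, seed = 1)
#' @export
ses_phylodiv <- function(comm, tree = NULL, dist = NULL,
                         metric = c("MPD", "MNTD", "PD"),
                         n_reps = 999, seed = NULL, alpha = 0.05,
                         include_root = TRUE, min_taxa = 2) {
  metric <- match.arg(metric, several.ok = TRUE)
  stopifnot(n_reps >= 1)
  if (is.character(comm) && is.null(dim(comm))) {
    m <- matrix(1L, 1, length(unique(comm)),
                dimnames = list("community", unique(comm)))
    comm <- m
  }
  comm <- as_community_matrix(comm)
  if (is.null(tree) && is.null(dist)) stop("supply a tree or a distance matrix")
  if ("PD" %in% metric && is.null(tree)) stop("PD requires a tree")
  if (!is.null(tree) && !is.null(dist) &&
      !setequal(tree$tip.label, rownames(dist))) {
    stop("tree and distance matrix disagree on the taxon pool")
  }
  pool <- sort(if (!is.null(tree)) tree$tip.label else rownames(dist))
  npool <- length(pool)
  need_dist <- any(metric %in% c("MPD", "MNTD"))
  if (need_dist) {
    if (is.null(dist)) dist <- patristic_matrix(tree)
    dist <- dist[pool, pool]
  }
  tip_of_pool <- if (!is.null(tree)) match(pool, tree$tip.label) else NULL
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)

  out <- vector("list", nrow(comm) * length(metric))
  row <- 0L
  for (i in seq_len(nrow(comm))) {
    present <- colnames(comm)[comm[i, ] == 1L]
    used <- sort(intersect(present, pool))
    k <- length(used)
    if (k < min_taxa) {
      for (mt in metric) {
        row <- row + 1L
        out[[row]] <- result_row(rownames(comm)[i], mt, k)
      }
      next
    }
    set.seed(child_seed(seed, i))
    idx <- matrix(0L, n_reps, k)
    for (r in seq_len(n_reps)) idx[r, ] <- sample.int(npool, k)

    obs_idx <- match(used, pool)
    vals <- list()
    if ("PD" %in% metric) {
      pool_idx <- rbind(obs_idx, idx)
      pd_all <- pd_engine(tree,
                          matrix(tip_of_pool[pool_idx], nrow = nrow(pool_idx)),
                          include_root = include_root)
      vals$PD <- list(obs = pd_all[1L], null = pd_all[-1L])
    }
    if (need_dist) {
      mpd_null <- mntd_null <- numeric(n_reps)
      want_mpd <- "MPD" %in% metric
      want_mntd <- "MNTD" %in% metric
      for (r in seq_len(n_reps)) {
        sub <- dist[idx[r, ], idx[r, ], drop = FALSE]
        if (want_mpd) mpd_null[r] <- sum(sub) / (k * (k - 1))
        if (want_mntd) {
          diag(sub) <- Inf
          mntd_null[r] <- mean(apply(sub, 1L, min))
        }
      }
      sub <- dist[obs_idx, obs_idx, drop = FALSE]
      if (want_mpd) vals$MPD <- list(obs = sum(sub) / (k * (k - 1)),
                                     null = mpd_null)
      if (want_mntd) {
        diag(sub) <- Inf
        vals$MNTD <- list(obs = mean(apply(sub, 1L, min)), null = mntd_null)
      }
    }
    for (mt in metric) {
      row <- row + 1L
      v <- vals[[mt]]
      out[[row]] <- result_row(rownames(comm)[i], mt, k,
                               obs = v$obs, null = v$null,
                               full_pool = (k == npool), alpha = alpha)
    }
  }
  do.call(rbind, out[seq_len(row)])
}

# Assemble one PhylodivResult row; NA row when obs is missing.
result_row <- function(site, metric, k, obs = NULL, null = NULL,
                       full_pool = FALSE, alpha = 0.05) {
  if (is.null(obs)) {
    return(data.frame(site = site, metric = metric, n_taxa = k,
                      observed = NA_real_, null_mean = NA_real_,
                      null_sd = NA_real_, ses = NA_real_, rank_p = NA_real_,
                      pattern = NA_character_, stringsAsFactors = FALSE))
  }
  R <- length(null)
  mu <- mean(null)
  sdv <- stats::sd(null)             # denominator R - 1
  # ties count as <=; detected with a 1e-9 relative tolerance so that the
  # rank is stable under global branch rescaling and equivalent computation
  # routes (metric values on trees tie often, e.g. on ultrametric trees)
  rank_p <- (sum(null - obs <= 1e-9 * pmax(abs(null), abs(obs))) + 1) /
    (R + 1)
  degenerate <- full_pool || !is.finite(sdv) || sdv == 0
  ses <- if (degenerate) NA_real_ else (obs - mu) / sdv
  pattern <- if (degenerate) NA_character_ else classify_pattern(rank_p, alpha)
  data.frame(site = site, metric = metric, n_taxa = k, observed = obs,
             null_mean = mu, null_sd = sdv, ses = ses, rank_p = rank_p,
             pattern = pattern, stringsAsFactors = FALSE)
}

#' Classify a community's phylogenetic pattern from its rank p-value
#'
#' Two-tailed rank test: `clustered` when `rank_p <= alpha/2` (observed
#' phylodiversity in the lower null tail), `overdispersed` when
#' `rank_p >= 1 - alpha/2`, otherwise `random`.  `NA` propagates.
#'
#' @param rank_p Numeric vector of rank p-values in (0, 1].
#' @param alpha Two-tailed significance level, default 0.05.
#' @return Character vector among `"clustered"`, `"overdispersed"`,
#'   `"random"`, `NA`.
#' @export
classify_pattern <- function(rank_p, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  ifelse(is.na(rank_p), NA_character_,
         ifelse(rank_p <= alpha / 2, "clustered",
                ifelse(rank_p >= 1 - alpha / 2, "overdispersed", "random")))
}

#' NRI / NTI view of SES results
#'
#' Webb's net relatedness index (NRI) and nearest taxon index (NTI) are the
#' negatives of the SES of MPD and MNTD respectively; positive NRI means
#' phylogenetic clustering.
#'
#' @param result A result data frame from [ses_phylodiv()] whose rows are all
#'   MPD or MNTD (PD has no NRI/NTI analogue and errors).
#' @return Numeric vector `-ses`, named `NRI` or `NTI` per row.
#' @export
nri_nti <- function(result) {
  stopifnot(is.data.frame(result), all(c("metric", "ses") %in% names(result)))
  if (any(result$metric == "PD")) stop("NRI/NTI are undefined for PD")
  out <- -result$ses
  names(out) <- ifelse(result$metric == "MPD", "NRI", "NTI")
  out
}

#' Derive a stable child seed from a master seed
#'
#' Counter-based: stream `i` is the same no matter how many other streams are
#' drawn, which keeps replicate r (or site i) reproducible when the number of
#' replicates changes.
#'
#' @param seed Master seed (integer-like).
#' @param i Stream index (integer-like scalar).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
child_seed <- function(seed, i) {
  s <- (abs(as.double(seed)) %% 2147483647) + 1
  x <- (s * 48271 + as.double(i) * 69621 + 12345) %% 2147483647
  as.integer(x)
}
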