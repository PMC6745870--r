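# Generators for regional trees, taxonomies, and community matrices with the
# statistical structure the sensitivity experiments assume, so every
# experiment runs without external data.

#' Simulate an ultrametric regional tree (chronogram)
#'
#' Birth-death (or pure-birth Yule) tree conditioned on `n_tips` extant tips,
#' rescaled to unit root depth.  Tips are labelled `s001, s002, ...`.
#'
#' @param n_tips Number of tips (>= 4).
#' @param model `"yule"` (death rate forced to 0) or `"birth_death"`.
#' @param birth,death Speciation and extinction rates (`birth > death >= 0`).
#' @param seed Random seed.
#' @return A `phylo` chronogram with unit root depth and
#'   `units = "chronogram"`.
#' @export
simulate_chronogram <- function(n_tips, model = c("yule", "birth_death"),
                                birth = 1, death = 0, seed = NULL) {
  model <- match.arg(model)
  stopifnot(n_tips >= 4)
  if (model == "yule") death <- 0
  if (!(birth > death && death >= 0)) stop("need birth > death >= 0")
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = birth, death = death)
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  tree$tip.label <- sprintf("s%03d", seq_len(n_tips))
  attr(tree, "units") <- "chronogram"
  tree
}

#' Derive a rate-heterogeneous phylogram from a chronogram
#'
#' Multiplies every branch by an i.i.d. lognormal(0, `sigma`) rate, leaving
#' the topology untouched.  `sigma = 0` returns the chronogram itself (every
#' multiplier is exactly 1), so the "phylogram" is then still a clock tree.
#'
#' @param chronogram An ultrametric `phylo` object.
#' @param sigma Lognormal sd of branch-rate multipliers (>= 0).
#' @param seed Random seed.
#' @return A `phylo` object with `units = "phylogram"`.
#' @export
derive_phylogram <- function(chronogram, sigma, seed = NULL) {
  stopifnot(inherits(chronogram, "phylo"), sigma >= 0)
  if (!is_ultrametric(chronogram)) stop("input must be ultrametric")
  out <- chronogram
  if (sigma > 0) {
    if (!is.null(seed)) set.seed(seed)
    out$edge.length <- out$edge.length *
      stats::rlnorm(length(out$edge.length), 0, sigma)
  }
  attr(out, "units") <- "phylogram"
  out
}

#' Derive a family taxonomy by cutting a chronogram at a depth
#'
#' Every maximal clade whose stem branch crosses `cut_depth` (measured from
#' the root) becomes one family, so families are monophyletic by
#' construction and partition the tips.
#'
#' @param tree An ultrametric `phylo` object.
#' @param cut_depth Depth of the cut, strictly between 0 and the tree height.
#' @return A taxonomy data frame (`species`, `family`), families labelled
#'   `F01, F02, ...` in tree order.
#' @export
derive_families <- function(tree, cut_depth) {
  stopifnot(inherits(tree, "phylo"))
  if (!is_ultrametric(tree)) stop("family derivation expects a chronogram")
  depths <- ape::node.depth.edgelength(tree)
  height <- max(depths[seq_along(tree$tip.label)])
  if (!(cut_depth > 0 && cut_depth < height)) {
    stop("cut_depth must lie strictly between 0 and the tree height")
  }
  e <- tree$edge
  crossing <- which(depths[e[, 1L]] < cut_depth & depths[e[, 2L]] >= cut_depth)
  ntip <- length(tree$tip.label)
  fam <- character(ntip)
  for (i in seq_along(crossing)) {
    node <- e[crossing[i], 2L]
    tips <- if (node <= ntip) node else {
      which(tree$tip.label %in% ape::extract.clade(tree, node)$tip.label)
    }
    fam[tips] <- sprintf("F%02d", i)
  }
  stopifnot(all(fam != ""))            # partition: every tip assigned once
  data.frame(species = tree$tip.label, family = fam,
             stringsAsFactors = FALSE)
}

#' Default community-assembly scenario table
#'
#' One row per site.  The mix emulates a field survey over a heterogeneous
#' landscape: a majority of sites assembled neutrally, the rest under
#' phylogenetic filtering (clustering) or repulsion (overdispersion), with a
#' right-skewed site-richness profile (many small sites, few large) whose
#' fractions of the pool sum to ~1 so that most species end up occupying a
#' single site.
#'
#' @param n_sites Number of sites (default 14).
#' @param n_tips Pool size used to convert richness fractions to counts.
#' @param strength Assembly strength for the non-neutral sites (default 2).
#' @return Data frame with columns `kind`, `strength`, `richness`.
#' @export
default_scenarios <- function(n_sites = 14, n_tips = 200, strength = 2) {
  frac <- c(0.02, 0.03, 0.03, 0.04, 0.04, 0.05, 0.05, 0.06,
            0.07, 0.08, 0.09, 0.10, 0.13, 0.18)
  frac <- rep_len(frac, n_sites)
  kind <- rep_len(c("neutral", "filtering", "neutral", "repulsion",
                    "neutral", "filtering", "repulsion"), n_sites)
  data.frame(kind = kind,
             strength = ifelse(kind == "neutral", 0, strength),
             richness = pmax(5L, as.integer(round(frac * n_tips))),
             stringsAsFactors = FALSE)
}

#' Simulate a community matrix under assembly scenarios
#'
#' Site draws by scenario kind:
#' \describe{
#'   \item{neutral}{uniform draw of `richness` tips.}
#'   \item{filtering}{a focal tip is drawn uniformly; the remaining members
#'     are sampled without replacement with weight
#'     `exp(-strength * d(focal, i))`, concentrating the community around the
#'     focal lineage (phylogenetic clustering).}
#'   \item{repulsion}{greedy max-min patristic selection seeded at a random
#'     tip with softmax temperature `1/strength`: each next member is drawn
#'     with probability proportional to `exp(strength * min_d(i, selected))`
#'     (phylogenetic overdispersion).}
#' }
#' `strength = 0` makes filtering and repulsion collapse exactly to the
#' neutral draw.
#'
#' @param tree Regional `phylo` tree.
#' @param scenarios Data frame with columns `kind`, `strength`, `richness`
#'   (one row per site), e.g. [default_scenarios()].
#' @param seed Master seed; site `i` uses `child_seed(seed, i)`.
#' @return Binary community matrix, sites `C01, C02, ...` x species (sorted
#'   tip labels).
#' @export
simulate_communities <- function(tree, scenarios, seed = NULL) {
  stopifnot(inherits(tree, "phylo"), is.data.frame(scenarios),
            all(c("kind", "strength", "richness") %in% names(scenarios)))
  if (any(scenarios$richness < 2)) stop("site richness must be at least 2")
  if (any(scenarios$richness > length(tree$tip.label))) {
    stop("site richness exceeds pool size")
  }
  if (any(scenarios$strength < 0)) stop("strength must be >= 0")
  pool <- sort(tree$tip.label)
  d <- patristic_matrix(tree)[pool, pool]
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  n_sites <- nrow(scenarios)
  m <- matrix(0L, n_sites, length(pool),
              dimnames = list(sprintf("C%02d", seq_len(n_sites)), pool))
  for (i in seq_len(n_sites)) {
    set.seed(child_seed(seed, i))
    k <- scenarios$richness[i]
    lambda <- scenarios$strength[i]
    kind <- if (lambda == 0) "neutral" else scenarios$kind[i]
    members <- switch(
      kind,
      neutral = sample(pool, k),
      filtering = {
        focal <- sample(pool, 1L)
        others <- setdiff(pool, focal)
        w <- exp(-lambda * d[focal, others])
        c(focal, sample(others, k - 1L, prob = w))
      },
      repulsion = {
        sel <- sample(pool, 1L)
        remaining <- setdiff(pool, sel)
        mind <- d[remaining, sel]
        while (length(sel) < k) {
          logw <- lambda * mind
          w <- exp(logw - max(logw))
          nxt <- sample(length(remaining), 1L, prob = w)
          sel <- c(sel, remaining[nxt])
          mind <- pmin(mind[-nxt], d[remaining[-nxt], remaining[nxt]])
          remaining <- remaining[-nxt]
        }
        sel
      },
      stop("unknown scenario kind: ", scenarios$kind[i])
    )
    m[i, members] <- 1L
  }
  m
}

#' Perturb a tree to emulate independent re-estimation
#'
#' Applies `n_nni` random rooted nearest-neighbour-interchange moves and
#' multiplies every branch by an i.i.d. lognormal(0, `tau`) factor.  This is
#' a synthetic stand-in for re-estimating the tree from data: topology and
#' branch lengths are jittered while the tip set is preserved.  With
#' `n_nni = 0` and `tau = 0` the tree is returned unchanged.
#'
#' @param tree A rooted binary `phylo` object.
#' @param n_nni Number of NNI moves (default 5).
#' @param tau Lognormal sd of branch-length noise (default 0.2).
#' @param seed Random seed.
#' @return A perturbed `phylo` object on the same tips.
#' @export
perturb_tree <- function(tree, n_nni = 5, tau = 0.2, seed = NULL) {
  stopifnot(inherits(tree, "phylo"), n_nni >= 0, tau >= 0)
  if (!is.null(seed)) set.seed(seed)
  out <- tree
  ntip <- length(out$tip.label)
  root <- ntip + 1L
  for (m in seq_len(n_nni)) {
    e <- out$edge
    # internal, non-root nodes with a parent: swap one child with its uncle
    internal <- setdiff(unique(e[, 1L]), root)
    if (!length(internal)) break
    v <- if (length(internal) == 1L) internal else sample(internal, 1L)
    p <- e[match(v, e[, 2L]), 1L]
    sibs <- setdiff(e[e[, 1L] == p, 2L], v)
    kids <- e[e[, 1L] == v, 2L]
    s <- if (length(sibs) == 1L) sibs else sample(sibs, 1L)
    cc <- if (length(kids) == 1L) kids else sample(kids, 1L)
    out$edge[which(e[, 1L] == p & e[, 2L] == s), 1L] <- v
    out$edge[which(e[, 1L] == v & e[, 2L] == cc), 1L] <- p
    out <- ape::read.tree(text = ape::write.tree(out))  # renormalize
  }
  if (tau > 0) {
    out$edge.length <- out$edge.length *
      stats::rlnorm(length(out$edge.length), 0, tau)
  }
  attr(out, "units") <- tree_units(tree)
  out
}
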