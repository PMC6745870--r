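# Taxon subsampling strategies for the regional species pool.

#' Uniform random taxon subsets
#'
#' Each replicate is an independent uniform draw without replacement of
#' `size` species from the pool.  Replicate `r` uses child seed
#' `child_seed(seed, r)`, so it is stable no matter how many replicates are
#' requested.
#'
#' @param pool Character vector of species ids (the regional pool).
#' @param size Target subset size.
#' @param n_reps Number of replicates (default 1).
#' @param seed Master seed.
#' @return A list of character vectors, one per replicate, with attributes
#'   `strategy`, `target_size`, `seed`.
#' @export
random_subset <- function(pool, size, n_reps = 1, seed = NULL) {
  pool <- as.character(pool)
  stopifnot(!anyDuplicated(pool), n_reps >= 1)
  if (size > length(pool)) stop("target size exceeds pool size")
  if (size < 1) stop("target size must be positive")
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  reps <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    set.seed(child_seed(seed, r))
    reps[[r]] <- pool[sample.int(length(pool), size)]
  }
  structure(reps, strategy = "random", target_size = size, seed = seed)
}

#' Family-proportional quotas by largest remainder
#'
#' Splits `target` seats over families proportionally to their pool richness:
#' `q_f = floor(target * n_f / N)`, with the leftover seats (largest-remainder
#' mode) assigned by decreasing fractional remainder, ties broken by larger
#' family and then lexicographic id.  `"floor"` mode skips the leftover seats,
#' which under-shoots the target the way richness-proportional designs often
#' do in practice.
#'
#' @param counts Named integer vector of per-family pool richness.
#' @param target Total target size.
#' @param method `"largest_remainder"` (default) or `"floor"`.
#' @return Named integer vector of quotas.
#' @export
family_quotas <- function(counts, target,
                          method = c("largest_remainder", "floor")) {
  method <- match.arg(method)
  stopifnot(!is.null(names(counts)), all(counts >= 0))
  n <- sum(counts)
  if (target > n) stop("target exceeds pool size")
  share <- target * counts / n
  q <- floor(share)
  if (method == "largest_remainder") {
    left <- target - sum(q)
    if (left > 0) {
      frac <- share - q
      ord <- order(-frac, -counts, names(counts))
      q[ord[seq_len(left)]] <- q[ord[seq_len(left)]] + 1
    }
  }
  storage.mode(q) <- "integer"
  q
}

#' Family-proportional taxon subsets
#'
#' Draws, per replicate, `q_f` species uniformly without replacement from
#' within each family, with quotas proportional to family representation in
#' the complete pool (see [family_quotas()]).  Realized sizes can differ from
#' the target under `"floor"` rounding and are recorded on the result.
#'
#' @inheritParams random_subset
#' @param taxonomy Taxonomy data frame ([as_taxonomy()]) covering the pool.
#' @param method Quota rounding rule, see [family_quotas()].
#' @return A list of character vectors with attributes `strategy`,
#'   `target_size`, `realized_size`, `quotas`, `seed`.
#' @export
family_proportional_subset <- function(pool, taxonomy, size, n_reps = 1,
                                       seed = NULL,
                                       method = c("largest_remainder",
                                                  "floor")) {
  method <- match.arg(method)
  pool <- as.character(pool)
  taxonomy <- as_taxonomy(taxonomy)
  missing <- setdiff(pool, taxonomy$species)
  if (length(missing)) {
    stop("pool species missing from taxonomy: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  fam <- taxonomy$family[match(pool, taxonomy$species)]
  counts <- table(fam)
  q <- family_quotas(stats::setNames(as.integer(counts), names(counts)),
                     size, method = method)
  fams <- sort(names(q)[q > 0])
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  reps <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    set.seed(child_seed(seed, r))
    picked <- character(0)
    for (f in fams) {
      members <- sort(pool[fam == f])
      picked <- c(picked, members[sample.int(length(members), q[[f]])])
    }
    reps[[r]] <- picked
  }
  structure(reps, strategy = "family_proportional", target_size = size,
            realized_size = sum(q), quotas = q, seed = seed)
}

#' Clade-restricted pool
#'
#' Deterministic list of all pool species belonging to a named family or
#' higher clade from the taxonomy table.
#'
#' @inheritParams family_proportional_subset
#' @param clade_id A family name or a value of any higher-clade column of the
#'   taxonomy.
#' @return Character vector of species ids (sorted).
#' @export
clade_subset <- function(pool, taxonomy, clade_id) {
  pool <- as.character(pool)
  taxonomy <- as_taxonomy(taxonomy)
  cols <- setdiff(names(taxonomy), "species")
  members <- character(0)
  for (col in cols) {
    hit <- taxonomy$species[which(taxonomy[[col]] == clade_id)]
    if (length(hit)) members <- union(members, hit)
  }
  if (!length(members)) stop("unknown clade id: ", clade_id)
  out <- sort(intersect(members, pool))
  if (!length(out)) stop("clade '", clade_id, "' has no members in the pool")
  out
}
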