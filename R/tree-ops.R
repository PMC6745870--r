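#' Read a rooted phylogeny from Newick text or a file
#'
#' Thin, validating wrapper around [ape::read.tree()].  Single-quoted labels
#' and underscores are passed through as-is, and square-bracket comments are
#' stripped before parsing.  Branch lengths are mandatory because every
#' downstream phylodiversity metric consumes them; negative lengths are
#' rejected (zero-length branches, as produced by arbitrarily resolved
#' polytomies, are allowed).
#'
#' @param x Path to a Newick file, or a Newick string.
#' @param units Branch-length units tag: `"phylogram"` (substitutions/site),
#'   `"chronogram"` (time; the tree must then be ultrametric within
#'   `rtol = 1e-6`), or `"unknown"` (default).
#' @return An [ape::phylo] object with a `units` attribute.
#' @seealso [write_newick()], [is_ultrametric()]
#' @export
read_newick <- function(x, units = c("unknown", "phylogram", "chronogram")) {
  units <- match.arg(units)
  stopifnot(is.character(x), length(x) == 1L)
  txt <- if (file.exists(x) && !grepl("\\(", x)) {
    paste(readLines(x, warn = FALSE), collapse = "")
  } else if (grepl("\\(", x)) {
    x
  } else {
    stop("'", x, "' is neither an existing file nor Newick text")
  }
  txt <- gsub("\\[[^]]*\\]", "", txt)       # drop bracket comments
  if (!grepl(";", txt)) stop("malformed Newick: missing terminating ';'")
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) stop("Newick parse failure: ",
                                            conditionMessage(e)))
  if (is.null(tree) || !inherits(tree, "phylo")) {
    stop("Newick parse failure")
  }
  tree$tip.label <- gsub("^'(.*)'$", "\\1", tree$tip.label)  # unquote
  validate_phylogeny(tree, units = units)
  attr(tree, "units") <- units
  tree
}

#' Write a phylogeny as Newick
#'
#' @param tree A `phylo` object.
#' @param path Optional file path; when `NULL` the Newick string is returned.
#' @return The Newick string (invisibly when written to a file).
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  txt <- ape::write.tree(tree)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' @return The tree's branch-length units tag (`"phylogram"`, `"chronogram"`,
#'   or `"unknown"`).
#' @rdname read_newick
#' @export
tree_units <- function(tree) {
  u <- attr(tree, "units")
  if (is.null(u)) "unknown" else u
}

# Shared invariant checks for trees entering the package.
validate_phylogeny <- function(tree, units = "unknown") {
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  }
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(!is.finite(tree$edge.length))) {
    stop("tree has missing or non-finite branch lengths")
  }
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  if (identical(units, "chronogram") && !is_ultrametric(tree)) {
    stop("chronogram-tagged tree is not ultrametric within tolerance")
  }
  invisible(tree)
}

#' Prune a phylogeny to a set of taxa
#'
#' Retains exactly `keep`, suppressing the unifurcations created by tip
#' removal and summing their incident branch lengths (classic `drop.tip`
#' semantics), so patristic distances among the kept tips are unchanged.
#'
#' @param tree A `phylo` object with branch lengths.
#' @param keep Character vector of tip labels to retain (at least 2).
#' @return The pruned `phylo` object; the `units` attribute is carried over.
#' @export
prune_to_taxa <- function(tree, keep) {
  stopifnot(inherits(tree, "phylo"))
  keep <- unique(as.character(keep))
  unknown <- setdiff(keep, tree$tip.label)
  if (length(unknown)) {
    stop("unknown tip labels: ", paste(utils::head(unknown, 5), collapse = ", "))
  }
  if (length(keep) < 2L) stop("need at least 2 taxa to keep")
  out <- ape::keep.tip(tree, keep)
  attr(out, "units") <- tree_units(tree)
  out
}

#' Root a phylogeny by a ladder of successively less basal outgroups
#'
#' Walks an ordered list of candidate outgroup tip sets (most basal first,
#' e.g. lycophytes, then ferns, ...) and re-roots the tree on the branch
#' subtending the first set with any members present.  When a set is only
#' partially present the most recent common ancestor (MRCA) of the present
#' members is used.  This mirrors the common workflow of rooting subset trees
#' on the most basal lineage that survived taxon subsampling.
#'
#' @param tree A `phylo` object.
#' @param ladder A list of character vectors of tip labels, ordered from most
#'   basal inward.
#' @return The re-rooted `phylo` object.
#' @export
root_by_ladder <- function(tree, ladder) {
  stopifnot(inherits(tree, "phylo"), is.list(ladder), length(ladder) > 0L)
  if (any(lengths(ladder) == 0L)) stop("empty ladder entry")
  for (entry in ladder) {
    present <- intersect(as.character(entry), tree$tip.label)
    if (!length(present)) next
    if (length(present) == length(tree$tip.label)) {
      stop("ladder entry spans every tip; cannot root on it")
    }
    out <- if (length(present) == 1L) {
      ape::root(tree, outgroup = present, resolve.root = TRUE)
    } else {
      node <- ape::getMRCA(tree, present)
      root_node <- length(tree$tip.label) + 1L
      if (node == root_node) tree   # already rooted compatibly
      else ape::root(tree, node = node, resolve.root = TRUE)
    }
    attr(out, "units") <- tree_units(tree)
    return(out)
  }
  stop("no ladder entry has any member present in the tree")
}

#' Patristic distance matrix
#'
#' Sum of branch lengths along the path between every pair of tips
#' (via [stats::cophenetic()] on the `phylo` object).
#'
#' @param tree A `phylo` object with branch lengths.
#' @return Symmetric numeric matrix with tip labels as dimnames.
#' @export
patristic_matrix <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  stats::cophenetic(tree)
}

#' Is a tree ultrametric?
#'
#' A tree is taken as ultrametric when the ratio of the deepest to the
#' shallowest root-to-tip path length is at most `1 + rtol`.  The default
#' tolerance absorbs the rounding noise of time-calibration software.
#'
#' @param tree A rooted `phylo` object with branch lengths.
#' @param rtol Relative tolerance (default `1e-6`).
#' @return `TRUE` or `FALSE`.
#' @export
is_ultrametric <- function(tree, rtol = 1e-6) {
  stopifnot(inherits(tree, "phylo"))
  depths <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  if (max(depths) == 0) return(TRUE)
  if (min(depths) <= 0) return(FALSE)
  max(depths) / min(depths) <= 1 + rtol
}
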