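#' Build or validate a community presence/absence matrix
#'
#' Communities are stored as a binary sites-by-species matrix over a regional
#' species pool.  Sites with fewer taxa than the analysis minimum are kept
#' (and later flagged `NA` by the metrics), never silently dropped.
#'
#' @param x A matrix or data frame with site ids as row names and species ids
#'   as column names, entries 0/1.
#' @return An integer 0/1 matrix.
#' @export
as_community_matrix <- function(x) {
  m <- as.matrix(x)
  if (is.null(rownames(m))) rownames(m) <- paste0("site", seq_len(nrow(m)))
  if (is.null(colnames(m))) stop("community matrix needs species column names")
  if (anyDuplicated(colnames(m))) stop("duplicate species ids")
  suppressWarnings(storage.mode(m) <- "integer")
  if (anyNA(m) || !all(m %in% c(0L, 1L))) {
    stop("community matrix entries must be 0/1")
  }
  m
}

#' Read a community matrix from delimited text
#'
#' Expects a header row of species ids and a first column of site ids;
#' remaining cells are 0/1.
#'
#' @param path File path.
#' @param sep Field separator (default comma).
#' @return An integer 0/1 matrix, sites in rows.
#' @export
read_community <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE)
  as_community_matrix(df)
}

#' @param comm Community matrix as returned by [as_community_matrix()].
#' @rdname read_community
#' @export
write_community <- function(comm, path, sep = ",") {
  comm <- as_community_matrix(comm)
  df <- data.frame(site = rownames(comm), comm, check.names = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a taxonomy table (species to family, plus optional higher clades)
#'
#' Two or more delimited columns: `species`, `family`, and optionally further
#' columns naming higher clades (e.g. a `clade` column holding "rosids").
#' Every species must appear exactly once.
#'
#' @param path File path.
#' @param sep Field separator (default comma).
#' @return A data frame with at least `species` and `family` columns.
#' @export
read_taxonomy <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  as_taxonomy(df)
}

#' @param x A data frame with `species` and `family` columns.
#' @rdname read_taxonomy
#' @export
as_taxonomy <- function(x) {
  df <- as.data.frame(x, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("taxonomy needs at least species and family columns")
  if (!all(c("species", "family") %in% names(df))) {
    names(df)[1:2] <- c("species", "family")
  }
  df$species <- as.character(df$species)
  df$family <- as.character(df$family)
  if (anyDuplicated(df$species)) stop("duplicate species in taxonomy")
  if (anyNA(df$species) || anyNA(df$family)) stop("missing taxonomy entries")
  df
}

#' Check that taxonomy clades are monophyletic on a reference tree
#'
#' Warns (does not error) for every family or higher clade whose members do
#' not form a monophyletic group on `tree`; taxonomic ranks are not guaranteed
#' to be clades in real data.
#'
#' @param taxonomy A taxonomy data frame ([as_taxonomy()]).
#' @param tree Reference `phylo` object.
#' @return Invisibly, a character vector of non-monophyletic group ids.
#' @export
check_taxonomy <- function(taxonomy, tree) {
  taxonomy <- as_taxonomy(taxonomy)
  bad <- character()
  cols <- setdiff(names(taxonomy), "species")
  for (col in cols) {
    for (id in unique(stats::na.omit(taxonomy[[col]]))) {
      tips <- intersect(taxonomy$species[which(taxonomy[[col]] == id)],
                        tree$tip.label)
      if (length(tips) > 1L && length(tips) < length(tree$tip.label) &&
          !ape::is.monophyletic(tree, tips)) {
        bad <- c(bad, id)
      }
    }
  }
  if (length(bad)) {
    warning("non-monophyletic groups on the reference tree: ",
            paste(bad, collapse = ", "))
  }
  invisible(bad)
}
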