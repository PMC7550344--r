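#' Normalize taxon names
#'
#' Taxon matching throughout the package is exact string match after trimming
#' surrounding whitespace and replacing internal whitespace runs with a single
#' underscore, so `"Morganucodon watsoni"` and `"Morganucodon_watsoni"` refer
#' to the same tip.
#'
#' @param x character vector of taxon names.
#' @return character vector of normalized names.
#' @export
#' @examples
#' normalize_taxa(c(" Morganucodon watsoni", "Kuehneotherium_praecursoris"))
normalize_taxa <- function(x) {
  gsub("[ \t]+", "_", trimws(as.character(x)))
}

#' Read a rooted phylogeny from Newick
#'
#' Thin, validating wrapper around [ape::read.tree()]. Branch lengths are
#' mandatory (they carry time, in Myr, for all downstream covariance work),
#' tip labels must be unique after normalization, and malformed input errors
#' rather than returning `NULL`.
#'
#' @param text a Newick string (ending in `;`).
#' @param file path to a Newick file; supply exactly one of `text`/`file`.
#' @return an object of class `phylo`.
#' @export
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
read_newick <- function(text = NULL, file = NULL) {
  if (is.null(text) == is.null(file))
    stop("supply exactly one of `text` or `file`")
  if (is.null(text))
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  # normalize embedded spaces in labels before parsing (ape would silently
  # delete them): strip whitespace around structural characters, then turn
  # remaining runs into underscores
  text <- gsub("[ \t]*([(),:;])[ \t]*", "\\1", text)
  text <- gsub("[ \t]+", "_", text)
  n_open <- nchar(gsub("[^(]", "", text))
  n_close <- nchar(gsub("[^)]", "", text))
  if (n_open != n_close)
    stop("unbalanced parentheses in Newick input (", n_open, " '(' vs ",
         n_close, " ')')")
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) stop("Newick parse error: ",
                                            conditionMessage(e)),
                   warning = function(w) stop("Newick parse error: ",
                                              conditionMessage(w)))
  if (is.null(tree)) stop("Newick parse error: could not interpret input")
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("Newick input is missing branch lengths")
  if (any(tree$edge.length < 0))
    stop("negative branch lengths in Newick input")
  tree$tip.label <- normalize_taxa(tree$tip.label)
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup))
    stop("duplicate tip labels: ", paste(dup, collapse = ", "))
  tree
}

#' Write a phylogeny as Newick
#'
#' @param tree a `phylo` object.
#' @param file optional path; if `NULL` the Newick string is returned.
#' @return the Newick string (invisibly when written to file).
#' @export
write_newick <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "phylo"))
  s <- ape::write.tree(tree)
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}

#' Root-to-tip depths and tree height
#'
#' `tip_depths()` returns the root-to-tip path length of every tip;
#' `tree_height()` the maximum. For an ultrametric (time-calibrated) tree
#' all depths are equal and `tree_height()` is the age of the root in the
#' branch-length unit (Myr throughout this package).
#'
#' @param tree a `phylo` object with branch lengths.
#' @return numeric vector (named by tip) / a single number.
#' @export
tip_depths <- function(tree) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  d <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  names(d) <- tree$tip.label
  # a root (stem) edge — e.g. retained by pruning — is shared history of
  # every tip and counts towards all depths
  d + (tree$root.edge %||% 0)
}

#' @rdname tip_depths
#' @export
tree_height <- function(tree) max(tip_depths(tree))

#' Test ultrametricity
#'
#' A tree is treated as ultrametric when the spread of root-to-tip depths is
#' within a relative tolerance of the height.
#'
#' @param tree a `phylo` object.
#' @param tol relative tolerance (default `1e-6`).
#' @return logical.
#' @export
is_ultrametric_tree <- function(tree, tol = 1e-6) {
  d <- tip_depths(tree)
  (max(d) - min(d)) <= tol * max(d)
}

#' Phylogenetic variance-covariance matrix with Pagel's lambda transform
#'
#' Builds the taxa-by-taxa shared-path matrix of a rooted tree (entries in the
#' branch-length unit, Myr) and applies the standard Pagel transform: every
#' off-diagonal covariance is multiplied by `lambda` while the diagonal
#' (root-to-tip distances) is left untouched. `lambda = 0` removes all
#' phylogenetic covariance; `lambda = 1` is the Brownian-motion expectation.
#'
#' Lambda is restricted to `[0, 1]`: values outside the unit interval can
#' break positive semi-definiteness, so they error unless
#' `allow_out_of_range = TRUE` is set deliberately.
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @param lambda Pagel's lambda in `[0, 1]`.
#' @param allow_out_of_range set `TRUE` to permit lambda outside `[0, 1]`.
#' @return a symmetric matrix with taxa in `tree$tip.label` order.
#' @export
#' @examples
#' vcv_pagel(read_newick("((A:1,B:1):1,C:2);"), lambda = 0.5)
vcv_pagel <- function(tree, lambda = 1, allow_out_of_range = FALSE) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda))
    stop("lambda must be a single number")
  if (!allow_out_of_range && (lambda < 0 || lambda > 1))
    stop("lambda = ", lambda, " is outside [0, 1]; ",
         "set allow_out_of_range = TRUE to override")
  V <- ape::vcv.phylo(tree) + (tree$root.edge %||% 0)
  d <- diag(V)
  V <- V * lambda
  diag(V) <- d
  V
}

#' Graft two clades at a dated common-ancestor node
#'
#' Joins two ultrametric trees under a new root whose age is fixed (e.g. a
#' squamate+crocodilian clade and a mammal clade joined at an amniote ancestor
#' dated 325.5 Ma). Each clade receives a stem branch of length
#' `lca_age - height(clade)`, so the grafted tree is ultrametric with height
#' `lca_age`.
#'
#' @param tree_a,tree_b ultrametric `phylo` objects with disjoint tip sets
#'   and at least two tips each.
#' @param lca_age age of the new root (Myr); must exceed both clade heights.
#' @return an ultrametric `phylo` of height `lca_age`.
#' @export
graft_clades <- function(tree_a, tree_b, lca_age) {
  stopifnot(inherits(tree_a, "phylo"), inherits(tree_b, "phylo"))
  if (!is_ultrametric_tree(tree_a) || !is_ultrametric_tree(tree_b))
    stop("both input trees must be ultrametric for dated grafting")
  ha <- tree_height(tree_a)
  hb <- tree_height(tree_b)
  if (lca_age <= ha || lca_age <= hb)
    stop("dating conflict: lca_age (", lca_age,
         ") must exceed both clade heights (", signif(ha, 6), ", ",
         signif(hb, 6), ")")
  common <- intersect(tree_a$tip.label, tree_b$tip.label)
  if (length(common))
    stop("tip labels shared between clades: ",
         paste(utils::head(common, 5), collapse = ", "))
  n_a <- ape::Ntip(tree_a); m_a <- tree_a$Nnode
  n_b <- ape::Ntip(tree_b); m_b <- tree_b$Nnode
  n <- n_a + n_b
  root <- n + 1L
  # renumber: tips of a keep 1..n_a, tips of b become n_a+1..n;
  # new root is n+1; internals of a follow, then internals of b
  map_a <- function(v) ifelse(v <= n_a, v, v + n_b + 1L)
  map_b <- function(v) ifelse(v <= n_b, v + n_a, v + n_a + m_a + 1L)
  edge <- rbind(
    c(root, map_a(n_a + 1L)),
    c(root, map_b(n_b + 1L)),
    cbind(map_a(tree_a$edge[, 1]), map_a(tree_a$edge[, 2])),
    cbind(map_b(tree_b$edge[, 1]), map_b(tree_b$edge[, 2]))
  )
  out <- list(
    edge = edge,
    edge.length = c(lca_age - ha, lca_age - hb,
                    tree_a$edge.length, tree_b$edge.length),
    tip.label = c(tree_a$tip.label, tree_b$tip.label),
    Nnode = m_a + m_b + 1L
  )
  storage.mode(out$edge) <- "integer"
  class(out) <- "phylo"
  ape::reorder.phylo(out, "cladewise")
}

#' Prune a tree to a set of taxa
#'
#' Returns the induced subtree on the intersection of `taxa` with the tree's
#' tips: internal degree-2 nodes are suppressed and root-to-tip path lengths
#' are preserved. When the kept taxa's ancestor lies below the original
#' root, the path from the original root is retained as the pruned tree's
#' root edge, so depths and phylogenetic covariances ([vcv_pagel()]) are
#' unchanged by pruning. Requested names absent from the tree are reported
#' in a warning and attached as the `"dropped_request"` attribute.
#'
#' @param tree a `phylo` object.
#' @param taxa character vector of tip names (normalized before matching).
#' @return a `phylo` object on the matched taxa.
#' @export
prune_to_taxa <- function(tree, taxa) {
  stopifnot(inherits(tree, "phylo"))
  taxa <- normalize_taxa(taxa)
  keep <- intersect(tree$tip.label, taxa)
  missing <- setdiff(taxa, tree$tip.label)
  if (!length(keep))
    stop("none of the requested taxa are in the tree")
  if (length(missing))
    warning("taxa not in tree (dropped from request): ",
            paste(missing, collapse = ", "))
  if (length(keep) == ape::Ntip(tree)) {
    out <- tree
  } else {
    out <- ape::drop.tip(tree, setdiff(tree$tip.label, keep),
                         collapse.singles = TRUE)
    # retain the path from the original root to the kept taxa's ancestor as
    # a stem (root edge), so depths and covariances survive pruning
    stem <- tree$root.edge %||% 0
    if (length(keep) > 1) {
      mrca <- ape::getMRCA(tree, keep)
      stem <- stem + ape::node.depth.edgelength(tree)[mrca]
    }
    if (stem > 0) out$root.edge <- stem
  }
  attr(out, "dropped_request") <- missing
  out
}
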