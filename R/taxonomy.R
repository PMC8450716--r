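#' Default super-kingdom root TaxIds
#'
#' The four super-kingdom roots (NCBI TaxIds): Bacteria 2, Archaea 2157,
#' Eukaryota 2759, Viruses 10239.  Synthetic worlds reuse these ids so
#' window sizes and screening thresholds resolve the same way as against
#' the real taxonomy.
#'
#' @return named integer vector mapping super-kingdom name to root TaxId.
#' @export
default_superkingdoms <- function() {
  c(Bacteria = 2L, Archaea = 2157L, Eukaryota = 2759L, Viruses = 10239L)
}

#' Construct a taxonomy tree from child/parent pairs
#'
#' A node whose parent equals itself is a root.  The tree is validated to
#' be acyclic with every referenced parent present.
#'
#' @param child,parent integer vectors of equal length: each child TaxId
#'   and its parent TaxId.
#' @param name,rank optional character vectors parallel to `child` (or
#'   named by TaxId) carrying display names and ranks.
#' @param superkingdoms named integer vector declaring the super-kingdom
#'   root TaxIds (see [default_superkingdoms()]).
#' @return an object of class `tax_tree`.
#' @export
tax_tree <- function(child, parent, name = NULL, rank = NULL,
                     superkingdoms = default_superkingdoms()) {
  child <- as.integer(child)
  parent <- as.integer(parent)
  stopifnot(length(child) == length(parent))
  if (anyNA(child) || anyNA(parent) || any(child <= 0L) || any(parent <= 0L))
    stop("TaxIds must be positive integers")
  if (anyDuplicated(child))
    stop("duplicate child TaxId in parents table: ",
         child[duplicated(child)][1])
  orphan <- setdiff(parent, child)
  if (length(orphan))
    stop("parent TaxId not defined as a node: ", orphan[1])

  idx <- seq_along(child)
  names(idx) <- as.character(child)
  pidx <- idx[as.character(parent)]

  # depth by memoized walk; a walk longer than the node count is a cycle
  n <- length(child)
  depth <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    path <- integer(0)
    j <- i
    while (is.na(depth[j]) && pidx[j] != j) {
      path <- c(path, j)
      j <- pidx[j]
      if (length(path) > n || j %in% path)
        stop("cycle detected in taxonomy at TaxId ", child[i])
    }
    base <- if (pidx[j] == j) 0L else depth[j]
    if (length(path))
      depth[path] <- base + rev(seq_along(path))
    if (pidx[i] == i) depth[i] <- 0L
  }

  get_meta <- function(x) {
    if (is.null(x)) return(rep(NA_character_, n))
    x <- as.character(x)
    if (!is.null(names(x))) {
      out <- x[as.character(child)]
      names(out) <- NULL
      return(out)
    }
    stopifnot(length(x) == n)
    x
  }

  structure(
    list(ids = child, parent = parent, depth = depth,
         name = get_meta(name), rank = get_meta(rank),
         index = idx,
         superkingdoms = superkingdoms[names(superkingdoms)[superkingdoms %in% child]]),
    class = "tax_tree")
}

#' @export
print.tax_tree <- function(x, ...) {
  cat("tax_tree:", length(x$ids), "nodes,",
      sum(x$parent == x$ids), "root(s);",
      "super-kingdoms:", if (length(x$superkingdoms))
        paste(names(x$superkingdoms), collapse = ", ") else "none", "\n")
  invisible(x)
}

.tax_idx <- function(tree, taxid) {
  i <- tree$index[as.character(taxid)]
  if (anyNA(i))
    stop("TaxId not in tree: ", paste(taxid[is.na(i)], collapse = ", "))
  unname(i)
}

#' Load a taxonomy from a two-column "parents" file
#'
#' Each line holds a node TaxId and its parent TaxId, whitespace separated;
#' `#` starts a comment.  A node listed as its own parent is a root.
#'
#' @param path path to the parents file.
#' @param names_path optional path to a names table with lines
#'   `TaxId<TAB>name<TAB>rank`.
#' @inheritParams tax_tree
#' @return a `tax_tree`.
#' @export
load_parents <- function(path, names_path = NULL,
                         superkingdoms = default_superkingdoms()) {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           col.names = c("child", "parent"),
                           colClasses = "integer")
  name <- rank <- NULL
  if (!is.null(names_path)) {
    nm <- utils::read.table(names_path, header = FALSE, sep = "\t",
                            quote = "", comment.char = "#",
                            col.names = c("taxid", "name", "rank"),
                            colClasses = c("integer", "character", "character"))
    name <- stats::setNames(nm$name, nm$taxid)
    rank <- stats::setNames(nm$rank, nm$taxid)
  }
  tax_tree(tab$child, tab$parent, name = name, rank = rank,
           superkingdoms = superkingdoms)
}

#' Write a taxonomy as a two-column parents file
#'
#' @param tree a `tax_tree`.
#' @param path output path.
#' @param names_path optional path for the `TaxId<TAB>name<TAB>rank` table.
#' @return `path`, invisibly.
#' @export
write_parents <- function(tree, path, names_path = NULL) {
  writeLines(paste(tree$ids, tree$parent, sep = "\t"), path)
  if (!is.null(names_path)) {
    keep <- !is.na(tree$name) | !is.na(tree$rank)
    writeLines(paste(tree$ids[keep],
                     ifelse(is.na(tree$name[keep]), "", tree$name[keep]),
                     ifelse(is.na(tree$rank[keep]), "", tree$rank[keep]),
                     sep = "\t"), names_path)
  }
  invisible(path)
}

#' Lineage of a node: the path from the node up to its root
#'
#' @param tree a `tax_tree`.
#' @param taxid a single TaxId present in the tree.
#' @return integer vector starting at `taxid` and ending at a root, each
#'   consecutive pair child then parent.
#' @export
tax_lineage <- function(tree, taxid) {
  i <- .tax_idx(tree, taxid[1])
  out <- integer(tree$depth[i] + 1L)
  for (j in seq_along(out)) {
    out[j] <- tree$ids[i]
    i <- .tax_idx(tree, tree$parent[i])
  }
  out
}

#' Lowest common ancestor of a set of nodes
#'
#' The deepest node that is ancestor-or-self of every member.  Members
#' lying under different roots resolve to the global root when one exists
#' (conventionally TaxId 1); otherwise an error is raised.
#'
#' @param tree a `tax_tree`.
#' @param taxids nonempty vector of TaxIds in the tree.
#' @return a single TaxId.
#' @export
tax_lca <- function(tree, taxids) {
  taxids <- unique(as.integer(taxids))
  stopifnot(length(taxids) >= 1)
  lin <- rev(tax_lineage(tree, taxids[1]))
  for (t in taxids[-1]) {
    lin2 <- rev(tax_lineage(tree, t))
    m <- min(length(lin), length(lin2))
    same <- lin[seq_len(m)] == lin2[seq_len(m)]
    common <- if (all(same)) m else which(!same)[1] - 1L
    if (common == 0L) stop("TaxIds lie under different roots and no common ",
                           "root joins them")
    lin <- lin[seq_len(common)]
  }
  lin[length(lin)]
}

#' Super-kingdom of a node
#'
#' @param tree a `tax_tree` with declared super-kingdom roots.
#' @param taxid a TaxId in the tree.
#' @return the super-kingdom name (`"Bacteria"`, `"Archaea"`,
#'   `"Eukaryota"`, `"Viruses"`) whose root lies on the node's lineage, or
#'   `NA` when the node is under none of the declared roots.
#' @export
superkingdom_of <- function(tree, taxid) {
  lin <- tax_lineage(tree, taxid)
  hit <- match(tree$superkingdoms, lin)
  if (all(is.na(hit))) return(NA_character_)
  names(tree$superkingdoms)[which(!is.na(hit))[1]]
}

#' Post-order traversal of the taxonomy
#'
#' @param tree a `tax_tree`.
#' @return integer vector of all TaxIds in which every child precedes its
#'   parent (deepest nodes first).
#' @export
tax_postorder <- function(tree) {
  tree$ids[order(tree$depth, decreasing = TRUE)]
}

#' Root nodes of the taxonomy
#' @param tree a `tax_tree`.
#' @return integer vector of root TaxIds (nodes that are their own parent).
#' @export
tax_roots <- function(tree) tree$ids[tree$parent == tree$ids]

#' All descendants of a node, including the node itself
#'
#' @inheritParams tax_lineage
#' @return integer vector of TaxIds in the node's subtree.
#' @export
tax_subtree <- function(tree, taxid) {
  .tax_idx(tree, taxid)  # validates
  inside <- tree$ids == taxid
  # nodes in depth order: a node is inside iff its parent is inside
  ord <- order(tree$depth)
  for (i in ord) {
    if (tree$ids[i] == taxid) next
    if (tree$parent[i] != tree$ids[i])
      inside[i] <- inside[i] || inside[.tax_idx(tree, tree$parent[i])]
  }
  tree$ids[inside]
}

#' Leaf nodes of the taxonomy
#' @param tree a `tax_tree`.
#' @return integer vector of TaxIds that are nobody's parent.
#' @export
tax_leaves <- function(tree) {
  tree$ids[!(tree$ids %in% tree$parent[tree$parent != tree$ids])]
}
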