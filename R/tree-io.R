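#' Read and validate a Newick tree
#'
#' Thin validating wrapper around [ape::read.tree()]: accepts a Newick
#' string or a file path, and enforces the contracts the rest of the
#' pipeline relies on — unique tip labels, branch lengths present on every
#' edge and non-negative. Quoted labels and underscores are supported by the
#' underlying parser.
#'
#' @param x A Newick string (containing `(` or `;`) or a path to a file.
#' @return A `phylo` object.
#' @export
read_newick <- function(x) {
  stopifnot(is.character(x), length(x) == 1)
  is_text <- grepl("[(;]", x)
  if (is_text) {
    n_open <- lengths(regmatches(x, gregexpr("(", x, fixed = TRUE)))
    n_close <- lengths(regmatches(x, gregexpr(")", x, fixed = TRUE)))
    if (n_open != n_close) {
      abort(sprintf("malformed Newick: %d '(' vs %d ')' (near character %d)",
                    n_open, n_close, nchar(x)))
    }
    tr <- tryCatch(ape::read.tree(text = x),
                   error = function(e) abort(paste("Newick parse error:", conditionMessage(e))))
  } else {
    if (!file.exists(x)) abort(paste("no such file:", x))
    tr <- tryCatch(ape::read.tree(x),
                   error = function(e) abort(paste("Newick parse error:", conditionMessage(e))))
  }
  if (is.null(tr)) abort("Newick parse error: no tree found")
  validate_tree(tr)
}

validate_tree <- function(tr) {
  if (!inherits(tr, "phylo")) abort("not a phylo object")
  dup <- unique(tr$tip.label[duplicated(tr$tip.label)])
  if (length(dup)) {
    abort(paste("duplicate tip labels:", paste(dup, collapse = ", ")))
  }
  if (is.null(tr$edge.length) || anyNA(tr$edge.length)) {
    abort("branch lengths missing on one or more edges")
  }
  if (any(tr$edge.length < 0)) abort("negative branch lengths")
  tr
}

#' Patristic distance matrix of a tree
#'
#' d(i, j) is the sum of branch lengths on the unique path between tips i
#' and j.
#'
#' @param tree A `phylo` object with branch lengths (or Newick string/path,
#'   passed through [read_newick()]).
#' @return Symmetric matrix, zero diagonal, tip labels as dimnames.
#' @export
patristic_matrix <- function(tree) {
  if (is.character(tree)) tree <- read_newick(tree)
  validate_tree(tree)
  if (length(tree$tip.label) < 2) abort("tree must have at least 2 tips")
  d <- stats::cophenetic(tree)
  # fixed label order for reproducibility
  ord <- sort(rownames(d))
  d[ord, ord, drop = FALSE]
}

#' Node heights of an ultrametric tree
#'
#' Height = time above the tips. Errors when tip depths differ by more than
#' `tol` (relative to tree depth), i.e. the tree is not ultrametric.
#' @param tree phylo
#' @param tol relative tolerance on tip-depth spread
#' @return numeric vector of heights indexed by node number (tips then
#'   internal nodes, ape convention)
#' @keywords internal
node_heights <- function(tree, tol = 1e-6) {
  depth <- ape::node.depth.edgelength(tree)
  ntip <- length(tree$tip.label)
  td <- depth[seq_len(ntip)]
  span <- max(td)
  if (span > 0 && (max(td) - min(td)) > tol * span) {
    abort(sprintf("tree is not ultrametric: tip depth spread %.3g exceeds %.0e of depth",
                  max(td) - min(td), tol))
  }
  max(td) - depth
}
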