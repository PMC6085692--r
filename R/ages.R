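#' Species (clade) ages from an ultrametric chronogram
#'
#' Reads each clade's age of origin off an ultrametric, time-calibrated
#' species tree. `stem` age (default) is the height of the parent node of
#' the clade's most recent common ancestor — when the lineage split from its
#' sister; it is defined even for clades represented by a single tip.
#' `crown` age is the height of the MRCA itself — the clade's own deepest
#' divergence — and falls back to stem age with a warning for single-tip
#' clades, for which no crown exists.
#'
#' @param chronogram Ultrametric `phylo` with branch lengths in time units
#'   (e.g. Myr).
#' @param clade_map Data frame with columns `tip` (tip labels of the
#'   chronogram) and `clade`. Each clade's tips must be monophyletic.
#' @param mode `"stem"` or `"crown"`.
#' @return Tibble: `clade`, `n_tips`, `age` (same units as branch lengths).
#' @export
species_age <- function(chronogram, clade_map, mode = c("stem", "crown")) {
  mode <- match.arg(mode)
  validate_tree(chronogram)
  stopifnot(is.data.frame(clade_map))
  if (!all(c("tip", "clade") %in% names(clade_map))) {
    abort("clade_map must have columns tip, clade")
  }
  missing <- setdiff(clade_map$tip, chronogram$tip.label)
  if (length(missing)) {
    abort(paste("tips absent from chronogram:", paste(missing, collapse = ", ")))
  }
  h <- node_heights(chronogram)  # errors if not ultrametric
  ntip <- length(chronogram$tip.label)
  root <- ntip + 1L
  parent <- rep(NA_integer_, ntip + chronogram$Nnode)
  parent[chronogram$edge[, 2]] <- chronogram$edge[, 1]

  clades <- split(clade_map$tip, clade_map$clade)
  purrr::imap_dfr(clades, function(tips, cl) {
    idx <- match(tips, chronogram$tip.label)
    if (length(idx) == 1) {
      mrca <- idx
    } else {
      mrca <- ape::getMRCA(chronogram, tips)
      desc <- ape::extract.clade(chronogram, mrca)$tip.label
      intruders <- setdiff(desc, tips)
      if (length(intruders)) {
        abort(paste0("clade '", cl, "' is not monophyletic; intruding tips: ",
                     paste(intruders, collapse = ", ")))
      }
    }
    age <- if (mode == "stem") {
      if (mrca == root) h[root] else h[parent[mrca]]
    } else {
      if (length(idx) == 1) {
        warn(paste0("clade '", cl, "' has a single tip: no crown age; using stem"))
        h[parent[mrca]]
      } else {
        h[mrca]
      }
    }
    tibble::tibble(clade = cl, n_tips = length(tips), age = age)
  })
}
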