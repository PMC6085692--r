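#' Pairwise distances from an alignment
#'
#' Species-level genetic distances from aligned sequences under simple
#' substitution models. Columns containing a gap (`-`) or an ambiguous base
#' (anything outside A/C/G/T) in any sequence are removed before distances
#' are computed (complete deletion), then distances are taken with
#' [ape::dist.dna()]:
#' \describe{
#'   \item{p}{proportion of mismatching sites}
#'   \item{JC69}{-(3/4) log(1 - 4p/3)}
#'   \item{K2P}{Kimura two-parameter, from transition and transversion
#'     proportions}
#' }
#'
#' @param alignment Named character vector of equal-length sequences, or an
#'   `ape` `DNAbin` matrix.
#' @param model One of `"p"`, `"JC69"`, `"K2P"`.
#' @return Symmetric distance matrix with sequence names as dimnames.
#' @export
sequence_distance <- function(alignment, model = c("p", "JC69", "K2P")) {
  model <- match.arg(model)
  if (inherits(alignment, "DNAbin")) {
    aln <- alignment
    if (!is.matrix(aln)) aln <- as.matrix(aln)
    chr <- toupper(apply(as.character(aln), 1, paste, collapse = ""))
  } else {
    stopifnot(is.character(alignment))
    if (is.null(names(alignment)) || anyDuplicated(names(alignment))) {
      abort("alignment must have unique sequence names")
    }
    if (length(unique(nchar(alignment))) != 1) {
      abort("sequences must be aligned to equal length")
    }
    chr <- toupper(alignment)
  }
  if (length(chr) < 2) abort("need at least 2 sequences")
  m <- do.call(rbind, strsplit(chr, ""))
  rownames(m) <- names(chr)
  keep <- apply(m, 2, function(col) all(col %in% c("A", "C", "G", "T")))
  if (!any(keep)) abort("no shared unambiguous sites after complete deletion")
  m <- m[, keep, drop = FALSE]
  bin <- ape::as.DNAbin(m)
  amod <- c(p = "raw", JC69 = "JC69", K2P = "K80")[[model]]
  d <- as.matrix(ape::dist.dna(bin, model = amod, pairwise.deletion = FALSE))
  if (anyNA(d) || any(!is.finite(d))) {
    bad <- which(!is.finite(d) | is.na(d), arr.ind = TRUE)
    bad <- bad[bad[, 1] < bad[, 2], , drop = FALSE]
    pairs <- apply(bad, 1, function(ij) {
      paste(rownames(d)[ij[1]], rownames(d)[ij[2]], sep = " vs ")
    })
    abort(paste0("distance undefined under ", model, " (log of non-positive ",
                 "argument) for: ", paste(pairs, collapse = "; ")))
  }
  d
}
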