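#' Construct a clade-rule set
#'
#' Encodes the bookkeeping applied before divergence is averaged: splitting
#' a paraphyletic species into independent monophyletic clades by locality,
#' excluding suspected hybrid samples, excluding whole clades, and the
#' minimum-locality rule (clades sampled at fewer than `min_localities`
#' distinct localities are excluded, since an average over locality pairs is
#' not meaningful for a range represented by one or two points).
#'
#' @param splits Named list: species/clade id -> named list of new clade id
#'   -> character vector of locality ids.
#' @param exclude_samples Character vector of sample ids to drop, or a named
#'   character vector whose names are sample ids and values are reasons.
#' @param exclude_clades Character vector of clade ids to drop (named vector
#'   for reasons, as above).
#' @param min_localities Minimum distinct localities for a clade to be
#'   retained (default 3).
#' @return A `clade_rules` list.
#' @export
clade_rules <- function(splits = list(), exclude_samples = character(),
                        exclude_clades = character(), min_localities = 3) {
  stopifnot(is.list(splits), min_localities >= 1)
  structure(list(splits = splits,
                 exclude_samples = exclude_samples,
                 exclude_clades = exclude_clades,
                 min_localities = min_localities),
            class = "clade_rules")
}

reason_vec <- function(x, default) {
  if (is.null(names(x)) || all(names(x) == "")) {
    setNames(rep(default, length(x)), as.character(x))
  } else {
    setNames(ifelse(nzchar(x), x, default), names(x))
  }
}

#' Apply clade rules to a sample map
#'
#' @param sample_map Data frame with columns `sample`, `clade`, `locality`
#'   (and optionally `excluded`, `reason`).
#' @param rules A [clade_rules()] object.
#' @return Tibble with columns `sample`, `clade`, `locality`, `excluded`
#'   (logical), `reason`. Splits are applied first, then sample/clade
#'   exclusions; finally any clade left with fewer than `min_localities`
#'   distinct non-excluded localities has all its samples flagged with
#'   reason `"min-localities"`.
#' @export
apply_clade_rules <- function(sample_map, rules = clade_rules()) {
  stopifnot(is.data.frame(sample_map), inherits(rules, "clade_rules"))
  need <- c("sample", "clade", "locality")
  if (!all(need %in% names(sample_map))) {
    abort(paste("sample map must have columns:", paste(need, collapse = ", ")))
  }
  map <- tibble::as_tibble(sample_map) |>
    dplyr::mutate(dplyr::across(dplyr::all_of(need), as.character))
  if (any(!nzchar(map$clade)) || any(!nzchar(map$locality))) {
    abort("clade and locality ids must be non-empty")
  }
  if (!"excluded" %in% names(map)) map$excluded <- FALSE
  if (!"reason" %in% names(map)) map$reason <- NA_character_

  for (sp in names(rules$splits)) {
    if (!sp %in% map$clade) {
      abort(paste("split rule references unknown species/clade:", sp))
    }
    spec_loc <- unlist(rules$splits[[sp]], use.names = FALSE)
    known <- map$locality[map$clade == sp]
    bad <- setdiff(spec_loc, known)
    if (length(bad)) {
      abort(paste0("split for '", sp, "' references unknown localities: ",
                   paste(bad, collapse = ", ")))
    }
    for (new_id in names(rules$splits[[sp]])) {
      locs <- rules$splits[[sp]][[new_id]]
      map$clade[map$clade == sp & map$locality %in% locs] <- new_id
    }
  }

  ex_s <- reason_vec(rules$exclude_samples, "excluded-sample")
  hit <- map$sample %in% names(ex_s)
  map$excluded[hit] <- TRUE
  map$reason[hit] <- unname(ex_s[map$sample[hit]])

  ex_c <- reason_vec(rules$exclude_clades, "excluded-clade")
  hit <- map$clade %in% names(ex_c) & !map$excluded
  map$excluded[hit] <- TRUE
  map$reason[hit] <- unname(ex_c[map$clade[hit]])

  n_loc <- map |>
    dplyr::filter(!.data$excluded) |>
    dplyr::group_by(.data$clade) |>
    dplyr::summarise(n = dplyr::n_distinct(.data$locality), .groups = "drop")
  thin <- n_loc$clade[n_loc$n < rules$min_localities]
  hit <- map$clade %in% thin & !map$excluded
  map$excluded[hit] <- TRUE
  map$reason[hit] <- "min-localities"
  map
}

#' Retained clades of a processed sample map
#' @param sample_map Output of [apply_clade_rules()].
#' @return Character vector of clade ids with at least one retained sample.
#' @export
retained_clades <- function(sample_map) {
  sort(unique(sample_map$clade[!sample_map$excluded]))
}
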