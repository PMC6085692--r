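#' Backward stepwise PGLS model reduction by likelihood-ratio tests
#'
#' Starting from the full model, repeatedly refits without each droppable
#' term, computes the likelihood-ratio test against the current model, and
#' removes the droppable term with the largest p-value above `alpha`;
#' iteration stops when every droppable term is significant. Interactions
#' are considered before their main effects: a main effect is droppable
#' only while no retained interaction contains it.
#'
#' A final pruning step then applies the rule that a main effect kept only
#' because it takes part in a retained interaction stays in the final model
#' only if it was itself significant (sequential F) in the full model;
#' otherwise it is removed even though the interaction is retained.
#'
#' @inheritParams pgls_fit
#' @param alpha Significance level for retention (default 0.05).
#' @return List with `final` (the final `pgls_fit`), `full` (the full-model
#'   fit) and `trace`, a tibble of one row per elimination: step, term,
#'   statistic, df, p.value, action.
#' @export
backward_stepwise <- function(data, formula, cov = NULL, alpha = 0.05,
                              clade_col = "clade") {
  stopifnot(alpha > 0, alpha < 1)
  full_fit <- pgls_fit(data, formula, cov, clade_col)
  response <- all.vars(formula)[1]
  cur <- full_fit
  trace <- list()
  step <- 0L

  repeat {
    labels <- cur$term_labels
    if (!length(labels)) break
    ord <- attr(terms(cur$formula), "order")
    dropp <- vapply(seq_along(labels), function(i) {
      if (ord[i] > 1) return(TRUE)  # interactions always droppable
      v <- labels[i]
      inters <- labels[ord > 1]
      !any(vapply(inters, function(tm) v %in% strsplit(tm, ":", fixed = TRUE)[[1]],
                  logical(1)))
    }, logical(1))
    if (!any(dropp)) break
    cand <- labels[dropp]
    tests <- purrr::map_dfr(cand, function(tm) {
      red_labels <- setdiff(labels, tm)
      red_formula <- if (length(red_labels)) {
        stats::reformulate(red_labels, response)
      } else {
        stats::as.formula(paste(response, "~ 1"))
      }
      red <- pgls_fit(data, red_formula, cov, clade_col)
      dplyr::mutate(lrt(cur, red), term = tm)
    })
    worst <- tests[which.max(tests$p.value), ]
    if (worst$p.value <= alpha) break
    step <- step + 1L
    trace[[step]] <- tibble::tibble(step = step, term = worst$term,
                                    statistic = worst$statistic, df = worst$df,
                                    p.value = worst$p.value, action = "dropped")
    new_labels <- setdiff(labels, worst$term)
    new_formula <- if (length(new_labels)) {
      stats::reformulate(new_labels, response)
    } else {
      stats::as.formula(paste(response, "~ 1"))
    }
    cur <- pgls_fit(data, new_formula, cov, clade_col)
  }

  # paper-style pruning: a main effect retained only through an interaction
  # must have been significant in the FULL model to stay
  labels <- cur$term_labels
  ord <- attr(terms(cur$formula), "order")
  inters <- labels[ord > 1]
  if (length(inters)) {
    protected <- unique(unlist(strsplit(inters, ":", fixed = TRUE)))
    full_p <- setNames(full_fit$anova$p.value, full_fit$anova$term)
    for (v in intersect(protected, labels[ord == 1])) {
      pv <- full_p[[v]]
      if (!is.null(pv) && pv > alpha) {
        step <- step + 1L
        trace[[step]] <- tibble::tibble(step = step, term = v,
                                        statistic = NA_real_, df = NA_integer_,
                                        p.value = pv,
                                        action = "dropped-nonsignificant-in-full")
        labels <- setdiff(labels, v)
      }
    }
    if (!identical(labels, cur$term_labels)) {
      new_formula <- if (length(labels)) {
        stats::reformulate(labels, response)
      } else {
        stats::as.formula(paste(response, "~ 1"))
      }
      cur <- pgls_fit(data, new_formula, cov, clade_col)
    }
  }

  list(final = cur, full = full_fit,
       trace = if (length(trace)) dplyr::bind_rows(trace) else
         tibble::tibble(step = integer(), term = character(),
                        statistic = numeric(), df = integer(),
                        p.value = numeric(), action = character()))
}
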