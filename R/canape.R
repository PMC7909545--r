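#' CANAPE classification of endemism centres
#'
#' Classifies every cell of a null-model result into one of
#' `not_significant`, `neo`, `paleo`, `mixed`, `super`:
#'
#' 1. A cell is a *candidate* endemism centre iff PE on the observed tree
#'    or PE on the comparison tree is significantly high
#'    (`p_high < alpha_primary`); all other cells are `not_significant`.
#' 2. Among candidates, a significantly high RPE tail
#'    (`p_high(RPE) < alpha_rpe_tail`) marks *paleo*-endemism (restricted
#'    long branches), a significantly low tail *neo*-endemism (restricted
#'    short branches); the rest are *mixed*.
#' 3. Mixed cells whose PE is significant on both trees at the stricter
#'    `alpha_super` are promoted to *super*-endemism centres.
#'
#' @param null A [null_pvalues()] result containing `PE_obs`, `PE_alt`
#'   and `RPE`.
#' @param alpha_primary Candidate threshold (default 0.05).
#' @param alpha_rpe_tail Per-tail RPE threshold (default 0.025, i.e. a
#'   two-tailed 0.05 test).
#' @param alpha_super Strict threshold for super-endemism (default 0.01).
#' @return A `canape_classification`: tibble with columns `cell`,
#'   `category` (factor), `candidate` (logical), plus the thresholds as
#'   attributes.
#' @export
classify_cells <- function(null, alpha_primary = 0.05,
                           alpha_rpe_tail = 0.025, alpha_super = 0.01) {
  stopifnot(inherits(null, "null_result"))
  need <- c("PE_obs", "PE_alt", "RPE")
  miss <- setdiff(need, colnames(null$p_high))
  if (length(miss))
    stop("null result lacks required metrics: ",
         paste(miss, collapse = ", "), call. = FALSE)

  ph_obs <- null$p_high[, "PE_obs"]
  ph_alt <- null$p_high[, "PE_alt"]
  ph_rpe <- null$p_high[, "RPE"]
  pl_rpe <- null$p_low[, "RPE"]

  cand <- ph_obs < alpha_primary | ph_alt < alpha_primary
  cat <- rep("not_significant", length(cand))
  cat[cand & ph_rpe < alpha_rpe_tail] <- "paleo"
  cat[cand & pl_rpe < alpha_rpe_tail & cat == "not_significant"] <- "neo"
  cat[cand & cat == "not_significant"] <- "mixed"
  super <- cat == "mixed" & ph_obs < alpha_super & ph_alt < alpha_super
  cat[super] <- "super"

  out <- tibble::tibble(
    cell = null$cell_id,
    category = factor(cat, levels = c("not_significant", "neo", "paleo",
                                      "mixed", "super")),
    candidate = cand
  )
  structure(out, class = c("canape_classification", class(out)),
            alpha_primary = alpha_primary, alpha_rpe_tail = alpha_rpe_tail,
            alpha_super = alpha_super)
}

#' Category counts of a CANAPE classification
#'
#' @param x A `canape_classification`.
#' @param ... Unused.
#' @return A one-row tibble of per-category counts plus `candidates`.
#' @method glance canape_classification
#' @export
glance.canape_classification <- function(x, ...) {
  tb <- table(x$category)
  out <- tibble::as_tibble(as.list(tb))
  out$candidates <- sum(x$candidate)
  out
}
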