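# Percentages and the wild-type complement.
#
# percentage = 100 * hits / denominator. The default denominator is the
# informative count: fragments covering every variant position of the row
# (jointly, unmasked). The alternative `sum_positions` mode divides by the
# sum of per-variant coverages instead -- a literal reading of
# hits / sum_i coverage(variant_i) -- which shrinks multi-variant
# percentages with the number of variants; both are exposed because the
# two disagree exactly when clones span several variants.

#' Attach percentages to a haplotype table
#'
#' @param table `HaplotypeTable` from [tabulate_haplotypes()] or
#'   [infer_scattered()].
#' @param fragments the fragment list the table was built from; required
#'   for `denominator_mode = "sum_positions"`.
#' @param denominator_mode `"informative"` (default) or `"sum_positions"`.
#' @return the table with `rows$percentage` and `wildtype_percentage`
#'   filled in. Rows with a zero denominator get 0% and a warning. The sum
#'   of percentages may exceed 100 when rows have different denominators;
#'   this is reported via a message, never an error.
#' @export
quantify_table <- function(table, fragments = NULL,
                           denominator_mode = c("informative",
                                                "sum_positions")) {
  denominator_mode <- match.arg(denominator_mode)
  rows <- table$rows
  if (nrow(rows) == 0L) {
    table$wildtype_percentage <- 100
    return(table)
  }
  if (denominator_mode == "informative") {
    denom <- rows$informative
  } else {
    if (is.null(fragments))
      stop("sum_positions mode needs the fragment list")
    geom <- fragment_geometry(fragments)
    cov1 <- vapply(table$selected, function(k)
      count_covering(geom, variant_positions(k)), 0)
    names(cov1) <- table$selected
    denom <- vapply(rows$id, function(id)
      sum(cov1[haplotype_members(id)]), 0, USE.NAMES = FALSE)
  }
  if (any(denom == 0L & rows$hits > 0L))
    warning(sum(denom == 0L & rows$hits > 0L),
            " haplotype row(s) have a zero denominator; percentage set to 0")
  rows$percentage <- ifelse(denom > 0, 100 * rows$hits / denom, 0)
  table$rows <- rows
  table$wildtype_percentage <- wildtype_estimate(rows$percentage)
  if (sum(rows$percentage) > 100 + 1e-9)
    message(sprintf(
      "haplotype percentages sum to %.1f%% (>100%%): rows use different %s",
      sum(rows$percentage), "denominators; wild type clamped to 0"))
  table
}

#' Wild-type percentage estimate
#'
#' The wild type is whatever carries none of the selected variants; it is
#' estimated as the complement of the detected clones, clamped at zero.
#'
#' @param percentages numeric vector of clone percentages (0-100).
#' @return `max(0, 100 - sum(percentages))`.
#' @export
wildtype_estimate <- function(percentages) {
  max(0, 100 - sum(percentages))
}
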