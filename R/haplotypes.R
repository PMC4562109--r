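# Fragment assembly and exact haplotype tabulation.
#
# The counting unit is the fragment: a single read, or a forward/reverse
# mate pair merged into one observation of one DNA molecule. Each fragment
# is counted exactly once. Ambiguous evidence in a mate-pair overlap (one
# mate calls a variant, the other reads reference there) is not counted as
# a variant -- by definition one of the two is a sequencing error -- and the
# position is masked for that fragment.

new_fragment <- function(fragment_key, cov, masked, variants) {
  structure(list(fragment_key = fragment_key, cov = cov,
                 masked = masked, variants = variants),
            class = "Fragment")
}

#' Merge read observations into fragments
#'
#' Observations are grouped by query name. In paired mode the two mates of
#' a fragment are merged: coverage is the union; a variant present on both
#' mates is kept once; a variant present on one mate but contradicted by
#' reference-matching, unmasked coverage of its positions on the other mate
#' is dropped and its positions are masked; a variant opposite an N (masked)
#' base is kept. In unpaired mode each observation becomes one fragment.
#'
#' @param observations list of `ReadObservation`.
#' @param paired logical.
#' @return list of `Fragment` (one per query name).
#' @export
assemble_fragments <- function(observations, paired = FALSE) {
  if (!paired) {
    return(lapply(observations, function(o)
      new_fragment(o$fragment_key, o$cov, o$masked, o$variants)))
  }
  keys <- vapply(observations, `[[`, "", "fragment_key")
  groups <- split(seq_along(observations), factor(keys, levels = unique(keys)))
  unname(lapply(groups, function(idx) {
    if (length(idx) > 2L)
      stop("more than two alignments share query name '",
           observations[[idx[1L]]]$fragment_key, "'")
    if (length(idx) == 1L) {
      o <- observations[[idx]]
      return(new_fragment(o$fragment_key, o$cov, o$masked, o$variants))
    }
    merge_mates(observations[[idx[1L]]], observations[[idx[2L]]])
  }))
}

merge_mates <- function(a, b) {
  cov <- merge_intervals(rbind(a$cov, b$cov))
  masked <- sort(unique(c(a$masked, b$masked)))
  variants <- character(0)
  for (key in unique(c(a$variants, b$variants))) {
    pos <- variant_positions(key)
    on_a <- key %in% a$variants
    on_b <- key %in% b$variants
    other <- if (on_a && !on_b) b else if (on_b && !on_a) a else NULL
    if (is.null(other)) {            # on both mates: keep once
      variants <- c(variants, key)
      next
    }
    # contradiction: the other mate covers the variant's positions with
    # confident (unmasked) reference-matching bases and no such variant
    if (covers_all(other$cov, other$masked, pos)) {
      masked <- sort(unique(c(masked, pos)))
    } else {
      variants <- c(variants, key)
    }
  }
  # a position that still backs a kept variant cannot stay masked
  vpos <- unlist(lapply(variants, variant_positions))
  masked <- setdiff(masked, vpos)
  new_fragment(a$fragment_key, cov, masked, variants)
}

# does the fragment cover all positions of variant `key`, unmasked?
fragment_covers_variant <- function(fragment, key) {
  covers_all(fragment$cov, fragment$masked, variant_positions(key))
}

# Precomputed coverage geometry for a fragment list. Fragments whose
# coverage is one interval without masked positions (the overwhelming
# majority) are handled vectorised; the rest fall back to covers_all().
fragment_geometry <- function(fragments) {
  simple <- vapply(fragments, function(f)
    nrow(f$cov) == 1L && length(f$masked) == 0L, FALSE)
  list(simple = simple,
       s_start = vapply(fragments[simple], function(f) f$cov[1L, 1L],
                        numeric(1)),
       s_end = vapply(fragments[simple], function(f) f$cov[1L, 2L],
                      numeric(1)),
       complex_frags = fragments[!simple])
}

# number of fragments covering all positions in `pos` unmasked
count_covering <- function(geom, pos) {
  lo <- min(pos); hi <- max(pos)
  n <- sum(geom$s_start <= lo & geom$s_end > hi)
  if (length(geom$complex_frags))
    n <- n + sum(vapply(geom$complex_frags, function(f)
      covers_all(f$cov, f$masked, pos), FALSE))
  n
}

# logical over fragments: covers all of pos unmasked (order: simple then
# complex, matching fragment_geometry's partition)
which_covering <- function(geom, pos) {
  lo <- min(pos); hi <- max(pos)
  c(geom$s_start <= lo & geom$s_end > hi,
    vapply(geom$complex_frags, function(f)
      covers_all(f$cov, f$masked, pos), FALSE))
}

#' Per-variant detection summary
#'
#' @param fragments list of `Fragment`.
#' @return data.frame with one row per distinct variant: `key`,
#'   `supporting` (fragments carrying it), `covering` (fragments covering
#'   all its positions unmasked) and `frequency = supporting / covering`.
#' @export
detect_variant_table <- function(fragments) {
  keys <- sort_variant_keys(unique(unlist(lapply(fragments, `[[`,
                                                 "variants"))))
  if (length(keys) == 0L)
    return(data.frame(key = character(0), supporting = integer(0),
                      covering = integer(0), frequency = numeric(0),
                      stringsAsFactors = FALSE))
  support_tab <- table(unlist(lapply(fragments, function(f)
    unique(f$variants))))
  geom <- fragment_geometry(fragments)
  covering <- vapply(keys, function(k)
    count_covering(geom, variant_positions(k)), 0)
  supporting <- as.integer(support_tab[keys])
  supporting[is.na(supporting)] <- 0L
  data.frame(key = keys, supporting = supporting,
             covering = as.integer(covering),
             frequency = supporting / pmax(1, covering),
             stringsAsFactors = FALSE)
}

#' Tabulate exact haplotype counts
#'
#' Each fragment is reduced to its key set: its variants intersected with
#' the selection (a fragment covering only part of a multi-variant clone
#' contributes to the partial haplotype it actually shows). Fragments with
#' identical non-empty key sets form one row with `hits = group size`;
#' `informative` counts the fragments -- carriers or not -- that cover all
#' of the row's variant positions unmasked. Fragments with empty key sets
#' contribute to no row; those covering at least one selected variant
#' position count as wild type, the rest as uncovered. Exactly:
#' `sum(hits) + n_wildtype + n_uncovered = n_fragments`.
#'
#' @param fragments list of `Fragment`.
#' @param selected character vector of canonical variant keys; defaults to
#'   every detected variant.
#' @return object of class `HaplotypeTable` with fields `rows` (`id`,
#'   `hits`, `informative`, `percentage`, `inferred`), `selected`,
#'   `mode = "default"`, `n_fragments`, `n_wildtype`, `n_uncovered`.
#' @export
tabulate_haplotypes <- function(fragments, selected = NULL) {
  if (is.null(selected) || length(selected) == 0L)
    selected <- detect_variant_table(fragments)$key
  selected <- sort_variant_keys(unique(selected))
  ids <- vapply(fragments, function(f)
    haplotype_id(intersect(f$variants, selected)), "")
  nonempty <- nzchar(ids)
  geom <- fragment_geometry(fragments)
  # empty key set: wild type if the fragment confidently covers at least
  # one selected variant, otherwise uninformative
  n_wt <- 0L; n_uncov <- 0L
  if (any(!nonempty)) {
    covers_any <- rep(FALSE, length(fragments))
    geom_order <- c(which(geom$simple), which(!geom$simple))
    for (k in selected) {
      cov_k <- which_covering(geom, variant_positions(k))
      covers_any[geom_order] <- covers_any[geom_order] | cov_k
    }
    n_wt <- sum(!nonempty & covers_any)
    n_uncov <- sum(!nonempty & !covers_any)
  }
  tab <- table(ids[nonempty])
  row_ids <- if (is.null(names(tab))) character(0) else names(tab)
  informative <- vapply(row_ids, function(id) {
    pos <- sort(unique(unlist(lapply(haplotype_members(id),
                                     variant_positions))))
    count_covering(geom, pos)
  }, 0, USE.NAMES = FALSE)
  rows <- data.frame(id = row_ids, hits = as.integer(tab),
                     informative = as.integer(informative),
                     percentage = rep(NA_real_, length(row_ids)),
                     inferred = rep(FALSE, length(row_ids)),
                     stringsAsFactors = FALSE)
  rows <- rows[order(-rows$hits, rows$id), , drop = FALSE]
  rownames(rows) <- NULL
  structure(list(rows = rows, selected = selected, mode = "default",
                 wildtype_percentage = NA_real_,
                 n_fragments = length(fragments),
                 n_wildtype = n_wt, n_uncovered = n_uncov),
            class = "HaplotypeTable")
}

#' @export
print.HaplotypeTable <- function(x, ...) {
  cat(sprintf("<HaplotypeTable> mode=%s, %d rows, %d fragments\n",
              x$mode, nrow(x$rows), x$n_fragments))
  print(x$rows, ...)
  if (!is.na(x$wildtype_percentage))
    cat(sprintf("wild type: %.1f%%\n", x$wildtype_percentage))
  invisible(x)
}
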