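# Reconnecting haplotypes scattered over overlapping amplicons.
#
# When the amplicon design tiles a region longer than the read length, one
# clone's variants end up on different fragment types and the default
# tabulation only ever sees partial haplotypes. The inference builds a
# symmetric, unweighted graph -- nodes are selected variants, an edge means
# co-occurrence on at least one fragment -- and repeatedly extracts the
# maximum clique: the clique defines a new haplotype, its fragment counts
# are recalculated and deducted from the pool, exhausted entries and edges
# disappear, and the next largest clique is searched. The search is exact
# (the clique problem is NP-complete, tractable at the enforced caps of 15
# rounds and 20 variants). Clique-derived rows are flagged `inferred`:
# a connection can be deduced that is never seen on a single read.

# index of the amplicon a fragment belongs to: maximal covered overlap,
# ties to the first amplicon in design order
assign_fragment_amplicon <- function(fragment, design) {
  overlaps <- vapply(design$amplicons, function(a) {
    sum(vapply(seq_len(nrow(a$segments)), function(i) {
      s <- a$segments$start[i]; e <- a$segments$end[i]
      sum(pmax(0, pmin(fragment$cov[, 2L], e) -
                   pmax(fragment$cov[, 1L], s)))
    }, 0))
  }, 0)
  which.max(overlaps)
}

# pool of per-amplicon haplotype observations:
#   entries: data.frame(amp, id, count), non-empty ids only
#   amp_totals: all fragments per amplicon (wild type included)
build_pool <- function(fragments, selected, design) {
  amp <- vapply(fragments, assign_fragment_amplicon, 0L, design = design)
  ids <- vapply(fragments, function(f)
    haplotype_id(intersect(f$variants, selected)), "")
  amp_totals <- tabulate(amp, nbins = length(design$amplicons))
  keep <- nzchar(ids)
  if (!any(keep)) {
    entries <- data.frame(amp = integer(0), id = character(0),
                          count = integer(0), stringsAsFactors = FALSE)
  } else {
    tab <- table(amp = amp[keep], id = ids[keep])
    entries <- as.data.frame(tab, stringsAsFactors = FALSE)
    entries <- entries[entries$Freq > 0L, ]
    entries <- data.frame(amp = as.integer(entries$amp), id = entries$id,
                          count = as.integer(entries$Freq),
                          stringsAsFactors = FALSE)
  }
  list(entries = entries, amp_totals = amp_totals)
}

#' Build the variant co-occurrence graph
#'
#' @param fragments list of `Fragment`.
#' @param selected canonical variant keys (at most `max_variants`).
#' @param design optional `AmpliconDesign` used to pool fragments per
#'   amplicon; without one, all fragments form a single pool.
#' @param max_variants refusal cap on the number of selected variants.
#' @return object of class `VariantGraph`: `nodes` (variants with at least
#'   one supporting fragment), `edges` (data.frame `a`, `b`, `support`),
#'   and the fragment `pool`.
#' @export
build_cooccurrence_graph <- function(fragments, selected, design = NULL,
                                     max_variants = 20L) {
  selected <- sort_variant_keys(unique(selected))
  if (length(selected) > max_variants)
    stop("inference is limited to ", max_variants, " variants (",
         length(selected), " selected)")
  if (is.null(design)) {
    span <- range(unlist(lapply(fragments, function(f) f$cov)))
    design <- new_amplicon_design(data.frame(start = span[1L],
                                             end = span[2L], label = "all"))
  }
  pool <- build_pool(fragments, selected, design)
  graph_from_pool(pool, selected)
}

graph_from_pool <- function(pool, selected) {
  entries <- pool$entries[pool$entries$count > 0L, , drop = FALSE]
  members <- lapply(entries$id, haplotype_members)
  nodes <- sort_variant_keys(intersect(selected,
                                       unique(unlist(members))))
  edge_env <- new.env(parent = emptyenv())
  for (i in seq_along(members)) {
    m <- members[[i]]
    if (length(m) < 2L) next
    prs <- utils::combn(sort_variant_keys(m), 2L)
    for (j in seq_len(ncol(prs))) {
      ek <- paste(prs[1L, j], prs[2L, j], sep = "\r")
      edge_env[[ek]] <- (if (is.null(edge_env[[ek]])) 0L else edge_env[[ek]]) +
        entries$count[i]
    }
  }
  eks <- ls(edge_env)
  if (length(eks)) {
    ab <- do.call(rbind, strsplit(eks, "\r", fixed = TRUE))
    edges <- data.frame(a = ab[, 1L], b = ab[, 2L],
                        support = vapply(eks, function(k) edge_env[[k]], 0L),
                        stringsAsFactors = FALSE)
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(a = character(0), b = character(0),
                        support = integer(0), stringsAsFactors = FALSE)
  }
  structure(list(nodes = nodes, edges = edges, pool = pool),
            class = "VariantGraph")
}

#' Exact maximum clique with deterministic tie-breaking
#'
#' Finds a maximum clique of the co-occurrence graph (exact search via
#' branch and bound). Among equally large cliques the one with the larger
#' total supporting fragment count (sum of its edge supports) wins; further
#' ties go to the lexicographically smallest sorted position tuple.
#'
#' @param graph `VariantGraph`.
#' @return character vector of variant keys (empty for an empty graph).
#' @export
maximum_clique <- function(graph) {
  if (length(graph$nodes) == 0L) return(character(0))
  if (nrow(graph$edges) == 0L) {
    # edgeless: every node is a maximum clique of size 1
    return(graph$nodes[1L])
  }
  g <- igraph::graph_from_data_frame(graph$edges[, c("a", "b")],
                                     directed = FALSE,
                                     vertices = data.frame(name = graph$nodes))
  cliques <- igraph::largest_cliques(g)
  cand <- lapply(cliques, function(cl)
    sort_variant_keys(igraph::V(g)$name[as.integer(cl)]))
  if (length(cand) == 1L) return(cand[[1L]])
  support <- vapply(cand, function(cl) clique_support(graph, cl), 0)
  cand <- cand[support == max(support)]
  if (length(cand) == 1L) return(cand[[1L]])
  # lexicographically smallest sorted position tuple
  tuples <- lapply(cand, variant_start)
  best <- 1L
  for (i in seq_along(cand)[-1L])
    if (tuple_less(tuples[[i]], tuples[[best]])) best <- i
  cand[[best]]
}

clique_support <- function(graph, members) {
  e <- graph$edges
  sum(e$support[e$a %in% members & e$b %in% members])
}

tuple_less <- function(x, y) {
  n <- min(length(x), length(y))
  for (i in seq_len(n)) {
    if (x[i] < y[i]) return(TRUE)
    if (x[i] > y[i]) return(FALSE)
  }
  length(x) < length(y)
}

# variants of clique C whose positions fall entirely inside amplicon `a`
restrict_to_amplicon <- function(members, amp_positions) {
  members[vapply(members, function(k)
    all(variant_positions(k) %in% amp_positions), FALSE)]
}

#' Reconnect haplotypes scattered over overlapping amplicons
#'
#' Iterates (at most `max_rounds` times): build the co-occurrence graph
#' from the remaining pool, find the maximum clique C, stop if it has one
#' node or less; compute C's clone-unit count as the bottleneck -- the
#' minimum over C-covering amplicons of the remaining count of entries
#' exactly consistent with C (an entry is consistent when its variant set
#' equals C restricted to what its amplicon covers; a fragment covering a
#' C position without C's variant cannot come from clone C); emit the row,
#' deduct the count from the consistent entries, prune exhausted entries,
#' repeat. A round whose count is 0 terminates the loop. Remaining
#' haplotypes still in the pool are emitted afterwards as directly observed
#' rows with their bottleneck counts.
#'
#' Counts in the returned table are clone units, not fragments: each clone
#' unit contributes one fragment per amplicon, so the denominator
#' (`informative`) is `floor(total fragments / number of amplicons)`.
#'
#' @param fragments list of `Fragment`.
#' @param selected canonical variant keys (at most `max_variants`).
#' @param design `AmpliconDesign`; required.
#' @param max_rounds clique rounds cap (default 15).
#' @param max_variants selected-variant cap (default 20).
#' @return `HaplotypeTable` with `mode = "inferred"`; clique-derived rows
#'   have `inferred = TRUE`.
#' @export
infer_scattered <- function(fragments, selected, design,
                            max_rounds = 15L, max_variants = 20L) {
  if (is.null(design) || !inherits(design, "AmpliconDesign"))
    stop("inference requires an amplicon design")
  selected <- sort_variant_keys(unique(selected))
  if (length(selected) > max_variants)
    stop("inference is limited to ", max_variants, " variants (",
         length(selected), " selected)")
  amp_pos <- lapply(design$amplicons, amplicon_positions)
  pool <- build_pool(fragments, selected, design)
  rows <- list()
  for (round in seq_len(max_rounds)) {
    graph <- graph_from_pool(pool, selected)
    clique <- maximum_clique(graph)
    if (length(clique) <= 1L) break
    amps <- which(vapply(amp_pos, function(p)
      length(restrict_to_amplicon(clique, p)) > 0L, FALSE))
    counts <- vapply(amps, function(a) {
      want <- haplotype_id(restrict_to_amplicon(clique, amp_pos[[a]]))
      sum(pool$entries$count[pool$entries$amp == a &
                               pool$entries$id == want])
    }, 0L)
    n <- min(counts)
    if (n <= 0L) {
      warning("maximum clique {",
              paste(vapply(clique, function(k)
                parse_variant_key(k)$start + 1L, 0L), collapse = ","),
              "} has no consistent fragment support; stopping inference")
      break
    }
    rows[[length(rows) + 1L]] <- list(id = haplotype_id(clique),
                                      hits = n, inferred = TRUE)
    for (a in amps) {
      want <- haplotype_id(restrict_to_amplicon(clique, amp_pos[[a]]))
      hit <- which(pool$entries$amp == a & pool$entries$id == want)
      hit <- hit[order(-pool$entries$count[hit])]
      left <- n
      for (h in hit) {
        take <- min(left, pool$entries$count[h])
        pool$entries$count[h] <- pool$entries$count[h] - take
        left <- left - take
        if (left == 0L) break
      }
    }
    pool$entries <- pool$entries[pool$entries$count > 0L, , drop = FALSE]
  }
  # residual directly observed haplotypes: bottleneck over the amplicons
  # that fully cover them
  residual <- pool$entries[pool$entries$count > 0L, , drop = FALSE]
  emitted <- vapply(rows, `[[`, "", "id")
  for (id in setdiff(unique(residual$id), emitted)) {
    members <- haplotype_members(id)
    amps <- which(vapply(amp_pos, function(p)
      all(unlist(lapply(members, variant_positions)) %in% p), FALSE))
    if (length(amps) == 0L) amps <- unique(residual$amp[residual$id == id])
    cnt <- min(vapply(amps, function(a)
      sum(residual$count[residual$amp == a & residual$id == id]), 0L))
    if (cnt > 0L)
      rows[[length(rows) + 1L]] <- list(id = id, hits = cnt, inferred = FALSE)
  }
  units <- max(1L, sum(pool$amp_totals) %/% length(design$amplicons))
  df <- if (length(rows)) {
    d <- data.frame(id = vapply(rows, `[[`, "", "id"),
                    hits = vapply(rows, function(r) as.integer(r$hits), 0L),
                    informative = units, percentage = NA_real_,
                    inferred = vapply(rows, `[[`, FALSE, "inferred"),
                    stringsAsFactors = FALSE)
    # a clique can be emitted in several rounds until an amplicon runs dry
    do.call(rbind, lapply(split(d, d$id), function(g)
      data.frame(id = g$id[1L], hits = sum(g$hits),
                 informative = g$informative[1L], percentage = NA_real_,
                 inferred = any(g$inferred), stringsAsFactors = FALSE)))
  } else {
    data.frame(id = character(0), hits = integer(0),
               informative = integer(0), percentage = numeric(0),
               inferred = logical(0), stringsAsFactors = FALSE)
  }
  df <- df[order(-df$hits, df$id), , drop = FALSE]
  rownames(df) <- NULL
  structure(list(rows = df, selected = selected, mode = "inferred",
                 wildtype_percentage = NA_real_,
                 n_fragments = length(fragments),
                 n_wildtype = NA_integer_, n_uncovered = NA_integer_,
                 clone_units = units),
            class = "HaplotypeTable")
}
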