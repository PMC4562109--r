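# Independent oracles. These deliberately take the dumb, exhaustive route
# and never share code with the implementation paths they check.

# --- padded-matrix variant oracle -----------------------------------------
# Rebuild the gapped alignment (two parallel character rows) from the
# operation list, then call variants column by column.
oracle_read_variants <- function(read, reference) {
  refc <- strsplit(reference$sequence, "", fixed = TRUE)[[1L]]
  qc <- strsplit(read$seq, "", fixed = TRUE)[[1L]]
  top <- character(0); bot <- character(0); rpos <- integer(0)
  r <- read$ref_start; q <- 0L
  for (k in seq_along(read$ops$op)) {
    op <- read$ops$op[k]; len <- read$ops$len[k]
    if (op %in% c("M", "=", "X")) {
      top <- c(top, refc[(r + 1L):(r + len)])
      bot <- c(bot, qc[(q + 1L):(q + len)])
      rpos <- c(rpos, r:(r + len - 1L))
      r <- r + len; q <- q + len
    } else if (op == "I") {
      top <- c(top, rep("-", len))
      bot <- c(bot, qc[(q + 1L):(q + len)])
      rpos <- c(rpos, rep(r, len))
      q <- q + len
    } else if (op %in% c("D", "N")) {
      top <- c(top, refc[(r + 1L):(r + len)])
      bot <- c(bot, rep(if (op == "D") "-" else ".", len))
      rpos <- c(rpos, r:(r + len - 1L))
      r <- r + len
    } else if (op == "S") {
      q <- q + len
    }
  }
  variants <- character(0)
  i <- 1L
  while (i <= length(top)) {
    if (top[i] == "-") {                      # insertion run
      j <- i
      while (j < length(top) && top[j + 1L] == "-") j <- j + 1L
      alt <- paste(bot[i:j], collapse = "")
      if (!grepl("N", alt, fixed = TRUE))
        variants <- c(variants, variant_key("INS", rpos[i], alt = alt))
      i <- j + 1L
    } else if (bot[i] == "-") {               # deletion run
      j <- i
      while (j < length(top) && bot[j + 1L] == "-") j <- j + 1L
      variants <- c(variants,
                    variant_key("DEL", rpos[i],
                                ref = paste(top[i:j], collapse = "")))
      i <- j + 1L
    } else {
      if (top[i] != bot[i] && top[i] != "N" && bot[i] != "N" &&
          bot[i] != ".")
        variants <- c(variants, variant_key("SNV", rpos[i], top[i], bot[i]))
      i <- i + 1L
    }
  }
  sort_variant_keys(variants)
}

# --- indel left-alignment oracle ------------------------------------------
# Enumerate every placement of the same edit that reproduces the identical
# mutated sequence; report the smallest start.
oracle_left_align <- function(key, reference) {
  v <- parse_variant_key(key)
  if (v$kind == "SNV") return(key)
  seq <- reference$sequence
  apply_edit <- function(kind, s, ref, alt) {
    if (kind == "DEL")
      paste0(substr(seq, 1L, s), substr(seq, s + nchar(ref) + 1L,
                                        nchar(seq)))
    else paste0(substr(seq, 1L, s), alt, substr(seq, s + 1L, nchar(seq)))
  }
  target <- apply_edit(v$kind, v$start, v$ref, v$alt)
  L <- if (v$kind == "DEL") nchar(v$ref) else nchar(v$alt)
  for (s in 0:nchar(seq)) {
    if (v$kind == "DEL") {
      if (s + L > nchar(seq)) break
      ref_s <- substr(seq, s + 1L, s + L)
      if (apply_edit("DEL", s, ref_s, "") == target)
        return(variant_key("DEL", s, ref = ref_s))
    } else {
      alt_s <- substr(target, s + 1L, s + L)
      if (apply_edit("INS", s, "", alt_s) == target)
        return(variant_key("INS", s, alt = alt_s))
    }
  }
  stop("oracle found no placement for ", key)
}

# --- maximum clique by subset enumeration ---------------------------------
# adj: symmetric logical matrix. Returns the maximum clique size.
oracle_max_clique_size <- function(adj) {
  n <- nrow(adj)
  best <- if (n > 0L) 1L else 0L
  for (code in seq_len(2^n) - 1L) {
    members <- which(bitwAnd(code, 2^(seq_len(n) - 1L)) > 0L)
    k <- length(members)
    if (k <= best) next
    ok <- TRUE
    if (k > 1L) {
      prs <- utils::combn(members, 2L)
      ok <- all(adj[t(prs)])
    }
    if (ok) best <- k
  }
  best
}

# --- haplotype recount oracle ---------------------------------------------
# Brute-force recount of tabulate_haplotypes() from first principles.
oracle_tabulate <- function(fragments, selected) {
  covers <- function(f, pos)
    all(vapply(pos, function(p)
      any(f$cov[, 1L] <= p & f$cov[, 2L] > p) && !(p %in% f$masked), FALSE))
  key_sets <- vapply(fragments, function(f)
    paste(sort_variant_keys(intersect(f$variants, selected)),
          collapse = "|"), "")
  ids <- setdiff(unique(key_sets), "")
  hits <- vapply(ids, function(id) sum(key_sets == id), 0L)
  informative <- vapply(ids, function(id) {
    pos <- unique(unlist(lapply(strsplit(id, "|", fixed = TRUE)[[1L]],
                                ampliclone:::variant_positions)))
    sum(vapply(fragments, covers, FALSE, pos = pos))
  }, 0L)
  n_wt <- sum(vapply(which(key_sets == ""), function(i) {
    any(vapply(selected, function(k)
      covers(fragments[[i]], ampliclone:::variant_positions(k)), FALSE))
  }, FALSE))
  list(ids = ids[order(ids)], hits = hits[order(ids)],
       informative = informative[order(ids)], n_wildtype = n_wt,
       n_uncovered = sum(key_sets == "") - n_wt)
}

# --- mixture enumeration oracle for scattered designs ---------------------
# Enumerate every non-negative assignment of `units` clone units to the
# candidate clone variant sets and keep those reproducing the observed
# per-amplicon key-set counts exactly.
oracle_mixtures <- function(fragments, selected, design, units) {
  amp_pos <- lapply(design$amplicons, ampliclone:::amplicon_positions)
  amp <- vapply(fragments, ampliclone:::assign_fragment_amplicon, 0L,
                design = design)
  ids <- vapply(fragments, function(f)
    paste(sort_variant_keys(intersect(f$variants, selected)),
          collapse = "|"), "")
  ids[ids == ""] <- "<wt>"   # empty-string dimnames cannot be indexed
  observed <- table(amp = amp, id = ids)
  selected <- sort_variant_keys(selected)
  n <- length(selected)
  subsets <- lapply(seq_len(2^n) - 1L, function(code)
    selected[bitwAnd(code, 2^(seq_len(n) - 1L)) > 0L])
  expected_id <- function(subset, a) {
    inside <- subset[vapply(subset, function(k)
      all(ampliclone:::variant_positions(k) %in% amp_pos[[a]]), FALSE)]
    paste(sort_variant_keys(inside), collapse = "|")
  }
  # counts per subset summing to `units`
  solutions <- list()
  recurse <- function(i, left, counts) {
    if (i > length(subsets)) {
      if (left != 0L) return()
      pred <- table(amp = integer(0), id = character(0))
      amp_v <- integer(0); id_v <- character(0); n_v <- integer(0)
      for (s in seq_along(subsets)) {
        if (counts[s] == 0L) next
        for (a in seq_along(amp_pos)) {
          amp_v <- c(amp_v, a)
          eid <- expected_id(subsets[[s]], a)
          id_v <- c(id_v, if (eid == "") "<wt>" else eid)
          n_v <- c(n_v, counts[s])
        }
      }
      pred <- stats::xtabs(n_v ~ amp_v + id_v)
      ok <- TRUE
      all_amp <- union(rownames(observed), rownames(pred))
      all_id <- union(colnames(observed), colnames(pred))
      for (a in all_amp) for (id in all_id) {
        o <- if (a %in% rownames(observed) && id %in% colnames(observed))
          observed[a, id] else 0L
        p <- if (a %in% rownames(pred) && id %in% colnames(pred))
          pred[a, id] else 0L
        if (o != p) { ok <- FALSE; break }
      }
      if (ok) {
        nms <- vapply(subsets, paste, "", collapse = "|")
        nms[nms == ""] <- "<wt>"
        solutions[[length(solutions) + 1L]] <<- stats::setNames(counts, nms)
      }
      return()
    }
    for (c_i in 0:left) recurse(i + 1L, left - c_i, c(counts, c_i))
  }
  recurse(1L, units, integer(0))
  solutions
}
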