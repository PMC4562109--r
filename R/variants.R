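# Per-read variant extraction and annotation.
#
# Every usable alignment becomes a ReadObservation: the reference positions
# it covers (as half-open intervals; deleted positions are covered -- a
# spanning read observes the deletion), the positions masked by ambiguous
# bases (N), and the set of atomic variants (canonical keys). At this stage
# every difference to the reference is kept, sequencing errors included;
# filtering happens later on the selection.

new_observation <- function(fragment_key, mate, cov, masked, variants) {
  structure(list(fragment_key = fragment_key, mate = mate,
                 cov = cov, masked = masked, variants = variants),
            class = "ReadObservation")
}

# merge adjacent/overlapping rows of a 2-column (start,end) interval matrix
merge_intervals <- function(iv) {
  if (is.null(iv) || nrow(iv) == 0L) return(matrix(integer(0), ncol = 2L))
  iv <- iv[order(iv[, 1L]), , drop = FALSE]
  s <- iv[1L, 1L]; e <- iv[1L, 2L]
  out <- list()
  if (nrow(iv) > 1L) for (i in 2L:nrow(iv)) {
    if (iv[i, 1L] <= e) e <- max(e, iv[i, 2L])
    else { out[[length(out) + 1L]] <- c(s, e); s <- iv[i, 1L]; e <- iv[i, 2L] }
  }
  out[[length(out) + 1L]] <- c(s, e)
  do.call(rbind, out)
}

# TRUE iff every 0-based position in pos lies inside the intervals and
# outside masked
covers_all <- function(cov, masked, pos) {
  if (length(pos) == 0L) return(TRUE)
  ok <- vapply(pos, function(p)
    any(cov[, 1L] <= p & cov[, 2L] > p), FALSE)
  all(ok) && !any(pos %in% masked)
}

RAW_N <- charToRaw("N")

#' Extract atomic variants from one read alignment
#'
#' Walks the alignment operations: mismatching aligned bases give SNVs,
#' insertion operations give INS variants anchored at the following
#' reference position, deletions give DEL variants whose deleted positions
#' remain covered, soft clips contribute nothing, and an N in the read (or
#' reference) masks the position instead of calling a variant.
#'
#' @param read `ReadAlignment` from [parse_alignment()].
#' @param reference `Reference`.
#' @return `ReadObservation` with fields `fragment_key`, `mate`, `cov`
#'   (interval matrix of covered 0-based positions), `masked` (integer
#'   vector) and `variants` (canonical keys).
#' @export
call_read_variants <- function(read, reference) {
  qraw <- charToRaw(read$seq)
  r <- read$ref_start
  q <- 0L
  variants <- character(0)
  masked <- integer(0)
  iv <- list()
  ops <- read$ops
  for (k in seq_along(ops$op)) {
    op <- ops$op[k]; len <- ops$len[k]
    if (op %in% c("M", "=", "X")) {
      rw <- reference$raw[(r + 1L):(r + len)]
      qw <- qraw[(q + 1L):(q + len)]
      iv[[length(iv) + 1L]] <- c(r, r + len)
      amb <- qw == RAW_N | rw == RAW_N
      mis <- which(qw != rw & !amb)
      if (length(mis))
        variants <- c(variants, sprintf("SNV:%d:%s:%s", r + mis - 1L,
                                        rawToChar(rw[mis], multiple = TRUE),
                                        rawToChar(qw[mis], multiple = TRUE)))
      if (any(amb)) masked <- c(masked, r + which(amb) - 1L)
      r <- r + len; q <- q + len
    } else if (op == "I") {
      alt <- substr(read$seq, q + 1L, q + len)
      if (!grepl("N", alt, fixed = TRUE))
        variants <- c(variants, variant_key("INS", r, alt = alt))
      q <- q + len
    } else if (op == "D" || op == "N") {
      if (op == "D") {
        variants <- c(variants,
                      variant_key("DEL", r, ref = ref_chars(reference, r, len)))
        iv[[length(iv) + 1L]] <- c(r, r + len)
      }
      r <- r + len
    } else if (op == "S") {
      q <- q + len
    } # H, P: nothing consumed
  }
  new_observation(read$qname, read$mate,
                  merge_intervals(do.call(rbind, iv)),
                  masked, variants)
}

#' Left-align insertions and deletions
#'
#' Shifts every INS/DEL to its leftmost equivalent placement in its
#' homopolymer/repeat context so that alignments from gap-placement-happy
#' aligners collapse onto one canonical key. Idempotent; SNVs pass through.
#'
#' @param observation `ReadObservation` (or a bare character vector of keys).
#' @param reference `Reference`.
#' @return the observation with normalized variant keys.
#' @export
normalize_indels <- function(observation, reference) {
  keys <- if (is.character(observation)) observation else observation$variants
  keys <- vapply(keys, normalize_one_indel, "", reference = reference,
                 USE.NAMES = FALSE)
  if (is.character(observation)) return(keys)
  observation$variants <- keys
  observation
}

normalize_one_indel <- function(key, reference) {
  v <- parse_variant_key(key)
  if (v$kind == "SNV") return(key)
  refc <- strsplit(reference$sequence, "", fixed = TRUE)[[1L]]
  if (v$kind == "DEL") {
    s <- v$start; L <- nchar(v$ref)
    while (s > 0L && refc[s] == refc[s + L]) s <- s - 1L  # refc is 1-based
    if (s == v$start) return(key)
    variant_key("DEL", s, ref = ref_chars(reference, s, L))
  } else {
    s <- v$start
    alt <- strsplit(v$alt, "", fixed = TRUE)[[1L]]
    L <- length(alt)
    while (s > 0L && refc[s] == alt[L]) {
      alt <- c(alt[L], alt[-L])
      s <- s - 1L
    }
    if (s == v$start) return(key)
    variant_key("INS", s, alt = paste(alt, collapse = ""))
  }
}

#' Combine consecutive and same-codon variants for reporting
#'
#' Maximal runs of reference-adjacent SNVs are combined into one
#' multi-nucleotide record (`reason = "consecutive"`); non-adjacent SNV
#' pairs/triples sharing a codon (given a `GeneModel`) are combined as
#' `reason = "same_codon"`. Combination is reporting-only: haplotype
#' identity always uses the atomic members.
#'
#' @param keys character vector of canonical variant keys (one fragment's
#'   variants, or any set to be displayed together).
#' @param model optional `GeneModel` for codon grouping and labels.
#' @param reference optional `Reference` for labels.
#' @return list of combined-variant records: `members` (keys),
#'   `combined_label`, `reason` (`"consecutive"`, `"same_codon"` or
#'   `"single"`).
#' @export
combine_variants <- function(keys, model = NULL, reference = NULL) {
  keys <- sort_variant_keys(keys)
  parsed <- lapply(keys, parse_variant_key)
  is_snv <- vapply(parsed, function(v) v$kind == "SNV", FALSE)
  starts <- vapply(parsed, `[[`, 0L, "start")
  group <- seq_along(keys)
  # consecutive runs of SNVs
  for (i in seq_along(keys)[-1L]) {
    if (is_snv[i] && is_snv[i - 1L] && starts[i] == starts[i - 1L] + 1L)
      group[i] <- group[i - 1L]
  }
  # same-codon SNVs among remaining singletons
  if (!is.null(model)) {
    singleton <- is_snv & !(group %in% group[duplicated(group)])
    codon <- vapply(starts, function(p) {
      k <- if (p >= 0L && p < length(model$pos2cds)) model$pos2cds[p + 1L]
           else NA_integer_
      if (is.na(k)) NA_integer_ else (k - 1L) %/% 3L + 1L
    }, 0L)
    for (cd in unique(codon[singleton & !is.na(codon)])) {
      idx <- which(singleton & !is.na(codon) & codon == cd)
      if (length(idx) > 1L) group[idx] <- group[idx[1L]]
    }
  }
  lapply(unique(group), function(g) {
    idx <- which(group == g)
    members <- keys[idx]
    if (length(idx) == 1L) {
      return(list(members = members,
                  combined_label = variant_cds_label(members, model, reference),
                  reason = "single"))
    }
    reason <- if (all(diff(starts[idx]) == 1L)) "consecutive" else "same_codon"
    list(members = members,
         combined_label = combined_label(members, reason, model, reference),
         reason = reason)
  })
}

combined_label <- function(members, reason, model, reference) {
  parsed <- lapply(members, parse_variant_key)
  if (reason == "consecutive" && !is.null(reference)) {
    s <- parsed[[1L]]$start; e <- parsed[[length(parsed)]]$start
    ref <- paste(vapply(parsed, `[[`, "", "ref"), collapse = "")
    alt <- paste(vapply(parsed, `[[`, "", "alt"), collapse = "")
    cs <- cds_coord(s, model); ce <- cds_coord(e, model)
    if (!is.na(cs) && !is.na(ce)) {
      if (model$strand == "-") { ref <- rev_comp(ref); alt <- rev_comp(alt) }
      return(sprintf("c.%d_%d%s>%s", min(cs, ce), max(cs, ce), ref, alt))
    }
    return(sprintf("g.%d_%d%s>%s", s + 1L, e + 1L, ref, alt))
  }
  paste(vapply(members, variant_cds_label, "", model = model,
               reference = reference), collapse = "+")
}

rev_comp <- function(x) {
  paste(rev(comp_base(strsplit(x, "", fixed = TRUE)[[1L]])), collapse = "")
}

cds_coord <- function(pos, model) {
  # 0-based reference position -> 1-based c. coordinate, NA outside the CDS
  if (is.null(model) || pos < 0L || pos >= length(model$pos2cds))
    return(NA_integer_)
  model$pos2cds[pos + 1L]
}

#' Annotate a variant with coding-sequence and amino-acid labels
#'
#' Label dialect: SNV `c.<pos><ref>><alt>`; deletion
#' `c.<start>_<end>del<length>` (single base: `c.<pos>del1`); insertion
#' `c.<left>_<right>ins<length>` -- the indel labels carry the length, the
#' allele itself stays in the variant key and is reported in a separate
#' column. Variants outside the CDS (or without a gene model) get 1-based
#' `g.` labels. Amino-acid labels use the single-letter
#' `<ref><codon><alt>` form for substitutions and `fs`/`del`/`ins` markers
#' for frame-affecting changes.
#'
#' @param key canonical variant key.
#' @param model optional `GeneModel`.
#' @param reference optional `Reference` (unused for labels, kept for
#'   interface symmetry).
#' @return list with `cds_label` and `aa_label` (`""` when not applicable).
#' @export
annotate_variant <- function(key, model = NULL, reference = NULL) {
  list(cds_label = variant_cds_label(key, model, reference),
       aa_label = variant_aa_label(key, model))
}

variant_cds_label <- function(key, model = NULL, reference = NULL) {
  v <- parse_variant_key(key)
  if (v$kind == "SNV") {
    c1 <- cds_coord(v$start, model)
    if (!is.na(c1)) {
      ref <- v$ref; alt <- v$alt
      if (model$strand == "-") { ref <- comp_base(ref); alt <- comp_base(alt) }
      return(sprintf("c.%d%s>%s", c1, ref, alt))
    }
    return(sprintf("g.%d%s>%s", v$start + 1L, v$ref, v$alt))
  }
  if (v$kind == "DEL") {
    L <- nchar(v$ref)
    c1 <- cds_coord(v$start, model)
    c2 <- cds_coord(v$start + L - 1L, model)
    if (!is.na(c1) && !is.na(c2)) {
      lo <- min(c1, c2); hi <- max(c1, c2)
      if (L == 1L) return(sprintf("c.%ddel1", lo))
      return(sprintf("c.%d_%ddel%d", lo, hi, L))
    }
    if (L == 1L) return(sprintf("g.%ddel1", v$start + 1L))
    return(sprintf("g.%d_%ddel%d", v$start + 1L, v$start + L, L))
  }
  # INS anchored before 0-based v$start
  L <- nchar(v$alt)
  cl <- cds_coord(v$start - 1L, model)
  cr <- cds_coord(v$start, model)
  if (!is.na(cl) && !is.na(cr))
    return(sprintf("c.%d_%dins%d", min(cl, cr), max(cl, cr), L))
  sprintf("g.%d_%dins%d", v$start, v$start + 1L, L)
}

variant_aa_label <- function(key, model = NULL) {
  if (is.null(model)) return("")
  v <- parse_variant_key(key)
  n_codons <- nchar(model$cds_seq) %/% 3L
  if (v$kind == "SNV") {
    cpos <- cds_coord(v$start, model)
    if (is.na(cpos)) return("")
    codon_i <- (cpos - 1L) %/% 3L + 1L
    if (codon_i > n_codons) return("")
    codon <- substr(model$cds_seq, (codon_i - 1L) * 3L + 1L, codon_i * 3L)
    alt <- v$alt
    if (model$strand == "-") alt <- comp_base(alt)
    within <- (cpos - 1L) %% 3L + 1L
    alt_codon <- codon
    substr(alt_codon, within, within) <- alt
    sprintf("%s%d%s", translate_codon(codon), codon_i,
            translate_codon(alt_codon))
  } else {
    L <- if (v$kind == "DEL") nchar(v$ref) else nchar(v$alt)
    anchor <- if (v$kind == "DEL") v$start else max(0L, v$start - 1L)
    cpos <- cds_coord(anchor, model)
    if (is.na(cpos)) return("")
    codon_i <- min((cpos - 1L) %/% 3L + 1L, n_codons)
    codon <- substr(model$cds_seq, (codon_i - 1L) * 3L + 1L, codon_i * 3L)
    aa <- translate_codon(codon)
    if (L %% 3L != 0L) return(sprintf("%s%dfs", aa, codon_i))
    sprintf("%s%d%s", aa, codon_i, if (v$kind == "DEL") "del" else "ins")
  }
}

translate_codon <- function(codon) {
  if (grepl("N", codon, fixed = TRUE) || nchar(codon) != 3L) return("X")
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa) || is.na(aa)) "X" else aa
}
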