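# Seeded mixed-clone amplicon read simulator with ground truth.
#
# Generates pre-aligned reads (the true alignment is recorded directly, no
# aligner involved) for a mixture of clones -- each clone a set of variants
# applied to the reference -- at specified proportions, optionally pushed
# through a substitution/indel error model. The error model replaces an
# empirical 454 profile with a uniform per-base substitution rate plus a
# homopolymer-biased indel rate (pyrosequencing's characteristic failure
# mode), defaults 0.01 and 0.002.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

#' Clone ground truth
#'
#' @param variants canonical variant keys (empty = wild type).
#' @param proportion mixture fraction in `[0, 1]`.
#' @return `CloneTruth` list.
#' @export
clone_truth <- function(variants, proportion) {
  structure(list(variants = sort_variant_keys(variants),
                 proportion = proportion), class = "CloneTruth")
}

#' Simulation configuration
#'
#' @param reference `Reference`, or `NULL` to generate a random one of
#'   `ref_length` bp.
#' @param ref_length length of the generated reference (default 924).
#' @param design optional `AmpliconDesign`; with a design, `n_fragments` is
#'   the number of clone units and every unit emits one fragment per
#'   amplicon (a two-segment amplicon becomes a mate pair). Without a
#'   design, fragments are single reads of `read_length` bp with uniform
#'   random start (or mate pairs covering the ends of a `fragment_span`
#'   window when `paired = TRUE`).
#' @param n_fragments fragments (or clone units, see above), >= 1.
#' @param read_length read length for design-free simulation (default 600).
#' @param paired simulate mate pairs in design-free mode.
#' @param fragment_span outer span of a design-free mate pair.
#' @param error_rate per-base substitution error probability in `[0, 1)`.
#' @param indel_error_rate mean per-base indel error probability; indel
#'   positions are drawn weighted by homopolymer run length.
#' @param allocation `"largest_remainder"` (exact, deterministic; default)
#'   or `"multinomial"` (sampled).
#' @param seed mandatory integer seed.
#' @return `SimConfig` list.
#' @export
sim_config <- function(reference = NULL, ref_length = 924L, design = NULL,
                       n_fragments = 1000L, read_length = 600L,
                       paired = FALSE, fragment_span = NULL,
                       error_rate = 0.01, indel_error_rate = 0.002,
                       allocation = c("largest_remainder", "multinomial"),
                       seed) {
  if (missing(seed) || is.null(seed) || is.na(seed))
    stop("sim_config requires a seed")
  stopifnot(n_fragments >= 1L, error_rate >= 0, error_rate < 1,
            indel_error_rate >= 0, indel_error_rate < 1)
  if (is.null(fragment_span)) fragment_span <- as.integer(1.5 * read_length)
  structure(list(reference = reference, ref_length = as.integer(ref_length),
                 design = design, n_fragments = as.integer(n_fragments),
                 read_length = as.integer(read_length), paired = paired,
                 fragment_span = as.integer(fragment_span),
                 error_rate = error_rate,
                 indel_error_rate = indel_error_rate,
                 allocation = match.arg(allocation),
                 seed = as.integer(seed)),
            class = "SimConfig")
}

#' Random reference sequence
#'
#' @param length sequence length.
#' @param seed integer seed.
#' @param name record name.
#' @return `Reference`.
#' @export
random_reference <- function(length, seed, name = "simref") {
  with_seed(seed, {
    new_reference(name, paste(sample(c("A", "C", "G", "T"), length,
                                     replace = TRUE), collapse = ""))
  })
}

# exact deterministic largest-remainder apportionment of n into proportions
allocate_counts <- function(n, proportions) {
  raw <- n * proportions / sum(proportions)
  counts <- floor(raw)
  left <- n - sum(counts)
  if (left > 0L) {
    extra <- order(-(raw - counts), seq_along(raw))[seq_len(left)]
    counts[extra] <- counts[extra] + 1L
  }
  as.integer(counts)
}

# homopolymer run length per position, capped
homopolymer_weights <- function(sequence, cap = 4L) {
  r <- rle(strsplit(sequence, "", fixed = TRUE)[[1L]])
  pmin(rep(r$lengths, r$lengths), cap)
}

#' Simulate a mixed-clone sequencing sample
#'
#' Fragment counts per clone are apportioned exactly by largest remainder
#' (or drawn multinomially). Every read's true alignment (position and
#' operation list) is recorded; clone variants and injected errors are
#' expressed in the CIGAR, so parsing the written SAM and calling variants
#' with `error_rate = 0` recovers each clone's variant set on every
#' fragment. Same config and seed give byte-identical output.
#'
#' @param truth list of `CloneTruth` (proportions must sum to 1 within
#'   1e-9; a clone with no variants is the wild type).
#' @param config `SimConfig`.
#' @return list with `reads` (each: `qname`, `mate`, `ref_start`, `cigar`,
#'   `seq`, `clone`), `reference`, `design`, and `truth_table`
#'   (`clone_id`, `variants`, `proportion`, `n_units`).
#' @export
simulate_mixture <- function(truth, config) {
  stopifnot(inherits(config, "SimConfig"))
  props <- vapply(truth, `[[`, 0, "proportion")
  if (abs(sum(props) - 1) > 1e-9)
    stop("clone proportions must sum to 1 (got ", sum(props), ")")
  reference <- config$reference
  if (is.null(reference))
    reference <- random_reference(config$ref_length, config$seed + 7L)
  check_truth_in_bounds(truth, reference, config)
  with_seed(config$seed, {
    n_units <- if (config$allocation == "largest_remainder")
      allocate_counts(config$n_fragments, props)
    else as.integer(stats::rmultinom(1L, config$n_fragments, props))
    hp_w <- homopolymer_weights(reference$sequence)
    refc <- strsplit(reference$sequence, "", fixed = TRUE)[[1L]]
    clone_of <- rep(seq_along(truth), n_units)
    per_unit <- if (!is.null(config$design))
      sum(vapply(config$design$amplicons, function(a) nrow(a$segments), 0L))
    else if (config$paired) 2L else 1L
    reads <- vector("list", per_unit * config$n_fragments)
    nr <- 0L
    for (u in seq_along(clone_of)) {
      cl <- truth[[clone_of[u]]]
      qbase <- sprintf("u%06d", u)
      if (!is.null(config$design)) {
        for (ai in seq_along(config$design$amplicons)) {
          amp <- config$design$amplicons[[ai]]
          segs <- amp$segments
          n_seg <- nrow(segs)
          for (si in seq_len(n_seg)) {
            nr <- nr + 1L
            reads[[nr]] <- sim_one_read(
              refc, hp_w, segs$start[si], segs$end[si], cl$variants,
              config, qname = sprintf("%s_%s", qbase, amp$label),
              mate = if (n_seg == 2L) si else 0L, clone = clone_of[u])
          }
        }
      } else if (config$paired) {
        span <- min(config$fragment_span, length(refc))
        s <- sample.int(length(refc) - span + 1L, 1L) - 1L
        rl <- min(config$read_length, span)
        for (si in 1:2) {
          st <- if (si == 1L) s else s + span - rl
          nr <- nr + 1L
          reads[[nr]] <- sim_one_read(refc, hp_w, st, st + rl, cl$variants,
                                      config, qname = qbase, mate = si,
                                      clone = clone_of[u])
        }
      } else {
        rl <- min(config$read_length, length(refc))
        s <- sample.int(length(refc) - rl + 1L, 1L) - 1L
        nr <- nr + 1L
        reads[[nr]] <- sim_one_read(refc, hp_w, s, s + rl, cl$variants,
                                    config, qname = qbase, mate = 0L,
                                    clone = clone_of[u])
      }
    }
    truth_table <- data.frame(
      clone_id = vapply(seq_along(truth), function(i)
        if (length(truth[[i]]$variants)) haplotype_id(truth[[i]]$variants)
        else "wildtype", ""),
      n_variants = vapply(truth, function(t) length(t$variants), 0L),
      proportion = props, n_units = n_units, stringsAsFactors = FALSE)
    list(reads = reads[seq_len(nr)], reference = reference,
         design = config$design, truth_table = truth_table)
  })
}

check_truth_in_bounds <- function(truth, reference, config) {
  for (cl in truth) {
    for (k in cl$variants) {
      v <- parse_variant_key(k)
      last <- v$start + max(0L, nchar(v$ref) - 1L)
      if (v$start < 0L || last >= reference$length)
        stop("clone variant ", k, " lies outside the reference")
      if (!is.null(config$design)) {
        pos <- variant_positions(k)
        inside <- any(vapply(config$design$amplicons, function(a)
          all(pos %in% amplicon_positions(a)), FALSE))
        if (!inside)
          stop("clone variant ", k, " is not covered by any amplicon")
      }
    }
  }
}

BASES <- c("A", "C", "G", "T")

# one read over reference window [s, e): apply the clone variants that fall
# fully inside the window, then inject substitution and indel errors; the
# read's true CIGAR is assembled from the edit events
sim_one_read <- function(refc, hp_w, s, e, variants, config, qname, mate,
                         clone) {
  len <- e - s
  bases <- refc[(s + 1L):e]
  deleted <- logical(len)
  ins_at <- list()   # name = 0-based anchor position, value = inserted text
  for (k in variants) {
    v <- parse_variant_key(k)
    if (v$kind == "SNV") {
      if (v$start >= s && v$start < e) bases[v$start - s + 1L] <- v$alt
    } else if (v$kind == "DEL") {
      dl <- nchar(v$ref)
      if (v$start >= s && v$start + dl <= e)
        deleted[(v$start - s + 1L):(v$start - s + dl)] <- TRUE
    } else if (v$kind == "INS") {
      if (v$start > s && v$start < e)
        ins_at[[as.character(v$start)]] <- v$alt
    }
  }
  # substitution errors (never on deleted positions)
  if (config$error_rate > 0) {
    k <- stats::rbinom(1L, len, config$error_rate)
    if (k > 0L) {
      at <- sample.int(len, k)
      at <- at[!deleted[at]]
      if (length(at)) {
        cur <- match(bases[at], BASES)
        shift <- sample.int(3L, length(at), replace = TRUE)
        bases[at] <- BASES[(cur - 1L + shift) %% 4L + 1L]
      }
    }
  }
  # homopolymer-biased indel errors: duplicate or drop one base
  if (config$indel_error_rate > 0) {
    k <- stats::rbinom(1L, len, config$indel_error_rate)
    if (k > 0L) {
      w <- hp_w[(s + 1L):e]
      at <- sample.int(len, min(k, len), prob = w)
      for (p in at) {
        if (deleted[p]) next
        if (stats::runif(1L) < 0.5) deleted[p] <- TRUE
        else {
          key <- as.character(s + p)
          ins_at[[key]] <- paste0(bases[p], ins_at[[key]])
        }
      }
    }
  }
  # assemble CIGAR and sequence from events
  anchors <- sort(as.integer(names(ins_at)))
  ops <- character(0); lens <- integer(0); chunks <- character(0)
  push <- function(op, n, chunk = NULL) {
    m <- length(ops)
    if (m > 0L && ops[m] == op) lens[m] <<- lens[m] + n
    else { ops[m + 1L] <<- op; lens[m + 1L] <<- n }
    if (!is.null(chunk)) chunks[length(chunks) + 1L] <<- chunk
  }
  p <- s
  dstarts <- s - 1L + which(deleted & !c(FALSE, deleted[-len]))
  dends <- s - 1L + which(deleted & !c(deleted[-1L], FALSE)) + 1L
  events <- sort(unique(c(anchors, dstarts)))
  for (ev in events) {
    if (ev > p)
      push("M", ev - p, paste(bases[(p - s + 1L):(ev - s)][
        !deleted[(p - s + 1L):(ev - s)]], collapse = ""))
    p <- max(p, ev)
    if (!is.null(ins_at[[as.character(ev)]]))
      push("I", nchar(ins_at[[as.character(ev)]]),
           ins_at[[as.character(ev)]])
    di <- match(ev, dstarts)
    if (!is.na(di)) {
      push("D", dends[di] - dstarts[di])
      p <- dends[di]
    }
  }
  if (e > p)
    push("M", e - p, paste(bases[(p - s + 1L):len][
      !deleted[(p - s + 1L):len]], collapse = ""))
  # M blocks above still contained deleted positions only outside D runs --
  # they never do, deletions are events; the filter is belt and braces
  list(qname = qname, mate = mate, ref_start = s,
       cigar = paste0(lens, ops, collapse = ""),
       seq = paste(chunks, collapse = ""), clone = clone)
}

#' Write simulated reads as SAM
#'
#' Emits a valid headered SAM file, one primary record per read (two per
#' mate pair, with pairing flags and mate positions set), that parses back
#' through [parse_alignment()] unchanged.
#'
#' @param sim result of [simulate_mixture()] (or a bare list of reads plus
#'   a `reference`).
#' @param path output file.
#' @param reference `Reference`; defaults to `sim$reference`.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(sim, path, reference = NULL) {
  reads <- if (!is.null(sim$reads)) sim$reads else sim
  if (is.null(reference)) reference <- sim$reference
  qn <- vapply(reads, `[[`, "", "qname")
  mate <- vapply(reads, `[[`, 0L, "mate")
  pos <- vapply(reads, `[[`, 0L, "ref_start")
  cig <- vapply(reads, `[[`, "", "cigar")
  seqs <- vapply(reads, `[[`, "", "seq")
  flag <- ifelse(mate == 0L, 0L,
                 ifelse(mate == 1L, FLAG_PAIRED + 2L + FLAG_MATE1,
                        FLAG_PAIRED + 2L + FLAG_MATE2))
  rnext <- ifelse(mate == 0L, "*", "=")
  pnext <- rep(0L, length(reads))
  if (any(mate > 0L)) {
    # mate position lookup by query name
    for (q in unique(qn[mate > 0L])) {
      idx <- which(qn == q)
      if (length(idx) == 2L) pnext[idx] <- pos[rev(idx)] + 1L
    }
  }
  lines <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", reference$name, reference$length),
    sprintf("%s\t%d\t%s\t%d\t60\t%s\t%s\t%d\t0\t%s\t*",
            qn, flag, reference$name, pos + 1L, cig, rnext, pnext, seqs))
  writeLines(lines, path)
  invisible(path)
}

#' Write a reference as FASTA
#'
#' @param reference `Reference`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_reference <- function(reference, path) {
  Biostrings::writeXStringSet(
    stats::setNames(Biostrings::DNAStringSet(reference$sequence),
                    reference$name), path, width = 70L)
  invisible(path)
}

#' Random clone mixture ground truth
#'
#' Draws a mixture in the style of a multi-haplotype simulation experiment:
#' `n_clones` clones with 1-9 SNVs each (mean about 4.2), clone variant
#' positions mutually disjoint and confined to a per-clone window of
#' `window` bp so a read of typical length can span a whole clone, plus a
#' wild-type remainder. Proportions are uniform random rescaled to
#' `1 - wt_proportion`.
#'
#' @param reference `Reference`.
#' @param n_clones number of variant-carrying clones.
#' @param seed integer seed.
#' @param window clone variant span in bp (default 300).
#' @param wt_proportion wild-type fraction (default drawn in `[0.1, 0.3]`).
#' @return list of `CloneTruth` (wild type last).
#' @export
random_clone_truth <- function(reference, n_clones, seed, window = 300L,
                               wt_proportion = NULL) {
  with_seed(seed, {
    refc <- strsplit(reference$sequence, "", fixed = TRUE)[[1L]]
    L <- length(refc)
    used <- integer(0)
    clones <- vector("list", n_clones)
    sizes <- sample(1:9, n_clones, replace = TRUE,
                    prob = c(9, 13, 15, 16, 15, 12, 9, 6, 5))
    for (i in seq_len(n_clones)) {
      repeat {
        w <- sample.int(L - window + 1L, 1L) - 1L
        avail <- setdiff(seq.int(w, w + window - 1L), used)
        if (length(avail) >= sizes[i]) break
      }
      pos <- sort(sample(avail, sizes[i]))
      used <- c(used, pos)
      alts <- vapply(pos, function(p) {
        cur <- match(refc[p + 1L], BASES)
        BASES[(cur - 1L + sample.int(3L, 1L)) %% 4L + 1L]
      }, "")
      clones[[i]] <- clone_truth(
        sprintf("SNV:%d:%s:%s", pos, refc[pos + 1L], alts), NA_real_)
    }
    if (is.null(wt_proportion)) wt_proportion <- stats::runif(1L, 0.1, 0.3)
    p <- stats::runif(n_clones, 0.2, 1)
    p <- p / sum(p) * (1 - wt_proportion)
    for (i in seq_len(n_clones)) clones[[i]]$proportion <- p[i]
    c(clones, list(clone_truth(character(0), wt_proportion)))
  })
}
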