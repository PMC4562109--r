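# Input layer: reference FASTA, gene annotation, amplicon design, variant
# selection lists, and SAM alignments. All internal coordinates are 0-based
# half-open; report output is 1-based.

#' Load a reference sequence from FASTA
#'
#' Reads the first record of a FASTA file, uppercases it and validates the
#' alphabet. A warning is emitted if the file holds more than one record.
#'
#' @param path FASTA file.
#' @return object of class `Reference`: list with `name`, `sequence`
#'   (uppercase character scalar) and `length`.
#' @export
load_reference <- function(path) {
  if (!file.exists(path)) stop("reference file not found: ", path)
  set <- tryCatch(suppressWarnings(Biostrings::readDNAStringSet(path)),
                  error = function(e) stop("cannot read FASTA '", path, "': ",
                                           conditionMessage(e)))
  if (length(set) == 0L) stop("no sequence records in ", path)
  if (length(set) > 1L)
    warning(length(set), " records in ", path, "; using the first")
  seq <- toupper(as.character(set[[1L]]))
  if (nchar(seq) < 1L) stop("empty reference sequence in ", path)
  # Biostrings silently drops some invalid letters: cross-check the raw text
  lines <- readLines(path, warn = FALSE)
  starts <- which(startsWith(lines, ">"))
  body_end <- if (length(starts) > 1L) starts[2L] - 1L else length(lines)
  raw_len <- sum(nchar(gsub("\\s", "", lines[(starts[1L] + 1L):body_end])))
  if (grepl("[^ACGTN]", seq) || raw_len != nchar(seq))
    stop("reference contains characters outside {A,C,G,T,N}")
  new_reference(sub("\\s.*$", "", names(set)[1L]), seq)
}

#' @rdname load_reference
#' @param name sequence identifier.
#' @param sequence nucleotide string (case-insensitive, A/C/G/T/N only).
#' @export
new_reference <- function(name, sequence) {
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence) || nchar(sequence) < 1L)
    stop("reference sequence must be non-empty over {A,C,G,T,N}")
  structure(list(name = as.character(name), sequence = sequence,
                 length = nchar(sequence),
                 raw = charToRaw(sequence)),
            class = "Reference")
}

#' @export
print.Reference <- function(x, ...) {
  cat(sprintf("<Reference> %s, %d bp\n", x$name, x$length))
  invisible(x)
}

ref_chars <- function(reference, start, len) {
  # 0-based start; returns character scalar
  substr(reference$sequence, start + 1L, start + len)
}

## ---------------------------------------------------------------------------
## Gene model (CDS definition) for c./p. annotation

#' Construct a gene model from CDS intervals
#'
#' @param intervals data.frame/matrix with columns `start`, `end` (0-based
#'   half-open reference coordinates), sorted and non-overlapping.
#' @param strand `"+"` or `"-"`.
#' @param reference `Reference`; required to extract the coding sequence.
#' @return object of class `GeneModel` with `intervals`, `strand`,
#'   `cds_positions` (0-based reference position of c.1, c.2, ... in coding
#'   order) and `cds_seq` (coding-strand sequence).
#' @export
new_gene_model <- function(intervals, strand, reference) {
  intervals <- as.data.frame(intervals)[, c("start", "end")]
  intervals <- intervals[order(intervals$start), , drop = FALSE]
  if (nrow(intervals) == 0L || sum(intervals$end - intervals$start) <= 0L)
    stop("gene model needs at least one non-empty CDS interval")
  if (any(intervals$start < 0L) || any(intervals$end > reference$length))
    stop("CDS extends past the reference")
  if (nrow(intervals) > 1L &&
      any(intervals$start[-1L] < intervals$end[-nrow(intervals)]))
    stop("CDS intervals overlap")
  pos <- unlist(mapply(seq.int, intervals$start, intervals$end - 1L,
                       SIMPLIFY = FALSE), use.names = FALSE)
  strand <- match.arg(strand, c("+", "-"))
  if (strand == "-") pos <- rev(pos)
  bases <- strsplit(reference$sequence, "", fixed = TRUE)[[1L]][pos + 1L]
  if (strand == "-") bases <- comp_base(bases)
  if (length(pos) %% 3L != 0L)
    warning("CDS length ", length(pos), " is not a multiple of 3; ",
            "trailing partial codon ignored for amino-acid annotation")
  pos2cds <- rep(NA_integer_, reference$length)
  pos2cds[pos + 1L] <- seq_along(pos)
  structure(list(intervals = intervals, strand = strand,
                 cds_positions = pos, cds_seq = paste(bases, collapse = ""),
                 pos2cds = pos2cds),
            class = "GeneModel")
}

comp_base <- function(x) {
  chartr("ACGTN", "TGCAN", x)
}

#' Load a gene model from a GenBank-style flat file or a CDS table
#'
#' Two formats are accepted: a GenBank flat file, from which the first `CDS`
#' feature (or the one whose `/gene=` or `/locus_tag=` qualifier matches
#' `cds_name`) is taken; or a whitespace-separated table with lines
#' `CDS <start> <end> <strand>` using 1-based inclusive coordinates as in
#' GenBank.
#'
#' @param path annotation file.
#' @param reference `Reference`.
#' @param cds_name optional name selecting one of several CDS features.
#' @return `GeneModel`.
#' @export
load_gene_model <- function(path, reference, cds_name = NULL) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (any(grepl("^\\s{2,}CDS\\s", lines)) || any(grepl("^LOCUS", lines))) {
    load_gene_model_genbank(lines, reference, cds_name)
  } else {
    load_gene_model_table(lines, reference, cds_name)
  }
}

load_gene_model_table <- function(lines, reference, cds_name) {
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  recs <- lapply(strsplit(lines, "\\s+"), function(f) {
    if (length(f) < 4L || toupper(f[1L]) != "CDS")
      stop("expected lines 'CDS <start> <end> <strand>', got: ",
           paste(f, collapse = " "))
    list(start = as.integer(f[2L]), end = as.integer(f[3L]), strand = f[4L],
         name = if (length(f) >= 5L) f[5L] else NA_character_)
  })
  if (length(recs) == 0L) stop("no CDS definition found")
  if (!is.null(cds_name)) {
    recs <- Filter(function(r) identical(r$name, cds_name), recs)
    if (length(recs) == 0L) stop("no CDS named '", cds_name, "'")
  } else if (length(unique(vapply(recs, function(r)
             paste0(r$name, r$strand), ""))) > 1L) {
    stop("multiple CDS definitions present; select one with cds_name")
  }
  strand <- recs[[1L]]$strand
  iv <- data.frame(start = vapply(recs, `[[`, 0L, "start") - 1L,
                   end = vapply(recs, `[[`, 0L, "end"))
  new_gene_model(iv, strand, reference)
}

load_gene_model_genbank <- function(lines, reference, cds_name) {
  idx <- grep("^\\s{2,}CDS\\s", lines)
  if (length(idx) == 0L) stop("no CDS feature found")
  features <- lapply(idx, function(i) {
    loc <- sub("^\\s+CDS\\s+", "", lines[i])
    j <- i + 1L
    quals <- character(0)
    while (j <= length(lines) && grepl("^\\s{10,}", lines[j]) &&
           !grepl("^\\s{2,}\\S+\\s+(complement|join|\\d)", lines[j])) {
      if (grepl("^\\s+/", lines[j])) quals <- c(quals, trimws(lines[j]))
      else if (!grepl("/", lines[j])) loc <- paste0(loc, trimws(lines[j]))
      j <- j + 1L
    }
    name <- NA_character_
    m <- regmatches(quals, regexec('/(gene|locus_tag)="?([^"]+)"?', quals))
    m <- Filter(length, m)
    if (length(m)) name <- m[[1L]][3L]
    list(location = loc, name = name)
  })
  if (!is.null(cds_name)) {
    features <- Filter(function(f) identical(f$name, cds_name), features)
    if (length(features) == 0L) stop("no CDS feature named '", cds_name, "'")
  } else if (length(features) > 1L) {
    stop(length(features), " CDS features present; select one with cds_name")
  }
  loc <- features[[1L]]$location
  strand <- if (grepl("complement", loc)) "-" else "+"
  spans <- regmatches(loc, gregexpr("[0-9]+\\.\\.[0-9]+", loc))[[1L]]
  if (length(spans) == 0L) stop("cannot parse CDS location: ", loc)
  parts <- do.call(rbind, lapply(strsplit(spans, "..", fixed = TRUE),
                                 as.integer))
  new_gene_model(data.frame(start = parts[, 1L] - 1L, end = parts[, 2L]),
                 strand, reference)
}

## ---------------------------------------------------------------------------
## Amplicon design

#' Load an amplicon design from BED
#'
#' BED intervals are 0-based half-open. An optional 4th column groups
#' segments that belong to the same fragment type: a paired-end amplicon
#' with an uncovered gap is given as two rows sharing one name.
#'
#' @param path BED file.
#' @param reference `Reference` used for bounds checking.
#' @return object of class `AmpliconDesign`: list of amplicons, each with
#'   `label` and a `segments` data.frame (`start`, `end`).
#' @export
load_amplicon_design <- function(path, reference) {
  if (!file.exists(path)) stop("amplicon design file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                 !startsWith(lines, "track")]
  if (length(lines) == 0L) stop("empty amplicon design: ", path)
  fields <- strsplit(lines, "\t|\\s+")
  start <- vapply(fields, function(f) as.integer(f[2L]), 0L)
  end <- vapply(fields, function(f) as.integer(f[3L]), 0L)
  label <- vapply(fields, function(f)
    if (length(f) >= 4L) f[4L] else NA_character_, "")
  label[is.na(label)] <- paste0("amplicon", which(is.na(label)))
  if (any(is.na(start)) || any(is.na(end)) || any(start < 0L) ||
      any(end <= start))
    stop("malformed BED interval in ", path)
  if (any(end > reference$length))
    stop("amplicon interval beyond reference end (", reference$length, " bp)")
  new_amplicon_design(data.frame(start = start, end = end, label = label,
                                 stringsAsFactors = FALSE))
}

#' @rdname load_amplicon_design
#' @param segments data.frame with `start`, `end` (0-based half-open) and
#'   `label`; rows sharing a label form one amplicon.
#' @export
new_amplicon_design <- function(segments) {
  segments <- as.data.frame(segments)
  amps <- lapply(split(segments, factor(segments$label,
                                        levels = unique(segments$label))),
                 function(d) {
                   d <- d[order(d$start), , drop = FALSE]
                   list(label = d$label[1L],
                        segments = d[, c("start", "end"), drop = FALSE])
                 })
  structure(list(amplicons = unname(amps)), class = "AmpliconDesign")
}

#' @export
print.AmpliconDesign <- function(x, ...) {
  cat(sprintf("<AmpliconDesign> %d amplicons\n", length(x$amplicons)))
  for (a in x$amplicons)
    cat(sprintf("  %s: %s\n", a$label,
                paste(sprintf("[%d,%d)", a$segments$start, a$segments$end),
                      collapse = " + ")))
  invisible(x)
}

# positions (0-based) covered by one amplicon's segment union
amplicon_positions <- function(amplicon) {
  unlist(mapply(seq.int, amplicon$segments$start, amplicon$segments$end - 1L,
                SIMPLIFY = FALSE), use.names = FALSE)
}

## ---------------------------------------------------------------------------
## Variant selection lists

#' Load a variant selection list
#'
#' One variant label per line, `#` comments allowed. Labels use the c.
#' dialect of the report (`c.749G>A`, `c.1423_1424ins35`,
#' `c.1086_1270del185`), with or without the `c.` prefix, or g.-prefixed
#' reference coordinates. Insertion/deletion labels carry a length, so a
#' selection entry is a matcher resolved against detected variants with
#' [resolve_selection()].
#'
#' @param path text file.
#' @param model optional `GeneModel`; required for c. labels.
#' @return data.frame of matchers with columns `kind`, `start` (0-based
#'   reference), `length`, `ref`, `alt`, `label`.
#' @export
load_variant_selection <- function(path, model = NULL) {
  if (!file.exists(path)) stop("variant selection file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  keep <- nzchar(lines) & !startsWith(lines, "#")
  out <- lapply(which(keep), function(i) {
    m <- parse_variant_label(lines[i], model)
    if (is.null(m))
      stop("line ", i, ": cannot parse variant label '", lines[i], "'")
    m
  })
  do.call(rbind, c(list(empty_selection()), out))
}

empty_selection <- function() {
  data.frame(kind = character(0), start = integer(0), length = integer(0),
             ref = character(0), alt = character(0), label = character(0),
             stringsAsFactors = FALSE)
}

#' Parse one variant label into a selection matcher
#'
#' @param label e.g. `"c.749G>A"`, `"749G>A"`, `"c.1423_1424ins35"`,
#'   `"g.1086_1270del185"`.
#' @param model optional `GeneModel` mapping c. coordinates to the reference.
#' @return one-row matcher data.frame, or `NULL` if the syntax is unknown.
#' @export
parse_variant_label <- function(label, model = NULL) {
  x <- gsub("\\s", "", label)
  genomic <- startsWith(x, "g.")
  body <- sub("^[cg]\\.", "", x)
  to_ref <- function(cpos) {
    # 1-based c./g. coordinate -> 0-based reference position
    if (genomic || is.null(model)) return(cpos - 1L)
    if (cpos < 1L || cpos > length(model$cds_positions))
      stop("coding position c.", cpos, " outside the CDS")
    model$cds_positions[cpos]
  }
  row <- function(kind, start, length, ref = NA_character_,
                  alt = NA_character_) {
    data.frame(kind = kind, start = as.integer(start),
               length = as.integer(length), ref = ref, alt = alt,
               label = label, stringsAsFactors = FALSE)
  }
  m <- regmatches(body, regexec("^([0-9]+)([ACGT])>([ACGT])$", body))[[1L]]
  if (length(m)) {
    start <- to_ref(as.integer(m[2L]))
    ref <- m[3L]; alt <- m[4L]
    if (!genomic && !is.null(model) && model$strand == "-") {
      ref <- comp_base(ref); alt <- comp_base(alt)
    }
    return(row("SNV", start, 1L, ref, alt))
  }
  m <- regmatches(body,
                  regexec("^([0-9]+)_([0-9]+)ins([0-9]+|[ACGT]+)$", body))[[1L]]
  if (length(m)) {
    len <- suppressWarnings(as.integer(m[4L]))
    alt <- if (is.na(len)) m[4L] else NA_character_
    if (is.na(len)) len <- nchar(m[4L])
    # anchored at the base after the insertion point
    return(row("INS", to_ref(as.integer(m[3L])), len, alt = alt))
  }
  m <- regmatches(body,
                  regexec("^([0-9]+)(_([0-9]+))?del([0-9]*)$", body))[[1L]]
  if (length(m)) {
    s <- as.integer(m[2L])
    e <- if (nzchar(m[4L])) as.integer(m[4L]) else s
    return(row("DEL", to_ref(s), e - s + 1L))
  }
  NULL
}

#' Resolve selection matchers against detected variant keys
#'
#' @param selection matcher data.frame from [load_variant_selection()]; an
#'   empty selection selects everything (`detected` is returned).
#' @param detected character vector of canonical variant keys.
#' @return subset of `detected` matching at least one entry, in position
#'   order; a warning names entries that match nothing.
#' @export
resolve_selection <- function(selection, detected) {
  detected <- sort_variant_keys(unique(detected))
  if (is.null(selection) || nrow(selection) == 0L) return(detected)
  hit <- rep(FALSE, length(detected))
  parsed <- lapply(detected, parse_variant_key)
  for (i in seq_len(nrow(selection))) {
    s <- selection[i, ]
    ok <- vapply(parsed, function(v) {
      if (v$kind != s$kind || v$start != s$start) return(FALSE)
      len <- max(nchar(v$ref), nchar(v$alt))
      if (len != s$length) return(FALSE)
      if (!is.na(s$ref) && v$ref != s$ref) return(FALSE)
      if (!is.na(s$alt) && v$alt != s$alt) return(FALSE)
      TRUE
    }, FALSE)
    if (!any(ok))
      warning("selected variant '", s$label, "' was not detected")
    hit <- hit | ok
  }
  detected[hit]
}

## ---------------------------------------------------------------------------
## SAM parsing

FLAG_PAIRED <- 0x1L
FLAG_UNMAPPED <- 0x4L
FLAG_REVERSE <- 0x10L
FLAG_MATE1 <- 0x40L
FLAG_MATE2 <- 0x80L
FLAG_SECONDARY <- 0x100L
FLAG_SUPPLEMENTARY <- 0x800L

cigar_ops <- function(cigar) {
  m <- gregexpr("[0-9]+[MIDNSHP=X]", cigar)[[1L]]
  if (m[1L] == -1L) return(NULL)
  toks <- regmatches(cigar, list(m))[[1L]]
  op <- substr(toks, nchar(toks), nchar(toks))
  len <- as.integer(substr(toks, 1L, nchar(toks) - 1L))
  # collapse adjacent identical operations ("3I2I" == "5I") so every run
  # yields exactly one variant downstream
  if (length(op) > 1L && any(op[-1L] == op[-length(op)])) {
    grp <- cumsum(c(TRUE, op[-1L] != op[-length(op)]))
    len <- as.integer(tapply(len, grp, sum))
    op <- op[!duplicated(grp)]
  }
  list(op = op, len = len)
}

QUERY_OPS <- c("M", "I", "S", "=", "X")
REF_OPS <- c("M", "D", "N", "=", "X")

#' Parse a SAM file into read alignments
#'
#' Accepts unpadded and padded dialects (pad `P` operations consume neither
#' query nor reference and are dropped at load, so a padded record yields the
#' same internal alignment as its unpadded equivalent). Unmapped, secondary
#' and supplementary records are skipped and counted; records on a different
#' reference than `reference$name` are skipped unless the file refers to a
#' single other target, which is then accepted with a warning. A header is
#' optional.
#'
#' @param path SAM file.
#' @param reference `Reference`.
#' @param paired if `TRUE`, mate flags are kept so fragments can be merged
#'   downstream; otherwise every record is its own fragment.
#' @return list of `ReadAlignment` objects (fields `qname`, `mate`, `flag`,
#'   `ref_start` 0-based, `ops`, `seq`), with a `load_report` attribute
#'   counting `records_in`, `records_used` and the skip reasons
#'   (`records_in = records_used + records_skipped` exactly).
#' @export
parse_alignment <- function(path, reference, paired = FALSE) {
  if (!file.exists(path)) stop("SAM file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "@")]
  n_in <- length(lines)
  skipped <- c(unmapped = 0L, secondary = 0L, supplementary = 0L,
               other_reference = 0L, malformed = 0L)
  if (n_in == 0L) {
    out <- list()
    attr(out, "load_report") <- c(records_in = 0L, records_used = 0L, skipped)
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  rnames <- vapply(fields, function(f) f[3L], "")
  known <- unique(rnames[rnames != "*"])
  accept_rname <- reference$name
  if (!reference$name %in% known && length(known) == 1L) {
    warning("SAM reference '", known, "' does not match '", reference$name,
            "'; accepting it as the single target")
    accept_rname <- known
  }
  out <- vector("list", n_in)
  used <- 0L
  for (i in seq_len(n_in)) {
    f <- fields[[i]]
    if (length(f) < 11L) { skipped["malformed"] <- skipped["malformed"] + 1L; next }
    flag <- suppressWarnings(as.integer(f[2L]))
    if (is.na(flag)) { skipped["malformed"] <- skipped["malformed"] + 1L; next }
    if (bitwAnd(flag, FLAG_UNMAPPED) != 0L) {
      skipped["unmapped"] <- skipped["unmapped"] + 1L; next
    }
    if (bitwAnd(flag, FLAG_SECONDARY) != 0L) {
      skipped["secondary"] <- skipped["secondary"] + 1L; next
    }
    if (bitwAnd(flag, FLAG_SUPPLEMENTARY) != 0L) {
      skipped["supplementary"] <- skipped["supplementary"] + 1L; next
    }
    if (f[3L] != accept_rname) {
      skipped["other_reference"] <- skipped["other_reference"] + 1L; next
    }
    ops <- cigar_ops(f[6L])
    seq <- toupper(f[10L])
    pos <- suppressWarnings(as.integer(f[4L])) - 1L
    bad <- is.null(ops) || is.na(pos) || pos < 0L || seq == "*" ||
      sum(ops$len[ops$op %in% QUERY_OPS]) != nchar(seq) ||
      pos + sum(ops$len[ops$op %in% REF_OPS]) > reference$length
    if (bad) { skipped["malformed"] <- skipped["malformed"] + 1L; next }
    # drop pads: consume neither query nor reference
    keep <- ops$op != "P"
    ops <- list(op = ops$op[keep], len = ops$len[keep])
    mate <- 0L
    if (paired && bitwAnd(flag, FLAG_PAIRED) != 0L)
      mate <- if (bitwAnd(flag, FLAG_MATE1) != 0L) 1L else 2L
    used <- used + 1L
    out[[used]] <- structure(list(qname = f[1L], mate = mate, flag = flag,
                                  ref_start = pos, ops = ops, seq = seq),
                             class = "ReadAlignment")
  }
  if (skipped["malformed"] > max(1L, n_in %/% 100L))
    stop(skipped["malformed"], " of ", n_in,
         " SAM records are malformed (>1%); aborting")
  out <- out[seq_len(used)]
  attr(out, "load_report") <- c(records_in = n_in, records_used = used,
                                skipped)
  out
}
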