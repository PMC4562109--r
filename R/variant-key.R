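# Canonical variant keys.
#
# A variant is identified throughout the package by a plain-text key that is
# a pure function of (kind, start, ref, alt):
#
#   SNV:<start>:<ref>:<alt>   single-nucleotide substitution at 0-based start
#   DEL:<start>:<ref>:        deletion of ref starting at 0-based start
#   INS:<start>::<alt>        insertion of alt before 0-based position start
#
# Keys are the haplotype identity; human-readable c./g. labels are derived
# from keys by the annotation layer and never fed back into counting.

#' Build a canonical variant key
#'
#' @param kind one of `"SNV"`, `"INS"`, `"DEL"`.
#' @param start 0-based reference position. For an insertion this is the
#'   position of the reference base immediately *after* the insertion point.
#' @param ref reference allele (`""` for insertions).
#' @param alt alternate allele (`""` for deletions).
#' @return character scalar key.
#' @examples
#' variant_key("SNV", 748, "G", "A")
#' @export
variant_key <- function(kind, start, ref = "", alt = "") {
  kind <- match.arg(kind, c("SNV", "INS", "DEL"))
  if (kind == "SNV" && (nchar(ref) != 1L || nchar(alt) != 1L || ref == alt))
    stop("SNV requires single, differing ref and alt alleles")
  if (kind == "INS" && (nzchar(ref) || !nzchar(alt)))
    stop("INS requires empty ref and non-empty alt")
  if (kind == "DEL" && (!nzchar(ref) || nzchar(alt)))
    stop("DEL requires non-empty ref and empty alt")
  sprintf("%s:%d:%s:%s", kind, as.integer(start), ref, alt)
}

#' Parse a canonical variant key
#'
#' @param key character scalar produced by [variant_key()].
#' @return list with `kind`, `start` (0-based), `ref`, `alt`.
#' @export
parse_variant_key <- function(key) {
  parts <- strsplit(key, ":", fixed = TRUE)[[1L]]
  if (length(parts) < 2L) stop("malformed variant key: ", key)
  list(kind = parts[1L], start = as.integer(parts[2L]),
       ref = if (length(parts) >= 3L) parts[3L] else "",
       alt = if (length(parts) >= 4L) parts[4L] else "")
}

# 0-based reference positions a fragment must cover to assert presence or
# absence of the variant. An insertion is anchored between start-1 and start:
# an alignment spanning both without an insertion operation contradicts it.
variant_positions <- function(key) {
  v <- parse_variant_key(key)
  switch(v$kind,
    SNV = v$start,
    DEL = seq.int(v$start, v$start + nchar(v$ref) - 1L),
    INS = unique(pmax(0L, c(v$start - 1L, v$start))),
    stop("unknown variant kind: ", v$kind))
}

#' @rdname sort_variant_keys
#' @export
variant_start <- function(keys) {
  as.integer(vapply(strsplit(keys, ":", fixed = TRUE),
                    function(p) p[2L], ""))
}

#' Key utilities
#'
#' `variant_start()` extracts the 0-based start positions of a key vector;
#' `sort_variant_keys()` orders keys deterministically (position, then kind,
#' then alleles); `haplotype_id()` collapses a variant set into the
#' canonical haplotype identifier used in `HaplotypeTable` rows;
#' `haplotype_members()` splits it back.
#'
#' @param keys character vector of canonical variant keys.
#' @return see description.
#' @export
sort_variant_keys <- function(keys) {
  if (length(keys) == 0L) return(character(0))
  keys[order(variant_start(keys), keys)]
}

#' @rdname sort_variant_keys
#' @export
haplotype_id <- function(keys) {
  paste(sort_variant_keys(keys), collapse = "|")
}

#' @rdname sort_variant_keys
#' @param id haplotype identifier from `haplotype_id()`.
#' @export
haplotype_members <- function(id) {
  if (!nzchar(id)) character(0) else strsplit(id, "|", fixed = TRUE)[[1L]]
}
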