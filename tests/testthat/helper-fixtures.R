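# Shared fixture builders. Everything is generated in code; no binary data.

`%&%` <- function(a, b) paste0(a, b)

base_at <- function(reference, pos) {
  substr(reference$sequence, pos + 1L, pos + 1L)
}

other_base <- function(b) {
  setdiff(c("A", "C", "G", "T"), b)[1L]
}

snv_at <- function(reference, pos, alt = NULL) {
  ref <- base_at(reference, pos)
  if (is.null(alt)) alt <- other_base(ref)
  variant_key("SNV", pos, ref, alt)
}

# a bare ReadAlignment without going through a SAM file
make_read <- function(qname, ref_start, cigar, seq, mate = 0L, flag = 0L) {
  structure(list(qname = qname, mate = mate, flag = flag,
                 ref_start = ref_start,
                 ops = ampliclone:::cigar_ops(cigar), seq = seq),
            class = "ReadAlignment")
}

# one SAM record line (1-based pos in the file)
sam_line <- function(qname, flag, rname, pos0, cigar, seq,
                     rnext = "*", pnext = 0L) {
  sprintf("%s\t%d\t%s\t%d\t60\t%s\t%s\t%d\t0\t%s\t*",
          qname, flag, rname, pos0 + 1L, cigar, rnext, pnext, seq)
}

write_sam <- function(lines, reference, path = tempfile(fileext = ".sam"),
                      header = TRUE) {
  if (header)
    lines <- c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", reference$name,
                       reference$length), lines)
  writeLines(lines, path)
  path
}

# fragment built directly (cov intervals given as list of c(start, end))
make_fragment <- function(key, intervals, variants = character(0),
                          masked = integer(0)) {
  ampliclone:::new_fragment(key, do.call(rbind, intervals), masked, variants)
}

# Fig 3a-style scattered-haplotype world: three variants, three overlapping
# amplicons (the third a gapped mate pair covering p1 and p3 but not p2)
scattered_fixture <- function(seed = 11L) {
  ref <- random_reference(90L, seed)
  v <- c(snv_at(ref, 10L), snv_at(ref, 45L), snv_at(ref, 80L))
  design <- new_amplicon_design(data.frame(
    start = c(0L, 30L, 0L, 60L), end = c(60L, 90L, 30L, 90L),
    label = c("A", "B", "C", "C")))
  truth <- list(clone_truth(v[c(1L, 3L)], 2 / 7),
                clone_truth(v, 1 / 7),
                clone_truth(character(0), 4 / 7))
  list(reference = ref, variants = v, design = design, truth = truth)
}

# run simulate -> SAM -> parse -> observations -> fragments
sim_to_fragments <- function(sim, paired = FALSE) {
  sam <- tempfile(fileext = ".sam")
  write_alignment(sim, sam)
  reads <- parse_alignment(sam, sim$reference, paired = paired)
  obs <- lapply(reads, function(r) {
    normalize_indels(call_read_variants(r, sim$reference), sim$reference)
  })
  assemble_fragments(obs, paired = paired)
}
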