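test_that("variant keys are pure, parseable and sortable", {
  k <- variant_key("SNV", 748, "G", "A")
  expect_equal(k, "SNV:748:G:A")
  expect_equal(parse_variant_key(k),
               list(kind = "SNV", start = 748L, ref = "G", alt = "A"))
  expect_error(variant_key("SNV", 1, "G", "G"))
  expect_error(variant_key("INS", 1, "A", "C"))
  expect_error(variant_key("DEL", 1, "", ""))
  keys <- c("SNV:100:A:C", "DEL:20:AC:", "INS:100::T", "SNV:5:G:T")
  expect_equal(sort_variant_keys(keys)[1L], "SNV:5:G:T")
  expect_equal(variant_start(sort_variant_keys(keys)), c(5L, 20L, 100L, 100L))
})

test_that("call_read_variants walks operations correctly", {
  ref <- new_reference("r", "ACGTACGTACGTACGTACGT")  # 20 bp
  # identity
  obs <- call_read_variants(make_read("a", 4L, "12M",
                                      substr(ref$sequence, 5, 16)), ref)
  expect_length(obs$variants, 0L)
  expect_equal(obs$cov, rbind(c(4L, 16L)))
  # SNV + soft clip + N masking; window [2,11) of ref is GTACGTACG
  seq <- "GGGTACGNACT"  # 2 clipped bases, N at position 7, SNV at 10
  obs <- call_read_variants(make_read("b", 2L, "2S9M", seq), ref)
  expect_equal(obs$cov, rbind(c(2L, 11L)))
  expect_equal(obs$masked, 7L)
  expect_equal(obs$variants, "SNV:10:G:T")
  # insertion anchored at following reference position; deletion covered
  seq <- paste0(substr(ref$sequence, 1, 4), "TTT",
                substr(ref$sequence, 5, 8), substr(ref$sequence, 12, 14))
  obs <- call_read_variants(make_read("c", 0L, "4M3I4M3D3M", seq), ref)
  expect_setequal(obs$variants, c("INS:4::TTT", "DEL:8:ACG:"))
  expect_equal(obs$cov, rbind(c(0L, 14L)))  # deletion span stays covered
})

test_that("call_read_variants agrees with the padded-matrix oracle on random reads", {
  ref <- random_reference(300L, 99L)
  set.seed(1234)
  for (i in 1:120) {
    # random alignment: start, blocks of M with random edits via CIGAR
    s <- sample(0:150, 1)
    ops <- c("M", sample(c("M", "I", "D", "S"), 4, replace = TRUE,
                         prob = c(.5, .2, .2, .1)), "M")
    lens <- sample(1:25, length(ops), replace = TRUE)
    # build a consistent query: walk reference, mutate some bases
    q <- character(0); r <- s
    for (j in seq_along(ops)) {
      if (ops[j] == "M") {
        chunk <- strsplit(substr(ref$sequence, r + 1, r + lens[j]), "")[[1]]
        flip <- runif(lens[j]) < 0.15
        chunk[flip] <- vapply(chunk[flip], other_base, "")
        if (runif(1) < 0.2) chunk[sample(lens[j], 1)] <- "N"
        q <- c(q, chunk); r <- r + lens[j]
      } else if (ops[j] %in% c("I", "S")) {
        q <- c(q, sample(c("A", "C", "G", "T"), lens[j], replace = TRUE))
      } else r <- r + lens[j]
    }
    if (r > ref$length) next
    read <- make_read(paste0("rr", i), s,
                      paste0(lens, ops, collapse = ""), paste(q, collapse = ""))
    got <- call_read_variants(read, ref)
    expect_equal(sort_variant_keys(got$variants),
                 oracle_read_variants(read, ref))
  }
})

test_that("normalize_indels left-aligns and is idempotent", {
  ref <- new_reference("r", "GCAAATGCGCGCTA")
  # DEL of one A placed at the last A of the homopolymer -> first A
  expect_equal(normalize_indels("DEL:4:A:", ref), "DEL:2:A:")
  # already left-aligned stays put
  expect_equal(normalize_indels("DEL:2:A:", ref), "DEL:2:A:")
  # insertion of GC inside the GC repeat shifts to the repeat start
  expect_equal(normalize_indels("INS:10::GC", ref), "INS:6::GC")
  # idempotence + oracle agreement on random repeats
  set.seed(77)
  for (i in 1:150) {
    rr <- new_reference("r", paste(sample(c("A", "C"), 40, replace = TRUE),
                                   collapse = ""))
    if (runif(1) < 0.5) {
      s <- sample(0:35, 1); L <- sample(1:4, 1)
      if (s + L > 40) next
      key <- variant_key("DEL", s, ref = ref_chars <- substr(rr$sequence,
                                                             s + 1, s + L))
    } else {
      s <- sample(1:39, 1)
      key <- variant_key("INS", s, alt = paste(
        sample(c("A", "C"), sample(1:3, 1), replace = TRUE), collapse = ""))
    }
    norm <- normalize_indels(key, rr)
    expect_equal(norm, oracle_left_align(key, rr))
    expect_equal(normalize_indels(norm, rr), norm)
  }
})

test_that("combine_variants groups consecutive and same-codon SNVs", {
  ref <- random_reference(300L, 3L)
  tab <- tempfile(); writeLines("CDS 1 300 +", tab)
  gm <- load_gene_model(tab, ref)
  # c.10 and c.11 (0-based 9, 10): consecutive
  out <- combine_variants(c(snv_at(ref, 9L), snv_at(ref, 10L)), gm, ref)
  expect_length(out, 1L)
  expect_equal(out[[1L]]$reason, "consecutive")
  expect_length(out[[1L]]$members, 2L)
  expect_match(out[[1L]]$combined_label, "^c\\.10_11")
  # c.7 and c.9: same codon 3, not adjacent
  out <- combine_variants(c(snv_at(ref, 6L), snv_at(ref, 8L)), gm, ref)
  expect_length(out, 1L)
  expect_equal(out[[1L]]$reason, "same_codon")
  # c.10 and c.20: nothing to combine
  out <- combine_variants(c(snv_at(ref, 9L), snv_at(ref, 19L)), gm, ref)
  expect_length(out, 2L)
  expect_true(all(vapply(out, `[[`, "", "reason") == "single"))
})

test_that("annotation reproduces the published label dialect", {
  ref <- random_reference(2000L, 5L)
  tab <- tempfile(); writeLines("CDS 1 1800 +", tab)
  gm <- load_gene_model(tab, ref)
  # 185 bp deletion spanning c.1086-c.1270
  del <- variant_key("DEL", 1085L, ref = ref_chars <- substr(ref$sequence,
                                                             1086, 1270))
  expect_equal(annotate_variant(del, gm, ref)$cds_label, "c.1086_1270del185")
  # 35 bp insertion between c.1423 and c.1424 (0-based anchor 1423)
  ins <- variant_key("INS", 1423L, alt = strrep("CAT", 12) %&% "AA")
  ann <- annotate_variant(ins, gm, ref)
  expect_equal(ann$cds_label, sprintf("c.1423_1424ins%d", 38L))
  ins35 <- variant_key("INS", 1423L, alt = strrep("A", 35))
  expect_equal(annotate_variant(ins35, gm, ref)$cds_label,
               "c.1423_1424ins35")
  # SNV label
  snv <- snv_at(ref, 748L)
  expect_equal(annotate_variant(snv, gm, ref)$cds_label,
               sprintf("c.749%s>%s", base_at(ref, 748L),
                       other_base(base_at(ref, 748L))))
  # outside the CDS -> g. label, 1-based
  far <- snv_at(ref, 1900L)
  expect_match(annotate_variant(far, gm, ref)$cds_label, "^g\\.1901")
})

test_that("amino-acid labels translate ref and alt codons", {
  # codon 315 is ACT (threonine); c.943A>G makes it GCT (alanine)
  seq <- strrep("GCT", 400)                 # 1200 bp of alanine codons
  substr(seq, 943, 945) <- "ACT"            # codon 315 = positions 943-945
  ref <- new_reference("r", seq)
  tab <- tempfile(); writeLines("CDS 1 1200 +", tab)
  gm <- load_gene_model(tab, ref)
  k <- variant_key("SNV", 942L, "A", "G")   # c.943 is 0-based 942
  expect_equal(annotate_variant(k, gm, ref)$aa_label, "T315A")
  # frameshift deletion and in-frame deletion markers
  expect_match(variant_aa_label <- annotate_variant(
    variant_key("DEL", 942L, ref = "AC"), gm, ref)$aa_label, "fs$")
  expect_match(annotate_variant(variant_key("DEL", 942L, ref = "ACT"),
                                gm, ref)$aa_label, "del$")
})

test_that("labels round-trip through the selection parser (bijectivity)", {
  ref <- random_reference(1000L, 8L)
  tab <- tempfile(); writeLines("CDS 1 900 +", tab)
  gm <- load_gene_model(tab, ref)
  keys <- c(snv_at(ref, 100L), snv_at(ref, 500L),
            variant_key("DEL", 200L, ref = substr(ref$sequence, 201, 232)),
            variant_key("INS", 400L, alt = strrep("TG", 10)))
  for (k in keys) {
    label <- annotate_variant(k, gm, ref)$cds_label
    matcher <- parse_variant_label(label, gm)
    expect_false(is.null(matcher))
    expect_equal(resolve_selection(matcher, keys), k)
  }
})
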