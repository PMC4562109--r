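# Filtering, formatting, CSV export, and pipeline orchestration.

#' Drop haplotype rows below a reporting threshold
#'
#' @param table quantified `HaplotypeTable`.
#' @param min_percent reporting threshold in percent (default 1, the usual
#'   investigation cut-off for ultra-deep amplicon data; 0 disables).
#' @return the filtered table; the number of dropped rows is reported via
#'   a message and kept in attribute `dropped`.
#' @export
apply_threshold <- function(table, min_percent = 1) {
  keep <- table$rows$percentage >= min_percent
  dropped <- sum(!keep)
  if (dropped > 0L)
    message(dropped, " haplotype row(s) below ", min_percent, "% dropped")
  table$rows <- table$rows[keep, , drop = FALSE]
  rownames(table$rows) <- NULL
  if (nrow(table$rows) == 0L && min_percent > 0)
    warning("all haplotype rows fell below the ", min_percent,
            "% threshold; only the wild-type estimate remains")
  attr(table, "dropped") <- dropped
  table
}

#' Build a clone report from a quantified table
#'
#' Rows are sorted by percentage descending (ties by variant position
#' tuple), annotated with c./g. and amino-acid labels plus the combined
#' (consecutive / same-codon) display form, and the wild-type row is
#' appended last.
#'
#' @param table quantified (and optionally thresholded) `HaplotypeTable`.
#' @param model optional `GeneModel` for annotation.
#' @param reference optional `Reference`.
#' @param metadata named character vector written as `#` comment lines.
#' @return object of class `CloneReport`: `rows` data.frame (`variants`,
#'   `combined`, `cds_changes`, `aa_changes`, `alleles`, `hits`,
#'   `percentage`, `inferred`), `wildtype_percentage`, `metadata`.
#' @export
build_report <- function(table, model = NULL, reference = NULL,
                         metadata = character(0)) {
  rows <- table$rows
  ord <- order(-rows$percentage,
               vapply(rows$id, function(id)
                 paste(sprintf("%09d", variant_start(haplotype_members(id))),
                       collapse = ","), ""))
  rows <- rows[ord, , drop = FALSE]
  ann <- lapply(rows$id, function(id) {
    members <- haplotype_members(id)
    cds <- vapply(members, variant_cds_label, "", model = model,
                  reference = reference)
    aa <- vapply(members, variant_aa_label, "", model = model)
    comb <- combine_variants(members, model, reference)
    alleles <- vapply(members, function(k) {
      v <- parse_variant_key(k)
      if (v$kind == "INS") v$alt else if (v$kind == "DEL") v$ref else ""
    }, "")
    list(variants = paste(cds, collapse = ", "),
         combined = paste(vapply(comb, `[[`, "", "combined_label"),
                          collapse = ", "),
         cds_changes = paste(cds, collapse = ", "),
         aa_changes = paste(aa[nzchar(aa)], collapse = ", "),
         alleles = paste(alleles[nzchar(alleles)], collapse = ", "))
  })
  df <- data.frame(
    variants = vapply(ann, `[[`, "", "variants"),
    combined = vapply(ann, `[[`, "", "combined"),
    cds_changes = vapply(ann, `[[`, "", "cds_changes"),
    aa_changes = vapply(ann, `[[`, "", "aa_changes"),
    alleles = vapply(ann, `[[`, "", "alleles"),
    hits = rows$hits, percentage = rows$percentage,
    inferred = rows$inferred, stringsAsFactors = FALSE)
  rownames(df) <- NULL
  structure(list(rows = df, wildtype_percentage = table$wildtype_percentage,
                 metadata = metadata, ids = rows$id),
            class = "CloneReport")
}

#' @export
print.CloneReport <- function(x, ...) {
  cat("<CloneReport>\n")
  if (nrow(x$rows)) {
    shown <- x$rows[, c("variants", "hits", "percentage", "inferred")]
    shown$percentage <- sprintf("%.1f", shown$percentage)
    print(shown, right = FALSE)
  }
  cat(sprintf("wild type: %.1f%%\n", x$wildtype_percentage))
  invisible(x)
}

#' Export a clone report to CSV
#'
#' Metadata becomes leading `#` comment lines; percentages are printed with
#' one decimal (full precision lives in the `CloneReport`); the wild-type
#' row comes last. Output is byte-identical across runs on identical input
#' (stable sort, fixed formatting, no timestamps).
#'
#' @param report `CloneReport`.
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
export_report <- function(report, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (nm in names(report$metadata))
    writeLines(sprintf("# %s: %s", nm, report$metadata[[nm]]), con)
  header <- c("variants", "combined", "cds_changes", "aa_changes",
              "alleles", "hits", "percentage", "inferred")
  writeLines(paste(header, collapse = ","), con)
  if (nrow(report$rows)) {
    body <- report$rows
    lines <- sprintf('"%s","%s","%s","%s","%s",%d,%.1f,%s',
                     body$variants, body$combined, body$cds_changes,
                     body$aa_changes, body$alleles, body$hits,
                     body$percentage, ifelse(body$inferred, "yes", "no"))
    writeLines(lines, con)
  }
  writeLines(sprintf('"wild type","","","","",,%.1f,',
                     report$wildtype_percentage), con)
  invisible(path)
}

#' Re-parse an exported clone report
#'
#' @param path CSV written by [export_report()].
#' @return `CloneReport` with percentages at the printed (1-decimal)
#'   precision.
#' @export
parse_report <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta_lines <- lines[startsWith(lines, "#")]
  metadata <- character(0)
  if (length(meta_lines)) {
    km <- regmatches(meta_lines, regexec("^# ([^:]+): (.*)$", meta_lines))
    metadata <- stats::setNames(vapply(km, `[`, "", 3L),
                                vapply(km, `[`, "", 2L))
  }
  body <- read.csv(text = lines[!startsWith(lines, "#")],
                   stringsAsFactors = FALSE, colClasses = "character")
  wt_i <- which(body$variants == "wild type")
  wt <- as.numeric(body$percentage[wt_i])
  rows <- body[-wt_i, , drop = FALSE]
  rows$hits <- as.integer(rows$hits)
  rows$percentage <- as.numeric(rows$percentage)
  rows$inferred <- rows$inferred == "yes"
  rownames(rows) <- NULL
  structure(list(rows = rows, wildtype_percentage = wt, metadata = metadata,
                 ids = NULL),
            class = "CloneReport")
}

#' Run the full analysis pipeline
#'
#' Load reference (and optional annotation, amplicon design, variant
#' selection), parse the SAM alignments, extract and left-align per-read
#' variants, merge mates into fragments, tabulate haplotypes (or infer
#' scattered ones over an amplicon design), quantify, threshold, and
#' optionally export CSV. Stage counts are collected in the report
#' metadata.
#'
#' @param sam SAM file path.
#' @param ref reference FASTA path (or a `Reference`).
#' @param annotation optional annotation file path (or a `GeneModel`).
#' @param amplicons optional BED path (or an `AmpliconDesign`).
#' @param variants optional variant selection file path (or a matcher
#'   data.frame from [load_variant_selection()], or a character vector of
#'   canonical keys).
#' @param paired treat alignments as mate pairs.
#' @param infer reconnect haplotypes over the amplicon design (requires
#'   `amplicons`).
#' @param min_percent reporting threshold (default 1).
#' @param denominator `"informative"` or `"sum_positions"`.
#' @param max_rounds,max_clique_variants inference caps (defaults 15, 20).
#' @param out optional CSV output path.
#' @return `CloneReport`.
#' @export
run_pipeline <- function(sam, ref, annotation = NULL, amplicons = NULL,
                         variants = NULL, paired = FALSE, infer = FALSE,
                         min_percent = 1, denominator = "informative",
                         max_rounds = 15L, max_clique_variants = 20L,
                         out = NULL) {
  if (infer && is.null(amplicons))
    stop("--infer requires an amplicon design (--amplicons): without the ",
         "amplicon positions, scattered haplotypes cannot be reconnected")
  reference <- if (inherits(ref, "Reference")) ref else load_reference(ref)
  model <- if (is.null(annotation) || inherits(annotation, "GeneModel"))
    annotation else load_gene_model(annotation, reference)
  design <- if (is.null(amplicons) || inherits(amplicons, "AmpliconDesign"))
    amplicons else load_amplicon_design(amplicons, reference)
  reads <- parse_alignment(sam, reference, paired = paired)
  load_report <- attr(reads, "load_report")
  observations <- lapply(reads, function(r)
    normalize_indels(call_read_variants(r, reference), reference))
  fragments <- assemble_fragments(observations, paired = paired)
  detected <- detect_variant_table(fragments)
  selected <- if (is.null(variants)) {
    detected$key
  } else if (is.character(variants) && length(variants) == 1L &&
             file.exists(variants)) {
    resolve_selection(load_variant_selection(variants, model), detected$key)
  } else if (is.data.frame(variants)) {
    resolve_selection(variants, detected$key)
  } else {
    sort_variant_keys(intersect(detected$key, variants))
  }
  table <- if (infer) {
    infer_scattered(fragments, selected, design, max_rounds = max_rounds,
                    max_variants = max_clique_variants)
  } else {
    tabulate_haplotypes(fragments, selected)
  }
  table <- quantify_table(table, fragments, denominator_mode = denominator)
  table <- apply_threshold(table, min_percent)
  metadata <- c(tool = "ampliclone",
                version = as.character(utils::packageVersion("ampliclone")),
                reference = reference$name,
                records_in = unname(load_report["records_in"]),
                records_used = unname(load_report["records_used"]),
                fragments = length(fragments),
                selected_variants = length(selected),
                mode = table$mode,
                denominator = denominator,
                min_percent = format(min_percent))
  report <- build_report(table, model, reference, metadata = metadata)
  if (!is.null(out)) export_report(report, out)
  report
}
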