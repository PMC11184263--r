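#' Read a per-species differential-expression table
#'
#' Reads a TSV with columns `gene_id`, `log2fc`, `fdr`. An optional
#' metadata header line `# contrast: <tissue1>_vs_<tissue2>` declares the
#' contrast orientation (positive log2fc = higher in tissue1) and is
#' stored in the `contrast` attribute; [conserved_de()] refuses to
#' combine tables whose declared orientations differ.
#'
#' @param path path to the table.
#' @return data.frame with `gene_id`, `log2fc`, `fdr` and a `contrast`
#'   attribute (`NA` when undeclared).
#' @export
read_de_table <- function(path) {
  if (!file.exists(path)) stop_ck("DE table not found: ", path)
  first <- readLines(path, n = 1)
  contrast <- if (grepl("^#\\s*contrast:", first))
    trimws(sub("^#\\s*contrast:", "", first)) else NA_character_
  tab <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
  names(tab)[1:3] <- c("gene_id", "log2fc", "fdr")
  if (any(tab$fdr < 0 | tab$fdr > 1)) stop_ck("fdr outside [0, 1]")
  attr(tab, "contrast") <- contrast
  tab
}

#' Write a differential-expression table with contrast metadata
#'
#' @param de data.frame with `gene_id`, `log2fc`, `fdr`.
#' @param path output path.
#' @param contrast contrast label written to the metadata header.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(de, path, contrast = attr(de, "contrast")) {
  con <- file(path, "wt")
  on.exit(close(con))
  if (!is.null(contrast) && !is.na(contrast))
    writeLines(paste0("# contrast: ", contrast), con)
  writeLines(paste(c("gene_id", "log2fc", "fdr"), collapse = "\t"), con)
  writeLines(paste(de$gene_id, de$log2fc, de$fdr, sep = "\t"), con)
  invisible(path)
}

reduce_to_min_fdr <- function(de) {
  ord <- order(de$gene_id, de$fdr)
  sorted <- de[ord, , drop = FALSE]
  sorted[!duplicated(sorted$gene_id), , drop = FALSE]
}

#' Cross-species conserved differential expression filter
#'
#' An ortholog pair shows conserved tissue-specific expression when the
#' change is strong in one species and at least nominally significant in
#' the other: the strict criterion (FDR and absolute log2 fold change)
#' must hold in one species and the relaxed criterion (FDR only) in the
#' other, in either assignment of roles, and by default the fold-change
#' signs must agree. All thresholds are inclusive (`<=`, `>=`).
#'
#' Genes with multiple table rows (isoform-level statistics) are reduced
#' to the row with minimum FDR before filtering. Pairs whose genes are
#' missing from either table are skipped and counted.
#'
#' @param de_a,de_b DE tables for species A and B (see
#'   [read_de_table()]); an identical declared contrast orientation is
#'   required when both declare one.
#' @param pairs ortholog pairs data.frame with `gene_a`, `gene_b`.
#' @param strict_fdr,strict_lfc strict-species thresholds (default FDR
#'   <= 0.001 and |log2FC| >= 2).
#' @param relaxed_fdr relaxed-species threshold (default FDR <= 0.01).
#' @param require_direction require `sign(log2fc_a) == sign(log2fc_b)`;
#'   disable only for sensitivity analysis.
#' @return data.frame with one row per conserved pair: `gene_a`,
#'   `gene_b`, `direction` (`up_tissue1`/`up_tissue2`), `strong_species`
#'   (`"A"`, `"B"`, or `"AB"` when both satisfy the strict criterion),
#'   per-species `log2fc_*` and `fdr_*`. Attribute `n_skipped` counts
#'   pairs unresolvable in the tables.
#' @export
conserved_de <- function(de_a, de_b, pairs,
                         strict_fdr = 0.001, strict_lfc = 2,
                         relaxed_fdr = 0.01, require_direction = TRUE) {
  ca <- attr(de_a, "contrast"); cb <- attr(de_b, "contrast")
  if (!is.null(ca) && !is.null(cb) && !is.na(ca) && !is.na(cb) && ca != cb)
    stop_ck("contrast orientation mismatch: '", ca, "' vs '", cb, "'")
  de_a <- reduce_to_min_fdr(de_a)
  de_b <- reduce_to_min_fdr(de_b)
  ia <- match(pairs$gene_a, de_a$gene_id)
  ib <- match(pairs$gene_b, de_b$gene_id)
  resolvable <- !is.na(ia) & !is.na(ib)
  n_skipped <- sum(!resolvable)
  ia <- ia[resolvable]; ib <- ib[resolvable]
  p <- pairs[resolvable, , drop = FALSE]
  lfc_a <- de_a$log2fc[ia]; fdr_a <- de_a$fdr[ia]
  lfc_b <- de_b$log2fc[ib]; fdr_b <- de_b$fdr[ib]
  strict_a <- fdr_a <= strict_fdr & abs(lfc_a) >= strict_lfc
  strict_b <- fdr_b <= strict_fdr & abs(lfc_b) >= strict_lfc
  relaxed_a <- fdr_a <= relaxed_fdr
  relaxed_b <- fdr_b <= relaxed_fdr
  qualifies <- (strict_a & relaxed_b) | (strict_b & relaxed_a)
  if (require_direction) qualifies <- qualifies & sign(lfc_a) == sign(lfc_b)
  out <- data.frame(
    gene_a = p$gene_a[qualifies], gene_b = p$gene_b[qualifies],
    direction = as.character(
      ifelse(lfc_a[qualifies] > 0, "up_tissue1", "up_tissue2")),
    strong_species = as.character(
      ifelse(strict_a[qualifies] & strict_b[qualifies],
             "AB", ifelse(strict_a[qualifies], "A", "B"))),
    log2fc_a = lfc_a[qualifies], fdr_a = fdr_a[qualifies],
    log2fc_b = lfc_b[qualifies], fdr_b = fdr_b[qualifies],
    stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Joined expression matrix over ortholog pairs
#'
#' Joins two per-sample expression (TPM) tables on ortholog pairs,
#' producing a pairs x samples matrix of `log2(TPM + 1)` values suitable
#' as input to a principal component analysis. Pairs whose gene is
#' missing from either table are dropped and counted.
#'
#' @param tpm_a,tpm_b numeric matrices (genes x samples) of TPM values,
#'   with rownames = gene ids and colnames = sample labels.
#' @param pairs ortholog pairs data.frame with `gene_a`, `gene_b`.
#' @return Matrix with one row per retained pair (rownames
#'   `gene_a|gene_b`) and the columns of both sample sets; attribute
#'   `n_dropped` counts pairs lost to missing genes.
#' @export
pca_input_matrix <- function(tpm_a, tpm_b, pairs) {
  ia <- match(pairs$gene_a, rownames(tpm_a))
  ib <- match(pairs$gene_b, rownames(tpm_b))
  keep <- !is.na(ia) & !is.na(ib)
  m <- cbind(log2(tpm_a[ia[keep], , drop = FALSE] + 1),
             log2(tpm_b[ib[keep], , drop = FALSE] + 1))
  rownames(m) <- paste(pairs$gene_a[keep], pairs$gene_b[keep], sep = "|")
  attr(m, "n_dropped") <- sum(!keep)
  m
}
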