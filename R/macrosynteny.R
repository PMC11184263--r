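#' Place ortholog pairs on their genomes
#'
#' Joins ortholog pairs with two gene annotations to obtain, per pair,
#' the species-A scaffold and species-B chromosome holding the genes and
#' the gene midpoint positions. Pairs with a gene missing from either
#' annotation are skipped and counted.
#'
#' @param pairs ortholog pairs data.frame with `gene_a`, `gene_b`.
#' @param genes_a,genes_b gene tables (see [read_gff3_genes()]) for
#'   species A and B.
#' @return data.frame with `gene_a`, `gene_b`, `scaffold_a`,
#'   `position_a`, `chromosome_b`, `position_b`; attribute `n_skipped`.
#' @export
place_orthologs <- function(pairs, genes_a, genes_b) {
  ia <- match(pairs$gene_a, genes_a$gene_id)
  ib <- match(pairs$gene_b, genes_b$gene_id)
  keep <- !is.na(ia) & !is.na(ib)
  ia <- ia[keep]; ib <- ib[keep]
  out <- data.frame(
    gene_a = pairs$gene_a[keep], gene_b = pairs$gene_b[keep],
    scaffold_a = genes_a$seqid[ia],
    position_a = (genes_a$start[ia] + genes_a$end[ia]) / 2,
    chromosome_b = genes_b$seqid[ib],
    position_b = (genes_b$start[ib] + genes_b$end[ib]) / 2,
    stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- sum(!keep)
  out
}

#' Assign scaffolds to reference chromosomes by ortholog enrichment
#'
#' For every (scaffold, chromosome) cell holding at least `min_orthologs`
#' shared orthologs, a one-sided hypergeometric enrichment p-value is
#' computed from the contingency of orthologs on that scaffold vs that
#' chromosome against the genome-wide totals, then Benjamini-Hochberg
#' corrected across all tested cells. A cell is significant when its
#' q-value is `<= alpha`. Each scaffold's primary chromosome is its most
#' ortholog-rich significant cell (ties resolve by smaller q-value, then
#' lexicographic chromosome id, and are logged in the `n_ties`
#' attribute).
#'
#' With a single reference chromosome the enrichment test is vacuous
#' (every cell saturates its margins); cells meeting the ortholog floor
#' are then assigned deterministically with `NA` p-values.
#'
#' @param placements data.frame from [place_orthologs()].
#' @param alpha significance level after BH correction.
#' @param min_orthologs minimum shared orthologs for a cell to be tested
#'   (avoids degenerate single-gene blocks).
#' @return data.frame with one row per tested cell: `scaffold_a`,
#'   `chromosome_b`, `n_shared`, `p_value`, `q_value`, `significant`,
#'   `primary` (TRUE on the scaffold's primary-chromosome cell).
#' @export
assign_scaffolds <- function(placements, alpha = 0.05, min_orthologs = 3L) {
  if (nrow(placements) == 0) stop_ck("no placements")
  tab <- table(placements$scaffold_a, placements$chromosome_b)
  total <- sum(tab)
  scaffold_tot <- rowSums(tab)
  chrom_tot <- colSums(tab)
  cells <- which(tab >= min_orthologs, arr.ind = TRUE)
  if (nrow(cells) == 0) {
    warning("no cell reaches min_orthologs; nothing tested")
    return(data.frame(scaffold_a = character(), chromosome_b = character(),
                      n_shared = integer(), p_value = numeric(),
                      q_value = numeric(), significant = logical(),
                      primary = logical(), stringsAsFactors = FALSE))
  }
  n_shared <- tab[cells]
  if (ncol(tab) == 1L) {
    # degenerate: one reference chromosome, enrichment untestable
    p <- rep(NA_real_, nrow(cells))
    q <- p
    sig <- rep(TRUE, nrow(cells))
  } else {
    m <- chrom_tot[cells[, 2]]      # orthologs on the chromosome
    k <- scaffold_tot[cells[, 1]]   # orthologs on the scaffold
    p <- phyper(n_shared - 1, m, total - m, k, lower.tail = FALSE)
    q <- p.adjust(p, method = "BH")
    sig <- q <= alpha
  }
  out <- data.frame(
    scaffold_a = rownames(tab)[cells[, 1]],
    chromosome_b = colnames(tab)[cells[, 2]],
    n_shared = as.integer(n_shared),
    p_value = unname(p), q_value = unname(q),
    significant = unname(sig),
    primary = FALSE, stringsAsFactors = FALSE)
  n_ties <- 0L
  for (sc in unique(out$scaffold_a)) {
    rows <- which(out$scaffold_a == sc & out$significant)
    if (length(rows) == 0) next
    o <- rows[order(-out$n_shared[rows], out$q_value[rows],
                    out$chromosome_b[rows])]
    if (length(o) > 1 && out$n_shared[o[1]] == out$n_shared[o[2]])
      n_ties <- n_ties + 1L
    out$primary[o[1]] <- TRUE
  }
  attr(out, "n_ties") <- n_ties
  out
}

#' Infer the chromosome count from scaffold assignments
#'
#' The chromosome count of the fragmented species is the number of
#' distinct reference chromosomes that receive at least one significantly
#' assigned scaffold: when scaffolds map to mutually exclusive reference
#' chromosomes, this recovers the karyotype.
#'
#' @param assignments data.frame from [assign_scaffolds()].
#' @return List with `count` and `membership` (named list: chromosome ->
#'   assigned scaffolds).
#' @export
chromosome_count <- function(assignments) {
  prim <- assignments[assignments$primary & assignments$significant, ,
                      drop = FALSE]
  if (nrow(prim) == 0) {
    warning("no significantly assigned scaffolds")
    return(list(count = 0L, membership = list()))
  }
  membership <- split(prim$scaffold_a, prim$chromosome_b)
  list(count = length(membership), membership = membership)
}

#' Flag scaffolds with putative translocations
#'
#' A scaffold is flagged when, besides its primary chromosome, a second
#' chromosome holds at least `min_secondary` of its orthologs and at
#' least `min_fraction` of its total, and that secondary cell is itself
#' significant: the scaffold's linkage group is dispersed across
#' reference chromosomes (or the scaffold is misassembled).
#'
#' @param assignments data.frame from [assign_scaffolds()].
#' @param placements data.frame from [place_orthologs()].
#' @param min_secondary minimum orthologs on the secondary chromosome.
#' @param min_fraction minimum fraction of the scaffold's orthologs on
#'   the secondary chromosome.
#' @return data.frame with `scaffold_a`, `primary_chromosome`,
#'   `secondary_chromosome`, `n_primary`, `n_secondary`.
#' @export
flag_translocations <- function(assignments, placements,
                                min_secondary = 5L, min_fraction = 0.1) {
  empty <- data.frame(scaffold_a = character(),
                      primary_chromosome = character(),
                      secondary_chromosome = character(),
                      n_primary = integer(), n_secondary = integer(),
                      stringsAsFactors = FALSE)
  prim <- assignments[assignments$primary, , drop = FALSE]
  if (nrow(prim) == 0) return(empty)
  scaffold_tot <- table(placements$scaffold_a)
  flags <- list()
  for (i in seq_len(nrow(prim))) {
    sc <- prim$scaffold_a[i]
    sec <- assignments[assignments$scaffold_a == sc &
                       assignments$chromosome_b != prim$chromosome_b[i] &
                       assignments$significant, , drop = FALSE]
    if (nrow(sec) == 0) next
    ok <- sec$n_shared >= min_secondary &
      sec$n_shared / scaffold_tot[[sc]] >= min_fraction
    for (j in which(ok)) {
      flags[[length(flags) + 1L]] <- data.frame(
        scaffold_a = sc, primary_chromosome = prim$chromosome_b[i],
        secondary_chromosome = sec$chromosome_b[j],
        n_primary = prim$n_shared[i], n_secondary = sec$n_shared[j],
        stringsAsFactors = FALSE)
    }
  }
  if (length(flags) == 0) return(empty)
  out <- do.call(rbind, flags)
  rownames(out) <- NULL
  out
}

#' Oxford dot-plot table
#'
#' Converts placements to cumulative-offset coordinates for an Oxford
#' dot plot: each sequence is laid end to end in the supplied order and a
#' pair's (x, y) is its position plus the prefix sum of preceding
#' sequence lengths. `x` is the species-B (chromosome) axis, `y` the
#' species-A (scaffold) axis. The output depends only on the placements
#' and orderings, not on input row order.
#'
#' @param placements data.frame from [place_orthologs()].
#' @param lengths_a,lengths_b named numeric vectors of sequence lengths.
#' @param order_a,order_b sequence id order along each axis; the default
#'   orders species A scaffolds by assigned chromosome is left to the
#'   caller -- here the default is decreasing length.
#' @return data.frame with `gene_a`, `gene_b`, `x`, `y`.
#' @export
dotplot_table <- function(placements, lengths_a, lengths_b,
                          order_a = names(sort(lengths_a,
                                               decreasing = TRUE)),
                          order_b = names(sort(lengths_b,
                                               decreasing = TRUE))) {
  offset_a <- setNames(cumsum(c(0, lengths_a[order_a]))[
    seq_along(order_a)], order_a)
  offset_b <- setNames(cumsum(c(0, lengths_b[order_b]))[
    seq_along(order_b)], order_b)
  out <- data.frame(
    gene_a = placements$gene_a, gene_b = placements$gene_b,
    x = unname(offset_b[placements$chromosome_b]) + placements$position_b,
    y = unname(offset_a[placements$scaffold_a]) + placements$position_a,
    stringsAsFactors = FALSE)
  out <- out[order(out$gene_a), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Order scaffolds by assigned chromosome then size
#'
#' Helper producing the species-A axis ordering used in Oxford dot
#' plots: scaffolds grouped by their primary chromosome (in chromosome
#' order), larger scaffolds first within a group, unassigned scaffolds
#' last.
#'
#' @param assignments data.frame from [assign_scaffolds()].
#' @param lengths_a named lengths of species-A scaffolds.
#' @return Character vector of scaffold ids.
#' @export
scaffold_order <- function(assignments, lengths_a) {
  prim <- assignments[assignments$primary, c("scaffold_a", "chromosome_b")]
  chrom <- setNames(prim$chromosome_b, prim$scaffold_a)
  ids <- names(lengths_a)
  assigned <- chrom[ids]
  ids[order(is.na(assigned), assigned, -lengths_a[ids])]
}
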