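pair_frame <- function(gene_a = character(), gene_b = character(),
                       source_runs = character(length(gene_a))) {
  data.frame(gene_a = gene_a, gene_b = gene_b, source_runs = source_runs,
             stringsAsFactors = FALSE)
}

#' Direct one-to-one orthologs from a single clustering run
#'
#' Emits a pair for every orthogroup containing exactly one member of
#' species A and exactly one member of species B; members of any other
#' species are ignored.
#'
#' @param run an `orthogroup_table`.
#' @param species_a,species_b species column names.
#' @param run_label label recorded in `source_runs` (e.g. the MCL
#'   inflation setting of the run).
#' @return data.frame with `gene_a`, `gene_b`, `source_runs`.
#' @export
direct_one_to_ones <- function(run, species_a, species_b, run_label = "") {
  species <- attr(run, "species")
  if (!all(c(species_a, species_b) %in% species))
    stop_ck("species column(s) absent: ",
            paste(setdiff(c(species_a, species_b), species), collapse = ", "))
  a <- lapply(run, `[[`, species_a)
  b <- lapply(run, `[[`, species_b)
  keep <- lengths(a) == 1L & lengths(b) == 1L
  pair_frame(unlist(a[keep], use.names = FALSE) %||% character(0),
             unlist(b[keep], use.names = FALSE) %||% character(0),
             rep(run_label, sum(keep)))
}

genes_with_multiple_partners <- function(pairs) {
  key <- paste(pairs$gene_a, pairs$gene_b, sep = "\r")
  uni <- pairs[!duplicated(key), , drop = FALSE]
  conflicted <- c(
    unique(uni$gene_a[uni$gene_a %in% uni$gene_a[duplicated(uni$gene_a)]]),
    unique(uni$gene_b[uni$gene_b %in% uni$gene_b[duplicated(uni$gene_b)]]))
  unique(conflicted)
}

#' Union single-copy ortholog pairs across clustering runs
#'
#' Takes the pair sets from several clustering runs (e.g. different MCL
#' inflation settings) and unions them. A gene observed with two or more
#' distinct partners across runs is a conflict: the gene and every pair
#' it touches are removed from the union and reported. `source_runs`
#' records which runs contributed each surviving pair.
#'
#' @param runs named list of pair data.frames (from
#'   [direct_one_to_ones()]); names are used as run labels when a pair's
#'   `source_runs` is empty.
#' @return List with `pairs` (union, conflict-free) and `conflicts`
#'   (character vector of conflicting gene ids).
#' @export
union_runs <- function(runs) {
  if (length(runs) == 0) stop_ck("at least one run required")
  if (is.null(names(runs))) names(runs) <- paste0("run", seq_along(runs))
  all_pairs <- do.call(rbind, lapply(names(runs), function(lab) {
    p <- runs[[lab]]
    p$source_runs <- ifelse(nzchar(p$source_runs), p$source_runs, lab)
    p
  }))
  key <- paste(all_pairs$gene_a, all_pairs$gene_b, sep = "\r")
  merged <- lapply(split(seq_len(nrow(all_pairs)), key), function(idx) {
    row <- all_pairs[idx[1], , drop = FALSE]
    row$source_runs <- paste(sort(unique(all_pairs$source_runs[idx])),
                             collapse = ",")
    row
  })
  uni <- do.call(rbind, merged)
  rownames(uni) <- NULL
  conflicts <- genes_with_multiple_partners(uni)
  keep <- !(uni$gene_a %in% conflicts | uni$gene_b %in% conflicts)
  list(pairs = uni[keep, , drop = FALSE], conflicts = conflicts)
}

#' Midpoint-root a gene tree
#'
#' Places the root at the midpoint of the longest leaf-to-leaf path. If
#' the midpoint falls exactly on an internal node the tree is rooted at
#' that node; ties among equally longest paths break by the
#' lexicographically smallest (sorted) leaf-label pair. A tree whose
#' branch lengths are all zero cannot be midpoint-rooted; it is rooted at
#' its first internal node with a warning.
#'
#' @param tree an [ape::phylo] with >= 2 leaves and non-negative branch
#'   lengths.
#' @return A rooted `phylo`.
#' @export
midpoint_root <- function(tree) {
  n <- length(tree$tip.label)
  if (n < 2) stop_ck("tree must have >= 2 leaves")
  if (is.null(tree$edge.length))
    stop_ck("tree has no branch lengths")
  if (any(tree$edge.length < 0))
    stop_ck("negative branch lengths")
  dn <- ape::dist.nodes(tree)
  tipd <- dn[seq_len(n), seq_len(n), drop = FALSE]
  D <- max(tipd)
  if (D == 0) {
    warning("all-zero branch lengths; rooting at the first internal node")
    if (ape::is.rooted(tree)) return(tree)
    return(ape::multi2di(tree, random = FALSE))
  }
  hits <- which(tipd == D, arr.ind = TRUE)
  hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
  lab_pairs <- apply(hits, 1, function(rc)
    paste(sort(tree$tip.label[rc]), collapse = "\r"))
  pick <- hits[order(lab_pairs)[1], ]
  u <- pick[[1]]; v <- pick[[2]]
  if (tree$tip.label[u] > tree$tip.label[v]) { tmp <- u; u <- v; v <- tmp }
  path <- ape::nodepath(tree, u, v)
  half <- D / 2
  cum <- dn[u, path]
  tol <- max(1e-9, 1e-9 * D)
  at_node <- which(abs(cum - half) <= tol)
  if (length(at_node) > 0) {
    node <- path[at_node[1]]
    if (node > n)  # midpoint exactly on an internal node
      return(ape::root(tree, node = node, resolve.root = TRUE))
  }
  i <- max(which(cum < half))
  p_from <- path[i]; p_to <- path[i + 1]
  x <- half - cum[i]  # distance from p_from toward p_to
  edge_row <- which((tree$edge[, 1] == p_from & tree$edge[, 2] == p_to) |
                    (tree$edge[, 1] == p_to & tree$edge[, 2] == p_from))
  len <- tree$edge.length[edge_row]
  if (tree$edge[edge_row, 1] == p_from) {
    child <- p_to; pos <- x
  } else {
    child <- p_from; pos <- len - x
  }
  phytools::reroot(tree, node.number = child, position = pos)
}

leaf_species <- function(labels) {
  has_sep <- grepl("_", labels, fixed = TRUE)
  if (!all(has_sep))
    stop_ck("cannot parse species from leaf label(s): ",
            paste(labels[!has_sep], collapse = ", "))
  sub("_.*$", "", labels)
}

#' Rescue ortholog pairs from gene-tree cherries
#'
#' Scans rooted gene trees for cherries -- internal nodes whose leaf set
#' is exactly two leaves -- consisting of one species-A and one species-B
#' gene, and emits those as ortholog pairs. Unrooted trees are
#' midpoint-rooted first. Trees with fewer than `min_leaves` leaves are
#' skipped (the consolidation workflow builds trees only for orthogroups
#' with four or more genes). A gene appearing in more than one distinct
#' cherry pairing across the tree set is ambiguous and dropped.
#'
#' Leaf labels encode species as a prefix before the first underscore
#' (`Bo_g1`-style); an override can be supplied via `species_of`.
#'
#' @param trees a list of [ape::phylo] objects (or a `multiPhylo`).
#' @param species_a,species_b species prefixes to pair.
#' @param min_leaves skip trees with fewer leaves.
#' @param species_of optional function mapping leaf labels to species
#'   names, replacing the prefix rule.
#' @return data.frame with `gene_a`, `gene_b`, `source_runs` (tree index
#'   of the cherry).
#' @export
cherry_rescue <- function(trees, species_a, species_b, min_leaves = 4L,
                          species_of = leaf_species) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  found <- list()
  for (t in seq_along(trees)) {
    tree <- trees[[t]]
    n <- length(tree$tip.label)
    if (n < min_leaves) next
    if (!ape::is.rooted(tree)) tree <- midpoint_root(tree)
    sp <- species_of(tree$tip.label)
    for (node in unique(tree$edge[, 1])) {
      kids <- tree$edge[tree$edge[, 1] == node, 2]
      if (length(kids) != 2L || any(kids > n)) next
      ksp <- sp[kids]
      if (setequal(ksp, c(species_a, species_b)) &&
          ksp[1] != ksp[2]) {
        a <- tree$tip.label[kids[ksp == species_a]]
        b <- tree$tip.label[kids[ksp == species_b]]
        found[[length(found) + 1L]] <-
          pair_frame(a, b, paste0("tree", t))
      }
    }
  }
  if (length(found) == 0) return(pair_frame())
  pairs <- do.call(rbind, found)
  key <- paste(pairs$gene_a, pairs$gene_b, sep = "\r")
  pairs <- pairs[!duplicated(key), , drop = FALSE]
  ambiguous <- genes_with_multiple_partners(pairs)
  pairs[!(pairs$gene_a %in% ambiguous | pairs$gene_b %in% ambiguous), ,
        drop = FALSE]
}

#' Build a transcript-to-locus isoform map
#'
#' @param ids transcript ids.
#' @param pattern regular expression stripped from ids to obtain the
#'   locus id (default: a trailing `.t<digits>` or `.i<digits>` isoform
#'   suffix).
#' @return Named character vector mapping transcript id -> locus id.
#' @export
isoform_map <- function(ids, pattern = "\\.(t|i)\\d+$") {
  setNames(sub(pattern, "", ids), ids)
}

#' Rescue single-copy orthologs blocked by isoform expansion
#'
#' An orthogroup that is not one-to-one at the transcript level may still
#' be single-copy at the locus level when its extra members are isoforms
#' of one locus. Collapsing members through the isoform map, an
#' orthogroup contributes the pair `(locusA, locusB)` iff exactly one
#' locus per species remains. Locus pairs that conflict across runs
#' (a locus seen with two distinct partners) are discarded.
#'
#' @param runs an `orthogroup_table` or named list of them (one per
#'   clustering run).
#' @param species_a,species_b species column names.
#' @param pattern isoform-suffix pattern (see [isoform_map()]).
#' @param only_blocked emit only orthogroups that are not already
#'   one-to-one at the member level, i.e. those genuinely blocked by
#'   isoform expansion (the default); `FALSE` also re-emits plain
#'   one-to-ones, which [finalize_orthologs()] would merge anyway.
#' @return List with `pairs` (data.frame `gene_a`, `gene_b`,
#'   `source_runs`) and `conflicts` (discarded locus ids).
#' @export
isoform_rescue <- function(runs, species_a, species_b,
                           pattern = "\\.(t|i)\\d+$",
                           only_blocked = TRUE) {
  if (inherits(runs, "orthogroup_table")) runs <- list(run1 = runs)
  if (is.null(names(runs))) names(runs) <- paste0("run", seq_along(runs))
  per_run <- lapply(names(runs), function(lab) {
    run <- runs[[lab]]
    raw_a <- lapply(run, `[[`, species_a)
    raw_b <- lapply(run, `[[`, species_b)
    a <- lapply(raw_a, function(m) unique(isoform_map(m, pattern)))
    b <- lapply(raw_b, function(m) unique(isoform_map(m, pattern)))
    keep <- lengths(a) == 1L & lengths(b) == 1L
    if (only_blocked)
      keep <- keep & (lengths(raw_a) > 1L | lengths(raw_b) > 1L)
    pair_frame(unlist(a[keep], use.names = FALSE) %||% character(0),
               unlist(b[keep], use.names = FALSE) %||% character(0),
               rep(lab, sum(keep)))
  })
  names(per_run) <- names(runs)
  union_runs(per_run)
}

#' Finalize the single-copy ortholog set
#'
#' Unions pairs from the three evidence routes with precedence
#' `direct > tree > isoform`. A gene contributed by two routes with the
#' same partner is kept once with merged provenance; a gene contributed
#' with different partners is removed entirely and reported. The result
#' is a partial matching: no gene occurs in more than one pair.
#'
#' @param direct pairs from [union_runs()] over [direct_one_to_ones()].
#' @param tree_pairs pairs from [cherry_rescue()].
#' @param isoform_pairs pairs from [isoform_rescue()].
#' @return List with `pairs` (data.frame `gene_a`, `gene_b`,
#'   `provenance`, `source_runs`) and `conflicts` (data.frame of removed
#'   genes and the partners that clashed).
#' @export
finalize_orthologs <- function(direct = pair_frame(),
                               tree_pairs = pair_frame(),
                               isoform_pairs = pair_frame()) {
  sources <- list(direct = direct, tree = tree_pairs,
                  isoform = isoform_pairs)
  rows <- do.call(rbind, lapply(names(sources), function(prov) {
    p <- sources[[prov]]
    if (nrow(p) == 0) return(NULL)
    data.frame(gene_a = p$gene_a, gene_b = p$gene_b, provenance = prov,
               source_runs = p$source_runs, stringsAsFactors = FALSE)
  }))
  if (is.null(rows))
    return(list(pairs = data.frame(gene_a = character(),
                                   gene_b = character(),
                                   provenance = character(),
                                   source_runs = character(),
                                   stringsAsFactors = FALSE),
                conflicts = data.frame(gene = character(),
                                       partners = character(),
                                       stringsAsFactors = FALSE)))
  key <- paste(rows$gene_a, rows$gene_b, sep = "\r")
  merged <- lapply(split(seq_len(nrow(rows)), key), function(idx) {
    r <- rows[idx[1], , drop = FALSE]
    r$provenance <- paste(unique(rows$provenance[idx]), collapse = ",")
    r$source_runs <- paste(unique(unlist(
      strsplit(rows$source_runs[idx], ","))), collapse = ",")
    r
  })
  uni <- do.call(rbind, merged)
  rownames(uni) <- NULL
  conflicted <- genes_with_multiple_partners(uni)
  keep <- !(uni$gene_a %in% conflicted | uni$gene_b %in% conflicted)
  conflicts <- do.call(rbind, lapply(conflicted, function(g) {
    touched <- uni$gene_a == g | uni$gene_b == g
    partners <- ifelse(uni$gene_a[touched] == g, uni$gene_b[touched],
                       uni$gene_a[touched])
    data.frame(gene = g, partners = paste(sort(partners), collapse = ","),
               stringsAsFactors = FALSE)
  })) %||% data.frame(gene = character(), partners = character(),
                      stringsAsFactors = FALSE)
  ord_prov <- c(direct = 1L, tree = 2L, isoform = 3L)
  first_prov <- vapply(strsplit(uni$provenance, ","), function(p)
    min(ord_prov[p]), integer(1))
  out <- uni[keep, , drop = FALSE]
  out <- out[order(first_prov[keep], out$gene_a), , drop = FALSE]
  rownames(out) <- NULL
  list(pairs = out, conflicts = conflicts)
}
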