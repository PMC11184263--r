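#' Evaluate code under a local random seed
#'
#' Runs `code` with the RNG seeded to `seed`, restoring the caller's RNG
#' state afterwards, so generators are reproducible without clobbering
#' global random state.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Minimal 12-column hit table constructor
#'
#' Builds a hit table in the layout of [read_tabular_hits()] from the
#' fields that matter, filling the rest with consistent defaults.
#'
#' @param qseqid,sseqid query and subject ids.
#' @param bitscore,evalue alignment score and significance.
#' @param qstart,qend,sstart,send alignment coordinates.
#' @param pident,aln_length,mismatch,gapopen remaining columns.
#' @return data.frame with the 12 standard columns.
#' @export
hit_table <- function(qseqid = character(), sseqid = character(),
                      bitscore = numeric(length(qseqid)),
                      evalue = numeric(length(qseqid)),
                      qstart = rep(1, length(qseqid)),
                      qend = rep(100, length(qseqid)),
                      sstart = rep(1, length(qseqid)),
                      send = rep(100, length(qseqid)),
                      pident = rep(100, length(qseqid)),
                      aln_length = abs(qend - qstart) + 1,
                      mismatch = rep(0, length(qseqid)),
                      gapopen = rep(0, length(qseqid))) {
  data.frame(qseqid = qseqid, sseqid = sseqid, pident = pident,
             length = aln_length, mismatch = mismatch, gapopen = gapopen,
             qstart = qstart, qend = qend, sstart = sstart, send = send,
             evalue = evalue, bitscore = bitscore,
             stringsAsFactors = FALSE)
}

#' Simulate two genomes with known chromosome and linkage structure
#'
#' Emulates the data structure behind a macrosynteny comparison between
#' a chromosome-level reference (species B) and a fragmented assembly
#' (species A). Both species share `n_genes` one-to-one orthologous
#' genes laid out colinearly; species B keeps intact chromosomes while
#' species A's chromosomes are fragmented into scaffolds carrying
#' assembly gaps (some strictly longer than 5 kb, for gap-breaking
#' tests). Linkage is respected except for planted block translocations
#' and uniform placement shuffling.
#'
#' @param seed integer seed; identical seeds give identical output.
#' @param n_chromosomes chromosomes in species B (default 13, a typical
#'   ctenophore karyotype).
#' @param n_genes total orthologous genes, distributed evenly.
#' @param scaffolds_per_chromosome fragmentation of species A; a scalar
#'   or a vector recycled across chromosomes.
#' @param gene_length,spacer gene and intergenic lengths (bp).
#' @param big_gap_fraction fraction of species-A scaffolds receiving one
#'   N-run strictly longer than 5 kb.
#' @param big_gap_length,small_gap_length N-run lengths (bp); every
#'   scaffold gets one small run, flagged scaffolds also get the big one.
#' @param n_translocations planted block translocations: a block of
#'   `translocation_block` genes from another chromosome appended to a
#'   scaffold.
#' @param translocation_block genes per translocated block.
#' @param shuffle_rate fraction of genes whose species-A scaffold is
#'   reassigned uniformly at random (placement noise).
#' @param sequences generate nucleotide sequences; `FALSE` returns the
#'   layout only (coordinates and manifests), which is much faster for
#'   placement-level simulations.
#' @return List with `genome_a`, `genome_b` (`DNAStringSet` or `NULL`),
#'   `genes_a`, `genes_b` (gene tables as in [read_gff3_genes()]) and
#'   `manifest` (ground truth: per-gene chromosome/scaffold, ortholog
#'   pairs, planted translocations, shuffled genes, gap positions).
#' @export
simulate_two_species_genomes <- function(seed, n_chromosomes = 13L,
                                         n_genes = 1300L,
                                         scaffolds_per_chromosome = 4L,
                                         gene_length = 900L, spacer = 300L,
                                         big_gap_fraction = 0.15,
                                         big_gap_length = 6000L,
                                         small_gap_length = 100L,
                                         n_translocations = 0L,
                                         translocation_block = 6L,
                                         shuffle_rate = 0,
                                         sequences = TRUE) {
  stopifnot(n_chromosomes >= 1, n_genes >= n_chromosomes)
  with_seed(seed, {
    gene_ids <- sprintf("g%04d", seq_len(n_genes))
    chrom_of <- sort(rep_len(seq_len(n_chromosomes), n_genes))
    chrom_ids <- sprintf("B_chr%02d", seq_len(n_chromosomes))
    spc <- rep_len(scaffolds_per_chromosome, n_chromosomes)
    # species A scaffolds: contiguous blocks of each chromosome's genes
    scaffold_of <- integer(n_genes)
    scaffold_ids <- character(0)
    scaffold_chrom <- integer(0)
    for (c in seq_len(n_chromosomes)) {
      idx <- which(chrom_of == c)
      pieces <- sort(rep_len(seq_len(spc[c]), length(idx)))
      for (p in seq_len(spc[c])) {
        scaffold_ids <- c(scaffold_ids, sprintf("A_sc%02d.%d", c, p))
        scaffold_chrom <- c(scaffold_chrom, c)
        scaffold_of[idx[pieces == p]] <- length(scaffold_ids)
      }
    }
    # ordered gene lists per scaffold (build order = coordinate order)
    genes_on <- split(seq_len(n_genes), scaffold_of)
    translocated <- logical(n_genes)
    translocations <- list()
    if (n_translocations > 0) {
      for (t in seq_len(n_translocations)) {
        dest <- sample(seq_along(scaffold_ids), 1)
        donor_chroms <- setdiff(seq_len(n_chromosomes),
                                scaffold_chrom[dest])
        donor <- sample(donor_chroms, 1)
        avail <- setdiff(which(chrom_of == donor), which(translocated))
        if (length(avail) < translocation_block) next
        block <- avail[seq_len(translocation_block)]
        translocated[block] <- TRUE
        for (g in block) {
          src <- as.character(scaffold_of[g])
          genes_on[[src]] <- setdiff(genes_on[[src]], g)
          scaffold_of[g] <- dest
        }
        genes_on[[as.character(dest)]] <-
          c(genes_on[[as.character(dest)]], block)
        translocations[[t]] <- data.frame(
          scaffold = scaffold_ids[dest],
          donor_chromosome = chrom_ids[donor],
          genes = I(list(gene_ids[block])), stringsAsFactors = FALSE)
      }
    }
    shuffled <- logical(n_genes)
    if (shuffle_rate > 0) {
      n_shuffle <- round(shuffle_rate * n_genes)
      pick <- sample(which(!translocated), n_shuffle)
      shuffled[pick] <- TRUE
      for (g in pick) {
        dest <- sample(setdiff(seq_along(scaffold_ids), scaffold_of[g]), 1)
        src <- as.character(scaffold_of[g])
        genes_on[[src]] <- setdiff(genes_on[[src]], g)
        scaffold_of[g] <- dest
        genes_on[[as.character(dest)]] <-
          c(genes_on[[as.character(dest)]], g)
      }
    }
    has_big_gap <- runif(length(scaffold_ids)) < big_gap_fraction
    build_seq <- sequences
    # species B chromosomes: genes in index order, uniform spacers
    gb_start <- integer(n_genes); gb_end <- integer(n_genes)
    chrom_seqs <- character(n_chromosomes)
    for (c in seq_len(n_chromosomes)) {
      idx <- which(chrom_of == c)
      pos <- spacer + 1L
      parts <- if (build_seq) list(random_dna(spacer)) else NULL
      for (g in idx) {
        gb_start[g] <- pos; gb_end[g] <- pos + gene_length - 1L
        if (build_seq)
          parts <- c(parts, random_dna(gene_length), random_dna(spacer))
        pos <- pos + gene_length + spacer
      }
      if (build_seq) chrom_seqs[c] <- paste(unlist(parts), collapse = "")
    }
    chrom_len <- vapply(seq_len(n_chromosomes), function(c)
      spacer + sum(chrom_of == c) * (gene_length + spacer), numeric(1))
    # species A scaffolds: per-scaffold gene order, gaps in spacers
    ga_start <- integer(n_genes); ga_end <- integer(n_genes)
    scafs <- character(length(scaffold_ids))
    scaf_len <- numeric(length(scaffold_ids))
    gap_manifest <- list()
    for (s in seq_along(scaffold_ids)) {
      idx <- genes_on[[as.character(s)]]
      pos <- spacer + 1L
      parts <- if (build_seq) list(random_dna(spacer)) else NULL
      mid <- if (length(idx) > 0) ceiling(length(idx) / 2) else 0L
      for (k in seq_along(idx)) {
        g <- idx[k]
        ga_start[g] <- pos; ga_end[g] <- pos + gene_length - 1L
        pos <- pos + gene_length
        if (build_seq) parts <- c(parts, random_dna(gene_length))
        gap_here <- if (k == mid && has_big_gap[s]) big_gap_length
                    else if (k == 1L) small_gap_length else 0L
        if (gap_here > 0) {
          gap_manifest[[length(gap_manifest) + 1L]] <- data.frame(
            scaffold = scaffold_ids[s], start = pos,
            length = gap_here, stringsAsFactors = FALSE)
          if (build_seq)
            parts <- c(parts, strrep("N", gap_here))
          pos <- pos + gap_here
        }
        if (build_seq) parts <- c(parts, random_dna(spacer))
        pos <- pos + spacer
      }
      scaf_len[s] <- pos - 1L
      if (build_seq) scafs[s] <- paste(unlist(parts), collapse = "")
    }
    genome_b <- if (build_seq)
      setNames(Biostrings::DNAStringSet(chrom_seqs), chrom_ids) else NULL
    genome_a <- if (build_seq)
      setNames(Biostrings::DNAStringSet(scafs), scaffold_ids) else NULL
    genes_b <- data.frame(
      gene_id = paste0("B_", gene_ids), seqid = chrom_ids[chrom_of],
      start = gb_start, end = gb_end, strand = "+",
      transcript_ids = I(as.list(paste0("B_", gene_ids, ".t1"))),
      stringsAsFactors = FALSE)
    genes_a <- data.frame(
      gene_id = paste0("A_", gene_ids), seqid = scaffold_ids[scaffold_of],
      start = ga_start, end = ga_end, strand = "+",
      transcript_ids = I(as.list(paste0("A_", gene_ids, ".t1"))),
      stringsAsFactors = FALSE)
    manifest <- list(
      seed = seed, n_chromosomes = n_chromosomes, n_genes = n_genes,
      genes = data.frame(gene = gene_ids,
                         chromosome_b = chrom_ids[chrom_of],
                         scaffold_a = scaffold_ids[scaffold_of],
                         translocated = translocated, shuffled = shuffled,
                         stringsAsFactors = FALSE),
      pairs = data.frame(gene_a = paste0("A_", gene_ids),
                         gene_b = paste0("B_", gene_ids),
                         stringsAsFactors = FALSE),
      scaffold_chromosome = data.frame(scaffold = scaffold_ids,
                                       chromosome =
                                         chrom_ids[scaffold_chrom],
                                       stringsAsFactors = FALSE),
      chromosome_lengths = setNames(chrom_len, chrom_ids),
      scaffold_lengths = setNames(scaf_len, scaffold_ids),
      translocations = if (length(translocations) > 0)
        do.call(rbind, translocations) else NULL,
      gaps = if (length(gap_manifest) > 0)
        do.call(rbind, gap_manifest) else NULL)
    list(genome_a = genome_a, genome_b = genome_b,
         genes_a = genes_a, genes_b = genes_b, manifest = manifest)
  })
}

#' Simulate orthogroup tables, gene trees and rescue inputs
#'
#' Builds the true orthogroup per gene (focal protein model, focal
#' transcript, and one or two outgroup proteins), then perturbs it:
#' a fraction of focal genes lose their protein model but keep their
#' transcript (missed-annotation rescue targets); a fraction gain
#' isoform-suffixed focal models (`.t1`, `.t2`) that block direct
#' one-to-one detection; a fraction gain an outgroup-B paralog that also
#' blocks direct detection but leaves a recoverable focal/outgroup
#' cherry in the orthogroup's gene tree; per run, genes are mis-clustered
#' at `misclustering_rate` (their outgroup-B member is moved into the
#' next orthogroup).
#'
#' @param seed integer seed.
#' @param manifest genome manifest from
#'   [simulate_two_species_genomes()].
#' @param n_runs clustering runs emitted (labels `run1..runN`,
#'   emulating different MCL inflation settings).
#' @param misclustering_rate per-run probability of mis-clustering a
#'   gene's outgroup-B member.
#' @param missing_annotation_rate fraction of genes that become rescue
#'   targets.
#' @param isoform_rate fraction of genes whose focal model is expanded
#'   into two isoforms.
#' @param cherry_rate fraction of genes converted into tree-rescuable
#'   paralog-expanded orthogroups.
#' @param outgroup2_presence probability the second outgroup (species C)
#'   is present in an orthogroup.
#' @param orf_codons coding length (codons, excluding start/stop) of the
#'   planted ORFs in rescue-target transcripts.
#' @return List: `runs` (named list of `orthogroup_table`), `trees`
#'   (list of [ape::phylo] with planted focal/outgroup cherries),
#'   `transcripts` (`DNAStringSet` for rescue targets), `model_hits`,
#'   `genome_hits` (hit tables for the rescue pipeline) and `manifest`
#'   (planted ground truth: rescue targets, isoform and cherry genes,
#'   expected pairs per evidence route and the expected final set).
#' @export
simulate_orthogroups <- function(seed, manifest, n_runs = 4L,
                                 misclustering_rate = 0,
                                 missing_annotation_rate = 0,
                                 isoform_rate = 0, cherry_rate = 0,
                                 outgroup2_presence = 0.8,
                                 orf_codons = 60L) {
  genes <- manifest$genes$gene
  n <- length(genes)
  with_seed(seed, {
    n_rescue <- round(missing_annotation_rate * n)
    n_iso <- round(isoform_rate * n)
    n_cherry <- round(cherry_rate * n)
    pick <- sample(genes, n_rescue + n_iso + n_cherry)
    rescue_targets <- pick[seq_len(n_rescue)]
    iso_genes <- pick[n_rescue + seq_len(n_iso)]
    cherry_genes <- pick[n_rescue + n_iso + seq_len(n_cherry)]
    has_c <- runif(n) < outgroup2_presence
    base <- lapply(seq_len(n), function(i) {
      g <- genes[i]
      og <- list(
        A_prot = if (g %in% rescue_targets) character(0)
                 else if (g %in% iso_genes)
                   paste0("A_", g, ".t", 1:2)
                 else paste0("A_", g),
        A_tx = paste0("tx_", g),
        B_prot = if (g %in% cherry_genes)
                   c(paste0("B_", g), paste0("B_", g, "para"))
                 else paste0("B_", g),
        C_prot = if (has_c[i]) paste0("C_", g) else character(0))
      og
    })
    names(base) <- sprintf("OG%04d", seq_len(n))
    species <- c("A_prot", "A_tx", "B_prot", "C_prot")
    runs <- lapply(seq_len(n_runs), function(r) {
      ogs <- base
      if (misclustering_rate > 0) {
        miss <- which(runif(n) < misclustering_rate)
        for (i in miss) {
          j <- if (i == n) 1L else i + 1L
          ogs[[j]]$B_prot <- c(ogs[[j]]$B_prot, ogs[[i]]$B_prot)
          ogs[[i]]$B_prot <- character(0)
        }
      }
      structure(ogs, species = species, class = "orthogroup_table")
    })
    names(runs) <- paste0("run", seq_len(n_runs))
    # gene trees for the paralog-expanded (cherry) orthogroups
    trees <- lapply(cherry_genes, function(g) {
      bl <- function() round(runif(1, 0.05, 1.5), 3)
      extra <- if (runif(1) < 0.5)
        sprintf("(B_%spara:%s,C_%s:%s):%s", g, bl(), g, bl(), bl())
      else
        sprintf("(C_%s:%s,B_%spara:%s):%s", g, bl(), g, bl(), bl())
      txt <- sprintf("((A_%s:%s,B_%s:%s):%s,%s);",
                     g, bl(), g, bl(), bl(), extra)
      ape::read.tree(text = txt)
    })
    # rescue-target transcripts with one planted dominant ORF
    non_stop <- names(Biostrings::GENETIC_CODE)[
      Biostrings::GENETIC_CODE != "*"]
    transcripts <- character(0)
    for (g in rescue_targets) {
      cds <- paste0("ATG", paste(sample(non_stop, orf_codons,
                                        replace = TRUE), collapse = ""),
                    "TAA")
      transcripts[paste0("tx_", g)] <-
        paste0(random_dna(50), cds, random_dna(50))
    }
    transcripts <- Biostrings::DNAStringSet(transcripts)
    scaf_of <- setNames(manifest$genes$scaffold_a, manifest$genes$gene)
    ga <- manifest$genes
    genome_hits <- if (n_rescue > 0) {
      w <- Biostrings::width(transcripts)
      hit_table(qseqid = paste0("tx_", rescue_targets),
                sseqid = unname(scaf_of[rescue_targets]),
                bitscore = rep(500, n_rescue),
                evalue = rep(0, n_rescue),
                qstart = rep(1, n_rescue), qend = w,
                sstart = rep(1000, n_rescue), send = 999 + w)
    } else hit_table()
    plain <- setdiff(genes, c(rescue_targets, iso_genes, cherry_genes))
    expected_direct <- data.frame(gene_a = paste0("A_", plain),
                                  gene_b = paste0("B_", plain),
                                  stringsAsFactors = FALSE)
    expected_isoform <- data.frame(gene_a = paste0("A_", iso_genes),
                                   gene_b = paste0("B_", iso_genes),
                                   stringsAsFactors = FALSE)
    expected_tree <- data.frame(gene_a = paste0("A_", cherry_genes),
                                gene_b = paste0("B_", cherry_genes),
                                stringsAsFactors = FALSE)
    list(runs = runs, trees = trees, transcripts = transcripts,
         model_hits = hit_table(), genome_hits = genome_hits,
         manifest = list(
           rescue_targets = rescue_targets,
           isoform_genes = iso_genes,
           cherry_genes = cherry_genes,
           expected_direct = expected_direct,
           expected_isoform = expected_isoform,
           expected_tree = expected_tree,
           expected_final = rbind(expected_direct, expected_tree,
                                  expected_isoform)))
  })
}

#' Simulate cross-species differential-expression tables
#'
#' Produces two per-species DE tables sharing planted conserved
#' tissue-specific genes. Planted genes draw log2 fold changes from
#' Normal(+/-3, 0.5) truncated to clear the strict |log2FC| threshold,
#' with the same sign in both species, and p-values from the extreme
#' lower tail of Beta(0.01, 1) so the planted genes remain significant
#' after Benjamini-Hochberg correction by construction. Null genes draw
#' log2FC from Normal(0, 0.5) and p-values from Uniform(0, 1). The `fdr`
#' column is the BH adjustment of the simulated p-values within each
#' table.
#'
#' @param seed integer seed.
#' @param pairs ortholog pairs data.frame (`gene_a`, `gene_b`); planted
#'   genes are drawn from it, the remainder are nulls.
#' @param n_conserved_per_direction planted conserved genes per
#'   direction (up in tissue 1 / up in tissue 2).
#' @param effect_mean,effect_sd planted effect distribution (log2FC).
#' @param min_effect truncation bound so planted effects clear the
#'   strict fold-change criterion.
#' @param contrast contrast label stored on both tables.
#' @return List with `de_a`, `de_b` (data.frames with a `contrast`
#'   attribute) and `manifest` (data.frame of planted genes with
#'   `direction`).
#' @export
simulate_de_tables <- function(seed, pairs, n_conserved_per_direction = 10L,
                               effect_mean = 3, effect_sd = 0.5,
                               min_effect = 2,
                               contrast = "tissue1_vs_tissue2") {
  n_pairs <- nrow(pairs)
  k <- n_conserved_per_direction
  if (2 * k > n_pairs) stop_ck("not enough pairs to plant ", 2 * k,
                               " conserved genes")
  with_seed(seed, {
    planted_idx <- sample(n_pairs, 2 * k)
    up_idx <- planted_idx[seq_len(k)]
    down_idx <- planted_idx[k + seq_len(k)]
    r_effect <- function(m) {
      x <- rnorm(m, effect_mean, effect_sd)
      while (any(x < min_effect))
        x[x < min_effect] <- rnorm(sum(x < min_effect), effect_mean,
                                   effect_sd)
      x
    }
    r_planted_p <- function(m) 1e-8 * runif(m)^100
    make_table <- function(gene_col) {
      lfc <- rnorm(n_pairs, 0, 0.5)
      p <- runif(n_pairs)
      lfc[up_idx] <- r_effect(k)
      lfc[down_idx] <- -r_effect(k)
      p[planted_idx] <- r_planted_p(2 * k)
      tab <- data.frame(gene_id = pairs[[gene_col]], log2fc = lfc,
                        fdr = p.adjust(p, method = "BH"),
                        stringsAsFactors = FALSE)
      attr(tab, "contrast") <- contrast
      tab
    }
    de_a <- make_table("gene_a")
    de_b <- make_table("gene_b")
    manifest <- data.frame(
      gene_a = pairs$gene_a[c(up_idx, down_idx)],
      gene_b = pairs$gene_b[c(up_idx, down_idx)],
      direction = rep(c("up_tissue1", "up_tissue2"), each = k),
      stringsAsFactors = FALSE)
    list(de_a = de_a, de_b = de_b, manifest = manifest)
  })
}

#' Plant catalytic-motif sites into a genome
#'
#' Back-translates realizations of the catalytic motif (uniform codon
#' choice per residue; the optional residue present with probability
#' `p_optional`) and writes them into the genome at random
#' non-overlapping positions on the requested strands, recording the
#' exact genomic span, frame and peptide of every site.
#'
#' @param seed integer seed.
#' @param genome nucleotide `DNAStringSet`.
#' @param n_sites number of sites to plant.
#' @param strand_mix `"both"`, `"forward"` or `"reverse"`.
#' @param p_optional probability the optional residue is present.
#' @param max_tries redraw attempts per site before erroring on
#'   overlap congestion.
#' @return List with `genome` (modified `DNAStringSet`) and `sites`
#'   (data.frame: `scaffold`, `genomic_start`, `genomic_end`, `frame`,
#'   `peptide`).
#' @export
plant_motifs <- function(seed, genome, n_sites = 5L,
                         strand_mix = c("both", "forward", "reverse"),
                         p_optional = 0.5, max_tries = 100L) {
  strand_mix <- match.arg(strand_mix)
  code <- Biostrings::GENETIC_CODE
  codons_for <- split(names(code), code)
  non_stop_res <- setdiff(unique(code), "*")
  seqs <- as.character(genome)
  lens <- nchar(seqs)
  with_seed(seed, {
    sites <- list()
    occupied <- lapply(seqs, function(x) integer(0))
    for (k in seq_len(n_sites)) {
      residues <- c("F", "D", "G",
                    if (runif(1) < p_optional)
                      sample(non_stop_res, 1),
                    "D", sample(non_stop_res, 1),
                    "D", sample(non_stop_res, 1), "E")
      dna <- paste(vapply(residues, function(r)
        sample(codons_for[[r]], 1), character(1)), collapse = "")
      span <- nchar(dna)
      strand <- switch(strand_mix, both = sample(c("+", "-"), 1),
                       forward = "+", reverse = "-")
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        sc <- sample(seq_along(seqs), 1, prob = lens)
        if (lens[sc] < span) next
        gs <- sample(lens[sc] - span + 1L, 1)
        ge <- gs + span - 1L
        if (any(gs:ge %in% occupied[[sc]])) next
        insert <- if (strand == "+") dna else revcomp(dna)
        substr(seqs[sc], gs, ge) <- insert
        occupied[[sc]] <- c(occupied[[sc]], gs:ge)
        frame <- if (strand == "+") ((gs - 1L) %% 3L) + 1L
                 else -((((lens[sc] - ge + 1L) - 1L) %% 3L) + 1L)
        sites[[k]] <- data.frame(
          scaffold = names(genome)[sc], genomic_start = gs,
          genomic_end = ge, frame = frame,
          peptide = paste(residues, collapse = ""),
          stringsAsFactors = FALSE)
        placed <- TRUE
        break
      }
      if (!placed) stop_ck("could not place motif site ", k,
                           " without overlap after ", max_tries, " tries")
    }
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- names(genome)
    list(genome = out,
         sites = if (length(sites) > 0) do.call(rbind, sites) else
           data.frame(scaffold = character(), genomic_start = integer(),
                      genomic_end = integer(), frame = integer(),
                      peptide = character(), stringsAsFactors = FALSE))
  })
}
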