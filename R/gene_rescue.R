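#' Find orthogroups that evidence missed gene predictions
#'
#' An orthogroup is a rescue candidate when the focal species contributed
#' no protein model but did contribute transcripts, while at least one
#' outgroup species contributed protein models: the locus is real and
#' conserved, and the predictor simply missed it.
#'
#' @param ogs an `orthogroup_table` from [read_orthogroups()].
#' @param focal_model_col species column holding focal protein models.
#' @param focal_transcript_col species column holding focal transcripts.
#' @param outgroup_cols species columns of supporting outgroup proteomes.
#' @return data.frame ledger with one row per candidate orthogroup:
#'   `orthogroup_id`, list-columns `transcript_ids` and
#'   `supporting_species`, and `status` (`"candidate"`).
#' @export
find_candidates <- function(ogs, focal_model_col, focal_transcript_col,
                            outgroup_cols) {
  species <- attr(ogs, "species")
  needed <- c(focal_model_col, focal_transcript_col, outgroup_cols)
  missing <- setdiff(needed, species)
  if (length(missing) > 0)
    stop_ck("column(s) absent from orthogroup table: ",
            paste(missing, collapse = ", "))
  rows <- lapply(names(ogs), function(og_id) {
    og <- ogs[[og_id]]
    support <- outgroup_cols[lengths(og[outgroup_cols]) > 0]
    if (length(og[[focal_model_col]]) == 0 &&
        length(og[[focal_transcript_col]]) > 0 &&
        length(support) > 0) {
      data.frame(orthogroup_id = og_id,
                 transcript_ids = I(list(og[[focal_transcript_col]])),
                 supporting_species = I(list(support)),
                 status = "candidate", stringsAsFactors = FALSE)
    } else NULL
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0)
    return(data.frame(orthogroup_id = character(),
                      transcript_ids = I(list()),
                      supporting_species = I(list()),
                      status = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Confirm candidate novelty against existing gene models
#'
#' A candidate is only novel if none of its transcripts aligns
#' significantly to an existing focal gene model. Candidates with any hit
#' at `evalue < evalue_cutoff` (strict) are rejected with reason
#' `has_model_hit`; hits at exactly the cutoff do not reject.
#'
#' @param cands candidate ledger from [find_candidates()].
#' @param hits hit table of focal transcripts vs focal gene models
#'   ([read_tabular_hits()]).
#' @param evalue_cutoff significance cutoff (strict `<`).
#' @return The ledger with `status` updated to `"confirmed"` or
#'   `"rejected:has_model_hit"`.
#' @export
confirm_novel <- function(cands, hits, evalue_cutoff = 1e-6) {
  sig_queries <- unique(hits$qseqid[hits$evalue < evalue_cutoff])
  active <- cands$status == "candidate"
  has_hit <- vapply(cands$transcript_ids, function(tx)
    any(tx %in% sig_queries), logical(1))
  cands$status[active & has_hit] <- "rejected:has_model_hit"
  cands$status[active & !has_hit] <- "confirmed"
  cands
}

#' Single longest open reading frame over six frames
#'
#' Scans all six reading frames of a transcript. An ORF is a maximal
#' stop-free codon run ending at a stop codon or the end of the frame;
#' within a run the ORF starts at the first `ATG`, or -- when
#' `allow_partial` and the run begins at the very start of the frame --
#' at the frame start without a start codon (`has_start_codon = FALSE`,
#' mirroring a 5'-partial coding region). The single longest ORF by
#' peptide length is returned; ties break by frame order
#' `+1,+2,+3,-1,-2,-3` then by smaller `nt_start`.
#'
#' @param transcript a `DNAString`/`DNAStringSet` element or character
#'   string of length >= 3.
#' @param allow_partial allow ORFs starting at the frame start without
#'   `ATG`.
#' @param min_codons minimum peptide length in codons; shorter ORFs are
#'   not reported (`NULL` result).
#' @return List with `frame` (+1..+3, -1..-3), `nt_start`, `nt_end`
#'   (1-based inclusive on the forward strand of the transcript, spanning
#'   exactly `3 * nchar(peptide)` bases, stop codon excluded), `peptide`,
#'   `has_start_codon`; or `NULL` when no qualifying ORF exists.
#' @export
longest_orf <- function(transcript, allow_partial = TRUE, min_codons = 30L) {
  s <- toupper(as.character(transcript)[1])
  L <- nchar(s)
  if (L < 3L) stop_ck("transcript shorter than one codon")
  candidates <- list()
  frames <- list(`1` = s, `2` = s, `3` = s,
                 `-1` = revcomp(s), `-2` = revcomp(s), `-3` = revcomp(s))
  frame_rank <- 0L
  for (fr in c(1L, 2L, 3L, -1L, -2L, -3L)) {
    frame_rank <- frame_rank + 1L
    str <- frames[[as.character(fr)]]
    off <- abs(fr)
    ncod <- (L - off + 1L) %/% 3L
    if (ncod < 1L) next
    sub <- substr(str, off, off + 3L * ncod - 1L)
    pep <- as.character(Biostrings::translate(
      Biostrings::DNAString(sub), if.fuzzy.codon = "X",
      no.init.codon = TRUE))
    aa <- strsplit(pep, "")[[1]]
    stops <- which(aa == "*")
    run_starts <- c(1L, stops + 1L)
    run_ends <- c(stops - 1L, length(aa))
    keep <- run_starts <= run_ends & run_starts <= length(aa)
    run_starts <- run_starts[keep]; run_ends <- run_ends[keep]
    for (k in seq_along(run_starts)) {
      i <- run_starts[k]; j <- run_ends[k]
      orf_starts <- integer(0)
      m_pos <- which(aa[i:j] == "M")
      if (length(m_pos) > 0) orf_starts <- i + m_pos[1] - 1L
      if (allow_partial && i == 1L) orf_starts <- unique(c(1L, orf_starts))
      for (a0 in orf_starts) {
        plen <- j - a0 + 1L
        if (plen < min_codons) next
        nt_s_local <- off + 3L * (a0 - 1L)
        nt_e_local <- off + 3L * j - 1L
        if (fr > 0) { nt_s <- nt_s_local; nt_e <- nt_e_local }
        else { nt_s <- L - nt_e_local + 1L; nt_e <- L - nt_s_local + 1L }
        candidates[[length(candidates) + 1L]] <- list(
          frame = fr, nt_start = nt_s, nt_end = nt_e,
          peptide = paste(aa[a0:j], collapse = ""),
          has_start_codon = aa[a0] == "M",
          len = plen, frame_rank = frame_rank)
      }
    }
  }
  if (length(candidates) == 0) return(NULL)
  lens <- vapply(candidates, `[[`, integer(1), "len")
  ranks <- vapply(candidates, `[[`, integer(1), "frame_rank")
  starts <- vapply(candidates, `[[`, integer(1), "nt_start")
  best <- order(-lens, ranks, starts)[1]
  out <- candidates[[best]]
  out$len <- NULL; out$frame_rank <- NULL
  out
}

#' Extract the coding region for each confirmed candidate
#'
#' Evaluates [longest_orf()] on every transcript of every confirmed
#' candidate and keeps the single longest ORF per orthogroup (alternates
#' are counted in `n_alternates`). Candidates with no qualifying ORF are
#' rejected with reason `no_orf`.
#'
#' @param cands ledger from [confirm_novel()].
#' @param transcripts nucleotide `DNAStringSet` holding the candidate
#'   transcripts.
#' @param allow_partial,min_codons passed to [longest_orf()].
#' @return The ledger with `status` updated to `"orf_extracted"` or
#'   `"rejected:no_orf"`, plus columns `coding_transcript`, a list-column
#'   `orf`, and `n_alternates`.
#' @export
extract_orfs <- function(cands, transcripts, allow_partial = TRUE,
                         min_codons = 30L) {
  cands$coding_transcript <- NA_character_
  cands$orf <- I(vector("list", nrow(cands)))
  cands$n_alternates <- 0L
  for (i in seq_len(nrow(cands))) {
    if (cands$status[i] != "confirmed") next
    tx_ids <- intersect(cands$transcript_ids[[i]], names(transcripts))
    orfs <- lapply(tx_ids, function(id)
      longest_orf(transcripts[[id]], allow_partial, min_codons))
    found <- !vapply(orfs, is.null, logical(1))
    if (!any(found)) { cands$status[i] <- "rejected:no_orf"; next }
    tx_ids <- tx_ids[found]; orfs <- orfs[found]
    lens <- vapply(orfs, function(o) nchar(o$peptide), integer(1))
    best <- which.max(lens)
    cands$status[i] <- "orf_extracted"
    cands$coding_transcript[i] <- tx_ids[best]
    cands$orf[[i]] <- orfs[[best]]
    cands$n_alternates[i] <- length(orfs) - 1L
  }
  cands
}

#' Resolve genome placement of candidate coding regions
#'
#' A rescued gene must map to a single genomic scaffold; coding regions
#' aligning to more than one scaffold are ignored because their genomic
#' origin is ambiguous. Only scaffold identity matters: multiple HSPs on
#' the same scaffold count as one placement.
#'
#' @param cands ledger from [extract_orfs()].
#' @param genome_hits hit table of coding regions (queries are transcript
#'   ids) vs genomic scaffolds.
#' @return The ledger with `status` updated to `"placed"`,
#'   `"rejected:multi_scaffold"` or `"rejected:no_alignment"`, plus a
#'   `scaffold` column for placed candidates.
#' @export
place_on_genome <- function(cands, genome_hits) {
  hits_by_query <- split(genome_hits$sseqid, genome_hits$qseqid)
  cands$scaffold <- NA_character_
  for (i in seq_len(nrow(cands))) {
    if (cands$status[i] != "orf_extracted") next
    tx_ids <- intersect(cands$transcript_ids[[i]], names(hits_by_query))
    if (length(tx_ids) == 0) {
      cands$status[i] <- "rejected:no_alignment"; next
    }
    per_tx <- lapply(hits_by_query[tx_ids], unique)
    if (any(lengths(per_tx) > 1L) || length(unique(unlist(per_tx))) > 1L) {
      cands$status[i] <- "rejected:multi_scaffold"; next
    }
    cands$status[i] <- "placed"
    cands$scaffold[i] <- unlist(per_tx)[1]
  }
  cands
}

#' Emit rescued gene models as GFF3 features and peptides
#'
#' Builds one `gene`/`mRNA`/`CDS` feature set per placed candidate, with
#' ids namespaced `rescue.<orthogroup>`. Genomic coordinates are derived
#' from the best-scoring hit of the coding transcript on its placed
#' scaffold, assuming a collinear ungapped alignment between the
#' transcript and the scaffold (the noise-free case; spliced alignments
#' are outside this writer's contract). ORFs without a start codon are
#' flagged `partial=5prime` in the CDS attributes rather than
#' coordinate-adjusted.
#'
#' @param cands ledger from [place_on_genome()].
#' @param genome_hits the hit table used for placement (coordinates are
#'   read from it).
#' @return List with `features` (GFF3 rows for [write_gff3()]) and
#'   `peptides` (`AAStringSet` named `rescue.<orthogroup>`).
#' @export
emit_rescued_models <- function(cands, genome_hits) {
  features <- list(); peps <- character(0)
  placed <- which(cands$status == "placed")
  for (i in placed) {
    og <- cands$orthogroup_id[i]
    tx <- cands$coding_transcript[i]
    orf <- cands$orf[[i]]
    h <- genome_hits[genome_hits$qseqid == tx &
                     genome_hits$sseqid == cands$scaffold[i], , drop = FALSE]
    h <- h[order(-h$bitscore), , drop = FALSE][1, ]
    hit_plus <- h$sstart <= h$send
    map <- function(t) {  # transcript coord -> scaffold coord
      if (hit_plus) h$sstart + (t - h$qstart) else h$sstart - (t - h$qstart)
    }
    g1 <- map(orf$nt_start); g2 <- map(orf$nt_end)
    cds_start <- min(g1, g2); cds_end <- max(g1, g2)
    strand <- if (hit_plus == (orf$frame > 0)) "+" else "-"
    gene_id <- paste0("rescue.", og)
    mrna_id <- paste0(gene_id, ".t1")
    partial <- if (orf$has_start_codon) "" else ";partial=5prime"
    features[[length(features) + 1L]] <- data.frame(
      seqid = cands$scaffold[i], source = "ctenokit_rescue",
      type = c("gene", "mRNA", "CDS"),
      start = cds_start, end = cds_end, score = ".",
      strand = strand, phase = c(".", ".", "0"),
      attributes = c(paste0("ID=", gene_id),
                     paste0("ID=", mrna_id, ";Parent=", gene_id),
                     paste0("ID=", mrna_id, ".cds;Parent=", mrna_id,
                            partial)),
      stringsAsFactors = FALSE)
    peps[gene_id] <- orf$peptide
  }
  feat <- if (length(features) > 0) do.call(rbind, features) else
    genes_to_gff3(data.frame(gene_id = character(), seqid = character(),
                             start = integer(), end = integer(),
                             strand = character(),
                             transcript_ids = I(list())))
  pep_set <- Biostrings::AAStringSet(peps)
  list(features = feat, peptides = pep_set)
}

#' Run the full missed-gene rescue pipeline
#'
#' Chains [find_candidates()], [confirm_novel()], [extract_orfs()],
#' [place_on_genome()] and [emit_rescued_models()]. The returned ledger
#' accounts for every candidate: statuses partition candidates at every
#' stage, so counts always reconcile.
#'
#' @param ogs orthogroup table.
#' @param transcripts focal transcript sequences (`DNAStringSet`).
#' @param model_hits hit table of transcripts vs existing gene models.
#' @param genome_hits hit table of coding regions vs genomic scaffolds.
#' @param focal_model_col,focal_transcript_col,outgroup_cols see
#'   [find_candidates()].
#' @param evalue_cutoff see [confirm_novel()].
#' @param allow_partial,min_codons see [longest_orf()].
#' @return List with `ledger` (the per-candidate status table),
#'   `features` and `peptides` (see [emit_rescued_models()]).
#' @export
rescue_genes <- function(ogs, transcripts, model_hits, genome_hits,
                         focal_model_col, focal_transcript_col,
                         outgroup_cols, evalue_cutoff = 1e-6,
                         allow_partial = TRUE, min_codons = 30L) {
  cands <- find_candidates(ogs, focal_model_col, focal_transcript_col,
                           outgroup_cols)
  cands <- confirm_novel(cands, model_hits, evalue_cutoff)
  cands <- extract_orfs(cands, transcripts, allow_partial, min_codons)
  cands <- place_on_genome(cands, genome_hits)
  out <- emit_rescued_models(cands, genome_hits)
  list(ledger = cands, features = out$features, peptides = out$peptides)
}
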