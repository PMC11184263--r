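#' The canonical chitinase catalytic-site pattern
#'
#' The chitin-degrading active site of glycoside hydrolase family 18
#' chitinases, FDG(X)DXDXE, expressed as a regular expression over
#' peptide strings: the `X` positions admit any residue except a stop
#' (`*`), and the residue after the G is optional.
#'
#' @return The pattern string `FDG[^*]?D[^*]D[^*]E`.
#' @export
chitinase_motif <- function() "FDG[^*]?D[^*]D[^*]E"

#' Six-frame translation
#'
#' Translates a nucleotide sequence in all six reading frames under the
#' standard genetic code. Stop codons are rendered `*`; codons containing
#' `N` are rendered `X`; frames `-1..-3` translate the reverse
#' complement; trailing 1-2 nt that do not complete a codon are dropped.
#'
#' @param seq a `DNAString`, single-sequence `DNAStringSet`, or character
#'   string of length >= 3 nt.
#' @return Named character vector of 6 peptides, names
#'   `"+1","+2","+3","-1","-2","-3"`.
#' @export
six_frame_translate <- function(seq) {
  s <- toupper(as.character(seq)[1])
  L <- nchar(s)
  if (L < 3L) stop_ck("sequence shorter than one codon")
  rc <- revcomp(s)
  one <- function(str, off) {
    ncod <- (L - off + 1L) %/% 3L
    if (ncod < 1L) return("")
    as.character(Biostrings::translate(
      Biostrings::DNAString(substr(str, off, off + 3L * ncod - 1L)),
      if.fuzzy.codon = "X", no.init.codon = TRUE))
  }
  c("+1" = one(s, 1L), "+2" = one(s, 2L), "+3" = one(s, 3L),
    "-1" = one(rc, 1L), "-2" = one(rc, 2L), "-3" = one(rc, 3L))
}

motif_hit_frame <- function() {
  data.frame(source_id = character(), level = character(),
             frame = integer(), aa_start = integer(),
             genomic_start = integer(), genomic_end = integer(),
             matched_peptide = character(), stringsAsFactors = FALSE)
}

#' Scan peptides or a genome for a catalytic motif
#'
#' Peptide mode scans protein sequences directly; genome mode six-frame
#' translates every sequence and reports hits with forward-strand genomic
#' coordinates (the genomic span is exactly `3 *` the matched peptide
#' length, so translating the reported span reproduces the match).
#' Matches are enumerated leftmost non-overlapping per frame with the
#' optional pattern element matched greedily. Translation does not splice
#' across introns, so a motif interrupted by an intron in real genomic
#' sequence is missed.
#'
#' Ambiguous codons translate to `X`, which fails literal pattern
#' positions but satisfies the `[^*]` wildcard classes; `strict_x = TRUE`
#' makes `X` fail the wildcard classes too.
#'
#' @param x an `AAStringSet`/named character vector (peptide mode) or
#'   `DNAStringSet` (genome mode).
#' @param pattern peptide regular expression; default [chitinase_motif()].
#' @param strict_x reject `X` at wildcard (`[^*]`) positions.
#' @return data.frame of hits: `source_id`, `level`
#'   (`"protein"`/`"genome"`), `frame` (genome mode), `aa_start` (1-based
#'   within the frame translation), `genomic_start`/`genomic_end`
#'   (1-based forward strand, genome mode), `matched_peptide`.
#' @export
scan_motif <- function(x, pattern = chitinase_motif(), strict_x = FALSE) {
  if (strict_x) pattern <- gsub("[^*]", "[^*X]", pattern, fixed = TRUE)
  genome_mode <- methods::is(x, "DNAStringSet") ||
    methods::is(x, "DNAString")
  if (methods::is(x, "DNAString")) x <- Biostrings::DNAStringSet(x)
  hits <- list()
  if (!genome_mode) {
    seqs <- as.character(x)
    ids <- names(seqs) %||% as.character(seq_along(seqs))
    for (i in seq_along(seqs)) {
      m <- gregexpr(pattern, seqs[i])[[1]]
      if (m[1] == -1L) next
      hits[[length(hits) + 1L]] <- data.frame(
        source_id = ids[i], level = "protein", frame = NA_integer_,
        aa_start = as.integer(m),
        genomic_start = NA_integer_, genomic_end = NA_integer_,
        matched_peptide = substring(seqs[i], m,
                                    m + attr(m, "match.length") - 1L),
        stringsAsFactors = FALSE)
    }
  } else {
    ids <- names(x) %||% as.character(seq_along(x))
    for (i in seq_along(x)) {
      L <- Biostrings::width(x)[i]
      if (L < 3L) next
      frames <- six_frame_translate(x[[i]])
      for (fname in names(frames)) {
        pep <- frames[[fname]]
        if (!nzchar(pep)) next
        m <- gregexpr(pattern, pep)[[1]]
        if (m[1] == -1L) next
        f <- as.integer(fname)
        aa_start <- as.integer(m)
        w <- attr(m, "match.length")
        off <- abs(f)
        loc_start <- off + 3L * (aa_start - 1L)
        loc_end <- off + 3L * (aa_start + w - 1L) - 1L
        if (f > 0) { gs <- loc_start; ge <- loc_end }
        else { gs <- L - loc_end + 1L; ge <- L - loc_start + 1L }
        hits[[length(hits) + 1L]] <- data.frame(
          source_id = ids[i], level = "genome", frame = f,
          aa_start = aa_start, genomic_start = gs, genomic_end = ge,
          matched_peptide = substring(pep, m, m + w - 1L),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0) return(motif_hit_frame())
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}

#' Write motif hits as a BED-like table
#'
#' Exports genome-level motif hits with BED half-open, 0-based start
#' coordinates (this export is the only place the package uses the
#' half-open convention; a header comment flags it).
#'
#' @param hits data.frame from [scan_motif()] in genome mode.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_motif_bed <- function(hits, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(paste0("# seq\tstart\tend\tframe\tpeptide",
                    " (BED half-open, 0-based start)"), con)
  if (nrow(hits) > 0)
    writeLines(paste(hits$source_id, hits$genomic_start - 1L,
                     hits$genomic_end, hits$frame, hits$matched_peptide,
                     sep = "\t"), con)
  invisible(path)
}

best_hits_per_query <- function(hits) {
  if (nrow(hits) == 0)
    return(list(best = setNames(character(0), character(0)), n_ties = 0L))
  ord <- order(hits$qseqid, -hits$bitscore, hits$evalue, hits$sseqid)
  sorted <- hits[ord, , drop = FALSE]
  first <- !duplicated(sorted$qseqid)
  best <- setNames(sorted$sseqid[first], sorted$qseqid[first])
  # a tie event: >1 subject sharing the query's top bitscore
  top_score <- tapply(hits$bitscore, hits$qseqid, max)
  n_at_top <- mapply(function(q, s)
    sum(hits$bitscore[hits$qseqid == q] == s),
    names(top_score), top_score)
  list(best = best, n_ties = sum(n_at_top > 1L))
}

#' Reciprocal best hits between two directed hit tables
#'
#' The best hit per query is the maximum-bitscore subject, with ties
#' broken by smaller evalue then lexicographic subject id (tie events are
#' counted in the `n_ties` attribute). `(a, b)` is a reciprocal best hit
#' iff `b` is `a`'s best hit in `ab` and `a` is `b`'s best hit in `ba`.
#'
#' @param ab hit table of species-A queries vs species-B subjects.
#' @param ba hit table of species-B queries vs species-A subjects.
#' @return data.frame with `gene_a`, `gene_b`; attribute `n_ties` holds
#'   the number of tie events observed across both directions.
#' @export
reciprocal_best_hits <- function(ab, ba) {
  fa <- best_hits_per_query(ab)
  fb <- best_hits_per_query(ba)
  a_ids <- names(fa$best)
  b_for_a <- unname(fa$best)
  mutual <- !is.na(fb$best[b_for_a]) & fb$best[b_for_a] == a_ids
  mutual[is.na(mutual)] <- FALSE
  out <- data.frame(gene_a = a_ids[mutual], gene_b = b_for_a[mutual],
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_a), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_ties") <- fa$n_ties + fb$n_ties
  out
}

#' Classify proteins as chitinases or chitinase-like
#'
#' True chitinases and chitinase-like proteins both carry the
#' Glyco_hydro_18 domain and bind chitin, but only true chitinases have
#' the chitin-degrading catalytic site. A protein is called `chitinase`
#' when it is a reciprocal best hit to a true-chitinase query and its
#' sequence contains the catalytic motif; `chitinase_like` when it has a
#' significant Glyco_hydro_18 domain (independent E-value strictly below
#' `domain_evalue`) but lacks the motif; otherwise `neither`.
#'
#' @param proteins `AAStringSet` of protein sequences.
#' @param rbh data.frame of reciprocal best hits with `gene_a` = protein
#'   ids, `gene_b` = query ids (from [reciprocal_best_hits()] against the
#'   reference chitinase queries).
#' @param domains domain-hit table from [read_domtbl()].
#' @param chitinase_queries ids of true-chitinase queries; defaults to
#'   every query present in `rbh`.
#' @param domain_evalue independent E-value cutoff (strict `<`).
#' @param domain_name Pfam domain name of the chitin-binding family.
#' @param pattern catalytic-motif pattern.
#' @return data.frame with `protein_id`, `classification`, `rbh_to`,
#'   `has_domain`, `has_catalytic_motif`.
#' @export
classify_chitinases <- function(proteins, rbh, domains,
                                chitinase_queries = unique(rbh$gene_b),
                                domain_evalue = 0.05,
                                domain_name = "Glyco_hydro_18",
                                pattern = chitinase_motif()) {
  ids <- names(proteins)
  dom_ok <- domains$domain_name == domain_name &
    domains$independent_evalue < domain_evalue
  with_domain <- unique(domains$protein_id[dom_ok])
  motif_hits <- scan_motif(proteins, pattern = pattern)
  with_motif <- unique(motif_hits$source_id)
  rbh_true <- rbh[rbh$gene_b %in% chitinase_queries, , drop = FALSE]
  rbh_to <- setNames(rbh_true$gene_b, rbh_true$gene_a)
  out <- data.frame(
    protein_id = ids,
    rbh_to = unname(rbh_to[ids]),
    has_domain = ids %in% with_domain,
    has_catalytic_motif = ids %in% with_motif,
    stringsAsFactors = FALSE)
  out$classification <- ifelse(
    !is.na(out$rbh_to) & out$has_catalytic_motif, "chitinase",
    ifelse(out$has_domain & !out$has_catalytic_motif, "chitinase_like",
           "neither"))
  out[, c("protein_id", "classification", "rbh_to", "has_domain",
          "has_catalytic_motif")]
}
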