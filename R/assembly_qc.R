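#' Assembly summary statistics
#'
#' Computes the standard summary block for a nucleotide assembly:
#' total length, number of sequences, N50, GC content and the bases held
#' in sequences of at least 25 kb.
#'
#' N50 is the length of the sequence at which the cumulative length of
#' sequences sorted in descending order first reaches half the total, so
#' it is always the length of an actual sequence in the assembly. GC is
#' `100 * (G + C) / (A + C + G + T)`: gap `N`s are excluded from the
#' denominator, the usual convention for scaffolded assemblies.
#'
#' @param asm nucleotide `DNAStringSet`, non-empty.
#' @return List with `total_bp`, `n_sequences`, `n50_bp`, `gc_percent`
#'   (2 decimals, half-up), `bp_in_sequences_ge_25kb`, `n_gap_bp`.
#' @export
compute_stats <- function(asm) {
  if (length(asm) == 0) stop_ck("empty assembly")
  len <- Biostrings::width(asm)
  total <- sum(as.numeric(len))
  sorted <- sort(len, decreasing = TRUE)
  n50 <- sorted[which(cumsum(as.numeric(sorted)) >= total / 2)[1]]
  freq <- colSums(Biostrings::alphabetFrequency(asm, baseOnly = TRUE))
  acgt <- sum(freq[c("A", "C", "G", "T")])
  gc <- round_half_up(100 * sum(freq[c("G", "C")]) / acgt, 2)
  n_count <- colSums(Biostrings::alphabetFrequency(asm))["N"]
  list(total_bp = total,
       n_sequences = length(asm),
       n50_bp = n50,
       gc_percent = gc,
       bp_in_sequences_ge_25kb = sum(as.numeric(len[len >= 25000L])),
       n_gap_bp = unname(n_count))
}

#' Completeness percentage from found/total gene counts
#'
#' Formats a core-gene completeness score (BUSCO/CEGMA style) as
#' `100 * n_found / n_total` rounded half-up to 2 decimals, the precision
#' at which such scores are conventionally reported.
#'
#' @param n_found number of core genes found (complete, or complete plus
#'   partial).
#' @param n_total size of the core gene set; must be positive.
#' @return Percentage with 2 decimals.
#' @export
completeness_percent <- function(n_found, n_total) {
  if (n_total <= 0) stop_ck("n_total must be positive")
  if (n_found < 0 || n_found > n_total)
    stop_ck("n_found must be in [0, n_total]")
  round_half_up(100 * n_found / n_total, 2)
}

#' Sequencing throughput in gigabases
#'
#' Converts a read (or read-pair) count and read length to total
#' gigabases, rounded half-up to 1 decimal as reported in sequencing
#' summaries.
#'
#' @param read_pairs number of reads, or read pairs when `paired`.
#' @param read_length read length in bp.
#' @param paired logical; multiply by 2 for paired-end data.
#' @return Gigabases, 1 decimal.
#' @export
gigabases <- function(read_pairs, read_length, paired = TRUE) {
  if (read_length <= 0) stop_ck("read_length must be positive")
  round_half_up(read_pairs * read_length * (if (paired) 2 else 1) / 1e9, 1)
}
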