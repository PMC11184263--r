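#' Configuration for in-silico mate-pair generation
#'
#' In-silico mate pairs transfer the contiguity of a donor assembly to a
#' scaffolder: fixed-length fragments are tiled along each donor sequence
#' and the two fragment ends are emitted as a read pair. Insert-size
#' presets follow common practice for hybrid scaffolding: 2/5/10/15 kb
#' when the donor is a short-read assembly and 2/5/10/20/50/75/100 kb
#' when the donor is a long-read assembly.
#'
#' @param insert_sizes positive integer vector of insert sizes in bp, or
#'   a preset name `"short_read_donor"` / `"long_read_donor"`.
#' @param read_length read length in bp (>= 20).
#' @param step tiling step in bp between fragment starts.
#' @param orientation `"FR"` (innie; read2 reverse-complemented) or
#'   `"RF"` (outie; read1 reverse-complemented).
#' @param max_n_fraction drop a pair when either read's fraction of `N`
#'   exceeds this; pairs dominated by gap Ns carry no linking signal.
#' @return A `mate_pair_config` list.
#' @export
mate_pair_config <- function(insert_sizes = "short_read_donor",
                             read_length = 100L, step = 500L,
                             orientation = c("FR", "RF"),
                             max_n_fraction = 0.1) {
  orientation <- match.arg(orientation)
  if (is.character(insert_sizes)) {
    insert_sizes <- switch(insert_sizes,
      short_read_donor = c(2000L, 5000L, 10000L, 15000L),
      long_read_donor = c(2000L, 5000L, 10000L, 20000L, 50000L, 75000L,
                          100000L),
      stop_ck("unknown insert-size preset: ", insert_sizes))
  }
  insert_sizes <- as.integer(insert_sizes)
  read_length <- as.integer(read_length)
  step <- as.integer(step)
  if (read_length < 20L) stop_ck("read_length must be >= 20")
  if (step < 1L) stop_ck("step must be >= 1")
  if (any(insert_sizes < 2L * read_length))
    stop_ck("every insert size must be >= 2 * read_length")
  if (max_n_fraction < 0 || max_n_fraction > 1)
    stop_ck("max_n_fraction must be in [0, 1]")
  structure(list(insert_sizes = insert_sizes, read_length = read_length,
                 step = step, orientation = orientation,
                 max_n_fraction = max_n_fraction),
            class = "mate_pair_config")
}

#' Generate in-silico mate pairs from a donor assembly
#'
#' For each insert size and each donor sequence of length `L >=` insert,
#' fragments are tiled at 1-based starts `1, 1+step, 1+2*step, ...` while
#' the fragment fits. `read1` is the first `read_length` bases of the
#' fragment and `read2` the last `read_length` bases; under `FR`
#' orientation `read2` is reverse-complemented, under `RF` `read1` is.
#' Pairs where either read's N fraction exceeds `max_n_fraction` are
#' dropped and counted. Pair ids are `<donor>|<start>|<insert>` so every
#' pair is traceable to its fragment.
#'
#' @param donor a nucleotide `DNAStringSet` (e.g. from [read_fasta()]).
#' @param cfg a [mate_pair_config()].
#' @return Named list, one element per insert size (`"lib<insert>"`),
#'   each a list with `pairs` (data.frame: `pair_id`, `read1`, `read2`,
#'   `donor_id`, `donor_start`, `insert_size`) and `n_dropped_n` (pairs
#'   dropped for excess N).
#' @export
make_mate_pairs <- function(donor, cfg = mate_pair_config()) {
  stopifnot(inherits(cfg, "mate_pair_config"))
  seqs <- as.character(donor)
  ids <- names(donor)
  rl <- cfg$read_length
  out <- lapply(cfg$insert_sizes, function(ins) {
    chunks <- lapply(seq_along(seqs), function(i) {
      L <- nchar(seqs[i])
      if (L < ins) return(NULL)
      starts <- seq.int(1L, L - ins + 1L, by = cfg$step)
      r1 <- substring(seqs[i], starts, starts + rl - 1L)
      r2 <- substring(seqs[i], starts + ins - rl, starts + ins - 1L)
      if (cfg$orientation == "FR") r2 <- revcomp(r2) else r1 <- revcomp(r1)
      data.frame(pair_id = paste(ids[i], starts, ins, sep = "|"),
                 read1 = r1, read2 = r2, donor_id = ids[i],
                 donor_start = starts, insert_size = ins,
                 stringsAsFactors = FALSE)
    })
    pairs <- do.call(rbind, chunks)
    if (is.null(pairs))
      pairs <- data.frame(pair_id = character(), read1 = character(),
                          read2 = character(), donor_id = character(),
                          donor_start = integer(), insert_size = integer(),
                          stringsAsFactors = FALSE)
    n_frac <- function(x) {
      vapply(gregexpr("N", x, fixed = TRUE), function(m)
        if (m[1] == -1L) 0L else length(m), integer(1)) / nchar(x)
    }
    keep <- n_frac(pairs$read1) <= cfg$max_n_fraction &
            n_frac(pairs$read2) <= cfg$max_n_fraction
    list(pairs = pairs[keep, , drop = FALSE],
         n_dropped_n = sum(!keep))
  })
  names(out) <- paste0("lib", cfg$insert_sizes)
  out
}

#' Write mate-pair libraries as paired FASTA plus a scaffolder manifest
#'
#' Writes `lib<insert>_1.fasta` / `lib<insert>_2.fasta` per insert size
#' (read ids suffixed `/1` and `/2`) and a library manifest with one line
#' per insert size in the SSPACE style:
#' `lib<insert> <file1> <file2> <insert> <error> <orientation>`.
#'
#' @param libs result of [make_mate_pairs()].
#' @param dir output directory (created if needed).
#' @param cfg the [mate_pair_config()] used (for the orientation field).
#' @param error insert-size error fraction declared to the scaffolder.
#' @return Path to the manifest file, invisibly.
#' @export
write_mate_pair_libraries <- function(libs, dir, cfg = mate_pair_config(),
                                      error = 0.25) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- character(0)
  for (lib in names(libs)) {
    pairs <- libs[[lib]]$pairs
    ins <- sub("^lib", "", lib)
    f1 <- file.path(dir, paste0(lib, "_1.fasta"))
    f2 <- file.path(dir, paste0(lib, "_2.fasta"))
    write_fasta(setNames(pairs$read1, paste0(pairs$pair_id, "/1")), f1)
    write_fasta(setNames(pairs$read2, paste0(pairs$pair_id, "/2")), f2)
    manifest <- c(manifest,
                  paste(lib, basename(f1), basename(f2), ins, error,
                        cfg$orientation))
  }
  manifest_path <- file.path(dir, "libraries.txt")
  writeLines(manifest, manifest_path)
  invisible(manifest_path)
}

#' Break scaffolds at large assembly gaps
#'
#' Scaffolders bridge joins with runs of `N`; implausibly long runs are
#' more likely mis-joins than real gaps. Every maximal run of consecutive
#' `N` whose length is strictly greater than `max_gap` is removed and the
#' scaffold is split there. Runs of length `<= max_gap` are left intact.
#' Pieces are renamed `<orig>.<k>` left to right (scaffolds that are not
#' split keep their name); pieces shorter than `min_piece_length` are
#' dropped and reported.
#'
#' @param asm nucleotide `DNAStringSet`.
#' @param max_gap split at N runs strictly longer than this (bp).
#' @param min_piece_length drop resulting pieces shorter than this (bp).
#' @return List with `assembly` (the broken `DNAStringSet`) and `report`,
#'   a list holding `removed_runs` (data.frame: `scaffold`, `start`,
#'   `end`, `length`), `dropped_pieces` (`DNAStringSet` of pieces removed
#'   by the length filter) and `n_dropped`.
#' @export
break_at_gaps <- function(asm, max_gap = 5000L, min_piece_length = 200L) {
  if (max_gap < 1L) stop_ck("max_gap must be >= 1")
  seqs <- as.character(asm)
  ids <- names(asm)
  pieces <- character(0); piece_ids <- character(0)
  removed <- list()
  for (i in seq_along(seqs)) {
    s <- seqs[i]
    m <- gregexpr("N+", s)[[1]]
    runs_start <- as.integer(m)
    runs_len <- attr(m, "match.length")
    big <- runs_start[1] != -1L & runs_len > max_gap
    if (!any(big)) {
      pieces <- c(pieces, s); piece_ids <- c(piece_ids, ids[i])
      next
    }
    bs <- runs_start[big]; bl <- runs_len[big]
    removed[[length(removed) + 1L]] <-
      data.frame(scaffold = ids[i], start = bs, end = bs + bl - 1L,
                 length = bl, stringsAsFactors = FALSE)
    cut_starts <- c(1L, bs + bl)
    cut_ends <- c(bs - 1L, nchar(s))
    part <- substring(s, cut_starts, cut_ends)
    keep <- nchar(part) > 0L  # a gap at either scaffold end leaves an
    part <- part[keep]        # empty flank, which is not a piece
    pieces <- c(pieces, part)
    piece_ids <- c(piece_ids, paste0(ids[i], ".", seq_along(part)))
  }
  long_enough <- nchar(pieces) >= min_piece_length
  out <- Biostrings::DNAStringSet(pieces[long_enough])
  names(out) <- piece_ids[long_enough]
  dropped <- Biostrings::DNAStringSet(pieces[!long_enough])
  names(dropped) <- piece_ids[!long_enough]
  removed_runs <- if (length(removed) > 0) do.call(rbind, removed) else
    data.frame(scaffold = character(), start = integer(), end = integer(),
               length = integer(), stringsAsFactors = FALSE)
  list(assembly = out,
       report = list(removed_runs = removed_runs,
                     dropped_pieces = dropped,
                     n_dropped = sum(!long_enough)))
}

#' Filter sequences by minimum length
#'
#' Keeps records of length `>= min_len` (the cutoff is applied strictly:
#' shorter records are removed, records exactly at the cutoff kept).
#' Order is preserved.
#'
#' @param asm an `XStringSet`.
#' @param min_len minimum length in bp; 0 keeps everything.
#' @return The filtered `XStringSet`.
#' @export
filter_min_length <- function(asm, min_len = 200L) {
  if (min_len < 0L) stop_ck("min_len must be >= 0")
  asm[Biostrings::width(asm) >= min_len]
}
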