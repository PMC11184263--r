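#' Read a FASTA file with strict alphabet validation
#'
#' Reads nucleotide or peptide FASTA into a [Biostrings::DNAStringSet] /
#' [Biostrings::AAStringSet]. Residues are uppercased; record order is
#' preserved; the part of the header after the first whitespace is kept as
#' the record description (in `mcols(x)$description`).
#'
#' Validation is deliberately strict: duplicated ids, empty sequences and
#' residues outside the declared alphabet (`A/C/G/T/N` for nucleotide;
#' the 20 amino acids plus `*` and `X` for peptide) are hard errors, not
#' warnings. In particular `U` is rejected in nucleotide mode rather than
#' converted: the pipeline never consumes RNA FASTA.
#'
#' @param path path to a FASTA file.
#' @param mode `"nucleotide"` or `"peptide"`.
#' @return A `DNAStringSet` (nucleotide) or `AAStringSet` (peptide), named
#'   by record id, with a `description` metadata column.
#' @seealso [write_fasta()] for the inverse operation.
#' @export
read_fasta <- function(path, mode = c("nucleotide", "peptide")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop_ck("FASTA file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  headers <- names(raw)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(ids == "")) stop_ck("FASTA record with empty id in ", path)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0)
    stop_ck("duplicate FASTA id(s): ", paste(dup, collapse = ", "))
  seqs <- toupper(as.character(raw))
  if (any(nchar(seqs) == 0))
    stop_ck("empty sequence for id(s): ",
            paste(ids[nchar(seqs) == 0], collapse = ", "))
  allowed <- if (mode == "nucleotide") "ACGTN" else "ACDEFGHIKLMNPQRSTVWY*X"
  bad <- setdiff(unique(unlist(strsplit(seqs, ""))),
                 strsplit(allowed, "")[[1]])
  if (length(bad) > 0)
    stop_ck("residues outside the ", mode, " alphabet: ",
            paste(sort(bad), collapse = ", "))
  out <- if (mode == "nucleotide") Biostrings::DNAStringSet(seqs)
         else Biostrings::AAStringSet(seqs)
  names(out) <- ids
  S4Vectors::mcols(out)$description <- desc
  out
}

#' Write sequences as FASTA
#'
#' Writes an `XStringSet` (or named character vector) wrapping sequence
#' lines at a fixed width (default 60 columns). Descriptions stored in
#' `mcols(x)$description` are appended to headers after a space, so
#' `write_fasta(read_fasta(f))` reproduces `f` byte-identically when `f`
#' uses the same line width.
#'
#' @param x an `XStringSet` or named character vector.
#' @param path output path.
#' @param width line-wrap width in columns.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 60L) {
  if (is.character(x)) x <- Biostrings::BStringSet(x)
  ids <- names(x)
  if (is.null(ids) || any(ids == ""))
    stop_ck("all sequences must be named to write FASTA")
  desc <- S4Vectors::mcols(x)$description
  headers <- if (is.null(desc)) ids else
    ifelse(desc == "", ids, paste(ids, desc))
  seqs <- as.character(x)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", headers[i]), con)
    n <- nchar(seqs[i])
    starts <- seq(1L, n, by = width)
    writeLines(substring(seqs[i], starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}

#' Read a 12-column tabular alignment hit file
#'
#' Parses the tab-separated pairwise-hit dialect written by
#' `blastp -outfmt 6`, diamond and compatible tools. The first 12 columns
#' are `qseqid sseqid pident length mismatch gapopen qstart qend sstart
#' send evalue bitscore`; extra columns are ignored; row order is
#' preserved. Rows with non-numeric evalue or bitscore are a hard error
#' reporting the offending line number, so no hit is ever silently
#' dropped.
#'
#' @param path path to the hit file. An empty file yields an empty table.
#' @return data.frame with the 12 standard columns.
#' @export
read_tabular_hits <- function(path) {
  if (!file.exists(path)) stop_ck("hit file not found: ", path)
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  numeric_cols <- setdiff(cols, c("qseqid", "sseqid"))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    out <- as.data.frame(setNames(rep(list(character()), 12), cols))
    out[numeric_cols] <- lapply(out[numeric_cols], as.numeric)
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(fields)
  if (any(nfield < 12))
    stop_ck("line ", which(nfield < 12)[1], ": expected >= 12 columns, got ",
            nfield[which(nfield < 12)[1]])
  mat <- t(vapply(fields, function(f) f[1:12], character(12)))
  out <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(out) <- cols
  for (col in numeric_cols) {
    val <- suppressWarnings(as.numeric(out[[col]]))
    if (anyNA(val))
      stop_ck("line ", which(is.na(val))[1], ": non-numeric ", col,
              " value '", out[[col]][which(is.na(val))[1]], "'")
    out[[col]] <- val
  }
  if (any(out$evalue < 0))
    stop_ck("line ", which(out$evalue < 0)[1], ": negative evalue")
  if (any(out$qseqid == "" | out$sseqid == ""))
    stop_ck("line ", which(out$qseqid == "" | out$sseqid == "")[1],
            ": empty query or subject id")
  out
}

#' Write a hit table in 12-column tabular format
#'
#' @param hits data.frame as returned by [read_tabular_hits()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tabular_hits <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an orthogroup table
#'
#' Parses the tab-separated `Orthogroups.tsv` dialect: a header row with
#' an orthogroup-id column followed by one column per species, cells
#' holding comma-separated member ids. Empty cells become empty character
#' vectors (never missing keys).
#'
#' @param path path to the table.
#' @param species_columns character vector of species column names that
#'   must be present; an absent name is a hard error. `NULL` accepts all
#'   non-id columns.
#' @return An `orthogroup_table`: a named list (one element per
#'   orthogroup) of named lists mapping species -> character vector of
#'   member ids, with a `species` attribute.
#' @export
read_orthogroups <- function(path, species_columns = NULL) {
  if (!file.exists(path)) stop_ck("orthogroup file not found: ", path)
  tab <- read.table(path, header = TRUE, sep = "\t", quote = "",
                    check.names = FALSE, colClasses = "character",
                    stringsAsFactors = FALSE)
  species <- names(tab)[-1]
  if (!is.null(species_columns)) {
    missing <- setdiff(species_columns, species)
    if (length(missing) > 0)
      stop_ck("species column(s) absent from header: ",
              paste(missing, collapse = ", "))
    species <- species_columns
  }
  ogs <- lapply(seq_len(nrow(tab)), function(i) {
    members <- lapply(species, function(sp) {
      cell <- tab[[sp]][i]
      if (is.na(cell) || !nzchar(trimws(cell))) character(0)
      else trimws(strsplit(cell, ",", fixed = TRUE)[[1]])
    })
    names(members) <- species
    members
  })
  names(ogs) <- tab[[1]]
  structure(ogs, species = species, class = "orthogroup_table")
}

#' Write an orthogroup table
#'
#' Inverse of [read_orthogroups()]: members joined with `", "` within each
#' species cell.
#'
#' @param ogs an `orthogroup_table`.
#' @param path output path.
#' @param id_column header name for the orthogroup-id column.
#' @return `path`, invisibly.
#' @export
write_orthogroups <- function(ogs, path, id_column = "Orthogroup") {
  species <- attr(ogs, "species")
  rows <- vapply(ogs, function(og) {
    paste(vapply(species, function(sp) paste(og[[sp]], collapse = ", "),
                 character(1)), collapse = "\t")
  }, character(1))
  lines <- c(paste(c(id_column, species), collapse = "\t"),
             paste(names(ogs), rows, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read protein-domain hits from an hmmscan domain table
#'
#' Parses the whitespace-delimited `--domtblout` dialect of hmmscan:
#' comment lines starting with `#` are skipped; the domain (target) name,
#' accession, query protein, independent (domain-specific) E-value and
#' alignment coordinates are extracted.
#'
#' @param path path to the domain table.
#' @return data.frame with columns `protein_id`, `domain_name`,
#'   `domain_accession`, `independent_evalue`, `ali_start`, `ali_end`.
#' @export
read_domtbl <- function(path) {
  if (!file.exists(path)) stop_ck("domain table not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  empty <- data.frame(protein_id = character(), domain_name = character(),
                      domain_accession = character(),
                      independent_evalue = numeric(),
                      ali_start = integer(), ali_end = integer(),
                      stringsAsFactors = FALSE)
  if (length(lines) == 0) return(empty)
  fields <- strsplit(trimws(lines), "\\s+")
  if (any(lengths(fields) < 19))
    stop_ck("domain-table line with fewer than 19 fields")
  out <- data.frame(
    protein_id = vapply(fields, `[`, character(1), 4),
    domain_name = vapply(fields, `[`, character(1), 1),
    domain_accession = vapply(fields, `[`, character(1), 2),
    independent_evalue = as.numeric(vapply(fields, `[`, character(1), 13)),
    ali_start = as.integer(vapply(fields, `[`, character(1), 18)),
    ali_end = as.integer(vapply(fields, `[`, character(1), 19)),
    stringsAsFactors = FALSE)
  if (anyNA(out$independent_evalue) || any(out$independent_evalue < 0))
    stop_ck("invalid independent E-value in domain table")
  if (any(out$ali_start > out$ali_end))
    stop_ck("domain alignment with ali_start > ali_end")
  out
}

#' Read gene loci from a GFF3 annotation
#'
#' Imports a GFF3 file (via rtracklayer) and returns one row per `gene`
#' feature with 1-based inclusive coordinates and the ids of its `mRNA`
#' children.
#'
#' @param path path to a GFF3 file.
#' @return data.frame with columns `gene_id`, `seqid`, `start`, `end`,
#'   `strand` and a list-column `transcript_ids`.
#' @export
read_gff3_genes <- function(path) {
  if (!file.exists(path)) stop_ck("GFF3 file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  genes <- gr[gr$type == "gene"]
  mrnas <- gr[gr$type == "mRNA"]
  parent <- vapply(mrnas$Parent, function(p) p[1] %||% NA_character_,
                   character(1))
  tx_by_gene <- split(mrnas$ID, parent)
  gene_ids <- genes$ID
  data.frame(
    gene_id = gene_ids,
    seqid = as.character(GenomeInfoDb::seqnames(genes)),
    start = BiocGenerics::start(genes),
    end = BiocGenerics::end(genes),
    strand = as.character(BiocGenerics::strand(genes)),
    transcript_ids = I(unname(lapply(gene_ids, function(g)
      as.character(tx_by_gene[[g]] %||% character(0))))),
    stringsAsFactors = FALSE)
}

#' Write GFF3 feature rows
#'
#' Low-level writer for a data.frame of GFF3 columns (`seqid`, `source`,
#' `type`, `start`, `end`, `score`, `strand`, `phase`, `attributes`).
#' An empty feature frame yields a valid header-only file.
#'
#' @param features data.frame of GFF3 columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(features) > 0) {
    lines <- paste(features$seqid, features$source, features$type,
                   features$start, features$end, features$score,
                   features$strand, features$phase, features$attributes,
                   sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Build gene/mRNA GFF3 feature rows from a gene table
#'
#' Converts a gene table (as returned by [read_gff3_genes()] or produced
#' by the genome simulator) to GFF3 feature rows with one `gene` and one
#' `mRNA` feature per transcript.
#'
#' @param genes data.frame with `gene_id`, `seqid`, `start`, `end`,
#'   `strand` and list-column `transcript_ids`.
#' @param source value for the GFF3 source column.
#' @return data.frame of GFF3 feature rows for [write_gff3()].
#' @export
genes_to_gff3 <- function(genes, source = "ctenokit") {
  if (nrow(genes) == 0)
    return(data.frame(seqid = character(), source = character(),
                      type = character(), start = integer(),
                      end = integer(), score = character(),
                      strand = character(), phase = character(),
                      attributes = character(), stringsAsFactors = FALSE))
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    tx <- g$transcript_ids[[1]]
    rbind(
      data.frame(seqid = g$seqid, source = source, type = "gene",
                 start = g$start, end = g$end, score = ".",
                 strand = g$strand, phase = ".",
                 attributes = paste0("ID=", g$gene_id),
                 stringsAsFactors = FALSE),
      data.frame(seqid = g$seqid, source = source, type = "mRNA",
                 start = g$start, end = g$end, score = ".",
                 strand = g$strand, phase = ".",
                 attributes = paste0("ID=", tx, ";Parent=", g$gene_id),
                 stringsAsFactors = FALSE))
  })
  do.call(rbind, rows)
}
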