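og_table <- function(rows, species) {
  structure(rows, species = species, class = "orthogroup_table")
}

toy_ogs <- og_table(list(
  OG1 = list(models = "g1", tx = "t1", outA = "x1", outB = character(0)),
  OG2 = list(models = character(0), tx = "t2", outA = character(0),
             outB = character(0)),
  OG3 = list(models = character(0), tx = c("t3", "t3b"), outA = "x3",
             outB = character(0)),
  OG4 = list(models = character(0), tx = character(0), outA = "x4",
             outB = "y4")),
  species = c("models", "tx", "outA", "outB"))

test_that("candidates need absent models, present transcripts and outgroup support", {
  cands <- find_candidates(toy_ogs, "models", "tx", c("outA", "outB"))
  expect_equal(cands$orthogroup_id, "OG3")  # OG1 has a model, OG2 lacks
  expect_equal(cands$transcript_ids[[1]], c("t3", "t3b"))  # support, OG4
  expect_equal(cands$supporting_species[[1]], "outA")      # lacks tx
  expect_error(find_candidates(toy_ogs, "models", "tx", "outC"), "outC")
})

test_that("novelty confirmation applies a strict E-value boundary", {
  cands <- find_candidates(toy_ogs, "models", "tx", c("outA", "outB"))
  reject <- confirm_novel(cands, hit_table("t3", "m1", 100, evalue = 1e-7))
  expect_equal(reject$status, "rejected:has_model_hit")
  at_cutoff <- confirm_novel(cands, hit_table("t3", "m1", 100,
                                              evalue = 1e-6))
  expect_equal(at_cutoff$status, "confirmed")  # 1e-6 is not < 1e-6
  no_hit <- confirm_novel(cands, hit_table("other", "m1", 100,
                                           evalue = 1e-30))
  expect_equal(no_hit$status, "confirmed")
})

test_that("longest_orf translates the textbook example", {
  orf <- longest_orf("ATGAAATAA", allow_partial = FALSE, min_codons = 1)
  expect_equal(orf$peptide, "MK")
  expect_true(orf$has_start_codon)
  expect_equal(orf$frame, 1)
  expect_equal(c(orf$nt_start, orf$nt_end), c(1L, 6L))
})

test_that("longest_orf is symmetric under reverse complement", {
  set.seed(31)
  for (rep in 1:30) {
    s <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
               collapse = "")
    a <- longest_orf(s, min_codons = 5)
    b <- longest_orf(revcomp(s), min_codons = 5)
    expect_equal(a$peptide, b$peptide)
    expect_equal(sign(a$frame), -sign(b$frame))
  }
})

test_that("longest_orf agrees with exhaustive six-frame enumeration", {
  set.seed(32)
  for (rep in 1:200) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(60:400, 1),
                      replace = TRUE), collapse = "")
    for (partial in c(TRUE, FALSE))
      expect_equal(longest_orf(s, partial, min_codons = 5),
                   oracle_longest_orf(s, partial, min_codons = 5))
  }
})

test_that("ORFs below the minimum codon floor are not reported", {
  expect_null(longest_orf("ATGAAATAA", min_codons = 30))
})

test_that("placement needs exactly one genomic scaffold", {
  cands <- find_candidates(toy_ogs, "models", "tx", c("outA", "outB"))
  cands$status <- "orf_extracted"
  multi <- place_on_genome(cands, hit_table(c("t3", "t3"), c("s1", "s2"),
                                            c(100, 90)))
  expect_equal(multi$status, "rejected:multi_scaffold")
  hsps <- place_on_genome(cands, hit_table(rep("t3", 3), rep("s1", 3),
                                           c(100, 90, 80)))
  expect_equal(hsps$status, "placed")  # 3 HSPs, one distinct scaffold
  expect_equal(hsps$scaffold, "s1")
  none <- place_on_genome(cands, hit_table("other", "s1", 100))
  expect_equal(none$status, "rejected:no_alignment")
})

test_that("emitted CDS translates back to the stored peptide, both strands", {
  set.seed(33)
  non_stop <- names(Biostrings::GENETIC_CODE)[
    Biostrings::GENETIC_CODE != "*"]
  for (strand_case in c("forward", "transcript_minus")) {
    cds <- paste0("ATG", paste(sample(non_stop, 40, replace = TRUE),
                               collapse = ""), "TAA")
    tx <- if (strand_case == "forward") cds else revcomp(cds)
    flank_l <- paste(sample(c("A", "C"), 37, replace = TRUE),
                     collapse = "")
    flank_r <- paste(sample(c("G", "T"), 23, replace = TRUE),
                     collapse = "")
    scaffold <- paste0(flank_l, tx, flank_r)
    ogs <- og_table(list(OGx = list(models = character(0), tx = "txA",
                                    out = "o1")),
                    species = c("models", "tx", "out"))
    genome_hits <- hit_table("txA", "sc1", 500, qstart = 1,
                             qend = nchar(tx), sstart = 38,
                             send = 37 + nchar(tx))
    res <- rescue_genes(ogs,
                        Biostrings::DNAStringSet(c(txA = tx)),
                        hit_table(), genome_hits,
                        "models", "tx", "out", min_codons = 10)
    expect_equal(res$ledger$status, "placed")
    cds_row <- res$features[res$features$type == "CDS", ]
    span <- substr(scaffold, cds_row$start, cds_row$end)
    if (cds_row$strand == "-") span <- revcomp(span)
    translated <- as.character(Biostrings::translate(
      Biostrings::DNAString(span), no.init.codon = TRUE))
    expect_equal(translated,
                 as.character(res$peptides[[paste0("rescue.OGx")]]))
  }
})

test_that("empty input yields a valid header-only GFF3 and partial ORFs are flagged", {
  empty <- emit_rescued_models(
    data.frame(orthogroup_id = character(), status = character(),
               stringsAsFactors = FALSE), hit_table())
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(empty$features, f)
  expect_equal(readLines(f), "##gff-version 3")

  # ORF with no ATG anywhere: emitted 5'-partial
  pep_src <- paste(rep("GAA", 40), collapse = "")  # E repeats, no M
  tx <- paste0(pep_src, "TAA")
  ogs <- og_table(list(OGp = list(models = character(0), tx = "txP",
                                  out = "o1")),
                  species = c("models", "tx", "out"))
  res <- rescue_genes(ogs, Biostrings::DNAStringSet(c(txP = tx)),
                      hit_table(),
                      hit_table("txP", "sc1", 500, qstart = 1,
                                qend = nchar(tx), sstart = 1,
                                send = nchar(tx)),
                      "models", "tx", "out", min_codons = 10)
  cds_attr <- res$features$attributes[res$features$type == "CDS"]
  expect_match(cds_attr, "partial=5prime")
})

test_that("pipeline statuses reconcile and noise-free recovery is exact", {
  sim <- simulate_two_species_genomes(41, n_chromosomes = 3, n_genes = 90,
                                      sequences = FALSE)
  og <- simulate_orthogroups(42, sim$manifest,
                             missing_annotation_rate = 0.15,
                             isoform_rate = 0.1)
  res <- rescue_genes(og$runs$run1, og$transcripts, og$model_hits,
                      og$genome_hits, "A_prot", "A_tx",
                      c("B_prot", "C_prot"))
  targets <- og$manifest$rescue_targets
  expect_equal(nrow(res$ledger), length(targets))  # candidates = planted
  expect_true(all(res$ledger$status %in%
    c("placed", "rejected:has_model_hit", "rejected:no_orf",
      "rejected:multi_scaffold", "rejected:no_alignment")))
  placed <- res$ledger$orthogroup_id[res$ledger$status == "placed"]
  # precision and recall both 1: placed orthogroups are exactly the
  # planted rescue targets
  placed_genes <- sub("^tx_", "",
                      res$ledger$coding_transcript[res$ledger$status ==
                                                   "placed"])
  expect_setequal(placed_genes, targets)
  expect_equal(length(res$peptides), length(targets))
})
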