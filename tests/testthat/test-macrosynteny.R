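test_that("placements use gene midpoints and skip missing genes", {
  pairs <- data.frame(gene_a = c("a1", "a2"), gene_b = c("b1", "b2"),
                      stringsAsFactors = FALSE)
  genes_a <- data.frame(gene_id = "a1", seqid = "sc1", start = 100L,
                        end = 200L, strand = "+",
                        transcript_ids = I(list("a1.t1")),
                        stringsAsFactors = FALSE)
  genes_b <- data.frame(gene_id = c("b1", "b2"), seqid = "chr1",
                        start = c(10L, 50L), end = c(20L, 90L),
                        strand = "+",
                        transcript_ids = I(list("b1.t1", "b2.t1")),
                        stringsAsFactors = FALSE)
  pl <- place_orthologs(pairs, genes_a, genes_b)
  expect_equal(nrow(pl), 1L)
  expect_equal(pl$position_a, 150)
  expect_equal(pl$position_b, 15)
  expect_equal(attr(pl, "n_skipped"), 1L)
})

concentrated_placements <- function(n_chrom = 13, per_chrom = 20) {
  # one scaffold per chromosome, all orthologs concentrated
  do.call(rbind, lapply(seq_len(n_chrom), function(c)
    data.frame(gene_a = paste0("a", c, "_", seq_len(per_chrom)),
               gene_b = paste0("b", c, "_", seq_len(per_chrom)),
               scaffold_a = paste0("sc", c),
               position_a = seq_len(per_chrom) * 1000,
               chromosome_b = sprintf("chr%02d", c),
               position_b = seq_len(per_chrom) * 1000,
               stringsAsFactors = FALSE)))
}

test_that("enrichment p-values equal the exact hypergeometric oracle", {
  pl <- concentrated_placements()
  asg <- assign_scaffolds(pl)
  expect_true(all(asg$significant))
  for (i in seq_len(nrow(asg))) {
    # 20 of the scaffold's 20 orthologs on a chromosome holding 20 of 260
    expect_equal(asg$p_value[i], oracle_hyper_upper(20, 20, 240, 20),
                 tolerance = 1e-12)
  }
  expect_equal(chromosome_count(asg)$count, 13L)
})

test_that("cells below the ortholog floor are never tested", {
  pl <- data.frame(gene_a = paste0("a", 1:3), gene_b = paste0("b", 1:3),
                   scaffold_a = "sc1", position_a = 1:3 * 100,
                   chromosome_b = paste0("chr", 1:3),
                   position_b = 1:3 * 100, stringsAsFactors = FALSE)
  expect_warning(asg <- assign_scaffolds(pl, min_orthologs = 3L),
                 "min_orthologs")
  expect_equal(nrow(asg), 0L)
})

test_that("BH correction matches the textbook step-up rule", {
  set.seed(91)
  sim <- simulate_two_species_genomes(92, n_chromosomes = 6,
                                      n_genes = 600,
                                      scaffolds_per_chromosome = 3,
                                      shuffle_rate = 0.1,
                                      sequences = FALSE)
  pl <- place_orthologs(sim$manifest$pairs, sim$genes_a, sim$genes_b)
  asg <- assign_scaffolds(pl, alpha = 0.05)
  expect_equal(asg$significant,
               oracle_bh_reject(asg$p_value, 0.05))
  # q-values are monotone non-decreasing in p-rank
  ord <- order(asg$p_value)
  expect_true(all(diff(asg$q_value[ord]) >= -1e-12))
  expect_true(all(asg$p_value >= 0 & asg$p_value <= 1))
})

test_that("label permutation destroys significance almost always", {
  set.seed(93)
  # 26 scaffolds of 50 orthologs over 13 chromosomes, perfectly linked
  pl <- do.call(rbind, lapply(1:26, function(s)
    data.frame(gene_a = paste0("a", s, "_", 1:50),
               gene_b = paste0("b", s, "_", 1:50),
               scaffold_a = sprintf("sc%02d", s),
               position_a = 1:50 * 1000,
               chromosome_b = sprintf("chr%02d", (s - 1) %/% 2 + 1),
               position_b = 1:50 * 1000, stringsAsFactors = FALSE)))
  destroyed <- 0L
  n_rep <- 20L
  for (r in seq_len(n_rep)) {
    perm <- pl
    perm$chromosome_b <- sample(perm$chromosome_b)
    asg <- suppressWarnings(assign_scaffolds(perm))
    if (nrow(asg) == 0L || !any(asg$significant))
      destroyed <- destroyed + 1L
  }
  expect_gte(destroyed, ceiling(0.95 * n_rep))
})

test_that("chromosome count handles toy and empty cases", {
  pl <- concentrated_placements(n_chrom = 1, per_chrom = 10)
  pl$chromosome_b <- "chrZ"
  asg <- assign_scaffolds(pl)
  expect_equal(chromosome_count(asg)$count, 1L)
  asg$significant <- FALSE
  asg$primary <- FALSE
  expect_warning(cc <- chromosome_count(asg), "no significantly")
  expect_equal(cc$count, 0L)
})

test_that("translocation flags respect both floors", {
  # the rule itself, on hand-built assignments with known significance
  mk <- function(n_main, n_sec) {
    asg <- data.frame(
      scaffold_a = c("scT", "scT"),
      chromosome_b = c("chr1", "chr7"),
      n_shared = c(n_main, n_sec),
      p_value = c(1e-20, 1e-6), q_value = c(1e-18, 1e-5),
      significant = TRUE, primary = c(TRUE, FALSE),
      stringsAsFactors = FALSE)
    pl <- data.frame(
      gene_a = paste0("t", seq_len(n_main + n_sec)),
      gene_b = paste0("u", seq_len(n_main + n_sec)),
      scaffold_a = "scT", position_a = seq_len(n_main + n_sec),
      chromosome_b = c(rep("chr1", n_main), rep("chr7", n_sec)),
      position_b = seq_len(n_main + n_sec), stringsAsFactors = FALSE)
    list(asg = asg, pl = pl)
  }
  x <- mk(24, 6)
  fl <- flag_translocations(x$asg, x$pl)
  expect_equal(fl$scaffold_a, "scT")
  expect_equal(fl$primary_chromosome, "chr1")
  expect_equal(fl$secondary_chromosome, "chr7")
  expect_equal(fl$n_secondary, 6L)

  y <- mk(29, 1)  # secondary below both floors
  expect_equal(nrow(flag_translocations(y$asg, y$pl)), 0L)

  # a non-significant secondary cell never flags, whatever its size
  z <- mk(24, 6)
  z$asg$significant[2] <- FALSE
  expect_equal(nrow(flag_translocations(z$asg, z$pl)), 0L)
})

test_that("planted translocations are recovered from simulated genomes", {
  sim <- simulate_two_species_genomes(94, n_chromosomes = 13,
                                      n_genes = 1300,
                                      scaffolds_per_chromosome = 8,
                                      n_translocations = 3,
                                      translocation_block = 8,
                                      sequences = FALSE)
  pl <- place_orthologs(sim$manifest$pairs, sim$genes_a, sim$genes_b)
  asg <- assign_scaffolds(pl)
  fl <- flag_translocations(asg, pl)
  planted <- sim$manifest$translocations
  expect_equal(nrow(fl), nrow(planted))
  expect_setequal(paste(fl$scaffold_a, fl$secondary_chromosome),
                  paste(planted$scaffold, planted$donor_chromosome))

  clean <- simulate_two_species_genomes(95, n_chromosomes = 8,
                                        n_genes = 800,
                                        scaffolds_per_chromosome = 2,
                                        sequences = FALSE)
  plc <- place_orthologs(clean$manifest$pairs, clean$genes_a,
                         clean$genes_b)
  expect_equal(nrow(flag_translocations(assign_scaffolds(plc), plc)), 0L)
})

test_that("dot-plot coordinates are prefix sums, invariant to row order", {
  pl <- data.frame(gene_a = c("a1", "a2"), gene_b = c("b1", "b2"),
                   scaffold_a = c("sc1", "sc2"),
                   position_a = c(100, 200),
                   chromosome_b = c("chr1", "chr2"),
                   position_b = c(50, 70), stringsAsFactors = FALSE)
  la <- c(sc1 = 1000, sc2 = 500)
  lb <- c(chr1 = 2000, chr2 = 800)
  dp <- dotplot_table(pl, la, lb, order_a = c("sc1", "sc2"),
                      order_b = c("chr1", "chr2"))
  expect_equal(dp$y, c(100, 1000 + 200))
  expect_equal(dp$x, c(50, 2000 + 70))
  dp2 <- dotplot_table(pl[2:1, ], la, lb, order_a = c("sc1", "sc2"),
                       order_b = c("chr1", "chr2"))
  expect_equal(dp, dp2)
  empty <- dotplot_table(pl[0, ], la, lb)
  expect_equal(nrow(empty), 0L)
})

test_that("scaffold ordering groups by assigned chromosome then size", {
  pl <- concentrated_placements(n_chrom = 3, per_chrom = 10)
  asg <- assign_scaffolds(pl)
  lens <- c(sc1 = 500, sc2 = 900, sc3 = 700, scX = 10000)
  ord <- scaffold_order(asg, lens)
  expect_equal(ord, c("sc1", "sc2", "sc3", "scX"))  # unassigned last
})
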