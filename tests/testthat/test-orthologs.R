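og_table <- function(rows, species) {
  structure(rows, species = species, class = "orthogroup_table")
}

test_that("direct one-to-ones count only the two focal species", {
  run <- og_table(list(
    OG1 = list(A = "a1", B = "b1", C = c("c1", "c2")),
    OG2 = list(A = c("a2", "a3"), B = "b2", C = character(0)),
    OG3 = list(A = "a4", B = character(0), C = "c3")),
    species = c("A", "B", "C"))
  pairs <- direct_one_to_ones(run, "A", "B", "i1.5")
  expect_equal(pairs$gene_a, "a1")  # OG2 blocked by multiplicity,
  expect_equal(pairs$gene_b, "b1")  # OG3 by absence
  expect_equal(pairs$source_runs, "i1.5")
  expect_error(direct_one_to_ones(run, "A", "Z"), "Z")
})

test_that("union over runs merges labels and removes conflicting genes", {
  r1 <- data.frame(gene_a = "a1", gene_b = "b1", source_runs = "",
                   stringsAsFactors = FALSE)
  same <- union_runs(list(x = r1, y = r1))
  expect_equal(nrow(same$pairs), 1L)
  expect_equal(same$pairs$source_runs, "x,y")
  expect_equal(same$conflicts, character(0))

  r2 <- data.frame(gene_a = "a1", gene_b = "b2", source_runs = "",
                   stringsAsFactors = FALSE)
  clash <- union_runs(list(x = r1, y = r2))
  expect_equal(nrow(clash$pairs), 0L)
  expect_equal(clash$conflicts, "a1")
})

test_that("conflict detection matches a brute-force partner census", {
  set.seed(51)
  for (rep in 1:30) {
    runs <- lapply(1:3, function(r) {
      n <- sample(3:10, 1)
      data.frame(gene_a = paste0("a", sample(8, n, TRUE)),
                 gene_b = paste0("b", sample(8, n, TRUE)),
                 source_runs = "", stringsAsFactors = FALSE)
    })
    res <- union_runs(runs)
    all_pairs <- unique(do.call(rbind,
                                lapply(runs, `[`, c("gene_a", "gene_b"))))
    census_conflicts <- character(0)
    for (g in unique(c(all_pairs$gene_a, all_pairs$gene_b))) {
      partners <- unique(c(
        all_pairs$gene_b[all_pairs$gene_a == g],
        all_pairs$gene_a[all_pairs$gene_b == g]))
      if (length(partners) > 1) census_conflicts <- c(census_conflicts, g)
    }
    expect_setequal(res$conflicts, census_conflicts)
    expect_false(any(res$pairs$gene_a %in% census_conflicts |
                     res$pairs$gene_b %in% census_conflicts))
  }
})

test_that("midpoint root lands half the diameter from the farthest leaves", {
  tr <- ape::read.tree(text = "(A:1,B:4,(C:2,D:3):2);")
  rt <- midpoint_root(tr)
  dep <- ape::node.depth.edgelength(rt)[1:4]
  names(dep) <- rt$tip.label
  expect_equal(unname(dep["B"]), 4.5)  # B<->D path is 9
  expect_equal(unname(dep["D"]), 4.5)
  expect_equal(unname(dep["A"]), 1.5)

  two <- midpoint_root(ape::read.tree(text = "(A:1,B:3);"))
  expect_equal(unname(ape::node.depth.edgelength(two)[1:2]), c(2, 2))
})

test_that("midpoint rooting is invariant to leaf order and warns on zero lengths", {
  tr1 <- ape::read.tree(text = "(A:1,B:4,(C:2,D:3):2);")
  tr2 <- ape::read.tree(text = "((D:3,C:2):2,B:4,A:1);")
  r1 <- midpoint_root(tr1); r2 <- midpoint_root(tr2)
  expect_equal(as.numeric(suppressWarnings(ape::dist.topo(r1, r2))), 0)
  zero <- ape::read.tree(text = "(A:0,B:0,(C:0,D:0):0);")
  expect_warning(rz <- midpoint_root(zero), "all-zero")
  expect_true(ape::is.rooted(rz))
})

test_that("midpoint rooting matches the exhaustive path-length oracle", {
  set.seed(52)
  for (rep in 1:200) {
    tr <- random_tree(sample(4:8, 1))
    d <- oracle_tip_distances(tr)
    rt <- midpoint_root(tr)
    n <- length(rt$tip.label)
    dep <- ape::node.depth.edgelength(rt)[1:n]
    expect_equal(max(dep), max(d) / 2, tolerance = 1e-9)
    kids <- rt$edge[rt$edge[, 1] == n + 1, 2]
    expect_length(kids, 2)  # binary root
  }
})

test_that("cherry rescue keeps only cross-species two-leaf clades", {
  t1 <- ape::read.tree(text =
    "((Bo_g1:1,Ml_g2:1):1,(Bo_g3:1,Hc_g4:1):1);")
  pairs <- cherry_rescue(list(t1), "Bo", "Ml")
  expect_equal(pairs$gene_a, "Bo_g1")
  expect_equal(pairs$gene_b, "Ml_g2")

  t2 <- ape::read.tree(text = "((Ml_g1:1,Ml_g2:1):1,Bo_g1:1,Hc_g1:1);")
  expect_equal(nrow(cherry_rescue(list(t2), "Bo", "Ml")), 0L)

  small <- ape::read.tree(text = "(Bo_g9:1,Ml_g9:1);")
  expect_equal(nrow(cherry_rescue(list(small), "Bo", "Ml")), 0L)
  expect_equal(nrow(cherry_rescue(list(small), "Bo", "Ml",
                                  min_leaves = 2)), 1L)

  bad <- ape::read.tree(text = "((Bog1:1,Ml_g2:1):1,Hc_g1:1,Hc_g2:1);")
  expect_error(cherry_rescue(list(bad), "Bo", "Ml"), "Bog1")
})

test_that("genes in multiple distinct cherries are dropped as ambiguous", {
  t1 <- ape::read.tree(text = "((Bo_g1:1,Ml_g2:1):1,Hc_a:1,Hc_b:1);")
  t2 <- ape::read.tree(text = "((Bo_g1:1,Ml_g9:1):1,Hc_a:1,Hc_b:1);")
  expect_equal(nrow(cherry_rescue(list(t1, t2), "Bo", "Ml")), 0L)
  # the same pairing twice is not ambiguous
  expect_equal(nrow(cherry_rescue(list(t1, t1), "Bo", "Ml")), 1L)
})

test_that("planted cherries are recovered exactly from simulated trees", {
  sim <- simulate_two_species_genomes(53, n_chromosomes = 2, n_genes = 40,
                                      sequences = FALSE)
  og <- simulate_orthogroups(54, sim$manifest, cherry_rate = 0.2)
  pairs <- cherry_rescue(og$trees, "A", "B")
  expect_equal(nrow(pairs), length(og$manifest$cherry_genes))
  expect_setequal(pairs$gene_a, og$manifest$expected_tree$gene_a)
})

test_that("isoform collapse rescues blocked orthogroups only", {
  run <- og_table(list(
    OG1 = list(A = c("a1.t1", "a1.t2"), B = "b1.t1"),
    OG2 = list(A = c("a1.t1", "a2.t1"), B = "b2.t1"),
    OG3 = list(A = "a3", B = "b3")),
    species = c("A", "B"))
  res <- isoform_rescue(run, "A", "B")
  expect_equal(res$pairs$gene_a, "a1")  # OG2 has two loci, OG3 is a
  expect_equal(res$pairs$gene_b, "b1")  # plain one-to-one
  all_single <- isoform_rescue(run, "A", "B", only_blocked = FALSE)
  expect_setequal(all_single$pairs$gene_a, c("a1", "a3"))
})

test_that("isoform pairs conflicting across runs are discarded", {
  r1 <- og_table(list(OG1 = list(A = c("a1.t1", "a1.t2"), B = "b1.t1")),
                 species = c("A", "B"))
  r2 <- og_table(list(OG1 = list(A = c("a1.t1", "a1.t2"), B = "b9.t1")),
                 species = c("A", "B"))
  res <- isoform_rescue(list(x = r1, y = r2), "A", "B")
  expect_equal(nrow(res$pairs), 0L)
  expect_true("a1" %in% res$conflicts)
})

test_that("planted isoform expansions are recovered from the generator", {
  sim <- simulate_two_species_genomes(55, n_chromosomes = 2, n_genes = 50,
                                      sequences = FALSE)
  og <- simulate_orthogroups(56, sim$manifest, isoform_rate = 0.2)
  res <- isoform_rescue(og$runs, "A_prot", "B_prot")
  expect_equal(nrow(res$pairs), length(og$manifest$isoform_genes))
  expect_setequal(res$pairs$gene_a, og$manifest$expected_isoform$gene_a)
})

test_that("finalize merges provenance and removes cross-source clashes", {
  d <- data.frame(gene_a = "a1", gene_b = "b1", source_runs = "i1.5",
                  stringsAsFactors = FALSE)
  t <- data.frame(gene_a = "a1", gene_b = "b1", source_runs = "tree1",
                  stringsAsFactors = FALSE)
  merged <- finalize_orthologs(d, t)
  expect_equal(nrow(merged$pairs), 1L)
  expect_equal(merged$pairs$provenance, "direct,tree")

  iso <- data.frame(gene_a = "a1", gene_b = "b2", source_runs = "run1",
                    stringsAsFactors = FALSE)
  clash <- finalize_orthologs(d, isoform_pairs = iso)
  expect_equal(nrow(clash$pairs), 0L)
  expect_equal(clash$conflicts$gene, "a1")
  expect_equal(clash$conflicts$partners, "b1,b2")
})

test_that("the final set is always a partial matching", {
  set.seed(57)
  for (rep in 1:20) {
    mk <- function(n) data.frame(
      gene_a = paste0("a", sample(10, n, TRUE)),
      gene_b = paste0("b", sample(10, n, TRUE)),
      source_runs = "r", stringsAsFactors = FALSE)
    fin <- finalize_orthologs(mk(6), mk(6), mk(6))
    expect_false(any(duplicated(fin$pairs$gene_a)))
    expect_false(any(duplicated(fin$pairs$gene_b)))
  }
})

test_that("adding a clustering run can only grow the pre-conflict union", {
  sim <- simulate_two_species_genomes(58, n_chromosomes = 2, n_genes = 40,
                                      sequences = FALSE)
  og <- simulate_orthogroups(59, sim$manifest, misclustering_rate = 0.1)
  per_run <- lapply(og$runs, direct_one_to_ones, "A_prot", "B_prot")
  raw_union <- function(runs) {
    unique(do.call(rbind, lapply(runs, `[`, c("gene_a", "gene_b"))))
  }
  for (k in 2:4) {
    prev <- raw_union(per_run[seq_len(k - 1)])
    now <- raw_union(per_run[seq_len(k)])
    expect_true(nrow(merge(prev, now)) == nrow(prev))  # prev subset of now
  }
})

test_that("full consolidation recovers the planted manifest when noise-free", {
  sim <- simulate_two_species_genomes(60, n_chromosomes = 3, n_genes = 90,
                                      sequences = FALSE)
  og <- simulate_orthogroups(61, sim$manifest, isoform_rate = 0.1,
                             cherry_rate = 0.1,
                             missing_annotation_rate = 0.1)
  direct <- union_runs(lapply(og$runs, direct_one_to_ones,
                              "A_prot", "B_prot"))
  trees <- cherry_rescue(og$trees, "A", "B")
  iso <- isoform_rescue(og$runs, "A_prot", "B_prot")
  fin <- finalize_orthologs(direct$pairs, trees, iso$pairs)
  # rescue-target genes lost their focal protein model, so they are
  # absent from every route and from the expected final set
  expected <- og$manifest$expected_final
  expect_setequal(paste(fin$pairs$gene_a, fin$pairs$gene_b),
                  paste(expected$gene_a, expected$gene_b))
})
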