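# blocks A and B cover the same sorghum genes (the two subgenome copies);
# C sits elsewhere and should join the bigger group
abc_anchors <- function() {
  dplyr::bind_rows(
    simple_block("A", 20, from = 0L, maize_chrom = "chr1"),
    simple_block("B", 14, from = 0L, maize_chrom = "chr5"),
    simple_block("C", 13, from = 20L, maize_chrom = "chr2")
  )
}

test_that("greedy grouping separates overlapping blocks and pools disjoint ones", {
  bp <- greedy_bipartition(abc_anchors())
  grp <- setNames(bp$blocks$group, bp$blocks$block_id)
  expect_equal(grp[["A"]], 1L)   # largest placed first
  expect_equal(grp[["B"]], 2L)   # clashes with A on s1..s20
  expect_equal(grp[["C"]], 1L)   # disjoint, group 1 tried first
  expect_true(validate_bipartition(bp))
})

test_that("a block clashing with both groups becomes an orphan", {
  anchors <- dplyr::bind_rows(
    simple_block("A", 20, from = 0L, maize_chrom = "chr1"),
    simple_block("B", 14, from = 0L, maize_chrom = "chr5"),
    simple_block("D", 12, from = 10L, maize_chrom = "chr7")  # overlaps A and B
  )
  bp <- greedy_bipartition(anchors)
  grp <- setNames(bp$blocks$group, bp$blocks$block_id)
  expect_true(is.na(grp[["D"]]))
  expect_true(validate_bipartition(bp))
})

test_that("same-id sorghum genes on different chromosomes do not clash", {
  anchors <- dplyr::bind_rows(
    simple_block("A", 15, from = 0L, sorghum_chrom = "S1"),
    simple_block("B", 12, from = 0L, maize_chrom = "chr3", sorghum_chrom = "S2")
  )
  bp <- greedy_bipartition(anchors)
  expect_equal(sort(bp$blocks$group), c(1L, 1L))
})

test_that("duplicate block ids are rejected", {
  anchors <- dplyr::bind_rows(
    simple_block("A", 12, from = 0L),
    simple_block("B", 12, from = 20L),
    simple_block("A", 12, from = 40L, prefix = "A2")
  )
  expect_error(greedy_bipartition(anchors), "duplicate block_id")
})

test_that("subgenome labels follow group membership and count invariant", {
  bp <- greedy_bipartition(abc_anchors())
  asg <- label_subgenomes(bp)
  expect_equal(sum(asg$subgenome == "SUB1"), 33L)  # A(20) + C(13)
  expect_equal(sum(asg$subgenome == "SUB2"), 14L)
  expect_true(sum(asg$subgenome == "SUB1") >= sum(asg$subgenome == "SUB2"))

  # degenerate: a single block puts every anchored gene in SUB1
  bp1 <- greedy_bipartition(simple_block("A", 12))
  asg1 <- label_subgenomes(bp1)
  expect_true(all(asg1$subgenome == "SUB1"))

  # a gene anchored in both groups is an integrity error
  broken <- bp
  broken$anchors$maize_gene[broken$anchors$block_id == "B"][1L] <-
    broken$anchors$maize_gene[broken$anchors$block_id == "A"][1L]
  expect_error(label_subgenomes(broken), "both groups")
})

test_that("homeolog pairs pair each doubly-anchored sorghum gene once", {
  bp <- greedy_bipartition(abc_anchors())
  pairs <- extract_homeolog_pairs(bp)
  # s1..s14 are anchored in A (group1) and B (group2); the rest are single
  expect_equal(nrow(pairs), 14L)
  expect_equal(pairs$sorghum_gene, sort(sprintf("s%d", 1:14)))
  expect_true(all(startsWith(pairs$sub1_gene, "A_")))
  expect_true(all(startsWith(pairs$sub2_gene, "B_")))
})

test_that("duplicate anchors within a group resolve to lowest Ks then gene id", {
  # s1 anchored twice in the group-1 block: m1b (ks 0.4) and m1a (ks 0.2)
  g1 <- anchor_block("A", sprintf("A_m%d", 1:12), c(0L, 0:10),
                     ks = c(0.4, 0.2, rep(0.5, 10)))
  g1$maize_gene[1:2] <- c("m1b", "m1a")
  g2 <- simple_block("B", 12, from = 0L, maize_chrom = "chr5", prefix = "B")
  bp <- greedy_bipartition(dplyr::bind_rows(g1, g2))
  pairs <- extract_homeolog_pairs(bp)
  p1 <- pairs[pairs$sorghum_gene == "s1", ]
  # oracle: enumerate the candidate anchors and take min ks
  expect_equal(p1$sub1_gene, "m1a")
  expect_equal(p1$ks1, 0.2)

  # exact Ks tie resolves to the lexicographically smaller gene id
  g1$ks[1:2] <- 0.2
  bp2 <- greedy_bipartition(dplyr::bind_rows(g1, g2))
  expect_equal(extract_homeolog_pairs(bp2)$sub1_gene[1L], "m1a")
})

test_that("noiseless simulated genomes are recovered exactly", {
  for (s in c(2, 9)) {
    cfg <- sim_config(n_sorghum_genes = 400L, n_noise_blocks = 0L, seed = s)
    sim <- simulate_genome(cfg)
    bp <- greedy_bipartition(filter_blocks(sim$anchors))
    expect_true(validate_bipartition(bp))
    asg <- label_subgenomes(bp)
    truth <- sim$truth$genes
    m <- dplyr::inner_join(asg[asg$subgenome != "UNASSIGNED", ], truth, by = "gene")
    expect_equal(m$subgenome.x, m$subgenome.y)
    pairs <- extract_homeolog_pairs(bp, asg)
    want <- paste(sim$truth$pairs$sub1_gene, sim$truth$pairs$sub2_gene)
    got <- paste(pairs$sub1_gene, pairs$sub2_gene)
    expect_true(all(want %in% got))            # 100% recall
    expect_lte(nrow(pairs), min(sum(asg$subgenome == "SUB1"),
                                sum(asg$subgenome == "SUB2")))
    expect_false(anyDuplicated(asg$gene) > 0)  # one label per gene
  }
})

test_that("per-chromosome scope also yields a valid bipartition", {
  sim <- simulate_genome(sim_config(n_sorghum_genes = 400L, seed = 5))
  bp <- greedy_bipartition(filter_blocks(sim$anchors), scope = "per_chromosome")
  expect_true(validate_bipartition(bp))
})
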