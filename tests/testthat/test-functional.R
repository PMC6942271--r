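asg2 <- tibble::tibble(
  gene = c("m1", "m2", "m3", "m4", "u1"),
  subgenome = c("SUB1", "SUB1", "SUB2", "SUB2", "UNASSIGNED")
)

test_that("GO term comparison splits repertoires after filters", {
  ann <- tibble::tibble(
    gene = c("m1", "m2", "m3", "m4", "u1"),
    term = c("GO:0000001", "GO:0000002", "GO:0000002", "GO:0000003", "GO:0000009"),
    aspect = c("MF", "MF", "MF", "BP", "MF"),
    evidence = c("IDA", "IEA", "IMP", "IDA", "IDA")
  )
  cmp <- compare_go_terms(ann, asg2)
  expect_equal(cmp$shared, "GO:0000002")
  expect_equal(cmp$unique1, "GO:0000001")
  expect_equal(cmp$unique2, "GO:0000003")   # u1 is UNASSIGNED: ignored
  expect_set_comparison_valid(cmp)

  # experimental-evidence filter drops the IEA row, aspect filter drops BP
  gold <- compare_go_terms(ann, asg2, aspect = "MF",
                           evidence = go_experimental_codes)
  expect_equal(gold$unique1, "GO:0000001")
  expect_equal(gold$shared, character(0))
  expect_equal(gold$unique2, "GO:0000002")

  empty <- compare_go_terms(ann[0, ], asg2)
  expect_equal(lengths(empty[c("shared", "unique1", "unique2")]),
               c(shared = 0L, unique1 = 0L, unique2 = 0L))
})

test_that("unfiltered GO comparison covers every filtered term", {
  set.seed(61)
  ann <- tibble::tibble(
    gene = sample(asg2$gene, 300, replace = TRUE),
    term = sprintf("GO:%07d", sample(1:40, 300, replace = TRUE)),
    aspect = sample(c("MF", "BP", "CC"), 300, replace = TRUE),
    evidence = sample(c("IEA", "IDA", "IMP", "ISS"), 300, replace = TRUE)
  )
  all_terms <- compare_go_terms(ann, asg2)
  filt <- compare_go_terms(ann, asg2, aspect = "MF",
                           evidence = go_experimental_codes)
  universe <- function(cmp) c(cmp$shared, cmp$unique1, cmp$unique2)
  expect_true(all(universe(filt) %in% universe(all_terms)))
  expect_set_comparison_valid(all_terms)

  # relabeling the subgenomes swaps the unique sets
  flipped <- dplyr::mutate(asg2, subgenome = dplyr::case_match(
    subgenome, "SUB1" ~ "SUB2", "SUB2" ~ "SUB1", .default = subgenome))
  cmp_f <- compare_go_terms(ann, flipped)
  expect_equal(cmp_f$unique1, all_terms$unique2)
  expect_equal(cmp_f$unique2, all_terms$unique1)
  expect_equal(cmp_f$shared, all_terms$shared)
})

test_that("per-pair GO assignments never share across pairs", {
  pairs <- tibble::tibble(sub1_gene = c("m1", "m2"), sub2_gene = c("m3", "m4"))
  ann <- tibble::tibble(
    gene = c("m1", "m3", "m2", "m1", "m4"),
    term = c("GO:0000005", "GO:0000005", "GO:0000006", "GO:0000007", "GO:0000007"),
    aspect = "MF", evidence = "IDA"
  )
  cmp <- compare_go_assignments(ann, pairs)
  expect_equal(cmp$shared, "m1|m3|GO:0000005")     # same term, both members
  expect_true("m2|m4|GO:0000006" %in% cmp$unique1) # one side only
  # GO:0000007 on m1 (pair 1, side 1) and m4 (pair 2, side 2): both unique
  expect_true("m1|m3|GO:0000007" %in% cmp$unique1)
  expect_true("m2|m4|GO:0000007" %in% cmp$unique2)
})

test_that("GAF parsing recodes aspects and skips malformed terms", {
  f <- withr::local_tempfile(fileext = ".gaf")
  writeLines(c(
    "!gaf-version: 2.2",
    paste("DB", "m1", "m1", "", "GO:0000123", "REF", "IDA", "", "F", "", "",
          "protein", "taxon:4577", "20200101", "src", "", "", sep = "\t"),
    paste("DB", "m2", "m2", "", "GO:12", "REF", "IEA", "", "P", "", "",
          "protein", "taxon:4577", "20200101", "src", "", "", sep = "\t")
  ), f)
  expect_warning(ann <- read_gaf(f), "1 row.*malformed")
  expect_equal(nrow(ann), 1L)
  expect_equal(ann$aspect, "MF")
  expect_equal(ann$evidence, "IDA")
})

test_that("reaction comparison matches brute-force set algebra", {
  links <- tibble::tibble(
    gene = c("m1", "m2", "m3", "m3", "m4"),
    reaction = c("r1", "r2", "r2", "r3", "r4"),
    pathways = c("p1", "", "p1;p2", "p2", "")
  )
  cmp <- compare_reactions(links, asg2)
  want <- setsplit_oracle(c("r1", "r2"), c("r2", "r3", "r4"))
  expect_equal(cmp$reactions[c("shared", "unique1", "unique2")], want)
  # pathways touched by each side's unique reactions
  expect_equal(cmp$pathway_counts$n_pathways, c(1L, 1L))  # r1->p1 ; r3->p2 (r4 none)

  # pathway_only drops reactions with no pathway (r4 and the r2 links)
  cmp2 <- compare_reactions(links, asg2, pathway_only = TRUE)
  expect_equal(cmp2$reactions$unique2, c("r2", "r3"))

  # restricting to pair genes removes everything not in a pair
  pairs <- tibble::tibble(sub1_gene = "m1", sub2_gene = "m3")
  cmp3 <- compare_reactions(links, asg2, restrict_to_pairs = pairs)
  expect_equal(cmp3$reactions$unique1, "r1")
  expect_equal(cmp3$reactions$unique2, c("r2", "r3"))
})

test_that("random reaction fixtures agree with the set-ops oracle", {
  set.seed(71)
  for (rep in 1:10) {
    links <- tibble::tibble(
      gene = sample(asg2$gene[1:4], 40, replace = TRUE),
      reaction = sprintf("r%d", sample(1:12, 40, replace = TRUE)),
      pathways = ""
    )
    cmp <- compare_reactions(links, asg2)$reactions
    lab <- setNames(asg2$subgenome, asg2$gene)
    want <- setsplit_oracle(links$reaction[lab[links$gene] == "SUB1"],
                            links$reaction[lab[links$gene] == "SUB2"])
    expect_equal(cmp[c("shared", "unique1", "unique2")], want)
  }
})

test_that("isoform counting walks the gene/transcript hierarchy", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t100\t250\t.\t+\t.\tID=g1",
    "chr1\tsrc\tmRNA\t100\t250\t.\t+\t.\tID=g1_T1;Parent=g1",
    "chr1\tsrc\tmRNA\t100\t250\t.\t+\t.\tID=g1_T2;Parent=g1",
    "chr1\tsrc\tmRNA\t100\t200\t.\t+\t.\tID=g1_T3;Parent=g1",
    "chr1\tsrc\texon\t100\t200\t.\t+\t.\tID=g1_T1.e1;Parent=g1_T1",
    "chr1\tsrc\tgene\t500\t900\t.\t+\t.\tID=g2",
    "chr1\tsrc\tmRNA\t500\t900\t.\t+\t.\tID=g2_T1;Parent=g2",
    "chr1\tsrc\tgene\t1000\t1200\t.\t+\t.\tID=g3"
  ), f)
  cnt <- isoform_counts(f)
  expect_equal(cnt$n_isoforms[match(c("g1", "g2", "g3"), cnt$gene)],
               c(3L, 1L, 0L))

  # a transcript with an unknown parent is counted under its own id
  cat("chr1\tsrc\tmRNA\t2000\t2100\t.\t+\t.\tID=tX;Parent=gX\n",
      file = f, append = TRUE)
  expect_warning(cnt2 <- isoform_counts(f), "unknown parent")
  expect_equal(cnt2$n_isoforms[cnt2$gene == "tX"], 1L)
})

test_that("GTF transcripts count once despite multi-exon records", {
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    paste("chr1", "src", "transcript", "100", "250", ".", "+", ".",
          'gene_id "g1"; transcript_id "g1.t1";', sep = "\t"),
    paste("chr1", "src", "exon", "100", "150", ".", "+", ".",
          'gene_id "g1"; transcript_id "g1.t1";', sep = "\t"),
    paste("chr1", "src", "exon", "200", "250", ".", "+", ".",
          'gene_id "g1"; transcript_id "g1.t1";', sep = "\t"),
    paste("chr1", "src", "transcript", "300", "400", ".", "+", ".",
          'gene_id "g1"; transcript_id "g1.t2";', sep = "\t")
  ), f)
  cnt <- isoform_counts(f)
  expect_equal(cnt$n_isoforms[cnt$gene == "g1"], 2L)
})

test_that("isoform comparison reports differences and log ratios", {
  pairs <- tibble::tibble(sub1_gene = c("a1", "a2", "a3", "a4"),
                          sub2_gene = c("b1", "b2", "b3", "b4"))
  counts <- tibble::tibble(gene = c("a1", "b1", "a2", "b2", "a3", "b3", "a4"),
                           n_isoforms = c(4L, 2L, 3L, 3L, 2L, 0L, 1L))
  expect_message(cmp <- compare_isoforms(pairs, counts), "1 pair")
  expect_equal(nrow(cmp), 3L)
  expect_equal(cmp$log2_ratio, c(1, 0, NA))   # (4,2), (3,3), (2,0)
  expect_equal(cmp$diff, c(2L, 0L, 2L))
  s <- isoform_summary(cmp)
  expect_equal(s$frac_sub1_more, 2 / 3)
  expect_equal(s$frac_equal, 1 / 3)
})
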