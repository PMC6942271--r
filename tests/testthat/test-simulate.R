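test_that("the generator is deterministic per seed and sensitive to it", {
  cfg <- sim_config(n_sorghum_genes = 300L, seed = 4L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  d3 <- withr::local_tempdir()
  simulate_study(cfg, d1)
  simulate_study(cfg, d2)
  simulate_study(sim_config(n_sorghum_genes = 300L, seed = 5L), d3)
  for (f in c("anchors.tsv", "expr.tsv", "abun.tsv", "ann.gaf",
              "reactions.tsv", "models.gff3", "truth.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  expect_false(identical(readLines(file.path(d1, "anchors.tsv")),
                         readLines(file.path(d3, "anchors.tsv"))))
})

test_that("full retention with no decoys pairs every ancestral gene", {
  cfg <- sim_config(n_sorghum_genes = 200L, retention_prob_sub1 = 1,
                    retention_prob_sub2 = 1, n_noise_blocks = 0L, seed = 2L)
  sim <- simulate_genome(cfg)
  expect_equal(nrow(sim$truth$pairs), 200L)
})

test_that("biased retention leaves subgenome 1 with more genes", {
  cfg <- sim_config(n_sorghum_genes = 5000L, n_blocks_per_subgenome = 25L,
                    seed = 3L)
  sim <- simulate_genome(cfg)
  tab <- table(sim$truth$genes$subgenome)
  expect_gt(tab[["SUB1"]], tab[["SUB2"]])
})

test_that("invalid configurations are refused", {
  expect_error(sim_config(fold_signal = 1), "fold_signal")
  expect_error(sim_config(retention_prob_sub2 = 1.4), "probabilities")
  expect_error(sim_config(category_fractions = c(NO_SIGNAL = 0.5, ONE_SILENT = 0.3,
                                                 ALTERNATING = 0.2, CORRELATED = 0.2)),
               "sum")
  cfg <- sim_config(retention_prob_sub1 = 0, retention_prob_sub2 = 0)
  expect_error(simulate_genome(cfg), "deleted every gene")
})

test_that("every emitted file round-trips through its reader cleanly", {
  d <- withr::local_tempdir()
  st <- simulate_study(sim_config(n_sorghum_genes = 300L, seed = 6L), d)
  expect_no_warning({
    anchors <- read_anchor_blocks(file.path(d, "anchors.tsv"))
    expr <- read_quant_matrix(file.path(d, "expr.tsv"), "FPKM")
    abun <- read_quant_matrix(file.path(d, "abun.tsv"), "dNSAF")
    gaf <- read_gaf(file.path(d, "ann.gaf"))
    links <- read_reaction_links(file.path(d, "reactions.tsv"))
    iso <- isoform_counts(file.path(d, "models.gff3"))
  })
  expect_equal(anchors, st$anchors)
  expect_equal(expr$gene_id, st$quant$expr$gene_id)
  expect_equal(as.matrix(expr[-1]), as.matrix(st$quant$expr[-1]),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(dplyr::arrange(gaf, gene, term),
               dplyr::arrange(st$annotations$go, gene, term))
  expect_equal(links, st$annotations$reactions, ignore_attr = TRUE)
  expect_equal(dplyr::arrange(iso, gene),
               dplyr::arrange(st$annotations$isoforms, gene),
               ignore_attr = TRUE)
})

test_that("planted GO sets are reproduced from the emitted GAF", {
  st <- simulate_study(sim_config(n_sorghum_genes = 300L, seed = 8L))
  truth_asg <- st$truth$genes[, c("gene", "subgenome")]
  cmp <- compare_go_terms(st$annotations$go, truth_asg)
  planted <- st$annotations$planted$go
  expect_equal(sort(c(cmp$shared, cmp$unique1)), planted$sub1)
  expect_equal(sort(c(cmp$shared, cmp$unique2)), planted$sub2)
})

test_that("symmetric annotation rates produce balanced unique sets", {
  diffs <- sapply(1:8, function(s) {
    st <- simulate_annotations(
      simulate_pair_truth(300L),
      sim_config(annotation_asym = 1, seed = s)
    )
    length(st$planted$go$sub1) - length(st$planted$go$sub2)
  })
  # pooled two-sided binomial check at alpha 0.01
  w <- sum(pmax(diffs, 0)); tot <- sum(abs(diffs))
  if (tot > 0) {
    p <- stats::binom.test(w, tot, 0.5)$p.value
    expect_gt(p, 0.01)
  }
  succeed()
})

test_that("planted asymmetries surface in annotations and isoforms", {
  truth <- simulate_pair_truth(500L)
  ann <- simulate_annotations(truth, sim_config(annotation_asym = 2, seed = 9L))
  expect_gt(length(ann$planted$go$sub1), length(ann$planted$go$sub2))
  iso_cmp <- compare_isoforms(truth$pairs, ann$isoforms)
  expect_gt(isoform_summary(iso_cmp)$frac_sub1_more, 0.5)
})

test_that("perfect coupling makes abundance a rank transform of expression", {
  cfg <- sim_config(abun_coupling_rho = 0.99999, decouple_tissue = NA,
                    noise_cv = 0, seed = 10L)
  truth <- simulate_pair_truth(150L)
  q <- simulate_quant(truth, cfg)
  ep <- suppressMessages(build_pair_profiles(truth$pairs, q$expr))
  ap <- suppressMessages(build_pair_profiles(truth$pairs, q$abun))
  cm <- suppressWarnings(correlation_matrix(ep, ap))
  rows12 <- cm$rho[cm$comparison %in% c("sub1_expr_abun", "sub2_expr_abun")]
  expect_true(all(rows12[!is.na(rows12)] > 0.99))
})

test_that("the decoupled tissue shows weaker expression-abundance coupling", {
  cfg <- sim_config(seed = 12L)
  truth <- simulate_pair_truth(800L)
  q <- simulate_quant(truth, cfg)
  ep <- suppressMessages(build_pair_profiles(truth$pairs, q$expr))
  ap <- suppressMessages(build_pair_profiles(truth$pairs, q$abun))
  cm <- correlation_matrix(ep, ap)
  r12 <- cm[cm$comparison == "sub1_expr_abun", ]
  pollen <- r12$rho[r12$tissue == "pollen"]
  others <- r12$rho[r12$tissue != "pollen"]
  expect_lt(pollen, min(others))
})
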