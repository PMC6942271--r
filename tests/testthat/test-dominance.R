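test_that("per-tissue dominance applies the inclusive fold rule", {
  expect_equal(tissue_dominance(4, 2), "SUB1_DOM")    # exactly 2-fold counts
  expect_equal(tissue_dominance(3.9, 2), "NEITHER")
  expect_equal(tissue_dominance(0, 0), "NEITHER")
  expect_equal(tissue_dominance(1, 0), "SUB1_DOM")    # signal vs silence
  expect_equal(tissue_dominance(0, 0.01), "SUB2_DOM")
  expect_true(is.na(tissue_dominance(NA, 1)))
  expect_error(tissue_dominance(-1, 1), "negative")
  expect_error(tissue_dominance(1, 1, fold = 1), "fold > 1")
})

test_that("dominance is antisymmetric under swapping the homeologs", {
  set.seed(31)
  a <- c(runif(200) * 20, 0, 0, 5)
  b <- c(runif(200) * 20, 0, 5, 0)
  for (fold in c(1.5, 2, 3)) {
    d1 <- tissue_dominance(a, b, fold)
    d2 <- tissue_dominance(b, a, fold)
    expect_equal(d2, dplyr::case_match(d1, "SUB1_DOM" ~ "SUB2_DOM",
                                       "SUB2_DOM" ~ "SUB1_DOM",
                                       .default = "NEITHER"))
  }
})

test_that("average dominance is the fold rule applied to tissue means", {
  prof <- profiles_of(
    list(c(4, 4), c(10, 0), c(3, 1)),
    list(c(2, 2), c(0, 10), c(1, 1))
  )
  avg <- average_dominance(prof)
  expect_equal(avg$call, c("SUB1_DOM", "NEITHER", "SUB1_DOM"))
  expect_equal(avg$mean1, c(4, 5, 2))
  expect_equal(avg$mean2, c(2, 5, 1))
})

test_that("the five-way classification follows its precedence order", {
  prof <- profiles_of(
    list(c(0, 0, 0),       # nothing anywhere
         c(5, 2, 1),       # partner silent
         c(10, 1, 5),      # alternating
         c(1, 2, 3),       # proportional
         c(10, 1, 8)),     # one-sided dominance, corr modest
    list(c(0, 0, 0),
         c(0, 0, 0),
         c(1, 10, 5),
         c(1.1, 2.2, 3.3),
         c(4, 0.6, 1))
  )
  cl <- suppressMessages(classify_pairs(prof))
  expect_equal(as.character(cl$category),
               c("NO_SIGNAL", "ONE_SILENT", "ALTERNATING", "CORRELATED", "OTHER"))
  # proportional vectors: Pearson exactly 1
  expect_equal(cl$corr[4L], 1)
  # counts always partition the pair set
  expect_equal(sum(count_categories(cl)$n), nrow(cl))
})

test_that("classification is invariant under tissue permutation", {
  set.seed(17)
  prof <- profiles_of(
    replicate(30, rexp(6) * 8, simplify = FALSE),
    replicate(30, rexp(6) * 8, simplify = FALSE)
  )
  perm <- sample(sprintf("t%d", 1:6))
  prof2 <- dplyr::mutate(prof, tissue = setNames(perm, sprintf("t%d", 1:6))[tissue])
  c1 <- suppressMessages(classify_pairs(prof))
  c2 <- suppressMessages(classify_pairs(prof2))
  expect_equal(c1$category, c2$category)
})

test_that("raising the fold threshold never creates alternating pairs", {
  set.seed(19)
  prof <- profiles_of(
    replicate(100, rexp(8) * 10, simplify = FALSE),
    replicate(100, rexp(8) * 10, simplify = FALSE)
  )
  n_alt <- sapply(c(1.5, 2, 3, 5, 8), function(f) {
    cl <- suppressMessages(classify_pairs(prof, fold = f))
    sum(cl$category == "ALTERNATING")
  })
  expect_true(all(diff(n_alt) <= 0))
})

test_that("spearman matches its definition and R's asymptotic test", {
  r <- spearman_rho(c(1, 2, 3), c(10, 20, 30))
  expect_equal(r$rho, 1)
  expect_equal(spearman_rho(c(1, 2, 3), c(3, 2, 1))$rho, -1)

  set.seed(41)
  x <- sample(1:10, 25, replace = TRUE)   # ties on purpose
  y <- x + rnorm(25, 0, 3)
  mine <- spearman_rho(x, y)
  expect_equal(mine$rho, spearman_oracle(x, y), tolerance = 1e-12)
  ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = FALSE))
  expect_equal(mine$rho, unname(ref$estimate))
  expect_equal(mine$p, ref$p.value, tolerance = 1e-12)

  expect_warning(bad <- spearman_rho(rep(1, 5), 1:5), "constant")
  expect_true(is.na(bad$rho))
  expect_error(spearman_rho(c(1, NA), c(1, 2)), "at least 3")
})

test_that("joint classification gates on data completeness", {
  alt1 <- list(c(10, 1, 5), c(8, 1, 4))
  alt2 <- list(c(1, 10, 5), c(1, 9, 4))
  expr <- profiles_of(c(alt1, list(c(5, 5, 5))), c(alt2, list(c(5, 5, 5))))
  abun <- profiles_of(
    list(c(0.4, 0.05, 0.2), c(0.4, 0.05, 0.2), c(0.1, 0.1, 0.1)),
    list(c(0.05, 0.4, 0.2), c(0, 0, 0), c(0.1, 0.1, 0.1))
  )
  j <- suppressMessages(joint_classification(expr, abun))
  jc <- count_joint(j)
  expect_equal(jc$n_pairs, 3L)
  expect_equal(jc$n_data_complete, 2L)        # pair 2 has a silent protein
  expect_equal(jc$n_joint_alternating, 1L)    # only pair 1 alternates in both
  # pair 3 is flat in both kinds: constant vectors give no correlation call
  expect_equal(jc$n_joint_correlated, 0L)
})

test_that("strict joint alternation requires coinciding tissues", {
  expr <- profiles_of(list(c(10, 1, 5, 5)), list(c(1, 10, 5, 5)))
  # abundance alternates, but in the other pair of tissues
  abun <- profiles_of(list(c(0.2, 0.2, 0.4, 0.04)), list(c(0.2, 0.2, 0.04, 0.4)))
  loose <- suppressMessages(joint_classification(expr, abun))
  strict <- suppressMessages(joint_classification(expr, abun, same_tissue = TRUE))
  expect_true(loose$joint_alternating)
  expect_false(strict$joint_alternating)
})

test_that("the correlation structure has the 4 x tissues shape and bounds", {
  set.seed(53)
  n <- 60
  v1 <- replicate(n, rexp(5) * 10, simplify = FALSE)
  v2 <- replicate(n, rexp(5) * 10, simplify = FALSE)
  expr <- profiles_of(v1, v2)
  # abundance as a monotone transform of expression
  abun <- dplyr::mutate(expr, v1 = sqrt(v1) * 1e-3, v2 = sqrt(v2) * 1e-3)
  cm <- correlation_matrix(expr, abun)
  expect_equal(nrow(cm), 4L * 5L)
  expect_true(all(abs(cm$rho) <= 1))
  expect_true(all(cm$rho[cm$comparison %in% c("sub1_expr_abun", "sub2_expr_abun")] == 1))

  # a tissue missing from one side is dropped with a warning
  expect_warning(cm2 <- correlation_matrix(expr, abun[abun$tissue != "t5", ]),
                 "t5")
  expect_false("t5" %in% cm2$tissue)
})
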