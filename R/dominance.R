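#' Per-tissue expression-level dominance call
#'
#' One homeolog dominates the other in a tissue when its value is at least
#' `fold` times the other's ("at least 2-fold" by default, boundary
#' inclusive). A positive value always dominates a zero, at any fold; two
#' zeros are `NEITHER`. Vectorized over `a`/`b`; a missing value on either
#' side yields `NA`.
#'
#' @param a,b Non-negative values for the SUB1 and SUB2 homeolog.
#' @param fold Fold threshold, > 1.
#' @return Character vector in `SUB1_DOM`, `SUB2_DOM`, `NEITHER`.
#' @export
tissue_dominance <- function(a, b, fold = 2.0) {
  stopifnot(fold > 1)
  if (any(a < 0, na.rm = TRUE) || any(b < 0, na.rm = TRUE)) {
    abort("negative values are not valid quantifications")
  }
  dplyr::case_when(
    is.na(a) | is.na(b) ~ NA_character_,
    a >= fold * b & a > 0 ~ "SUB1_DOM",
    b >= fold * a & b > 0 ~ "SUB2_DOM",
    .default = "NEITHER"
  )
}

#' Build tissue-aligned value profiles for homeolog pairs
#'
#' Joins each pair against a genes-by-tissues matrix, producing one row per
#' pair and tissue with the two homeolog values side by side. Pairs with
#' either gene absent from the matrix are dropped and counted in a message.
#'
#' @param pairs Homeolog pair tibble ([extract_homeolog_pairs()]); only
#'   `sub1_gene` and `sub2_gene` are used.
#' @param m Quantification tibble (genes x tissues, after
#'   [average_replicates()] if the matrix carried replicates).
#' @return A long tibble `sub1_gene`, `sub2_gene`, `tissue`, `v1`, `v2`,
#'   tissues in matrix column order; carries the matrix's `kind` attribute.
#' @export
build_pair_profiles <- function(pairs, m) {
  tissues <- setdiff(names(m), "gene_id")
  long <- tidyr::pivot_longer(m, -"gene_id", names_to = "tissue", values_to = "value")
  p <- pairs[, c("sub1_gene", "sub2_gene")]
  missing <- !(p$sub1_gene %in% m$gene_id) | !(p$sub2_gene %in% m$gene_id)
  if (any(missing)) {
    inform(sprintf("%d pair(s) dropped: gene absent from the matrix", sum(missing)))
    p <- p[!missing, ]
  }
  out <- p |>
    inner_join(rename(long, sub1_gene = "gene_id", v1 = "value"), by = "sub1_gene") |>
    inner_join(rename(long, sub2_gene = "gene_id", v2 = "value", tissue2 = "tissue"),
               by = c("sub2_gene", "tissue" = "tissue2")) |>
    mutate(tissue = factor(.data$tissue, levels = tissues)) |>
    arrange(.data$sub1_gene, .data$sub2_gene, .data$tissue) |>
    mutate(tissue = as.character(.data$tissue))
  attr(out, "kind") <- attr(m, "kind")
  out
}

#' Average dominance across tissues
#'
#' Computes each homeolog's mean over non-missing tissues, then applies the
#' fold rule to the two means ("2-fold averaged across all tissues" read as
#' fold change of the tissue averages). Pairs missing everywhere on both
#' sides are `NEITHER` with a warning.
#'
#' @param profiles Long profile tibble from [build_pair_profiles()].
#' @param fold Fold threshold, > 1.
#' @return A tibble `sub1_gene`, `sub2_gene`, `mean1`, `mean2`, `call`.
#' @export
average_dominance <- function(profiles, fold = 2.0) {
  out <- profiles |>
    group_by(.data$sub1_gene, .data$sub2_gene) |>
    summarise(
      mean1 = mean(.data$v1, na.rm = TRUE),
      mean2 = mean(.data$v2, na.rm = TRUE),
      .groups = "drop"
    )
  all_missing <- !is.finite(out$mean1) & !is.finite(out$mean2)
  if (any(all_missing)) {
    warn(sprintf("%d pair(s) with no measurements at all: call set to NEITHER",
                 sum(all_missing)))
  }
  out$mean1[!is.finite(out$mean1)] <- NA_real_
  out$mean2[!is.finite(out$mean2)] <- NA_real_
  out$call <- tissue_dominance(out$mean1, out$mean2, fold = fold)
  out$call[all_missing] <- "NEITHER"
  out
}

pair_categories <- c("NO_SIGNAL", "ONE_SILENT", "ALTERNATING", "CORRELATED", "OTHER")

#' Classify homeolog pairs by tissue-specific dominance pattern
#'
#' Mutually exclusive five-way scheme, applied in precedence order:
#' \describe{
#'   \item{NO_SIGNAL}{nothing detected for either homeolog in any tissue;}
#'   \item{ONE_SILENT}{exactly one homeolog undetected everywhere;}
#'   \item{ALTERNATING}{each homeolog has at least one tissue in which it is
#'     the (at least) `fold`-fold dominant copy — the signature of
#'     tissue-specific regulatory divergence;}
#'   \item{CORRELATED}{per-tissue values correlate above `corr_threshold`
#'     (Pearson on untransformed values by default);}
#'   \item{OTHER}{everything else.}
#' }
#' Values that are missing (not measured, as opposed to measured zero) are
#' ignored tissue-wise; a homeolog missing everywhere counts as undetected.
#' Pairs with fewer than 3 tissues measured on both sides cannot reach
#' `CORRELATED`; their number is reported.
#'
#' @param profiles Long profile tibble from [build_pair_profiles()].
#' @param fold Fold threshold for per-tissue dominance.
#' @param corr_threshold Correlation above which a pair is `CORRELATED`.
#' @param corr_method `"pearson"` (default) or `"spearman"`.
#' @return One row per pair: `sub1_gene`, `sub2_gene`, `category`, `corr`,
#'   `n_tissues_sub1_dom`, `n_tissues_sub2_dom`, `any_sub1`, `any_sub2`,
#'   `n_tissues_complete`.
#' @export
classify_pairs <- function(profiles, fold = 2.0, corr_threshold = 0.95,
                           corr_method = c("pearson", "spearman")) {
  corr_method <- match.arg(corr_method)
  out <- profiles |>
    mutate(dom = tissue_dominance(.data$v1, .data$v2, fold = fold)) |>
    group_by(.data$sub1_gene, .data$sub2_gene) |>
    summarise(
      any_sub1 = any(.data$v1 > 0, na.rm = TRUE),
      any_sub2 = any(.data$v2 > 0, na.rm = TRUE),
      n_tissues_sub1_dom = sum(.data$dom == "SUB1_DOM", na.rm = TRUE),
      n_tissues_sub2_dom = sum(.data$dom == "SUB2_DOM", na.rm = TRUE),
      n_tissues_complete = sum(!is.na(.data$v1) & !is.na(.data$v2)),
      corr = pair_corr(.data$v1, .data$v2, corr_method),
      .groups = "drop"
    )
  n_short <- sum(out$n_tissues_complete < 3L)
  if (n_short > 0L) {
    inform(sprintf("%d pair(s) with < 3 complete tissues: CORRELATED unreachable", n_short))
  }
  out$category <- dplyr::case_when(
    !out$any_sub1 & !out$any_sub2 ~ "NO_SIGNAL",
    xor(out$any_sub1, out$any_sub2) ~ "ONE_SILENT",
    out$n_tissues_sub1_dom > 0L & out$n_tissues_sub2_dom > 0L ~ "ALTERNATING",
    !is.na(out$corr) & out$corr > corr_threshold ~ "CORRELATED",
    .default = "OTHER"
  )
  out$category <- factor(out$category, levels = pair_categories)
  select(out, "sub1_gene", "sub2_gene", "category", "corr",
         "n_tissues_sub1_dom", "n_tissues_sub2_dom", "any_sub1", "any_sub2",
         "n_tissues_complete")
}

pair_corr <- function(v1, v2, method) {
  ok <- !is.na(v1) & !is.na(v2)
  if (sum(ok) < 3L) return(NA_real_)
  if (sd(v1[ok]) == 0 || sd(v2[ok]) == 0) return(NA_real_)
  cor(v1[ok], v2[ok], method = method)
}

#' Count pairs per classification category
#'
#' @param classification Output of [classify_pairs()].
#' @return A tibble `category`, `n` covering all five categories (zeros
#'   included); `n` sums to the number of classified pairs.
#' @export
count_categories <- function(classification) {
  classification |>
    count(category = factor(.data$category, levels = pair_categories),
          .drop = FALSE, name = "n")
}

#' Joint expression/abundance classification
#'
#' Combines the five-way classification of the same pair universe measured
#' twice — transcript level (FPKM) and protein level (dNSAF). A pair is
#' "data complete" when all four vectors show a detection somewhere. Among
#' data-complete pairs, `joint_alternating` marks pairs alternating in both
#' data kinds; among the remaining data-complete pairs, `joint_correlated`
#' marks pairs exceeding the correlation threshold in both.
#'
#' @param expr_profiles,abun_profiles Long profile tibbles for the same
#'   pairs (expression and abundance). Pairs present in only one input are
#'   excluded and counted in a message.
#' @param fold,corr_threshold,corr_method Passed to [classify_pairs()].
#' @param same_tissue If `TRUE`, joint alternation additionally requires
#'   that some tissue shows SUB1 dominance in both kinds and some tissue
#'   SUB2 dominance in both kinds (strict coincidence); the default only
#'   requires alternation within each kind.
#' @return One row per common pair: `sub1_gene`, `sub2_gene`,
#'   `expr_category`, `abun_category`, `expr_corr`, `abun_corr`,
#'   `data_complete`, `joint_alternating`, `joint_correlated`.
#' @seealso [count_joint()]
#' @export
joint_classification <- function(expr_profiles, abun_profiles, fold = 2.0,
                                 corr_threshold = 0.95,
                                 corr_method = c("pearson", "spearman"),
                                 same_tissue = FALSE) {
  corr_method <- match.arg(corr_method)
  ce <- classify_pairs(expr_profiles, fold, corr_threshold, corr_method)
  ca <- classify_pairs(abun_profiles, fold, corr_threshold, corr_method)
  key <- c("sub1_gene", "sub2_gene")
  n_only <- nrow(anti_join(ce, ca, by = key)) + nrow(anti_join(ca, ce, by = key))
  if (n_only > 0L) {
    inform(sprintf("%d pair(s) present in only one data kind were excluded", n_only))
  }
  out <- inner_join(
    select(ce, dplyr::all_of(key), expr_category = "category", expr_corr = "corr",
           e_any1 = "any_sub1", e_any2 = "any_sub2"),
    select(ca, dplyr::all_of(key), abun_category = "category", abun_corr = "corr",
           a_any1 = "any_sub1", a_any2 = "any_sub2"),
    by = key
  ) |>
    mutate(
      data_complete = .data$e_any1 & .data$e_any2 & .data$a_any1 & .data$a_any2,
      joint_alternating = .data$data_complete &
        .data$expr_category == "ALTERNATING" & .data$abun_category == "ALTERNATING"
    )
  if (same_tissue) {
    strict <- inner_join(
      mutate(expr_profiles, edom = tissue_dominance(.data$v1, .data$v2, fold)),
      mutate(abun_profiles, adom = tissue_dominance(.data$v1, .data$v2, fold)) |>
        select(dplyr::all_of(key), "tissue", "adom"),
      by = c(key, "tissue")
    ) |>
      group_by(.data$sub1_gene, .data$sub2_gene) |>
      summarise(
        strict_alt = any(.data$edom == "SUB1_DOM" & .data$adom == "SUB1_DOM", na.rm = TRUE) &
          any(.data$edom == "SUB2_DOM" & .data$adom == "SUB2_DOM", na.rm = TRUE),
        .groups = "drop"
      )
    out <- left_join(out, strict, by = key) |>
      mutate(joint_alternating = .data$joint_alternating & !is.na(.data$strict_alt) &
               .data$strict_alt) |>
      select(-"strict_alt")
  }
  out |>
    mutate(
      joint_correlated = .data$data_complete & !.data$joint_alternating &
        !is.na(.data$expr_corr) & .data$expr_corr > corr_threshold &
        !is.na(.data$abun_corr) & .data$abun_corr > corr_threshold
    ) |>
    select(-"e_any1", -"e_any2", -"a_any1", -"a_any2")
}

#' Summarise a joint classification into headline counts
#'
#' @param joint Output of [joint_classification()].
#' @return One-row tibble: `n_pairs`, `n_data_complete`,
#'   `n_joint_alternating`, `n_joint_correlated`.
#' @export
count_joint <- function(joint) {
  summarise(
    joint,
    n_pairs = n(),
    n_data_complete = sum(.data$data_complete),
    n_joint_alternating = sum(.data$joint_alternating),
    n_joint_correlated = sum(.data$joint_correlated)
  )
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Rank correlation with average (mid) ranks for ties; the p-value uses the
#' t-distribution approximation on `n - 2` degrees of freedom. Missing
#' values are dropped pairwise.
#'
#' @param x,y Numeric vectors of equal length with at least 3 complete
#'   pairs.
#' @return One-row tibble `rho`, `p`, `n`. A constant vector yields `rho =
#'   NA` with a warning.
#' @export
spearman_rho <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 3L) abort("need at least 3 complete observation pairs")
  if (sd(x[ok]) == 0 || sd(y[ok]) == 0) {
    warn("constant vector: Spearman correlation undefined")
    return(tibble(rho = NA_real_, p = NA_real_, n = n))
  }
  rho <- cor(x[ok], y[ok], method = "spearman")
  if (abs(rho) == 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  tibble(rho = rho, p = p, n = n)
}

#' Per-tissue correlation structure of expression and abundance
#'
#' For every tissue shared by the two profile sets, computes four Spearman
#' correlations across pairs: SUB1 expression vs SUB1 abundance, SUB2
#' expression vs SUB2 abundance, SUB1 vs SUB2 expression, and SUB1 vs SUB2
#' abundance. This is the 4-row by n-tissue summary in which, in maize, the
#' mature-pollen column stands out as the one tissue where protein
#' abundance decouples from transcript level.
#'
#' @param expr_profiles,abun_profiles Long profile tibbles over the same
#'   pairs.
#' @return A tibble `tissue`, `comparison`, `rho`, `p`, `n` with
#'   `comparison` in `sub1_expr_abun`, `sub2_expr_abun`, `expr_sub1_sub2`,
#'   `abun_sub1_sub2`.
#' @export
correlation_matrix <- function(expr_profiles, abun_profiles) {
  te <- unique(expr_profiles$tissue)
  ta <- unique(abun_profiles$tissue)
  dropped <- union(setdiff(te, ta), setdiff(ta, te))
  if (length(dropped) > 0L) {
    warn(sprintf("tissue(s) absent from one matrix omitted: %s",
                 paste(dropped, collapse = ", ")))
  }
  tissues <- intersect(te, ta)
  key <- c("sub1_gene", "sub2_gene", "tissue")
  both <- inner_join(
    rename(expr_profiles, e1 = "v1", e2 = "v2"),
    rename(abun_profiles, a1 = "v1", a2 = "v2"),
    by = key
  )
  purrr::map_dfr(tissues, function(tt) {
    d <- both[both$tissue == tt, ]
    comps <- list(
      sub1_expr_abun = c("e1", "a1"),
      sub2_expr_abun = c("e2", "a2"),
      expr_sub1_sub2 = c("e1", "e2"),
      abun_sub1_sub2 = c("a1", "a2")
    )
    purrr::imap_dfr(comps, function(cols, nm) {
      r <- spearman_rho(d[[cols[1L]]], d[[cols[2L]]])
      tibble(tissue = tt, comparison = nm, rho = r$rho, p = r$p, n = r$n)
    })
  })
}
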