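#' Configuration for the synthetic fractionation-study generator
#'
#' Bundles every knob of the simulated study. Defaults emulate a
#' maize-versus-sorghum setting: two subgenomes fractionated with a bias
#' (the retained fraction is higher in subgenome 1), anchors to the outgroup
#' carrying Ks values clustered well below the 1.0 filter cutoff, a handful
#' of old/noise blocks above the cutoff, 23 tissues with one pollen-like
#' tissue whose protein abundance decouples from expression, and planted
#' dominance-category fractions matching the proportions observed in maize
#' (about 1% silent pairs, 7.5% half-silent, 25% alternating, 7%
#' near-perfectly correlated, the rest unpatterned).
#'
#' @param n_sorghum_genes Number of outgroup genes (ancestral gene order).
#' @param n_sorghum_chroms Outgroup chromosomes the gene order is split over.
#' @param n_blocks_per_subgenome Contiguous block templates; each is
#'   duplicated into the two subgenome copies.
#' @param retention_prob_sub1,retention_prob_sub2 Stationary probability
#'   that a gene survives fractionation in each subgenome copy
#'   (`sub1 > sub2` gives biased fractionation).
#' @param deletion_run_length Mean geometric run length of deletion tracts
#'   (the "short deletion" mechanism).
#' @param ks_wgd_mean,ks_wgd_sd Normal (truncated at 0) parameters of
#'   per-anchor Ks for true syntenic blocks.
#' @param n_noise_blocks Number of decoy blocks whose Ks sits above the
#'   filter cutoff.
#' @param ks_noise_mean,ks_noise_sd Ks distribution of noise blocks.
#' @param n_tissues Number of tissues (last one is named `pollen`).
#' @param category_fractions Named fractions for `NO_SIGNAL`, `ONE_SILENT`,
#'   `ALTERNATING`, `CORRELATED`; the remainder is `OTHER`. Must sum to at
#'   most 1.
#' @param fold_signal Planted dominance ratio for alternating pairs; must
#'   exceed 1 (and should comfortably exceed the classifier fold).
#' @param noise_cv Coefficient of variation of multiplicative lognormal
#'   measurement noise applied to alternating and unpatterned profiles.
#' @param abun_coupling_rho Target Spearman correlation between expression
#'   and abundance over detected values.
#' @param decouple_tissue Tissue whose abundance coupling is weakened to
#'   `decouple_rho` (the pollen effect); `NA` disables decoupling.
#' @param decouple_rho Coupling in the decoupled tissue.
#' @param abun_shared_noise Fraction of the abundance-noise variance shared
#'   between the two homeologs of a pair within a tissue. Homeologs are
#'   near-identical proteins quantified in the same sample, so most of what
#'   decouples their abundance from their transcript level is common to
#'   both; with fully independent noise (0) within-pair abundance ratios
#'   would be noise-dominated and abundance dominance patterns meaningless.
#' @param n_go_terms,go_rate,go_shared_rate GO universe size, mean
#'   side-specific terms per gene, and mean terms planted on both homeologs
#'   of a pair.
#' @param n_reactions,n_pathways,reaction_rate Reaction/pathway universe and
#'   mean reactions per gene.
#' @param iso_mean Mean number of extra isoforms per gene (every gene has at
#'   least one).
#' @param annotation_asym SUB1:SUB2 rate ratio planted into GO, reaction and
#'   isoform annotations (1 = no asymmetry).
#' @param seed Integer seed; every `simulate_*` stage derives its own
#'   sub-stream from it, so outputs are fully reproducible.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_sorghum_genes = 2000L,
                       n_sorghum_chroms = 3L,
                       n_blocks_per_subgenome = 10L,
                       retention_prob_sub1 = 0.8,
                       retention_prob_sub2 = 0.5,
                       deletion_run_length = 2,
                       ks_wgd_mean = 0.75,
                       ks_wgd_sd = 0.1,
                       n_noise_blocks = 4L,
                       ks_noise_mean = 1.6,
                       ks_noise_sd = 0.15,
                       n_tissues = 23L,
                       category_fractions = c(NO_SIGNAL = 0.01, ONE_SILENT = 0.075,
                                              ALTERNATING = 0.25, CORRELATED = 0.07),
                       fold_signal = 4,
                       noise_cv = 0.2,
                       abun_coupling_rho = 0.55,
                       decouple_tissue = "pollen",
                       decouple_rho = 0.2,
                       abun_shared_noise = 0.95,
                       n_go_terms = 300L,
                       go_rate = 0.8,
                       go_shared_rate = 0.5,
                       n_reactions = 150L,
                       n_pathways = 40L,
                       reaction_rate = 0.3,
                       iso_mean = 1.5,
                       annotation_asym = 1.5,
                       seed = 1L) {
  cfg <- as.list(environment())
  probs <- c(cfg$retention_prob_sub1, cfg$retention_prob_sub2, cfg$category_fractions)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  if (sum(cfg$category_fractions) > 1 + 1e-12) {
    abort("category_fractions must sum to at most 1")
  }
  need <- c("NO_SIGNAL", "ONE_SILENT", "ALTERNATING", "CORRELATED")
  if (!all(need %in% names(cfg$category_fractions))) {
    abort(sprintf("category_fractions must be named: %s", paste(need, collapse = ", ")))
  }
  if (cfg$fold_signal <= 1) abort("fold_signal must exceed 1")
  if (cfg$deletion_run_length < 1) abort("deletion_run_length must be >= 1")
  if (cfg$noise_cv < 0) abort("noise_cv must be non-negative")
  if (abs(cfg$abun_coupling_rho) > 1) abort("abun_coupling_rho out of range")
  if (cfg$abun_shared_noise < 0 || cfg$abun_shared_noise > 1) {
    abort("abun_shared_noise must lie in [0, 1]")
  }
  if (cfg$n_tissues < 2L) abort("need at least 2 tissues")
  structure(cfg, class = "sim_config")
}

# run code under a seed derived from (seed, stage), leaving the caller's RNG
# state untouched; stage order is fixed so new stages never reshuffle old ones
with_stage_seed <- function(seed, stage, code) {
  idx <- match(stage, c("genome", "quant", "annotations", "misc"))
  if (is.na(idx)) abort(sprintf("unknown RNG stage '%s'", stage))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(((as.integer(seed) %% 1000003L) * 2039L + idx * 97L) %% 2147483647L)
  force(code)
}

# normal truncated at zero via inverse-CDF
rtnorm0 <- function(n, mean, sd) {
  if (sd == 0) return(rep(max(mean, 0), n))
  qnorm(runif(n, pnorm(0, mean, sd), 1), mean, sd)
}

# two-state Markov chain with stationary retention probability r and mean
# deletion run length len; TRUE = retained
markov_retain <- function(n, r, len) {
  if (r >= 1) return(rep(TRUE, n))
  if (r <= 0) return(rep(FALSE, n))
  p_dd <- 1 - 1 / len                  # stay deleted
  p_rd <- min(1, (1 - r) / (r * len))  # retained -> deleted
  out <- logical(n)
  state <- runif(1) < r
  for (i in seq_len(n)) {
    out[i] <- state
    state <- if (state) runif(1) >= p_rd else runif(1) < 1 - p_dd
  }
  out
}

#' Simulate a duplicated, asymmetrically fractionated genome
#'
#' Lays out an ancestral (sorghum-like) gene order, cuts it into contiguous
#' block templates, instantiates every template twice (the two subgenome
#' copies, on different maize-like chromosomes), deletes genes in
#' geometric-length runs with per-subgenome retention rates, assigns each
#' surviving gene an anchor with truncated-normal Ks, and appends decoy
#' blocks with Ks above the filter cutoff. Deterministic given
#' `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return A list with `anchors` (anchor tibble, the same shape
#'   [read_anchor_blocks()] returns) and `truth` (list: `genes` — planted
#'   label and coordinates per maize gene; `pairs` — planted retained
#'   duplicates; `config`).
#' @export
simulate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_stage_seed(cfg$seed, "genome", {
    n <- cfg$n_sorghum_genes
    chrom_of <- sort(rep_len(seq_len(cfg$n_sorghum_chroms), n))
    order_in_chrom <- unname(unlist(lapply(split(seq_len(n), chrom_of), seq_along))) - 1L
    sorghum <- tibble(
      sorghum_gene = sprintf("Sb%05d", seq_len(n)),
      sorghum_chrom = sprintf("Chr%02d", chrom_of),
      sorghum_order = order_in_chrom
    )
    # contiguous templates, never crossing a chromosome boundary
    template <- integer(n)
    tpl <- 0L
    for (ch in unique(chrom_of)) {
      idx <- which(chrom_of == ch)
      k <- max(1L, round(cfg$n_blocks_per_subgenome * length(idx) / n))
      template[idx] <- tpl + as.integer(cut(seq_along(idx), k, labels = FALSE))
      tpl <- max(template[idx])
    }

    cursor <- new.env(parent = emptyenv())
    next_pos <- function(chrom) {
      cur <- if (exists(chrom, cursor, inherits = FALSE)) get(chrom, cursor) else 0
      assign(chrom, cur + 10000, cursor)
      cur + 1
    }

    rows <- list()
    retained <- matrix(FALSE, nrow = n, ncol = 2L)
    rprob <- c(cfg$retention_prob_sub1, cfg$retention_prob_sub2)
    for (t in sort(unique(template))) {
      idx <- which(template == t)
      # realize the fractionation bias within every template: the subgenome-1
      # copy must retain strictly more genes than the subgenome-2 copy (when
      # the configured rates are biased), and surviving copies must share at
      # least one ancestral gene — otherwise the planted labels would not be
      # identifiable by synteny even in principle
      biased <- rprob[1L] > rprob[2L]
      for (attempt in 1:1000) {
        keep1 <- markov_retain(length(idx), rprob[1L], cfg$deletion_run_length)
        keep2 <- markov_retain(length(idx), rprob[2L], cfg$deletion_run_length)
        size_ok <- !biased || sum(keep1) > sum(keep2)
        overlap_ok <- !any(keep1) || !any(keep2) || any(keep1 & keep2)
        if (size_ok && overlap_ok) break
      }
      keeps <- list(keep1, keep2)
      for (g in 1:2) {
        keep <- keeps[[g]]
        if (!any(keep)) next
        retained[idx[keep], g] <- TRUE
        mchrom <- sprintf("chr%d", ((2L * t + g) %% 10L) + 1L)
        starts <- vapply(idx[keep], function(i) next_pos(mchrom), numeric(1))
        rows[[length(rows) + 1L]] <- tibble(
          block_id = sprintf("blk%03d_g%d", t, g),
          maize_gene = sprintf("Zm%d_%05d", g, idx[keep]),
          maize_chrom = mchrom,
          maize_start = starts,
          maize_end = starts + 2999,
          sorghum_gene = sorghum$sorghum_gene[idx[keep]],
          sorghum_chrom = sorghum$sorghum_chrom[idx[keep]],
          sorghum_order = sorghum$sorghum_order[idx[keep]],
          ks = rtnorm0(sum(keep), cfg$ks_wgd_mean, cfg$ks_wgd_sd),
          subgenome = if (g == 1L) "SUB1" else "SUB2"
        )
      }
    }
    if (length(rows) == 0L) abort("configuration deleted every gene")

    if (cfg$n_noise_blocks > 0L) {
      for (b in seq_len(cfg$n_noise_blocks)) {
        len <- sample(12:20, 1L)
        ch <- sample(unique(sorghum$sorghum_chrom), 1L)
        on_ch <- sorghum[sorghum$sorghum_chrom == ch, ]
        start <- sample(max(1L, nrow(on_ch) - len), 1L)
        seg <- on_ch[start:(start + len - 1L), ]
        mchrom <- sprintf("chr%d", sample(10L, 1L))
        starts <- vapply(seq_len(nrow(seg)), function(i) next_pos(mchrom), numeric(1))
        rows[[length(rows) + 1L]] <- tibble(
          block_id = sprintf("noise%02d", b),
          maize_gene = sprintf("ZmN%02d_%03d", b, seq_len(nrow(seg))),
          maize_chrom = mchrom,
          maize_start = starts,
          maize_end = starts + 2999,
          sorghum_gene = seg$sorghum_gene,
          sorghum_chrom = seg$sorghum_chrom,
          sorghum_order = seg$sorghum_order,
          ks = rtnorm0(nrow(seg), cfg$ks_noise_mean, cfg$ks_noise_sd),
          subgenome = "UNASSIGNED"
        )
      }
    }
    all_rows <- dplyr::bind_rows(rows)
    anchors <- select(all_rows, -"subgenome")
    genes <- all_rows |>
      distinct(gene = .data$maize_gene, subgenome = .data$subgenome,
               chrom = .data$maize_chrom, start = .data$maize_start,
               end = .data$maize_end)
    both <- which(retained[, 1L] & retained[, 2L])
    pairs <- tibble(
      sub1_gene = sprintf("Zm1_%05d", both),
      sub2_gene = sprintf("Zm2_%05d", both),
      sorghum_gene = sorghum$sorghum_gene[both]
    ) |> arrange(.data$sorghum_gene)
    list(anchors = anchors,
         truth = list(genes = genes, pairs = pairs, config = cfg))
  })
}

#' Minimal planted truth with a given number of pairs
#'
#' Convenience constructor for quantification-only experiments: `n_pairs`
#' retained duplicates with synthetic ids and coordinates, no fractionated
#' singletons, no decoys.
#'
#' @param n_pairs Number of homeolog pairs.
#' @param cfg A [sim_config()] (used for bookkeeping only).
#' @return A truth list like the one [simulate_genome()] returns.
#' @export
simulate_pair_truth <- function(n_pairs, cfg = sim_config()) {
  idx <- seq_len(n_pairs)
  genes <- tibble(
    gene = c(sprintf("Zm1_%05d", idx), sprintf("Zm2_%05d", idx)),
    subgenome = rep(c("SUB1", "SUB2"), each = n_pairs),
    chrom = rep(c("chr1", "chr2"), each = n_pairs),
    start = rep(1 + (idx - 1) * 10000, 2L),
    end = rep(3000 + (idx - 1) * 10000, 2L)
  )
  pairs <- tibble(
    sub1_gene = sprintf("Zm1_%05d", idx),
    sub2_gene = sprintf("Zm2_%05d", idx),
    sorghum_gene = sprintf("Sb%05d", idx)
  )
  list(genes = genes, pairs = pairs, config = cfg)
}

sim_tissue_names <- function(n_tissues) {
  c(sprintf("tissue_%02d", seq_len(n_tissues - 1L)), "pollen")
}

#' Simulate expression and abundance matrices with planted pair categories
#'
#' Draws one dominance category per pair from `cfg$category_fractions` and
#' constructs tissue profiles realising it: silent pairs are all-zero;
#' half-silent pairs zero one side; alternating pairs plant one tissue per
#' direction at `fold_signal`-fold dominance (plus multiplicative lognormal
#' measurement noise of cv `noise_cv`); correlated pairs are exactly
#' proportional with a ratio below the classifier fold; unpatterned pairs
#' get one-sided ratios (2.5x-10x, random side, resampled until their
#' Pearson correlation is at most 0.90) plus measurement noise, so that at
#' zero noise every planted category is recovered exactly by
#' [classify_pairs()]. Protein abundance is generated from expression
#' through a Gaussian copula whose parameter is calibrated so the Spearman
#' correlation over detected values equals `abun_coupling_rho`; one tissue
#' can be decoupled to a weaker coupling (the pollen effect). Genes outside
#' pairs get independent lognormal profiles. Deterministic given
#' `cfg$seed`.
#'
#' @param truth Truth list from [simulate_genome()] or
#'   [simulate_pair_truth()].
#' @param cfg A [sim_config()].
#' @return A list with `expr` and `abun` (wide tibbles, genes x tissues)
#'   and `categories` (tibble `sub1_gene`, `sub2_gene`, `category`).
#' @export
simulate_quant <- function(truth, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_stage_seed(cfg$seed, "quant", {
    tissues <- sim_tissue_names(cfg$n_tissues)
    ntis <- cfg$n_tissues
    pairs <- truth$pairs
    npair <- nrow(pairs)
    fr <- cfg$category_fractions
    cats <- sample(
      c(names(fr), "OTHER"), npair, replace = TRUE,
      prob = c(unname(fr), max(0, 1 - sum(fr)))
    )
    sdlog_noise <- sqrt(log(1 + cfg$noise_cv^2))
    noise <- function(k) {
      if (cfg$noise_cv == 0) rep(1, k) else exp(rnorm(k, 0, sdlog_noise))
    }
    base_profile <- function() {
      exp(rnorm(1, log(10), 0.8) + rnorm(ntis, 0, 1.2))
    }

    v1 <- matrix(0, npair, ntis)
    v2 <- matrix(0, npair, ntis)
    for (i in seq_len(npair)) {
      b <- base_profile()
      switch(cats[i],
        NO_SIGNAL = NULL,
        ONE_SILENT = {
          if (runif(1) < 0.5) v1[i, ] <- b else v2[i, ] <- b
        },
        ALTERNATING = {
          ij <- sample(ntis, 2L)
          a1 <- b; a2 <- b
          a1[ij[1L]] <- b[ij[1L]] * cfg$fold_signal
          a2[ij[2L]] <- b[ij[2L]] * cfg$fold_signal
          v1[i, ] <- a1 * noise(ntis)
          v2[i, ] <- a2 * noise(ntis)
        },
        CORRELATED = {
          v1[i, ] <- b
          v2[i, ] <- runif(1, 0.75, 1.3) * b
        },
        OTHER = {
          # one-sided profile, resampled until the emitted (noisy) vectors
          # are unambiguously none-of-the-other-categories: dominated side
          # never within 2-fold, Pearson at most 0.90
          side1 <- runif(1) < 0.5
          for (try in 1:100) {
            bb <- base_profile()   # fresh base too: a single outlier tissue
            ratio <- exp(runif(ntis, log(2.5), log(10)))   # pins Pearson near 1
            hi <- bb * noise(ntis)
            lo <- (bb / ratio) * noise(ntis)
            r <- suppressWarnings(cor(hi, lo))
            if ((is.na(r) || r <= 0.90) && max(lo / hi) < 0.5) break
          }
          if (side1) { v1[i, ] <- hi; v2[i, ] <- lo } else { v1[i, ] <- lo; v2[i, ] <- hi }
        }
      )
    }

    single <- setdiff(truth$genes$gene, c(pairs$sub1_gene, pairs$sub2_gene))
    vs <- matrix(exp(rnorm(length(single) * ntis, log(8), 1.2)),
                 nrow = length(single), ncol = ntis)

    expr_mat <- rbind(v1, v2, vs)
    gene_ids <- c(pairs$sub1_gene, pairs$sub2_gene, single)

    # abundance via Gaussian copula on pooled normal scores of detected values
    rho_star <- function(rho_s) 2 * sin(pi * rho_s / 6)
    abun_mat <- matrix(0, nrow(expr_mat), ntis)
    pos <- expr_mat > 0
    if (any(pos)) {
      z <- matrix(NA_real_, nrow(expr_mat), ntis)
      e <- expr_mat[pos]
      z[pos] <- qnorm((rank(e, ties.method = "average") - 0.5) / length(e))
      rs <- rep(rho_star(cfg$abun_coupling_rho), ntis)
      if (!is.na(cfg$decouple_tissue)) {
        rs[match(cfg$decouple_tissue, tissues)] <- rho_star(cfg$decouple_rho)
      }
      # noise: standard normal per entry, but with a variance fraction shared
      # between the two members of a pair within a tissue (marginals, and
      # hence the Spearman coupling, are unchanged)
      w <- cfg$abun_shared_noise
      eta <- matrix(rnorm(nrow(expr_mat) * ntis), ncol = ntis)
      if (npair > 0L && w > 0) {
        common <- matrix(rnorm(npair * ntis), ncol = ntis)
        own <- matrix(rnorm(2L * npair * ntis), ncol = ntis)
        eta[seq_len(2L * npair), ] <-
          sqrt(w) * rbind(common, common) + sqrt(1 - w) * own
      }
      for (t in seq_len(ntis)) {
        p <- pos[, t]
        if (!any(p)) next
        za <- rs[t] * z[p, t] + sqrt(1 - rs[t]^2) * eta[p, t]
        abun_mat[p, t] <- 1e-4 * exp(za)
      }
    }

    wide <- function(mat, kind) {
      colnames(mat) <- tissues
      out <- dplyr::bind_cols(tibble(gene_id = gene_ids), as_tibble(mat))
      attr(out, "kind") <- kind
      out
    }
    list(
      expr = wide(expr_mat, "FPKM"),
      abun = wide(abun_mat, "dNSAF"),
      categories = tibble(sub1_gene = pairs$sub1_gene,
                          sub2_gene = pairs$sub2_gene,
                          category = cats)
    )
  })
}

#' Simulate GO, reaction/pathway and isoform annotations
#'
#' Plants a configurable SUB1:SUB2 asymmetry (`annotation_asym`) into three
#' annotation layers: GO terms (a shared component planted on both homeologs
#' of a pair plus side-specific components; evidence codes mix IEA with the
#' experimental set; aspects cycle over MF/BP/CC), gene-to-reaction links
#' with pathway membership (some reactions belong to no pathway), and
#' per-gene isoform counts. Also records the planted ground truth the
#' comparison operations are tested against. Deterministic given
#' `cfg$seed`.
#'
#' @param truth Truth list from [simulate_genome()] or
#'   [simulate_pair_truth()].
#' @param cfg A [sim_config()].
#' @return A list with `go` (annotation tibble as from [read_gaf()]),
#'   `reactions` (link tibble), `isoforms` (tibble `gene`, `n_isoforms`),
#'   and `planted` (list: per-subgenome GO term sets and reaction sets).
#' @export
simulate_annotations <- function(truth, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_stage_seed(cfg$seed, "annotations", {
    genes <- truth$genes
    pairs <- truth$pairs
    terms <- sprintf("GO:%07d", seq_len(cfg$n_go_terms))
    aspect_of <- setNames(rep_len(c("MF", "BP", "CC"), cfg$n_go_terms), terms)
    rxns <- sprintf("RXN-%04d", seq_len(cfg$n_reactions))
    pways <- sprintf("PWY-%03d", seq_len(cfg$n_pathways))
    # each reaction belongs to 0-2 pathways
    rxn_pw <- vapply(rxns, function(r) {
      k <- sample(0:2, 1L)
      if (k == 0L) "" else paste(sample(pways, k), collapse = ";")
    }, character(1))

    asym1 <- sqrt(cfg$annotation_asym)
    rate_of <- function(sub, base) {
      ifelse(sub == "SUB1", base * asym1,
             ifelse(sub == "SUB2", base / asym1, base))
    }
    evid <- function(k) {
      ifelse(runif(k) < 0.3, sample(go_experimental_codes, k, replace = TRUE), "IEA")
    }

    # side-specific GO terms for every gene
    k_go <- rpois(nrow(genes), rate_of(genes$subgenome, cfg$go_rate))
    go_side <- tibble(
      gene = rep(genes$gene, k_go),
      term = sample(terms, sum(k_go), replace = TRUE)
    )
    # shared terms planted on both homeologs of a pair
    k_sh <- rpois(nrow(pairs), cfg$go_shared_rate)
    sh_terms <- sample(terms, sum(k_sh), replace = TRUE)
    go_shared <- tibble(
      gene = c(rep(pairs$sub1_gene, k_sh), rep(pairs$sub2_gene, k_sh)),
      term = c(sh_terms, sh_terms)
    )
    go <- bind_rows(go_side, go_shared) |>
      distinct() |>
      mutate(aspect = unname(aspect_of[.data$term]), evidence = evid(n())) |>
      arrange(.data$gene, .data$term)

    # reactions, with a shared component across pair members as well
    k_rx <- rpois(nrow(genes), rate_of(genes$subgenome, cfg$reaction_rate))
    rx_side <- tibble(gene = rep(genes$gene, k_rx),
                      reaction = sample(rxns, sum(k_rx), replace = TRUE))
    k_rsh <- rpois(nrow(pairs), cfg$reaction_rate / 2)
    rsh <- sample(rxns, sum(k_rsh), replace = TRUE)
    rx_shared <- tibble(
      gene = c(rep(pairs$sub1_gene, k_rsh), rep(pairs$sub2_gene, k_rsh)),
      reaction = c(rsh, rsh)
    )
    reactions <- bind_rows(rx_side, rx_shared) |>
      distinct() |>
      mutate(pathways = unname(rxn_pw[.data$reaction])) |>
      arrange(.data$gene, .data$reaction)

    isoforms <- tibble(
      gene = genes$gene,
      n_isoforms = 1L + rpois(nrow(genes), rate_of(genes$subgenome, cfg$iso_mean))
    )

    lab <- setNames(genes$subgenome, genes$gene)
    planted_sets <- function(d, col) {
      s <- lab[d$gene]
      list(sub1 = sort(unique(d[[col]][s %in% "SUB1"])),
           sub2 = sort(unique(d[[col]][s %in% "SUB2"])))
    }
    list(
      go = go, reactions = reactions, isoforms = isoforms,
      planted = list(go = planted_sets(go, "term"),
                     reactions = planted_sets(reactions, "reaction"))
    )
  })
}

#' Write annotations as a GAF 2.2 file
#'
#' @param ann Annotation tibble (`gene`, `term`, `aspect`, `evidence`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gaf <- function(ann, path) {
  aspect_code <- c(MF = "F", BP = "P", CC = "C")
  lines <- c(
    "!gaf-version: 2.2",
    paste("SIM", ann$gene, ann$gene, "", ann$term, "SIM:0000001",
          ann$evidence, "", unname(aspect_code[ann$aspect]), "", "",
          "protein", "taxon:4577", "20200101", "homeologr", "", "",
          sep = "\t")
  )
  readr::write_lines(lines, path)
  invisible(path)
}

#' Write gene models (with isoforms) as GFF3
#'
#' Emits one `gene` feature per gene and `n_isoforms` `mRNA` children, using
#' the 1-based inclusive coordinates recorded in the truth table.
#'
#' @param genes Tibble `gene`, `chrom`, `start`, `end`.
#' @param isoforms Tibble `gene`, `n_isoforms`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models_gff3 <- function(genes, isoforms, path) {
  d <- inner_join(genes, isoforms, by = "gene")
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(d))) {
    g <- d[i, ]
    lines <- c(lines, sprintf(
      "%s\thomeologr\tgene\t%d\t%d\t.\t+\t.\tID=%s",
      g$chrom, as.integer(g$start), as.integer(g$end), g$gene))
    if (g$n_isoforms > 0L) {
      tx <- sprintf("%s_T%03d", g$gene, seq_len(g$n_isoforms))
      lines <- c(lines, sprintf(
        "%s\thomeologr\tmRNA\t%d\t%d\t.\t+\t.\tID=%s;Parent=%s",
        g$chrom, as.integer(g$start), as.integer(g$end), tx, g$gene))
    }
  }
  readr::write_lines(lines, path)
  invisible(path)
}

#' Write reaction links as TSV
#'
#' @param reactions Tibble `gene`, `reaction`, `pathways`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reaction_links <- function(reactions, path) {
  readr::write_lines(
    paste(reactions$gene, reactions$reaction, reactions$pathways, sep = "\t"),
    path
  )
  invisible(path)
}

#' Generate a complete synthetic study on disk
#'
#' Runs [simulate_genome()], [simulate_quant()] and
#' [simulate_annotations()] and, when `out_dir` is given, writes
#' `anchors.tsv`, `expr.tsv`, `abun.tsv`, `ann.gaf`, `reactions.tsv`,
#' `models.gff3` and `truth.json` — a full fake study every pipeline stage
#' can be run on with no downloads.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Output directory (created if needed), or `NULL` to skip
#'   writing.
#' @return Invisibly, a list with `anchors`, `truth`, `quant`,
#'   `annotations`, and `files` (named paths, when written).
#' @export
simulate_study <- function(cfg = sim_config(), out_dir = NULL) {
  gen <- simulate_genome(cfg)
  quant <- simulate_quant(gen$truth, cfg)
  ann <- simulate_annotations(gen$truth, cfg)
  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- c(
      anchors = file.path(out_dir, "anchors.tsv"),
      expr = file.path(out_dir, "expr.tsv"),
      abun = file.path(out_dir, "abun.tsv"),
      gaf = file.path(out_dir, "ann.gaf"),
      reactions = file.path(out_dir, "reactions.tsv"),
      gff3 = file.path(out_dir, "models.gff3"),
      truth = file.path(out_dir, "truth.json")
    )
    write_anchor_blocks(gen$anchors, files[["anchors"]])
    write_quant_matrix(quant$expr, files[["expr"]])
    write_quant_matrix(quant$abun, files[["abun"]])
    write_gaf(ann$go, files[["gaf"]])
    write_reaction_links(ann$reactions, files[["reactions"]])
    write_gene_models_gff3(gen$truth$genes, ann$isoforms, files[["gff3"]])
    jsonlite::write_json(
      list(
        genes = gen$truth$genes, pairs = gen$truth$pairs,
        categories = quant$categories,
        planted_annotation_sets = ann$planted,
        seed = cfg$seed
      ),
      files[["truth"]], dataframe = "columns", auto_unbox = TRUE, digits = NA
    )
  }
  invisible(list(anchors = gen$anchors, truth = gen$truth, quant = quant,
                 annotations = ann, files = files))
}
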