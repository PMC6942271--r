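pkg_version <- function() {
  as.character(utils::packageVersion("homeologr"))
}

# every pipeline output carries the tool version and a hash of the settings
# used, so a results directory is self-describing
write_tsv_report <- function(d, path, config) {
  readr::write_lines(sprintf("# homeologr %s config=%s", pkg_version(),
                             rlang::hash(config)), path)
  readr::write_tsv(d, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

require_file <- function(path, what) {
  if (!is.character(path) || !file.exists(path)) {
    abort(sprintf("%s not found: '%s'", what, path %||% "<NULL>"))
  }
  invisible(path)
}

#' Run the subgenome-reconstruction stage
#'
#' Reads an anchor-block file, applies the block filters, greedily
#' bipartitions the blocks, labels the subgenomes and extracts retained
#' homeolog pairs. Writes `assignment.tsv`, `pairs.tsv` and
#' `subgenomes_report.json` into `out_dir`.
#'
#' @param anchor_file Anchor-block file path.
#' @param out_dir Output directory (created if needed).
#' @param min_anchors,max_mean_ks Block filters ([filter_blocks()]).
#' @param scope Greedy grouping scope ([greedy_bipartition()]).
#' @return Invisibly, a list with `assignment`, `pairs`, `bipartition` and
#'   `report`.
#' @export
run_subgenomes <- function(anchor_file, out_dir, min_anchors = 12L,
                           max_mean_ks = 1.0,
                           scope = c("global", "per_chromosome")) {
  scope <- match.arg(scope)
  require_file(anchor_file, "anchor-block file")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  config <- list(min_anchors = min_anchors, max_mean_ks = max_mean_ks, scope = scope)

  anchors <- read_anchor_blocks(anchor_file)
  n_blocks_before <- length(unique(anchors$block_id))
  filtered <- filter_blocks(anchors, min_anchors = min_anchors,
                            max_mean_ks = max_mean_ks)
  n_blocks_after <- length(unique(filtered$block_id))
  if (nrow(filtered) == 0L) {
    warn("no blocks survive filtering; writing empty outputs")
    assignment <- tibble(gene = character(), subgenome = character())
    pairs <- tibble(sub1_gene = character(), sub2_gene = character(),
                    sorghum_gene = character(), ks1 = numeric(), ks2 = numeric())
    bp <- NULL
  } else {
    bp <- greedy_bipartition(filtered, scope = scope)
    assignment <- label_subgenomes(bp)
    pairs <- extract_homeolog_pairs(bp, assignment)
  }
  write_tsv_report(assignment, file.path(out_dir, "assignment.tsv"), config)
  write_tsv_report(pairs, file.path(out_dir, "pairs.tsv"), config)
  report <- c(
    config,
    list(
      n_blocks_before = n_blocks_before,
      n_blocks_after = n_blocks_after,
      n_pairs = nrow(pairs),
      n_sub1 = sum(assignment$subgenome == "SUB1"),
      n_sub2 = sum(assignment$subgenome == "SUB2"),
      n_unassigned = sum(assignment$subgenome == "UNASSIGNED")
    ),
    if (!is.null(bp)) as.list(glance(bp))
  )
  jsonlite::write_json(report, file.path(out_dir, "subgenomes_report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(assignment = assignment, pairs = pairs, bipartition = bp,
                 report = report))
}

# centralized GFF (1-based inclusive) -> BED (0-based half-open) conversion
gff_to_bed_start <- function(start) as.integer(start) - 1L

#' Write a karyotype BED track of subgenome labels and dominance calls
#'
#' One BED record per gene (0-based half-open coordinates) with the
#' subgenome label and, for members of a homeolog pair, that pair's
#' average-dominance call in the two extra columns — the data behind a
#' chromosome-paint figure with a dominance side-track.
#'
#' @param assignment Label tibble ([label_subgenomes()]).
#' @param gene_coords Tibble `gene`, `chrom`, `start`, `end` (1-based
#'   inclusive).
#' @param avg_dom Average-dominance tibble ([average_dominance()]), or
#'   `NULL`.
#' @param path Output BED path.
#' @return The BED tibble, invisibly.
#' @export
write_karyotype_bed <- function(assignment, gene_coords, avg_dom = NULL, path) {
  bed <- inner_join(assignment, gene_coords, by = "gene") |>
    mutate(bed_start = gff_to_bed_start(.data$start), bed_end = as.integer(.data$end))
  call_of <- character(0)
  if (!is.null(avg_dom)) {
    # expressed from each member's own side
    side1 <- dplyr::case_match(avg_dom$call, "SUB1_DOM" ~ "SELF_DOM",
                               "SUB2_DOM" ~ "PARTNER_DOM", .default = "NEITHER")
    side2 <- dplyr::case_match(avg_dom$call, "SUB2_DOM" ~ "SELF_DOM",
                               "SUB1_DOM" ~ "PARTNER_DOM", .default = "NEITHER")
    call_of <- c(setNames(side1, avg_dom$sub1_gene),
                 setNames(side2, avg_dom$sub2_gene))
  }
  dom <- unname(call_of[bed$gene])
  dom[is.na(dom)] <- "."
  out <- tibble(
    chrom = bed$chrom, start = bed$bed_start, end = bed$bed_end,
    name = bed$gene, score = 0L, strand = ".",
    subgenome = bed$subgenome, dominance = dom
  ) |> arrange(.data$chrom, .data$start)
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(out)
}

#' Run the dominance-classification stage
#'
#' Builds pair profiles from the expression (and optionally abundance)
#' matrix, writes per-pair classifications, average-dominance calls, the
#' per-tissue correlation structure (when both kinds are present), a
#' karyotype BED track (when gene coordinates are available from the anchor
#' file) and `dominance_report.json`.
#'
#' @param pairs_file Homeolog pair TSV from [run_subgenomes()].
#' @param expr_file Expression matrix TSV (genes x tissues).
#' @param out_dir Output directory.
#' @param abun_file Optional abundance matrix TSV.
#' @param assignment_file Optional assignment TSV (needed for the BED track).
#' @param anchor_file Optional anchor file supplying gene coordinates.
#' @param fold,corr_threshold,corr_method Classifier settings
#'   ([classify_pairs()]).
#' @return Invisibly, a list with the classification tables and the report.
#' @export
run_dominance <- function(pairs_file, expr_file, out_dir, abun_file = NULL,
                          assignment_file = NULL, anchor_file = NULL,
                          fold = 2.0, corr_threshold = 0.95,
                          corr_method = c("pearson", "spearman")) {
  corr_method <- match.arg(corr_method)
  require_file(pairs_file, "pair file")
  require_file(expr_file, "expression matrix")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  config <- list(fold = fold, corr_threshold = corr_threshold,
                 corr_method = corr_method)

  pairs <- readr::read_tsv(pairs_file, comment = "#",
                           col_types = readr::cols(
                             sub1_gene = readr::col_character(),
                             sub2_gene = readr::col_character(),
                             .default = readr::col_guess()))
  expr <- read_quant_matrix(expr_file, "FPKM")
  ep <- build_pair_profiles(pairs, expr)
  expr_class <- classify_pairs(ep, fold, corr_threshold, corr_method)
  avg <- average_dominance(ep, fold)
  write_tsv_report(mutate(expr_class, kind = "FPKM", .after = "sub2_gene"),
                   file.path(out_dir, "classification_expr.tsv"), config)
  write_tsv_report(avg, file.path(out_dir, "average_dominance.tsv"), config)
  # per-pair tissue profiles, the data behind archetype plots
  write_tsv_report(ep, file.path(out_dir, "pair_profiles_expr.tsv"), config)

  report <- c(config, list(
    n_pairs_expr = nrow(expr_class),
    expr_counts = setNames(as.list(count_categories(expr_class)$n), pair_categories),
    avg_dominance = list(
      sub1_dom = sum(avg$call == "SUB1_DOM"),
      sub2_dom = sum(avg$call == "SUB2_DOM"),
      neither = sum(avg$call == "NEITHER")
    )
  ))

  abun_class <- joint <- cm <- NULL
  if (!is.null(abun_file)) {
    require_file(abun_file, "abundance matrix")
    abun <- read_quant_matrix(abun_file, "dNSAF")
    ap <- build_pair_profiles(pairs, abun)
    abun_class <- classify_pairs(ap, fold, corr_threshold, corr_method)
    joint <- joint_classification(ep, ap, fold, corr_threshold, corr_method)
    cm <- correlation_matrix(ep, ap)
    write_tsv_report(mutate(abun_class, kind = "dNSAF", .after = "sub2_gene"),
                     file.path(out_dir, "classification_abun.tsv"), config)
    write_tsv_report(joint, file.path(out_dir, "joint_classification.tsv"), config)
    write_tsv_report(cm, file.path(out_dir, "correlation_matrix.tsv"), config)
    report <- c(report, list(
      abun_counts = setNames(as.list(count_categories(abun_class)$n), pair_categories),
      joint = as.list(count_joint(joint))
    ))
  }

  if (!is.null(assignment_file) && !is.null(anchor_file)) {
    require_file(assignment_file, "assignment file")
    require_file(anchor_file, "anchor-block file")
    assignment <- readr::read_tsv(assignment_file, comment = "#",
                                  col_types = "cc")
    coords <- read_anchor_blocks(anchor_file) |>
      distinct(gene = .data$maize_gene, chrom = .data$maize_chrom,
               start = .data$maize_start, end = .data$maize_end)
    write_karyotype_bed(assignment, coords, avg,
                        file.path(out_dir, "karyotype.bed"))
  }

  jsonlite::write_json(report, file.path(out_dir, "dominance_report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(expr_class = expr_class, abun_class = abun_class,
                 average_dominance = avg, joint = joint,
                 correlation_matrix = cm, report = report))
}

#' Run the functional-divergence stage
#'
#' Compares GO term repertoires (all evidence, and the experimental
#' "gold standard" restricted to molecular function), per-pair GO
#' assignments, reaction/pathway repertoires (genome-wide, and restricted
#' to pair genes with pathway-linked reactions only) and isoform counts.
#' Writes the comparison tables and `functional_report.json`.
#'
#' @param assignment_file Assignment TSV from [run_subgenomes()].
#' @param pairs_file Pair TSV from [run_subgenomes()].
#' @param gaf_file GO annotations (GAF 2.x).
#' @param reactions_file Reaction link TSV.
#' @param gff3_file Gene-model annotation (GFF3 or GTF).
#' @param out_dir Output directory.
#' @param gold_aspect,gold_evidence Filters for the gold-standard GO
#'   comparison.
#' @return Invisibly, a list of comparison objects plus the report.
#' @export
run_functional <- function(assignment_file, pairs_file, gaf_file,
                           reactions_file, gff3_file, out_dir,
                           gold_aspect = "MF",
                           gold_evidence = go_experimental_codes) {
  require_file(assignment_file, "assignment file")
  require_file(pairs_file, "pair file")
  require_file(gaf_file, "GAF file")
  require_file(reactions_file, "reaction link file")
  require_file(gff3_file, "gene-model annotation")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  config <- list(gold_aspect = gold_aspect, gold_evidence = gold_evidence)

  assignment <- readr::read_tsv(assignment_file, comment = "#", col_types = "cc")
  pairs <- readr::read_tsv(pairs_file, comment = "#",
                           col_types = readr::cols(
                             sub1_gene = readr::col_character(),
                             sub2_gene = readr::col_character(),
                             .default = readr::col_guess()))
  ann <- read_gaf(gaf_file)
  links <- read_reaction_links(reactions_file)

  go_all <- compare_go_terms(ann, assignment)
  go_gold <- compare_go_terms(ann, assignment, aspect = gold_aspect,
                              evidence = gold_evidence)
  go_assign <- compare_go_assignments(ann, pairs, aspect = gold_aspect,
                                      evidence = gold_evidence)
  rx_all <- compare_reactions(links, assignment)
  rx_pairs <- compare_reactions(links, assignment, restrict_to_pairs = pairs,
                                pathway_only = TRUE)
  iso <- compare_isoforms(pairs, isoform_counts(gff3_file))

  write_tsv_report(tidy(go_all), file.path(out_dir, "go_terms_all.tsv"), config)
  write_tsv_report(tidy(go_gold), file.path(out_dir, "go_terms_gold.tsv"), config)
  write_tsv_report(tidy(go_assign), file.path(out_dir, "go_assignments.tsv"), config)
  write_tsv_report(tidy(rx_all$reactions), file.path(out_dir, "reactions_all.tsv"), config)
  write_tsv_report(tidy(rx_pairs$reactions),
                   file.path(out_dir, "reactions_pairs_pathway.tsv"), config)
  write_tsv_report(iso, file.path(out_dir, "isoforms.tsv"), config)

  report <- c(config, list(
    go_all = as.list(glance(go_all)),
    go_gold = as.list(glance(go_gold)),
    go_assignments = as.list(glance(go_assign)),
    reactions_all = as.list(glance(rx_all$reactions)),
    reactions_pairs_pathway = c(
      as.list(glance(rx_pairs$reactions)),
      list(pathways_unique1 = rx_pairs$pathway_counts$n_pathways[1L],
           pathways_unique2 = rx_pairs$pathway_counts$n_pathways[2L])
    ),
    isoforms = as.list(isoform_summary(iso))
  ))
  jsonlite::write_json(report, file.path(out_dir, "functional_report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(go_all = go_all, go_gold = go_gold, go_assignments = go_assign,
                 reactions_all = rx_all, reactions_pairs = rx_pairs,
                 isoforms = iso, report = report))
}

#' Run the whole pipeline on a study directory
#'
#' Convenience wrapper expecting the file layout written by
#' [simulate_study()] (`anchors.tsv`, `expr.tsv`, `abun.tsv`, `ann.gaf`,
#' `reactions.tsv`, `models.gff3`), running all three stages in order.
#'
#' @param study_dir Input directory.
#' @param out_dir Output directory.
#' @param ... Passed on to [run_dominance()] (classifier settings).
#' @return Invisibly, a list with the three stage results.
#' @export
run_all <- function(study_dir, out_dir, ...) {
  p <- function(f) file.path(study_dir, f)
  sub <- run_subgenomes(p("anchors.tsv"), out_dir)
  dom <- run_dominance(
    pairs_file = file.path(out_dir, "pairs.tsv"),
    expr_file = p("expr.tsv"), out_dir = out_dir,
    abun_file = p("abun.tsv"),
    assignment_file = file.path(out_dir, "assignment.tsv"),
    anchor_file = p("anchors.tsv"), ...
  )
  fun <- run_functional(
    assignment_file = file.path(out_dir, "assignment.tsv"),
    pairs_file = file.path(out_dir, "pairs.tsv"),
    gaf_file = p("ann.gaf"), reactions_file = p("reactions.tsv"),
    gff3_file = p("models.gff3"), out_dir = out_dir
  )
  invisible(list(subgenomes = sub, dominance = dom, functional = fun))
}
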