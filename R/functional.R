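#' @rdname compare_go_terms
#' @format NULL
#' @export
go_experimental_codes <- c("EXP", "IDA", "IPI", "IMP", "IGI", "IEP")

new_set_comparison <- function(shared, unique1, unique2,
                               labels = c("SUB1", "SUB2")) {
  structure(
    list(shared = sort(unique(shared)), unique1 = sort(unique(unique1)),
         unique2 = sort(unique(unique2)), labels = labels),
    class = "set_comparison"
  )
}

# three-way split of two item sets; the basic primitive behind every
# subgenome-level comparison
set_comparison <- function(items1, items2, labels = c("SUB1", "SUB2")) {
  items1 <- unique(items1)
  items2 <- unique(items2)
  new_set_comparison(
    shared = intersect(items1, items2),
    unique1 = setdiff(items1, items2),
    unique2 = setdiff(items2, items1),
    labels = labels
  )
}

#' @export
print.set_comparison <- function(x, ...) {
  cat(sprintf("<set_comparison> %s vs %s\n", x$labels[1L], x$labels[2L]))
  cat(sprintf("  shared: %d   unique to %s: %d   unique to %s: %d\n",
              length(x$shared), x$labels[1L], length(x$unique1),
              x$labels[2L], length(x$unique2)))
  invisible(x)
}

#' @rdname compare_go_terms
#' @param x A `set_comparison`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.set_comparison <- function(x, ...) {
  tibble(
    item = c(x$shared, x$unique1, x$unique2),
    status = rep(c("shared", "unique1", "unique2"),
                 c(length(x$shared), length(x$unique1), length(x$unique2)))
  )
}

#' @rdname compare_go_terms
#' @exportS3Method generics::glance
glance.set_comparison <- function(x, ...) {
  tibble(n_shared = length(x$shared), n_unique1 = length(x$unique1),
         n_unique2 = length(x$unique2))
}

#' Read a GAF 2.x gene-association file
#'
#' Keeps columns 2 (gene), 5 (GO term), 7 (evidence code) and 9 (aspect,
#' recoded F/P/C to MF/BP/CC). Comment lines starting with `!` are skipped;
#' rows whose term does not match `GO:` + 7 digits are dropped with a
#' warning count.
#'
#' @param path GAF path.
#' @return A tibble `gene`, `term`, `aspect`, `evidence`.
#' @export
read_gaf <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  if (length(lines) == 0L) {
    return(tibble(gene = character(), term = character(),
                  aspect = character(), evidence = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 9L
  if (any(short)) abort(sprintf("GAF row %d has fewer than 9 columns", which(short)[1L]))
  mat <- t(vapply(fields, function(f) f[c(2L, 5L, 7L, 9L)], character(4)))
  ann <- tibble(
    gene = mat[, 1L], term = mat[, 2L], evidence = mat[, 3L],
    aspect = dplyr::recode(mat[, 4L], F = "MF", P = "BP", C = "CC",
                           .default = mat[, 4L])
  )
  bad <- !stringr::str_detect(ann$term, "^GO:\\d{7}$")
  if (any(bad)) {
    warn(sprintf("%d row(s) with malformed GO id skipped", sum(bad)))
    ann <- ann[!bad, ]
  }
  ann[, c("gene", "term", "aspect", "evidence")]
}

filter_go <- function(ann, aspect, evidence) {
  if (!is.null(aspect)) ann <- ann[ann$aspect %in% aspect, ]
  if (!is.null(evidence)) ann <- ann[ann$evidence %in% evidence, ]
  ann
}

#' Compare GO term repertoires between subgenomes
#'
#' Builds the set of GO terms annotated to at least one gene of each
#' subgenome (after optional aspect and evidence-code filters) and splits
#' them into shared / unique-to-SUB1 / unique-to-SUB2. `UNASSIGNED` genes
#' are ignored. The "gold standard" comparison uses molecular-function
#' terms with experimental evidence only (`aspect = "MF"`,
#' `evidence = go_experimental_codes`); the default compares everything.
#'
#' @param ann GO annotation tibble from [read_gaf()].
#' @param assignment Subgenome label tibble ([label_subgenomes()]).
#' @param aspect `NULL` (all) or subset of `"MF"`, `"BP"`, `"CC"`.
#' @param evidence `NULL` (all) or a set of GAF evidence codes;
#'   `go_experimental_codes` holds the standard experimental set
#'   EXP/IDA/IPI/IMP/IGI/IEP.
#' @return A `set_comparison`; see [tidy()] and [glance()] methods.
#' @export
compare_go_terms <- function(ann, assignment, aspect = NULL, evidence = NULL) {
  ann <- filter_go(ann, aspect, evidence)
  lab <- setNames(assignment$subgenome, assignment$gene)
  side <- lab[ann$gene]
  set_comparison(ann$term[side %in% "SUB1"], ann$term[side %in% "SUB2"])
}

#' Compare per-gene GO assignments within homeolog pairs
#'
#' Here the unit is an assignment of a term to one side of a pair, not the
#' term itself: a term annotating both genes of a pair is one shared
#' assignment; a term annotating only one side is unique to that side. A
#' term on the SUB1 gene of one pair and on the SUB2 gene of a different
#' pair stays unique on both sides — annotations are never shared across
#' pairs.
#'
#' @param ann GO annotation tibble.
#' @param pairs Homeolog pair tibble.
#' @inheritParams compare_go_terms
#' @return A `set_comparison` whose items are `"sub1_gene|sub2_gene|term"`
#'   strings.
#' @export
compare_go_assignments <- function(ann, pairs, aspect = NULL, evidence = NULL) {
  ann <- filter_go(ann, aspect, evidence)
  terms_of <- function(genes) {
    sub <- ann[ann$gene %in% genes, c("gene", "term")]
    split(sub$term, factor(sub$gene, levels = genes))
  }
  t1 <- terms_of(pairs$sub1_gene)
  t2 <- terms_of(pairs$sub2_gene)
  key <- paste(pairs$sub1_gene, pairs$sub2_gene, sep = "|")
  items1 <- unlist(purrr::map2(key, t1, function(k, tt) {
    if (length(tt) == 0L) character(0) else paste(k, unique(tt), sep = "|")
  }))
  items2 <- unlist(purrr::map2(key, t2, function(k, tt) {
    if (length(tt) == 0L) character(0) else paste(k, unique(tt), sep = "|")
  }))
  set_comparison(items1, items2)
}

#' Read a gene-to-reaction link table
#'
#' Format: `gene<TAB>reaction<TAB>pathway1;pathway2;...` (pathway field may
#' be empty — a reaction not placed in any pathway).
#'
#' @param path TSV path.
#' @return A tibble `gene`, `reaction`, `pathways` (`;`-joined string,
#'   possibly empty).
#' @export
read_reaction_links <- function(path) {
  readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    col_names = c("gene", "reaction", "pathways"), comment = "#"
  ) |>
    mutate(pathways = dplyr::coalesce(.data$pathways, ""))
}

#' Compare reaction repertoires between subgenomes
#'
#' Splits the reactions linked to each subgenome's genes into shared and
#' unique sets, optionally restricted to genes that are members of retained
#' homeolog pairs and/or to reactions placed in at least one pathway. Also
#' reports, per side, how many pathways contain at least one of that side's
#' unique reactions — a reaction set can be larger yet touch fewer
#' pathways.
#'
#' @param links Reaction link tibble from [read_reaction_links()].
#' @param assignment Subgenome label tibble.
#' @param restrict_to_pairs Optional homeolog pair tibble; when given, only
#'   genes occurring in pairs are counted.
#' @param pathway_only Drop reactions with an empty pathway set first.
#' @return A list with `reactions` (a `set_comparison`) and
#'   `pathway_counts` (tibble `side`, `n_pathways`).
#' @export
compare_reactions <- function(links, assignment, restrict_to_pairs = NULL,
                              pathway_only = FALSE) {
  if (pathway_only) links <- links[nzchar(links$pathways), ]
  if (!is.null(restrict_to_pairs)) {
    keep <- c(restrict_to_pairs$sub1_gene, restrict_to_pairs$sub2_gene)
    links <- links[links$gene %in% keep, ]
  }
  lab <- setNames(assignment$subgenome, assignment$gene)
  side <- lab[links$gene]
  cmp <- set_comparison(links$reaction[side %in% "SUB1"],
                        links$reaction[side %in% "SUB2"])
  pw_of <- function(rxns) {
    p <- unlist(strsplit(links$pathways[links$reaction %in% rxns], ";", fixed = TRUE))
    unique(p[nzchar(p)])
  }
  list(
    reactions = cmp,
    pathway_counts = tibble(
      side = c("SUB1", "SUB2"),
      n_pathways = c(length(pw_of(cmp$unique1)), length(pw_of(cmp$unique2)))
    )
  )
}

transcript_types <- c(
  "mRNA", "transcript", "tRNA", "rRNA", "ncRNA", "lnc_RNA", "snoRNA",
  "snRNA", "miRNA", "pre_miRNA", "pseudogenic_transcript", "antisense_RNA"
)

#' Count transcript isoforms per gene from a GFF3 or GTF annotation
#'
#' Uses the gene/transcript hierarchy: GFF3 transcripts are features of a
#' transcript type whose `Parent` is a gene; GTF transcripts are distinct
#' `transcript_id` values per `gene_id`. Duplicate transcript records
#' (multi-exon GTF) count once; genes with no transcript records count 0. A
#' transcript whose parent gene is unknown is counted under its own id,
#' with a warning.
#'
#' @param path Annotation path, `.gff3`/`.gff` or `.gtf`.
#' @param format `"gff3"` or `"gtf"`; guessed from the extension by default.
#' @return A tibble `gene`, `n_isoforms`.
#' @export
isoform_counts <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.gtf$", path, ignore.case = TRUE)) "gtf" else "gff3"
  }
  gr <- rtracklayer::import(path, format = format)
  md <- S4Vectors::mcols(gr)
  if (format == "gtf") {
    d <- tibble(gene = as.character(md$gene_id),
                tx = as.character(md$transcript_id))
    genes <- unique(d$gene[!is.na(d$gene)])
    tx <- distinct(d[!is.na(d$tx) & !is.na(d$gene), ])
  } else {
    ids <- as.character(md$ID)
    parents <- vapply(as.list(md$Parent), function(p) {
      if (length(p) == 0L) NA_character_ else p[[1L]]
    }, character(1))
    types <- as.character(md$type)
    genes <- unique(ids[types == "gene" & !is.na(ids)])
    is_tx <- types %in% transcript_types
    tx_gene <- parents[is_tx]
    tx_id <- ids[is_tx]
    orphan <- is.na(tx_gene) | !tx_gene %in% genes
    if (any(orphan)) {
      warn(sprintf("%d transcript(s) with unknown parent gene counted under their own id",
                   sum(orphan)))
      tx_gene[orphan] <- tx_id[orphan]
    }
    tx <- distinct(tibble(gene = tx_gene, tx = tx_id))
  }
  counts <- count(tx, .data$gene, name = "n_isoforms")
  zero <- setdiff(genes, counts$gene)
  bind_rows(counts, tibble(gene = zero, n_isoforms = 0L)) |>
    arrange(.data$gene)
}

#' Compare isoform counts within homeolog pairs
#'
#' Per pair, reports both isoform counts, their difference and the log2 of
#' their ratio (undefined, hence `NA`, when either count is 0; the raw
#' difference is always defined). Pairs with a missing count on either side
#' are excluded and counted in a message.
#'
#' @param pairs Homeolog pair tibble.
#' @param counts Isoform count tibble from [isoform_counts()].
#' @return A tibble `sub1_gene`, `sub2_gene`, `n1`, `n2`, `diff`,
#'   `log2_ratio`, sorted by pair.
#' @seealso [isoform_summary()]
#' @export
compare_isoforms <- function(pairs, counts) {
  cnt <- setNames(counts$n_isoforms, counts$gene)
  out <- tibble(
    sub1_gene = pairs$sub1_gene, sub2_gene = pairs$sub2_gene,
    n1 = unname(cnt[pairs$sub1_gene]), n2 = unname(cnt[pairs$sub2_gene])
  )
  missing <- is.na(out$n1) | is.na(out$n2)
  if (any(missing)) {
    inform(sprintf("%d pair(s) without isoform counts on both sides excluded",
                   sum(missing)))
    out <- out[!missing, ]
  }
  out |>
    mutate(
      diff = .data$n1 - .data$n2,
      log2_ratio = if_else(.data$n1 > 0 & .data$n2 > 0,
                           log2(.data$n1 / .data$n2), NA_real_)
    ) |>
    arrange(.data$sub1_gene, .data$sub2_gene)
}

#' Summarise an isoform comparison
#'
#' @param cmp Output of [compare_isoforms()].
#' @return One-row tibble with the fractions of pairs in which the SUB1
#'   copy has more, equally many, or fewer isoforms.
#' @export
isoform_summary <- function(cmp) {
  summarise(
    cmp,
    n_pairs = n(),
    frac_sub1_more = mean(.data$n1 > .data$n2),
    frac_equal = mean(.data$n1 == .data$n2),
    frac_sub2_more = mean(.data$n1 < .data$n2)
  )
}
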