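#' Greedily bipartition syntenic blocks into two subgenomes
#'
#' After a whole-genome duplication, every region of the outgroup (sorghum)
#' genome is expected to be syntenic to up to two regions of the duplicated
#' (maize) genome — one per ancestral subgenome. Blocks are therefore grouped
#' into two sets such that, within a set, no two blocks on the same sorghum
#' chromosome anchor the same sorghum gene. The grouping is greedy: blocks
#' are visited in decreasing size (anchor count, ties broken by lower mean
#' Ks, then block id) and each joins the first group it does not conflict
#' with (group 1 tried first). A block conflicting with both groups — a
#' third-copy artefact or a mischained block — is set aside as an orphan.
#' On return the groups are oriented so that group 1 carries at least as
#' many anchors as group 2.
#'
#' @param anchors Anchor tibble (ideally after [filter_blocks()]).
#' @param scope `"global"` (default) runs one greedy pass over all blocks;
#'   `"per_chromosome"` repeats the procedure independently within each
#'   sorghum chromosome, orienting each chromosome's two groups by local
#'   anchor count.
#' @return An object of class `bipartition`: a list with `blocks` (the
#'   [summarise_blocks()] table plus a `group` column: 1, 2 or `NA` for
#'   orphans), `anchors` (input anchors plus `group`), and `scope`.
#' @seealso [label_subgenomes()], [extract_homeolog_pairs()],
#'   [validate_bipartition()]
#' @export
greedy_bipartition <- function(anchors, scope = c("global", "per_chromosome")) {
  scope <- match.arg(scope)
  runs <- rle(anchors$block_id)
  if (anyDuplicated(runs$values)) {
    abort(sprintf("duplicate block_id '%s'", runs$values[duplicated(runs$values)][1L]))
  }

  if (scope == "per_chromosome") {
    parts <- split(anchors, anchors$sorghum_chrom)
    grp <- lapply(parts, greedy_pass)
    group_of <- unlist(grp, use.names = TRUE)
    names(group_of) <- unlist(lapply(grp, names))
  } else {
    group_of <- greedy_pass(anchors)
  }

  blocks <- summarise_blocks(anchors)
  blocks$group <- unname(group_of[blocks$block_id])
  anchors$group <- unname(group_of[anchors$block_id])

  # orient globally: group 1 is the larger set by total anchors
  n1 <- sum(blocks$n_anchors[blocks$group %in% 1L])
  n2 <- sum(blocks$n_anchors[blocks$group %in% 2L])
  if (n2 > n1) {
    blocks$group <- 3L - blocks$group
    anchors$group <- 3L - anchors$group
  }
  structure(list(blocks = blocks, anchors = anchors, scope = scope),
            class = "bipartition")
}

# one greedy pass; returns named integer vector block_id -> group (NA = orphan)
greedy_pass <- function(anchors) {
  blocks <- summarise_blocks(anchors)
  ord <- order(-blocks$n_anchors, blocks$mean_ks, blocks$block_id,
               na.last = TRUE)
  keysets <- split(paste0(anchors$sorghum_chrom, "\r", anchors$sorghum_gene),
                   anchors$block_id)
  occupied <- list(new.env(parent = emptyenv()), new.env(parent = emptyenv()))
  group_of <- setNames(rep(NA_integer_, nrow(blocks)), blocks$block_id)
  for (i in ord) {
    keys <- unique(keysets[[blocks$block_id[i]]])
    placed <- FALSE
    for (g in 1:2) {
      if (!any(vapply(keys, exists, logical(1), envir = occupied[[g]],
                      inherits = FALSE))) {
        for (k in keys) assign(k, TRUE, envir = occupied[[g]])
        group_of[[blocks$block_id[i]]] <- g
        placed <- TRUE
        break
      }
    }
  }
  group_of
}

#' Validate a bipartition against its defining invariants
#'
#' Independent re-check of a [greedy_bipartition()] result: it rescans the
#' anchors from scratch and verifies that (i) no block sits in both groups,
#' (ii) within each group no two distinct blocks on the same sorghum
#' chromosome share a sorghum gene, and (iii) group 1 carries at least as
#' many anchors as group 2. Written as a brute-force pairwise scan on
#' purpose, so it shares no code with the greedy construction.
#'
#' @param bp A `bipartition`.
#' @return `TRUE` if all invariants hold, otherwise `FALSE` with a
#'   `problems` attribute describing the first violations found.
#' @export
validate_bipartition <- function(bp) {
  problems <- character(0)
  a <- bp$anchors
  for (g in 1:2) {
    ag <- a[!is.na(a$group) & a$group == g, ]
    ids <- unique(ag$block_id)
    if (length(ids) < 2L) next
    per_block <- lapply(ids, function(id) {
      unique(paste0(ag$sorghum_chrom[ag$block_id == id], "\r",
                    ag$sorghum_gene[ag$block_id == id]))
    })
    for (i in seq_along(ids)) {
      for (j in seq_len(i - 1L)) {
        ov <- intersect(per_block[[i]], per_block[[j]])
        if (length(ov) > 0L) {
          problems <- c(problems, sprintf(
            "group %d: blocks '%s' and '%s' share %d sorghum gene(s)",
            g, ids[i], ids[j], length(ov)))
        }
      }
    }
  }
  b <- bp$blocks
  if (anyDuplicated(b$block_id)) problems <- c(problems, "duplicate block ids")
  n1 <- sum(b$n_anchors[b$group %in% 1L])
  n2 <- sum(b$n_anchors[b$group %in% 2L])
  if (n1 < n2) problems <- c(problems, "group 1 smaller than group 2 by anchors")
  ok <- length(problems) == 0L
  if (!ok) attr(ok, "problems") <- problems
  ok
}

#' Label maize genes by subgenome
#'
#' Maps every maize gene to `SUB1`, `SUB2` or `UNASSIGNED`. The larger, less
#' fractionated gene set (by count of distinct retained genes, anchor total
#' breaking ties) is labeled `SUB1` — in maize this is the conventional
#' Maize1 subgenome. Genes appearing only in orphan blocks are `UNASSIGNED`.
#'
#' @param bp A `bipartition`.
#' @return A tibble `gene`, `subgenome`, one row per maize gene seen in any
#'   anchor, sorted by gene.
#' @export
label_subgenomes <- function(bp) {
  a <- bp$anchors
  placed <- a[!is.na(a$group), ]
  by_gene <- placed |>
    distinct(.data$maize_gene, .data$group) |>
    count(.data$maize_gene)
  conflict <- by_gene$maize_gene[by_gene$n > 1L]
  if (length(conflict) > 0L) {
    abort(sprintf("gene '%s' is anchored in both groups; bipartition is inconsistent",
                  conflict[1L]))
  }
  genes1 <- unique(placed$maize_gene[placed$group == 1L])
  genes2 <- unique(placed$maize_gene[placed$group == 2L])
  # orient by retained gene count; anchors break ties (matches bipartition)
  if (length(genes2) > length(genes1)) {
    tmp <- genes1; genes1 <- genes2; genes2 <- tmp
  }
  orphan_genes <- setdiff(unique(a$maize_gene), c(genes1, genes2))
  tibble(
    gene = c(genes1, genes2, orphan_genes),
    subgenome = rep(c("SUB1", "SUB2", "UNASSIGNED"),
                    c(length(genes1), length(genes2), length(orphan_genes)))
  ) |>
    arrange(.data$gene)
}

#' Extract retained homeolog pairs
#'
#' A retained duplicate (homeolog pair) is witnessed by one sorghum gene
#' anchored both in a group-1 block and a group-2 block: its two maize
#' anchors are the two surviving post-duplication copies. When a sorghum
#' gene has several anchors within one group, the anchor with the lowest Ks
#' is kept (missing Ks sorts last; remaining ties go to the
#' lexicographically smallest maize gene id).
#'
#' @param bp A `bipartition`.
#' @param assignment Optional label table from [label_subgenomes()]; computed
#'   from `bp` when omitted. Used to decide which group is `SUB1`.
#' @return A tibble `sub1_gene`, `sub2_gene`, `sorghum_gene`, `ks1`, `ks2`,
#'   sorted by `sorghum_gene`.
#' @export
extract_homeolog_pairs <- function(bp, assignment = NULL) {
  if (is.null(assignment)) assignment <- label_subgenomes(bp)
  a <- bp$anchors
  placed <- a[!is.na(a$group), ]
  if (nrow(placed) == 0L) {
    return(tibble(sub1_gene = character(), sub2_gene = character(),
                  sorghum_gene = character(), ks1 = numeric(), ks2 = numeric()))
  }
  best <- placed |>
    mutate(.ks_sort = if_else(is.na(.data$ks), Inf, .data$ks)) |>
    arrange(.data$.ks_sort, .data$maize_gene) |>
    group_by(.data$group, .data$sorghum_gene) |>
    dplyr::slice(1L) |>
    ungroup()

  lab <- setNames(assignment$subgenome, assignment$gene)
  sub1_group <- unique(best$group[lab[best$maize_gene] == "SUB1"])
  if (length(sub1_group) == 0L) sub1_group <- 1L

  g1 <- best[best$group == sub1_group, c("sorghum_gene", "maize_gene", "ks")]
  g2 <- best[best$group == (3L - sub1_group), c("sorghum_gene", "maize_gene", "ks")]
  inner_join(
    rename(g1, sub1_gene = "maize_gene", ks1 = "ks"),
    rename(g2, sub2_gene = "maize_gene", ks2 = "ks"),
    by = "sorghum_gene"
  ) |>
    select("sub1_gene", "sub2_gene", "sorghum_gene", "ks1", "ks2") |>
    arrange(.data$sorghum_gene)
}

#' @export
print.bipartition <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<bipartition> %d blocks (%s scope)\n", nrow(x$blocks), x$scope))
  cat(sprintf("  group 1: %d blocks, %d anchors, %d genes\n",
              g$n_blocks1, g$n_anchors1, g$n_genes1))
  cat(sprintf("  group 2: %d blocks, %d anchors, %d genes\n",
              g$n_blocks2, g$n_anchors2, g$n_genes2))
  cat(sprintf("  orphans: %d blocks\n", g$n_orphans))
  invisible(x)
}

#' @rdname greedy_bipartition
#' @param x A `bipartition`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.bipartition <- function(x, ...) {
  as_tibble(x$blocks)
}

#' @rdname greedy_bipartition
#' @exportS3Method generics::glance
glance.bipartition <- function(x, ...) {
  a <- x$anchors
  ngenes <- function(g) length(unique(a$maize_gene[a$group %in% g]))
  tibble(
    n_blocks1 = sum(x$blocks$group %in% 1L),
    n_blocks2 = sum(x$blocks$group %in% 2L),
    n_orphans = sum(is.na(x$blocks$group)),
    n_anchors1 = sum(a$group %in% 1L),
    n_anchors2 = sum(a$group %in% 2L),
    n_genes1 = ngenes(1L),
    n_genes2 = ngenes(2L)
  )
}
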