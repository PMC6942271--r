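#' Read a syntenic anchor-block file
#'
#' Parses the tab-separated anchor-block dialect used throughout the package.
#' A line beginning with `#` opens a new block and carries
#' `block_id<TAB>maize_chrom<TAB>sorghum_chrom`; every following line until
#' the next header is one anchor:
#' `maize_gene<TAB>maize_chrom<TAB>maize_start<TAB>maize_end<TAB>sorghum_gene<TAB>sorghum_chrom<TAB>sorghum_order<TAB>ks`,
#' with `NA` marking an anchor whose synonymous substitution rate (Ks) could
#' not be estimated. Maize coordinates are 1-based inclusive base pairs;
#' `sorghum_order` is the 0-based gene-order index of the sorghum gene along
#' its chromosome.
#'
#' @param path Path to an anchor-block file (or a connection).
#' @return A tibble with one row per anchor and columns `block_id`,
#'   `maize_gene`, `maize_chrom`, `maize_start`, `maize_end`, `sorghum_gene`,
#'   `sorghum_chrom`, `sorghum_order`, `ks`. Blocks appear in file order.
#' @seealso [summarise_blocks()], [filter_blocks()], [greedy_bipartition()]
#' @export
read_anchor_blocks <- function(path) {
  lines <- readr::read_lines(path)
  keep <- nzchar(trimws(lines))
  lineno <- seq_along(lines)[keep]
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(empty_anchor_tbl())
  }
  is_header <- startsWith(lines, "#")
  if (!is_header[1L]) {
    abort(sprintf("line %d: anchor row before any block header", lineno[1L]))
  }

  hdr_fields <- strsplit(sub("^#\\s*", "", lines[is_header]), "\t", fixed = TRUE)
  bad_hdr <- which(lengths(hdr_fields) != 3L)
  if (length(bad_hdr) > 0L) {
    abort(sprintf(
      "line %d: block header must have 3 tab-separated fields (block_id, maize_chrom, sorghum_chrom)",
      lineno[is_header][bad_hdr[1L]]
    ))
  }
  block_idx <- cumsum(is_header)

  # a header immediately followed by another header (or end of file) has no anchors
  n_per_block <- tabulate(block_idx[!is_header], nbins = sum(is_header))
  if (any(n_per_block == 0L)) {
    abort(sprintf(
      "line %d: block header with zero anchor rows",
      lineno[is_header][which(n_per_block == 0L)[1L]]
    ))
  }

  afields <- strsplit(lines[!is_header], "\t", fixed = TRUE)
  alineno <- lineno[!is_header]
  bad <- which(lengths(afields) != 8L)
  if (length(bad) > 0L) {
    abort(sprintf("line %d: anchor row must have 8 tab-separated fields", alineno[bad[1L]]))
  }
  amat <- matrix(unlist(afields), ncol = 8L, byrow = TRUE)

  num <- function(col, what, allow_na = FALSE) {
    x <- suppressWarnings(as.numeric(amat[, col]))
    bad <- is.na(x) & !(allow_na & amat[, col] == "NA")
    if (any(bad)) {
      abort(sprintf("line %d: non-numeric %s '%s'", alineno[which(bad)[1L]], what, amat[which(bad)[1L], col]))
    }
    x
  }

  hdr <- do.call(rbind, hdr_fields)
  anchors <- tibble(
    block_id      = hdr[block_idx[!is_header], 1L],
    maize_gene    = amat[, 1L],
    maize_chrom   = amat[, 2L],
    maize_start   = num(3L, "maize_start"),
    maize_end     = num(4L, "maize_end"),
    sorghum_gene  = amat[, 5L],
    sorghum_chrom = amat[, 6L],
    sorghum_order = num(7L, "sorghum_order"),
    ks            = num(8L, "ks", allow_na = TRUE)
  )

  validate_anchors(anchors, alineno)
  hdr_chrom <- tibble(
    block_id = hdr[, 1L], h_maize_chrom = hdr[, 2L], h_sorghum_chrom = hdr[, 3L]
  )
  chk <- dplyr::left_join(anchors, hdr_chrom, by = "block_id",
                          relationship = "many-to-many")
  mismatch <- chk$maize_chrom != chk$h_maize_chrom | chk$sorghum_chrom != chk$h_sorghum_chrom
  if (any(mismatch)) {
    abort(sprintf(
      "line %d: anchor chromosomes disagree with block header '%s'",
      alineno[which(mismatch)[1L]], chk$block_id[which(mismatch)[1L]]
    ))
  }
  anchors
}

empty_anchor_tbl <- function() {
  tibble(
    block_id = character(), maize_gene = character(), maize_chrom = character(),
    maize_start = numeric(), maize_end = numeric(), sorghum_gene = character(),
    sorghum_chrom = character(), sorghum_order = numeric(), ks = numeric()
  )
}

validate_anchors <- function(anchors, lineno = NULL) {
  at <- function(i) if (is.null(lineno)) sprintf("anchor %d", i) else sprintf("line %d", lineno[i])
  bad <- which(anchors$maize_start > anchors$maize_end)
  if (length(bad) > 0L) abort(sprintf("%s: maize_start > maize_end", at(bad[1L])))
  bad <- which(anchors$sorghum_order < 0)
  if (length(bad) > 0L) abort(sprintf("%s: negative sorghum_order", at(bad[1L])))
  bad <- which(!is.na(anchors$ks) & anchors$ks < 0)
  if (length(bad) > 0L) abort(sprintf("%s: negative ks", at(bad[1L])))
  invisible(anchors)
}

#' Write anchors back to the anchor-block dialect
#'
#' @param anchors Anchor tibble as returned by [read_anchor_blocks()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_anchor_blocks <- function(anchors, path) {
  out <- character(0)
  for (bid in unique(anchors$block_id)) {
    b <- anchors[anchors$block_id == bid, ]
    out <- c(
      out,
      paste0("#", paste(bid, b$maize_chrom[1L], b$sorghum_chrom[1L], sep = "\t")),
      paste(b$maize_gene, b$maize_chrom, format_num(b$maize_start),
            format_num(b$maize_end), b$sorghum_gene, b$sorghum_chrom,
            format_num(b$sorghum_order),
            ifelse(is.na(b$ks), "NA", format_num(b$ks)), sep = "\t")
    )
  }
  readr::write_lines(out, path)
  invisible(path)
}

format_num <- function(x) format(x, scientific = FALSE, trim = TRUE, digits = 15)

#' Summarise anchors into per-block statistics
#'
#' Computes, per syntenic block, the anchor count, the arithmetic mean of the
#' Ks values that are present, and the closed span of sorghum gene-order
#' indices covered. Blocks whose anchors all lack a Ks value get `mean_ks =
#' NA`.
#'
#' @param anchors Anchor tibble from [read_anchor_blocks()].
#' @return A tibble with one row per block, in order of first appearance:
#'   `block_id`, `maize_chrom`, `sorghum_chrom`, `n_anchors`, `mean_ks`,
#'   `sorghum_min`, `sorghum_max`.
#' @export
summarise_blocks <- function(anchors) {
  anchors |>
    mutate(.ord = row_number()) |>
    group_by(.data$block_id) |>
    summarise(
      maize_chrom   = first(.data$maize_chrom),
      sorghum_chrom = first(.data$sorghum_chrom),
      n_anchors     = n(),
      mean_ks       = if (all(is.na(.data$ks))) NA_real_ else mean(.data$ks, na.rm = TRUE),
      sorghum_min   = min(.data$sorghum_order),
      sorghum_max   = max(.data$sorghum_order),
      .ord          = min(.data$.ord)
    ) |>
    arrange(.data$.ord) |>
    select(-".ord")
}

#' Filter syntenic blocks by size and mean Ks
#'
#' Removes small blocks and blocks whose average Ks indicates an age other
#' than the whole-genome duplication of interest. Defaults follow the usual
#' reading for a maize/sorghum comparison: blocks with fewer than 12 anchored
#' genes are dropped, and blocks with mean Ks strictly above 1.0 are dropped
#' (a block sitting exactly on the cutoff is kept). Both boundaries are
#' configurable.
#'
#' @param anchors Anchor tibble.
#' @param min_anchors Minimum anchor count for a block to be kept (inclusive).
#' @param max_mean_ks Maximum block-average Ks for a block to be kept
#'   (inclusive by default; see `ks_inclusive`).
#' @param ks_inclusive If `TRUE` (default) a block with `mean_ks ==
#'   max_mean_ks` is kept; if `FALSE` the boundary is excluded too.
#' @param drop_missing_ks If `TRUE`, blocks whose anchors all lack Ks are
#'   dropped; by default they are kept and a message reports how many.
#' @return The filtered anchor tibble, block order preserved.
#' @export
filter_blocks <- function(anchors, min_anchors = 12L, max_mean_ks = 1.0,
                          ks_inclusive = TRUE, drop_missing_ks = FALSE) {
  stopifnot(min_anchors > 0, max_mean_ks > 0)
  blocks <- summarise_blocks(anchors)
  ks_ok <- if (ks_inclusive) blocks$mean_ks <= max_mean_ks else blocks$mean_ks < max_mean_ks
  missing_ks <- is.na(blocks$mean_ks)
  if (any(missing_ks) && !drop_missing_ks) {
    inform(sprintf("%d block(s) with no Ks on any anchor kept unchecked against the Ks filter",
                   sum(missing_ks)))
  }
  ks_ok[missing_ks] <- !drop_missing_ks
  keep <- blocks$block_id[blocks$n_anchors >= min_anchors & ks_ok]
  anchors[anchors$block_id %in% keep, ]
}
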