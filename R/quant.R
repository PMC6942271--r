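#' Read a genes-by-samples quantification matrix
#'
#' Reads a TSV whose first column holds gene ids (header `gene_id`) and whose
#' remaining columns hold one tissue sample each, carrying non-negative FPKM
#' (RNA-seq expression) or dNSAF (label-free protein abundance) values.
#' Empty cells become `NA` (absent measurement, distinct from 0 = nothing
#' detected) and are excluded from downstream means and correlations.
#'
#' @param path TSV path or connection.
#' @param kind `"FPKM"` or `"dNSAF"`; recorded in the `kind` attribute.
#' @return A tibble, genes in file order, with a `kind` attribute.
#' @export
read_quant_matrix <- function(path, kind = c("FPKM", "dNSAF")) {
  kind <- match.arg(kind)
  m <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), .default = readr::col_double()
  ))
  validate_quant_matrix(m)
  attr(m, "kind") <- kind
  m
}

validate_quant_matrix <- function(m) {
  if (names(m)[1L] != "gene_id") abort("first column must be 'gene_id'")
  if (anyDuplicated(m$gene_id)) {
    abort(sprintf("duplicate gene id '%s'", m$gene_id[duplicated(m$gene_id)][1L]))
  }
  if (anyDuplicated(names(m))) abort("duplicate sample column names")
  vals <- as.matrix(m[-1L])
  neg <- which(vals < 0, arr.ind = TRUE)
  if (nrow(neg) > 0L) {
    abort(sprintf("negative value for gene '%s', sample '%s'",
                  m$gene_id[neg[1L, 1L]], colnames(vals)[neg[1L, 2L]]))
  }
  invisible(m)
}

#' Write a quantification matrix as TSV
#'
#' @param m Quantification tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_quant_matrix <- function(m, path) {
  readr::write_tsv(m, path)
  invisible(path)
}

#' Average biological replicates into per-tissue columns
#'
#' Collapses sample columns to one column per tissue by the unweighted
#' arithmetic mean of the non-missing replicate values; a tissue whose
#' replicates are all missing for a gene stays missing.
#'
#' @param m Quantification tibble (genes x samples).
#' @param replicate_map Data frame with columns `sample`, `tissue` covering
#'   every sample column of `m`.
#' @return A tibble genes x tissues; tissue columns follow first appearance
#'   in `replicate_map`.
#' @export
average_replicates <- function(m, replicate_map) {
  samples <- setdiff(names(m), "gene_id")
  unmapped <- setdiff(samples, replicate_map$sample)
  if (length(unmapped) > 0L) {
    abort(sprintf("sample column '%s' missing from replicate map", unmapped[1L]))
  }
  kind <- attr(m, "kind")
  tissues <- unique(replicate_map$tissue)
  out <- tibble(gene_id = m$gene_id)
  for (t in tissues) {
    cols <- intersect(replicate_map$sample[replicate_map$tissue == t], samples)
    if (length(cols) == 0L) next
    sub <- as.matrix(m[cols])
    means <- rowMeans(sub, na.rm = TRUE)
    means[!is.finite(means)] <- NA_real_
    out[[t]] <- means
  }
  attr(out, "kind") <- kind
  out
}

#' Read a replicate map (`sample<TAB>tissue`)
#' @param path TSV path with header `sample`, `tissue`.
#' @return A tibble.
#' @export
read_replicate_map <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
}

#' Read a gene-model id mapping table
#'
#' Format: `old_ids<TAB>new_ids<TAB>relation` with comma-separated id lists
#' and relation in `ONE_TO_ONE`, `SPLIT`, `MERGE`.
#'
#' @param path TSV path.
#' @return A tibble `old_ids`, `new_ids`, `relation`.
#' @export
read_id_mapping <- function(path) {
  map <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  validate_id_mapping(map)
}

validate_id_mapping <- function(map) {
  stopifnot(all(c("old_ids", "new_ids", "relation") %in% names(map)))
  bad <- !map$relation %in% c("ONE_TO_ONE", "SPLIT", "MERGE")
  if (any(bad)) abort(sprintf("unknown relation '%s'", map$relation[bad][1L]))
  n_old <- lengths(strsplit(map$old_ids, ",", fixed = TRUE))
  n_new <- lengths(strsplit(map$new_ids, ",", fixed = TRUE))
  ok <- (map$relation == "ONE_TO_ONE" & n_old == 1L & n_new == 1L) |
    (map$relation == "SPLIT" & n_old == 1L & n_new >= 2L) |
    (map$relation == "MERGE" & n_old >= 2L & n_new == 1L)
  if (any(!ok)) {
    abort(sprintf("record %d: id counts inconsistent with relation '%s'",
                  which(!ok)[1L], map$relation[!ok][1L]))
  }
  map
}

#' Project a quantification matrix across assembly versions
#'
#' Carries per-tissue measurements from an old gene-model set to a new one
#' using split/merge relations: a gene model that split keeps its value on
#' every descendant unchanged; gene models that merged contribute the
#' per-tissue sum to the merged model; one-to-one models copy. Genes of `m`
#' not covered by any mapping record are dropped (their count is reported).
#'
#' @param m Quantification tibble keyed by old gene ids.
#' @param mapping Mapping tibble as from [read_id_mapping()].
#' @return A tibble keyed by new gene ids, one row per new gene, ordered by
#'   first appearance in the mapping.
#' @export
project_ids <- function(m, mapping) {
  mapping <- validate_id_mapping(mapping)
  old_sets <- strsplit(mapping$old_ids, ",", fixed = TRUE)
  new_sets <- strsplit(mapping$new_ids, ",", fixed = TRUE)
  all_new <- unlist(new_sets)
  if (anyDuplicated(all_new)) {
    abort(sprintf("new gene '%s' produced by more than one mapping record",
                  all_new[duplicated(all_new)][1L]))
  }
  covered <- unlist(old_sets)
  n_uncovered <- sum(!m$gene_id %in% covered)
  if (n_uncovered > 0L) {
    inform(sprintf("%d gene(s) not covered by the id mapping were dropped", n_uncovered))
  }
  vals <- as.matrix(m[-1L])
  rownames(vals) <- m$gene_id

  rows <- purrr::map2(old_sets, new_sets, function(old, new) {
    present <- old[old %in% m$gene_id]
    if (length(present) == 0L) return(NULL)
    if (length(present) == 1L) {
      v <- vals[present, , drop = TRUE]
    } else {
      sub <- vals[present, , drop = FALSE]
      v <- colSums(sub, na.rm = TRUE)
      v[colSums(!is.na(sub)) == 0L] <- NA_real_
    }
    cbind(tibble(gene_id = new), as_tibble(as.list(v)))
  })
  out <- as_tibble(dplyr::bind_rows(rows))
  attr(out, "kind") <- attr(m, "kind")
  out
}
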