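# build a one-block anchor tibble; sorghum genes s<order+1> on one chromosome
anchor_block <- function(block_id, maize_genes, sorghum_orders,
                         maize_chrom = "chr1", sorghum_chrom = "S1",
                         ks = rep(0.5, length(maize_genes)),
                         sorghum_genes = sprintf("s%d", sorghum_orders + 1L)) {
  tibble::tibble(
    block_id = block_id,
    maize_gene = maize_genes,
    maize_chrom = maize_chrom,
    maize_start = 1 + 10000 * seq_along(maize_genes),
    maize_end = 3000 + 10000 * seq_along(maize_genes),
    sorghum_gene = sorghum_genes,
    sorghum_chrom = sorghum_chrom,
    sorghum_order = sorghum_orders,
    ks = ks
  )
}

# n anchors covering sorghum orders from..from+n-1
simple_block <- function(block_id, n, from = 0L, prefix = block_id, ...) {
  anchor_block(block_id, sprintf("%s_m%d", prefix, seq_len(n)),
               from + seq_len(n) - 1L, ...)
}

anchor_file_of <- function(anchors) {
  f <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  write_anchor_blocks(anchors, f)
  f
}

# wide quant tibble from a named list of per-gene value vectors
quant_of <- function(values, tissues = NULL, kind = "FPKM") {
  n <- length(values[[1L]])
  if (is.null(tissues)) tissues <- sprintf("t%d", seq_len(n))
  m <- tibble::as_tibble(do.call(rbind, values), .name_repair = ~tissues)
  out <- dplyr::bind_cols(tibble::tibble(gene_id = names(values)), m)
  attr(out, "kind") <- kind
  out
}

# profiles for one synthetic pair universe given lists of v1/v2 vectors
profiles_of <- function(v1s, v2s, kind = "FPKM") {
  n_pairs <- length(v1s)
  ntis <- length(v1s[[1L]])
  purrr::map_dfr(seq_len(n_pairs), function(i) {
    tibble::tibble(
      sub1_gene = sprintf("a%03d", i), sub2_gene = sprintf("b%03d", i),
      tissue = sprintf("t%d", seq_len(ntis)),
      v1 = v1s[[i]], v2 = v2s[[i]]
    )
  })
}
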