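# shared synthetic fixtures used by the recruitment and acceptance tests

# small synthetic reference: n forward-strand genes of `len` bp CDS with
# short intergenic gaps, returning contig + genes
tiny_reference <- function(n = 6L, len = 450L, contig_id = "ref1") {
  lay <- layout_genes(contig_id, rep(len, n), rep("+", n),
                      intergenic = c(20L, 20L))
  list(contig = contig_table(contig_id, lay$sequence), genes = lay$genes)
}

# substitution-only reads tiling a sequence at fixed stride
tile_reads <- function(seqc, read_len = 400L, stride = 150L) {
  starts <- seq(1L, nchar(seqc) - read_len + 1L, by = stride)
  reads <- substring(seqc, starts, starts + read_len - 1L)
  names(reads) <- sprintf("t%04d", seq_along(reads))
  reads
}

# run the per-contig region scan over a pooled gene table
scan_all_contigs <- function(genes, ...) {
  calls <- lapply(split(genes, genes$contig_id), scan_unknown_regions, ...)
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}

# Rand index between two partitions given as membership vectors
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  mean(same_a == same_b)
}
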