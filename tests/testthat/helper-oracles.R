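# Independent oracles used by the tests. These deliberately re-derive
# results by brute force or via a different library code path than the
# package implementation.

# Brute-force region scanner: enumerate EVERY window of >= min_region_genes
# consecutive genes, keep windows meeting both architecture criteria, and
# merge overlapping/adjacent qualifying windows into maximal regions.
oracle_scan_regions <- function(genes, min_region_genes = 8L,
                                min_unchar = 0.5, min_strand = 0.8) {
  g <- genes[order(genes$start, genes$end), , drop = FALSE]
  n <- nrow(g)
  qual <- NULL
  if (n >= min_region_genes) {
    for (i in seq_len(n - min_region_genes + 1L)) {
      for (j in seq.int(i + min_region_genes - 1L, n)) {
        unchar <- mean(!g$characterized[i:j])
        p <- mean(g$strand[i:j] == "+")
        if (unchar >= min_unchar && max(p, 1 - p) >= min_strand) {
          qual <- rbind(qual, c(i, j))
        }
      }
    }
  }
  if (is.null(qual)) {
    return(data.frame(gene_from = integer(), gene_to = integer()))
  }
  qual <- qual[order(qual[, 1L], qual[, 2L]), , drop = FALSE]
  merged <- qual[1L, , drop = FALSE]
  if (nrow(qual) > 1L) {
    for (r in 2:nrow(qual)) {
      last <- nrow(merged)
      if (qual[r, 1L] <= merged[last, 2L]) {
        merged[last, 2L] <- max(merged[last, 2L], qual[r, 2L])
      } else {
        merged <- rbind(merged, qual[r, , drop = FALSE])
      }
    }
  }
  data.frame(gene_from = as.integer(merged[, 1L]),
             gene_to = as.integer(merged[, 2L]))
}

# Exhaustive two-sided Fisher p-value by direct enumeration of all tables
# with the observed margins, using choose() only (no dhyper).
oracle_fisher_2x2 <- function(tb) {
  a <- tb[1L, 1L]
  r1 <- sum(tb[1L, ]); c1 <- sum(tb[, 1L]); N <- sum(tb)
  support <- max(0L, c1 - (N - r1)):min(r1, c1)
  probs <- vapply(support, function(x) {
    exp(lchoose(r1, x) + lchoose(N - r1, c1 - x) - lchoose(N, c1))
  }, 0)
  p_obs <- probs[match(a, support)]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Forced full-length protein alignment identity oracle: global alignment via
# Biostrings directly (independent of the package's local-alignment path).
oracle_global_identity <- function(p1, p2) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(p1), Biostrings::AAString(p2),
    substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1,
    type = "global")
  qa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  match <- qa == sa & qa != "-" & qa != "X"
  100 * sum(match) / length(qa)
}

# A tiny deterministic gene table for worked examples.
make_gene_row <- function(contig_id, start, end, strand, characterized,
                          id = NULL) {
  gene_table(
    id = if (is.null(id)) sprintf("%s_%d", contig_id, start) else id,
    contig_id = contig_id, start = as.integer(start), end = as.integer(end),
    strand = strand, characterized = characterized
  )
}

# Random gene architecture on one contig, for property tests.
random_gene_arch <- function(n, contig_id = "c1", p_char = 0.5,
                             p_plus = 0.5) {
  starts <- cumsum(c(1L, rep(300L, n - 1L)))
  gene_table(
    id = sprintf("%s_g%03d", contig_id, seq_len(n)),
    contig_id = contig_id, start = starts, end = starts + 299L,
    strand = ifelse(runif(n) < p_plus, "+", "-"),
    characterized = runif(n) < p_char
  )
}
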