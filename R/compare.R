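#' Fraction of genes shared between two genomes
#'
#' Computes the two directed fractions (genes of A with a qualifying protein
#' hit in B, over |A|; and vice versa) and combines them. Qualifying hits use
#' E-value <= 1e-3 and bit score >= 50. The genus criterion for tailed
#' phages (40% of genes shared) is applied to this value by
#' [cluster_genera()].
#'
#' @param genesA,genesB gene tables of the two genomes.
#' @param protein_hits gene-vs-gene hit table (either direction).
#' @param mode `"mean"` (default) or `"min_denominator"` (the directed
#'   fraction with the larger genome in the denominator is the smaller one;
#'   `min_denominator` returns the fraction over the smaller gene count).
#' @param max_evalue,min_bit hit thresholds.
#' @return shared-gene fraction in `[0, 1]`.
#' @export
shared_gene_fraction <- function(genesA, genesB, protein_hits,
                                 mode = c("mean", "min_denominator"),
                                 max_evalue = 1e-3, min_bit = 50) {
  mode <- match.arg(mode)
  if (nrow(genesA) == 0L || nrow(genesB) == 0L) stop("empty genome")
  h <- qualify_hits(protein_hits, max_evalue, min_bit)
  pairs <- rbind(data.frame(g1 = h$query_id, g2 = h$subject_id),
                 data.frame(g1 = h$subject_id, g2 = h$query_id))
  a_hit <- unique(pairs$g1[pairs$g1 %in% genesA$id & pairs$g2 %in% genesB$id])
  b_hit <- unique(pairs$g1[pairs$g1 %in% genesB$id & pairs$g2 %in% genesA$id])
  f_ab <- length(a_hit) / nrow(genesA)
  f_ba <- length(b_hit) / nrow(genesB)
  if (mode == "mean") mean(c(f_ab, f_ba)) else max(f_ab, f_ba)
}

#' Cluster phage genomes into genera by shared gene content
#'
#' Single-linkage connected components over the graph whose edges join
#' genome pairs sharing at least `threshold` of their genes (genomes sharing
#' less than 40% of their genes belong to distinct genera; equality joins).
#'
#' @param ids genome identifiers (matrix row order).
#' @param fraction_matrix symmetric matrix of shared-gene fractions.
#' @param threshold genus threshold (default 0.40, inclusive).
#' @return list of clusters; each a list with `members` and the submatrix
#'   `pairwise_shared_fraction`.
#' @export
cluster_genera <- function(ids, fraction_matrix, threshold = 0.40) {
  stopifnot(nrow(fraction_matrix) == length(ids),
            ncol(fraction_matrix) == length(ids))
  if (!isTRUE(all.equal(fraction_matrix, t(fraction_matrix)))) {
    stop("fraction matrix must be symmetric")
  }
  adj <- fraction_matrix >= threshold
  diag(adj) <- TRUE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  lapply(sort(unique(comp)), function(cc) {
    sel <- which(comp == cc)
    m <- fraction_matrix[sel, sel, drop = FALSE]
    diag(m) <- 1
    dimnames(m) <- list(ids[sel], ids[sel])
    list(members = ids[sel], pairwise_shared_fraction = m)
  })
}

# best-rotation global identity between two (possibly circular) sequences:
# anchor the first k-mer of `a` in the doubled `b` (both strands) to pick
# candidate rotations, then align end to end
rotation_identity <- function(a, b, circular = TRUE, k = 20L) {
  if (!circular) {
    return(max(nucleotide_identity(a, b), nucleotide_identity(a, revcomp(b))))
  }
  nb <- nchar(b)
  best <- 0
  for (bs in c(b, revcomp(b))) {
    doubled <- paste0(bs, bs)
    if (a == bs) return(100)
    # exact substring => pure rotation
    if (nchar(a) == nb &&
        length(Biostrings::matchPattern(a, Biostrings::DNAString(doubled))) > 0L) {
      return(100)
    }
    probe <- substr(a, 1L, min(k, nchar(a)))
    m <- Biostrings::matchPattern(probe, Biostrings::DNAString(doubled),
                                  max.mismatch = 2L)
    offs <- IRanges::start(m)
    offs <- unique(((offs - 1L) %% nb) + 1L)
    if (length(offs) == 0L) offs <- 1L
    for (off in offs) {
      rot <- paste0(substr(bs, off, nb), substr(bs, 1L, off - 1L))
      best <- max(best, nucleotide_identity(a, rot))
      if (best == 100) return(100)
    }
  }
  best
}

#' Clonality of a set of genomes
#'
#' Computes all pairwise global nucleotide identities, normalizing circular
#' genomes over rotation and strand (best rotation found by exact anchoring
#' in the doubled sequence). The set is clonal when the minimum pairwise
#' identity is 100.
#'
#' @param sequences named character vector of >= 2 genome sequences.
#' @param circular are the genomes circular (default `TRUE`)?
#' @return list with `pairwise` (`data.frame`: `id1`, `id2`, `identity`),
#'   `min_identity` and `clonal`.
#' @export
clonality <- function(sequences, circular = TRUE) {
  stopifnot(length(sequences) >= 2L, !is.null(names(sequences)))
  ids <- names(sequences)
  pairs <- utils::combn(length(sequences), 2L)
  pw <- data.frame(
    id1 = ids[pairs[1L, ]], id2 = ids[pairs[2L, ]],
    identity = vapply(seq_len(ncol(pairs)), function(i) {
      rotation_identity(sequences[[pairs[1L, i]]], sequences[[pairs[2L, i]]],
                        circular = circular)
    }, 0),
    stringsAsFactors = FALSE
  )
  list(pairwise = pw, min_identity = min(pw$identity),
       clonal = min(pw$identity) == 100)
}

#' Co-infection contingency table
#'
#' Builds the 2x2 table of SAGs infected by viral group A and/or group B
#' over a SAG subset: `a` both, `b` A only, `c` B only, `d` neither.
#'
#' @param per_sag_calls `data.frame` with columns `sag_id` and `group` (one
#'   row per detected infection).
#' @param groupA,groupB viral group labels (e.g. family names).
#' @param sag_subset SAG ids defining the table's universe.
#' @return a 2x2 integer matrix with informative dimnames.
#' @export
cooccurrence_table <- function(per_sag_calls, groupA, groupB, sag_subset) {
  if (length(sag_subset) == 0L) stop("empty SAG subset")
  known <- unique(per_sag_calls$group)
  for (g in c(groupA, groupB)) {
    if (!g %in% known) stop("unknown group label: ", g)
  }
  hasA <- sag_subset %in% per_sag_calls$sag_id[per_sag_calls$group == groupA]
  hasB <- sag_subset %in% per_sag_calls$sag_id[per_sag_calls$group == groupB]
  matrix(c(sum(hasA & hasB), sum(hasA & !hasB),
           sum(!hasA & hasB), sum(!hasA & !hasB)),
         nrow = 2L, byrow = TRUE,
         dimnames = list(c(groupA, paste0("no_", groupA)),
                         c(groupB, paste0("no_", groupB))))
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value by hypergeometric enumeration: with margins
#' fixed, the probabilities of all tables whose probability does not exceed
#' that of the observed table (up to a relative tolerance of 1e-7) are
#' summed.
#'
#' @param table 2x2 matrix of non-negative integer counts
#'   (rows: infected by virus A / not; columns: infected by virus B / not).
#' @return the two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  stopifnot(all(dim(table) == c(2L, 2L)))
  x <- as.vector(t(table))  # a, b, c, d
  if (any(x < 0) || any(x != round(x))) stop("counts must be non-negative integers")
  n <- sum(x)
  if (n == 0L) stop("all-zero table")
  a <- x[1L]; b <- x[2L]; c_ <- x[3L]; d <- x[4L]
  m <- a + b          # row 1 total (A infected)
  k <- a + c_         # column 1 total (B infected)
  lo <- max(0L, k - (n - m))
  hi <- min(k, m)
  support <- lo:hi
  p <- dhyper(support, m, n - m, k)
  p_obs <- p[match(a, support)]
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}
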