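# ---- exact-match anchoring (mummer-like) -----------------------------------

# k-mer start positions of `seq`, grouped by k-mer
kmer_index <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(list())
  starts <- 1:(n - k + 1L)
  split(starts, substring(seq, starts, starts + k - 1L))
}

# exact-match anchors of one query against an indexed reference: seeds at
# `stride` spacing merged along diagonals into exact runs >= k; returns a
# list of parallel integer vectors (q_start, q_end, s_start, s_end) or NULL
seed_anchors <- function(query, index, k, stride) {
  nq <- nchar(query)
  if (nq < k) return(NULL)
  qs <- unique(c(seq.int(1L, nq - k + 1L, by = stride), nq - k + 1L))
  km <- substring(query, qs, qs + k - 1L)
  hit <- index[km]
  nh <- lengths(hit)
  if (sum(nh) == 0L) return(NULL)
  qpos <- rep.int(qs, nh)
  rpos <- unlist(hit, use.names = FALSE)
  diag <- rpos - qpos
  o <- order(diag, qpos)
  qpos <- qpos[o]; diag <- diag[o]
  # merge seeds on the same diagonal whose spans touch/overlap
  new_run <- c(TRUE, diff(diag) != 0L | diff(qpos) > k)
  st <- which(new_run)
  en <- c(st[-1L] - 1L, length(qpos))
  q1 <- qpos[st]
  q2 <- qpos[en] + k - 1L
  d <- diag[st]
  list(q_start = q1, q_end = q2, s_start = q1 + d, s_end = q2 + d)
}

# chain co-linear anchors (gap <= max_gap on both sequences) into clusters;
# returns the anchors sorted by q_start plus a cluster id vector
chain_anchors <- function(anc, max_gap) {
  o <- order(anc$q_start)
  q1 <- anc$q_start[o]; q2 <- anc$q_end[o]
  s1 <- anc$s_start[o]; s2 <- anc$s_end[o]
  n <- length(q1)
  cl <- if (n == 1L) 1L else {
    qgap <- q1[-1L] - q2[-n] - 1L
    sgap <- s1[-1L] - s2[-n] - 1L
    same <- qgap <= max_gap & sgap <= max_gap & s1[-1L] > s1[-n]
    cumsum(c(TRUE, !same))
  }
  list(q_start = q1, q_end = q2, s_start = s1, s_end = s2, cluster = cl)
}

total_interval_length <- function(from, to) {
  ivs <- merge_intervals(cbind(from, to))
  sum(ivs[, 2L] - ivs[, 1L] + 1L)
}

#' Map query sequences onto contigs by chained exact matches
#'
#' A mummer-style nucleotide mapper: exact-match anchors (>= `k` bp) are
#' chained into clusters when co-linear with gaps of at most `max_gap` bp on
#' both sequences; clusters with total anchor length below `min_cluster` are
#' discarded; per-cluster identity comes from a gap-filled end-to-end
#' alignment of the cluster spans (clusters whose anchors tile the whole
#' span are exact, identity 100). Both strands are searched.
#'
#' @param queries named character vector of nucleotide sequences (reads or
#'   region sequences).
#' @param contigs contig table (the reference set).
#' @param min_cluster minimum total anchor length per cluster (default 100).
#' @param max_gap maximum gap between two matches in a cluster (default 500).
#' @param k anchor seed length (default 20).
#' @param stride seed sampling stride along the query (default 10).
#' @return `data.frame` of accepted clusters: `query_id`, `contig_id`,
#'   `strand`, `q_start`, `q_end`, `s_start`, `s_end`, `anchor_len`,
#'   `identity`.
#' @export
map_nucleotide <- function(queries, contigs, min_cluster = 100L,
                           max_gap = 500L, k = 20L, stride = 10L) {
  stopifnot(!is.null(names(queries)))
  idx <- lapply(contigs$sequence, kmer_index, k = k)
  rcq <- if (length(queries) > 0L) revcomp(queries) else queries
  # one accumulator slot per (query, strand, contig) combination; each holds
  # column vectors over that call's accepted clusters
  acc <- vector("list", length(queries) * 2L * nrow(contigs))
  slot <- 0L
  for (qi in seq_along(queries)) {
    qname <- names(queries)[qi]
    for (str in c("+", "-")) {
      qseq <- if (str == "+") queries[[qi]] else rcq[[qi]]
      nq <- nchar(qseq)
      for (ci in seq_len(nrow(contigs))) {
        slot <- slot + 1L
        anc <- seed_anchors(qseq, idx[[ci]], k, stride)
        if (is.null(anc)) next
        ch <- chain_anchors(anc, max_gap)
        ucl <- unique(ch$cluster)
        q1 <- q2 <- s1 <- s2 <- alens <- integer(length(ucl))
        idents <- numeric(length(ucl))
        keep <- logical(length(ucl))
        for (u in seq_along(ucl)) {
          sel <- ch$cluster == ucl[u]
          alen <- total_interval_length(ch$q_start[sel], ch$q_end[sel])
          if (alen < min_cluster) next
          keep[u] <- TRUE
          qs <- min(ch$q_start[sel]); qe <- max(ch$q_end[sel])
          ss <- min(ch$s_start[sel]); se <- max(ch$s_end[sel])
          idents[u] <- if (alen == qe - qs + 1L && alen == se - ss + 1L) {
            100
          } else {
            nucleotide_identity(substr(qseq, qs, qe),
                                substr(contigs$sequence[ci], ss, se),
                                type = "global")
          }
          # report query coordinates on the original (+) orientation
          if (str == "+") {
            q1[u] <- qs; q2[u] <- qe
          } else {
            q1[u] <- nq - qe + 1L; q2[u] <- nq - qs + 1L
          }
          s1[u] <- ss; s2[u] <- se; alens[u] <- alen
        }
        if (!any(keep)) next
        acc[[slot]] <- list(
          query_id = rep.int(qname, sum(keep)),
          contig_id = rep.int(contigs$id[ci], sum(keep)),
          strand = rep.int(str, sum(keep)),
          q_start = q1[keep], q_end = q2[keep],
          s_start = s1[keep], s_end = s2[keep],
          anchor_len = alens[keep], identity = idents[keep]
        )
      }
    }
  }
  acc <- acc[!vapply(acc, is.null, TRUE)]
  col <- function(f, mode) {
    if (length(acc) == 0L) return(vector(mode, 0L))
    unlist(lapply(acc, `[[`, f), use.names = FALSE)
  }
  data.frame(query_id = col("query_id", "character"),
             contig_id = col("contig_id", "character"),
             strand = col("strand", "character"),
             q_start = col("q_start", "integer"),
             q_end = col("q_end", "integer"),
             s_start = col("s_start", "integer"),
             s_end = col("s_end", "integer"),
             anchor_len = col("anchor_len", "integer"),
             identity = col("identity", "numeric"),
             stringsAsFactors = FALSE)
}

# ---- recruitment profiles ---------------------------------------------------

new_recruitment_profile <- function(reference_id, metagenome_id, mode,
                                    per_gene_best_identity,
                                    gene_covered_fraction = NULL,
                                    cluster_ani = NA_real_,
                                    recruited_bases, coverage,
                                    reference_length) {
  structure(list(
    reference_id = reference_id, metagenome_id = metagenome_id, mode = mode,
    per_gene_best_identity = per_gene_best_identity,
    gene_covered_fraction = gene_covered_fraction,
    cluster_ani = cluster_ani,
    recruited_bases = recruited_bases, coverage = coverage,
    reference_length = reference_length
  ), class = "recruitment_profile")
}

#' @export
print.recruitment_profile <- function(x, ...) {
  det <- sum(!is.na(x$per_gene_best_identity))
  cat(sprintf(
    "<recruitment_profile> %s vs %s (%s)\n  genes detected: %d/%d; recruited bases: %d\n",
    x$reference_id, x$metagenome_id, x$mode, det,
    length(x$per_gene_best_identity), x$recruited_bases))
  if (!is.na(x$cluster_ani)) cat(sprintf("  ANI: %.2f\n", x$cluster_ani))
  invisible(x)
}

# six-frame translation of a nucleotide read, split at stops into peptides
six_frame_peptides <- function(read, min_peptide_aa = 15L) {
  out <- character(0)
  for (strand in c("f", "r")) {
    s <- if (strand == "f") read else revcomp(read)
    for (off in 0:2) {
      len <- nchar(s) - off
      len <- len - len %% 3L
      if (len < 3L) next
      aa <- translate_dna(substr(s, off + 1L, off + len),
                          allow_internal_stop = TRUE)
      segs <- strsplit(aa, "*", fixed = TRUE)[[1L]]
      segs <- segs[nchar(segs) >= min_peptide_aa]
      if (length(segs) > 0L) {
        names(segs) <- paste0(strand, off, "s", seq_along(segs))
        out <- c(out, segs)
      }
    }
  }
  out
}

#' Recruit metagenome sequences to reference genes at the protein level
#'
#' Nucleotide reads are translated in all six frames, split at stop codons,
#' and the resulting peptides aligned against the reference proteins;
#' predicted proteins are aligned directly. Hits qualify at E-value <=
#' `max_evalue` and bit score >= `min_bit`. Each read is assigned to at most
#' one reference gene (best bit score; ties broken by lowest gene
#' coordinate); recruited bases sum the nucleotide lengths of assigned
#' reads; each gene's identity is the best identity among its assigned
#' reads' hits.
#'
#' @param sequences named character vector: nucleotide reads
#'   (`input = "nucleotide"`) or predicted proteins (`input = "protein"`).
#' @param reference_genes gene table of one reference contig, with proteins.
#' @param reference_length reference length in bp (for the coverage vector);
#'   default: max gene end.
#' @param metagenome_id label for the profile.
#' @param input sequence type.
#' @param max_evalue,min_bit hit acceptance thresholds.
#' @param min_peptide_aa shortest translated segment kept.
#' @param seed_k exact-seed prefilter passed to [align_protein_sets()].
#' @return a `recruitment_profile`.
#' @export
recruit_protein <- function(sequences, reference_genes,
                            reference_length = NULL,
                            metagenome_id = "metagenome",
                            input = c("nucleotide", "protein"),
                            max_evalue = 1e-3, min_bit = 50,
                            min_peptide_aa = 15L, seed_k = 4L) {
  input <- match.arg(input)
  if (nrow(reference_genes) == 0L) stop("empty reference gene set")
  reference_genes <- order_genes(reference_genes)
  if (is.null(reference_length)) reference_length <- max(reference_genes$end)
  gene_ids <- reference_genes$id
  best_ident <- setNames(rep(NA_real_, length(gene_ids)), gene_ids)
  coverage <- integer(reference_length)
  recruited <- 0L
  prof <- function() new_recruitment_profile(
    reference_id = reference_genes$contig_id[1L],
    metagenome_id = metagenome_id, mode = "protein",
    per_gene_best_identity = best_ident, recruited_bases = recruited,
    coverage = setNames(list(coverage), reference_genes$contig_id[1L]),
    reference_length = reference_length
  )
  if (length(sequences) == 0L) return(prof())
  if (input == "nucleotide") {
    peps <- lapply(sequences, six_frame_peptides,
                   min_peptide_aa = min_peptide_aa)
    read_of <- rep(names(sequences), lengths(peps))
    queries <- unlist(unname(peps))
    if (length(queries) == 0L) return(prof())
    names(queries) <- paste0("pep", seq_along(queries))
    pep2read <- setNames(read_of, names(queries))
    read_len <- setNames(nchar(sequences), names(sequences))
  } else {
    queries <- sequences
    pep2read <- setNames(names(sequences), names(sequences))
    read_len <- setNames(3L * nchar(sequences), names(sequences))
  }
  refs <- setNames(reference_genes$protein, gene_ids)
  hits <- align_protein_sets(queries, refs, seed_k = seed_k,
                             min_bit = min_bit, max_evalue = max_evalue)
  if (nrow(hits) == 0L) return(prof())
  hits$read <- pep2read[hits$query_id]
  gene_start <- setNames(reference_genes$start, gene_ids)
  # best hit per read: highest bit, ties -> lowest gene start coordinate
  hits <- hits[order(hits$read, -hits$bit_score,
                     gene_start[hits$subject_id]), , drop = FALSE]
  best_gene <- hits[!duplicated(hits$read), c("read", "subject_id")]
  assigned <- merge(hits, best_gene, by = c("read", "subject_id"))
  recruited <- sum(read_len[best_gene$read])
  for (g in unique(assigned$subject_id)) {
    hh <- assigned[assigned$subject_id == g, , drop = FALSE]
    best_ident[[g]] <- max(hh$identity)
    gi <- match(g, gene_ids)
    for (r in seq_len(nrow(hh))) {
      if (reference_genes$strand[gi] == "+") {
        from <- reference_genes$start[gi] + 3L * (hh$s_start[r] - 1L)
        to <- min(reference_length, reference_genes$start[gi] + 3L * hh$s_end[r] - 1L)
      } else {
        to <- reference_genes$end[gi] - 3L * (hh$s_start[r] - 1L)
        from <- max(1L, reference_genes$end[gi] - 3L * hh$s_end[r] + 1L)
      }
      coverage[from:to] <- coverage[from:to] + 1L
    }
  }
  prof()
}

#' Recruit metagenome reads to a microbial contig set at the nucleotide level
#'
#' Maps reads onto the non-viral contigs of a SAG with [map_nucleotide()]
#' (minimum cluster length 100, maximum within-cluster gap 500 by default),
#' keeps each read's best cluster, and summarizes per-gene coverage (a gene
#' counts as covered when at least half its span lies under accepted
#' clusters) and the length-weighted mean cluster identity (ANI).
#'
#' @param reads named character vector of nucleotide reads.
#' @param contigs microbial contig table (the host reference set).
#' @param genes gene table on those contigs.
#' @param metagenome_id label for the profile.
#' @inheritParams map_nucleotide
#' @return a `recruitment_profile` (mode `"nucleotide"`).
#' @export
recruit_nucleotide <- function(reads, contigs, genes,
                               min_cluster = 100L, max_gap = 500L,
                               k = 20L, stride = 10L,
                               metagenome_id = "metagenome") {
  if (nrow(contigs) == 0L) stop("empty reference contig set")
  clusters <- map_nucleotide(reads, contigs, min_cluster = min_cluster,
                             max_gap = max_gap, k = k, stride = stride)
  coverage <- lapply(setNames(contigs$length, contigs$id), integer)
  gene_cov <- setNames(rep(0, nrow(genes)), genes$id)
  recruited <- 0L
  ani <- NA_real_
  if (nrow(clusters) > 0L) {
    # one cluster per read: the one with most anchored bases
    clusters <- clusters[order(clusters$query_id, -clusters$anchor_len), ,
                         drop = FALSE]
    clusters <- clusters[!duplicated(clusters$query_id), , drop = FALSE]
    recruited <- sum(nchar(reads[clusters$query_id]))
    w <- clusters$s_end - clusters$s_start + 1L
    ani <- sum(clusters$identity * w) / sum(w)
    for (r in seq_len(nrow(clusters))) {
      cid <- clusters$contig_id[r]
      sel <- clusters$s_start[r]:clusters$s_end[r]
      coverage[[cid]][sel] <- coverage[[cid]][sel] + 1L
    }
    for (gi in seq_len(nrow(genes))) {
      cc <- clusters[clusters$contig_id == genes$contig_id[gi], , drop = FALSE]
      if (nrow(cc) == 0L) next
      ov <- pmax(0L, pmin(cc$s_end, genes$end[gi]) -
                   pmax(cc$s_start, genes$start[gi]) + 1L)
      keep <- ov > 0L
      if (!any(keep)) next
      covered <- total_interval_length(
        pmax(cc$s_start[keep], genes$start[gi]),
        pmin(cc$s_end[keep], genes$end[gi]))
      gene_cov[[gi]] <- covered / (genes$end[gi] - genes$start[gi] + 1L)
    }
  }
  new_recruitment_profile(
    reference_id = paste(contigs$source_id[1L], "microbial", sep = ":"),
    metagenome_id = metagenome_id, mode = "nucleotide",
    per_gene_best_identity = setNames(rep(NA_real_, nrow(genes)), genes$id),
    gene_covered_fraction = gene_cov, cluster_ani = ani,
    recruited_bases = recruited, coverage = coverage,
    reference_length = sum(contigs$length)
  )
}

#' Classify viral presence in a metagenome from a recruitment profile
#'
#' A reference virus is `present` when more than 75% of its genes are
#' detected at more than 80% amino-acid identity; when the same fraction of
#' genes is detected at 60-80% identity a `related` but distinct virus is
#' inferred; otherwise the virus is `absent` -- except that an
#' ssDNA reference scored against a linker-amplified metagenome cannot be
#' called absent (library construction biases strongly against ssDNA
#' templates), so the call becomes `inconclusive`.
#'
#' @param profile a protein-mode `recruitment_profile`.
#' @param ssdna is the reference an ssDNA genome?
#' @param linker_amplified was the metagenome library linker-amplified?
#' @param high_identity,mid_identity,min_fraction classification thresholds.
#' @return list with `state`, `frac_genes_high`, `frac_genes_mid`.
#' @export
classify_presence <- function(profile, ssdna = FALSE, linker_amplified = FALSE,
                              high_identity = 80, mid_identity = 60,
                              min_fraction = 0.75) {
  ident <- profile$per_gene_best_identity
  f_high <- mean(!is.na(ident) & ident > high_identity)
  f_mid <- mean(!is.na(ident) & ident >= mid_identity)
  state <- if (f_high > min_fraction) {
    "present"
  } else if (f_mid > min_fraction) {
    "related"
  } else {
    "absent"
  }
  if (state == "absent" && ssdna && linker_amplified) state <- "inconclusive"
  structure(list(state = state, frac_genes_high = f_high,
                 frac_genes_mid = f_mid), class = "presence_call")
}

#' @export
print.presence_call <- function(x, ...) {
  cat(sprintf("<presence_call> %s (f_high=%.2f, f_mid=%.2f)\n",
              x$state, x$frac_genes_high, x$frac_genes_mid))
  invisible(x)
}

#' Classify host presence from a nucleotide recruitment profile
#'
#' The host is present when more than 75% of genes on its microbial contigs
#' are covered by metagenome clusters and the length-weighted mean cluster
#' identity (ANI) exceeds 95%.
#'
#' @param profile a nucleotide-mode `recruitment_profile`.
#' @param min_gene_fraction,min_ani thresholds.
#' @param min_gene_coverage fraction of a gene's span that must lie under
#'   accepted clusters for the gene to count as covered.
#' @return list with `state` (`present`/`absent`), `frac_genes_covered`,
#'   `ani`.
#' @export
host_presence <- function(profile, min_gene_fraction = 0.75, min_ani = 95,
                          min_gene_coverage = 0.5) {
  fc <- mean(profile$gene_covered_fraction >= min_gene_coverage)
  ok <- fc > min_gene_fraction && !is.na(profile$cluster_ani) &&
    profile$cluster_ani > min_ani
  structure(list(state = if (ok) "present" else "absent",
                 frac_genes_covered = fc, ani = profile$cluster_ani),
            class = "presence_call")
}

#' Normalized relative abundance of a reference in a metagenome
#'
#' Number of recruited bases (sum of the lengths of recruited reads) divided
#' by the reference length in bp and by the metagenome size in Mb.
#'
#' @param profile a `recruitment_profile`, or a number of recruited bases.
#' @param reference_length_bp reference length (taken from the profile if
#'   omitted).
#' @param metagenome_length_bases total bases in the metagenome read set.
#' @return recruited bases per reference bp per metagenome Mb.
#' @export
relative_abundance <- function(profile, reference_length_bp = NULL,
                               metagenome_length_bases) {
  rb <- if (inherits(profile, "recruitment_profile")) {
    if (is.null(reference_length_bp)) reference_length_bp <- profile$reference_length
    profile$recruited_bases
  } else as.numeric(profile)
  if (is.null(reference_length_bp) || reference_length_bp <= 0) {
    stop("reference length must be positive")
  }
  if (metagenome_length_bases <= 0) stop("metagenome size must be positive")
  rb / reference_length_bp / (metagenome_length_bases / 1e6)
}

#' Virus-to-host abundance ratio
#'
#' Relative abundance of the viral contig divided by the relative abundance
#' of the microbial contig set from the same SAG in the same metagenome.
#' Undefined (returned as `NA` with a warning) when the host abundance is 0.
#'
#' @param viral_ra,host_ra relative abundances from [relative_abundance()].
#' @return the ratio, or `NA` when the host is not detected.
#' @export
virus_host_ratio <- function(viral_ra, host_ra) {
  if (host_ra == 0) {
    warning("host relative abundance is 0; virus-to-host ratio undefined")
    return(NA_real_)
  }
  viral_ra / host_ra
}

#' Box summary of recruited-sequence identities
#'
#' Summarizes the identity distribution of qualifying recruitment hits
#' (identity >= `min_identity`, default 80): median and hinges are the first
#' and third quartiles (25th/75th percentiles, linear interpolation of order
#' statistics); outliers lie beyond 1.5 inter-quartile ranges from a hinge.
#'
#' @param identities numeric vector of percent identities.
#' @param min_identity qualifying threshold.
#' @return list with `median`, `hinge_lo`, `hinge_hi`, `outliers`, `n`.
#' @export
identity_distribution <- function(identities, min_identity = 80) {
  x <- identities[!is.na(identities) & identities >= min_identity]
  if (length(x) == 0L) stop("no qualifying identities")
  q <- unname(quantile(x, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3L] - q[1L]
  out <- x[x < q[1L] - 1.5 * iqr | x > q[3L] + 1.5 * iqr]
  list(median = q[2L], hinge_lo = q[1L], hinge_hi = q[3L],
       outliers = out, n = length(x))
}

#' Windowed mean coverage along a reference
#'
#' @param profile a `recruitment_profile`.
#' @param window_bp non-overlapping window size (>= 100); a window larger
#'   than the reference yields a single window.
#' @return `data.frame`: `contig_id`, `window_start`, `window_end`,
#'   `mean_coverage`.
#' @export
coverage_profile <- function(profile, window_bp = 1000L) {
  stopifnot(window_bp >= 100L)
  out <- lapply(names(profile$coverage), function(cid) {
    cov <- profile$coverage[[cid]]
    n <- length(cov)
    starts <- seq.int(1L, n, by = window_bp)
    ends <- pmin(starts + window_bp - 1L, n)
    data.frame(contig_id = cid, window_start = starts, window_end = ends,
               mean_coverage = vapply(seq_along(starts), function(i) {
                 mean(cov[starts[i]:ends[i]])
               }, 0), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
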