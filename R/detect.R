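HALLMARK_CATEGORIES <- c("virion_structure", "capsid", "portal", "tail",
                         "terminase")
HALLMARK_KEYWORDS <- c(virion_structure = "virion structure",
                       capsid = "capsid",
                       portal = "portal",
                       tail = "tail",
                       terminase = "terminase")
# obvious negations removed from the annotation text before keyword search
HALLMARK_STOPLIST <- c("tailless", "tail-less", "capsidless", "capsid-less")

viral_call_table <- function(contig_id = character(), method = character(),
                             gene_from = integer(), gene_to = integer(),
                             evidence = character()) {
  data.frame(contig_id = as.character(contig_id),
             method = as.character(method),
             gene_from = as.integer(gene_from),
             gene_to = as.integer(gene_to),
             evidence = as.character(evidence),
             stringsAsFactors = FALSE)
}

order_genes <- function(genes) genes[order(genes$start, genes$end), , drop = FALSE]

#' Gene-architecture metrics of a contig
#'
#' Three summary metrics that separate viral from microbial contigs:
#' average gene size (bp), ratio of strand changes (number of strand switches
#' between consecutive genes divided by the total number of genes on the
#' contig), and ratio of uncharacterized genes (genes with no qualifying
#' domain hit divided by the total number of genes).
#'
#' @param genes gene table of one contig (>= 1 gene).
#' @return a one-row `data.frame`: `contig_id`, `avg_gene_size`,
#'   `strand_change_ratio`, `uncharacterized_ratio`, `n_genes`.
#' @export
compute_metrics <- function(genes) {
  if (nrow(genes) == 0L) stop("compute_metrics needs at least one gene")
  if (length(unique(genes$contig_id)) != 1L) {
    stop("compute_metrics expects genes of a single contig")
  }
  genes <- order_genes(genes)
  n <- nrow(genes)
  changes <- if (n > 1L) sum(genes$strand[-1L] != genes$strand[-n]) else 0L
  data.frame(
    contig_id = genes$contig_id[1L],
    avg_gene_size = mean(genes$end - genes$start + 1),
    strand_change_ratio = changes / n,
    uncharacterized_ratio = mean(!genes$characterized),
    n_genes = n,
    stringsAsFactors = FALSE
  )
}

#' Detect viral contigs by hallmark gene annotation
#'
#' A contig is called viral when at least one of its genes is annotated with
#' a virion-associated keyword: "virion structure", "capsid", "portal",
#' "tail" or "terminase" (case-insensitive substring match, with a small
#' stop-list guarding obvious negations). Matching genes get their
#' `hallmark_category` set.
#'
#' @param genes gene table (any number of contigs).
#' @return a list with `calls` (viral-call table, method `"hallmark"`, one
#'   row per flagged contig) and `genes` (the gene table with
#'   `hallmark_category` updated).
#' @export
detect_hallmark <- function(genes) {
  txt <- tolower(genes$annotation_text)
  for (s in HALLMARK_STOPLIST) txt <- gsub(s, "", txt, fixed = TRUE)
  cat_hit <- rep("none", nrow(genes))
  for (cat in rev(HALLMARK_CATEGORIES)) {
    hit <- grepl(HALLMARK_KEYWORDS[[cat]], txt, fixed = TRUE)
    cat_hit[hit] <- cat
  }
  genes$hallmark_category <- cat_hit
  flagged <- genes[cat_hit != "none", , drop = FALSE]
  calls <- viral_call_table()
  if (nrow(flagged) > 0L) {
    by_contig <- split(flagged, flagged$contig_id)
    calls <- do.call(rbind, lapply(by_contig, function(g) {
      all_g <- genes[genes$contig_id == g$contig_id[1L], , drop = FALSE]
      viral_call_table(
        contig_id = g$contig_id[1L], method = "hallmark",
        gene_from = 1L, gene_to = nrow(all_g),
        evidence = paste0(g$id, ":", g$hallmark_category, collapse = ",")
      )
    }))
    rownames(calls) <- NULL
  }
  list(calls = calls, genes = genes)
}

# qualifying protein hits for association / shared-gene analyses
qualify_hits <- function(hits, max_evalue = 1e-3, min_bit = 50) {
  hits[hits$evalue <= max_evalue & hits$bit_score >= min_bit, , drop = FALSE]
}

#' Expand viral detection by protein similarity to detected viral contigs
#'
#' A candidate contig is flagged when at least half of its genes have a
#' qualifying protein hit (E-value <= 1e-3 and bit score >= 50) to genes of
#' a single already-detected viral contig. Applied iteratively until a fixed
#' point: contigs flagged in one pass serve as references in the next.
#'
#' @param candidate_ids contig ids eligible for expansion.
#' @param detected_ids contig ids already classified viral.
#' @param protein_hits gene-vs-gene hit table (either direction).
#' @param genes gene table covering every gene referenced by the hits.
#' @param min_fraction minimum fraction of candidate genes with a qualifying
#'   hit (default 0.5, inclusive).
#' @param max_evalue,min_bit hit acceptance thresholds.
#' @param pooled if `TRUE`, hits to all detected contigs are pooled instead
#'   of requiring a single best reference.
#' @return viral-call table, method `"association"`; evidence names the best
#'   reference contig and the fraction of genes matched.
#' @export
expand_by_association <- function(candidate_ids, detected_ids, protein_hits,
                                  genes, min_fraction = 0.5,
                                  max_evalue = 1e-3, min_bit = 50,
                                  pooled = FALSE) {
  known <- c(protein_hits$query_id, protein_hits$subject_id) %in% genes$id
  if (!all(known)) {
    bad <- c(protein_hits$query_id, protein_hits$subject_id)[!known][1L]
    stop("hit references unknown gene: ", bad)
  }
  hits <- qualify_hits(protein_hits, max_evalue, min_bit)
  gene2contig <- setNames(genes$contig_id, genes$id)
  # symmetric gene-pair edges with contig labels
  edges <- data.frame(
    g1 = c(hits$query_id, hits$subject_id),
    g2 = c(hits$subject_id, hits$query_id),
    stringsAsFactors = FALSE
  )
  edges$c1 <- gene2contig[edges$g1]
  edges$c2 <- gene2contig[edges$g2]
  detected <- unique(detected_ids)
  remaining <- setdiff(unique(candidate_ids), detected)
  calls <- viral_call_table()
  repeat {
    newly <- character(0)
    for (cid in remaining) {
      gids <- genes$id[genes$contig_id == cid]
      e <- edges[edges$c1 == cid & edges$c2 %in% detected &
                   edges$c2 != cid, , drop = FALSE]
      if (nrow(e) == 0L) next
      if (pooled) {
        frac <- length(unique(e$g1)) / length(gids)
        best_ref <- "pooled"
      } else {
        per_ref <- vapply(split(e$g1, e$c2), function(g) length(unique(g)), 0L)
        frac <- max(per_ref) / length(gids)
        best_ref <- names(per_ref)[which.max(per_ref)]
      }
      if (frac >= min_fraction) {
        newly <- c(newly, cid)
        calls <- rbind(calls, viral_call_table(
          contig_id = cid, method = "association",
          gene_from = 1L, gene_to = length(gids),
          evidence = sprintf("ref=%s;frac=%.3f", best_ref, frac)
        ))
      }
    }
    if (length(newly) == 0L) break
    detected <- c(detected, newly)
    remaining <- setdiff(remaining, newly)
  }
  rownames(calls) <- NULL
  calls
}

#' Detect viral contigs supported by virome reads
#'
#' A contig is flagged when at least `min_genes` distinct genes each have at
#' least one protein-level virome hit at >= `min_identity` percent identity.
#'
#' @param genes gene table of the candidate contigs.
#' @param virome_hits hit table from virome reads/genes to candidate genes
#'   (the gene may sit on either side of the hit).
#' @param min_genes minimum number of distinct supported genes (default 3).
#' @param min_identity minimum percent identity (default 90).
#' @return viral-call table, method `"virome_support"`.
#' @export
detect_by_virome_support <- function(genes, virome_hits, min_genes = 3L,
                                     min_identity = 90) {
  h <- virome_hits[virome_hits$identity >= min_identity, , drop = FALSE]
  gid <- ifelse(h$subject_id %in% genes$id, h$subject_id, h$query_id)
  gid <- gid[gid %in% genes$id]
  if (length(gid) == 0L) return(viral_call_table())
  per_contig <- tapply(gid, genes$contig_id[match(gid, genes$id)],
                       function(g) length(unique(g)))
  flagged <- names(per_contig)[per_contig >= min_genes]
  if (length(flagged) == 0L) return(viral_call_table())
  calls <- do.call(rbind, lapply(flagged, function(cid) {
    viral_call_table(
      contig_id = cid, method = "virome_support",
      gene_from = 1L, gene_to = sum(genes$contig_id == cid),
      evidence = sprintf("supported_genes=%d", per_contig[[cid]])
    )
  }))
  rownames(calls) <- NULL
  calls
}

# all qualifying windows of >= min_region_genes consecutive genes:
# uncharacterized fraction >= min_unchar AND max single-strand fraction
# >= min_strand; returns merged gene-index intervals
qualifying_regions <- function(unchar, plus, min_region_genes,
                               min_unchar = 0.5, min_strand = 0.8) {
  n <- length(unchar)
  if (n < min_region_genes) return(NULL)
  cu <- c(0, cumsum(unchar))
  cp <- c(0, cumsum(plus))
  ivs <- NULL
  for (i in 1:(n - min_region_genes + 1L)) {
    for (j in (i + min_region_genes - 1L):n) {
      len <- j - i + 1L
      u <- (cu[j + 1L] - cu[i]) / len
      p <- (cp[j + 1L] - cp[i]) / len
      if (u >= min_unchar && max(p, 1 - p) >= min_strand) {
        ivs <- rbind(ivs, c(i, j))
      }
    }
  }
  if (is.null(ivs)) return(NULL)
  merge_intervals(ivs)
}

# merge overlapping/adjacent-overlapping integer intervals (matrix: from,to)
merge_intervals <- function(ivs) {
  ivs <- ivs[order(ivs[, 1L], ivs[, 2L]), , drop = FALSE]
  out <- ivs[1L, , drop = FALSE]
  if (nrow(ivs) > 1L) {
    for (r in 2:nrow(ivs)) {
      last <- nrow(out)
      if (ivs[r, 1L] <= out[last, 2L]) {
        out[last, 2L] <- max(out[last, 2L], ivs[r, 2L])
      } else {
        out <- rbind(out, ivs[r, , drop = FALSE])
      }
    }
  }
  out
}

#' Scan a contig for reference-free viral-like regions
#'
#' Finds regions of consecutive genes that look viral without any database
#' support: at least half the genes uncharacterized and at least 80% of the
#' genes on the same coding strand. All windows of at least
#' `min_region_genes` consecutive genes satisfying both criteria are
#' enumerated and overlapping windows merged; the merged regions are maximal
#' (no one-gene extension still satisfies both criteria as a window).
#'
#' @param genes gene table of one contig, any order (sorted internally).
#' @param min_region_genes minimum window length in genes (>= 4; default 8).
#' @param min_unchar,min_strand the two fractions (inclusive thresholds).
#' @return viral-call table, method `"region_metric"`, with `gene_from` /
#'   `gene_to` as 1-based indexes into the position-sorted gene list.
#' @export
scan_unknown_regions <- function(genes, min_region_genes = 8L,
                                 min_unchar = 0.5, min_strand = 0.8) {
  stopifnot(min_region_genes >= 4L)
  if (nrow(genes) == 0L) return(viral_call_table())
  genes <- order_genes(genes)
  regs <- qualifying_regions(!genes$characterized, genes$strand == "+",
                             min_region_genes, min_unchar, min_strand)
  if (is.null(regs)) return(viral_call_table())
  calls <- viral_call_table(
    contig_id = genes$contig_id[1L], method = "region_metric",
    gene_from = regs[, 1L], gene_to = regs[, 2L],
    evidence = vapply(seq_len(nrow(regs)), function(r) {
      sel <- regs[r, 1L]:regs[r, 2L]
      p <- mean(genes$strand[sel] == "+")
      sprintf("unchar=%.3f;strand=%.3f",
              mean(!genes$characterized[sel]), max(p, 1 - p))
    }, "")
  )
  calls
}

#' Classify contigs from accumulated viral-detection evidence
#'
#' Applies the detection precedence hallmark, then association, then virome
#' support, then region metric. Hallmark- and association-detected contigs are reported
#' as `viral_hallmark`; virome-supported contigs and contigs whose
#' region-metric calls span (nearly) the whole gene complement are
#' `viral_putative`; contigs carrying only a sub-contig region call stay
#' `microbial` but keep the embedded region (prophage-candidate input).
#'
#' @param contigs contig table.
#' @param genes gene table.
#' @param calls viral-call table pooled from the detection operations.
#' @param whole_contig_fraction minimum fraction of a contig's genes covered
#'   by region-metric calls for the whole contig to be labelled viral
#'   (default 0.8; set to 1 to require full coverage).
#' @param min_unchar,min_strand contig-level architecture requirement for a
#'   whole-contig putative call: the contig's own uncharacterized-gene ratio
#'   and majority-strand fraction must also qualify, so that chains of
#'   marginal windows on an ordinary microbial contig are not promoted.
#' @return `data.frame`: `contig_id`, `label` (`viral_hallmark`,
#'   `viral_putative`, `microbial`), `method`, `has_embedded_region`.
#' @export
classify_contigs <- function(contigs, genes, calls,
                             whole_contig_fraction = 0.8,
                             min_unchar = 0.5, min_strand = 0.8) {
  out <- data.frame(contig_id = contigs$id, label = "microbial",
                    method = NA_character_, has_embedded_region = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(out))) {
    cid <- out$contig_id[i]
    cc <- calls[calls$contig_id == cid, , drop = FALSE]
    if (nrow(cc) == 0L) next
    n_genes <- sum(genes$contig_id == cid)
    if ("hallmark" %in% cc$method) {
      out$label[i] <- "viral_hallmark"; out$method[i] <- "hallmark"
    } else if ("association" %in% cc$method) {
      out$label[i] <- "viral_hallmark"; out$method[i] <- "association"
    } else if ("virome_support" %in% cc$method) {
      out$label[i] <- "viral_putative"; out$method[i] <- "virome_support"
    } else if ("region_metric" %in% cc$method && n_genes > 0L) {
      rr <- cc[cc$method == "region_metric", , drop = FALSE]
      covered <- sum(rr$gene_to - rr$gene_from + 1L)
      g <- genes[genes$contig_id == cid, , drop = FALSE]
      p <- mean(g$strand == "+")
      contig_viral_like <- mean(!g$characterized) >= min_unchar &&
        max(p, 1 - p) >= min_strand
      if (covered / n_genes >= whole_contig_fraction && contig_viral_like) {
        out$label[i] <- "viral_putative"; out$method[i] <- "region_metric"
      } else {
        out$has_embedded_region[i] <- TRUE
      }
    }
  }
  out
}
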