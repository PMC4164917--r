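# ---- CRISPR repeat-spacer arrays -------------------------------------------

new_crispr_array <- function(contig_id, repeat_consensus, repeat_positions,
                             spacers) {
  structure(list(contig_id = contig_id,
                 repeat_consensus = repeat_consensus,
                 repeat_positions = repeat_positions,  # data.frame start,end
                 spacers = spacers),                   # data.frame start,end,sequence
            class = "crispr_array")
}

#' @export
print.crispr_array <- function(x, ...) {
  cat(sprintf("<crispr_array> %s: %d repeats of %d bp, %d spacers\n",
              x$contig_id, nrow(x$repeat_positions),
              nchar(x$repeat_consensus), nrow(x$spacers)))
  invisible(x)
}

#' Validate a CRISPR array against the structural invariants
#'
#' Checks: at least `min_repeats` repeats; repeats and spacers strictly
#' alternate without overlap; repeat length within `repeat_len`; spacer
#' lengths within `spacer_len`; every repeat copy at least
#' `min_repeat_identity` identical to the consensus.
#'
#' @param array a `crispr_array`.
#' @param sequence the contig sequence the array lies on.
#' @param min_repeats,repeat_len,spacer_len,min_repeat_identity invariants.
#' @return `TRUE` or a character description of the first violation.
#' @export
validate_crispr_array <- function(array, sequence, min_repeats = 3L,
                                  repeat_len = c(19L, 48L),
                                  spacer_len = c(20L, 60L),
                                  min_repeat_identity = 0.85) {
  rp <- array$repeat_positions
  sp <- array$spacers
  if (nrow(rp) < min_repeats) return("fewer repeats than minimum")
  rl <- rp$end - rp$start + 1L
  if (any(rl < repeat_len[1L] | rl > repeat_len[2L])) {
    return("repeat length out of bounds")
  }
  if (nrow(sp) != nrow(rp) - 1L) return("repeats and spacers do not alternate")
  sl <- sp$end - sp$start + 1L
  if (any(sl < spacer_len[1L] | sl > spacer_len[2L])) {
    return("spacer length out of bounds")
  }
  for (i in seq_len(nrow(sp))) {
    if (sp$start[i] != rp$end[i] + 1L || sp$end[i] != rp$start[i + 1L] - 1L) {
      return("repeats and spacers overlap or leave gaps")
    }
  }
  cons <- strsplit(array$repeat_consensus, "")[[1L]]
  for (i in seq_len(nrow(rp))) {
    copy <- strsplit(substr(sequence, rp$start[i], rp$end[i]), "")[[1L]]
    if (length(copy) != length(cons)) return("repeat copy length differs")
    if (mean(copy == cons) < min_repeat_identity) {
      return("repeat copy below consensus identity")
    }
  }
  TRUE
}

#' Detect CRISPR repeat-spacer arrays on a contig
#'
#' Seeds on exact k-mers (default k = 8) recurring at periods between 39 and
#' 108 bp (minimum repeat + spacer to maximum repeat + spacer), extends each
#' seed chain to the maximal exact repeat shared by all copies, and accepts
#' arrays meeting the structural invariants (>= 3 repeats of 19-48 bp
#' alternating with 20-60 bp spacers). Overlapping candidates are resolved
#' in favour of the array with most repeats, ties by longer span.
#'
#' @param contig one-row contig table (>= 200 bp).
#' @param k seed k-mer length.
#' @param period allowed distance range between consecutive repeat starts.
#' @param min_repeats,repeat_len,spacer_len,min_repeat_identity array
#'   invariants (see [validate_crispr_array()]).
#' @return list of `crispr_array` objects (possibly empty).
#' @export
find_crispr_arrays <- function(contig, k = 8L, period = c(39L, 108L),
                               min_repeats = 3L, repeat_len = c(19L, 48L),
                               spacer_len = c(20L, 60L),
                               min_repeat_identity = 0.85) {
  seq <- contig$sequence[1L]
  n <- nchar(seq)
  if (n < 200L) return(list())
  chars <- strsplit(seq, "")[[1L]]
  starts <- 1:(n - k + 1L)
  km <- substring(seq, starts, starts + k - 1L)
  occ <- split(starts, km)
  occ <- occ[lengths(occ) >= min_repeats]
  cands <- list()
  seen <- character(0)
  for (p in occ) {
    p <- sort(p)
    gaps <- diff(p)
    ok <- gaps >= period[1L] & gaps <= period[2L]
    # maximal runs of consecutive in-range gaps
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    begins <- ends - r$lengths + 1L
    for (ri in which(r$values & r$lengths >= min_repeats - 1L)) {
      copies <- p[begins[ri]:(ends[ri] + 1L)]
      # maximal exact extension shared by all copies
      dl <- 0L
      while (all(copies - dl - 1L >= 1L) &&
             length(unique(chars[copies - dl - 1L])) == 1L) dl <- dl + 1L
      dr <- 0L
      while (all(copies + k + dr <= n) &&
             length(unique(chars[copies + k + dr])) == 1L) dr <- dr + 1L
      rs <- copies - dl
      re <- copies + k - 1L + dr
      key <- paste(rs, collapse = ",")
      if (key %in% seen) next
      seen <- c(seen, key)
      rlen <- k + dl + dr
      if (rlen < repeat_len[1L] || rlen > repeat_len[2L]) next
      if (any(re[-length(re)] >= rs[-1L])) next  # copies overlap
      slen <- rs[-1L] - re[-length(re)] - 1L
      if (any(slen < spacer_len[1L] | slen > spacer_len[2L])) next
      sp_start <- re[-length(re)] + 1L
      sp_end <- rs[-1L] - 1L
      arr <- new_crispr_array(
        contig_id = contig$id[1L],
        repeat_consensus = substr(seq, rs[1L], re[1L]),
        repeat_positions = data.frame(start = rs, end = re),
        spacers = data.frame(start = sp_start, end = sp_end,
                             sequence = substring(seq, sp_start, sp_end),
                             stringsAsFactors = FALSE)
      )
      if (isTRUE(validate_crispr_array(arr, seq, min_repeats, repeat_len,
                                       spacer_len, min_repeat_identity))) {
        cands[[length(cands) + 1L]] <- arr
      }
    }
  }
  if (length(cands) <= 1L) return(cands)
  # resolve overlapping candidates: most repeats, ties by longer span
  span <- t(vapply(cands, function(a) {
    c(min(a$repeat_positions$start), max(a$repeat_positions$end))
  }, c(0, 0)))
  nrep <- vapply(cands, function(a) nrow(a$repeat_positions), 0L)
  width <- span[, 2L] - span[, 1L]
  o <- order(-nrep, -width)
  keep <- logical(length(cands))
  occ_from <- numeric(0); occ_to <- numeric(0)
  for (i in o) {
    if (!any(span[i, 1L] <= occ_to & span[i, 2L] >= occ_from)) {
      keep[i] <- TRUE
      occ_from <- c(occ_from, span[i, 1L])
      occ_to <- c(occ_to, span[i, 2L])
    }
  }
  cands[keep]
}

# array footprint (nt interval) on its contig
array_span <- function(array) {
  c(min(array$repeat_positions$start), max(array$repeat_positions$end))
}

#' Match CRISPR spacers against contigs
#'
#' Each spacer is compared to every contig on both strands; a hit requires
#' at least `min_identity` percent identity over at least `min_coverage` of
#' the spacer length (substitution-only matching). Hits falling inside the
#' spacer's own array footprint are excluded.
#'
#' @param arrays list of `crispr_array` objects.
#' @param contigs contig table to search.
#' @param min_identity,min_coverage acceptance thresholds (defaults 95/0.95).
#' @return hit table (`kind = "nucleotide"`), query ids
#'   `<contig>:spacer<i>`.
#' @export
match_spacers <- function(arrays, contigs, min_identity = 95,
                          min_coverage = 0.95) {
  res <- list()
  for (arr in arrays) {
    span <- array_span(arr)
    for (si in seq_len(nrow(arr$spacers))) {
      sp <- arr$spacers$sequence[si]
      qid <- paste0(arr$contig_id, ":spacer", si)
      len <- nchar(sp)
      max_mm <- floor((1 - min_identity / 100) * len)
      for (pat in list(c("+", sp), c("-", revcomp(sp)))) {
        for (ci in seq_len(nrow(contigs))) {
          m <- Biostrings::matchPattern(pat[[2L]],
                                        Biostrings::DNAString(contigs$sequence[ci]),
                                        max.mismatch = max_mm)
          if (length(m) == 0L) next
          st <- IRanges::start(m); en <- IRanges::end(m)
          if (contigs$id[ci] == arr$contig_id) {
            inside <- st <= span[2L] & en >= span[1L]
            st <- st[!inside]; en <- en[!inside]
          }
          for (j in seq_along(st)) {
            mm <- sum(strsplit(pat[[2L]], "")[[1L]] !=
                        strsplit(substr(contigs$sequence[ci], st[j], en[j]),
                                 "")[[1L]])
            res[[length(res) + 1L]] <- hit_table(
              query_id = qid, subject_id = contigs$id[ci],
              kind = "nucleotide", identity = 100 * (len - mm) / len,
              aln_length = len, mismatches = mm, gaps = 0L,
              q_start = 1L, q_end = len, s_start = st[j], s_end = en[j],
              evalue = 0, bit_score = 2 * (len - mm)
            )
          }
        }
      }
    }
  }
  if (length(res) == 0L) return(hit_table(kind = "nucleotide"))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Flag defective prophages among embedded viral-like regions
#'
#' A region call embedded in a microbial contig is promoted to a putative
#' defective prophage when (a) at least one microbial gene flanks it on each
#' side and (b) a nucleotide match at >= `min_identity` percent identity
#' covering >= `min_region_coverage` of the region exists on a microbial
#' contig of a *different* SAG (the automated proxy for curating regions
#' "conserved between closely related bacterial contigs"). Because the
#' gene-architecture scan merges overlapping windows, a candidate region can
#' sprawl beyond the conserved element; when the whole-region coverage test
#' fails but a conserved core of at least `min_core_bp` exists, the region
#' is trimmed to that core and the flank test applied to the trimmed span --
#' the automated analogue of trimming a candidate to its conserved extent
#' during curation.
#'
#' @param contigs contig table (all SAGs).
#' @param genes gene table.
#' @param labels output of [classify_contigs()].
#' @param region_calls viral-call rows of method `"region_metric"` embedded
#'   in microbial contigs.
#' @param min_identity,min_region_coverage conservation thresholds.
#' @param min_core_bp minimum conserved-core length used when trimming.
#' @return `data.frame`: `contig_id`, `start`, `end`, `conserved_in`,
#'   `status`.
#' @export
flag_defective_prophages <- function(contigs, genes, labels, region_calls,
                                     min_identity = 95,
                                     min_region_coverage = 0.5,
                                     min_core_bp = 1000L) {
  microbial <- labels$contig_id[labels$label == "microbial"]
  out <- data.frame(contig_id = character(), start = integer(),
                    end = integer(), conserved_in = character(),
                    status = character(), stringsAsFactors = FALSE)
  rr <- region_calls[region_calls$method == "region_metric" &
                       region_calls$contig_id %in% microbial, , drop = FALSE]
  if (nrow(rr) == 0L) return(out)
  # extract all candidate regions, then map them all in one pass
  qseq <- character(0)
  meta <- list()
  for (i in seq_len(nrow(rr))) {
    cid <- rr$contig_id[i]
    g <- order_genes(genes[genes$contig_id == cid, , drop = FALSE])
    from <- g$start[rr$gene_from[i]]
    to <- g$end[rr$gene_to[i]]
    qid <- sprintf("region%d", length(qseq) + 1L)
    qseq[qid] <- substr(contigs$sequence[match(cid, contigs$id)], from, to)
    meta[[qid]] <- list(contig_id = cid, from = from, to = to,
                        src = contigs$source_id[match(cid, contigs$id)],
                        genes = g)
  }
  mic <- contigs[contigs$id %in% microbial, , drop = FALSE]
  if (length(qseq) == 0L || nrow(mic) == 0L) return(out)
  cl_all <- map_nucleotide(qseq, mic, min_cluster = 100L, max_gap = 500L)
  cl_all <- cl_all[cl_all$identity >= min_identity, , drop = FALSE]
  for (qid in names(qseq)) {
    m <- meta[[qid]]
    # conservation must come from a microbial contig of a different SAG
    other_src <- mic$source_id[match(cl_all$contig_id, mic$id)] != m$src
    cl <- cl_all[cl_all$query_id == qid & other_src, , drop = FALSE]
    if (nrow(cl) == 0L) next
    region_len <- nchar(qseq[[qid]])
    span <- c(1L, region_len)
    support <- character(0)
    for (oc in unique(cl$contig_id)) {
      cc <- cl[cl$contig_id == oc, , drop = FALSE]
      cov <- total_interval_length(cc$q_start, cc$q_end) / region_len
      if (cov >= min_region_coverage) support <- c(support, oc)
    }
    if (length(support) == 0L) {
      # whole-region conservation fails: trim to the conserved core (the
      # longest merged matched interval) and re-test coverage against it
      iv <- merge_intervals(cbind(cl$q_start, cl$q_end))
      iv_len <- iv[, 2L] - iv[, 1L] + 1L
      j <- which.max(iv_len)
      if (iv_len[j] < min_core_bp) next
      span <- c(iv[j, 1L], iv[j, 2L])
      core_len <- span[2L] - span[1L] + 1L
      for (oc in unique(cl$contig_id)) {
        cc <- cl[cl$contig_id == oc, , drop = FALSE]
        s <- pmax(cc$q_start, span[1L])
        e <- pmin(cc$q_end, span[2L])
        ok <- s <= e
        if (any(ok) &&
            total_interval_length(s[ok], e[ok]) / core_len >= min_region_coverage) {
          support <- c(support, oc)
        }
      }
      if (length(support) == 0L) next
    }
    from <- m$from + span[1L] - 1L
    to <- m$from + span[2L] - 1L
    # (a) at least one microbial gene strictly on each side of the span
    if (!any(m$genes$end < from) || !any(m$genes$start > to)) next
    out <- rbind(out, data.frame(
      contig_id = m$contig_id, start = from, end = to,
      conserved_in = paste(support, collapse = ","),
      status = "putative_defective_prophage", stringsAsFactors = FALSE
    ))
  }
  rownames(out) <- NULL
  out
}

#' Compare past-infection sequences against current viral contigs
#'
#' Spacers are compared with the spacer-match thresholds (at least 95%
#' identity over at least 95% of length); prophage regions require at least
#' 80% identity over at least 500 bp. An empty report means the past- and
#' current-infection
#' sequence sets are disjoint.
#'
#' @param arrays list of `crispr_array` objects (may be empty).
#' @param prophages prophage call table from [flag_defective_prophages()].
#' @param prophage_seqs named character vector of prophage region sequences
#'   (names matching `<contig_id>:<start>-<end>`); derived by the caller.
#' @param current_contigs contig table of current-infection viral contigs.
#' @return `data.frame` of matching pairs: `past_id`, `current_id`, `type`.
#' @export
check_past_vs_current <- function(arrays, prophages = NULL,
                                  prophage_seqs = character(0),
                                  current_contigs) {
  n_spacers <- sum(vapply(arrays, function(a) nrow(a$spacers), 0L))
  if (n_spacers + length(prophage_seqs) == 0L) {
    stop("nothing to compare: past-infection sequence set is empty")
  }
  if (nrow(current_contigs) == 0L) {
    stop("nothing to compare: current viral contig set is empty")
  }
  out <- data.frame(past_id = character(), current_id = character(),
                    type = character(), stringsAsFactors = FALSE)
  if (length(arrays) > 0L) {
    sh <- match_spacers(arrays, current_contigs)
    if (nrow(sh) > 0L) {
      out <- rbind(out, data.frame(past_id = sh$query_id,
                                   current_id = sh$subject_id,
                                   type = "crispr_spacer",
                                   stringsAsFactors = FALSE))
    }
  }
  if (length(prophage_seqs) > 0L) {
    cl <- map_nucleotide(prophage_seqs, current_contigs,
                         min_cluster = 100L, max_gap = 500L)
    cl <- cl[cl$identity >= 80 & (cl$q_end - cl$q_start + 1L) >= 500L, ,
             drop = FALSE]
    if (nrow(cl) > 0L) {
      pair <- unique(cl[, c("query_id", "contig_id")])
      out <- rbind(out, data.frame(past_id = pair$query_id,
                                   current_id = pair$contig_id,
                                   type = "prophage",
                                   stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  unique(out)
}
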