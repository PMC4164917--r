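# Karlin-Altschul gapped parameters for BLOSUM62 with gap open 11 / extend 1
# (the standard published values for this scoring system).
KA_BLOSUM62_11_1 <- list(lambda = 0.267, K = 0.041)

# percent identity over aligned columns; gap columns count in the
# denominator; ambiguity codes never count as a match (X for proteins, N for
# nucleotides -- N is a regular amino acid, asparagine)
aligned_identity <- function(p_aln, s_aln, ambiguous = "X") {
  a <- strsplit(p_aln, "", fixed = TRUE)
  b <- strsplit(s_aln, "", fixed = TRUE)
  vapply(seq_along(a), function(i) {
    m <- a[[i]] == b[[i]] & a[[i]] != "-" & !(a[[i]] %in% ambiguous)
    100 * sum(m) / length(a[[i]])
  }, 0)
}

ka_bits <- function(raw_score, ka = KA_BLOSUM62_11_1) {
  (ka$lambda * raw_score - log(ka$K)) / log(2)
}

#' Local protein alignment with bit score and E-value
#'
#' Smith-Waterman local alignment (via [Biostrings::pairwiseAlignment()])
#' with BLOSUM62 and affine gaps (open 11, extend 1) by default. The raw
#' score is converted to a bit score and expectation value with fixed
#' Karlin-Altschul gapped parameters for that scoring system; the search
#' space (product of effective sequence lengths) is an explicit argument.
#' Identity is matches divided by aligned columns (gap columns included;
#' `X` never counts as a match).
#'
#' @param query,subject amino-acid strings (nonempty).
#' @param matrix substitution matrix name (passed to Biostrings).
#' @param gap_open,gap_extend affine gap penalties (positive costs).
#' @param search_space search-space size for the E-value; default
#'   `nchar(query) * nchar(subject)`.
#' @param ka Karlin-Altschul parameters `list(lambda, K)` for the chosen
#'   scoring system.
#' @return a one-row hit table, or `NULL` when the optimal local score is
#'   not positive.
#' @export
align_proteins <- function(query, subject, matrix = "BLOSUM62",
                           gap_open = 11, gap_extend = 1,
                           search_space = NULL, ka = KA_BLOSUM62_11_1) {
  stopifnot(nchar(query) > 0L, nchar(subject) > 0L)
  hits <- align_protein_sets(c(q = query), c(s = subject), matrix = matrix,
                             gap_open = gap_open, gap_extend = gap_extend,
                             search_space = search_space, ka = ka,
                             seed_k = 0L)
  if (nrow(hits) == 0L) return(NULL)
  hits
}

#' Align many proteins against a set of subjects
#'
#' Vectorized many-vs-many local alignment used by recruitment and
#' guilt-by-association stages. An optional exact k-mer seed prefilter
#' (`seed_k` > 0) skips query/subject pairs that share no amino-acid k-mer,
#' which is how large read sets stay tractable; pairs that do share a seed
#' are aligned exactly.
#'
#' @param queries,subjects named character vectors of amino-acid sequences.
#' @param seed_k length of the exact seed prefilter k-mer; 0 disables it.
#' @param min_bit,max_evalue hit acceptance thresholds applied before
#'   returning (defaults keep everything with positive score).
#' @inheritParams align_proteins
#' @return a hit table (kind `"protein"`).
#' @export
align_protein_sets <- function(queries, subjects, matrix = "BLOSUM62",
                               gap_open = 11, gap_extend = 1,
                               search_space = NULL, ka = KA_BLOSUM62_11_1,
                               seed_k = 0L, min_bit = -Inf, max_evalue = Inf) {
  if (is.null(names(queries)) || is.null(names(subjects))) {
    stop("queries and subjects must be named")
  }
  queries <- queries[nchar(queries) > 0L]
  subjects <- subjects[nchar(subjects) > 0L]
  if (length(queries) == 0L || length(subjects) == 0L) {
    return(hit_table(kind = "protein"))
  }
  kmers_of <- function(s, k) {
    n <- nchar(s)
    if (n < k) return(character(0))
    unique(substring(s, 1:(n - k + 1L), k:n))
  }
  qk <- NULL
  if (seed_k > 0L) {
    qk <- lapply(queries, kmers_of, k = seed_k)
    # inverted index: k-mer -> query indices
    idx <- split(rep(seq_along(queries), lengths(qk)), unlist(qk))
  }
  res <- vector("list", length(subjects))
  for (j in seq_along(subjects)) {
    subj <- subjects[[j]]
    if (seed_k > 0L) {
      sk <- kmers_of(subj, seed_k)
      qi <- sort(unique(unlist(idx[sk], use.names = FALSE)))
      if (length(qi) == 0L) next
    } else {
      qi <- seq_along(queries)
    }
    aln <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::AAStringSet(queries[qi]),
      subject = Biostrings::AAString(subj),
      type = "local", substitutionMatrix = matrix,
      gapOpening = gap_open, gapExtension = gap_extend
    )
    raw <- Biostrings::score(aln)
    pos <- raw > 0
    if (!any(pos)) next
    aln <- aln[pos]; qi <- qi[pos]; raw <- raw[pos]
    # identity from match/mismatch/indel counts (fast path); sequences
    # containing ambiguity codes (X/N) fall back to the aligned strings so
    # that an ambiguous residue never counts as a match
    nm <- Biostrings::nmatch(aln)
    nmm <- Biostrings::nmismatch(aln)
    ind <- Biostrings::nindel(aln)
    ncols <- nm + nmm + Biostrings::insertion(ind)[, 2L] +
      Biostrings::deletion(ind)[, 2L]
    ident <- 100 * nm / ncols
    ambig <- grepl("X", queries[qi], fixed = TRUE) |
      grepl("X", subj, fixed = TRUE)
    if (any(ambig)) {
      p_aln <- as.character(Biostrings::alignedPattern(aln[ambig]))
      s_aln <- as.character(Biostrings::alignedSubject(aln[ambig]))
      ident[ambig] <- aligned_identity(p_aln, s_aln)
    }
    bits <- ka_bits(raw, ka)
    ss <- if (is.null(search_space)) {
      nchar(queries[qi]) * nchar(subj)
    } else rep(search_space, length(qi))
    ev <- ss * 2^(-bits)
    nmatch <- round(ident * ncols / 100)
    res[[j]] <- hit_table(
      query_id = names(queries)[qi],
      subject_id = names(subjects)[j],
      kind = "protein",
      identity = ident,
      aln_length = ncols,
      mismatches = pmax(0L, as.integer(ncols - nmatch)),
      gaps = 0L,
      q_start = IRanges::start(Biostrings::pattern(aln)),
      q_end = IRanges::end(Biostrings::pattern(aln)),
      s_start = IRanges::start(Biostrings::subject(aln)),
      s_end = IRanges::end(Biostrings::subject(aln)),
      evalue = ev,
      bit_score = bits
    )
  }
  out <- do.call(rbind, res[!vapply(res, is.null, TRUE)])
  if (is.null(out)) return(hit_table(kind = "protein"))
  out <- out[out$bit_score >= min_bit & out$evalue <= max_evalue, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# global(ish) nucleotide identity between two sequences; `type` follows
# Biostrings::pairwiseAlignment
nucleotide_identity <- function(a, b, type = "global") {
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                 baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(a), subject = Biostrings::DNAString(b),
    type = type, substitutionMatrix = sm, gapOpening = 4, gapExtension = 1
  )
  aligned_identity(as.character(Biostrings::alignedPattern(aln)),
                   as.character(Biostrings::alignedSubject(aln)),
                   ambiguous = "N")
}
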