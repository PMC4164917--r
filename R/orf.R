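ORF_STARTS <- c("ATG", "GTG", "TTG")
ORF_STOPS <- c("TAA", "TAG", "TGA")

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# bacterial genetic code (translation table 11), cached once
GENETIC_CODE_11 <- Biostrings::getGeneticCode("11")

#' Translate a coding sequence (bacterial code)
#'
#' Translation table 11; a trailing stop codon is dropped; codons containing
#' ambiguous nucleotides translate to `X`.
#'
#' @param dna nucleotide string, length divisible by 3.
#' @param allow_internal_stop keep internal stops as `*` instead of erroring.
#' @return amino-acid string.
#' @export
translate_dna <- function(dna, allow_internal_stop = FALSE) {
  dna <- toupper(dna)
  n <- nchar(dna)
  if (n %% 3L != 0L) stop("sequence length not divisible by 3")
  if (n == 0L) return("")
  codons <- substring(dna, seq.int(1L, n, 3L), seq.int(3L, n, 3L))
  aa <- unname(GENETIC_CODE_11[codons])
  aa[is.na(aa)] <- "X"
  if (aa[length(aa)] == "*") aa <- aa[-length(aa)]
  if (!allow_internal_stop && any(aa == "*")) {
    stop("internal stop codon in translation")
  }
  paste(aa, collapse = "")
}

# all ORF candidates on the forward strand of `seq`: start codon after the
# previous stop, first in-frame stop, full span >= min_len_nt (span includes
# the stop codon, GFF CDS convention)
orfs_one_strand <- function(seq, min_len_nt) {
  n <- nchar(seq)
  out <- list()
  for (frame in 0:2) {
    if (n - 2L < 1L + frame) next
    pos <- seq.int(1L + frame, n - 2L, by = 3L)
    codons <- substring(seq, pos, pos + 2L)
    is_stop <- codons %in% ORF_STOPS
    is_start <- codons %in% ORF_STARTS
    # for each stop, take the first start codon after the previous stop
    stop_idx <- which(is_stop)
    bound_lo <- 1L
    for (si in stop_idx) {
      cand <- which(is_start[bound_lo:si])
      if (length(cand) > 0L) {
        s <- bound_lo + cand[1L] - 1L
        span <- pos[si] + 2L - pos[s] + 1L
        if (span >= min_len_nt) {
          out[[length(out) + 1L]] <- c(start = pos[s], end = pos[si] + 2L)
        }
      }
      bound_lo <- si + 1L
    }
  }
  out
}

#' Call open reading frames on a contig
#'
#' Scans all six reading frames for maximal ORFs (start codon ATG/GTG/TTG,
#' stop TAA/TAG/TGA, span including the stop codon at least `min_len_nt`),
#' then greedily selects a non-overlapping set by descending length.
#' Intended for synthetic genomes; externally supplied gene calls (GFF3) are
#' the primary path for real assemblies.
#'
#' @param contig one-row contig table (or list with `id` and `sequence`).
#' @param min_len_nt minimum ORF span in nucleotides (>= 30, divisible by 3).
#' @return a gene table (possibly empty) with translations.
#' @export
call_orfs <- function(contig, min_len_nt = 90L) {
  stopifnot(min_len_nt >= 30L, min_len_nt %% 3L == 0L)
  seq <- contig$sequence[1L]
  n <- nchar(seq)
  fwd <- orfs_one_strand(seq, min_len_nt)
  rev <- orfs_one_strand(revcomp(seq), min_len_nt)
  cand <- data.frame(
    start = c(vapply(fwd, `[[`, 0, "start"),
              vapply(rev, function(x) n - x[["end"]] + 1L, 0)),
    end = c(vapply(fwd, `[[`, 0, "end"),
            vapply(rev, function(x) n - x[["start"]] + 1L, 0)),
    strand = rep(c("+", "-"), c(length(fwd), length(rev)))
  )
  if (nrow(cand) == 0L) {
    return(gene_table(character(), character(), integer(), integer(), character()))
  }
  cand <- cand[order(-(cand$end - cand$start), cand$start), , drop = FALSE]
  keep <- logical(nrow(cand))
  occ_start <- integer(0); occ_end <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (!any(cand$start[i] <= occ_end & cand$end[i] >= occ_start)) {
      keep[i] <- TRUE
      occ_start <- c(occ_start, cand$start[i])
      occ_end <- c(occ_end, cand$end[i])
    }
  }
  cand <- cand[keep, , drop = FALSE]
  cand <- cand[order(cand$start), , drop = FALSE]
  prot <- vapply(seq_len(nrow(cand)), function(i) {
    s <- substr(seq, cand$start[i], cand$end[i])
    if (cand$strand[i] == "-") s <- revcomp(s)
    translate_dna(s)
  }, "")
  gene_table(
    id = paste0(contig$id[1L], "_orf", seq_len(nrow(cand))),
    contig_id = contig$id[1L],
    start = as.integer(cand$start), end = as.integer(cand$end),
    strand = cand$strand, protein = prot
  )
}
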