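#' Construct a contig table
#'
#' Contigs are represented as a plain `data.frame` with one row per contig
#' and columns `id`, `source_id`, `sequence`, `length`, `role`. The `role`
#' records provenance: a SAG assembly contig, a metagenome sequence, or a
#' viral reference.
#'
#' @param id character vector of unique contig identifiers.
#' @param sequence character vector of nucleotide sequences (A/C/G/T/N).
#' @param source_id SAG or metagenome identifier each contig came from.
#' @param role one of `"sag_assembly"`, `"metagenome"`, `"viral_reference"`,
#'   recycled.
#' @return a `data.frame` with columns `id`, `source_id`, `sequence`,
#'   `length`, `role`.
#' @export
contig_table <- function(id, sequence, source_id = "unknown",
                         role = c("sag_assembly", "metagenome", "viral_reference")) {
  role <- match.arg(role)
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  if (anyDuplicated(id)) {
    stop("duplicate contig id: ", id[duplicated(id)][1L])
  }
  bad <- regexpr("[^ACGTN]", sequence)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop("non-nucleotide character in contig '", id[i], "' at position ", bad[i])
  }
  data.frame(
    id = id,
    source_id = rep_len(as.character(source_id), length(id)),
    sequence = sequence,
    length = nchar(sequence),
    role = rep_len(role, length(id)),
    stringsAsFactors = FALSE
  )
}

#' Construct a gene table
#'
#' Genes are oriented intervals (1-based, inclusive) on contigs, carrying the
#' protein translation, a characterization flag (does the gene have a
#' qualifying domain hit?), free-text annotation, and the hallmark category
#' assigned by [detect_hallmark()].
#'
#' @param id,contig_id character identifiers.
#' @param start,end 1-based inclusive coordinates on the contig.
#' @param strand `"+"` or `"-"`.
#' @param protein amino-acid translation (may be `""` if unknown).
#' @param characterized logical; `TRUE` when the gene has a significant
#'   domain-database hit.
#' @param annotation_text free-text functional annotation.
#' @param hallmark_category one of `"virion_structure"`, `"capsid"`,
#'   `"portal"`, `"tail"`, `"terminase"`, `"none"`.
#' @return a `data.frame` with one row per gene.
#' @export
gene_table <- function(id, contig_id, start, end, strand,
                       protein = "", characterized = FALSE,
                       annotation_text = "", hallmark_category = "none") {
  n <- length(id)
  stopifnot(all(strand %in% c("+", "-")))
  start <- as.integer(start); end <- as.integer(end)
  if (any(start < 1L) || any(end < start)) {
    stop("gene coordinates must satisfy 1 <= start <= end")
  }
  ok <- hallmark_category %in% c(HALLMARK_CATEGORIES, "none")
  if (!all(ok)) stop("unknown hallmark_category: ", hallmark_category[!ok][1L])
  data.frame(
    id = as.character(id),
    contig_id = rep_len(as.character(contig_id), n),
    start = start,
    end = end,
    strand = rep_len(strand, n),
    protein = rep_len(as.character(protein), n),
    characterized = rep_len(as.logical(characterized), n),
    annotation_text = rep_len(as.character(annotation_text), n),
    hallmark_category = rep_len(as.character(hallmark_category), n),
    stringsAsFactors = FALSE
  )
}

#' Construct a similarity-hit table
#'
#' One row per pairwise match in the 12-column tabular layout used by
#' protein and nucleotide search tools, plus a `kind` column.
#'
#' @param query_id,subject_id identifiers of the aligned sequences.
#' @param identity percent identity in `[0, 100]`.
#' @param aln_length alignment length in columns.
#' @param mismatches,gaps counts (bookkeeping only).
#' @param q_start,q_end,s_start,s_end 1-based inclusive coordinates.
#' @param evalue expectation value (>= 0).
#' @param bit_score bit score.
#' @param kind `"protein"` or `"nucleotide"`.
#' @return a `data.frame` of hits.
#' @export
hit_table <- function(query_id = character(), subject_id = character(),
                      identity = numeric(), aln_length = integer(),
                      mismatches = 0L, gaps = 0L,
                      q_start = integer(), q_end = integer(),
                      s_start = integer(), s_end = integer(),
                      evalue = numeric(), bit_score = numeric(),
                      kind = "protein") {
  n <- length(query_id)
  if (n > 0L) {
    if (any(identity < 0 | identity > 100)) {
      stop("identity must lie in [0, 100]")
    }
    if (any(aln_length < 1L)) stop("aln_length must be >= 1")
    if (any(evalue < 0)) stop("evalue must be >= 0")
  }
  data.frame(
    query_id = as.character(query_id),
    subject_id = as.character(subject_id),
    kind = rep_len(as.character(kind), n),
    identity = as.numeric(identity),
    aln_length = as.integer(aln_length),
    mismatches = rep_len(as.integer(mismatches), n),
    gaps = rep_len(as.integer(gaps), n),
    q_start = as.integer(q_start), q_end = as.integer(q_end),
    s_start = as.integer(s_start), s_end = as.integer(s_end),
    evalue = as.numeric(evalue),
    bit_score = as.numeric(bit_score),
    stringsAsFactors = FALSE
  )
}

#' Read and write nucleotide FASTA
#'
#' Thin wrappers around [Biostrings::readDNAStringSet()] and
#' [Biostrings::writeXStringSet()] that return / accept the package's contig
#' table. Reading an empty file returns an empty table with a warning.
#'
#' @param path file path.
#' @param source_id,role passed to [contig_table()].
#' @return `read_fasta`: a contig table; `write_fasta`: `path`, invisibly.
#' @export
read_fasta <- function(path, source_id = "unknown", role = "sag_assembly") {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) {
    warning("empty FASTA file: ", path)
    return(contig_table(character(), character(), source_id, role))
  }
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) {
    stop("duplicate contig id: ", ids[duplicated(ids)][1L])
  }
  contig_table(ids, as.character(ss), source_id = source_id, role = role)
}

#' @param contigs a contig table.
#' @rdname read_fasta
#' @export
write_fasta <- function(contigs, path) {
  ss <- Biostrings::DNAStringSet(setNames(contigs$sequence, contigs$id))
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Read and write gene calls as GFF3
#'
#' Genes travel as GFF3 `CDS` features. Attributes `ID`, `product` (the
#' annotation text), `characterized`, `hallmark_category` and `protein` carry
#' the package's gene fields so that a round trip preserves the gene table.
#' I/O is delegated to [rtracklayer::import.gff3()] / `export.gff3`.
#'
#' @param path file path.
#' @param contigs contig table the features must lie on.
#' @return `read_gff3`: a gene table; `write_gff3`: `path`, invisibly.
#' @export
read_gff3 <- function(path, contigs) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0L) {
    return(gene_table(character(), character(), integer(), integer(), character()))
  }
  seqid <- as.character(GenomicRanges::seqnames(gr))
  unknown <- setdiff(seqid, contigs$id)
  if (length(unknown) > 0L) stop("GFF3 seqid not among contigs: ", unknown[1L])
  clen <- contigs$length[match(seqid, contigs$id)]
  st <- GenomicRanges::start(gr); en <- GenomicRanges::end(gr)
  if (any(en > clen) || any(st < 1L)) {
    bad <- which(en > clen | st < 1L)[1L]
    stop("gene coordinates outside contig '", seqid[bad], "': ",
         st[bad], "-", en[bad], " (contig length ", clen[bad], ")")
  }
  mc <- S4Vectors::mcols(gr)
  grab <- function(field, default) {
    if (field %in% colnames(mc)) {
      v <- as.character(mc[[field]])
      v[is.na(v)] <- default
      v
    } else rep(default, length(gr))
  }
  ids <- grab("ID", "")
  ids[ids == ""] <- paste0("gene", seq_len(sum(ids == "")))
  gene_table(
    id = ids,
    contig_id = seqid,
    start = st,
    end = en,
    strand = as.character(GenomicRanges::strand(gr)),
    protein = grab("protein", ""),
    characterized = grab("characterized", "FALSE") == "TRUE",
    annotation_text = grab("product", ""),
    hallmark_category = grab("hallmark_category", "none")
  )
}

#' @param genes a gene table.
#' @rdname read_gff3
#' @export
write_gff3 <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$contig_id,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand
  )
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    source = "sagphage",
    type = "CDS",
    phase = 0L,
    ID = genes$id,
    product = genes$annotation_text,
    characterized = as.character(genes$characterized),
    hallmark_category = genes$hallmark_category,
    protein = genes$protein
  )
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read precomputed similarity hits in 12-column tabular format
#'
#' Accepts the tab-separated layout written by standard protein/nucleotide
#' search tools (query, subject, identity, alignment length, mismatches,
#' gap opens, qstart, qend, sstart, send, evalue, bitscore) so that external
#' search output can replace the in-package aligner at any stage.
#'
#' @param path file path.
#' @param kind `"protein"` or `"nucleotide"`.
#' @return a hit table (see [hit_table()]); empty file gives zero rows.
#' @export
read_hits_tabular <- function(path, kind = c("protein", "nucleotide")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) return(hit_table(kind = kind))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 12L)) {
    stop("malformed hit row at line ", which(nf != 12L)[1L],
         ": expected 12 tab-separated fields, got ", nf[nf != 12L][1L])
  }
  m <- do.call(rbind, parts)
  num <- function(j) {
    v <- suppressWarnings(as.numeric(m[, j]))
    if (anyNA(v)) stop("malformed numeric field at line ", which(is.na(v))[1L])
    v
  }
  hit_table(
    query_id = m[, 1L], subject_id = m[, 2L], kind = kind,
    identity = num(3L), aln_length = as.integer(num(4L)),
    mismatches = as.integer(num(5L)), gaps = as.integer(num(6L)),
    q_start = as.integer(num(7L)), q_end = as.integer(num(8L)),
    s_start = as.integer(num(9L)), s_end = as.integer(num(10L)),
    evalue = num(11L), bit_score = num(12L)
  )
}

#' @param hits a hit table.
#' @rdname read_hits_tabular
#' @export
write_hits_tabular <- function(hits, path) {
  cols <- c("query_id", "subject_id", "identity", "aln_length", "mismatches",
            "gaps", "q_start", "q_end", "s_start", "s_end", "evalue", "bit_score")
  write.table(hits[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Characterize genes from domain hits
#'
#' A gene counts as characterized when it has at least one domain hit with
#' E-value <= 1e-3 and score >= 30 (the standard domain-search acceptance
#' thresholds this pipeline uses throughout).
#'
#' @param genes a gene table.
#' @param domain_hits `data.frame` with columns `gene_id`, `domain_id`,
#'   `score`, `evalue`.
#' @param max_evalue,min_score acceptance thresholds.
#' @return the gene table with `characterized` updated.
#' @export
apply_domain_hits <- function(genes, domain_hits, max_evalue = 1e-3,
                              min_score = 30) {
  keep <- domain_hits$evalue <= max_evalue & domain_hits$score >= min_score
  genes$characterized <- genes$id %in% domain_hits$gene_id[keep]
  genes
}
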