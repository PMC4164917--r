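test_that("contig table enforces unique ids and a clean alphabet", {
  tb <- contig_table(c("c1", "c2"), c("ACGTN", "acgt"), source_id = "S1")
  expect_equal(tb$length, c(5L, 4L))
  expect_equal(tb$sequence[2L], "ACGT")  # normalized to upper case
  expect_error(contig_table(c("c1", "c1"), c("ACGT", "ACGT")),
               "duplicate contig id")
  expect_error(contig_table("c1", "ACXT"), "position 3")
})

test_that("gene table rejects impossible coordinates and strands", {
  expect_error(gene_table("g1", "c1", 10L, 5L, "+"), "1 <= start <= end")
  expect_error(gene_table("g1", "c1", 0L, 5L, "+"), "1 <= start <= end")
  expect_error(gene_table("g1", "c1", 1L, 5L, "*"))
  expect_error(gene_table("g1", "c1", 1L, 5L, "+",
                          hallmark_category = "integrase"),
               "unknown hallmark_category")
})

test_that("hit table validates identity, alignment length and evalue", {
  expect_error(hit_table("q", "s", identity = 101, aln_length = 10L,
                         q_start = 1L, q_end = 10L, s_start = 1L,
                         s_end = 10L, evalue = 0, bit_score = 20),
               "identity")
  expect_error(hit_table("q", "s", identity = 90, aln_length = 0L,
                         q_start = 1L, q_end = 10L, s_start = 1L,
                         s_end = 10L, evalue = 0, bit_score = 20),
               "aln_length")
  expect_error(hit_table("q", "s", identity = 90, aln_length = 10L,
                         q_start = 1L, q_end = 10L, s_start = 1L,
                         s_end = 10L, evalue = -1, bit_score = 20),
               "evalue")
})

test_that("FASTA survives a round trip on random contigs", {
  set.seed(101)
  tb <- contig_table(sprintf("ctg%02d", 1:5),
                     vapply(1:5, function(i) random_dna(sample(50:400, 1)), ""),
                     source_id = "SAGX")
  path <- tempfile(fileext = ".fasta")
  on.exit(unlink(path), add = TRUE)
  write_fasta(tb, path)
  back <- read_fasta(path, source_id = "SAGX")
  expect_equal(back$id, tb$id)
  expect_equal(back$sequence, tb$sequence)
  expect_equal(back$length, tb$length)
})

test_that("reading an empty FASTA warns and returns an empty contig table", {
  path <- tempfile(fileext = ".fasta")
  on.exit(unlink(path), add = TRUE)
  writeLines(character(0), path)
  expect_warning(tb <- read_fasta(path), "empty FASTA")
  expect_equal(nrow(tb), 0L)
  expect_error(read_fasta(file.path(tempdir(), "does-not-exist.fa")),
               "no such file")
})

test_that("GFF3 round trip preserves every gene field", {
  set.seed(102)
  ctg <- contig_table("c1", random_dna(3000))
  genes <- gene_table(
    id = c("g1", "g2", "g3"),
    contig_id = "c1",
    start = c(10L, 500L, 1200L), end = c(400L, 1100L, 2900L),
    strand = c("+", "-", "+"),
    protein = c("MKT", "", "MAL"),
    characterized = c(TRUE, FALSE, TRUE),
    annotation_text = c("major capsid protein", "", "DNA polymerase"),
    hallmark_category = c("capsid", "none", "none")
  )
  path <- tempfile(fileext = ".gff3")
  on.exit(unlink(path), add = TRUE)
  write_gff3(genes, path)
  back <- read_gff3(path, ctg)
  expect_equal(back, genes)
})

test_that("GFF3 reader rejects features off the contig or on unknown contigs", {
  ctg <- contig_table("c1", strrep("ACGT", 100))  # 400 bp
  path <- tempfile(fileext = ".gff3")
  on.exit(unlink(path), add = TRUE)
  write_gff3(gene_table("g1", "c1", 10L, 500L, "+"), path)
  expect_error(read_gff3(path, ctg), "outside contig")
  write_gff3(gene_table("g1", "cX", 10L, 50L, "+"), path)
  expect_error(read_gff3(path, ctg), "seqid not among contigs")
})

test_that("tabular hits round trip and malformed rows are reported by line", {
  h <- hit_table(
    query_id = c("q1", "q2"), subject_id = c("s1", "s2"),
    identity = c(99.5, 70), aln_length = c(100L, 80L),
    mismatches = c(0L, 24L), gaps = c(0L, 0L),
    q_start = c(1L, 1L), q_end = c(100L, 80L),
    s_start = c(1L, 5L), s_end = c(100L, 84L),
    evalue = c(1e-50, 1e-10), bit_score = c(200, 90)
  )
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path), add = TRUE)
  write_hits_tabular(h, path)
  back <- read_hits_tabular(path, kind = "protein")
  expect_equal(back, h)

  writeLines(c("# comment", "q\ts\t90\t50\t5\t0\t1\t50\t1\t50\t1e-5\t60",
               "q\ts\tbroken"), path)
  expect_error(read_hits_tabular(path), "line 2")
})

test_that("domain hits characterize genes at the documented thresholds", {
  genes <- gene_table(c("g1", "g2", "g3"), "c1",
                      c(1L, 100L, 200L), c(90L, 190L, 290L), "+")
  dh <- data.frame(
    gene_id = c("g1", "g2", "g3"),
    domain_id = "PFX",
    score = c(31, 29, 80),           # g2 fails the score threshold
    evalue = c(1e-4, 1e-4, 1e-2)     # g3 fails the evalue threshold
  )
  out <- apply_domain_hits(genes, dh)
  expect_equal(out$characterized, c(TRUE, FALSE, FALSE))
})

test_that("ORF calls are non-overlapping and re-scan clean", {
  set.seed(103)
  for (rep in 1:5) {
    ctg <- contig_table("c1", random_dna(4000))
    orfs <- call_orfs(ctg, min_len_nt = 150L)
    if (nrow(orfs) == 0L) next
    o <- orfs[order(orfs$start), ]
    if (nrow(o) > 1L) expect_true(all(o$start[-1L] > o$end[-nrow(o)]))
    # every ORF starts with a start codon, ends with a stop, obeys length
    for (i in seq_len(nrow(o))) {
      s <- substr(ctg$sequence, o$start[i], o$end[i])
      if (o$strand[i] == "-") {
        s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
      }
      expect_true(substr(s, 1, 3) %in% c("ATG", "GTG", "TTG"))
      expect_true(substr(s, nchar(s) - 2, nchar(s)) %in% c("TAA", "TAG", "TGA"))
      expect_gte(nchar(s), 150L)
      expect_equal(nchar(s) %% 3L, 0L)
    }
  }
})

test_that("translation follows the bacterial code and flags internal stops", {
  expect_equal(translate_dna("ATGGCT"), "MA")
  expect_equal(translate_dna("ATGGCTTAA"), "MA")      # trailing stop dropped
  expect_equal(translate_dna("ATGNCT"), "MX")          # ambiguity
  expect_error(translate_dna("ATGTAAGCT"), "internal stop")
  expect_equal(translate_dna("ATGTAAGCT", allow_internal_stop = TRUE), "M*A")
  expect_error(translate_dna("ATGG"), "divisible by 3")
})

test_that("self-alignment is perfect and scores the diagonal sum", {
  p <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ"
  h <- align_proteins(p, p)
  expect_equal(h$identity, 100)
  data("BLOSUM62", package = "Biostrings", envir = environment())
  diag_score <- sum(vapply(strsplit(p, "")[[1L]],
                           function(a) BLOSUM62[a, a], 0))
  raw <- (h$bit_score * log(2) + log(0.041)) / 0.267
  expect_equal(raw, diag_score, tolerance = 1e-8)
})

test_that("substituted residues lower identity by the substituted fraction", {
  set.seed(104)
  aas <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
           "F", "P", "S", "T", "W", "Y", "V")
  p <- paste(sample(aas, 100, replace = TRUE), collapse = "")
  chars <- strsplit(p, "")[[1L]]
  pos <- sample(100, 15)
  chars[pos] <- vapply(chars[pos], function(a) sample(setdiff(aas, a), 1), "")
  q <- paste(chars, collapse = "")
  oracle <- oracle_global_identity(p, q)
  h <- align_proteins(p, q)
  # local alignment may trim ragged ends; allow a small trimming tolerance
  expect_lt(abs(h$identity - oracle), 3)
  expect_lt(abs(h$identity - 85), 3)
})

test_that("unrelated random proteins rarely score above the thresholds", {
  set.seed(105)
  aas <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
           "F", "P", "S", "T", "W", "Y", "V")
  n_hit <- 0L
  for (i in 1:20) {
    a <- paste(sample(aas, 150, replace = TRUE), collapse = "")
    b <- paste(rev(sample(aas, 150, replace = TRUE)), collapse = "")
    h <- align_proteins(a, b)
    if (!is.null(h) && h$bit_score >= 50 && h$evalue <= 1e-3) n_hit <- n_hit + 1L
  }
  expect_lte(n_hit, 1L)  # >= 95% of trials give no qualifying hit
})
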