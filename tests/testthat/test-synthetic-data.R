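test_that("mutate_to_identity realizes the requested nucleotide identity", {
  set.seed(701)
  s <- random_dna(3000)
  for (target in c(99, 95, 80, 50)) {
    out <- mutate_to_identity(s, target, level = "nucleotide")
    a <- strsplit(s, "")[[1L]]
    b <- strsplit(out$sequence, "")[[1L]]
    realized <- 100 * mean(a == b)
    expect_equal(realized, out$realized_identity)
    expect_lt(abs(realized - target), 0.1)
  }
  expect_equal(mutate_to_identity(s, 100)$sequence, s)
  expect_error(mutate_to_identity(s, 20), "\\[30, 100\\]")
})

test_that("amino-acid mutation hits the protein identity and keeps the frame", {
  set.seed(702)
  cds <- random_cds(900)
  p0 <- translate_dna(cds)
  for (target in c(95, 70, 40)) {
    out <- mutate_to_identity(cds, target, level = "amino_acid")
    p1 <- translate_dna(out$sequence)  # still a clean CDS: no internal stops
    expect_equal(nchar(p1), nchar(p0))
    aa_ident <- 100 * mean(strsplit(p0, "")[[1L]] == strsplit(p1, "")[[1L]])
    expect_equal(aa_ident, out$realized_identity)
    expect_lt(abs(aa_ident - target), 1)
    expect_equal(substr(out$sequence, 1, 3), substr(cds, 1, 3))
  }
  expect_error(mutate_to_identity("ACGTA", 90, level = "amino_acid"),
               "divisible by 3")
})

test_that("host genomes have operon structure and the configured gene count", {
  set.seed(703)
  cfg <- scenario_config(seed = 703)
  h <- generate_host_genome(cfg, "h_c1", "SAGH")
  expect_equal(nrow(h$genes), cfg$host_genes_per_contig)
  expect_true(all(h$genes$end <= h$contigs$length))
  # roughly the configured characterized fraction
  expect_lt(abs(mean(h$genes$characterized) - cfg$characterized_fraction), 0.2)
  # every protein matches its CDS translation
  for (i in sample(nrow(h$genes), 5)) {
    cds <- substr(h$contigs$sequence, h$genes$start[i], h$genes$end[i])
    if (h$genes$strand[i] == "-") cds <- revcomp(cds)
    expect_equal(translate_dna(cds), h$genes$protein[i])
  }
})

test_that("viral genomes carry hallmarks, strand coherence and unknowns", {
  set.seed(704)
  cfg <- scenario_config(seed = 704)
  v <- generate_viral_genome(cfg, "caudovirales", "v1")
  expect_true(any(detect_hallmark(v$genes)$genes$hallmark_category != "none"))
  expect_gte(max(mean(v$genes$strand == "+"), mean(v$genes$strand == "-")),
             0.8)
  expect_gte(mean(!v$genes$characterized), 0.5)
  expect_gte(v$contigs$length, cfg$caudo_len_range[1L])
  expect_lte(v$contigs$length, cfg$caudo_len_range[2L])
  m <- generate_viral_genome(cfg, "microviridae", "v2")
  expect_gte(m$contigs$length, cfg$micro_len_range[1L])
  expect_lte(m$contigs$length, cfg$micro_len_range[2L])
})

test_that("metagenome reads are faithful substrings with recorded provenance", {
  set.seed(705)
  comm <- data.frame(genome_id = c("gA", "gB"),
                     sequence = c(random_dna(4000), random_dna(2000)),
                     copy_number = c(1, 5), circular = c(FALSE, TRUE),
                     stringsAsFactors = FALSE)
  rd <- simulate_metagenome(comm, n_reads = 200, read_length = 300)
  expect_length(rd$reads, 200L)
  expect_equal(nrow(rd$truth), 200L)
  for (i in sample(200, 20)) {
    tr <- rd$truth[i, ]
    src <- comm$sequence[comm$genome_id == tr$genome_id]
    if (comm$circular[comm$genome_id == tr$genome_id]) src <- paste0(src, src)
    expected <- substr(src, tr$start, tr$start + 299L)
    if (tr$strand == "-") expected <- revcomp(expected)
    expect_equal(rd$reads[[i]], expected)
  }
  # copy number biases sampling toward the high-copy genome
  expect_gt(sum(rd$truth$genome_id == "gB"), 100)
  # substitution errors hit roughly the requested rate
  rd2 <- simulate_metagenome(comm, n_reads = 50, read_length = 300,
                             error_rate = 0.05)
  mm <- vapply(seq_len(50), function(i) {
    tr <- rd2$truth[i, ]
    src <- comm$sequence[comm$genome_id == tr$genome_id]
    if (comm$circular[comm$genome_id == tr$genome_id]) src <- paste0(src, src)
    expected <- substr(src, tr$start, tr$start + 299L)
    if (tr$strand == "-") expected <- revcomp(expected)
    sum(strsplit(rd2$reads[[i]], "")[[1L]] != strsplit(expected, "")[[1L]])
  }, 0)
  expect_lt(abs(mean(mm) / 300 - 0.05), 0.02)
})

test_that("planting a prophage records exact coordinates and masks the block", {
  set.seed(706)
  cfg <- scenario_config(seed = 706)
  sag <- generate_host_genome(cfg, "s_c1", "SAGS")
  sag$truth <- list()
  virus <- generate_viral_genome(cfg, "caudovirales", "vp")
  out <- plant_infection(sag, virus, "prophage")
  tr <- out$truth[[1L]]
  expect_equal(tr$mode, "prophage")
  block <- substr(out$contigs$sequence, tr$start, tr$end)
  # the inserted block is a verbatim slice of the viral genome
  expect_gt(nchar(block), 1000L)
  expect_true(grepl(block, virus$contigs$sequence, fixed = TRUE))
  # inserted genes are annotation-masked (defective prophages are not
  # recognizable from annotation)
  ins <- out$genes[out$genes$start >= tr$start & out$genes$end <= tr$end, ]
  expect_equal(nrow(ins), 10L)
  expect_true(all(!ins$characterized))
  expect_true(all(ins$annotation_text == "hypothetical protein"))
  expect_true(all(ins$hallmark_category == "none"))
  # host gene count increased by the block size
  expect_equal(nrow(out$genes), nrow(sag$genes) + nrow(ins))
})

test_that("planting a CRISPR array yields a valid array with the viral spacer", {
  set.seed(707)
  cfg <- scenario_config(seed = 707)
  sag <- generate_host_genome(cfg, "s_c1", "SAGS")
  sag$truth <- list()
  virus <- generate_viral_genome(cfg, "caudovirales", "vc")
  out <- plant_infection(sag, virus, "crispr_spacer")
  tr <- out$truth[[1L]]
  expect_equal(tr$mode, "crispr_spacer")
  arrays <- find_crispr_arrays(out$contigs)
  expect_equal(length(arrays), 1L)
  spacers <- arrays[[1L]]$spacers$sequence
  # at least one spacer comes verbatim from the virus (either strand)
  vseq <- virus$contigs$sequence
  hitv <- vapply(spacers, function(sp) {
    grepl(sp, vseq, fixed = TRUE) || grepl(revcomp(sp), vseq, fixed = TRUE)
  }, TRUE)
  expect_true(any(hitv))
})

test_that("the default scenario is deterministic in its seed", {
  cfg <- scenario_config(seed = 9, n_sags = 6L)
  s1 <- simulate_scenario(cfg)
  s2 <- simulate_scenario(cfg)
  expect_identical(s1$contigs, s2$contigs)
  expect_identical(s1$genes, s2$genes)
  expect_identical(s1$infections, s2$infections)
  s3 <- simulate_scenario(scenario_config(seed = 10, n_sags = 6L))
  expect_false(identical(s1$contigs$sequence, s3$contigs$sequence))
})

test_that("scenario ground truth is structurally consistent", {
  sc <- simulate_scenario(scenario_config(seed = 11, n_sags = 9L))
  expect_equal(nrow(sc$sag_info), 9L)
  # every contig's genes lie inside it
  for (cid in unique(sc$genes$contig_id)) {
    clen <- sc$contigs$length[match(cid, sc$contigs$id)]
    g <- sc$genes[sc$genes$contig_id == cid, ]
    expect_true(all(g$start >= 1L & g$end <= clen))
  }
  # every recorded infection has matching truth entries
  for (i in seq_len(nrow(sc$infections))) {
    sid <- sc$infections$sag_id[i]
    modes <- vapply(sc$truth[[sid]], function(x) x$mode, "")
    expect_true(sc$infections$mode[i] %in% modes)
  }
  # current infections add viral contigs to the SAG assembly
  cur <- unique(sc$infections$sag_id[sc$infections$mode == "current"])
  for (sid in cur) {
    expect_gt(sum(sc$contigs$source_id == sid), 1L)
  }
})

test_that("scenario files round trip through the on-disk layout", {
  sc <- simulate_scenario(scenario_config(seed = 12, n_sags = 3L))
  outdir <- tempfile("scen")
  on.exit(unlink(outdir, recursive = TRUE), add = TRUE)
  write_scenario(sc, outdir)
  expect_true(all(file.exists(file.path(
    outdir, c("contigs.fasta", "genes.gff3", "ground_truth.json",
              "MANIFEST")))))
  contigs <- read_fasta(file.path(outdir, "contigs.fasta"))
  expect_setequal(contigs$id, sc$contigs$id)
  expect_equal(contigs$sequence[match(sc$contigs$id, contigs$id)],
               sc$contigs$sequence)
  genes <- read_gff3(file.path(outdir, "genes.gff3"), contigs)
  expect_equal(nrow(genes), nrow(sc$genes))
})
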