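test_that("gene-architecture metrics match a hand-computed example", {
  # 5 genes: sizes 300, 600, 300, 900, 300; strands + + - - +;
  # characterized T F F T F
  g <- gene_table(
    id = paste0("g", 1:5), contig_id = "c1",
    start = c(1L, 401L, 1101L, 1501L, 2501L),
    end = c(300L, 1000L, 1400L, 2400L, 2800L),
    strand = c("+", "+", "-", "-", "+"),
    characterized = c(TRUE, FALSE, FALSE, TRUE, FALSE)
  )
  m <- compute_metrics(g)
  expect_equal(m$avg_gene_size, (300 + 600 + 300 + 900 + 300) / 5)
  expect_equal(m$strand_change_ratio, 2 / 5)  # switches at g2->g3 and g4->g5
  expect_equal(m$uncharacterized_ratio, 3 / 5)
  expect_equal(m$n_genes, 5L)
})

test_that("metrics are order-invariant and a single gene has no strand change", {
  g <- gene_table(paste0("g", 1:3), "c1", c(500L, 1L, 900L),
                  c(800L, 400L, 1200L), c("-", "+", "+"),
                  characterized = c(FALSE, TRUE, TRUE))
  m1 <- compute_metrics(g)
  m2 <- compute_metrics(g[c(3, 1, 2), ])
  expect_equal(m1, m2)
  expect_equal(m1$strand_change_ratio, 2 / 3)  # sorted strands: + - +
  g1 <- gene_table("g1", "c1", 1L, 300L, "-")
  expect_equal(compute_metrics(g1)$strand_change_ratio, 0)
  expect_error(compute_metrics(g1[0, ]), "at least one gene")
  expect_error(compute_metrics(gene_table(c("a", "b"), c("c1", "c2"),
                                          c(1L, 1L), c(9L, 9L), "+")),
               "single contig")
})

test_that("hallmark keywords flag contigs and negations are guarded", {
  g <- gene_table(
    id = paste0("g", 1:6), contig_id = c("v1", "v1", "v2", "h1", "h2", "h3"),
    start = rep(1L, 6), end = rep(900L, 6), strand = "+",
    annotation_text = c("Major Capsid Protein", "hypothetical protein",
                        "phage TAIL fiber", "DNA gyrase subunit A",
                        "tailless phage remnant", "portal vertex protein")
  )
  out <- detect_hallmark(g)
  expect_setequal(out$calls$contig_id, c("v1", "v2", "h3"))
  expect_true(all(out$calls$method == "hallmark"))
  expect_equal(out$genes$hallmark_category[1L], "capsid")
  expect_equal(out$genes$hallmark_category[3L], "tail")   # case-insensitive
  expect_equal(out$genes$hallmark_category[5L], "none")   # stop-list guard
  expect_equal(out$genes$hallmark_category[6L], "portal")
})

test_that("association expansion needs half the genes hitting one reference", {
  genes <- gene_table(
    id = c(paste0("v", 1:4), paste0("a", 1:4), paste0("b", 1:4)),
    contig_id = rep(c("det1", "candA", "candB"), each = 4),
    start = rep(c(1L, 1001L, 2001L, 3001L), 3),
    end = rep(c(900L, 1900L, 2900L, 3900L), 3), strand = "+"
  )
  mk <- function(q, s, bit = 80, ev = 1e-9) {
    hit_table(q, s, identity = 60, aln_length = 200L, q_start = 1L,
              q_end = 200L, s_start = 1L, s_end = 200L, evalue = ev,
              bit_score = bit)
  }
  hits <- rbind(
    mk("a1", "v1"), mk("a2", "v2"),         # candA: 2/4 genes -> flagged
    mk("b1", "v3"),                          # candB: 1/4 -> not flagged
    mk("b2", "v4", bit = 40),                # fails bit threshold
    mk("b3", "v1", ev = 1e-2)                # fails evalue threshold
  )
  calls <- expand_by_association(c("candA", "candB"), "det1", hits, genes)
  expect_equal(calls$contig_id, "candA")
  expect_match(calls$evidence, "ref=det1")
  expect_match(calls$evidence, "frac=0.500")
})

test_that("association expansion iterates to a fixed point", {
  genes <- gene_table(
    id = c(paste0("v", 1:2), paste0("a", 1:2), paste0("b", 1:2)),
    contig_id = rep(c("det1", "candA", "candB"), each = 2),
    start = rep(c(1L, 1001L), 3), end = rep(c(900L, 1900L), 3), strand = "+"
  )
  mk <- function(q, s) {
    hit_table(q, s, identity = 60, aln_length = 200L, q_start = 1L,
              q_end = 200L, s_start = 1L, s_end = 200L, evalue = 1e-9,
              bit_score = 80)
  }
  # candB only matches candA: reachable solely through the second pass
  hits <- rbind(mk("a1", "v1"), mk("a2", "v2"), mk("b1", "a1"), mk("b2", "a2"))
  calls <- expand_by_association(c("candA", "candB"), "det1", hits, genes)
  expect_setequal(calls$contig_id, c("candA", "candB"))
  bad <- rbind(hits, mk("zz", "v1"))
  expect_error(expand_by_association("candA", "det1", bad, genes),
               "unknown gene: zz")
})

test_that("virome support needs three distinct genes at 90 percent identity", {
  genes <- gene_table(paste0("g", 1:4), "c1",
                      c(1L, 1001L, 2001L, 3001L),
                      c(900L, 1900L, 2900L, 3900L), "+")
  mk <- function(q, s, id) {
    hit_table(q, s, identity = id, aln_length = 100L, q_start = 1L,
              q_end = 100L, s_start = 1L, s_end = 100L, evalue = 1e-9,
              bit_score = 80)
  }
  two <- rbind(mk("r1", "g1", 95), mk("r2", "g2", 95), mk("r3", "g2", 99),
               mk("r4", "g3", 89.9))
  expect_equal(nrow(detect_by_virome_support(genes, two)), 0L)
  three <- rbind(two, mk("r5", "g3", 90), mk("r6", "g4", 91))
  calls <- detect_by_virome_support(genes, three)
  expect_equal(calls$contig_id, "c1")
  expect_equal(calls$method, "virome_support")
})

test_that("region scan matches the exhaustive all-window oracle on a worked case", {
  # genes 1-6 characterized mixed-strand host; genes 7-16 uncharacterized
  # same-strand block; genes 17-20 host again
  g <- gene_table(
    id = sprintf("g%02d", 1:20), contig_id = "c1",
    start = seq(1L, by = 400L, length.out = 20),
    end = seq(300L, by = 400L, length.out = 20),
    strand = c("+", "-", "+", "-", "+", "-", rep("+", 10), "-", "+", "-", "+"),
    characterized = c(rep(TRUE, 6), rep(FALSE, 10), rep(TRUE, 4))
  )
  calls <- scan_unknown_regions(g)
  oracle <- oracle_scan_regions(g)
  expect_equal(calls[, c("gene_from", "gene_to")], oracle,
               ignore_attr = TRUE)
  # union-of-windows semantics: the merged region must contain the planted
  # block; qualifying windows that reach into the flanks may extend it
  expect_equal(nrow(calls), 1L)
  expect_lte(calls$gene_from, 7L)
  expect_gte(calls$gene_to, 16L)
})

test_that("region scan equals the brute-force oracle on random architectures", {
  set.seed(301)
  for (i in 1:120) {
    n <- sample(8:30, 1)
    g <- random_gene_arch(n, p_char = runif(1, 0.2, 0.8),
                          p_plus = runif(1, 0.2, 0.8))
    calls <- scan_unknown_regions(g)
    oracle <- oracle_scan_regions(g)
    expect_equal(calls[, c("gene_from", "gene_to")], oracle,
                 ignore_attr = TRUE)
  }
})

test_that("short contigs yield no regions and thresholds are inclusive", {
  g <- random_gene_arch(7)  # below the 8-gene minimum
  expect_equal(nrow(scan_unknown_regions(g)), 0L)
  # exactly at both thresholds: 4/8 uncharacterized, strand fraction 0.875;
  # thresholds are inclusive so the window qualifies
  g8 <- gene_table(sprintf("g%d", 1:8), "c1",
                   seq(1L, by = 400L, length.out = 8),
                   seq(300L, by = 400L, length.out = 8),
                   c(rep("+", 7), "-"),
                   characterized = rep(c(TRUE, FALSE), 4))
  calls <- scan_unknown_regions(g8)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$gene_from, 1L)
  expect_equal(calls$gene_to, 8L)
  # one fewer uncharacterized gene and it no longer qualifies
  g8$characterized[2L] <- TRUE
  expect_equal(nrow(scan_unknown_regions(g8)), 0L)
})

test_that("classification precedence runs hallmark > association > support > region", {
  contigs <- contig_table(paste0("c", 1:5), strrep("ACGT", 250))
  genes <- do.call(rbind, lapply(paste0("c", 1:5), function(cid) {
    gene_table(paste0(cid, "_g", 1:10), cid,
               seq(1L, by = 100L, length.out = 10),
               seq(90L, by = 100L, length.out = 10), "+",
               characterized = FALSE)
  }))
  calls <- rbind(
    viral_call_table("c1", "hallmark", 1L, 10L, "e"),
    viral_call_table("c1", "region_metric", 1L, 10L, "e"),
    viral_call_table("c2", "association", 1L, 10L, "e"),
    viral_call_table("c3", "virome_support", 1L, 10L, "e"),
    viral_call_table("c4", "region_metric", 1L, 10L, "e"),
    viral_call_table("c5", "region_metric", 2L, 8L, "e")  # 7/10 < 0.8
  )
  lab <- classify_contigs(contigs, genes, calls)
  expect_equal(lab$label, c("viral_hallmark", "viral_hallmark",
                            "viral_putative", "viral_putative", "microbial"))
  expect_equal(lab$method[1:4],
               c("hallmark", "association", "virome_support", "region_metric"))
  expect_true(lab$has_embedded_region[5L])
  expect_false(any(lab$has_embedded_region[1:4]))
})

test_that("whole-contig promotion also requires viral-like architecture", {
  # region calls covering >= 80% of genes, but the contig itself is mixed
  # strand and mostly characterized: stays microbial with embedded region
  contigs <- contig_table("c1", strrep("ACGT", 250))
  genes <- gene_table(paste0("g", 1:10), "c1",
                      seq(1L, by = 100L, length.out = 10),
                      seq(90L, by = 100L, length.out = 10),
                      rep(c("+", "-"), 5), characterized = rep(TRUE, 10))
  calls <- viral_call_table("c1", "region_metric", 1L, 9L, "e")
  lab <- classify_contigs(contigs, genes, calls)
  expect_equal(lab$label, "microbial")
  expect_true(lab$has_embedded_region)
})
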