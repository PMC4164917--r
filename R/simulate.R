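BASES <- c("A", "C", "G", "T")
SENSE_CODONS <- {
  all3 <- as.vector(outer(as.vector(outer(BASES, BASES, paste0)), BASES, paste0))
  setdiff(all3, c("TAA", "TAG", "TGA"))
}
HOST_VOCAB <- c(
  "DNA polymerase III subunit alpha", "ABC transporter ATP-binding protein",
  "50S ribosomal protein L2", "NADH dehydrogenase subunit B",
  "dissimilatory sulfite reductase subunit A", "elongation factor Tu",
  "cell division protein FtsZ", "ATP synthase subunit beta",
  "chaperonin GroEL", "DNA gyrase subunit A", "RuBisCO form II",
  "cytochrome c oxidase subunit I"
)
VIRAL_NONHALLMARK_VOCAB <- c(
  "DNA polymerase A", "single-stranded DNA binding protein", "endolysin",
  "holin", "thymidylate synthase", "DNA primase", "replication protein"
)
HALLMARK_ANNOTATIONS <- c(
  capsid = "major capsid protein", terminase = "terminase large subunit",
  portal = "portal protein", tail = "tail fiber protein",
  virion_structure = "virion structure protein"
)

random_dna <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

#' Random sequence guaranteed free of repeated k-mers
#'
#' Rejection-samples random sequence until no exact k-mer occurs twice; used
#' to build negative controls for repeat/CRISPR detection.
#'
#' @param n sequence length.
#' @param k duplicate-free k-mer size (default 19, the minimum CRISPR repeat
#'   length).
#' @param max_tries rejection budget.
#' @return a nucleotide string.
#' @export
random_dna_norepeat <- function(n, k = 19L, max_tries = 100L) {
  for (i in seq_len(max_tries)) {
    s <- random_dna(n)
    km <- substring(s, 1:(n - k + 1L), k:n)
    if (!anyDuplicated(km)) return(s)
  }
  stop("could not generate repeat-free sequence")
}

# a synthetic CDS of `len` nt (multiple of 3, >= 9): start codon, sense
# codons, stop codon
random_cds <- function(len) {
  stopifnot(len %% 3L == 0L, len >= 9L)
  paste0("ATG",
         paste(sample(SENSE_CODONS, len / 3L - 2L, replace = TRUE),
               collapse = ""),
         sample(c("TAA", "TAG", "TGA"), 1L))
}

#' Lay out synthetic genes along a contig
#'
#' Builds a contig sequence from freshly sampled CDSs of the given lengths
#' and strands, separated by random intergenic gaps, and returns the exact
#' gene coordinates. This is the low-level primitive underneath the genome
#' generators; annotation fields of the returned gene table are left at
#' their defaults for the caller to fill.
#'
#' @param contig_id contig identifier used for gene ids.
#' @param lengths CDS lengths in nt (each a multiple of 3, >= 9).
#' @param strands `"+"`/`"-"` per gene.
#' @param intergenic inclusive range of intergenic gap lengths (bp).
#' @return list with `sequence` and `genes` (gene table with proteins).
#' @export
layout_genes <- function(contig_id, lengths, strands, intergenic = c(10L, 40L)) {
  seqs <- vapply(lengths, random_cds, "")
  gaps <- sample(intergenic[1L]:intergenic[2L], length(lengths) + 1L,
                 replace = TRUE)
  pieces <- character(0)
  start <- integer(length(lengths)); end <- integer(length(lengths))
  pos <- 0L
  for (i in seq_along(lengths)) {
    pieces <- c(pieces, random_dna(gaps[i]))
    pos <- pos + gaps[i]
    placed <- if (strands[i] == "+") seqs[i] else revcomp(seqs[i])
    pieces <- c(pieces, placed)
    start[i] <- pos + 1L
    end[i] <- pos + lengths[i]
    pos <- end[i]
  }
  pieces <- c(pieces, random_dna(gaps[length(gaps)]))
  genes <- gene_table(
    id = paste0(contig_id, "_g", seq_along(lengths)),
    contig_id = contig_id, start = start, end = end, strand = strands,
    protein = vapply(seqs, translate_dna, "")
  )
  list(sequence = paste(pieces, collapse = ""), genes = genes)
}

# gene lengths in nt (multiples of 3), log-normal
draw_gene_lengths <- function(n, meanlog, sdlog, min_len = 150L) {
  len <- pmax(min_len, round(rlnorm(n, meanlog, sdlog)))
  len <- len - len %% 3L
  pmax(min_len, len)
}

#' Scenario configuration for the synthetic-data generator
#'
#' Bundles every tunable of the end-to-end generator with the defaults that
#' define the package's reference study conditions: 30 SAGs spread over
#' three depth labels with infection probabilities 0.08 / 0.28 / 0.47
#' (shallow to deep), ssDNA-dsDNA co-infection linkage 0.9, host genes in
#' operon blocks (mean block 5, characterized fraction 0.7), and viral
#' genomes with 70% uncharacterized genes and 0.95 strand coherence.
#'
#' @param seed integer seed fixing all downstream randomness.
#' @param n_sags number of SAGs (split evenly over `depths`).
#' @param depths depth labels.
#' @param infection_prob per-depth current-infection probability.
#' @param coinfection_linkage probability that an ssDNA-infected SAG also
#'   carries the dsDNA virus.
#' @param prophage_prob,crispr_prob per-SAG past-infection probabilities.
#' @param host_genes_per_contig,host_gene_meanlog,host_gene_sdlog host gene
#'   count and log-normal gene-length parameters.
#' @param characterized_fraction,operon_mean_block host annotation fraction
#'   and mean same-strand operon block length.
#' @param caudo_len_range,micro_len_range viral genome length ranges (bp).
#' @param viral_uncharacterized,strand_coherence viral architecture.
#' @param viral_gene_meanlog,viral_gene_sdlog viral gene-length parameters.
#' @param n_reads,read_length,error_rate metagenome simulation defaults.
#' @param linker_amplified metagenome library flag (drives the ssDNA
#'   inconclusive rule downstream).
#' @return a list of class `scenario_config`.
#' @export
scenario_config <- function(seed = 1L,
                            n_sags = 30L,
                            depths = c("100m", "150m", "185m"),
                            infection_prob = c(0.08, 0.28, 0.47),
                            coinfection_linkage = 0.9,
                            prophage_prob = 0.15,
                            crispr_prob = 0.2,
                            host_genes_per_contig = 50L,
                            host_gene_meanlog = log(750),
                            host_gene_sdlog = 0.3,
                            characterized_fraction = 0.7,
                            operon_mean_block = 5,
                            caudo_len_range = c(15000L, 30000L),
                            micro_len_range = c(4500L, 6500L),
                            viral_uncharacterized = 0.7,
                            strand_coherence = 0.95,
                            viral_gene_meanlog = log(450),
                            viral_gene_sdlog = 0.3,
                            n_reads = 2000L,
                            read_length = 500L,
                            error_rate = 0,
                            linker_amplified = FALSE) {
  cfg <- as.list(environment())
  stopifnot(all(infection_prob >= 0 & infection_prob <= 1),
            coinfection_linkage >= 0 && coinfection_linkage <= 1,
            characterized_fraction >= 0 && characterized_fraction <= 1,
            viral_uncharacterized >= 0 && viral_uncharacterized <= 1,
            length(infection_prob) == length(depths))
  structure(cfg, class = "scenario_config")
}

#' Generate a host (microbial) contig with operon-structured genes
#'
#' Genes come in same-strand operon blocks (geometric block length with the
#' configured mean, so the strand-change ratio is about 1/mean block
#' length); each gene is characterized with the configured probability and
#' annotated from a housekeeping vocabulary, uncharacterized genes as
#' hypothetical proteins.
#'
#' @param config a [scenario_config()].
#' @param contig_id,source_id identifiers.
#' @param n_genes number of genes (default from config).
#' @return list with `contigs` (one-row contig table) and `genes`.
#' @export
generate_host_genome <- function(config, contig_id = "host1",
                                 source_id = "SAG1", n_genes = NULL) {
  if (is.null(n_genes)) n_genes <- config$host_genes_per_contig
  lengths <- draw_gene_lengths(n_genes, config$host_gene_meanlog,
                               config$host_gene_sdlog)
  switch_p <- 1 / config$operon_mean_block
  strands <- character(n_genes)
  strands[1L] <- sample(c("+", "-"), 1L)
  for (i in seq_len(n_genes - 1L)) {
    strands[i + 1L] <- if (runif(1) < switch_p) {
      setdiff(c("+", "-"), strands[i])
    } else strands[i]
  }
  lay <- layout_genes(contig_id, lengths, strands)
  genes <- lay$genes
  genes$characterized <- runif(n_genes) < config$characterized_fraction
  genes$annotation_text <- ifelse(
    genes$characterized,
    sample(HOST_VOCAB, n_genes, replace = TRUE),
    "hypothetical protein")
  list(contigs = contig_table(contig_id, lay$sequence, source_id,
                              role = "sag_assembly"),
       genes = genes)
}

#' Generate a viral genome (tailed dsDNA phage or small circular ssDNA phage)
#'
#' Tailed-phage (`caudovirales`) genomes are linear, 15-60 kb by default,
#' carry at least one capsid and one terminase hallmark gene, have a high
#' uncharacterized-gene fraction (default 0.7) and strong strand coherence.
#' `microviridae` genomes are 4.5-6.5 kb, circular, flagged ssDNA, with a
#' major-capsid hallmark gene.
#'
#' @param config a [scenario_config()].
#' @param kind `"caudovirales"` or `"microviridae"`.
#' @param contig_id identifier.
#' @return list: `contigs`, `genes`, `kind`, `circular`, `ssdna`.
#' @export
generate_viral_genome <- function(config, kind = c("caudovirales",
                                                   "microviridae"),
                                  contig_id = "virus1") {
  kind <- match.arg(kind)
  target <- if (kind == "caudovirales") {
    sample(config$caudo_len_range[1L]:config$caudo_len_range[2L], 1L)
  } else {
    sample(config$micro_len_range[1L]:config$micro_len_range[2L], 1L)
  }
  lengths <- integer(0)
  while (sum(lengths) + 20L * (length(lengths) + 1L) < target) {
    lengths <- c(lengths, draw_gene_lengths(1L, config$viral_gene_meanlog,
                                            config$viral_gene_sdlog))
  }
  n <- length(lengths)
  major <- sample(c("+", "-"), 1L)
  strands <- ifelse(runif(n) < config$strand_coherence, major,
                    setdiff(c("+", "-"), major))
  lay <- layout_genes(contig_id, lengths, strands, intergenic = c(5L, 20L))
  genes <- lay$genes
  # hallmark genes: always annotated with the keyword strings
  hallmarks <- if (kind == "caudovirales") {
    cats <- c("capsid", "terminase")
    if (n >= 8L) cats <- c(cats, sample(c("portal", "tail"), 1L))
    cats
  } else "capsid"
  hm_idx <- sample(n, length(hallmarks))
  unchar <- runif(n) < config$viral_uncharacterized
  unchar[hm_idx] <- FALSE
  genes$characterized <- !unchar
  genes$annotation_text <- ifelse(
    genes$characterized,
    sample(VIRAL_NONHALLMARK_VOCAB, n, replace = TRUE),
    "hypothetical protein")
  genes$annotation_text[hm_idx] <- HALLMARK_ANNOTATIONS[hallmarks]
  genes$hallmark_category[hm_idx] <- hallmarks
  list(contigs = contig_table(contig_id, lay$sequence, "viral_pool",
                              role = "viral_reference"),
       genes = genes, kind = kind,
       circular = kind == "microviridae", ssdna = kind == "microviridae")
}

#' Mask database annotations of genes
#'
#' Emulates a completely novel virus: every gene becomes uncharacterized
#' ("hypothetical protein", no hallmark category), leaving only
#' gene-architecture signal for detection.
#'
#' @param genes gene table.
#' @return the masked gene table.
#' @export
mask_annotations <- function(genes) {
  genes$characterized <- FALSE
  genes$annotation_text <- "hypothetical protein"
  genes$hallmark_category <- "none"
  genes
}

#' Mutate a sequence to a target identity
#'
#' Nucleotide level: random substitutions (always to a different base) at
#' exactly the number of positions giving the realized identity closest to
#' the target. Amino-acid level: the sequence is treated as a CDS; internal
#' codons are replaced by codons of a *different* amino acid (never a stop),
#' so nucleotide and protein identities stay jointly consistent.
#'
#' @param sequence nucleotide string (a CDS for `level = "amino_acid"`).
#' @param target_identity percent, in `[30, 100]`.
#' @param level `"nucleotide"` or `"amino_acid"`.
#' @return list with `sequence` and `realized_identity` (percent; amino-acid
#'   identity for `level = "amino_acid"`).
#' @export
mutate_to_identity <- function(sequence, target_identity,
                               level = c("nucleotide", "amino_acid")) {
  level <- match.arg(level)
  if (target_identity < 30 || target_identity > 100) {
    stop("target identity must lie in [30, 100]")
  }
  if (target_identity == 100) {
    return(list(sequence = sequence, realized_identity = 100))
  }
  chars <- strsplit(sequence, "")[[1L]]
  if (level == "nucleotide") {
    L <- length(chars)
    n_sub <- round((1 - target_identity / 100) * L)
    if (n_sub > L) stop("unreachable target identity")
    pos <- sample(L, n_sub)
    chars[pos] <- vapply(chars[pos], function(b) sample(setdiff(BASES, b), 1L), "")
    list(sequence = paste(chars, collapse = ""),
         realized_identity = 100 * (1 - n_sub / L))
  } else {
    L <- length(chars)
    if (L %% 3L != 0L) stop("amino-acid level mutation requires CDS length divisible by 3")
    n_cod <- L / 3L
    aa_len <- n_cod - 1L                      # trailing stop excluded
    internal <- 2:(n_cod - 1L)                # keep start and stop codons
    n_mut <- round((1 - target_identity / 100) * aa_len)
    if (n_mut > length(internal)) stop("unreachable target identity")
    gc <- GENETIC_CODE_11
    pick <- sample(internal, n_mut)
    for (ci in pick) {
      from <- 3L * (ci - 1L) + 1L
      old_codon <- paste(chars[from:(from + 2L)], collapse = "")
      old_aa <- gc[[old_codon]]
      alt <- names(gc)[gc != old_aa & gc != "*"]
      new_codon <- sample(alt, 1L)
      chars[from:(from + 2L)] <- strsplit(new_codon, "")[[1L]]
    }
    list(sequence = paste(chars, collapse = ""),
         realized_identity = 100 * (1 - n_mut / aa_len))
  }
}

#' Mutate every gene of a genome to a target amino-acid identity
#'
#' Applies [mutate_to_identity()] at the amino-acid level to each gene's CDS
#' in place (intergenic sequence untouched) and records per-gene realized
#' identities.
#'
#' @param genome a genome list (`contigs`, `genes`).
#' @param target_identity percent amino-acid identity.
#' @return the genome with mutated sequence and
#'   `realized_identity` (named per-gene vector) attached.
#' @export
mutate_genome_aa <- function(genome, target_identity) {
  seq <- genome$contigs$sequence[1L]
  genes <- genome$genes
  realized <- setNames(numeric(nrow(genes)), genes$id)
  for (i in seq_len(nrow(genes))) {
    cds <- substr(seq, genes$start[i], genes$end[i])
    if (genes$strand[i] == "-") cds <- revcomp(cds)
    m <- mutate_to_identity(cds, target_identity, level = "amino_acid")
    placed <- if (genes$strand[i] == "-") revcomp(m$sequence) else m$sequence
    substr(seq, genes$start[i], genes$end[i]) <- placed
    realized[i] <- m$realized_identity
  }
  genome$contigs$sequence[1L] <- seq
  genome$realized_identity <- realized
  genome
}

#' Simulate a metagenome read set from a community
#'
#' Reads are drawn from genomes with probability proportional to length
#' times copy number; start positions are uniform; circular genomes wrap;
#' substitution errors occur independently at `error_rate`; strands are
#' random. Read provenance is recorded as ground truth.
#'
#' @param community `data.frame` with columns `genome_id`, `sequence`,
#'   `copy_number`, and optionally `circular` (default `FALSE`).
#' @param read_length,n_reads,error_rate read-set parameters.
#' @return list: `reads` (named character vector) and `truth`
#'   (`data.frame`: `read_id`, `genome_id`, `start`, `strand`).
#' @export
simulate_metagenome <- function(community, read_length = 500L,
                                n_reads = 1000L, error_rate = 0) {
  stopifnot(all(community$copy_number > 0))
  if (is.null(community$circular)) community$circular <- FALSE
  len <- nchar(community$sequence)
  usable <- community$circular | len >= read_length
  if (any(!usable)) {
    warning("skipping linear genome(s) shorter than the read length: ",
            paste(community$genome_id[!usable], collapse = ", "))
    community <- community[usable, , drop = FALSE]
    len <- len[usable]
  }
  if (nrow(community) == 0L) stop("no usable genomes in community")
  w <- len * community$copy_number
  gi <- sample.int(nrow(community), n_reads, replace = TRUE, prob = w)
  reads <- character(n_reads)
  starts <- integer(n_reads)
  strands <- sample(c("+", "-"), n_reads, replace = TRUE)
  for (i in seq_len(n_reads)) {
    g <- gi[i]
    if (community$circular[g]) {
      st <- sample.int(len[g], 1L)
      doubled <- paste0(community$sequence[g], community$sequence[g])
      r <- substr(doubled, st, st + read_length - 1L)
    } else {
      st <- sample.int(len[g] - read_length + 1L, 1L)
      r <- substr(community$sequence[g], st, st + read_length - 1L)
    }
    if (error_rate > 0) {
      rc <- strsplit(r, "")[[1L]]
      err <- which(runif(length(rc)) < error_rate)
      if (length(err) > 0L) {
        rc[err] <- vapply(rc[err], function(b) sample(setdiff(BASES, b), 1L), "")
        r <- paste(rc, collapse = "")
      }
    }
    if (strands[i] == "-") r <- revcomp(r)
    reads[i] <- r
    starts[i] <- st
  }
  ids <- sprintf("read%06d", seq_len(n_reads))
  list(reads = setNames(reads, ids),
       truth = data.frame(read_id = ids, genome_id = community$genome_id[gi],
                          start = starts, strand = strands,
                          stringsAsFactors = FALSE))
}

# ---- planting infections -----------------------------------------------------

# relabel a viral genome's contigs/genes with a SAG-specific prefix
rebrand_genome <- function(virus, new_contig_id, source_id) {
  old <- virus$contigs$id[1L]
  virus$contigs$id[1L] <- new_contig_id
  virus$contigs$source_id[1L] <- source_id
  virus$genes$contig_id <- new_contig_id
  virus$genes$id <- sub(paste0("^", old), new_contig_id, virus$genes$id)
  virus
}

#' Plant an infection into a SAG assembly
#'
#' * `current`: the virus is added to the SAG as its own contig(s).
#' * `prophage`: a contiguous block of viral genes is inserted inside the
#'   host contig with host genes flanking on both sides; the viral genes are
#'   annotation-masked (defective remnant). With `conserve_into`, the same
#'   block is inserted into a second SAG so conservation-based detection can
#'   succeed.
#' * `crispr_spacer`: a repeat-spacer array is inserted into an intergenic
#'   position, with one spacer copied verbatim from the virus. Array
#'   boundaries are made identifiable (the characters flanking the repeat
#'   copies are not all equal), so the planted coordinates are the unique
#'   maximal-repeat answer.
#'
#' @param sag list with `contigs`, `genes` (and optionally prior plantings).
#' @param virus a genome from [generate_viral_genome()].
#' @param mode `"current"`, `"prophage"` or `"crispr_spacer"`.
#' @param conserve_into optional second SAG (prophage mode); returned as
#'   `$conserved_sag`.
#' @param n_prophage_genes number of viral genes in the prophage block.
#' @param repeat_len,spacer_len,n_spacers CRISPR array geometry.
#' @return the SAG with the planting applied plus a `truth` entry
#'   describing exact coordinates.
#' @export
plant_infection <- function(sag, virus,
                            mode = c("current", "prophage", "crispr_spacer"),
                            conserve_into = NULL, n_prophage_genes = 10L,
                            repeat_len = 28L, spacer_len = 32L,
                            n_spacers = 3L) {
  mode <- match.arg(mode)
  src <- sag$contigs$source_id[1L]
  if (mode == "current") {
    vc_id <- paste0(src, "_", virus$contigs$id[1L])
    v <- rebrand_genome(virus, vc_id, src)
    v$contigs$role <- "sag_assembly"
    sag$contigs <- rbind(sag$contigs, v$contigs)
    sag$genes <- rbind(sag$genes, v$genes)
    sag$truth <- c(sag$truth, list(list(
      mode = "current", contig_id = vc_id, virus_id = virus$contigs$id[1L],
      kind = virus$kind)))
    return(sag)
  }
  if (mode == "prophage") {
    vg <- order_genes(virus$genes)
    n_prophage_genes <- min(n_prophage_genes, nrow(vg))
    from_g <- sample(seq_len(nrow(vg) - n_prophage_genes + 1L), 1L)
    to_g <- from_g + n_prophage_genes - 1L
    block_from <- vg$start[from_g]; block_to <- vg$end[to_g]
    block <- substr(virus$contigs$sequence[1L], block_from, block_to)
    block_genes <- vg[from_g:to_g, , drop = FALSE]
    insert_block <- function(s, tag) {
      host_genes <- order_genes(s$genes[s$genes$contig_id == s$contigs$id[1L], ,
                                        drop = FALSE])
      n <- nrow(host_genes)
      # avoid insertion points inside already planted intergenic features
      forbidden <- lapply(s$truth, function(tr) {
        if (identical(tr$mode, "crispr_spacer") &&
            tr$contig_id == s$contigs$id[1L]) {
          c(min(tr$repeat_starts) - 1L,
            max(tr$repeat_starts) + tr$repeat_len)
        }
      })
      for (try in 1:50) {
        after <- sample(2:(n - 2L), 1L)  # keep >= 2 host genes on each side
        at <- host_genes$end[after] + 5L
        clash <- any(vapply(forbidden, function(f) {
          !is.null(f) && at >= f[1L] && at <= f[2L]
        }, TRUE))
        if (!clash) break
      }
      hseq <- s$contigs$sequence[1L]
      s$contigs$sequence[1L] <- paste0(substr(hseq, 1L, at), block,
                                       substr(hseq, at + 1L, nchar(hseq)))
      s$contigs$length[1L] <- nchar(s$contigs$sequence[1L])
      shift <- nchar(block)
      sel <- s$genes$contig_id == s$contigs$id[1L] & s$genes$start > at
      s$genes$start[sel] <- s$genes$start[sel] + shift
      s$genes$end[sel] <- s$genes$end[sel] + shift
      pg <- block_genes
      pg$contig_id <- s$contigs$id[1L]
      pg$id <- paste0(s$contigs$id[1L], "_pro", tag, "_", seq_len(nrow(pg)))
      pg$start <- pg$start - block_from + at + 1L
      pg$end <- pg$end - block_from + at + 1L
      pg <- mask_annotations(pg)
      s$genes <- order_genes(rbind(s$genes, pg))
      # shift coordinates of earlier planted features downstream of `at`
      s$truth <- lapply(s$truth, function(tr) {
        if (identical(tr$mode, "crispr_spacer") &&
            tr$contig_id == s$contigs$id[1L] && min(tr$repeat_starts) > at) {
          tr$repeat_starts <- tr$repeat_starts + shift
        }
        tr
      })
      s$truth <- c(s$truth, list(list(
        mode = "prophage", contig_id = s$contigs$id[1L],
        start = at + 1L, end = at + shift,
        gene_from = after + 1L, gene_to = after + nrow(pg),
        virus_id = virus$contigs$id[1L])))
      s
    }
    sag <- insert_block(sag, "a")
    if (!is.null(conserve_into)) {
      sag$conserved_sag <- insert_block(conserve_into, "b")
    }
    return(sag)
  }
  # crispr_spacer
  vseq <- virus$contigs$sequence[1L]
  if (nchar(vseq) < spacer_len) stop("virus too short to donate a spacer")
  rep_seq <- random_dna(repeat_len)
  sp_from <- sample(nchar(vseq) - spacer_len + 1L, 1L)
  spacers <- c(substr(vseq, sp_from, sp_from + spacer_len - 1L),
               replicate(n_spacers - 1L, random_dna(spacer_len)))
  # boundary identifiability: the characters flanking the repeat copies must
  # not all be equal, otherwise the true maximal repeat exceeds the planted
  # one; adjust a boundary character of a random (non-donated) spacer
  fix_boundary <- function(spacers, side, host_char) {
    flank <- if (side == "left") {
      c(host_char, substr(spacers, nchar(spacers), nchar(spacers)))
    } else {
      c(substr(spacers, 1L, 1L), host_char)
    }
    if (length(unique(flank)) > 1L) return(spacers)
    i <- if (length(spacers) > 1L) 2L else 1L
    alt <- sample(setdiff(BASES, flank[1L]), 1L)
    if (side == "left") {
      substr(spacers[i], nchar(spacers[i]), nchar(spacers[i])) <- alt
    } else {
      substr(spacers[i], 1L, 1L) <- alt
    }
    spacers
  }
  host_genes <- order_genes(sag$genes[sag$genes$contig_id == sag$contigs$id[1L], ,
                                      drop = FALSE])
  after <- sample(seq_len(nrow(host_genes) - 1L), 1L)
  at <- host_genes$end[after] + 3L
  hseq <- sag$contigs$sequence[1L]
  spacers <- fix_boundary(spacers, "left", substr(hseq, at, at))
  spacers <- fix_boundary(spacers, "right", substr(hseq, at + 1L, at + 1L))
  insert <- paste0(rep_seq, paste0(spacers, rep_seq, collapse = ""))
  sag$contigs$sequence[1L] <- paste0(substr(hseq, 1L, at), insert,
                                     substr(hseq, at + 1L, nchar(hseq)))
  sag$contigs$length[1L] <- nchar(sag$contigs$sequence[1L])
  shift <- nchar(insert)
  sel <- sag$genes$contig_id == sag$contigs$id[1L] & sag$genes$start > at
  sag$genes$start[sel] <- sag$genes$start[sel] + shift
  sag$genes$end[sel] <- sag$genes$end[sel] + shift
  period <- repeat_len + spacer_len
  rep_starts <- at + 1L + period * (0:n_spacers)
  sag$truth <- c(sag$truth, list(list(
    mode = "crispr_spacer", contig_id = sag$contigs$id[1L],
    repeat_starts = rep_starts, repeat_len = repeat_len,
    spacer_len = spacer_len, donated_spacer = 1L,
    virus_id = virus$contigs$id[1L])))
  sag
}

#' Simulate the default end-to-end study scenario
#'
#' Generates `n_sags` SAGs over the configured depth labels, plants current
#' infections with the per-depth probabilities (an ssDNA-infected SAG also
#' receives the dsDNA virus with the co-infection linkage probability),
#' plants CRISPR arrays (spacer donated by a dedicated "past" virus) and
#' conserved defective prophages (from a second past virus, copied into a
#' partner SAG), and returns the assemblies together with complete ground
#' truth.
#'
#' @param config a [scenario_config()].
#' @return list: `sags` (per-SAG lists), `contigs` / `genes` (pooled
#'   tables), `viruses` (current-infection genomes), `past_viruses`,
#'   `sag_info` (`data.frame`: `sag_id`, `depth`), `infections`
#'   (`data.frame`: `sag_id`, `virus_id`, `taxon`, `mode`), `truth`
#'   (per-SAG planted-feature records), `config`.
#' @export
simulate_scenario <- function(config = scenario_config()) {
  set.seed(config$seed)
  depths <- rep(config$depths, length.out = config$n_sags)
  sag_ids <- sprintf("SAG%02d", seq_len(config$n_sags))
  micro <- generate_viral_genome(config, "microviridae", "uvMicro1")
  podo <- generate_viral_genome(config, "caudovirales", "uvPodo1")
  past1 <- generate_viral_genome(config, "caudovirales", "pastPhage1")
  past2 <- generate_viral_genome(config, "caudovirales", "pastPhage2")
  sags <- list()
  infections <- data.frame(sag_id = character(), virus_id = character(),
                           taxon = character(), mode = character(),
                           stringsAsFactors = FALSE)
  # first pass: hosts + current infections + CRISPR arrays
  for (i in seq_along(sag_ids)) {
    sag <- generate_host_genome(config, contig_id = paste0(sag_ids[i], "_c1"),
                                source_id = sag_ids[i])
    sag$truth <- list()
    p <- config$infection_prob[match(depths[i], config$depths)]
    if (runif(1) < p) {
      if (runif(1) < 0.5) {
        sag <- plant_infection(sag, micro, "current")
        infections <- rbind(infections, data.frame(
          sag_id = sag_ids[i], virus_id = "uvMicro1",
          taxon = "Microviridae", mode = "current"))
        if (runif(1) < config$coinfection_linkage) {
          sag <- plant_infection(sag, podo, "current")
          infections <- rbind(infections, data.frame(
            sag_id = sag_ids[i], virus_id = "uvPodo1",
            taxon = "Podoviridae", mode = "current"))
        }
      } else {
        sag <- plant_infection(sag, podo, "current")
        infections <- rbind(infections, data.frame(
          sag_id = sag_ids[i], virus_id = "uvPodo1",
          taxon = "Podoviridae", mode = "current"))
      }
    }
    if (runif(1) < config$crispr_prob) {
      sag <- plant_infection(sag, past1, "crispr_spacer")
      infections <- rbind(infections, data.frame(
        sag_id = sag_ids[i], virus_id = "pastPhage1",
        taxon = "Caudovirales", mode = "crispr_spacer"))
    }
    sags[[sag_ids[i]]] <- sag
  }
  # second pass: conserved prophages planted into SAG pairs
  i <- 1L
  while (i < length(sag_ids)) {
    if (runif(1) < config$prophage_prob) {
      res <- plant_infection(sags[[sag_ids[i]]], past2, "prophage",
                             conserve_into = sags[[sag_ids[i + 1L]]])
      sags[[sag_ids[i + 1L]]] <- res$conserved_sag
      res$conserved_sag <- NULL
      sags[[sag_ids[i]]] <- res
      infections <- rbind(infections,
                          data.frame(sag_id = sag_ids[c(i, i + 1L)],
                                     virus_id = "pastPhage2",
                                     taxon = "Caudovirales",
                                     mode = "prophage"))
      i <- i + 2L
    } else {
      i <- i + 1L
    }
  }
  contigs <- do.call(rbind, lapply(sags, `[[`, "contigs"))
  genes <- do.call(rbind, lapply(sags, `[[`, "genes"))
  rownames(contigs) <- rownames(genes) <- NULL
  list(sags = sags, contigs = contigs, genes = genes,
       viruses = list(uvMicro1 = micro, uvPodo1 = podo),
       past_viruses = list(pastPhage1 = past1, pastPhage2 = past2),
       sag_info = data.frame(sag_id = sag_ids, depth = depths,
                             stringsAsFactors = FALSE),
       infections = infections,
       truth = lapply(sags, `[[`, "truth"),
       config = config)
}

#' Write a simulated scenario to disk
#'
#' Emits contig FASTA, gene GFF3, a ground-truth JSON and a manifest.
#'
#' @param scenario output of [simulate_scenario()].
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_scenario <- function(scenario, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(scenario$contigs, file.path(outdir, "contigs.fasta"))
  write_gff3(scenario$genes, file.path(outdir, "genes.gff3"))
  jsonlite::write_json(
    list(sag_info = scenario$sag_info, infections = scenario$infections,
         truth = scenario$truth),
    file.path(outdir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  writeLines(c("contigs.fasta", "genes.gff3", "ground_truth.json"),
             file.path(outdir, "MANIFEST"))
  invisible(outdir)
}
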