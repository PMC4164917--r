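---
title: "Methods: viral detection and virus-host ecology in SAGs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: viral detection and virus-host ecology in SAGs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific model behind `sagphage`, every
decision threshold with its default and rationale, the synthetic-data
generator used for validation, and the numerical conventions chosen where
more than one convention exists.

# Scientific model

A single-cell amplified genome (SAG) is the assembly of one flow-sorted,
whole-genome-amplified cell. Because sorting captures the cell contents,
a SAG assembly can contain, besides the host chromosome:

* **current infections** — assembled contigs of viruses replicating in
  the cell at sorting time;
* **defective prophages** — integrated viral remnants inside host
  contigs;
* **CRISPR repeat–spacer arrays** — a genomic record of past encounters
  with foreign DNA, each spacer a ~20–60 bp copy of a past invader.

Once viral genomes are in hand, fragment recruitment of metagenome reads
measures where (and at what sequence identity) each virus and each host
occurs across samples, giving presence states, normalized abundances and
virus-to-host ratios; gene sharing clusters the phages into genera; and a
2×2 exact test asks whether two viral groups co-infect the same cells
more often than chance.

# Detection of viral contigs

Four methods, applied in precedence order
(`classify_contigs()`): hallmark, association, virome support, region
metric.

**Hallmark annotation** (`detect_hallmark()`). A contig is viral when a
gene's annotation contains a virion-associated keyword: *virion
structure*, *capsid*, *portal*, *tail*, *terminase* (case-insensitive
substring, with a stop-list so e.g. "tailless" does not match). Keyword
detection is high precision, zero recall for novel viruses.

**Guilt by association** (`expand_by_association()`). An undetected
contig whose genes hit a single detected viral contig is pulled in when
at least 50% of its genes have qualifying hits (e-value ≤ 1e-3, bit
score ≥ 50) to that one contig. Iterated to a fixpoint so chains of
association resolve.

**Virome support** (`detect_by_virome_support()`). At least 3 distinct
genes of a contig matched by virome reads at ≥ 90% identity
(inclusive).

**Reference-free region scan** (`scan_unknown_regions()`). Viral
genomes are architecturally distinct: densely packed genes with no
database hits, transcribed from one strand. Every window of at least
`min_region_genes = 8` consecutive genes is tested for
uncharacterized-gene fraction ≥ 0.5 and majority-strand fraction ≥ 0.8
(both inclusive); overlapping qualifying windows are merged (union
semantics). The merged region is therefore *maximal*: it can extend a
few genes past a planted viral block wherever the extended window still
qualifies. The test suite pins this behavior against an exhaustive
all-window oracle. Eight genes is the shortest window at which the two
fractions are meaningful together (4 of 8 uncharacterized, 7 of 8 on
one strand); the 0.5/0.8 pair separates viral architecture (uncharacterized
fraction ~0.7, strand coherence ~0.95) from operon-structured host
architecture (uncharacterized ~0.3, strand runs of ~5 genes).

**Whole-contig promotion.** A contig whose region calls cover ≥ 80% of
its genes is labelled `viral_putative` only if the *contig-level*
architecture also qualifies (uncharacterized ≥ 0.5 and majority strand
≥ 0.8). Without this gate, chains of marginal windows on an ordinary
microbial contig would promote it. Contigs failing promotion keep their
embedded regions — these are the defective-prophage candidates.

**Architecture metrics** (`compute_metrics()`): average gene size,
strand-change ratio (strand switches between consecutive genes divided
by gene count — the denominator is the gene count, not the number of
junctions), uncharacterized-gene ratio.

# Past infections

**CRISPR arrays** (`find_crispr_arrays()`). Recurring 8-mers at periods
39–108 bp seed candidate repeats, which are extended to maximal exact
agreement across copies; accepted arrays need repeats of 19–48 bp,
spacers of 20–60 bp, at least 3 repeat copies, and strict
repeat/spacer alternation. Overlapping candidates resolve to the array
with most repeats, then longest span. `match_spacers()` matches spacers
to contigs on both strands at ≥ 95% identity over ≥ 95% of the spacer
(substitution-only), excluding hits inside the spacer's own array.

**Defective prophages** (`flag_defective_prophages()`). An embedded
viral-like region is promoted to a putative defective prophage when (a)
at least one microbial gene flanks it on each side and (b) the region is
conserved — a nucleotide match at ≥ 95% identity covering ≥ 50% of the
region — on a microbial contig of a *different* SAG. Conservation across
closely related cells is what distinguishes an integrated element from
assembly noise. Because union-merged regions can sprawl past the real
element, a failed whole-region conservation test falls back to the
longest conserved core (≥ 1 kb); the region is trimmed to that core and
the flank test applied to the trimmed span. This is the automated
analogue of manually trimming a candidate to its conserved extent.

**Past vs current** (`check_past_vs_current()`). Spacers are compared to
current viral contigs with the spacer thresholds; prophage regions
require ≥ 80% identity over ≥ 500 bp. An empty report means the past-
and current-infection sequence sets are disjoint.

# Fragment recruitment

**Protein mode** (`recruit_protein()`). Reads are translated in six
frames, split at stop codons (peptides ≥ 15 aa), and aligned to
reference proteins by Smith–Waterman (BLOSUM62, gap open 11, extend 1)
behind an exact 4-mer seed prefilter. Each read is assigned to its
best-bit gene; each gene keeps the best identity observed.

**Nucleotide mode** (`map_nucleotide()`, `recruit_nucleotide()`).
Exact 20-mers at stride 10 anchor diagonals, anchors chain into
clusters (gaps ≤ 500 bp), clusters ≥ 100 bp are scored; a read that
tiles the reference exactly short-circuits to identity 100, otherwise
gaps are filled by global alignment. A gene counts as covered when
clusters span ≥ 50% of it (inclusive); ANI is the length-weighted mean
cluster identity.

**Presence states** (`classify_presence()`): `present` when > 75% of
genes exceed 80% amino-acid identity; `related` when > 75% reach 60%;
otherwise `absent`; an ssDNA reference scored against a
linker-amplified library can never be called `absent` — the call becomes
`inconclusive`, because linker amplification biases strongly against
ssDNA templates. `host_presence()` requires > 75% of genes covered and
ANI > 95. Boundaries are strict (>) for the fractions, so exactly 75%
does not qualify; the identity boundary 80 belongs to the mid class.

**Abundance** (`relative_abundance()`): recruited bases divided by
reference length, normalized per Mb of metagenome.
`virus_host_ratio()` is the ratio of the two abundances (NA with a
warning when the host abundance is 0). Per-Mb abundances are
compositional — adding copies of one genome depresses the per-Mb
abundance of every other — so abundance is linear in copy number only at
fixed total community size, while abundance *ratios* are closure-free;
the validation experiments hold community size constant with a neutral
filler genome when testing linearity. `identity_distribution()`
summarizes recruited identities ≥ 80 with type-7 quartiles and flags
outliers beyond 1.5 IQR — the Tukey boxplot convention.

# Comparative analyses

`shared_gene_fraction()` averages the two directed fractions of genes
with qualifying hits (or uses the smaller genome as denominator);
`cluster_genera()` single-links genomes sharing ≥ 40% of genes
(inclusive) via graph components. `clonality()` compares circular
genomes rotation- and strand-invariantly (doubled-sequence anchoring),
declaring clonality only at 100% identity. `fisher_exact_2x2()` is the
exact two-sided test: the p-value sums all hypergeometric outcomes with
probability ≤ the observed one, with a 1 + 1e-7 relative tolerance on
the comparison to absorb floating-point ties — validated against full
enumeration for every table with N ≤ 40.

# Synthetic-data generator

The generator exists to make every stage falsifiable, not to imitate any
particular ocean. Scope and defaults (`scenario_config()`):

* hosts: one contig per SAG, 50 genes, log-normal lengths (median 750
  bp), same-strand operon blocks (geometric, mean 5), 70% characterized;
* viruses: tailed dsDNA phage (15–30 kb, linear) and small circular
  ssDNA phage (4.5–6.5 kb), ≥ 1 hallmark gene each, 70% uncharacterized,
  95% strand coherence;
* infections: per-depth current-infection probabilities (0.08 / 0.28 /
  0.47), ssDNA–dsDNA co-infection linkage 0.9, CRISPR arrays with one
  spacer copied verbatim from a past virus (array boundaries made
  identifiable so the planted coordinates are the unique maximal-repeat
  answer), conserved prophage pairs planted into two SAGs;
* metagenomes: reads drawn proportional to length × copy number,
  uniform starts, circular genomes wrap, optional substitution errors;
* controlled divergence: `mutate_to_identity()` hits a nucleotide or
  amino-acid identity target exactly (amino-acid mode substitutes whole
  codons to *different* amino acids, so protein and nucleotide identity
  stay jointly consistent).

Everything returns machine-readable ground truth (coordinates, donors,
modes), and `write_scenario()` emits FASTA/GFF3/JSON plus a manifest.

# Numerical conventions

* Alignment identity = matches / aligned columns, gap columns included
  in the denominator. Ambiguity codes never count as a match — `X` for
  proteins, `N` for nucleotides. (`N` is a valid amino acid,
  asparagine; treating it as ambiguous in protein space would deflate
  identities.)
* Bit scores use fixed gapped Karlin–Altschul parameters for
  BLOSUM62/11/1 (λ = 0.267, K = 0.041); the e-value search space is an
  explicit argument (default: product of sequence lengths).
* Quantiles are R type-7 (the `quantile()` default); outliers use the
  1.5 IQR Tukey fence.
* All thresholds stated as "at least" are inclusive; presence-state
  fractions are strict, as stated above.

# Design decisions and open questions

* **Union-merged regions sprawl.** Merging all qualifying windows makes
  the scan deterministic and oracle-checkable, but regions can extend
  past a planted element. Downstream consumers compensate
  (conserved-core trimming in prophage flagging); an alternative —
  reporting only minimal qualifying windows — would be tighter but
  unstable under small annotation changes.
* **Conservation as the prophage arbiter.** Requiring conservation in a
  second SAG makes lone prophages undetectable by design; that is the
  price of not using a viral reference database. The 1 kb conserved-core
  floor is a round lower bound well under the smallest planted element
  (~5 kb); it is not fitted.
* **Seeded alignment prefilters** (4-mer protein seeds, 20-mer
  nucleotide anchors at stride 10) trade a bounded miss risk for
  tractability; pairs sharing no seed are never aligned. At the identity
  ranges the classifications use (≥ 40%), misses were not observed
  against oracle alignments.
* **Fisher tie tolerance.** The 1 + 1e-7 relative tolerance when
  comparing outcome probabilities to the observed one matches the
  behavior of the standard implementation and absorbs floating-point
  ties; enumeration testing bounds its effect below 1e-10 for N ≤ 40.
* **Open**: the guilt-by-association rule keys on hits to a *single*
  detected contig; pooling evidence across several detected contigs is a
  plausible extension (`pooled = TRUE` implements it but it is off by
  default). The read simulator is substitution-only; indel error models
  would exercise the gap-handling paths of the mappers harder.
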