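---
title: "Mining MSDIN cyclic peptide genes and validating them by mass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining MSDIN cyclic peptide genes and validating them by mass}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msdinminer)
```

## The biology in brief

Poisonous *Amanita* mushrooms of section *Phalloideae* make their cyclic
peptide toxins — the amatoxins, phallotoxins and the non-toxic
cycloamanides — on ribosomes, as a family of short precursor genes named
for the conserved "MSDIN" start of the encoded peptide. A precursor is
33–37 amino acids long and has three segments:

* a 10-aa **leader** ending in Pro, where the dedicated prolyl
  oligopeptidase POPB cleaves;
* a variable 6–10-aa **core**, usually ending in Pro, which POPB
  transpeptidates into a head-to-tail cyclic peptide (the Pro stays in
  the product);
* a 17-aa **follower** whose strong consensus ends Leu-Cys; the terminal
  Cys (or, in several genes, Ser) is needed for cyclization.

At the genomic level the family has an equally rigid signature: a
two-exon gene whose single 52–58 bp intron interrupts the fourth codon
from the end of the coding sequence (counting the stop codon), with a GT
donor (GC in a minority of genes) and an AG acceptor. The mature product
is a macrocycle whose mass is the residue-mass sum — one water less than
the linear peptide — optionally shifted by up to four hydroxylations
(+O each) and, when the core contains both Trp and Cys, by the
tryptathionine cross-bridge (−2 H).

This package turns those regularities into a deterministic pipeline:
grammar validation, genome mining, mass prediction and MS annotation,
composition statistics, and seeded simulators that generate the test
substrate.

## The precursor grammar

`partition_precursor()` splits a precursor arithmetically: leader =
first 10 residues, follower = last 17, core = remainder. The split is
deliberately *not* anchored on Pro residues: annotated genomes contain
family members that lack the leader-terminal or core-terminal Pro yet
still have well-defined cores, so the two Pro residues are validation
flags rather than partition criteria. Sequences whose implied core
length falls outside 6–10 are reported as "MSDIN-like" with the computed
(possibly non-positive) core length instead of being dropped — coreless
loci where the leader abuts a follower are real observations, not
parsing noise.

```{r grammar}
p <- partition_precursor("MSDINATRLPIWGIGCNPCVGDDVNPTLTRGESLC")
p
validate_precursor(p)
```

`processable` requires the leader-terminal Pro, the core-terminal Pro,
an accepted C-terminal residue (Cys or its observed substitute Ser) and
an in-window length. This is deliberately a conjunction of all of the
POPB requirements: replacing the terminal Cys with Ala is known to block
cyclization, and transpeptidation needs the second Pro. Leaders are
classified from their first five residues only (`canonical`,
`listed-variant` for the single-mismatch variants seen in annotated
genes, `near-variant` for other single mismatches, else `divergent`);
leaders two or more mismatches away are never counted as MSDIN, matching
the practice of leaving such loci unannotated.

## Mining genome scaffolds

`mine_genome()` replaces the manual homology-plus-curation route with a
deterministic two-stage algorithm:

1. **Seeding** (`six_frame_seeds()`): every ATG on either strand whose
   in-frame 10-codon window translates to a leader classified better
   than `divergent`. A permissive translated-homology search with a very
   loose e-value cutoff is not reproducible as an algorithm; a motif
   scan with an explicit mismatch budget (one mismatch over the first
   five residues) is the equivalent sensitivity lever and is exposed in
   the configuration.
2. **Enumeration** (`enumerate_gene_models()`): for each seed, every
   combination of precursor length (33–37), intron phase and intron
   length (52–58) is tested against the splice rules. Phase 1 and 2
   models interrupt the fourth-from-last codon as the transcript
   evidence describes; phase 0 (intron exactly between codons) is
   enumerated by default but scored below interrupted phases, since the
   wording of the rule suggests true interruption. The spliced CDS must
   end in a stop, contain no internal stop and no N, and translate to a
   precursor that partitions under the grammar.

Models are scored additively (GT donor, terminal Leu-Cys, core-terminal
Pro, leader class, intron length near 55 bp, interrupted phase) with
documented weights; same-strand overlapping models compete by score with
ties broken by longer first exon, then leftmost coordinate.
Opposite-strand overlaps are both kept — there is no observation that
rules them out. Coordinates are 1-based inclusive on the forward strand
(GFF3 convention), with `exon1` always the first exon in transcript
order.

```{r mining}
sim <- generate_scaffolds(sim_config(seed = 42, n_scaffolds = 3,
                                     scaffold_len = 12000, n_genes = 5))
models <- mine_genome(sim$scaffolds)
models[, c("scaffold", "strand", "start", "end", "donor", "intron_len",
           "phase", "core", "leader_class", "score")]
evaluate_mining(models, sim$truth)
```

`dedupe_and_cluster()` separates total gene copies from unique core
sequences — the distinction behind "33 genes, 29 unique" style counts —
using the core as the identity key by default (duplicated toxin genes
share cores but can differ elsewhere), with full-precursor identity as
an option.

## Mass prediction and MS annotation

All masses are monoisotopic and derive from one atomic mass table
(CODATA values, six or more decimals). For a head-to-tail macrocycle the
neutral mass is the residue-mass sum; `candidate_masses()` enumerates 0–4
hydroxylations per core, doubled with the −2 H tryptathionine variant
when the core contains both Trp and Cys. Modifications are
composition-level only: extracted-ion searching uses masses, never
modification sites.

```{r masses}
cands <- candidate_masses("ISDPTAYP")
cands
```

One numerical subtlety is the charge carrier. Printed "predicted m/z"
values in the literature mix two conventions that differ by the electron
mass (0.55 mDa, about 0.7 ppm at m/z 800): neutral mass plus proton, and
neutral mass plus a neutral hydrogen atom. The package defaults to the
physically correct proton (1.007276 Da) and exposes
`convention = "h-atom"`; mass comparisons in the tests use a ±8e-4 Da
band that absorbs the difference.

`match_peaks()` pairs MS1 peaks with candidates inside a ppm tolerance
computed against the theoretical mass. The default tolerance is 10 ppm:
accepted identifications in this compound class sit at ≤ 5.5 ppm while
the documented rejection (the m/z 892.32 compound vs trihydroxylated
cyclo(ISDPTAYP)) is 68 ppm, so 10 ppm separates the regimes with a wide
margin on either side. It is a package default, not a literature value.

```{r match}
match_peaks(data.frame(mz = 892.3201, intensity = 1), cands)
```

For MS/MS verification, `fragment_ladder()` enumerates all n(n−1)
contiguous cyclic substrings of an unmodified ring as singly charged
b-type ions (residue-mass sum plus proton) — the "sequential loss"
pattern of cyclic peptides. `annotate_msms()` matches the ladder to a
peak list and reports backbone coverage: the fraction of the n
ring-opening positions adjacent to at least one matched fragment
boundary. Modified rings are excluded from ladders because hydroxylation
sites are unknown; the compounds verified this way are unmodified.

## Composition statistics

`aa_bias()` compares pooled residue counts in a core set against an
expected distribution. The background behind published
observed-vs-expected comparisons is not stated, so the default is
uniform (1/20) and any user-supplied distribution (e.g. proteome-wide
frequencies) can be given; the background id is recorded on every
result. The conserved core-terminal Pro is included in the counts by
default (the published Pro excess is attributed to internal *and*
terminal Pro), with an `exclude_terminal` option.
`hydrophobic_bias()` aggregates by a hydrophobicity classification
(default: A, C, F, G, I, L, M, P, V, W hydrophobic; the rest
polar/charged — overridable, since Gly and Cys are genuinely arguable).

## The synthetic data generators

The unreleased genome assemblies are replaced by seeded generators whose
defaults define the study conditions used by the test suite:

* **Precursors**: leaders drawn from the canonical-plus-variants pool
  (ending Pro), core lengths 6–10 weighted 0.1/0.2/0.4/0.2/0.1 so the
  mode is 8, core residues from a Pro/Ile/Phe-enriched distribution,
  followers of 15 uniform residues plus Leu-Cys.
* **Genes**: uniform synonymous back-translation (no codon-usage table
  exists for these fungi; the choice is exposed), an intron of uniform
  length 52–58 bp with donors weighted 85% GT / 15% GC (four of ~30
  annotated genes are GC-AG), interior bases i.i.d. at the background GC.
* **Scaffolds**: i.i.d. background at GC 0.48 (the reported genome-wide
  GC peak), 20 scaffolds × 50 kb carrying 30 genes on random strands at
  ≥ 500 bp spacing. No repeats, paralog families or assembly gaps are
  modelled: recovery results on this substrate demonstrate algorithmic
  correctness of the gene-structure search, not robustness to repetitive
  fungal genomes.
* **Peak lists**: one peak per peptide with Gaussian m/z noise (default
  2 ppm, typical of QToF instruments), uniform-random intensities, plus
  200 uniform decoy peaks; MS2 mode emits the fragment ladder instead.

Each top-level generator seeds one shared RNG stream and sub-generators
draw from it in documented order, so outputs are bit-reproducible and
adding a generator cannot silently shift existing fixtures.

## Problem sizes and numerical choices

The default test substrate (20 × 50 kb, 30 genes) mines in about a
second; the chemistry property suites run over 1000 random sequences and
ring sizes 3–12. Mass arithmetic is exact to well below 1e-9 Da;
equality tests on masses use the tolerances stated alongside each
published value (±8e-4 Da for m/z, ±0.05 for ppm figures). Ties in
length modes resolve to the smallest length; ties in model scores
resolve deterministically (longer exon 1, then leftmost). Degenerate
inputs follow explicit contracts: empty scaffold sets, empty candidate
lists and empty core sets are errors; empty peak lists and zero mined
models are valid results.

## Known limitations

* The published genomic head-counts (33/29 genes in *A. phalloides*,
  31/27 in *A. bisporigera*, 3 shared cores) cannot be reproduced here:
  the assemblies are not public and no accession exists. The miner is
  instead validated on synthetic genomes with planted truth.
* Whether any real MSDIN intron is phase 0 is unknown; the miner
  enumerates phase 0 but down-weights it.
* MS2 annotation covers unmodified monocycles only; bicyclic
  (tryptathionine-bridged) fragmentation is not modelled.
* The miner is specific to the two-exon MSDIN structure; it is not a
  general gene finder.
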