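---
title: "Characterizing the ribosomal tandem repeat from short reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing the ribosomal tandem repeat from short reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboperon)
library(dplyr)
```

## The problem

The nuclear ribosomal operon (the cistron 18S–ITS1–5.8S–ITS2–28S plus the
intergenic spacer, IGS) is arranged in tandem repeats in eukaryotic nuclear
genomes. Three of its properties matter for anyone using the ITS region as a
fungal DNA barcode:

* **copy number** — how many repeat units the genome carries;
* **intragenomic variation** — how different the copies are from one another,
  since reads from all copies are attributed to a single consensus; and
* **intron turnover** — group I introns in the 18S and 28S genes appear and
  disappear on short evolutionary time scales, changing operon length and
  primer-binding landscapes.

All three can be read out of ordinary short-read shotgun data without
assembling the array: mapping every read against a *single* reference copy of
the operon collapses the whole tandem array onto one coordinate system, so
read depth becomes proportional to copy number and minor-allele fractions in
the pileup become estimates of the fraction of copies carrying a variant.
`riboperon` implements that read-out, together with a fully ground-truthed
simulator so each stage can be verified end to end.

## The simulator

`build_operon_template()` draws a random repeat unit with the canonical
six-region architecture and optional introns placed strictly inside the 18S
or 28S. `build_genome()` then assembles a genome: a `rdna_tandem` contig with
`copy_number` concatenated copies (each independently mutated at
`per_copy_variant_rate`, plus explicitly planted intragenomic variants
realized in `round(fraction * copy_number)` copies drawn without
replacement), three short single-copy gene contigs (stand-ins for *MCM7*,
*RPB1*, *RPB2*), a 50-kb single-copy contig, and optionally an unrelated
contaminant contig standing in for a photobiont genome. Every planted
difference is recorded in a truth record.

`simulate_paired_reads()` draws fragments uniformly along contigs weighted by
length — the tandem contig therefore receives proportionally more pairs —
with Gaussian fragment lengths, reverse-complemented second mates, and
i.i.d. substitution errors. Defaults follow the sequencing design the
package targets: 100-bp paired-end reads, 350-bp inserts, 0.1% per-base
error, 50× single-copy depth. The insert-length SD defaults to 35 bp
(roughly 10% of the insert, typical for transposase libraries); base
qualities are written as a constant Q40 because nothing downstream uses
them. The error model is substitution-only with no quality gradient or GC
bias: the variance statistic counts substitutions, so indel and bias realism
would add cost without touching what the tests measure. This is also the
model's main limit — real libraries show position-dependent error, PCR
duplicates and mappability structure that the simulator does not emulate, so
green tests here demonstrate correctness of the estimators, not robustness
to every artifact of real data.

`simulate_species_set()` evolves the template's exon sequence down a species
tree by per-branch substitutions with region-specific rates (default: 18S
frozen, 5.8S nearly so, ITS variable, IGS most variable — a caricature of
the real rate hierarchy; branch lengths are ignored). Each species then
receives a fixed number of private diagnostic substitutions, planted only on
columns that are still invariant across species after background evolution,
which makes the recorded diagnostic truth exact by construction. Intron
presence toggles along each branch with a fixed probability, and the event
log upper-bounds any parsimony count of the resulting pattern. Because the
process is indel-free, the per-taxon exon sequences are mutually aligned for
free, and alignment columns coincide with template coordinates.

## Mapping and pileups

The internal mapper (`map_reads()`, Rcpp) is a deliberately minimal
seed-and-extend placement engine: exact 21-mer seeds at staggered offsets on
both strands, candidate positions ranked by seed support, ties broken by
smallest reference position then forward strand, gapless extension, and an
unmapped flag when mismatches exceed 10% of the read. It is substitution-only
because the simulator emits no indels; externally aligned real data can enter
through `read_sam()`, which reconciles CIGAR and MD into the same per-base
mismatch records. Mapping uses a single operon copy as reference — junction
reads spanning two copies find no gapless placement and drop out, which
depresses the tandem depth by roughly `read_length / unit_length` (about 1%
here); this small, known bias is visible in the copy-number sweeps and is
well inside the reported tolerances.

`extract_region_with_buffer()` reproduces the ITS mapping protocol of adding
a 600-bp flank on each side of the barcode region so reads that only
partially overlap the ITS are not lost. `build_pileup()` attributes
non-mismatching bases to the reference base, so base counts always sum to
depth; the consensus is the majority base with alphabetical tie-break, and
uncovered positions emit `N`.

All coordinates at the package surface — annotations, pileup positions,
alignment columns — are 0-based half-open; SAM input is converted on read.

## The variance statistic and its bins

Per site, variance is `(depth − count of consensus base) / depth`, undefined
(never silently 0) at depth 0. Sites are binned as: exactly zero; below 1%
but non-zero; 1–10% inclusive; above 10%. The middle bin's upper bound is
closed at 0.10 so the four bins form an exhaustive partition; values in the
nominal gap between "1–9%" and ">10%" land in the middle bin. With no
planted variants the per-site expectation equals the sequencing error rate,
which is why, at 0.1% error, essentially all sites fall in the two lowest
bins, and a variant carried by 10% of copies at ~300× is recovered within
binomial sampling error of 0.10.

`diagnostic_sites()` calls a column fixed for a species only when every
member carries the same unambiguous base (any gap or N breaks fixation —
conservative on purpose, since a single ambiguous taxon should not anchor a
barcode character), and diagnostic when every species is fixed and at least
two differ. `overlap_report()` cross-tabulates polymorphic pileup sites
(variance above a threshold defaulting to 0.01, the floor of the 1–9% bin)
against diagnostic columns. No attempt is made to classify individual reads
as error versus true variant; separation is by magnitude only.

## Copy number

`estimate_copy_number()` divides the nrDNA mean depth by each single-copy
locus's mean depth and reports the mean and the sample SD (n − 1) of those
per-locus ratios. Reporting the SD across loci is an interpretive choice:
the spread could equally be computed across windows or mapping replicates,
and no single choice is canonical; across-locus spread is what the
"estimates were similar across a range of comparisons" framing suggests and
is what the package documents. Zero-depth loci are excluded and reported; a
zero-depth nrDNA reference yields an estimate of 0 with a warning. An
optional exclusion mask removes ambiguous segments (such as a repeat-rich 5′
IGS stretch) from the nrDNA average. No GC or mappability correction is
applied. `copy_number_sweep()` wraps the full simulate–map–estimate loop.

At the study conditions (true copy numbers 9–48, 50× single-copy depth,
0.1% error, 7.66-kb repeat unit, ~31k–106k read pairs per genome) the sweep
recovers all four values within a few percent, strictly in order.

## Intron detection and event counting

`transfer_annotation()` globally aligns an assembled operon against an
annotated intron-free reference (the role an intron-poor yeast operon plays
for real data) with affine gaps, projects region boundaries through the
alignment, and reports query-only insertions of ≥ 50 bp strictly inside the
18S or 28S as candidate introns; the 50-bp floor keeps alignment jitter from
being called an intron. Transfers below 70% aligned identity are refused
rather than silently degraded. Presence calls are `present` when a candidate
insertion falls within 10 bp of a catalogued site, `unknown` when the site
lies in reference sequence with no aligned query (never imputed), otherwise
`absent`.

`junction_motif_support()` searches raw reads for the intron-absent junction
(flanks of 30 bp, requiring 10 bp on each side of the junction with at most
2 mismatches, both strands) and for the two exon/intron boundaries — with
100-bp reads, 30-bp flanks leave ample read to span the junction. The
spanned window is the minimal core (10 + 10 bp) rather than the full flank
concatenation, so partial-overlap reads still count.

`fitch_min_changes()` is unit-cost small parsimony implemented as the
two-state Sankoff dynamic program, which handles multifurcations exactly and
is provably root-invariant; tests verify it against a brute-force
enumeration of all ancestral labelings on every 5- and 6-leaf topology and
sampled larger trees, and against an independent phylogenetics library.
`dollo_min_losses()` assumes at most one gain, placed at the MRCA of the
present leaves (located on the stored orientation of the tree), and counts
maximal all-absent subtrees below it. Both are reported per intron by
`event_report()`, with the Fitch count as the headline number and
`single_event = fitch ≤ 1`, since it is not knowable from a presence matrix
alone whether history was Dollo-like. Unknown cells drop the taxon for that
character rather than being imputed.

## Phylogenetic read-out

`p_distance_matrix()` (pairwise deletion of gaps/N), `nj_tree()` (standard
neighbor joining with negative branches clamped to zero and the deficit
moved to an adjacent edge), and `is_monophyletic()` (edge-bipartition test on
the unrooted tree) support `monophyly_report()`: per annotated region, build
the NJ tree of the sub-alignment and test each species. A region with no
variable sites carries no signal and is reported `no_signal = TRUE` and
non-monophyletic — this is exactly how the frozen-18S analogue behaves in
the simulations, while ITS-analogue regions with a handful of private fixed
substitutions per species recover every species as a clade. NJ with
p-distances deliberately stands in for likelihood inference: the claims made
here are about monophyly recoverability on synthetic data, not about support
values, and bootstrap is out of scope.

## Numerical and design notes

* Seeds: every stochastic function takes an explicit seed (or inherits it
  from the `simulation_config`) and restores the caller's RNG state;
  identical seeds give byte-identical FASTQ output.
* Tie-breaks are deterministic everywhere: mapper (position, then strand),
  consensus (A < C < G < T, N last), NJ (delegated to the library's stable
  order).
* Degenerate inputs fail loudly: depth-0 variance, empty intervals, all
  zero-depth loci, ragged alignments, unparseable Newick, missing leaf
  states, annotation transfer below the identity floor.
* Problem sizes in the shipped tests and acceptance script: the full-scale
  copy-number sweep uses the 7.66-kb unit at 50× (up to ~106k pairs);
  variance calibration uses a 2.22-kb unit at ~300× operon depth with 100
  read-resampling replicates per planted fraction; parsimony checks
  enumerate all topologies to 6 leaves and sample at 7–8. These sizes were
  chosen so each claim is tested at, or safely above, the resolution at
  which the corresponding quantity is reported.
* The replicate-coverage check for the planted-variant confidence interval
  is itself a binomial observation (the exact interval's true coverage at
  ~300× is about 96%), so observed coverage over 100 replicates fluctuates
  by a few counts around 96; the property tests bound it at the 1st
  percentile of Bin(100, 0.95) alongside an unbiasedness check.

## Worked example

```{r example, eval = FALSE}
tpl <- build_operon_template(
  c(`18S` = 1800, ITS1 = 200, `5.8S` = 160, ITS2 = 200, `28S` = 3300,
    IGS = 2000))
cfg <- simulation_config(
  copy_number = 12, coverage_target = 30, seed = 7,
  intragenomic_variants = tibble::tibble(position = 1900, fraction = 0.25))

res <- run_copy_number_sim(tpl, cfg)
glance(res$estimate)
#   mean_copy_number sd_copy_number nrdna_mean_depth n_loci
#              11.5          0.222             354.     4

variance_profile(res$pileup, interval = its_interval(tpl),
                 reference = "operon") |>
  filter(variance > 0.05)
#   reference_name   pos depth variance bin
#   operon          1900   339    0.263 >10%
```

The estimate sits ~4% below truth (the junction-read bias discussed above
plus sampling noise), and the planted 25% variant surfaces at its planted
position as the only site above the error floor.
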