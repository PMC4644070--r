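---
title: "Predicting C/D box sRNA-guided rRNA 2'-O-methylation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting C/D box sRNA-guided rRNA 2'-O-methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdguide)
```

## The biological model

Archaeal C/D box sRNAs (homologs of eukaryotic C/D box snoRNAs) carry four
conserved sequence elements: box C and box C' (consensus RUGAUGA, R = A or G)
and box D and box D' (consensus CUGA).  The C/D and C'/D' pairs fold into
kink-turn motifs bound by L7Ae; Nop5 and the fibrillarin methyltransferase
complete the active sRNP.  Between the boxes lie two variable guide regions,
typically 10--12 nt, that base-pair antiparallel with complementary stretches
of 16S or 23S rRNA.  The enzyme methylates the 2'-hydroxyl of the rRNA
nucleotide that is base-paired with the guide nucleotide positioned five
nucleotides upstream of the downstream D or D' box start -- the *N plus five
rule*.  2'-O-methyl groups favour the 3'-endo sugar pucker and protect the
backbone against hydrolysis, which is why hyperthermophiles carry unusually
many of these guides.

The package implements this model as a deterministic pipeline:

1. **Box annotation** (`annotate_cd_srna`): exhaustive search for the best
   consistent C < D' < C' < D arrangement in a small RNA (< 100 nt by
   default), scored by total box mismatches, with guide-length bounds.
   Following the convention that the first box nucleotide can participate in
   the duplex, each guide *includes* the first nucleotide of its downstream
   box, so the +5 position sits at guide index `length - 5`.
2. **Duplex scanning** (`scan_guide`, `predict_targets`): every bulge-free
   antiparallel register of each guide against the species' 16S and 23S rRNA
   is classified pair by pair (Watson-Crick, G:U wobble, mismatch) and tested
   for significance (below).
3. **Pattern analysis** (`conservation_summary`, `hotspot_profile`,
   `find_redundant_sites`, `classify_guide_pairs`, `chaperone_candidates`):
   species-level predictions are projected through per-species alignment
   column maps onto a common coordinate system, where conserved sites,
   windowed methylation density, within-species redundant targets and
   distant-target (chaperone candidate) sRNAs are summarised.

## Significance and productivity rules

A duplex is **significant** in strict mode when it contains a run of at least
nine *consecutive* Watson-Crick pairs covering the +5 pairing column, with at
most one mismatch and two G:U pairs in the whole duplex; bulges are never
allowed.  Two deliberate refinements:

* **The +5 column itself is exempt from the pairing requirement.**  The run
  extends through consecutive pairing positions on both sides of the site and
  counts only actual pairing positions.  Without this, a duplex with a
  mismatch exactly at the predicted site could never be called significant --
  yet such duplexes are exactly the biologically interesting *non-productive*
  class (the complex forms, methylation fails for want of the critical
  Watson-Crick pair at the site).  With the exemption, a mismatch-at-site
  guide needs nine true Watson-Crick pairs around the site, which keeps the
  "nine consecutive WC pairs" reading literal for the pairs themselves.
* **Productive vs non-productive:** a significant duplex is productive only
  if the +5 pair is Watson-Crick.  A G:U at the site is non-productive and
  additionally flagged `uncertain_site_GU`, because wobble pairing at the
  catalytic position is borderline; it is recorded but excluded from
  conservation totals like every non-productive interaction.

In **relaxed mode** (used only for double-guide rescue) G:U pairs count as
pairing inside the run (`relaxed_run_counts_gu`, default on) and a single
mismatch is allowed in the whole duplex.  Rescue works in two passes: after a
strict scan keeps the best hit per guide, a guide with no strict hit whose
partner guide has one is rescanned in relaxed mode, and a relaxed hit is
kept only if its site lies within 100 nt (inclusive) of the partner's site on
the same molecule.  The rationale is thermodynamic: two guides engaging
adjacent rRNA stretches simultaneously form a more stable complex than either
alone, so weaker complementarity suffices.  Both relaxation knobs are
exposed in `scan_rules()` because the precise historical usage of "G:U
base pairs and/or a single mismatch" is underdetermined; the defaults are the
package's choice.

**Best-hit policy.** One prediction is retained per guide, chosen by longest
site-covering run, then fewest mismatches + G:U pairs, then 16S before 23S,
then the 5'-most target start (fully deterministic).  `multi_target = TRUE`
retains all passing hits for studying guides with genuinely two targets.

## The kink-turn register

`check_kturn` is a sequence-level proxy for k-turn competence.  Under the
consensus register the C and D boxes juxtapose so that C-box G3/A4 oppose
D-box A4/G3, forming the two tandem sheared G·A / A·G pairs, capped by the
C-box position 5 / D-box position 2 pair, which the check requires to be U·U
or Watson-Crick.  The flag is advisory: it is recorded and reported but never
rejects an sRNA, since k-turn formation ultimately depends on structure, not
sequence alone.  Box mismatch tolerances default to 1 for C, C' and D' and 0
for D -- the D box is the best-conserved element -- and are configurable.

## Distant targets and chaperone candidates

For every sRNA with two kept sites, the pair is classified `double_local`
(same molecule, separation of at most 100 nt), `double_distant` (same
molecule, further apart) or `cross_molecule`.  Given a secondary structure
(dot-bracket or CT), `structure_distance` measures the shortest path in the
graph whose edges are backbone adjacencies and base pairs; two strands of one
helix are one edge apart no matter how far they sit in the primary sequence.
`chaperone_candidates` keeps `double_distant` calls with structure distance
at most 10 edges (no published threshold exists for "close in secondary
structure space"; 10 edges spans roughly one helix plus a loop and is
configurable).  Without a structure the calls are returned unfiltered with a
warning rather than dropped.

## Conservation mapping and hotspots

Alignment projection is a pure coordinate operation: `build_column_map`
records the alignment column of every ungapped residue (strictly increasing,
round-trip exact), and predictions are joined per (species, molecule).
Conservation counts **productive interactions only**; a column's
`n_species` is the number of distinct species predicted modified there, and
`n_events` the number of mapped interactions, so within-species redundancy
inflates events but not species counts.  The accounting identities
`n_positions = n_single + n_multi` per molecule and
`sum(events) = total productive interactions` are asserted by the test suite
on every synthetic run.  Because published multi-species fractions have been
quoted with events as the denominator, `conservation_summary` reports both
ratios explicitly: multi-species sites over events and multi-species sites
over distinct sites.

Hotspot density is a centred moving-window sum (default 9 columns, truncated
at alignment ends, no wraparound), a linear operator on the event set.

## The synthetic-data generator

`generate_dataset` emulates the statistical structure of a seven-species
pan-archaeal survey rather than any real sequence: ancestral 16S/23S rRNAs of
1500/3000 nt (i.i.d. residues at 55% GC), per-species substitutions (rate
0.05) and indels (rate 0.01) with the true alignment retained, and ~70 sRNAs
per species.  Default class fractions mirror the survey proportions: 33%
decoy sRNAs (no rRNA target; both guides random), 13% with one empty guide,
a 2.2% per-guide mismatch-at-site rate and a 0.2% G:U-at-site rate; 17% of
sRNAs draw their D-guide target from a pool of cross-species conserved sites.
Functional guides are built as exact antiparallel complements of rRNA
windows positioned so the +5 rule lands on the chosen site; the residue
opposite the guide's 3' nucleotide is set to G so the guide ends on the C
that opens the downstream box.

Two generator guarantees make truth-based testing exact:

* Exact box motifs are unique within every emitted sRNA, so the planted
  arrangement is the unique zero-mismatch annotation; and each functional
  guide is verified during generation to recover its planted site as the
  *unique best* strict hit (sites are resampled otherwise).
* Decoy and empty guides record the actual scan outcome in the truth table,
  so a chance complementarity never produces a spurious test failure.

Seeded pseudo-randomness is part of the contract: the same
`synthetic_spec(seed = ...)` yields byte-identical datasets.

What the generator does **not** emulate: real rRNA base composition and
covariation, secondary-structure constraints on target accessibility,
expression levels, or sRNA genomic context.  Passing tests therefore
demonstrate the correctness of the algorithms under the stated model, not
sensitivity/specificity on real archaeal data, where box divergence and
manual curation judgement dominate.

## Numerical and scale choices

All coordinates are 1-based and inclusive everywhere (internally, TSV,
GFF3); U/T are normalised at the boundary so DNA input is acceptable; the
alignment gap character is `-` (`.` only via an explicit flag); all-gap
alignment rows yield empty maps with a warning.  Ties anywhere are broken
deterministically (documented sort orders), so reruns are byte-identical.

The test suite validates the scanner against a brute-force window oracle on
200 random guide/rRNA instances (300-nt rRNAs, guide lengths 10--14), full
recovery of 500+ planted guides at survey scale (7 species x 36 sRNAs,
1500/3000-nt rRNAs), the binomial consistency of the non-productive rate at
n > 500 guides, graph-distance agreement with an independent BFS on 100
random structures, and monotonicity of the hit set under rule tightening.
These sizes keep the default suite in the low tens of seconds while leaving
every property at a scale where failures would be visible.

## Known limitations

* The strict/relaxed rules are a deterministic reconstruction of criteria
  that historically included manual curation; counts on real data will
  differ where human judgement accepted divergent boxes or rejected
  borderline duplexes.
* tRNA and 5S rRNA targets are supported only generically (any FASTA can be
  scanned); no tRNA-specific logic exists.
* No thermodynamic scoring (nearest-neighbour free energies); ranking is by
  pair counts only.
* Secondary structures must be supplied; the package does not predict them.

## A minimal worked example

```{r, eval = FALSE}
library(cdguide)

ds <- generate_dataset(synthetic_spec(seed = 1, n_species = 3,
                                      n_srnas_per_species = 20))
dir <- tempfile()
write_dataset(ds, dir)
res <- run_pipeline(file.path(dir, "config.yaml"))
res$report$global
res$conservation$totals
head(res$guide_pairs)
```
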