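---
title: "Methods: characterising venom N-glycoproteomes from identification tables"
author: "venomglyco"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: characterising venom N-glycoproteomes from identification tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(venomglyco)
library(dplyr)
```

## The problem

Snake venoms are dominated by secreted, heavily N-glycosylated toxins
(metalloproteinases, serine proteinases, L-amino acid oxidases and others).
Bottom-up glycoproteomics characterises them along two complementary tracks:

1. **De-N-glycosylated peptides.** After enzymatic glycan release, the
   formerly glycosylated asparagine is deamidated to aspartate (+0.984 Da).
   A deamidated Asn sitting on a canonical sequon N-X-S/T (X ≠ Pro) is
   indirect evidence that the site carried a glycan.
2. **Intact glycopeptides.** Glycopeptide-aware searches assign a peptide
   backbone, a site and a glycan *composition* — a monosaccharide count
   vector such as (Hex)2 (HexNAc)2 (Deoxyhexose)1 (NeuAc)4 + (Man)3(GlcNAc)2
   — to each identified precursor.

`venomglyco` takes the tabular outputs of those searches (or a synthetic
stand-in with known ground truth) and computes the downstream
characterisation: glycosite calls, glycan classes, microheterogeneity,
co-occurrence networks, binary clustering and set intersections.

## Glycan composition calculus

Compositions are parsed from the `"(Sym)n ... + (Man)3(GlcNAc)2"` grammar;
the core segment's Man and GlcNAc counts fold into the Hex and HexNAc totals
for mass purposes and are retained for display. Masses are residue sums over
fixed monoisotopic residue masses (Hex 162.05282, HexNAc 203.07937,
Deoxyhexose 146.05791, NeuAc 291.09542 Da; water 18.010565, proton 1.00728).
A free glycan adds one water; a glycopeptide adds the glycan residue sum to
the peptide monoisotopic mass, because the Asn linkage condenses out the
water.

O-acetylation of sialic acids is modelled as a *count* attached to the
composition (never exceeding the NeuAc count), not as a localised
modification: composition-level searches generally cannot place the acetyl
group on a specific NeuAc. Each acetyl adds 42.010565 Da (C2H2O). Because
the published composition grammar has no token for this count, the package
formats it as an `(Acetyl)n` token in the antenna segment so that acetylated
variants round-trip through a single canonical string; the TSV interfaces
additionally carry an `o_acetyl` column.

Classification is the two-way split used for venom glycans: **high-mannose**
iff total HexNAc = 2, no deoxyhexose, no NeuAc and total Hex ≥ 5 (the named
high-mannose catalogue entries are Man5 and Man6); everything else is
**hybrid/complex** — the two are not separable from composition alone, so
they are reported jointly. Fucosylation and sialylation flags follow
directly from the deoxyhexose and NeuAc counts.

Diagnostic oxonium ions are computed as singly protonated fragments with 0–2
water losses:

```{r ions}
diagnostic_ion_table()
```

The three-member NeuAc-dimer dehydration series (m/z ≈ 583.198, 565.188,
547.177) is the MS/MS signature of a disialic antenna; the 334.113/316.103
pair marks an O-acetylated NeuAc. The package reproduces these masses
without asserting a specific isomeric structure behind them.

## Site calling from deamidation evidence

`find_sequons()` scans N-X(≠P)-S/T; N-X-C, N-X-V and the reverse S/T-X-N
variants can be reported but are flagged non-countable — they are described
in the literature but are not treated as putative sites.
`call_putative_glycopeptides()` applies the calling rule: a peptide is
putatively (formerly) N-glycosylated when a deamidated Asn falls on a
canonical sequon **and** the deamidated form was observed in at least 2
replicates. Two deliberate interpretations, both open in principle:

* **Replicates are pooled across fractions.** The rule counts distinct
  replicates per (sample, peptide, deamidated-site state), ignoring which
  enrichment fraction the observation came from, since fraction results are
  combined before calling.
* **Sequon context is the protein, not the peptide.** Tryptic or semitryptic
  cleavage can truncate a peptide at the sequon Asn; the S/T two residues
  downstream is then invisible in the peptide. The test therefore always
  looks up the parent protein sequence.

Redundancy collapse removes, within each (sample, protein, site), any
peptide that is an exact substring of another retained peptide covering the
same site. The surviving representatives map one-to-many onto nonredundant
sites, and the site/peptide percentage quantifies how much bottom-up
redundancy (missed cleavages, semitryptic forms, proteoforms) inflates the
peptide count.

## Intact glycopeptide assembly and statistics

`assemble_glycopeptides()` validates each row (parseable composition,
backbone mappable to the protein and covering the site, site on a canonical
sequon, optional neutral-mass consistency within 0.05 Da) and deduplicates
on (sample, backbone, site, composition, acetyl), keeping the best search
score. The counting unit for "N-glycopeptide" is the unique
(backbone, composition) pair per sample; charge states and retention times
are out of scope.

The **heterogeneity ratio** is the number of observed glycoforms divided by
the number of occupied sites, per sample and group. The numerator is the
count of unique (site, composition) pairs, which keeps the ratio ≥ 1 and
reads directly as "glycoforms per site"; an alternative numerator (distinct
compositions per group) is available behind `numerator = "compositions"`
and both counts are carried in the output, because supplementary tables in
the literature do not always disambiguate the two.

The **sialylation distribution** bins records by NeuAc count
{0, 1, 2, 3, ≥4}. By default it is restricted to hybrid/complex glycans
and, under that restriction, the zero bin is dropped so the proportions
describe the sialylated repertoire; both switches are exposed.

**Co-occurrence networks** count, for each site, every unordered pair of
distinct compositions observed there — once per site regardless of how many
records carry the pair — and keep pairs co-occurring at ≥ 3 sites. Sites
are keyed by (protein, position); networks are per sample, with a pooled
variant behind a flag.

## Clustering and intersections

Binary sample × feature matrices are built from glycopeptides
(backbone + composition), backbones, or neutral masses. Neutral masses have
no natural identity across runs, so masses are merged by single linkage with
a 0.02 Da tolerance (configurable); this tolerance is an implementation
choice, not a literature value. Samples are clustered with complete linkage
on Euclidean distances — for binary rows the squared distance is simply the
number of differing features. Samples are sorted lexicographically before
clustering, and the agglomeration is delegated to `stats::hclust`, which is
deterministic given that ordering; dendrograms export to Newick with merge
heights as branch lengths via `ape`. Exclusive (UpSet-style) intersections
count features present in *exactly* one subset of samples; the counts
conserve the union size.

## The synthetic study generator

`simulate_glyco_study()` emulates the structure of a seven-venom study so
that every stage is testable without the deposited raw data. Its defaults
are the study conditions:

* **7 samples in groups {3, 2, 2}**, mirroring the three venom groups
  observed in cross-sample clustering (a three-species complex plus two
  two-species groups).
* **12 proteins across five toxin classes** (4 SVMP with pro/catalytic/
  disintegrin/Cys-rich domain annotations, 3 SVSP, 1 LAAO, 2 CTL, 2 PLA2);
  SVMPs carry three planted sites — one each in the pro, catalytic and
  Cys-rich domains, none in the disintegrin domain — other classes two,
  for 28 planted sites. Site neighbourhoods are engineered so a clean
  12-residue tryptic peptide always covers each planted sequon.
* **Glycan repertoires of 10 compositions per group**: two high-mannose
  entries (Man5/Man6; catalogue ids A1/A2) shared by all groups plus eight
  group-specific hybrid/complex entries (including the named sialylated
  entries B11 and B43 for group 1, B22 for group 2, B32 for group 3), with
  group-graded sialylation (3–4, 2–3 and 1–2 NeuAc respectively).
* **Exactly k = 3 compositions per occupied site.** Group-level assignments
  are drawn once; each sample keeps an assignment with probability 0.9 and
  otherwise swaps it for another repertoire member, so the per-site count —
  and hence the planted global heterogeneity ratio of 3.0, inside the
  reported 1.8–3.5 range — is exact by construction. A shared high-mannose
  composition is forced into all groups' assignments at 60% of sites, which
  yields the targeted ~0.2 between-group feature overlap (0.2 × k).
* **Occupancy 0.55**: the probability that a planted site is identified in
  the intact analysis of a sample, matching the reported 40–67% recovery of
  expected sites.
* **Noise rates**: replicate dropout 0.1, spurious deamidation (on Asn
  outside sequons) 0.05, O-acetylation of sialylated records 0.15 (the
  reported acetylated proportion is 9–22%), missed-cleavage and semitryptic
  covering-peptide rates 0.5 and 0.3 — calibrated so the site/peptide
  redundancy percentage falls in the reported 52–77% band.
* **Spectra**: diagnostic ions implied by each record's composition (the
  dimer series iff ≥ 2 NeuAc, the acetyl pair iff acetylated), perturbed by
  a fixed-magnitude, random-sign 3 ppm offset. The fixed magnitude makes
  tolerance behaviour exact: at 3 ppm noise every planted ion matches at a
  10 ppm tolerance and none at 1 ppm.

One integer seed fixes the bundle bit-for-bit. What the generator does
*not* emulate: intensity and abundance models, retention time, chimeric
spectra, decoy/FDR behaviour of real search engines, shared peptides
between homologous proteins, and glycan structural isomers. Passing tests
therefore demonstrate the correctness of the *post-processing logic* under
controlled conditions, not search-engine performance on real venom data.

## Worked example

```{r pipeline}
bundle <- simulate_glyco_study(simulation_config(seed = 1, n_spectra = 10L))
res <- run_glyco_pipeline(bundle)

res$site_summary
res$glycopeptide_summary
res$expected_vs_identified
res$heterogeneity$global
head(res$cooccurrence$edges)
res$newick$glycopeptide
```

The dendrogram groups the three planted sample groups; the global
heterogeneity ratio equals the planted compositions-per-site; the
site/peptide and expected-site percentages fall in their configured bands.

## Numerical choices and limitations

* Monoisotopic residue masses are fixed to standard values; they reproduce
  the published diagnostic ion m/z to the printed 3 decimals.
* Frequency ties in composition rankings break lexicographically on the
  canonical composition string; co-occurrence edges are keyed with the
  lexicographically smaller composition first.
* `site_ratio()` and `expected_vs_identified()` refuse empty denominators
  rather than returning NaN.
* Peptides mapping to multiple proteins contribute a site per mapped protein
  but count once in peptide tallies; protein inference itself is out of
  scope, as are PSM scoring, FDR estimation, quantification, and glycan
  topology/linkage determination.
* Problem sizes used in the shipped tests (7 samples, 12 proteins, 28 sites,
  10–20 seeds for recovery statistics) were chosen as the smallest sizes at
  which the recovery statistics are well-resolved; they keep the whole suite
  comfortably fast on a single core.
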