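---
title: "Methods: discovering circRNA-encoded proteins with circpept"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discovering circRNA-encoded proteins with circpept}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`circpept` implements a cross-omics discovery analysis for proteins encoded
by circular RNAs in a two-group design (Sham-operated vs BOO — bladder
outlet obstruction — in the rat model the workflow emulates). This vignette
is the package's own account of the models and the choices behind them.

```{r setup, message = FALSE}
library(circpept)
```

## The circular ORF model

A mature circRNA of length $L$ is a covalent circle: position 1 abuts
position $L$ across the back-splice junction, with no inserted bases. An open
reading frame on this template may cross the junction and even traverse the
circle several times (rolling-circle translation). `find_junction_orfs()`
scans all three sense frames by working on a $(w+1)$-fold concatenation of
the sequence, where $w$ is `max_wraps` (default 4):

* every circular position carrying an ATG (including one whose codon itself
  straddles the junction) starts a candidate;
* translation proceeds codon by codon until the first in-frame stop or until
  the concatenation is exhausted; candidates without a stop are *rolling*
  ORFs, reported with `stop_found = FALSE` but never selected;
* a candidate is kept only if its codon span — stop codon included — crosses
  the junction at least once (`n_wraps >= 1`) and encodes at least `min_aa`
  residues, stop excluded.

Three conventions deserve a note. First, "more than 100 amino acids" is a
strict inequality, so `min_aa = 101`; a 100-residue ORF is rejected and a
101-residue ORF accepted, and the boundary is tested explicitly. Second,
`n_wraps` counts crossings of the *codon* span including the stop codon: on
the 12-nt worked example `TAAGCAATGGCA` the only ORF (start 7, protein `MA`)
reaches across the junction only through its stop codon, and is a junction
ORF with `n_wraps = 1`. Third, when only the stop codon crosses,
`junction_residue_index` is clamped to the last residue, keeping it inside
`[1, aa_length]`.

Only the sense strand is scanned (3 frames, not 6): the mature circle is a
single-stranded RNA, so antisense ORFs are not biologically meaningful here.
Start codons are ATG only and the standard genetic code is used — the scanner
has no alternative-initiation model.

`select_orf()` applies the "least amino acid residues" rule: among
stop-terminated junction-spanning candidates of one template, the shortest
protein wins, with ties broken by smallest start position and then by
lexicographically smallest protein. The minimum is global across frames.

## The unique region

The part of a circRNA-encoded protein that cannot come from the linear
parent — usually the junction-crossing C-terminal stretch — is its *unique
region*, the sequence that makes peptide evidence circRNA-specific. Without
a parent protein, `derive_unique_region()` uses
`[junction_residue_index, aa_length]`. With a parent, note that suffix
absence is monotone: if a suffix of the candidate is absent from the parent,
every longer suffix is absent too. The informative boundary is therefore the
*last* position whose suffix is absent (equivalently, the shortest absent
suffix): everything C-terminal of it has parent support one residue shorter,
everything from it on does not occur in the parent. The region starts there,
extended leftwards to include the junction residue when that lies earlier,
and falls back to `[junction_residue_index, aa_length]` when the candidate is
fully contained in the parent. This matches the biological reading — the
junction/C-terminal region is novel, the N-terminal region is shared — and
keeps the region non-empty for every junction-spanning candidate.

## Origin classification

Each back-splice event gets exactly one of seven classes, by fixed
precedence:

1. if both back-splice sites fall inside exons of a same-strand gene, the
   class is the highest-precedence feature type found at the two sites
   (CDS > 5'UTR > 3'UTR); if neither site lies in an annotated CDS/UTR the
   class is `exon_other`;
2. otherwise an event fully inside a same-strand gene is `intron`;
3. otherwise an event overlapping genes only on the opposite strand is
   `antisense`;
4. everything else is `intergenic`.

The precedence makes the partition deterministic, and classification is
invariant to the order of annotation rows (ties are resolved by sorted gene
id). Events with unknown strand are classified against genes of either
strand and treated as plus-strand for sequence extraction. Coordinates are
1-based inclusive throughout, matching GFF3. Some catalogs distinguish
"introns" from "intronic" events; the package deliberately exposes a single
`intron` class, since no published definition separates the two.

Mature sequences of exonic events are the concatenation of annotated exonic
segments inside the span, in transcript order and reverse-complemented for
minus-strand events, so position 1 is the back-splice acceptor side;
intronic/antisense/intergenic events use the raw genomic span. Catalog
length histograms use mature length (the molecule), not genomic span.

## Differential expression

Junction counts are TPM-normalized with mature circRNA length
(`rate = count / length_kb`, rescaled to $10^6$ per sample). The headline
test is Welch's t on `log2(x + pseudocount)` with `pseudocount = 1`; the
exact Mann-Whitney U test is available via `test = "mannwhitney"` and is the
test of choice for qPCR-style validation data. Neither choice is a claim
about how any particular published dataset was analysed — the test behind
printed circRNA p-values is typically unstated — so the default is explicit,
robust for small samples, and swappable.

Significance is the printed rule taken literally: linear fold change
*strictly* greater than 2 (circRNA) or 1.5 (protein) in either direction,
together with raw p < 0.05. Benjamini-Hochberg q-values (own step-up
implementation, checked against an independent oracle) are always reported
but not used for the headline filter, mirroring practice where BH-FDR
controls peptide identification rather than DE calling. Degenerate features
are defined away from NaN: a feature constant in both groups has p = 1 when
the group means agree and p = 0 when they differ (which only happens in
noise-free simulations).

The exact Mann-Whitney null distribution is enumerated over all
$\binom{n_1+n_2}{n_1}$ assignments of the observed (mid)ranks whenever
$n_1 + n_2 \le 16$ — which covers the 7-vs-8 design — with the two-sided
p-value $P(|U - \mu| \ge |U_{obs} - \mu|)$; larger samples use the
tie-corrected normal approximation without continuity correction.

## Peptide evidence

Tryptic digestion cleaves C-terminal to K/R except before P, emits fragments
with up to 2 missed cleavages, and keeps peptides of 6-45 residues — the
window in which tryptic peptides are realistically observable by MS.
Matching is exact substring search (I/L equivalence available as an opt-in
flag; mass- or spectrum-level modelling is out of scope). A peptide supports
a candidate when it overlaps the unique region by at least `min_overlap = 5`
residues — enough to rule out trivial 1-residue overlaps while staying
permissive for short junction peptides; the knob is exposed. Validation
requires at least one unique-region peptide; coverage is the union of
matched intervals divided by protein length, so overlapping peptides are not
double-counted.

## Cross-omics integration

ORF-bearing circRNAs are tiered: `predicted` (ORF only, or a layer missing),
`expression-consistent` (circRNA significant at its thresholds, mapped
protein significant at its thresholds, same direction of change — sign
agreement only, with no magnitude proportionality requirement), and
`peptide-validated` (expression-consistent plus unique-region peptide
evidence). The tiers are nested by construction. Keeping both of the upper
tiers separate leaves both readings of a "consistent candidate" available —
with or without requiring peptide evidence — without deciding the ambiguity
one way. CircRNA-to-protein identity comes from an explicit two-column map:
the simulator provides it, and real analyses must supply their own rather
than having the package guess accession linkage.

## The synthetic-data generator

`simulate_boo_study()` emulates the study design at the call-table level (no
reads, no chimeric alignments, no spectra):

* **Reference**: random chromosomes; non-overlapping genes with 2-4 exons,
  5'UTR / CDS / 3'UTR structure and 450-900 nt introns. Gene geometry is
  chosen so every origin class except `exon_other` is placeable (under this
  gene model every exon base is annotated CDS or UTR, so `exon_other` in the
  origin mix raises a placement error; the classifier still produces the
  class for real annotations with plain exons).
* **Events**: class counts follow the requested origin mix exactly (largest
  remainder); events are placed so the classifier provably reproduces the
  requested class. Planted (coding) spans are kept pairwise disjoint and no
  event may overlap one, so genome edits cannot collide.
* **ORF planting**: for each coding event the genome is edited inside the
  back-splice span so that the mature circle contains the planted ORF — the
  codons are written across the junction, and the G of every *other* ATG
  trigram on the circle is replaced by C. That substitution can neither
  create a new ATG nor a stop codon, so the planted ORF is provably the only
  candidate; downstream recovery runs entirely on unmodified pipeline logic.
  Every 20th codon of the ORF body is a lysine, guaranteeing tryptic
  peptides of observable length. Planted proteins are 101-140 residues with
  3-30 codons upstream of the junction.
* **Counts**: negative-binomial junction reads (dispersion 0.1 by default;
  Poisson in the zero-dispersion limit), baseline means log-uniform on
  [10, 5000] — spanning the junction-read depth regime without a
  zero-inflation model. Every coding circRNA gets a planted |log2 FC| of 2;
  30% of non-coding circRNAs get the same, sign-balanced, emulating the
  broad, roughly symmetric DE profile seen at the circRNA layer.
* **Proteomics**: one protein per coding circRNA plus 5x decoy background
  proteins whose tryptic peptides are disjoint from every candidate (so any
  unique-region match from a decoy would be a bug, and tests assert there is
  none). Consistent candidates get a protein |log2 FC| of 1 — comfortably
  above the 1.5-fold threshold — with log-normal noise, sd 0.2 on the log2
  scale; no published proteomic noise model exists for this design, so the
  knob is explicit. Observed peptides are the theoretical tryptic peptides
  of every candidate and decoy, each retained with `peptide_detect_prob`
  (default 0.5); every consistent candidate is guaranteed one unique-region
  peptide (adding a semi-tryptic unique-region peptide in the rare case no
  fully tryptic peptide overlaps the region — semi-tryptic identifications
  are routine in real MS data).
* **Noise-free mode** (`noise_free = TRUE`) replaces counts by rounded means
  and abundances by exact group means, enabling *exact* end-to-end recovery
  checks: the set of expression-consistent candidates then equals the planted
  consistent set exactly. The Poisson limit alone cannot give that guarantee.

Group sizes default to 8 Sham vs 7 BOO — the validation-arm design; replicate
counts for the sequencing/proteomics arms of such studies are typically not
reported, so the generator borrows the validation design rather than guessing
a different one.

What the simulation does *not* emulate: alignment and back-splice detection
artefacts, rRNA/RNase R chemistry, isoform structure inside a circle,
batch effects, spectrum-level identification errors, or shared peptides
between candidates and their true linear parents (decoys are
peptide-disjoint by construction). Passing the recovery tests therefore
shows the pipeline's logic is correct under the stated generative model, not
that thresholds are optimal for any real tissue.

## Determinism and numerical choices

Every generator stage derives its own sub-seed from the master seed, so
identical configs give byte-identical outputs, including the written files.
TPM conservation is exact to numerical tolerance ($10^{-6}$ relative).
Reported ORF lengths exclude the stop codon, which is what makes the
101-residue boundary meaningful. De-duplication of ORF candidates is keyed
on (circular start position, protein); rotation-equivalent duplicates cannot
arise because starts are restricted to one circle. In-silico circular PCR
requires exact, unique primer sites (ambiguous sites raise an error listing
all products) and reports the shortest product going forward around the
circle from the forward primer's 5' end; products longer than the circle are
impossible.

## Problem sizes used by the test suite

The package's own checks run at deliberately chosen sizes: the ORF scanner
is verified against an independent modular-arithmetic oracle on 200 random
circles up to 300 nt; BH against `stats::p.adjust` on 1000 random p-vectors;
exact Mann-Whitney against full enumeration for group sizes totalling up to
16; DE calibration on 20 null matrices of 200 features (observed type-I
error is required to sit in [0.03, 0.07] at $\alpha = 0.05$) and power on
planted 4-fold changes at depth 1000; and end-to-end recovery on the default
200-circRNA design, noise-free (exact recovery required) and stochastic
(at least 80% average recovery over 10 seeds). These sizes make the suite
informative while keeping a full run in a few minutes on one CPU.

## Known limitations

* ORF prediction has no model of IRES- or m6A-driven initiation and no
  coding-potential score; it is a sequence rule, as in the original
  GETORF-style analyses.
* The unique-region rule is purely sequence-based; a peptide that happens to
  occur elsewhere in the proteome would still count as unique evidence here.
  Real analyses should check candidate peptides against the full proteome.
* The DE module is a thresholded two-group comparison, not a count model; a
  negative-binomial GLM framework is out of scope by design.
* GO/KEGG enrichment and figure aesthetics (heatmaps, dendrograms) are out
  of scope; the package emits the underlying tables instead.
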