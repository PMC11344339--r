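---
title: "Methods: splice-consequence analysis and founder-haplotype IBD scanning"
author: "foundersplice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: splice-consequence analysis and founder-haplotype IBD scanning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, conventions and numerical choices behind
the package, in the spirit of how an analysis package should be auditable:
every default is stated with its reason, and everything the test suite
demonstrates is qualified by what the synthetic data do and do not emulate.

## 1. Transcript models and coordinate arithmetic

A `transcript_model()` is an ordered list of exons (1-based closed genomic
intervals, listed in transcription direction), a strand, and CDS bounds in
spliced-transcript coordinates. All splice arithmetic is done in transcript
orientation; minus-strand genes are first-class, because the large axonemal
dynein genes in which splice variants of interest occur (e.g. *DNAH5*) are
minus-strand, so their c. positions increase as the chromosomal coordinate
decreases.

Conventions:

* Genomic coordinates are 1-based and closed; c. positions are 1-based from
  the A of the start codon (HGVS).
* 5'UTR (negative) and 3'UTR (`*`) c. positions are unsupported. No variant
  in the targeted-panel context the package was built for uses them, and
  excluding them keeps `c_to_genomic()`/`genomic_to_c()` mutually inverse on
  their whole domain (a property tested on thousands of random coordinates
  per strand).
* Intronic offsets follow HGVS: `+n` anchors at the last base of an exon
  (donor side), `-n` at the first base of the next exon (acceptor side).
  `genomic_to_c()` expresses an intronic position relative to the nearer
  splice site, ties going to the donor side.
* Exon/intron ordinals count from the first transcribed exon. Where a gene
  has an alternative first exon, the model as constructed pins one
  numbering — the one of the transcript record the exon table encodes — and
  all region labels (e.g. "intron 14") refer to it.

The HGVS c. parser covers exactly the dialect that appears in diagnostic
panel tables — substitution, deletion, duplication, insertion, delins, with
optional intron offsets — and refuses anything else (inversions, alleles,
conversions) with an explicit "unsupported" error. A closed dialect parsed
strictly beats a permissive parser that silently misreads an edge case.

## 2. Splice events are declared, not discovered

The consequence engine takes aberrant-splicing outcomes as *inputs*
(`splice_event()`): exon skip, partial intron retention from either end, and
exonic acceptor truncation. This mirrors how such events are established in
practice — by RT-PCR and sequencing of patient cDNA — and deliberately avoids
any splice-site strength model; upstream tools (SpliceAI, dbscSNV) are
treated as annotation sources, not re-implemented. The only nod to site
exploration is `find_acceptor_ag_sites()`, which merely lists AG
dinucleotides near an acceptor.

`apply_splice_event()` rebuilds the mature mRNA and records `delta_nt`
(altered minus wild-type length), the transcript coordinate of the 5'-most
changed base, and the altered exon structure. Retained intron fragments are
merged into the adjacent exon (a cryptic acceptor extends the downstream
exon; a cryptic donor the upstream one), so the exon-junction count is
unchanged — this matters for NMD (below).

## 3. Translation, protein HGVS, and NMD

`translate_consequence()` translates the altered mRNA with the standard
genetic code (stops UAA/UAG/UGA) from the original start codon to the first
stop and compares it with the wild-type protein:

* `frame_class` follows the mod-3 law on `delta_nt`; in-frame events report
  `aa_delta = delta_nt/3`.
* Frameshifts report `novel_aa_count` — residues after the last
  wild-type-matching residue, before the stop — and `p.Xaa#Yaafs*N` with
  `N = novel_aa_count + 1`: the HGVS `fs*N` counts the stop codon itself.
  Both numbers are reported to avoid the classic off-by-one ambiguity.
* A substitution that directly creates a stop codon is nonsense,
  `p.Xaa#*`.
* A frameshift whose shifted frame reaches the end of the mRNA without a
  stop is reported `fs*?` with `novel_aa_count = NA` rather than a made-up
  count.
* An event that removes the start codon yields an explicit `no_orf` result,
  not an exception.
* In-frame insertion/deletion p. strings are descriptive (first differing
  residue onward) and are not 3'-normalized as full HGVS prescribes;
  exact in-frame p. normalization (repeat shifting) is a documented
  limitation.

NMD (`predict_nmd()`) uses the canonical last-junction rule: a termination
codon more than 55 nt (configurable; the literature uses 50–55) upstream of
the final exon–exon junction of *the altered transcript* is predicted to
trigger decay; single-exon transcripts and final-exon PTCs escape. The rule
is applied to the altered exon structure because skipping or retention moves
the junctions. The threshold is configurable precisely because the
underlying biology is a rule of thumb, and reported NMD claims in clinical
write-ups are qualitative.

## 4. RT-PCR amplicon prediction

`predict_amplicon_sizes()` is exact arithmetic: the wild-type band is
`reverse_tx_end - forward_tx_start + 1` and each allele's band shifts by its
event's `delta_nt`; a primer falling inside a removed region yields an
explicit `primer_lost` row. Gel readings are approximate, so `gel_match()`
offers a ±10% comparator for reconciling a predicted 242-nt band with a
"~250 bp" gel estimate; internally nothing is ever rounded.

## 5. Pairwise IBD by method of moments

`ibd_mom_estimate()` estimates (Z0, Z1, Z2) — the probabilities of sharing
0/1/2 alleles identical by descent — from identity-by-state counts over
biallelic SNPs with known allele frequency p (q = 1 − p), using the
standard conditional IBS probabilities:

| | Z0 | Z1 | Z2 |
|---|---|---|---|
| IBS0 | $2p^2q^2$ | 0 | 0 |
| IBS1 | $4p^3q + 4pq^3$ | $2pq$ | 0 |
| IBS2 | $p^4 + q^4 + 4p^2q^2$ | $p^2 + q^2$ | 1 |

The moment equations are solved in IBS order (Z0 from IBS0 counts, then Z1,
then Z2 from the remaining mass), estimates truncated to [0, 1] and
renormalized, and `PI_HAT = Z2 + Z1/2`. All terms are symmetric in p ↔ q,
so allele-labeling orientation (e.g. a PED file read by minor-allele
counting) cannot change an estimate. Small-sample bias-correction factors
used by some implementations are not applied; the plain estimator is easier
to audit, and the scan design (below) compares carriers against controls
computed with the same estimator, so a shared bias cancels at the
comparison.

Consequences worth knowing:

* Identical vectors give `pi_hat = 1` exactly (all three observed counts sit
  at their Z2 expectations).
* For truly unrelated pairs the truth lies on the simplex boundary
  (Z0 = 1), so truncation gives the null estimate a small *positive* bias
  (≈ 0.01–0.05 depending on SNP count). Null behaviour should therefore be
  judged against simulated controls, never against literal zero.
* Estimates from fewer than 20 informative SNPs (configurable) are flagged
  low-confidence.

## 6. The expanding-window founder scan

`windowed_scan()` computes, for half-widths h = step, 2·step, …, max_flank
*in SNP counts* (default 50 and 500, matching array-era practice of
counting flanking SNPs rather than base pairs), the mean pairwise PI_HAT
among the carrier set over the SNPs within h positions either side of the
index SNP. Windows truncate at chromosome ends with the effective flank
recorded. Per-pair curves are retained, and a cohort-baseline curve over all
sample pairs can be requested (`include_baseline = TRUE`; off by default
purely for cost).

`control_curves()` repeats the scan for the same carriers at index SNPs
drawn uniformly over eligible positions (full flank available; optionally
excluding the scan chromosome, since random draws elsewhere in the genome
are the intended null), by rejection sampling under a non-overlap rule:
same-chromosome intervals must be separated by more than `2 * max_flank`
SNP ranks. With a fixed seed the summary is reproducible; if the panel
cannot host the requested count the achievable maximum is used with a
warning.

### Calling the shared segment

`shared_segment_call()` separates two questions:

*Is there founder-level sharing?* Decided against the control envelope:
the carrier curve must exceed control mean + 3 control SDs at the smallest
window. This is where a dispersion-based threshold is meaningful, because
the smallest window is the least diluted.

*How long is the shared segment?* A threshold-crossing on the raw curve
cannot answer this: a segment of S shared SNPs inside a window of W SNPs
dilutes the mean roughly by min(S, W)/W — hyperbolically, not sharply — so
any segment strong enough to call keeps the curve above a 3-SD envelope all
the way to `max_flank`, and the crossing point would always return the scan
limit. The extent is instead *fitted*: the control-corrected excess curve
is regressed through the origin on the dilution shape min(S, W(h))/W(h),
and S is chosen by least squares over a fine grid. Using all ten window
sizes rather than two endpoints is what makes the estimate stable: across
20 seeded replicates with a planted 275-SNP segment the fit recovers the
extent within ±50 SNPs in 20/20 (mean 283, SD 17), where an endpoint ratio
managed 13/20. When the fitted S reaches the widest window (no dilution
observed — e.g. duplicate samples), the call is flagged `unbounded` rather
than reported as a measured extent.

The genomic span in Mb is interpolated from the widest window's base-pair
extent; with the default synthetic SNP spacing (mean 22,727 bp, uniform
±50% jitter) a 275-SNP segment spans ≈ 6.25 Mb.

## 7. The pre-curation variant filter and trio phasing

`passes_filters()` applies, clause by clause with a per-clause audit:
genotype quality > 20; depth > 5 (SNP) / > 10 (InDel); gnomAD AF < 0.01;
CADD > 20; ClinVar not Benign/Likely benign; at least one protein- or
splice-altering consequence (optionally rescued by a splice score above a
configurable cutoff). All inequalities are strict. Absent AF or CADD passes
by default — a novel variant has neither, and a rare-disease filter that
discards novel variants would be self-defeating — with a `strict_absent`
mode for the conservative reading. "Conflicting" ClinVar interpretations
are retained. The filter is monotone by construction: improving any single
metric can never turn a pass into a fail (property-tested under random
perturbation). ACMG classification is deliberately out of scope: it is
expert curation, and the package only passes such labels through.

`phase_by_parents()` calls two proband-heterozygous variants *in trans*
when each traces exclusively to a different parent, *in cis* when both
trace exclusively to the same parent, and *ambiguous* otherwise (missing
parent, a parent carrying both, de novo). `inheritance_model_check()`
layers the recessive and X-linked patterns on top (AR_hom, AR_comp_het,
XL_hemizygous, inconsistent-with-Mendelian).

## 8. Synthetic data: what it emulates, what it does not

All generators are seeded and bit-reproducible, and every fixture carries a
truth record computed by direct construction (naive string assembly, inline
rule application, Mendelian transmission) — never by the engine under test.

`gen_transcript_fixture()` builds transcripts whose CDS spans the spliced
transcript (ATG … TAA, no internal in-frame stop, canonical GT..AG introns)
and can engineer a frameshift to meet its first stop after an exact number
of novel residues by resampling the downstream coding sequence. Real
transcripts have UTRs, non-canonical splice sites and biased codon usage;
none of that affects the arithmetic under test.

`gen_cohort_fixture()` draws allele frequencies from Beta(2, 2) clipped to
[0.05, 0.95] (a bell-shaped common-variant spectrum; clipping avoids the
monomorphic SNPs the estimator excludes and emulates an array content
filter), genotypes under Hardy–Weinberg with no linkage disequilibrium, and
plants a founder segment as one shared base-identical haplotype plus an
independent second haplotype per carrier (`mode = "identical"` shares both,
for twin-like fixtures). There is no recombination model inside the segment
— the founder signal of interest is a contiguous block — but an
`erosion_snps` option shortens carriers' segments independently to probe
recovery tolerance. Defaults are the conditions under which the scan is
validated: 100 samples, 4 carriers, a 275-SNP segment, 22 chromosomes of
16,000 SNPs (sized so 200 non-overlapping control intervals fit), spacing
as above. Because real genotypes carry LD, their effective number of
independent SNPs is smaller than the nominal count; passing tests on
LD-free panels demonstrates the estimator and the scan logic, not
array-specific calibration.

`gen_variant_table()` produces one-hot records — for each of the seven
filter clauses, a record failing exactly that clause — plus all-pass and
random records, labelled by an independent inline application of the rule.

## 9. Problem sizes and numerical details

The test suite validates at these scales, chosen to exercise every code
path at desk scale: coordinate round-trips on 10 random models × ~150
coordinates each; 500 random splice fixtures against a brute-force
translation oracle; the IBD estimator against a naive per-SNP loop on 100
panels of ≤ 50 SNPs at 1e−9; null and parent–offspring calibration at
5,000 SNPs; and 20 full-scale cohort replicates (100 × 352,000 genotypes,
200 control intervals each) for founder-segment recovery.

Remaining numerical conventions: missing genotypes are excluded pairwise
per SNP; monomorphic SNPs are excluded from estimation and flagged;
nearest-SNP mapping of an index position breaks ties toward the lower
coordinate; random interval placement breaks none (pure rejection
sampling, seeded); all generator randomness is isolated with a local RNG
that restores the caller's stream.

## 10. Known limitations

* No real reference annotation or genome sequence ships with the package;
  checks against published transcript-specific values (e.g. a specific
  fs*N on a RefSeq transcript) require the user to supply the exon table
  and FASTA for that transcript version.
* In-frame protein HGVS is descriptive, not 3'-normalized.
* The IBD scan is method-of-moments only: no HMM segment inference, no
  phasing, no imputation, and pairwise estimates only.
* The synthetic cohorts are LD-free; segment extents are exact in SNP
  counts but only approximately convertible to Mb on real arrays.
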