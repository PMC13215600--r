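---
title: "Models and methods behind crypticex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind crypticex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`crypticex` implements the inference chain by which a deep-intronic,
cryptic-exon-creating variant is identified in an autosomal recessive
disease: cohort-level variant prioritisation, transcript-level confirmation
from spliced reads, isoform-level resolution from long-read amplicons,
protein-level consequence prediction, and population-level allele-frequency
estimation. This vignette documents the models, the tunable parameters, the
numerical choices, and the limits of what the synthetic data can show.

## The genetic model

The disease model is a fully penetrant autosomal recessive allele. For a
cohort with roles *case*, *obligate carrier* (a parent of an affected
individual, necessarily heterozygous), *control*, and *unknown*, the
segregation predicate keeps a variant iff every case is homozygous
alternate, every obligate carrier heterozygous, and no control homozygous
alternate. Missing genotypes fail the predicate by default (conservative);
`allow_missing = TRUE` relaxes this. Samples with role `unknown` are ignored
everywhere. Treating parents as obligate carriers (rather than coding them
as unknowns and excluding them, as association tools often do) is the
stricter, biologically motivated default; both behaviours are available
through the role column.

The allelic association test is the exact two-sided Fisher test on the 2×2
table of alternate/reference allele counts in cases versus controls: the sum
of hypergeometric probabilities of all tables with the observed margins whose
probability does not exceed that of the observed table, ties included within
a relative tolerance of 1e-12. This "probability ≤ observed" rule is the one
implemented by `stats::fisher.test`, which the test suite uses as an
independent oracle. The default genome-wide threshold is p < 1e-11. For the
default cohort (7 cases, 32 controls) a perfectly segregating variant with
allele-free controls reaches p = 1/C(78,14) ≈ 9.8e-16; a handful of carrier
chromosomes among the controls raises this by orders of magnitude, which is
why the control-arm background frequency matters (below).

The filter chain is explicit configuration — segregation, association
threshold, impact screen, cross-population exclusion, in that order — because
published narratives of this kind of analysis typically interleave these
steps ambiguously. The impact screen defaults to keeping all four SnpEff
classes (HIGH/MODERATE/LOW/MODIFIER): in the motivating study the causal
variant is a MODIFIER-class intronic SNV, so screening *for* HIGH/MODERATE
would discard it; the parameter exists to reproduce stricter protocols.

HGVS intronic names anchor to the cDNA coordinate of the nearer flanking
exonic base (`c.X+Y` when the upstream exon is nearer or equidistant,
`c.X-Y` otherwise), with alleles reported on the coding strand.

## Cryptic-exon calling from block evidence

Spliced-read evidence is consumed as block records (BED12), not raw
alignments; formalising "look at the pile-up in the intron" as merged
maximal intervals of read blocks lying strictly inside annotated introns,
with per-sample read counts. A call is emitted when summed case support is
at least `min_case_reads` (default 10) and control support divided by case
support is at most `max_control_fraction` (default 0.05). The source study
identified its cryptic exon visually and states no thresholds; these
defaults are this package's choices and both are exposed. Junction support
(a read carrying both an exonic and the intronic block) is reported but not
required, since short-read evidence typically does not define the boundaries
precisely — exact boundaries belong to the amplicon stage. Variant offsets
within a called exon are counted from the coding-strand 5' end, so "eighth
base pair" is well defined on minus-strand genes.

## Amplicon clustering and consensus

Long-read amplicons are subsampled per sample (default 100,000), trimmed by
exact primer match (forward primer at the 5' end and reverse-complemented
reverse primer at the 3' end, in either read orientation; anything else is
rejected with a reason code, mirroring the "inexact primer match omitted"
protocol), and greedily clustered: reads sorted by length descending (ties
by id ascending), each read joining the first cluster whose *founding read*
(centroid) it matches at ≥ 98% global identity, else founding a new cluster.

Identity is defined exactly: identical columns divided by total columns of
an optimal global alignment under match +1, mismatch −1, gap column −2, with
gap columns counting against identity. Word-based heuristics of common
clustering tools approximate this quantity; an exact DP definition is
reproducible and oracle-testable. The hot path uses a provably equivalent
decision cascade: (i) for equal lengths, if the gap-free (Hamming) identity
reaches the threshold the optimal alignment's identity can only be higher,
so accept; (ii) any alignment with identity ≥ t performs at most
2(1−t)·L/(1+t) edit operations, so a banded Levenshtein distance above that
bound rejects; (iii) remaining cases run a banded scoring DP whose band
provably contains every alignment able to reach the threshold. The test
suite checks the cascade against the plain full-matrix definition and
against a brute-force clustering oracle.

Significant clusters hold strictly more than `sig_frac = 0.10` of at least
one sample's post-trim reads (raw versus trimmed totals is ambiguous in the
protocol this models; post-trim is used). Classification: a cluster is
`case_only` iff every control sample holds fewer than `min_reads = 5` of its
reads and some case holds at least that many; symmetric for `control_only`;
else `shared`.

Consensus: up to `consensus_k = 25` members are star-aligned to the
centroid, per-column majority is taken (ties resolved to the centroid's
symbol, keeping the consensus in A/C/G/T; majority-gap columns deleted).
With i.i.d. substitution errors well below 50% per column the consensus
converges to the true template; per-column failure probability at 1% error
with 25 members is below 1e-4.

Consensus sequences are decomposed against the gene's genomic span by exact
18-mer seeding with maximal collinear extension. A block may absorb up to two
isolated substitutions, each backed by a run of at least four exact matches,
so a single planted SNV does not truncate a block while boundaries cannot
drift; collinear neighbours separated by ≤ 2 substituted bases are merged.
Blocks overlapping annotated exons are canonical (boundary overhangs are
reported as acceptor/donor extensions with their shift), intronic blocks are
novel. Micro-homology at splice junctions can make block ends ambiguous by a
few bases in general; the synthetic generator removes this ambiguity by
construction (below). `predict_amplicon_lengths()` reports insert lengths
*between* the primer footprints — i.e. post-trim amplicon lengths, the scale
on which cluster mean lengths are measured.

### Why the significant-cluster inventory is noisy at 98%

A consequence of clustering reads against a *raw founding read* is that two
reads with independent 1% substitution errors differ by ~2% — exactly at the
98% threshold. Membership of a cluster is then a coin-flip governed by the
error count of its centroid, and abundant templates stochastically fragment
into one large plus several smaller clusters. When a fragment of an abundant
(e.g. 50%-of-sample) haplotype exceeds the strict 10% rule, an extra
"significant" cluster appears; when the main fragment of a low-abundance
long isoform falls short, a real cluster disappears. The acceptance script
measures the probability of recovering the idealised inventory (exactly 2
shared + 2 case-only significant clusters) across 100 replicate cohorts; it
is far below 1 under these study conditions, and that measured rate should
be read as a property of greedy raw-read-centroid clustering at a threshold
equal to twice the error rate, not as a defect of the simulation. Real
pipelines mitigate this by polishing centroids (consensus-based
representatives) or clustering at a threshold clear of the noise floor; both
change the algorithm being modelled, so they are deliberately not applied
here.

## Translation and premature termination

Transcripts are spliced from exon block structures in transcription order
(reverse-complemented for minus-strand genes) and translated with the
standard genetic code from the annotated CDS offset. For a novel isoform the
package reports the number of complete codons from the first codon
overlapping the first novel block up to (and excluding) the stop codon.
Insertions whose length is not a multiple of 3 are flagged as frameshifts,
with the count still computed to the encountered stop — note that an
insertion at a codon boundary with an internal stop reads "in frame" up to
that stop regardless of its total length (the 92 bp fixture exon is exactly
this case: 24 in-frame amino acids, then TGA). Mapped consensus structures
cover only the amplified region, so their novel blocks and boundary
extensions are grafted onto the full annotated exon chain before
translation. The NMD flag uses the 55-nt last-exon-junction heuristic and is
advisory only, never a filter. Selenocysteine recoding and non-standard
codes are out of scope.

## Allele frequency and expression

The carrier-screen estimator is allele counting: f̂ = (n_het + 2
n_homalt)/(2n), with standard error √(f̂(1−f̂)/(2n)). The SE includes the
square root: without it the quantity has the units of a variance and cannot
be a standard error; the estimate's metadata records the radical-free
variance alongside for comparison with sources that print the formula
without it. Simulated panels draw genotypes from Hardy–Weinberg proportions;
`exclude_homalt` redraws homozygote-affected genotypes, emulating
ascertainment of presumed-unaffected animals for a lethal recessive
condition. qRT-PCR fold change is 2^−ΔΔCt with ΔΔCt = (Ct_target,case −
Ct_ref,case) − (Ct_target,ctrl − Ct_ref,ctrl).

## The synthetic generator

`build_toy_locus()` constructs a five-exon gene on a random contig with a
fully recorded truth. The default geometry mirrors the motivating study
system: exon 2 ends at coding position 177; a 92 bp cryptic exon starts
1,771 bp into intron 2, so the planted G>C SNV at its eighth base is
c.177+1778G>C; the exon carries 24 sense codons then TGA; the exon
downstream can be 5'-extended by 143 bp from an upstream acceptor; the
RT-PCR primer footprints are placed so the post-trim insert lengths are
306 / 398 / 541 bp. All intron boundaries are canonical GT…AG, and the
cryptic exon and acceptor extension are flanked by AG…GT on the coding
strand (the real splice sites are not published; canonical dinucleotides are
used). Both strands are supported: minus-strand loci are built as the
reverse complement with flipped coordinates, and every strand-sensitive
operation is tested on both.

Two deliberate sequence constraints:

- The canonical CDS is sampled from sense codons (no internal stop), and the
  first base of every non-first exon, of the cryptic exon, and of the
  acceptor extension is never G. Since every intron begins with the donor
  "G(T)", this removes chance micro-homology across splice junctions and
  makes block decomposition boundary-exact by construction.
- The planted alternate allele is C; because no stop codon contains C, the
  substitution can never create or destroy a stop, so the premature-stop
  geometry holds for the alternate isoform independent of the variant
  placement (the variant is also validated not to fall inside the planted
  stop codon).

Cohort genotypes: the causal variant segregates perfectly; controls carry it
at a background frequency of 0.012 by default — the carrier frequency
actually measured in the breed-wide panel — with hom-alt genotypes excluded
(a lethal recessive is not present in adult controls). Decoy variants are
drawn independently from Hardy–Weinberg at their own frequencies
(0.05–0.4), and 90% of decoys are marked as observed in other breeds to
exercise the cross-population exclusion.

Spliced reads are idealised: each read covers the full exon chain of its
source isoform, so block structures are exact. Amplicon reads are
`forward primer + insert + revcomp(reverse primer)` with i.i.d.
substitutions at `error_rate` (default 1%) applied to the insert; the primer
regions stay exact except for a configurable corrupted-primer fraction that
flips one primer base (this separation keeps the corruption knob
interpretable: with it, the expected number of trim rejections is exactly
the corruption fraction). Reads are emitted in either orientation with equal
probability. Not modelled: indels and homopolymer errors, quality-score
realism, PCR chimeras, coverage biases, partial splice intermediates. A
passing end-to-end suite therefore demonstrates the *logic* of the pipeline
on clean splice structures with substitution noise — not robustness to
nanopore indel noise or alignment artefacts.

Amplicon mixtures default to 0.2/0.2/0.3/0.3 over the two canonical
haplotypes, the cryptic and the extended isoform in affected samples
(matching a gel with three visible products and allelic diversity in the
canonical band) and 0.5/0.5 over the canonical haplotypes in controls. The
two canonical haplotypes differ by 8 substitutions (~2.6%), enough to found
separate clusters at the 98% threshold, as observed in the study's two
shared ~306 bp clusters. The faint ~480 bp control band reported in the
source gels is left unmodelled, as its isoform was never resolved.

## Reproducibility and problem sizes

Every generator takes one integer seed and leaves the global RNG untouched
(`withr::with_seed`); the pipeline derives one child seed per stage from its
master seed, and identical configurations produce byte-identical artifacts.
Standard problem sizes — 7/4/32 cohort, ~50 variants, 200 spliced reads and
1,000 amplicon reads per sample, 1,060-animal panels, 100-seed replicate
studies, 500-replicate estimator calibrations — were chosen so the full
suite and the acceptance script each run in minutes on a laptop core while
keeping Monte-Carlo margins (3 SE checks) comfortably away from flakiness.

## Known limitations

- Structural-variant detection, genome-wide association with kinship
  correction, differential-expression model fitting and splice-site strength
  scoring are out of scope.
- Block decomposition assumes a low-error consensus; raw noisy reads should
  be mapped with a spliced aligner instead (the block-record input is the
  documented extension point).
- The premature-stop generator only plants stops inside the cryptic exon;
  geometries whose stop falls in a downstream exon are rejected rather than
  constructed.
- The inventory-recovery ceiling discussed above is inherent to
  raw-read-centroid greedy clustering at a threshold equal to twice the read
  error rate.
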