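---
title: "Methods: two-step Sanger sequencing of monoclonal antibodies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-step Sanger sequencing of monoclonal antibodies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sangermab)
```

## The problem

Hybridoma cell lines are the classical source of monoclonal antibodies, but
they are fragile assets: clones are lost to cryo-storage accidents,
productivity drifts, and a substantial fraction of fusion partners carry
*aberrant* immunoglobulin transcripts — non-productive chains with a
frameshift at the V–J junction and a premature termination codon — that
contaminate sequencing experiments. Knowing the full-length antibody
sequence (variable *and* constant regions, at DNA and protein level)
removes the dependency on the living clone and enables recombinant
expression.

`sangermab` implements the computational layer of a two-step Sanger
workflow for exactly this task:

1. **Step 1 — variable regions.** Clone reads from RT-PCR amplicons of the
   heavy and light chain variable regions are clustered; per-cluster
   consensus sequences are called; aberrant chains are flagged; the CDR3
   junction and the closest germline V-(D-)J segments are reported; and the
   mouse IgG subclass is read directly off the CH1 stub that the
   chain-specific primers necessarily co-amplify.
2. **Step 2 — constant regions and verification.** A forward primer
   anchored on the clone-specific CDR3 is combined with an oligo(dT)
   adaptor at the poly-A tail (3' RACE) to amplify the constant regions;
   the consensus is compared against strain-level references; the
   full-length chain is assembled and translated; and the CDRs are
   verified at the protein level by MALDI-TOF peptide mass fingerprinting
   of acid- and trypsin-digested antibody.

## Consensus building and clustering

Clone reads of one transcript differ only by sequencing error, so the
package clusters reads by **single-linkage on pairwise global-alignment
identity** (identical columns / alignment columns; scoring match +1,
mismatch −1, gap open −2, gap extend −1). The default threshold of
**0.99** reflects post-trimming Sanger substitution error well below 1%;
genuinely distinct transcripts — in particular a productive kappa chain and
a fusion-partner aberrant kappa with a different V segment — fall far below
it and split cleanly. Note that two transcripts differing by *only* a
single indel on a full-length amplicon have identity ≈ 1 − 1/L and are
inseparable at any practical threshold; real aberrant transcripts differ
by much more than the junction frameshift, and the bundled synthetic
aberrant chain mirrors that.

Consensus is a **column-wise majority vote** over a progressive pairwise
alignment of members to the longest member (full MSA machinery is
unnecessary at ≥99% identity): strict majority emits the base; exact ties
emit the covering IUPAC ambiguity code; columns where gaps hold the
majority are deleted; `N` (Sanger ambiguity) never wins a vote and falls
back to the most frequent concrete base. Member order never changes the
result: members are sorted by id, and the backbone is the longest member
with ties broken by the lexicographically smallest id.

## Aberrant-chain QC

A consensus is flagged aberrant when either

* its global-alignment identity to a bundled known non-functional
  reference reaches **0.95** (the identity branch is monotone: raising the
  threshold can only un-flag), or
* its ORF contains a **premature stop**: a termination codon before 90% of
  the expected chain length. The expected length comes from the
  best-matching constant reference when available (so the natural stop in
  front of a 3' UTR is not mistaken for a premature one) and otherwise
  from the remaining coding capacity of the consensus itself.

ORF selection prefers reading frames whose first ATG falls within the
first 90 nt — a full-length antibody transcript starts with its secretion
leader, so the initiator ATG is the 5'-most start codon — and among those
picks the frame with the 5'-most ATG. Only when no frame has an ATG in the
window does the longest stop-free stretch from the frame start win.

## CDR3 localisation and germline assignment

The CDR3 is defined IMGT-style: the codons strictly between the conserved
second cysteine of framework 3 and the conserved J anchor (tryptophan for
heavy, phenylalanine/tryptophan for light chains). Rather than regex motif
search — which breaks on hypermutated frameworks — the package aligns the
best-scoring germline V and J references to the query and **projects their
annotated anchor codon positions** onto it. Reference records therefore
carry an `anchor` field (first nucleotide of the anchor codon).

Germline assignment is plain **fit-alignment percent identity** (reference
aligned end-to-end inside the query; identity over the aligned columns).
All references within **0.1 percentage points** of the best score are
reported as co-best calls, which is how multiple indistinguishable alleles
surface in practice. Both query strands are scored, since plasmid clones
sequence in either orientation. The package deliberately does not
reproduce any particular immunogenetics aligner's composite scoring;
identity percentages are descriptive.

## DNA-level isotyping

The CH1 exon of the five mouse IgG subclasses (IgG1, IgG2a, IgG2b, IgG2c,
IgG3) is highly conserved but carries short subclass-specific stretches.
`derive_motifs()` aligns one CH1 reference per subclass and reports every
**minimal-length window (8–20 nt) unique to one subclass**. Because the
chain-specific RT/PCR primers anneal inside CH1, every variable-region
amplicon automatically contains these discriminative motifs — the subclass
is read off the same consensus that yields the V region, which matters
most for IgG2c (made by C57BL/6 and NOD mice), a subclass that
protein-level lateral-flow kits often cannot distinguish from IgG2a.

Motif matching is exact (the motifs live in conserved sequence and the
query is a consensus, not a raw read). However, a minimal unique window
can be as short as 8 nt, and an isolated exact 8-mer hit occurs by chance
on a several-hundred-nt amplicon with non-trivial probability. A subclass
therefore counts as **supported only with ≥ 2 positionally coherent
hits** — same strand, same implied CH1 placement (hit position minus motif
offset). True stubs produce many coherent hits (every window overlapping
the subclass-specific block maps to the same placement); chance hits
scatter. Zero or two-plus supported subclasses yield `"ambiguous"`.

Light-chain class is assigned by **ends-free (overlap) alignment** of the
kappa/lambda constant references against the consensus, requiring at least
60 aligned columns and 0.80 identity — the amplicon carries only a
constant-region stub, so a pattern-global fit would dilute identity below
any usable threshold.

Primer binding sites are audited by **ungapped sliding** of the primer (or
its reverse complement, for the antisense RT/PCR roles) across each
reference, reporting the minimum-Hamming offset with mismatch positions in
primer 5'→3' coordinates. Ungapped is the right model: primer-site
evaluation is positional mismatch counting, and an indel under a primer
would abort annealing anyway.

## CDR3-anchored primer design and 3' RACE prediction

The constant regions are amplified between a clone-specific forward primer
and a universal oligo(dT)-ISPCR adaptor. The designed primer's **5' end is
fixed at the CDR3 start** — the junction is what makes it clone-specific —
and only the 3' end is trimmed into the CDR3 or extended into FR4 to meet
the melting-temperature window (default 55–65 °C) and length window
(15–40 nt), preferring the full CDR3. Uniqueness of the anchor in the
template is enforced.

Melting temperatures use two-state **nearest-neighbour thermodynamics**
with the unified duplex parameter set, entropy salt-corrected by
`0.368·(n−1)·ln[Na+]`, at 50 mM monovalent salt and 250 nM total primer
(`Tm = 1000·ΔH / (ΔS + R·ln(C/4)) − 273.15`). The wet protocol states no
Tm model; these are documented package constants, and
`Tm(s) = Tm(revcomp(s))` holds by construction.

The predicted 3' RACE product runs from the forward primer to the 5' end
of the poly-A tract (detected as ≥ 10 consecutive `A` within the final
50 nt) plus the full adaptor length. On the default synthetic templates
this yields 1299 nt for the heavy and 600 nt for the kappa constant
amplicon, matching the expected ~1300/~600 bp products.

## Strain-level constant-region comparison

`compare_to_strain()` globally aligns the sequenced constant region
against each strain reference, ranks by ascending nucleotide differences,
and derives amino-acid differences by codon-aligned translation.
Positions are reported **1-based in the assembled mature (leaderless)
chain** via an `aa_offset` argument (the V-(D-)J length in amino acids);
this linear numbering is the package's convention — no antibody-specific
numbering scheme (EU, Kabat) is implied — and is configurable through the
offset. On the bundled synthetic references the C57BL/6J and NOD IgG2c
constant regions differ by a single TG↔GT dinucleotide swap in CH3,
exchanging valine for glycine at mature-chain position 435.

## Peptide mass fingerprinting

CDRs are verified at the protein level by matching MALDI-TOF peak lists
against in-silico digests of the assembled chains:

* **Trypsin** cleaves after K or R except before P; default ≤ 2 missed
  sites.
* **Dilute sulfuric acid** cleaves on both sides of aspartate (Asp-X and
  X-Asp bonds); acid hydrolysis is deliberately partial, hence a higher
  default of ≤ 5 missed sites.
* Fragments outside **4–40 residues** are discarded (matrix region below,
  reflector window above).
* Masses are **monoisotopic [M+H]+** (residue masses + water 18.010565 +
  proton 1.007276); cysteine is unmodified by default because the
  reference protocol omits alkylation; carbamidomethyl is available as a
  fixed modification.
* Each peak is assigned to the theoretical peptide minimising |ppm error|
  within a **100 ppm** default tolerance (externally calibrated reflector
  MALDI); a peak matches at most one peptide, a peptide may explain many
  peaks.
* Coverage is the union of matched spans over the concatenated mature
  chains. Note that coverage is bounded above by digestibility: residues
  that no 4–40 aa fragment can contain (e.g. aspartate-free stretches
  longer than 40 aa under acid cleavage) are unreachable at any noise
  level.
* A CDR counts as **assigned only when one matched peptide fully contains
  its span** — partial overlap does not count. CDR1/CDR2 spans are
  user-supplied; the CDR3 span is located automatically from the
  annotation. Verdicts can be pooled across the trypsin and acid spectra.

## The synthetic-fixture generator

All tests run against deterministic synthetic data with known ground
truth; nothing is downloaded. The generator emulates:

* full mRNA architecture: leader + V-(D-)J + constant exons + 3' UTR +
  poly-A(30), with the documented CDR3 junctions embeddable;
* eight Sanger clone reads per chain with iid substitution errors
  (default 0.002/base, typical of trimmed Sanger traces);
* a kappa read set in which **half the reads derive from an aberrant
  transcript** (distinct V segment, 1-nt deletion at the V–J junction,
  stop codon within 25 codons of the junction), mirroring the clone
  composition that motivates the QC stage;
* CH1 references whose primer sites carry the documented per-subclass
  mismatch pattern (RT primer: exact in IgG1/2a/2b/2c, 5 mismatches in
  IgG3; PCR primer: 1 mismatch in IgG2b, 4 in IgG3) and whose motif
  blocks make every subclass identifiable;
* strain constant references differing only by the CH3 dinucleotide swap;
* MALDI peak lists from in-silico digests with peak dropout, Gaussian
  ppm jitter and uniform decoy peaks.

Back-translation randomises codon choice under a fixed internal seed:
with a one-codon-per-residue table, unrelated regions sharing a short
amino-acid run would collide at the nucleotide level and corrupt motif
uniqueness. Shared regions are back-translated once so the reference set
stays columnar. Somatic mutations are planted in the sample V regions
(4 substitutions over 294 nt heavy, 2 over 285 nt kappa), giving germline
identities of 98.6% and 99.3% — the flavour of a lightly hypermutated
clone.

What the fixtures do **not** emulate: chromatogram-level error profiles
(miscalls here are iid substitutions; real Sanger errors cluster at trace
ends), insertions/deletions in reads, chimeric reads, realistic MALDI
intensity models, isotope envelopes, and real germline databases. Passing
tests therefore demonstrate the correctness of the algorithms under the
stated error model, not database-grade annotation accuracy on arbitrary
real antibodies.

## Problem sizes and numerical choices

The test suite and the acceptance script run at the study's own scale:
8 reads per chain of 525–537 nt, reference bundles of a few kilobases,
digests of a 449-aa heavy and a 221-aa light chain (a few hundred
theoretical peptides), 200-replicate digestion oracle checks and
20-replicate consensus recovery checks. Alignment identity is always
matches/columns; ties in germline ranking are broken lexicographically;
duplicate peak m/z values are merged by intensity sum on input; peak
matching is greedy per peak (globally optimal assignment is unnecessary at
100 ppm on non-overlapping peptide masses).

## Known limitations

* Germline identity is plain alignment identity, not a composite
  immunogenetics score; values are comparable within this package only.
* CDR1/CDR2 boundaries are not called from DNA; they enter only as
  user-supplied spans to the fingerprint module.
* The premature-stop rule needs an expected chain length to be sharp near
  the 3' end; without any constant reference it falls back to the
  consensus length, which is conservative for templates with long 3' UTRs.
* Lambda light chains are handled by the same machinery as kappa but the
  bundled fixture set exercises only one lambda constant reference.
* Hairpin/dimer screening and genome-wide off-target checks are out of
  scope for the primer designer.
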