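---
title: "Methods and design notes for plastidkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for plastidkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, conventions and numerical choices behind
plastidkit, in the spirit of a methods section: what each procedure assumes,
which parameters matter, and where the design was genuinely open and a
choice had to be made. It states no empirical result that the package's
tests do not themselves compute.

## The finishing model

A chloroplast genome is treated as a circular string with the canonical
quadripartite layout LSC + IRa + SSC + IRb, where IRb is the reverse
complement of IRa and the LSC is the longer of the two single-copy regions.
Internally every coordinate is 0-based half-open on a linear representation
with an explicit circular flag; human-facing reports are 1-based inclusive,
which matches feature-table conventions. A region crossing the circular
origin is represented as two sub-intervals sharing a label.

**IR detection.** The genome is compared against its own reverse complement
by exact 31-mer seeding; co-linear exact runs on a shared diagonal are
merged while the implied mismatch fraction stays below
`max_mismatch_fraction` (default 0.001), and the maximal qualifying pair of
length ≥ `min_ir_length` (default 1,000 nt) becomes the IR. This replaces
the external homology search a manual workflow would use and is exact for
true IRs. Two open conventions had to be fixed:

* *Which copy is "IRa"?* The field does not define this consistently. Here
  IRa is the copy that follows the LSC in genome order. The label is
  internal and flagged as a convention in reports.
* *LSC vs SSC.* Disambiguated strictly by length; a tie is an error, never a
  guess. Equal-length single-copy regions do not occur in finished
  plastomes.

**Junction stitching.** The three draft contigs are joined in the order
LSC + IR + SSC + revcomp(IR). Overlap search is exact suffix–prefix matching
by default (`max_mismatches = 0`): junctions in finished assemblies are
validated by Sanger sequencing, implying exact joins, and mismatch tolerance
remains available as a parameter for noisy inputs. Both IR orientations are
tried; the orientation producing overlaps at more of the four junctions
(including the circular IRb–LSC junction, detected as a duplicated prefix of
the assembled string) wins. The 19–51 nt band on overlap lengths is purely
diagnostic — it reflects the overlap geometry draft assemblers tend to emit —
and never constrains stitching. A junction with no overlap produces a gap
record carrying ≥100 nt flanking windows (default 300 nt, motivated by the
low-GC ~300 nt stretches that confound short-read assembly near IR borders)
plus a short N placeholder in the emitted sequence; the inserted sequence
length is unknown to the stitcher, so the placeholder marks position, not
size.

**Canonical orientation.** `normalize_orientation()` rotates the circular
genome to LSC base 1. Against a reference, the LSC and SSC are flipped
independently — SSC orientation genuinely exists in two states in plastome
populations, and deposited genomes differ in LSC orientation — with the flip
decided by strand-specific k-mer identity of the two orientations
(`identity ≈ sharedFraction^(1/k)`, k = 15; below 60 % in both orientations
is an error, not a guess). Without a reference, the strand is the
lexicographically smaller of the two canonical rotations: arbitrary, but
deterministic and idempotent.

## Read mapping and coverage QC

Alignment is local (Smith–Waterman) with match +1, mismatch −2 and gap −3
per base, seeded by exact 21-mers; reads without a seed fall back to a
full-width alignment only against references under 5 kb. The published cost
parameters name costs but not an alignment mode; local alignment with free
read-end clipping is the standard short-read contract, and clipped bases
reduce the aligned read fraction exactly as a mapper's length-fraction
filter expects. Identity is defined as matches / alignment columns, with
gap columns counting — the definition is stated prominently because it
shifts boundary cases at the acceptance threshold. Acceptance is inclusive
(≥) at `length_fraction` 0.8 and `similarity_fraction` 0.9 (strict
remapping: 0.99/0.99).

Two conventions worth knowing:

* *Multi-mapping reads.* A read aligning equally well at both IR copies is
  counted at **both** placements (weight 1 each), matching the
  double-placement behavior of common mappers over identical IRs; this is
  why IR coverage is about twice single-copy coverage and whole-genome mean
  coverage exceeds nominal depth by a factor of (1 + 2·IR/L). Primary-only
  placement (leftmost reference start, then plus strand) is a switch.
* *The circular origin.* The last bases of a linear representation cannot be
  spanned by reads, so coverage screening at 40× always flags them. The
  concatenated remapping of the IRb end to the LSC start exists precisely to
  show this is an artifact of linearization rather than an assembly error;
  callers should inspect the junction vicinity of the returned profile (the
  concatenated segment has ends of its own).

## Repeats and microsatellites

**Dispersed repeats.** A hit is a maximal pair of equal-length segments that
match within `max_hamming` (default 3) mismatches at length ≥ `min_length`
(default 30 nt), under the four-kind taxonomy: forward (direct copy),
palindromic (reverse complement), reverse (reversed only), complement
(complemented only). Maximal means no single-base extension keeps the
Hamming distance within budget; with a budget of *h*, reported hits
generally carry exactly *h* mismatches (absorbing mismatches while extending
is allowed), so several overlapping maximal windows can coexist — all are
reported, each unordered pair once. Enumeration is exact per diagonal
(O(n²) worst case), which is deliberate: genome-scale inputs here are
≤ ~160 kb and exactness is what the oracle tests certify. The IRa/IRb
duplication and its internally mirrored sub-repeats are excluded by default
(both copies inside the IRs at mirrored offsets, with a small slack for
boundary chance-extension), since the quadripartite duplication would
otherwise dominate every tally.

**SSRs.** Maximal perfect tandem runs of 1–6 nt units with MISA-style
minimum repeat counts (10/6/5/3/3/3); partial trailing units are truncated,
and motifs must be minimal (an (AT)ₙ run is di-, never mono- or tetra-).
Qualifying runs separated by ≤ 100 nt merge into a compound locus; only the
compound increments the summary, its members stay listed. Scanning covers
the full genome including both IR copies, so totals are per-genome as
deposited. Cross-genome comparison anchors each locus by exact occurrence of
its 200 nt flank in the other genome (IR loci legitimately anchor at both
copies; all anchors are checked) and pairs loci of the same unit size with
cyclically equivalent motifs.

**Genomic context.** A repeat is assigned by the midpoint of its first copy:
exon inside a feature interval, intron inside a feature's span but between
intervals, intergenic otherwise. The midpoint rule is a documented choice —
hits spanning a boundary have no canonical assignment.

## Comparative analyses

**Pairwise variation.** Both genomes are rotated to LSC start; the second is
orientation-normalized against the first. Alignment chains 31-mers that are
unique in both genomes into exact blocks (longest increasing subsequence for
co-linearity) and aligns the residual segments globally with the same
+1/−2/−3 scoring; segments without unique anchors (the IRs, by definition)
recurse with locally computed uniqueness. A SNP is an aligned column with
two differing unambiguous bases; an indel event is a maximal run of gap
columns (events, not bases, for headline counts — both are reported).
Identity below 60 % is an error. Counts from different aligners can differ
in repetitive or low-complexity stretches; the package's own convention is
exact for variant sets spaced ≥ 50 nt apart, which the tests plant.

**Pseudogenes.** CDS features are translated under the bacterial/plastid
genetic code (table 11), honoring strand, `codon_start` and circular-origin
splits; every in-frame stop before the final codon is reported. CDS lengths
not divisible by three are flagged as frame anomalies but still scanned.

**IR boundaries.** The IR-internal copy of a designated boundary gene
(ycf1 by default) is measured as the number of gene bases covered by 31-mers
shared with the IR sequence: ≥95 % of the gene is a full copy (IR
expansion), ≥200 nt a partial pseudogene, else absent. IR expansion is
flagged against an explicit comparator length (> 1 kb excess), never an
implicit database lookup.

**Foreign inserts.** 500 nt windows at 250 nt step are scored against
plastid and mitochondrial reference collections by shared 31-mer fraction,
converted to an approximate identity via `fraction^(1/k)`; mito-like means
the mitochondrial identity exceeds both the plastid identity and 70 %. The
70 % threshold parameterizes an unstated "no significant similarity"
boundary and is exposed as `identity_threshold`. Runs of non-plastid
windows ≥ 1 kb are refined to base resolution as the maximal run of bases
not covered by any plastid-shared k-mer — exact when donor and host share no
31-mer. A coverage-consistency verdict (insert depth within 2× of flank
depth) distinguishes genuine plastome residency from assembly artifacts.

## The synthetic world

The generator emulates a Chenopodiaceae-type plastome: LSC 80–85 kb,
IR 23–29 kb, SSC 18–19 kb, genome GC ~36 % (per-region overrides support
the SSC's ~29 % and the IR's ~43 %), contig fragmentation with 19–51 nt
junction overlaps, optional 1,475 nt junction truncations for gap planting,
and 79 nt reads at configurable depth with i.i.d. substitution errors
(default 0.5 %, a defensible post-trimming short-read error rate).
Background bases are i.i.d. at the target GC.

Planting conventions make recovery *exact* rather than approximate, and are
worth knowing when reading the tests:

* SSR runs get period-breaking flank bases, and a 110 nt buffer around each
  planted run is scrubbed of chance tandem runs, so planted loci are
  reported at exact coordinates and never merge into accidental compounds.
  Background SSRs elsewhere are left in place — real genomes have them — so
  recovery tests assert membership, not uniqueness.
* Repeat copies get mismatching flank pairs under each kind's alignment
  geometry; a planted pair is a maximal hit exactly when searched at
  `max_hamming` equal to its planted distance (a larger budget legitimately
  extends windows past it).
* The mito donor is drawn at GC 0.45 and its edge bases are forced to differ
  from the adjacent host bases, so no junction k-mer coincides with a host
  k-mer and boundary refinement is base-exact.
* The first/last SSC bases are kept non-complementary so the maximal
  palindrome ends exactly at the constructed IR boundaries.

What the generator does **not** emulate: quality-dependent or indel
sequencing errors, paired-end fragment geometry, regional GC structure
beyond per-region targets, gene content beyond the planted boundary gene,
and real repeat/SSR landscapes. A green test therefore establishes
correctness of the algorithms under the stated world — not calibration
against any particular sequencing platform.

Determinism: all generator functions take explicit seeds, save and restore
the caller's RNG state, and are bit-identical across runs for a fixed seed.

## Known limitations

* The repeat finder's exact per-diagonal scan is quadratic; a full 160 kb
  genome takes minutes per kind on one CPU. This is acceptable at organelle
  scale and keeps the enumeration provably complete.
* The read mapper is desk-scale (tens of thousands of reads), intended for
  validation remapping, not production mapping of full HiSeq runs;
  subsample first.
* Reads wrapping the circular origin cannot fully align to the linear
  reference and are rejected at strict stringency — the same terminal
  artifact the concatenated-junction remap addresses.
* Percent-of-reads-mapped depends on the total-cellular-DNA composition of a
  real library and is reported as a statistic, never asserted against.
* IR detection assumes the IR pair does not span the circular origin of the
  input representation; inputs rotated into that state should be rotated
  (e.g. via `normalize_orientation()` on a detectable rotation) first.
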