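---
title: "Methods: SSM library design, selection enrichment, and ligand preparation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SSM library design, selection enrichment, and ligand preparation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssmenrich)
```

# Scope

`ssmenrich` implements the computational workflow used to engineer and
affinity-mature a designed small-molecule binder:

* **sequence side** — site-saturation mutagenesis (SSM) library
  enumeration and NNK primer design; paired-end read merging with Phred
  filters; single-mutant variant counting; masked log2 enrichment with
  heat-map output; and
* **structural side** — hydrated-ligand preparation (explicit water
  oxygens at idealized geometry), rotatable-bond counting, the
  design-pose filter cascade, and Shrake–Rupley buried surface area
  (dSASA).

A synthetic-data module generates libraries, selection rounds with known
per-variant fitness, and MiSeq-like paired reads, so the entire pipeline
is validated against ground truth without any external data.

# The enrichment model

For library $\ell$ (naive, or a selection round), let $f_{ij}^{\ell}$ be
the number of single-mutant reads carrying mutation type $j$ at protein
position $i$. Mutation types span $j = 1..21$: the 20 standard amino
acids plus stop. The per-position wild-type identity cell is flagged and
excluded everywhere (wild-type identities are not mutations).
Probabilities are flat normalisations over all positions and mutation
types,

$$p_{ij}^{\mathrm{select}} = \frac{f_{ij}^{\mathrm{select}}}
   {\sum_{i=1}^{N}\sum_{j=1}^{21} f_{ij}^{\mathrm{select}}},\qquad
  p_{ij}^{\mathrm{naive}} = \frac{f_{ij}^{\mathrm{naive}}}
   {\sum_{i=1}^{N}\sum_{j=1}^{21} f_{ij}^{\mathrm{naive}}},$$

and enrichment is the log2 ratio

$$E_{ij} = \log_2\!\left(\frac{p_{ij}^{\mathrm{select}}}
  {p_{ij}^{\mathrm{naive}}}\right).$$

$E_{ij}$ is reported only where the naive library has **more than 15
reads** for the mutation (`min_count = 15`, configurable). Other cells
carry an explicit mask code rather than a fudged number:

* `LOW_COUNT` — naive count at or below the threshold (drawn grey in the
  heat map, like positions with insufficient naive data);
* `WT_CELL` — the position's wild-type identity;
* `NO_DATA` — enough naive reads but zero selected reads. The true
  enrichment is strongly negative but unbounded; we report the mask
  instead of inventing a pseudocount.

Two upstream conventions are genuinely ambiguous and are exposed as
options rather than guessed:

* whether the count threshold applies to the naive library only
  (default, matching the attribution of grey heat-map cells to
  insufficient *naive* data) or to both (`require_selected = TRUE`);
* the mutation-type count: the summation range $j = 1..21$ (20 amino
  acids + stop, wild-type masked) is the default; because the wild-type
  cell is masked per position, each position effectively contributes 19
  substitutions plus stop, which reconciles the two conventions.

No pseudocount is applied by default. An optional additive
`pseudocount` exists for exploratory use and is recorded in the result
object, never silently.

Useful invariants (all property-tested): multiplying every count in both
libraries by a constant leaves all OK-cell $E_{ij}$ unchanged; swapping
the libraries negates them; adding selected reads to one cell strictly
increases its $E$ and weakly decreases every other OK cell through the
shared denominator.

# Read processing

Merging assumes ungapped suffix/prefix overlap: the reverse read is
reverse-complemented and slid along the 3' end of the forward read.
Among all overlap lengths of at least `min_overlap = 11` bases whose
mismatch fraction is at most 10%, the one maximising matched bases wins.
Two safeguards avoid silent errors:

* if two offsets tie on matched bases the pair is rejected as
  `ambiguous` — never resolved arbitrarily;
* if no offset qualifies the pair is rejected as `no_overlap`.

Within the overlap, agreeing bases take the capped Phred sum (cap 41,
the usual "both reads agree" ceiling); disagreeing bases take the
higher-Phred call, keeping that Phred (the forward call on exact ties).
The 10% mismatch tolerance and the cap are not dictated by the upstream
protocol; they match common merger behaviour and are recorded in the QC
parameter object. Merged reads then pass the Phred filters: mean
quality at least 18 and minimum per-position quality at least 12 —
both thresholds are inclusive, and raising either can only shrink the
passing set (tested as a monotonicity property).

The merge implementation is C++ (an exhaustive offset scan with a
best-so-far bound); its decisions are checked against a pure-R
exhaustive oracle on a thousand random pairs.

# Variant counting

Merged reads are anchored to the ORF by an exact match of their
amplicon's non-coding flank plus an exact length check; no gapped
alignment is attempted, so indels or a damaged anchor yield
`INDEL_OR_LEN`. The coding window is translated with the standard
genetic code (codons containing ambiguous bases mark the read
`UNTRANSLATABLE`) and compared to the wild type: zero differences is
`WT`, exactly one is `SINGLE` (with its position and substitution),
two or more is `MULTI`. Only `SINGLE` reads enter $f_{ij}$; the other
classes are tallied for QC. Counting is order-invariant and conserves
reads (tested).

The two-amplicon layout mirrors a gene too long for one MiSeq pair: the
coding sequence splits into two codon-aligned amplicons sharing 14
codons (42 bp), each carrying one non-coding flank as its anchor. A
mutation can therefore never damage an anchor. Reads from the amplicon
that does not contain a variant's position legitimately classify as
`WT`; this halves the informative depth per mutation, exactly as in the
real two-amplicon design, and cancels out of $E_{ij}$ because it
affects both libraries equally.

# Library design

`enumerate_ssm()` pairs every non-excluded position with all 20 amino
acids, *including* the wild-type identity (tagged `is_wt`), because the
library that motivated this package counts 20 per position: 184
positions × 20 amino acids = 3680 specs for a 185-residue protein with
the start methionine excluded.

NNK degenerate codons (N = A/C/G/T, K = G/T) cover 32 codons encoding
all 20 amino acids plus exactly one stop (TAG); `expand_degenerate()`
enumerates any IUPAC triplet. Primer layout follows the two-step
overlap-PCR scheme: a forward primer carrying NNK with `flank_len`
template nucleotides on each side, and a reverse primer
reverse-complementing a window that ends just 5' of the mutated codon
and overlaps the forward primer's upstream flank. The default
`flank_len = 18` nt is a design choice (upstream primer sequences are
not available here; 18 nt flanks give conventional ~39-mer primers).
Melting temperature and secondary-structure checks are out of scope.

# The synthetic experiment

`make_wt()` draws a random ORF (ATG start, no internal stop).
`synthetic_truth()` defines the stated world:

| parameter | default | why |
|---|---|---|
| protein length | 185 aa | the motivating design's size |
| library composition | uniform over all 184 × 19 protein-level single mutants | idealised SSM pool |
| wild-type fraction | 10% | carry-over of parental template, typical of SSM pools |
| fitness | uniform on [−2, 2] per variant; wild type 0 | broad, symmetric effect range |
| read lengths | 305 / 295 nt | the two-amplicon MiSeq design |
| amplicon overlap | 14 codons = 42 bp | the stated inter-amplicon overlap |
| substitution error | 0.1% per base | MiSeq-like |
| Phred model | truncated normal, mean 32, sd 4, floor 2 | realistic score spread; the 18/12 filters reject a small nonzero fraction |

Selection is deterministic: each round multiplies a variant's frequency
by $2^{\mathrm{fitness}}$ and renormalises, so true log2 enrichment
after round $r$ is $r \times$ fitness (up to a common normalisation
constant that shifts all $E_{ij}$ equally and does not affect
correlations). Sequencing is the only stochastic step: multinomial
sampling of variants, substitution errors, and Phred draws, all flowing
from one explicit integer seed (byte-identical FASTQ per seed, tested).

What the generator does **not** emulate: PCR amplification bias,
chimeras, indels (off by default; an `indel_rate` switch exercises the
`INDEL_OR_LEN` path), quality-by-cycle profiles, and the empirical
correlation between base errors and low quality scores. A green
end-to-end test therefore establishes that the estimator recovers known
fitness under idealised sequencing noise — not that it is robust to
instrument-specific artefacts.

## Statistical power at the stated depth

The end-to-end validation simulates 2×10⁵ read pairs per library over
3,680 variants. Split across two amplicons, a mutation's expected naive
count is ~25 (about 49 inside the shared 42-bp window). With counts
this small, the sampling variance of $E_{ij} = \log_2(n^{sel}/n^{naive})$
is approximately $(1/\mu_{sel} + 1/\mu_{naive})/\ln^2 2$, i.e. a
standard deviation near 0.4 at 25 counts per side. Two consequences,
both visible in the acceptance tests:

* the fitness-recovery correlation sits near $r \approx 0.92$ without
  sequencing errors and degrades a few points further once 0.1%
  substitution errors add a background of spurious singles;
* a neutral (all-zero fitness) pool cannot put 99% of cells inside
  $|E| < 0.5$ — that needs >100 naive counts per cell, i.e. roughly
  half a million read pairs per library even in a one-amplicon world.

We deliberately do **not** inflate the depth, drop the error rate, or
reuse one read set for both libraries to force these numbers green: the
generator's parameters are the stated world, and the acceptance test
reports what that world yields.

# Ligand hydration geometry

Water oxygens are placed as pseudo-atoms (never entering the covalent
graph) at idealized geometry on heavy atoms only:

* **Tertiary amine** (nitrogen with three carbon neighbours, none of
  them a carbonyl carbon, not aromatic — this excludes amide nitrogens
  and selects the protonatable piperidine nitrogen in a fentanyl-like
  molecule): the water sits on the ray opposite the normalised sum of
  the three N→C unit vectors — the fourth tetrahedral vertex — at
  exactly 3.0 Å. This is the unique symmetric construction and yields
  the 109.47° tetrahedral angle on ideal input, matching the 109°
  target; a spherical grid-search oracle minimising
  $\sum(\theta - 109°)^2$ agrees within 2° on perturbed input. Planar
  nitrogens (vector sum ≈ 0) are a hard error, not a guess.
* **Carbonyl**: the water lies in the sp2 plane (carbon, oxygen, one
  substituent) at 3.0 Å from the oxygen with a 120° C–O–O angle. The
  plane admits two solutions; the upstream specification does not say
  which lone pair, so the deterministic rule is *maximal clearance*:
  the candidate with the larger minimum distance to all other heavy
  atoms wins (first azimuth on ties), and the choice is recorded in the
  site object. A carbonyl with no plane-defining substituent falls back
  to an arbitrary 120° vector and is flagged.

Both constructions are exactly distance-preserving (tested to 1e-6 Å)
and equivariant under rigid motions (tested against random rotations).

# Rotatable bonds

A bond is rotatable iff it is a single bond, acyclic (a bridge of the
heavy-atom graph, computed by `igraph::bridges()` and cross-checked
against a BFS cycle oracle), joins two non-terminal heavy atoms, and is
not an amide C–N bond. Terminal-atom and amide exclusions follow the
medicinal-chemistry convention; this rule gives 6 for fentanyl's graph,
the count the design workflow relies on. The SMILES reader covers the
organic subset needed here (aromatic atoms, branches, ring closures,
charges in brackets); stereochemistry is ignored because only
connectivity matters to this counter.

# Pose filtering and dSASA

`apply_design_filters()` is a conjunction of eight thresholds with the
inequality strictness exactly as printed in the design protocol:
SC > 0.5 (strict), IFE < −10 REU (strict), dSASA ≥ 0.8 (non-strict),
restraint ≤ 5 (non-strict), pocket RMSD < 1 Å (strict), ddG < −10 REU
(strict), and both electrostatic-field signs negative. Boundary cases
are unit-tested. Records with any missing field fail with
`missing_data` — absence never passes a filter. The survivor set is
order-independent; attrition is charged to the first failing filter in
declared order. Interface energies, restraint scores, rotamer RMSD and
field signs are *consumed* as inputs: computing them requires the
external design program's energy model, which is out of scope.

dSASA is computed from coordinates:
$\mathrm{dSASA} = 1 - \mathrm{SASA}_{complex}(L)/\mathrm{SASA}_{alone}(L)$
with Shrake–Rupley numeric SASA — golden-spiral point lattices (960
points per atom by default), Bondi radii, 1.4 Å probe. A single
isolated sphere is exact by construction (every lattice point is
accessible, so the result is $4\pi(r+w)^2$); convergence and the
enclosed-atom limit (dSASA = 1) are tested. Dock scores are treated as
higher-is-better (PatchDock polarity) with a switch for other sources,
and top-k selection breaks score ties by pose id, deterministically.

# Numerical and degenerate-input choices

* Overlap mismatch allowance uses `floor(0.1 * ov + 1e-9)`; the epsilon
  guards against binary floating-point representation of 0.1 and is
  mirrored in the test oracle.
* Phred+33 encoding is assumed throughout; merged qualities are capped
  at 41 and clamped to the printable range on output.
* Empty count matrices raise `empty_library` rather than returning NaN.
* All-masked enrichment matrices render as an all-grey heat map with an
  empty numeric TSV — a valid, explicit result.
* `rmultinom()` handles variant sampling, so library draws are exact
  multinomials, not independent Poissons.

# Known limitations

* No gapped alignment: reads with real indels are counted only as
  `INDEL_OR_LEN`, never rescued.
* Codon-level counting, barcodes/UMIs, and regression-based scores
  (Enrich2-style variance models) are out of scope.
* The SMILES subset excludes stereo descriptors, isotopes beyond
  bracket digits, and multi-character organic-subset atoms other than
  Cl/Br.
* Shape complementarity and the design program's energies are consumed,
  never computed.
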