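---
title: "Methods: discovering polymorphic toxin effectors from annotated genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discovering polymorphic toxin effectors from annotated genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# The problem

Antibacterial secretion systems such as the type VI secretion system (T6SS)
deliver toxin effectors into competitor cells. Many effectors are modular:
an N-terminal marker or delivery domain specific to a secretion system,
fused to an interchangeable C-terminal toxin domain, with a cognate
immunity gene encoded immediately downstream. `toxscan` implements, as a
reusable tested pipeline, the comparative-genomics procedure for
discovering and characterizing such effector families from annotated
proteomes: iterative profile search anchored on a marker domain (FIX-like,
~80 aa) and a nuclease toxin domain (PoNe-like, a PD-(D/E)xK
phosphodiesterase family), hit curation, flank clustering,
effector/immunity neighborhood pairing, T6SS co-occurrence classification,
conservation/motif analysis, and a distance-based species tree.

Every stage is exercisable without downloads: a seeded generator emits
genomes with the statistical structure the pipeline assumes, together with
a ground-truth table, so recovery can be measured exactly.

# Profile search

## Model

A family is modeled as a pseudocounted position-specific scoring matrix.
For column $j$ and residue $a$,

$$f_{j,a} = \frac{c_{j,a} + \alpha q_a}{N_j + \alpha}, \qquad
  s(j,a) = \log_2 \frac{f_{j,a}}{q_a},$$

where $c_{j,a}$ counts residue $a$ among non-gap, non-X characters in
column $j$, $N_j$ is the column's observed count, $q$ is the background
distribution (Robinson–Robinson frequencies, renormalized) and $\alpha>0$
is the pseudocount weight (default 1). Frequencies form a simplex per
column; all scores are finite; X scores 0. Scanning is ungapped: the score
of a window is the sum of its column scores, and the best non-overlapping
windows are reported. Gapped local alignment is deliberately out of scope —
for planted-domain recovery at desk scale the ungapped scan is sufficient
and exactly checkable against a brute-force oracle.

## Empirical E-values

Analytic Karlin–Altschul statistics are replaced by calibration against
decoys drawn i.i.d. from $q$ with lengths resampled from the scanned
database. Each decoy contributes its best window score; within the observed
range the E-value of score $s$ is the fraction of decoys scoring $\ge s$.
Beyond the decoy maximum the right tail is extrapolated exponentially
(peaks-over-threshold; scale = mean excess over the upper decile of decoy
scores):

$$E(s) = \frac{1}{n}\exp\!\left(-\frac{s - s_{\max}}{\bar m}\right),
  \quad s > s_{\max}.$$

The mapping is monotone non-increasing with $E(s_{\max}+\varepsilon) \le
1/n$. The extrapolation matters: a pure step-function calibration admits on
the order of (database size)/(decoy count) random proteins per iteration,
and those admissions snowball across profile rebuilds — the classic
profile-corruption failure that large-database analytic statistics prevent.
With the exponential tail, the protocol's nominal thresholds of $10^{-6}$
(inclusion) and $10^{-9}$ (reporting) map to finite score cut-offs well
above every decoy. Resolution within the sample is $1/n$ (default decoy
count 1000).

## Iteration

Five iterations with a 500-hit admission cap per iteration (both
configurable). Each iteration recalibrates the current profile on the
fixed decoy set, scans all proteins, admits new proteins passing the
inclusion threshold (ties at the cap broken by bits descending then
protein id), and rebuilds the profile from the seed rows plus all admitted
hit windows. Because scanning is ungapped, hit windows align
column-to-column with the profile, which makes the rebuild the
reference-anchored alignment the conservation stage also uses. The
accumulated hit set never shrinks, and the entire search is a pure
function of (seed alignment, database, config).

# Hit curation

Four rules, all boundary-inclusive and order-independent:

* **Expect**: keep hits with empirical expect $\le 10^{-9}$.
* **Length**: toxin-domain proteins must be at least 80 aa (the marker
  search skips this rule).
* **Contig ends**: a locus whose CDS is the first or last feature of its
  contig is removed ("at the end" is read as first/last CDS by feature
  index; a single-gene contig is both). This guards against truncated
  domains on assembly edges.
* **Multi-contig dedup**: loci sharing (assembly, protein id) on more than
  one contig are collapsed to one copy (lexicographically smallest contig
  id) when every occurrence has the same same-strand downstream gene —
  matched by product label — at the same intergenic bp distance; any
  disagreement keeps all copies. Occurrences that all lack a same-strand
  downstream gene count as agreeing. Product-label equality is a proxy:
  whether the original procedure matched downstream genes by accession,
  product or domain content is not stated.

Hits are per protein; curation expands them to per-(contig, CDS) locus
rows, since the last two rules act on CDS occurrences.

# Flank clustering

Marker-anchored proteins are clustered by the sequence C-terminal to the
marker; toxin-anchored proteins by the sequence N-terminal to the toxin.
Clustering is greedy-incremental in the CD-HIT style: sequences in
canonical order (length descending, id ascending); each joins the
representative of maximal identity among those with identity $\ge 0.40$
and candidate/representative length ratio $\ge 0.50$, ties to the
earliest-founded cluster, otherwise it founds a new cluster. Identity is
defined as identical aligned pairs in a global end-gap-free BLOSUM62
alignment (gap opening 10, extension 0.5) divided by the shorter sequence
length; arguments are canonically ordered first, so the measure is
symmetric. CD-HIT's exact identity denominator differs in edge cases
(alignment length vs shorter sequence); ours is documented and
oracle-checkable. No k-mer prefilter is used (corpora are desk-scale); a
length-ratio prefilter skips impossible candidates.

# Neighborhoods

Adjacency is strand-aware: for a plus-strand gene the downstream neighbor
is the CDS at feature index + 1 and upstream at −1, reversed on the minus
strand. An adjacent CDS on the opposite strand yields no neighbor — the
strict reading of "directly upstream/downstream on the same strand"; a
`skip_opposite` option steps over opposite-strand genes for sensitivity
analysis. Distances are gap-only bp between CDS boundaries.

* **Pairing**: a toxin locus is paired iff its immediate same-strand
  downstream neighbor's protein carries DUF1911 (DUF1910 co-presence is
  flagged separately). Percentages are half-up at 2 decimals, so
  1389/1546 prints 89.84.
* **Upstream summary**: over marker loci with an existing same-strand
  upstream neighbor, the share whose neighbor carries a T6SS component
  (VgrG, TssL, DUF4123 or a core COG).
* **Architecture**: first matching label in the precedence order PAAR,
  DUF4280, LXG, WXG100, DUF637, Fil_haemagg_2, VgrG, SP, none; a delivery
  domain counts only N-terminal to the toxin hit, and SP requires both
  signal-peptide predictors (logical AND; a missing call is FALSE).

# T6SS classification

An assembly is T6SS-positive iff at least 9 of the 11 core-component COGs
(COG3516, COG3517, COG3157, COG3521, COG3522, COG3455, COG3523, COG3518,
COG3519, COG3520, COG3515) are present. VgrG (COG3501) is tracked
separately and excluded from the count by default — the core list is the
one shown to specifically predict T6SS, with VgrG only correlated — with an
`include_vgrg` switch for sensitivity analysis. Presence is binary per
assembly; copy number is ignored, so added evidence can only flip calls
negative-to-positive.

# Conservation and motif

A reference-anchored star alignment stands in for a full multiple
alignment: each member is globally aligned to the reference (BLOSUM62,
affine gaps) and projected onto reference columns, discarding member
insertions. This loses nothing the logo uses, because the downstream
convention removes alignment columns not represented in the reference
anyway; column numbering equals reference numbering.

Per column (gaps excluded from frequencies): $H = -\sum_a p_a \log_2 p_a$,
$IC = \log_2 20 - H - e_n$, letter heights $p_a \cdot IC$ summing to $IC$.
The small-sample correction $e_n = 19/(2 n \ln 2)$ is off by default (the
upstream rendering applies one, but the original settings are unstated).

The consensus motif emits one residue token per column whose dominant
frequency reaches $\tau$; maximal runs of $k$ non-conserved columns
collapse to `xk`, or to the variable spacer `xn` when at least 5% of
members carry a projected gap in the run. On the simulated family the
window 294–354 reads `Kx3GEx33GIDx2Yx9Yx3Ex1K`, whose conserved letters
K,G,E,G,I,D,Y,Y,E,K with the aspartate at reference position 335 are the
planted anchors; the two long spacers print as fixed-width because the
emission model plants substitutions only, never indels.

## Choosing the conservation threshold

$\tau$ is a genuinely free parameter: the level at which letters are read
off a sequence logo to write a motif string is a judgment call. Under the
generator's emission model — per-site substitution probability equal to
`divergence` except at the ten anchor columns, which mutate at a tenth of
that rate — expected column conservation is $1-d$ at background columns and
$1-0.1d$ at anchors. At the study divergence $d=0.3$ these are 0.70 and
0.97, so any threshold strictly between them separates planted signal from
family background; the default 0.5 (kept on `consensus_motif()` as a
neutral value) sits below the background level and reads the entire window
as letters, while the recovery analyses and the pipeline default use
$\tau = 0.8$, roughly midway between the two planted levels. This choice
follows from the emission model, not from tuning against test outcomes.

# Phylogeny

Conserved sites are alignment columns with no gap and no ambiguity code in
any row (complete deletion — one global site set, matching a single
printed site count). Pairwise mismatch proportions $p$ over those sites
are corrected with the one-parameter Jukes–Cantor model,
$d = -\tfrac34 \ln(1 - \tfrac43 p)$, which is monotone, satisfies
$d \ge p$, and is undefined (saturated) at $p \ge 0.75$ — saturated pairs
abort with the taxon pair named. Trees are built by standard Saitou–Nei
neighbor joining (exact on additive matrices), with negative branch-length
estimates clamped to zero under a warning; the agglomeration itself is
delegated to `ape::nj`, so Q-minimization tie-breaking is `ape`'s own —
unobservable on additive inputs, where the NJ result is unique. Newick
output prints branch lengths at a fixed 6 decimals for byte-stable
bundles.

# The synthetic corpus

`generate_corpus()` emits, as a pure function of (config, seed), feature
tables, a proteome, external-style domain annotations and ground truth.
What it emulates, and the defaults (probabilities are per the published
corpus statistics where those exist, otherwise fixed realistic choices):

* 200 assemblies of 2–4 contigs with 6–12 CDS each; decoy proteins i.i.d.
  from the background frequencies with lengths $\max(60, \mathcal N(300,
  75^2))$ — this makes decoy scan scores directly calibratable.
* Intergenic distances uniform on [1, 200] bp; adjacent decoy genes share
  strand with probability 0.8 (operon-like runs that exercise the
  same-strand adjacency rule).
* A genome carries a marker locus with probability 0.9 (occasionally two);
  a marker locus carries the C-terminal toxin domain with probability 0.7
  (otherwise only archetype residues 1–282). Family members are emitted
  from a fixed 449-residue archetype (marker region 43–121, toxin region
  283–449, motif instance 294–354, catalytic D at 335) at per-site
  divergence 0.3.
* A toxin locus has an immediately downstream same-strand DUF1911 gene
  with probability 0.8984 (DUF1910 co-annotated at 0.6); a non-truncated
  marker locus's upstream neighbor shares its strand and carries a T6SS
  component (VgrG/TssL/DUF4123) with probability 0.7014.
* A genome carries a full T6SS cluster (9–11 distinct core COGs, own
  contig) with probability 0.97; otherwise, half the genomes carry a
  partial 1–8 component cluster, so both classifier outcomes and the
  8-component near-boundary occur.
* With probability 0.05 a marker locus is placed as the first/last CDS of
  its contig (exercising the contig-end rule); with probability 0.05 a
  marker-bearing contig is duplicated, copying the downstream gene and
  distance exactly with probability 0.5 (dedupable) and perturbing the
  distance by +3 bp otherwise (non-dedupable), so both dedup branches are
  exercised. Ground truth records, per planted locus, whether it should
  survive curation.

What it does **not** emulate: nucleotide sequences (coordinates plus
protein sequences only — the tree stage consumes a separately simulated
nucleotide alignment, `simulate_rpob_alignment()`, evolved along a random
topology), indels within families, compositional bias, paralogy beyond
literal contig duplication, annotation errors, or any real divergence
statistics of the published families (no such statistics are reported;
divergence defaults are free parameters, not estimates). Passing recovery
tests therefore demonstrates correctness of the implemented rules under
the stated statistical structure, not performance on real proteomes.

# Determinism and numerical choices

One run seed fans out to per-stage child seeds via a fixed affine map
modulo $2^{31}-1$, so stages are independently re-runnable. Bundles print
floats at fixed precision (percentages 2 dp half-up, identities 4 dp,
branch lengths 6 dp), use LF line endings and "." for missing values, and
close with a manifest of md5 content hashes — identical config + seed give
byte-identical bundles. Thresholds are boundary-inclusive throughout
("at least 80 aa" keeps 80; expect $\le$ threshold keeps the boundary, a
documented choice). Degenerate inputs return empty, typed results (empty
corpus, proteins shorter than the profile, zero toxin loci print "." for
undefined percentages) rather than errors; malformed files are rejected
with named columns/rows rather than coerced.

# Problem sizes used by the tests

The test suite and the acceptance script run the full study conditions —
200 genomes (~7,400 proteins), 5 search iterations against 1000 decoys,
motif recovery over 10 family draws of 200 members, 100 random additive
matrices of 5–8 taxa, 100 clustering oracle trials of up to 20 flanks —
and smaller seeded corpora (6–40 genomes) for per-rule and property
checks. The pairing/upstream/co-occurrence statistics over the published
locus structure use deterministic preset tables carrying the published
counts (1546/1389 loci; 2881 marker proteins; 1000 genomes), built in
code; where the source prints only a percentage, the preset's
numerator/denominator are synthetic choices reproducing that percentage
under half-up 2-decimal rounding, and are labelled as such.

# Known limitations

* Ungapped scanning cannot localize domains interrupted by insertions;
  the generator plants none, real families have them.
* Empirical calibration resolution is bounded by the decoy count; the
  exponential tail extrapolation is an assumption (standard for score
  tails) rather than a guarantee.
* The star alignment is reference-biased: columns absent from the
  reference are invisible to the logo, by design.
* CD-HIT's identity definition differs from ours in edge cases; cluster
  memberships near the 40% boundary may differ from a CD-HIT run.
* `ape::nj` tie-breaking on non-additive matrices is its own; only
  additive inputs have a unique NJ tree.
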