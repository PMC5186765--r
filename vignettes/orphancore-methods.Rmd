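---
title: "Discovering and exploiting taxonomically restricted core gene families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering and exploiting taxonomically restricted core gene families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Some bacterial genera carry gene families that are present in every strain
of the genus (they belong to the *core genome*) yet have no detectable
homolog anywhere outside it. Such *orphan* (taxonomically restricted) core
genes are interesting twice over: their conservation under purifying
selection argues that they are real, functional proteins, and their
restriction to one genus makes them near-ideal molecular probes — a single
positive match in a metagenome is strong evidence that the genus is
present, and the nucleotide-level divergence between species is large
enough to tell species apart.

`orphancore` implements the complete desk-scale pipeline around this idea
for an acidophilic, biomining-associated genus of sulfur- and
iron-oxidizing bacteria and, by construction, for any comparable set of
proteomes:

1. **Discovery** — all-vs-all protein comparison, reciprocal best hits,
   single-linkage family construction, core/accessory partition, and a
   reference-database screen for taxonomic restriction.
2. **Characterization** — Nei–Gojobori Ka/Ks (the coding-evidence
   statistic), isoelectric point, molecular weight, hydropathy and
   transmembrane segments, and position relative to the replication origin.
3. **Exploitation** — concatenated nucleotide probes for species
   phylotyping, TETRA/ANI for whole-genome relatedness, and a translated
   (six-frame) screen of metagenomes and metatranscriptomes.
4. **Synthetic ground truth** — a seeded pan-genome generator that plants
   orphan families, diverged reference homologs, near-orphan traps, and
   shotgun reads, so every claim above is testable without downloads.

## Homology model

All homology decisions rest on exact affine-gap dynamic programming
(Smith–Waterman locally, Needleman–Wunsch globally), delegated to
`Biostrings::pairwiseAlignment()`, with BLOSUM62 and gap open/extend 11/1
for proteins and +2/−3 with 5/2 for nucleotides. A gap of length $L$ costs
`gap_open + (L-1) * gap_extend`, so equal open and extend penalties give
linear gap costs — the regime in which the test suite checks the affine
implementation against an independent brute-force DP oracle. We use full DP
rather than a seeded heuristic because the inputs are desk-scale; tie-breaks
among co-optimal tracebacks follow the deterministic traceback of the
underlying library, which affects only the reported alignment strings,
never the score, identity denominator, or E-value.

Raw scores become bit scores and E-values through the Karlin–Altschul
model,
$$\mathrm{bits} = \frac{\lambda S - \ln \kappa}{\ln 2},\qquad
  E = m\,n\,2^{-\mathrm{bits}},$$
with the published gapped parameters ($\lambda = 0.267$, $\kappa = 0.041$
for the protein defaults; $0.625/0.41$ for the nucleotide defaults) stored
in the scoring scheme, and $n$ equal to the total residue count of the
database actually searched at call time.

Percent identity is computed over all aligned columns *including* gap
columns, and coverage is demanded of **both** sequences. The published
family-building rule ("50% identity and 50% coverage") does not say which
sequence's coverage is meant; requiring both is the conservative, symmetric
reading, and both thresholds are exposed as arguments for sensitivity
analysis.

## Family construction and the orphan screen

Reciprocal best hits are computed per ordered genome pair (best = smallest
E-value, ties by bit score then subject id); within-genome paralog hits
never create edges. Edges surviving the identity/coverage thresholds are
clustered by connected components (single linkage), the minimal consistent
reading of "assigning each protein to one protein family"; proteins left
without edges become singleton families, so the family table is always a
partition of the input proteins (asserted on every run). A family is *core*
when every genome contributes a member — strains count as distinct genomes.

Core families are screened against a reference database that stands in for
a comprehensive protein collection with all target-genus entries removed: a
family is an orphan candidate only if **no** member has any hit at E ≤ 1e-5.
Candidates are then confirmed at the more permissive E ≤ 1e-4 with a
profile search: a PSSM is built from the family's multiple alignment
(log-odds with pseudocount 0.5, columns with >50% gaps dropped) and slid
ungapped along every reference sequence; significance is calibrated by
fitting a Gumbel law (method of moments) to maximal PSSM scores of 1000
residue-shuffled decoys drawn from the reference database, and
$E = N_{\mathrm{db}} \cdot P(\text{score} \ge S)$. This is a deliberate,
documented simplification of iterative profile searches and profile HMMs:
it has the property the pipeline needs — higher sensitivity than a single
pairwise comparison for remote homologs — without insert/delete states.

Family alignments use center-star progressive alignment (the member with
the best summed global score is the star; "once a gap, always a gap"). The
families this package aligns are by construction highly conserved, the
regime where center-star differs negligibly from iterative aligners, and
the star choice is tested against all alternative stars by sum-of-pairs
score.

## Ka/Ks as coding evidence

Codon alignments are obtained by back-translating the protein alignment
with each member's CDS (a hard precondition checks that the CDS translates
exactly to the aligned row, terminal stop codon excepted). Pairwise rates
follow Nei–Gojobori (1986): synonymous site counts per codon are the
fraction of the three possible changes per position that preserve the
amino acid, averaged over the two sequences; multi-substitution codons are
averaged over all substitution orders that avoid stop codons (falling back
to all orders in the rare all-blocked case); proportions are corrected with
Jukes–Cantor, $d = -\tfrac34\ln(1 - \tfrac43 p)$, with $p \ge \tfrac34$
flagged as saturated. Two conventions are worth stating explicitly:
stop-producing point changes count as nonsynonymous in the site
calculation, which keeps $S + N = 3\times$codons exactly (a tested
invariant), and pairs with $K_s = 0$ are excluded from the family mean
rather than treated as infinite, with the exclusion count reported. The
family-level statistic is the arithmetic mean of the defined pairwise
ratios. The implementation is validated against an independently coded
pathway-enumerating oracle and against simulations with a known
nonsynonymous acceptance probability (the generator accepts synonymous
proposals always, nonsynonymous ones with probability $\omega$, and stop
proposals never); mean recovered $\omega$ is required to sit within
max(0.05, 30%) of the target at 300 codons and 0.2 substitutions/site.

## Physicochemistry

The isoelectric point solves net charge = 0 by bisection on pH ∈ [0, 14]
to $|q| < 10^{-4}$, using the Bjellqvist pKa set — including its
residue-specific N- and C-terminal values — because that is the constant
set behind the web tool used for the published per-protein values;
molecular weights use the same tool's average residue masses plus one
water. The transmembrane caller is a Kyte–Doolittle sliding window (width
19, threshold 1.6): runs of above-threshold window centers are merged
across dips of ≤3 positions, expanded by half a window to the residues the
windows actually cover, united when overlapping, and reported if ≥19
residues. It is an explicitly documented stand-in for HMM-based membrane
topology predictors, exercised only on synthetic constructs; raising the
threshold provably never adds newly covered residues (the tested
monotonicity), though it can occasionally split one long segment in two.

## Whole-genome signatures

Tetranucleotide signatures follow the maximal-order Markov z-score
construction: for each 4-mer, the expected count from embedded 3- and
2-mer counts, its variance, and $z = (\mathrm{obs} - E)/\sqrt{\mathrm{var}}$,
computed on every contig **and its reverse complement** (counts never
cross contig boundaries), which makes the signature strand-symmetric by
construction. Palindromic 4-mers are observed twice per occurrence under
this pooling — their forward and reverse-complement observations coincide
— which would inflate their z by exactly $\sqrt2$; the signature rescales
them back to unit null variance. Relatedness is the Pearson correlation of
two 256-vectors.
On a 1-Mb i.i.d. genome the z-scores are approximately standard normal
(tested to ±0.1 in mean and standard deviation).

ANI uses the fragment method: the query is chopped into consecutive
1020-nt pieces, each aligned to the subject with `blastn` (reward/penalty
+1/−1, dust off), and fragments whose best hit reaches ≥30% identity over
≥70% of the fragment length contribute their identity to the mean;
the reported value averages the two directions, since single values per
genome pair are the convention. Genome-scale nucleotide alignment is the
one place the package shells out to the BLAST+ executables rather than
running its own DP — at 10^6×10^6 the exact matrix is not a desk-scale
object — and the calibration is tested end to end: a 1-Mb genome with 5%
random substitutions must return ANI = 95 ± 0.5.

## Probes and the translated screen

A species probe concatenates one CDS per orphan family (type strain,
family order fixed). A probe-versus-genome cell is the length-weighted
mean of per-gene best local-alignment identities (both strands, E ≤ 1e-10
per gene); genes with no passing hit contribute identity 0 at full weight,
so missing families depress the cell rather than silently shrinking the
denominator — the aggregation the published heat maps do not specify, made
explicit and configurable here. Species assignment is the arg-max over
probes with a 2-point ambiguity margin.

The metagenome screen translates every contig or read in six frames,
splits peptides at stop codons (retained as `*`), and aligns each stop-free
segment of ≥10 residues against the pooled family member proteins
(families × strains sequences) at E ≤ 1e-5, with the segment as query and
the pooled probe residues as database size. Per-hit identity is
amino-acid identity and is labelled as such — a screen that aligns
translated fragments cannot report nucleotide identity, whatever figure
captions elsewhere may suggest. A hit whose aligned segment reaches within
3 nt of a contig end while the probe protein is not fully covered is
flagged truncated.

## Replication-origin geometry

The origin is placed at the circular midpoint of the shorter intergenic
arc between *dnaA* and *dnaN* ("between the two genes" made deterministic);
a gene's position is the midpoint of its span, and its normalized origin
distance is circular distance divided by half the chromosome, so 0 is the
origin and 1 the terminus. The qualitative claim that a gene set "tends to
lie near the origin" is made quantitative with a one-sided permutation
test (10,000 same-size random subsets by default). Rotation invariance of
all distances is tested explicitly.

## The synthetic study design

The generator's defaults encode the study conditions the pipeline targets:
four species with 2/2/3/2 strains (nine genomes); 20 core families whose
reference homologs sit near 60% identity; 5 planted orphan core families;
2 "trap" families whose only out-of-genus homolog sits near 35% identity —
detectable, hence correctly rejected by the screen; 10 accessory genes per
strain; ~98% within-species and ~75% between-species protein identity
(each species branch substitutes $1-\sqrt{0.75}$ of residues, each strain
branch $1-\sqrt{0.98}$, so pairwise identities land near the targets — the
realized values are audited by global alignment in the tests); 500 decoy
reference proteins; protein lengths 80–400; and one extra strain at ~88%
identity to its nearest species, emulating a misassigned isolate that the
probes must place with its true relatives. Evolution is substitution-only
by default so that truth identities stay analytic; coding sequences follow
the protein history with uniform synonymous codon choice plus a synonymous
substitution rate per branch (10% species, 2% strain). Genomes are
single contigs: the strain's genes in shuffled order with 100–300 nt
random spacers, led by dnaA/dnaN markers.

What the generator deliberately does **not** emulate: indels and alignment
ambiguity, codon-usage and GC biases, sequencing error, paralogy and gene
transfer, and real intergenic structure. Passing tests therefore
demonstrate that the machinery is correct and calibrated on clean signals,
not that thresholds are optimal for any particular real genus.

## Problem sizes and numerical choices

The test and acceptance workloads are sized for a single CPU: the full
discovery benchmark uses the default nine-genome design (~330 proteins,
~530 reference sequences) and runs in a few minutes; phylotyping uses the
nine ~30-kb synthetic genomes; the screen's specificity check uses twenty
genus-free 10-kb shotgun communities at 1× in 150-nt reads and its
sensitivity check a ~5-kb family-gene mini-genome at 10× in three
replicates; signature calibration uses 1-Mb genomes. Bisection for pI runs
to a charge tolerance of 1e-4; permutation tests use 10,000 draws; the
profile-confirmation null uses 1000 shuffles. All randomness flows from
explicit seeds, and identical seeds reproduce outputs byte for byte
(tested).

## Known limitations

* Single-linkage over reciprocal best hits merges families connected by
  any surviving edge chain and keeps recent within-genome paralogs in
  separate families; paralog-aware orthology is out of scope.
* The profile confirmation is a PSSM, not a profile HMM; its E-values are
  calibrated empirically and are meaningful relatively, not absolutely.
* The transmembrane caller is a hydropathy heuristic; its counts are not
  comparable to HMM-based predictions on real membrane proteins.
* ANI depends on the BLAST+ executables being on the PATH.
* E-value parameters are fixed per scoring scheme rather than estimated
  per query-database composition.
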