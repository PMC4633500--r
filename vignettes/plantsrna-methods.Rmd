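---
title: "Methods: small-RNA miRNA discovery, expression and targets"
author: "plantsrna"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small-RNA miRNA discovery, expression and targets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model of the analysis

`plantsrna` re-creates, at desk scale, the standard computational
workflow used to annotate microRNAs from plant small-RNA sequencing
libraries and to measure their response to a treatment such as salt
stress.  The pipeline runs in six stages: (1) raw reads are trimmed of
their 3' adaptor, filtered to 18--25 nt, and collapsed to unique tags
with per-library counts; (2) tags matching annotated rRNA, tRNA,
snoRNA or snRNA are removed; (3) the remaining tags are mapped to the
genome ungapped, allowing at most one mismatch within the first 16 nt
of the tag; (4) genomic windows around alignments are folded and
candidate hairpin precursors pass a battery of structural criteria;
(5) accepted matures are classified against a reference catalogue as
conserved (0 mismatches), variant (1--2 by default) or novel (no
match, at least 10 supporting reads); (6) counts are normalized by
median-of-ratios size factors and tested for differential expression
with a fixed-dispersion negative-binomial exact test, and matures are
scanned against transcripts for complementarity-scored target sites.

# The folding surrogate

Hairpin evaluation needs a secondary-structure engine.  Bit-level
parity with a full thermodynamic folder is neither attainable nor
needed to test the *criteria logic*, so the package ships an explicit
surrogate energy model computed exactly by dynamic programming
(`foldRNA()`):

* pair energies: GC $-3.0$, AU $-2.0$, GU $-1.0$ kcal/mol;
* $-0.5$ for each pair stacked directly on another pair;
* $+3.0$ per hairpin loop (minimum 3 unpaired nt);
* $+1.0$ per bulge or internal loop; multiloops, which the model
  statement leaves open, also cost $+1.0$ -- the package treats "every
  loop occurrence other than a stack costs $+1.0$";
* exterior bases are free; only non-crossing structures are searched.

Energies are integers in tenths of kcal/mol, so DP comparisons are
exact; the traceback is deterministic (stack before internal loop
before hairpin before multiloop, smallest 5' index first).  Bulge and
internal loops are capped at 30 unpaired nt per side pair, the usual
Zuker-style bound; at the oracle scale ($n \le 18$) the cap is
unreachable, so the enumeration comparison is exact.  The test suite
checks the DP against complete structure enumeration on 500 random
short sequences.  Any real folding backend producing a dot-bracket
string and an MFE can replace the surrogate upstream of
`evaluateHairpin()`.

# Hairpin criteria and their operational definitions

`evaluateHairpin()` measures a folded candidate against fourteen
thresholds (`hairpinCriteria()`): at most 12 unpaired nt in any stem
bulge, at least 16 stem base pairs, MFE at most $-15$ kcal/mol,
hairpin span at least 50 nt, terminal loop at most 350 nt, mature-
region bounds (one bulge at most 8 nt, biased bulge at most 4 nt, at
most 2 biased bulges, at least 12 paired nt, at most 7 unpaired nt),
at least 80% of supporting-tag nucleotides on the stem arms, and the
stringent filter: at least 10 supporting reads, MFE at most $-40$
kcal/mol, and MFEI at least 0.85 where
$\mathrm{MFEI} = (|\mathrm{MFE}|/L \times 100) / \mathrm{GC\%}$.

The upstream pipeline never published operational definitions for
"errors", "biased errors" or "biased bulges"; the package adopts the
convention that an error is an unpaired nucleotide, a bulge is a
maximal unpaired run on one arm, and a biased bulge is a run with no
opposing unpaired run between the partners of its flanking pairs.
Every evaluation returns a per-criterion report (measured value,
threshold, verdict) so these interpretations are visible rather than
silent.  The per-bulge stem bound is applied per bulge, not summed.

Windows are excised on a ladder of flanks (20/60/120/250 nt, plus
asymmetric variants) bracketing the 57--264 nt range of known plant
precursors.  Because flanking sequence folds too, the window fold is
first decomposed into stem-loop substructures (chains of pairs
enclosing exactly one terminal loop, capped at 264 nt); each
substructure containing supporting tags is refolded on its own and
only then judged.  Overlapping accepted precursors are deduplicated
keeping the lowest MFE; strand is ignored during deduplication because
a perfect inverted repeat is a hairpin on both strands and a single
locus must not be reported twice.

The 5p/3p duplex check projects the two top-supported tags through the
pair table and demands exactly 2-nt 3' overhangs on both strands --
the signature of DCL processing.  A missing partner never invalidates
a candidate (partner strands degrade quickly in vivo); the duplex is
corroborating evidence.

# Classification

`matchReference()` scans every ungapped containment placement of the
shorter sequence in the longer (overlap at least 16 nt) and minimizes
mismatches, breaking ties toward longer overlap then smaller
identifier.  The variant band is 1--2 mismatches by default; the
methods literature sometimes uses 1--3, so
`variantMaxMismatches = 3` is available and neither convention is
silently preferred.  Novel matures require at least 10 reads summed
over all libraries and a criteria-passing precursor; their names embed
arm and read total (`pda-5p-12_17853`).  U/T is normalized everywhere
before comparison.

# Expression

Size factors follow the median-of-ratios estimator: for library $j$,
$s_j = \mathrm{median}_i\, c_{ij} / (\prod_k c_{ik})^{1/m}$ over rows
with all counts positive; the median of an even list is the mean of
the middle two.  With one library per condition, dispersion cannot be
estimated, so the negative-binomial dispersion is supplied:
$\varphi = \mathrm{BCV}^2 = 0.04$ at the default BCV of 0.2.  The
exact test conditions on the sum of the pseudo-counts (counts divided
by size factors, rounded half up) and sums the probabilities of all
splits no more probable than the observed one under
$\mathrm{NB}(\mu, \mu + \varphi\mu^2)$; with $\varphi = 0$ the
conditional law is Binomial$(s, 1/2)$.  This "small-p" construction is
checked against full enumeration and against edgeR's exact test at
equal library sizes.  Rounding pseudo-counts approximates edgeR's
quantile adjustment; the approximation is confined to
`exactTestTable()` and documented here.  Significance is the
conjunction p $< 0.05$ and BH-FDR $< 0.05$, as both thresholds are
always cited together for this analysis.  Heatmap ordering uses
complete-linkage clustering on Euclidean distances of
$\log_2(n + 1)$ normalized counts -- the distance is a package choice
(the upstream tool never states one) and is configurable.  qPCR
utilities implement $2^{-\Delta\Delta C_T}$.

# Target scanning

`scanTranscript()` slides a window of the miRNA's length along the
transcript and scores each placement position by position against the
site's reverse complement: Watson-Crick 0, G:U wobble 0.5, mismatch 1,
gap 2, doubled at miRNA positions 2--13.  The weighting scheme comes
from the cited target-prediction server's publication; only the
thresholds (expectation at most 3, hspsize 20, flanks 17/13 nt,
central window 9--11) are fixed by the analysis being reproduced, so
the weights are config-exposed (`targetParams()`).  A non-Watson-Crick
position inside the central window marks translational inhibition;
otherwise the site is a cleavage target.  Hits are selected greedily
by ascending expectation (ties leftmost) and never overlap.  The UPE
accessibility bound (25) is recorded but never computed: target-site
accessibility needs an RNA ensemble model that is out of scope, and
hits are never filtered on it.

# The synthetic world

`generateGenome()` plants MIR loci built as arm + loop + reverse-
complement arm, so the mature duplex carries 2-nt 3' overhangs by
construction; the terminal loop is drawn over {A, C} so it cannot pair
with itself, and every construct is validated by folding (single
stem-loop, planted pairing preserved) with the loop redrawn on the
rare failure.  Conserved loci copy a reference mature exactly; variant
loci plant 1--2 substitutions verified unambiguous against the whole
catalogue; novel loci stay at least 3 substitutions from every
reference.  Precursors span 57--264 nt; mature lengths are 18--25 nt
with 21 and 24 nt most common, echoing the characteristic bimodal
plant small-RNA length profile.  `simulateLibraries()` draws
negative-binomial counts (variance $\mu + \varphi\mu^2$) around
depth $\times$ baseline $\times$ fold change, splits them between arms
by the locus arm-abundance ratio (log-uniform on roughly 0.5--8, as
5p dominance is common but not universal), appends the 3' adaptor and
truncates to 36 nt -- a typical kit layout that forces nontrivial
trimming.  ncRNA contamination reads are uniform fragments of the
planted ncRNA loci with the design's length-peak weights.  Four
default libraries of unequal depth (28000/23000/21500/28100) mirror a
leaf/root by control/NaCl design scaled down ~2500-fold from a real
sequencing run so the full pipeline runs in minutes; dispersion 0.04
matches the DE model.  What the generator does *not* emulate:
sequencing errors beyond none, realistic quality strings, 24-nt
heterochromatic siRNA biogenesis, multi-locus miRNA families sharing
matures, or genome assembly artifacts.  A green end-to-end test
therefore establishes that the pipeline's logic is faithful on clean
data of realistic shape, not that it is robust to every failure mode
of a real sequencing run.

# Numerical choices and degenerate inputs

Integer energies make folding ties exact; the traceback order makes
them deterministic.  Exact-test probability ties use a relative
tolerance of $10^{-10}$, mirroring common practice for conditional
tests.  Zero-dispersion simulation rounds expectations half up rather
than sampling.  Reads whose adaptor is never found are rejected (the
insert presumably ran past the read); an adaptor match at position 1
leaves an empty insert, also rejected.  Tags must be 18--25 nt by
type contract.  All-zero count rows are removed before DE; rows with
any zero are excluded from the size-factor median but kept in the
matrix.  A count pair (0, 0) is refused by the exact test.  Empty
inputs yield empty outputs everywhere except where a contract forbids
them (empty genome, empty reference set).

# Known limitations

The energy model is a surrogate: absolute MFE values differ from
thermodynamic folders, so MFE/MFEI thresholds are meaningful relative
to this model's scale (the synthetic world is calibrated to it).
Mapping is exact-seed based and ungapped by design.  With single
libraries per condition the dispersion is an assumption, not an
estimate; p-values inherit that assumption.  GO/KEGG annotation,
phylogenetics, cross-species conservation tallies and target-site
accessibility are out of scope.
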