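---
title: "Deep mutational scanning of ParB/Noc DNA-binding specificity: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep mutational scanning of ParB/Noc DNA-binding specificity: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(b1hscan)
```

## The experiment this package analyses

ParB and Noc are paralogous bacterial DNA-binding proteins that recognise
two closely related palindromic operator sites, *parS* and *NBS*, which
differ at just two bases per half-site. Four protein residues — positions
173, 179, 184 and 201 — carry the specificity: ParB has R-T-A-G (RTAG) and
binds *parS*; Noc has Q-K-K-R (QKKR) and binds *NBS*. A combinatorial
library randomising these four positions with NNS codons (any base at the
first two codon positions, G or C at the third: all 20 amino acids plus the
single amber stop TAG; $20^4 = 160{,}000$ protein variants) is subjected to
bacterial one-hybrid (B1H) selection, in which binding to a *parS* or *NBS*
site drives *HIS3* expression and therefore growth. Deep sequencing of the
library before and after selection converts growth into per-variant read
enrichment.

`b1hscan` implements the full downstream analysis — read decoding, fitness
scoring, specificity classification, sequence-space network analysis, and
affinity-matrix clustering — together with a synthetic-data generator that
produces raw reads and count tables from a known ground-truth landscape, so
that every stage of the pipeline can be validated end to end without access
to the original sequencing archives.

## Read processing

Reads are 150-nt single-end amplicon sequences. A mixture of staggered
forward primers shifts the amplicon by 0–4 nt between reads, so decoding
cannot assume a fixed offset. The processing chain is:

1. **Trim** to the 1-based window 20–114 (`fastx_trimmer` semantics); reads
   shorter than the window are skipped.
2. **Quality filter** at Phred 28. Two modes exist because the two common
   formulations differ: `all_bases` keeps a read only if every base is at
   least Q28 (the behaviour of `fastq_quality_filter -q 28 -p 100`), while
   `mean` keeps reads whose average quality reaches Q28. The default is
   `all_bases`, matching the executable command form; the choice is logged
   in the per-stage tallies.
3. **Template match**: the read must contain, at any offset, the exact
   87-bp degenerate template — four NNS codon slots separated by fixed
   linkers. A read with no exact match, or with more than one match, is
   rejected (the ambiguous case is tallied separately rather than resolved
   by taking the first match — conservative and countable).
4. **Translate** codons at template offsets 1–3, 19–21, 34–36 and 85–87
   with the standard genetic code; variants containing the amber stop (TAG)
   or an ambiguous base are removed.
5. **Count and pool**: per-replicate counts are kept for diagnostics,
   replicates are pooled per library, and variants with a pooled count
   below 10 in a library are flagged absent from that library.

Every read lands in exactly one tally bucket (trim-skipped, quality-fail,
no-template, multi-template, stop/ambiguous, kept), and the tallies must sum
to the input count — this conservation law is enforced by the test suite
against a naive sliding-window decoder.

Reads are taken as-is in the amplicon orientation; a reverse-complement
search is available (`search_revcomp`) but off by default, since the
amplicon design fixes orientation.

## Fitness scores and classes

For each assay (parS, NBS) with its own wild type $wt$ (RTAG and QKKR
respectively), the raw fitness of variant $v$ is the log10 enrichment
relative to wild type:

$$ f_{raw}(v) \;=\; \log_{10}\frac{N_{v,\mathrm{post}}}{N_{wt,\mathrm{post}}}
 \;-\; \log_{10}\frac{N_{v,\mathrm{pre}}}{N_{wt,\mathrm{pre}}} $$

computed on pooled counts. Raw scores are then rescaled by the affine map
that sends the winning wild type to 1 and the opposite wild type to 0, so
that $f_{parS}(\mathrm{RTAG}) = 1$, $f_{parS}(\mathrm{QKKR}) = 0$,
$f_{NBS}(\mathrm{QKKR}) = 1$, $f_{NBS}(\mathrm{RTAG}) = 0$ exactly, on any
input. Variants absent (pooled count < 10) or with zero counts in the pre-
or post-library of an assay are *undefined* for that assay rather than
pseudocounted; undefined variants are excluded from the network. The two
anchors themselves are exempt from the abundance filter (they only need
nonzero counts): the losing anchor is depleted roughly tenfold in the
opposing selection and can fall below a pooled count of 10 at moderate
depth, yet the normalisation is defined in terms of its counts.

Classes use the strong/weak thresholds 0.6 and 0.2:

| class | $f_{parS}$ | $f_{NBS}$ |
|---|---|---|
| dark green | ≥ 0.6 | ≤ 0.2 |
| light green | ≥ 0.6 | 0.2–0.6 |
| magenta | ≤ 0.2 | ≥ 0.6 |
| pink | 0.2–0.6 | ≥ 0.6 |
| black (dual) | ≥ 0.6 | ≥ 0.6 |
| gray | otherwise / undefined | |

At an exact boundary the printed intervals overlap; the implementation
resolves ties by precedence — dark green over light green, magenta over
pink, and black over both weak bands — so that every score pair receives
exactly one label.

## Sequence-space networks

Functional (non-gray) variants become nodes; edges join variants that
differ by a single amino acid (`mode = "aa"`), or by a single amino acid
reachable through one nucleotide substitution (`mode = "nt"`). For the nt
graph the codon model matters: the library is NNS-encoded, so the default
codon set is the 31 NNS sense codons, but a `full_standard` model (all 61
sense codons) is available because single-nucleotide accessibility in
evolution is not constrained by the library encoding. Reports state which
model was used; under NNS, for example, alanine and lysine are two
substitutions apart (GCG vs AAG), so A–K edges exist in the aa graph but
not the nt graph.

Shortest mutational paths are enumerated exhaustively (breadth-first
distances plus full geodesic enumeration via igraph) from a source set —
by default the highly parS-specific dark-green variants matching `R..G`,
since R173 and G201 are essentially invariant in ParB orthologs — to the
NBS-specific target QKKR. From the path ensemble the package computes:

* **cumulative reach**: the fraction of sources whose geodesic distance is
  at most $k$, for $k = 0, 1, 2, \dots$ (unreachable sources never count);
* **step-feature fractions**: at step $k$, over all geodesics of length at
  least $k$ (each geodesic counted once), the fraction whose $k$-th node
  carries a feature — permissive K/R at 179 or 184, the switching residues
  Q173 or R201, or C/T/S at 201. The node at $k$ equal to the path length
  is the target itself, so every feature the target carries reaches 1 at
  the final step by construction;
* **class traversal**: the percentage of geodesics with at least one
  *intermediate* node (endpoints excluded — sources and target have fixed
  classes, and the scientific question concerns what lies between) of a
  given class.

### The random-graph null

Observed traversal percentages are compared against graphs with the same
node set and the same number of edges but random connectivity: each of the
(default 1,000) shuffles draws a uniform simple graph $G(n, m)$ on the
labelled node set — no self-loops, no multi-edges — which holds node count,
edge count and hence density fixed while destroying all structure. The
constraint list pins exactly these quantities; the degree sequence is *not*
preserved, which makes this a maximally unstructured null rather than a
configuration model. Sources disconnected from the target in a shuffle are
dropped from that shuffle's denominator (and counted). The observed value's
empirical percentile is $100 \cdot \mathrm{mean}(\mathrm{null} \le
\mathrm{obs})$; on four-node graphs this matches exhaustive enumeration of
all simple graphs with the given $(n, m)$, which the test suite verifies.

Graphs are exported as GraphML with `variant`, `class` and `degree` node
attributes — degree being the node-size proxy used by force-directed
renderings, which are deliberately out of scope (any Gephi-like tool can lay
out the exported file).

## Affinity clustering

The trajectory-scanning analysis takes a dissociation-constant matrix —
ParB plus the 15 ParB-to-Noc intermediates (every non-empty subset of the
four RTAG→QKKR substitutions) against the 16 transitional DNA sites (all
base combinations at the two discriminating positions) — and orders it by
agglomerative clustering with complete linkage on Euclidean distances,
independently for rows and columns, exactly the ordering a heatmap display
uses. Pairs with no detectable binding at the screening concentration carry
a sentinel (`NA` in memory, `ND` on disk) that is replaced by a cap value
(default 10,000 nM) before distances are computed; the published analysis
clusters a complete matrix without stating its imputation, so the cap is
exposed as a parameter. An optional log10 transform is available but off by
default, since the method statement specifies Euclidean distance on the
heatmap values themselves. Merge trees are exported as Newick strings.

The numeric values of the published affinity matrix exist only as a figure,
so the package ships a *synthetic* K_D generator (`synthetic_kd_matrix()`,
clearly labelled as such): binding strength is modelled as the variant's
parS-mode truth fitness times the site's similarity to the parS identity
bases plus the NBS-mode counterpart, with K_D = 50 nM / strength, 10%
log-normal noise, and a 4,000 nM detection limit. It reproduces the
qualitative structure — ParB binds the parS-identity site most tightly, QKKR
the NBS-identity site, and the single-swap QTAG intermediate binds nothing.

## The synthetic-data generator

The generator exists so that the pipeline's statistical behaviour can be
checked against a known truth. It has three layers.

**Truth landscape.** Every variant receives a pair $(t_{parS}, t_{NBS}) \in
[0,1]^2$. Each assay's score is a product of per-position residue weights
multiplied by a *permissive gate*: the gate is open if position 179 or 184
carries a gate residue for that assay ({K, R} for NBS — the positively
charged residues that buy non-specific phosphate-backbone affinity; {T, K,
R} at 179 and {A, K, R} at 184 for parS, since the native ParB residues
support the parS-binding mode without needing the electrostatic boost), and
multiplies the score by `gate_floor` otherwise. Hard zeros carry the
specificity logic: Q at 173 and R/K at 201 abolish the parS mode, G at 201
abolishes the NBS mode. This is the smallest rule set that reproduces the
qualitative epistasis of the selections: the single swaps R173Q (QTAG) and
G201R (RTAR) are dead, Q173+R201 together (QTAR) remain dead, and a single
K or R at 179 *or* 184 licenses them (QKAR, QTKR live on NBS).

The default weight tables are *graded*: within each position the non-zero
residues take log-spaced values from 1 down to a per-position floor (0.35
at 173, 0.75 at 179/184, 0.25 at 201), with the biologically preferred
residues at the top and the remaining order an arbitrary fixed permutation.
A graded landscape spreads true fitness broadly over $[0, 1]$, which is the
regime in which an enrichment-based estimator can be benchmarked against
truth in rank terms; a landscape concentrated at zero would make rank
recovery ill-defined regardless of sequencing depth, because the ranks
within a near-tied block are unidentifiable. The default `gate_floor` of
0.4 keeps gated variants sub-threshold (below the 0.6 class cutoff — so no
NBS binder ever lacks K/R at 179/184, preserving the permissive-residue
signature at the class level) while avoiding a large atom of exactly-dead
variants; `gate_floor = 0` recovers the hard gate. Noise is multiplicative
log-normal (`base * exp(N(0, noise_scale))`, clamped to $[0,1]$), so dead
variants stay exactly dead and the gate bound survives perturbation; the
default `noise_scale` is 0 and the two wild-type anchors are pinned to 1 by
construction.

**Selection and counts.** Pre-selection abundances are log-normal
(`abundance_sigma = 0.5`) — real libraries are uneven, and unevenness is
what exercises the 10-read filter; the true abundance distribution of the
original library is unknown, so this is a stand-in, not an inference.
Pre-library counts are multinomial draws of `depth` reads (default $10^6$
per library per replicate, three replicates); post-library probabilities
are proportional to abundance times $10^{\alpha t}$, the exact inverse of
the log10 enrichment estimator, with selection strength $\alpha = 1$.
Replicates are independent draws.

**Reads.** Each counted molecule gets NNS codons drawn uniformly among
those encoding its residues (the library was built from NNS oligos, which
weight residues by NNS codon multiplicity at synthesis but give no reason
to prefer one codon over another within a residue), embedded in the 87-bp
template at a stagger offset drawn from {0..4}, flanked to 150 nt,
subjected to per-base substitution errors at rate `error_rate`, and given
Phred qualities from a two-component mixture (Q38 / Q20 reads,
`low_qual_frac` low-quality weight) so the quality filter removes a known
fraction. With zero error rate and all-high qualities, decoding returns the
simulated counts exactly — the round-trip law the acceptance suite checks
at $10^4$ reads.

### What the generator does and does not emulate

It reproduces the features the pipeline's correctness depends on: staggered
exact-match templates, NNS codon degeneracy including amber stops, uneven
abundances, selection proportional to a known truth, sequencing error, and
a bimodal quality profile. It does **not** model PCR jackpotting, chimeric
reads, index hopping, position-dependent error profiles, or the URA3
counter-selection arm. Passing tests therefore demonstrate that the
*analysis* is correct and stable under the modelled noise sources — not
that every artefact of real sequencing data is handled.

### Parameter recovery and its depth limit

With adequate per-variant depth the estimator recovers truth accurately:
on a 2,000-variant sub-library at $10^6$ reads per library per replicate
(~1,500 reads per variant), Spearman correlation between normalised
estimates and truth exceeds 0.95 in both assays and the mean absolute error
is ~0.02 — the test suite asserts both.

At full library scale the same depth spreads ~19 pooled pre-selection reads
per variant. The estimator's noise floor is then
$\sigma \approx 0.434\sqrt{1/N_{\mathrm{pre}} + 1/N_{\mathrm{post}}}
\approx 0.13$ on the normalised scale (the wild-type count terms shift all
variants equally and cannot affect ranks), while with $\alpha = 1$ the
whole landscape is squeezed into one decade of enrichment. Rank correlation
against truth is therefore bounded near 0.86 under these conditions *even
for the most favourable possible truth distribution* (independent uniform
values), and the package's structured landscape reaches ~0.55. This is an
information limit of the measurement configuration, not an estimator
defect; the full-scale acceptance check of rank recovery at these exact
conditions is accordingly expected to fall short of high recovery
thresholds, and the depth-sufficient sub-library test above is the
demonstration that the machinery itself is sound.

## Numerical and design choices

* **Coordinates** are 1-based inclusive throughout (trimmer semantics).
* **Determinism**: every stochastic stage takes a seed; the pipeline
  expands one run seed into fixed per-stage substreams, so a stage rerun in
  isolation reproduces its output. Identical seeds give byte-identical
  FASTQ output.
* **Tie-breaks** in classification follow the stricter-class precedence
  above; leaf order in clustering follows `hclust` conventions.
* **Degenerate inputs**: empty read sets, empty classes, empty graphs and
  empty path ensembles return empty results with warnings rather than
  errors; all-zero abundance vectors, zero wild-type counts, equal anchors
  and out-of-range thresholds are hard errors.
* **Problem sizes in the test suite** were chosen to exercise every code
  path at desk scale: the exhaustive-oracle checks run on graphs of up to
  12 nodes (100 random trials), matrices of up to 6 rows, and all 210
  residue pairs; the round-trip check uses $10^4$ reads; the full-scale
  recovery run uses all 160,000 variants at $10^6$ reads per library per
  replicate; the null-model conservation check shuffles a 200-node graph
  1,000 times.
* The `pipeline_cli` surface is the exported function set
  (`validate_config()`, `run_pipeline()`, and the per-stage functions);
  a thin `Rscript` wrapper ships in `inst/scripts/b1hscan-run.R`.

## Known limitations

* Fitness has no replicate-level error model (none is defined for the
  assay); replicate agreement is reported as log-count $R^2$ instead.
* The nt-mode graph treats codon identity as unknown, using the *minimum*
  codon distance between residues; real evolutionary accessibility depends
  on the actual codon present.
* The synthetic K_D matrix is a labelled stand-in, not measured data.
* Force-directed layout is out of scope; the GraphML export carries
  everything a layout tool needs.
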