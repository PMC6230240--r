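---
title: "Can-SINE dynamics: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Can-SINE dynamics: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cansine)
```

# Scope

`cansine` analyses the dynamics of Carnivora-specific SINE retrotransposons
(Can-SINEs) from genome assemblies and RepeatMasker annotations. A typical
Can-SINE is a 150–300 bp tRNA-derived element with a (CT)n microsatellite,
an AATAAA polyadenylation signal, a poly-A tail, and 8–15 bp target site
duplications (TSDs) created at insertion. The package covers the full chain
of inference used in comparative studies of these elements:

1. fragment-aware parsing of RepeatMasker `.out` files and genome-wide
   repeat summaries with divergence landscapes;
2. selection of young, relatively intact element copies;
3. cross-species presence/absence calling at orthologous loci via flanking
   sequence similarity (the in-silico analogue of presence/absence PCR);
4. TSD detection around candidate insertions;
5. subfamily discovery from significantly co-segregating diagnostic
   mutations, with consensus refinement and median-joining networks;
6. CpG-aware age estimation and relative activity chronologies from nested
   (transposition-in-transposition, TinT) insertions.

Because none of these stages can be validated end-to-end on real genomes
without external assemblies, the package ships a first-class simulator that
evolves a four-taxon genome set with planted, fully recorded insertion
histories. Every stage is tested by truth recovery against that record.

# The substitution model

All sequence ageing uses one two-rate model. Over an interval of $t$ My,
each site is substituted independently with probability $1 - e^{-rt}$,
where $r = 0.0104$ substitutions/site/My if the site is part of a CG
dinucleotide at the start of the interval (CpG sites are hypermutable via
deamination of methylated cytosine) and $r = 0.0013$ otherwise. Both rates
are the neutral and CpG rates used for dating in the focal system. The
substituted base is uniform over the three alternatives. CpG status is
assessed once per interval (a branch of the species tree, or the age of an
inserted copy), so CpG loss within an interval is not modelled; at the
branch lengths used here (≤ 45 My) the induced bias in the realised CpG
fraction is small relative to the sampling error the tests allow for.

Age estimation inverts the same model per site class:
$\hat t_c = -\ln(1 - d_c) / r_c$ for observed class divergence $d_c$, and
the reported age is the mean of the CpG and non-CpG estimates. The
saturation-guarded logarithm matters for CpG divergences, which exceed 0.1
within ~10 My; it reduces to $d/r$ for small $d$.

# The simulator

`simulate_caniform_genomes()` evolves a uniform-random ancestral genome
(default 2 Mb, GC 0.41) down a rooted ultrametric tree. The default
topology places the dog lineage at the root (45 My), then the mustelid
(ferret) lineage (40 My), with the panda–polar bear split most recent at
15.5 My — the calibration used for absolute dating in this system.

On each branch the genome first accumulates substitutions for the branch
duration, then insertions are drawn per subfamily as a Poisson process with
rate `rate` insertions/My restricted to the subfamily's activity window
(and optionally to named branches). Rates are per lineage, not per bp:
retrotransposition intensity reflects master-element activity, not genome
size. Each copy is the subfamily source, 5'-truncated with probability
`trunc_prob` (uniform 0–50 % of the source removed; SINE truncation is
predominantly 5'), plus a sampled poly-A tail (8–30 bp), inserted on a
random strand at a uniform site with a TSD of 8–15 bp, and then aged from
its insertion time to the end of the branch. Insertions may nest inside
earlier elements — fragmenting them exactly as RepeatMasker reports
interrupted repeats — but never interrupt a recorded TSD (the site is
resampled), which keeps planted TSDs recoverable; such interruptions are
vanishingly rare at these densities in any case.

The default scenario plants three subfamilies: an older broadly active
family (window 35–5 My, 6 insertions/My), an independent older family
(45–12 My, 4/My), and a young family derived from the first by four
non-CpG diagnostic substitutions, active 15.5–0 My at 20/My. This is the
constellation the downstream stages are designed to resolve: the young
family supplies ~300 focal-branch insertions at 2 Mb, the older families
supply shared background copies and nesting hosts. No per-subfamily rate
magnitudes are available from real data at this genome size; the values
were chosen once for statistical power at 2 Mb and are not revisited.

Emitted annotations are truth-derived: the divergence column is the true
percent mismatch of each copy against the sequence that was inserted,
which deliberately decouples the simulator from the divergence estimator
under test. What the simulator does **not** model: indels outside TE
insertions, deletions of any kind, recombination, selection, assembly
error, and polymorphism within species. Consequences for interpretation:
passing tests demonstrate correctness of the inference machinery under the
stated generative model, not robustness to assembly artefacts or
polymorphic loci — both of which degrade real screens and are the reason
conservative `unresolved` handling exists.

# Presence/absence at orthologous loci

For each candidate element the package extracts 500 bp flanks, maps them
to each target genome, and classifies the locus:

* **Mapping** is seed-and-extend: exact 13-mers every 7 bp are matched
  against both strands (Aho–Corasick over all candidate flanks at once),
  grouped by diagonal into chained placements (diagonal jumps up to 2 kb
  within one placement tolerate TEs inserted into either lineage's flank),
  and the best placement is realigned with an affine local alignment whose
  gap extension is cheap (open 6, extend 0.05 against match +1 /
  mismatch −1.5), so that a 200–300 bp lineage-specific insertion in
  either sequence is bridged as one gap.
* **Repeat masking.** Flank positions covered by other annotated repeats
  are masked: they contribute no seeds, are N-masked in the extension
  alignment (N scores negatively, so the aligner bridges them as gaps
  anchored on unique sequence), and are excluded from the coverage
  denominator. A flank retaining fewer than 100 unmasked bp is treated as
  unalignable. The motivation is that repeat-derived flank sequence is not
  evidence for locus orthology — it matches every copy of its family — and
  judging the ≥ 90 % coverage rule on it produces both false negatives
  (query-side young elements can never be covered in the target) and false
  positives (the masked region aligning to a paralogous copy). Masked-flank
  comparison is the standard practice this implements.
* **Thresholds.** A hit must cover ≥ 90 % of the (unmasked) flank at
  ≥ 80 % identity over aligned bases. A locus with a second placement of
  comparable seed support, passing coverage, and identity within 0.02 of
  the best is declared paralog-ambiguous.
* **Calls.** With both flanks collinear on one scaffold and strand:
  `absent` when the inter-flank gap is ≤ 30 bp (down to −60 bp, since the
  single TSD copy at an empty site aligns to both flanks) and no
  same-family annotation is contained in the span; `present` when a
  same-family annotation contained in the span (20 bp slack) covers ≥ 50 %
  of it. Two refinements close systematic gaps observed in truth-recovery
  experiments: an element merely *crossing* a tiny span from outside
  (an adjacent copy) does not veto absence, and a larger gap fully
  accounted for by the target's own annotated insertions of other families
  is still an empty site for the queried element. Everything else is
  `unresolved` with a reason code, and any unresolved call removes the
  locus from the lineage-specific set — the conservative rule that keeps
  ambiguous and (in real data) polymorphic loci out of downstream claims.

On the default 2 Mb scenario this screen recovers ≥ 90 % of the truly
focal-branch insertions among screened candidates with a false-specific
rate ≤ 1 %; the dominant residual losses are genuine homoplasy (the target
lineage inserted a same-family copy into the same locus) and flanks almost
entirely composed of repeats, both of which are correctly left unresolved
or called shared rather than guessed.

# TSD detection

`find_tsd()` searches the 30 bp windows adjacent to the element for a
direct repeat of 6–15 bp with at most one mismatch, allowing up to 5 bp of
offset on each side because annotated element boundaries are imprecise.
The right window is taken after trimming a residual poly-A run (≥ 5 A
allowing one other base) from the element end — the Can-SINE tail sits
between the element body and the 3′ TSD copy; for minus-strand elements
the equivalent T-run on the left is trimmed. Candidates are ranked longest
first, exact before one-mismatch, then smallest offsets; the winner is
extended while the copies keep matching exactly, consuming offset slack,
so duplications longer than the search band are reported at the extent the
30 bp windows allow. Both copies must lie wholly within the windows. An
exhaustive enumeration over all (length, offset, offset) windows is kept
in the test suite as the oracle for the scanner.

# Subfamily discovery

Elements are globally aligned to the family template (affine
Needleman–Wunsch: match +1, mismatch −1, open −4, extend −1); insertions
relative to the template are dropped and deletions recorded, giving an
elements × template-columns state matrix. Copies covering < 50 % of the
template columns are excluded, mirroring the removal of heavily truncated
elements before subfamily analysis.

Splitting is recursive co-segregation testing: candidate diagnostics are
non-consensus substitution states carried by at least `min_size` members
(default 10; deletion states are excluded by default because shared
deletions are weak evidence of descent; CpG columns can be excluded since
recurrent CpG mutation produces convergent states). Every cross-column
pair of candidates is tested for association with a two-sided Fisher exact
test; the most significant pair below a Bonferroni-corrected α = 10⁻³
seeds a child subfamily, both consensuses are rebuilt by majority rule
(ties broken in the fixed order A<C<G<T<−), members are reassigned to the
nearest consensus (Hamming; ties to the larger group), and the process
recurses. The reference program's internal test is not documented, so an
explicit, reproducible test was substituted deliberately; pairwise
co-segregation (not triples) suffices for the splits exercised here and is
a documented limitation.

The median-joining network connects aligned consensuses by the
ε-relaxed minimum spanning network (with ε = 0, the union of all minimum
spanning trees), then expands the node set with median vectors
(coordinate-wise majority) of node triplets in batched passes and finally
prunes every median whose removal leaves the total tree length unchanged.
Batched addition matters: Steiner-optimal solutions can require a pair of
medians neither of which shortens the tree alone, so a greedy
one-at-a-time rule provably misses them.
Duplicate sequences merge into one node with a multiplicity. CpG columns
can be excluded from the distance, as is usual when networking CpG-rich
SINE consensuses. On small inputs the result matches a brute-force Steiner
search over added medians; on larger inputs the construction is heuristic,
as median-joining always is.

# TinT activity chronologies

`detect_nested_insertions()` counts, for each multi-fragment element,
complete elements of another family sandwiched between consecutive
fragments, requiring each adjacent outer fragment to span ≥ 4 bp (the
"minimum repeat extension", read per fragment — the reference tool leaves
this undocumented) and the outer fragments' consensus coordinates to be
collinear. The activity model fitted to the count matrix is the package's
concrete stand-in for the TinT probabilistic model: insertion times per
family are Gaussian on a relative timescale, and the expected nesting
count is $E[N_{fg}] = k\,a_f a_g\,P(T_g > T_f)$ with abundances $a$ and
independent $T$. Parameters are fitted by Poisson maximum likelihood from
multiple deterministic-plus-jittered starts (BFGS, log-parameterised
σ, k). The likelihood is invariant under affine rescaling of the
timescale, so the gauge is fixed afterwards by standardising the fitted
means (mean 0, variance 1); the reported 75th and 99th percentile
intervals are $\mu \pm z_{0.875}\sigma$ and $\mu \pm z_{0.995}\sigma$.
`simulate_tint_counts()` provides a model-independent forward simulation
(sequential insertion into an abstract genome with occupancy-proportional
nesting) used to verify that the fitted chronology recovers planted
activity peaks.

# Numerical and degenerate-input choices

* Divergence is the mismatch proportion over substitution columns (gaps
  and N excluded), optionally Kimura-2p corrected; an alignment with no
  substitution columns yields NA with an `undefined` flag, not an error.
* Boundary values are inclusive throughout the young-element filter
  (length ≥ 150/170 bp, divergence ≤ 10/15 %).
* The TSD scanner returns `found = FALSE` with a reason for empty flanks.
* All failure modes of a presence/absence call fold into `unresolved`
  with a reason code; nothing downstream consumes a partial call.
* `detect_subfamilies()` on fewer than `min_size` rows returns the single
  root subfamily; degenerate (all-zero) nesting matrices raise an error
  naming the problem.
* Every stochastic component consumes the R RNG stream only, so a single
  `set.seed()` (or the `seed` fields of the configs) reproduces runs
  byte-for-byte; the pipeline writes a manifest whose MD5 is identical
  across reruns.

# Problem sizes used in validation

The shipped validation uses the default 2 Mb × 4 species scenario
(~2,200 insertions, ~300 on the focal terminal branch) for the
presence/absence recovery study, a 1/10-scale scenario with rates scaled
to preserve TE density for TSD recovery, 200-element two-source sets for
subfamily recovery, 500-copy cohorts for dating, 100 replicates of the
nesting simulation for the chronology (with element density set so the
genome ends roughly a quarter repeat-derived, the occupancy regime of
carnivore genomes — a repeat-poor genome yields too few nestings for the
ordering to be identifiable at all), and 12 small haplotype sets for
the network-vs-brute-force comparison. These sizes were chosen to give
each check clear statistical resolution at interactive runtimes.

# Known limitations

* No indel evolution outside TE insertion, so alignment-based stages see
  cleaner data than real genomes provide.
* CpG status is interval-initial; extremely long branches would
  under-produce CpG decay.
* Pairwise (not triple) co-segregation; subfamilies defined only by joint
  triples would be missed.
* The activity model assumes Gaussian activity and independence between
  families; it recovers orderings and rough spans, not absolute times —
  calibration to absolute time is out of scope.
* The screen's conservative unresolved-handling trades recall for
  precision at repeat-dense loci; on real data, polymorphic insertions
  would additionally appear as discordant calls between individuals,
  which single reference assemblies cannot resolve.
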