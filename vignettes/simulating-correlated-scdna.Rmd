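---
title: "Simulating correlated single-cell and bulk DNA sequencing reads"
author: "scbulksim authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating correlated single-cell and bulk DNA sequencing reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scbulksim)
```

## The problem this package addresses

Many sequencing studies collect *nested* samples: a population of patients
(or biological replicates), several biopsies or technical replicates per
patient, and within them a mix of bulk tissue and single cells. Samples
from the same biological unit are correlated — in cancer, biopsies of one
tumor share clonal structure — and single-cell libraries carry
amplification artifacts that bulk libraries do not. Method developers who
want to benchmark variant callers or clonal-deconvolution tools on such
designs need simulated reads with known ground truth that reproduce both
features: the hierarchical correlation and the single-cell error modes.

`scbulksim` generates paired-end FASTQ reads for exactly this setting,
together with truth VCF/TSV files and a scoring module for caller output.

## The generative model

Everything starts from a single haploid reference region of length $L$ and
$K$ mutated diploid **prototype genomes** $H = [h_1, \dots, h_K]$ (clonal
genotypes, in the cancer analogy). The model is a truncated hierarchical
Dirichlet mixture:

$$
\begin{aligned}
G'' &\sim \mathrm{Dirichlet}(\alpha) \\
G'_i &\sim \mathrm{Dirichlet}(\beta_i\, G'') & i = 1, \dots, N \\
G_{ij} &\sim \mathrm{Dirichlet}(\gamma_{ij}\, G'_i) & j = 1, \dots, N_i
\end{aligned}
$$

$G''$ is the population distribution over the $K$ prototypes; $G'_i$ the
distribution for biological unit $i$, concentrated around $G''$ by
$\beta_i$; $G_{ij}$ the distribution for sample $j$ of unit $i$,
concentrated around $G'_i$ by $\gamma_{ij}$. Small concentrations
($\beta, \gamma \approx 0.1$) put draws near a simplex vertex, so samples
behave almost clonally; large values make them track their parent
distribution. With $K \to \infty$ and i.i.d. genotypes the truncated model
approaches a hierarchical Dirichlet process mixture; with the fixed,
small $K$ typical of sequencing studies the truncated form is the natural
choice, and it is what the package implements.

Each sample is then sequenced according to its type:

* **single cell** — one genotype $k \sim \mathrm{Categorical}(G_{ij})$ is
  chosen (a cell has one genome), a whole-genome-amplification error model
  is applied to prototype $k$, and paired-end reads are simulated from the
  resulting diploid genome;
* **bulk** — reads are drawn *without replacement* from pure per-prototype
  read pools, in exact proportions given by $G_{ij}$.

## Prototype genome construction

`placeSnvSites()` spaces $n$ potential SNV locations equally across the
central $(1 - 2m)$ of the region ($m$ = `marginFraction`, default 0.1):
the first site at $\lfloor mL \rfloor$ and spacing
$\lfloor (1-2m)L/(n-1) \rfloor$. With $L = 10^6$ and $n = 100$ this gives
8080 bp. The margin keeps sites away from region edges where read support
is mechanically thinner; `n = 1` degenerates to a single mid-region site.

Sharing tiers split the sites three ways: one third shared by **all**
prototypes, one third by **half** of them ($\lceil K/2 \rceil$, the
integer convention for odd $K$), and one third by a uniformly drawn
proportion — per site $p \sim U(0,1)$ and the site is present in
$\max(1, \mathrm{round}(pK))$ prototypes, the $\max(1,\cdot)$ guaranteeing
no orphan sites. For $n$ not divisible by 3 the counts are
$\lceil n/3 \rceil$, $\lceil (n - \lceil n/3 \rceil)/2 \rceil$ and the
remainder; tier labels are shuffled across positions under the stage seed
so no tier clusters spatially.

`assignSubstitutions()` draws one alternate allele per site from the row
of a 4×4 row-stochastic substitution matrix indexed by the reference base
(the same alt is shared by every prototype carrying the site — a site has
one location and one type), and a zygosity per present (site, prototype)
pair: heterozygous with probability `pHet` (default 0.5), else homozygous.
The default matrix puts 0.58 on the transition partner and 0.21 on each
transversion, giving an expected Ti/Tv of $0.58/0.42 \approx 1.38$, inside
the 1.2–1.6 band conventional for germline SNV sets; both `pHet` and the
matrix are user-configurable. Sites falling on an `N` reference base are
relocated deterministically rightward to the nearest usable base.

`buildPrototypeGenomes()` realizes each prototype as two haplotype edit
lists: homozygous sites edit both haplotypes, heterozygous sites exactly
one, chosen by a fair coin per site per prototype. Only SNVs are modeled —
no indels, structural variants, or context-dependent signatures.

## The WGA error model

Whole-genome amplification of a single cell introduces two artifact
classes, both applied by `applyWga()` to the chosen prototype *before*
read simulation:

* **Allelic dropout (ADO)** — independently per heterozygous site, with
  probability `adoRate` (default 0.20) one allele is lost; the survivor is
  chosen uniformly, so the site becomes homozygous-reference (variant
  disappears) or homozygous-alt with equal probability. Homozygous sites
  are untouched. A per-site rate is the only reading under which "20%
  dropout" is meaningful; a per-base interpretation would make dropout
  vanishingly rare.
* **False positives (FP)** — the FP count is
  $\mathrm{Binomial}(L, \texttt{fpRate})$ with `fpRate` defaulting to
  $3.2\times10^{-5}$ (expected 32 on 1 Mbp), i.e. per-base over the whole
  region. Positions are uniform without replacement over non-variant
  positions; each FP is heterozygous (amplification errors affect one
  allele), placed on a random haplotype, with the alternate base drawn
  from the substitution matrix.

Both events are recorded per cell and flagged in the cell truth VCF
(`FORMAT/ADO`, `INFO/WGAFP`), so downstream evaluations can separate
biological truth from amplification artifact.

## The read engine

Reads are produced by an internal, fully seeded paired-end engine rather
than an external simulator, which keeps runs self-contained and
byte-reproducible. Per pair: haplotype by fair coin (so each haplotype
receives about half the coverage); fragment length
$\mathrm{Normal}(\mu, \sigma)$ truncated by resampling to
$[2\ell, L]$ ($\ell$ = read length) and rounded; fragment start uniform
over valid positions; read 1 is the fragment prefix and read 2 the
reverse complement of the suffix. Each emitted base is substituted with
probability `errorRate` to a uniformly random different base; qualities
are constant at `baseQuality`. Defaults are Illumina-like: 100 bp reads,
500 ± 50 bp fragments, 0.1% error, Q30. The pair count for a target mean
coverage $c$ is $\mathrm{round}(cL / 2\ell)$, so total emitted bases equal
$cL$ up to rounding. Constant qualities and the absence of indel errors,
quality-by-cycle decay, adapters and GC bias are deliberate limitations:
callers need plausible, not empirical, qualities for benchmarking, and
each omitted artifact is orthogonal to the hierarchy/WGA machinery this
package exists to provide. Read names encode full provenance
(`origin:src:hap:fragStart:fragEnd:serial`), which is what makes the
bulk-composition and fragment-identity tests exact rather than
statistical.

## Bulk mixing

Per-prototype pure pools are generated once per run and shared by all bulk
samples, depleted monotonically — the strongest reading of "sampling
without replacement": no read is duplicated even across samples. A bulk
sample of $T$ total records takes $T/2$ pairs (mates are never separated,
so $T$ must be even), apportioned over prototypes by largest remainder
(Hamilton's method, ties to the lowest index): counts are non-negative
integers summing exactly to $T/2$ with each within 1 of its quota
$T g_k / 2$. Because the allocation is deterministic given the realized
$G_{ij}$, the exact pool demand is known before any read is simulated;
pools are generated at that size and a shortfall is therefore impossible
by construction (the pool-exhausted error remains for direct API use).

## Truth-aware evaluation

`scoreCalls()` matches call sets against truth at site level — same
1-based position *and* same alternate allele; genotype is deliberately not
compared, since the headline metrics of interest are site-level. Truth and
calls may be pooled across samples; duplicates collapse. Recall, precision
and F1 follow the usual identities, with precision reported as 0 (with a
warning) for an empty call set, and a warning — never a silent fix — when
nothing matches but an off-by-one shift would, the classic symptom of a
coordinate-system mix-up.

`applyPostFilters()` implements the standard hard filters for single-cell
calls with strict inequalities: mapping quality > 1, base quality > 30,
variant-supporting reads > 5, and strand-bias removal. "Remove strand
biasedness" has no canonical definition, so the default is the simple
deterministic rule — fail iff at least `strandMin` (4) alt reads exist and
all sit on one strand — with a Fisher-exact alternative
(`strandMethod = "fisher"`, p < 0.001) selectable. A record missing an
annotation a filter needs passes that filter, with a warning count:
silently dropping unevaluable records would bias recall. `titvRatio()`
reports transitions (A↔G, C↔T) over transversions, `Inf` when there are no
transversions and an error on empty input.

## Seeds and determinism

One master seed governs a run. Every stage draws under a child seed
derived by a stable string hash of (stage, unit id, sample id, master
seed) — `childSeed()` — so adding a sample to a design leaves every other
sample's draws untouched, and reruns are byte-identical down to the
gzipped FASTQ. The hierarchy draw, all child seeds and all per-sample
counts are recorded in `manifest.json`. $G''$ is drawn once per run; a
study needing replicate populations runs the simulator repeatedly with
different seeds.

Numerical edge cases: Dirichlet concentrations are clamped at $10^{-12}$
before drawing (child concentrations $\beta_i G''_k$ underflow when a
parent component is tiny) and output components are clamped at the same
floor and renormalized, so categorical draws never see an exact zero where
mass is merely minute; simplex sums are validated to $10^{-9}$.

## What the synthetic data does and does not show

`makeFixtureReference()` generates i.i.d. random references at a chosen GC
fraction (default 0.41, human-like), so tests and examples need no genome
download. Real genomes have repeats, homopolymers and composition
structure that i.i.d. sequence lacks; consequently the test suite
validates the *simulator's* distributional contracts (rates, compositions,
spacing, determinism), not the mapping behavior of reads on a real
reference. Alignment-dependent results — what a specific caller attains
after mapping to a real genome — require external aligners and callers and
are explicitly out of scope; the evaluation module scores any such output
once produced.

Problem sizes in the shipped tests are chosen to make each statistical
check sharp at desk scale: 10,000 draws for Monte-Carlo means (3-SE
bands), 3000 sites for Ti/Tv, 1200 heterozygous sites for the ADO rate, 20
replicates on 1 Mbp for the FP count, one full-size (1,000,000-record)
bulk composition check, and 100 kb / 20 kb regions for end-to-end runs.

## Known limitations

* SNVs only; no indels, CNVs or structural variants.
* No amplification-bias coverage model (uneven MDA coverage), doublets or
  chimeric reads for single cells; no WGA model for bulk samples.
* Constant base qualities; no sequencing-error structure beyond uniform
  substitutions.
* One population draw per run; replicate populations are separate runs.
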