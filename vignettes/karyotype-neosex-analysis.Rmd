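---
title: "Karyotype composition and the two routes to multiple sex chromosomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Karyotype composition and the two routes to multiple sex chromosomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyopairs)
```

## The scientific question

Mammals with a simple XY system occasionally acquire a *multiple* sex
chromosome system through a centromeric (Robertsonian) fusion between a sex
chromosome and an autosome. A Y–autosome fusion produces an X1X2Y system; an
X–autosome fusion produces an XY1Y2 system. Centromere-associated female
meiotic drive offers a mechanism for which route fixes where: during female
meiosis I only one chromatid pair reaches the egg, and species differ in
whether egg spindles favor chromosomes with more centromeres (acrocentric
karyotypes accumulate) or fewer (biarmed karyotypes accumulate). A fused
neo-X must pass through female meiosis, so X–autosome fusions should fix
preferentially in biarm-favoring species; Y–autosome fusions are male-limited
and escape female drive entirely, but arise more often where acrocentric
fusion substrates are abundant. The testable prediction is an association:
**XY1Y2 systems in biarm-rich karyotypes, X1X2Y systems in acrocentric-rich
karyotypes.**

`karyopairs` implements the comparative test of that prediction on a
compiled table of 41 mammalian species (18 X1X2Y, 23 XY1Y2), and a
simulation model of the drive mechanism so that every analysis stage can be
exercised and calibrated on data with known truth.

## Karyotype arithmetic

Each species is summarized by its diploid number 2n and fundamental number
NF (total chromosome arms), per sex. Following Levan's shape classes,
subtelocentric and telocentric chromosomes are pooled with acrocentrics (one
arm each); metacentric and submetacentric chromosomes are biarmed (two
arms). With $a$ acrocentrics and $b$ biarmed chromosomes, $2n = a + b$ and
$\mathrm{NF} = a + 2b$, so

$$\widehat{f}_{\mathrm{acro}} = \frac{2\cdot 2n - \mathrm{NF}}{2n}.$$

The *printed* percent-acrocentric column of the compiled table is the
authoritative analysis input; the 2n/NF estimate is a diagnostic
(`audit_table()`). The reason is visible in the data: the six *Gazella* rows
are inconsistent with the arm formula (NF conventions differ between source
papers over whether sex chromosomes or small arms are counted), while 35 of
41 rows agree to within 0.01. Recomputing fractions everywhere would
silently alter the compiled data, so the package never does.

All analyses run on the female karyotype; male columns are stored and
selectable (`sex = "male"`), mirroring the convention that the female
karyotype defines the acrocentric fraction (males of these species are
heterozygous for the fusion itself).

Data-curation note: the source compilation prints the genus of *Carollia
perspicillata* inconsistently ("Carolia"); the packaged table uses
*Carollia* so the two congeners form one cluster, as they do on the
reference phylogeny. The compilation's text also refers to 19 X1X2Y species
while printing 18 rows; the packaged table ships the 18 printed rows and the
loader reports counts, so the discrepancy is visible, not patched.

## The rank tests

The two inferential tools are implemented from first principles (base R
provides cross-checking oracles in the test suite, never the
implementation).

**Tie-aware Mann–Whitney U.** `mann_whitney()` counts pairs via the midrank
identity $U_1 = R_1 - n_1(n_1+1)/2$ (ties count 1/2) and standardizes
$U_{\min}$ with the tie-corrected variance
$\mathrm{Var}(U) = \frac{n_1 n_2}{12}\big[(n+1) - \sum_t (t^3-t)/(n(n-1))\big]$
over pooled tie-group sizes $t$, with no continuity correction — the most
common textbook convention, stated here so the reported Z is unambiguous.
When every pooled value is tied the variance is zero and the test returns
$z = 0$, $p = 1$.

**Exact Wilcoxon signed-rank.** `signed_rank_exact()` drops zero differences
(count reported), midranks the absolute values, and reports
$S = \min(W^+, W^-)$. For $n \le 20$ informative pairs the two-sided p-value
is exact: $p = \Pr\{\min(W^+, W^-) \le s\}$ over all $2^n$ equally likely
sign assignments. The null distribution is built by a generating-function
convolution over the doubled midranks (half-integer midranks become
integers), which is arithmetic-identical to enumerating the $2^n$ vectors;
the tests verify equality against literal enumeration for $n \le 12$. Nine
same-sign differences give the attainable floor
$p = 2/2^9 = 0.00390625$. Beyond $n = 20$ (configurable) a tie-corrected
normal approximation takes over and is labeled as such in the result.

## Phylogenetic correction

Shared ancestry makes species non-independent: whole genera share one
system. The correction collapses the tree into **cluster units** — maximal
monophyletic sets of tips sharing one system (`find_system_clusters()`,
bottom-up merge of same-system sibling clades) — and then tests
**phylogenetically independent pairs**, each opposing one X1X2Y unit to one
XY1Y2 unit, chosen so that the tree paths of different pairs share no edge
(`validate_pair_independence()` checks this explicitly).

On the packaged 41-species tree the units coincide with genera, with two
qualifications. The genus *Mus* splits into two singleton units of opposite
systems. And the four New World monkey genera (*Aotus*, *Alouatta*,
*Callimico*, *Cacajao* — nine species, all X1X2Y) merge into a single unit:
on a tree containing only multiple-system species no simple-system lineage
separates them, so the maximal same-system clade spans the genera. That
merged unit participates in no contrast pair, and the unit counts come out
10 X1X2Y versus 9 XY1Y2 — the nine available cross-system pairs are exactly
the nine the analysis uses.

The nine packaged pairs reconstruct the reference design from its figure:
congeneric *Mus*–*Mus*; within-family pairs for Bovidae
(*Tragelaphus*–*Gazella*), Phyllostomidae (*Mesophylla*–*Artibeus* and
*Choeroniscus*–*Carollia*), Macropodidae (*Lagorchestes*–*Wallabia*), and
Muridae (*Vandeleuria*–*Taterillus*); the remaining units join their nearest
cross-system partner (*Deltamys*–*Sorex*, *Herpestes*–*Muntiacus*,
*Choloepus*–*Potorous* — the three long-path pairs, placed at positions 3, 5
and 9 of the configuration). The configuration file is editable, and
`build_pairs()` without a configuration runs a deterministic automatic
algorithm instead: postorder over the tree, pairing the closest available
cross-system units within the first subtree containing both systems and then
retiring that whole subtree, which provably yields edge-disjoint paths.
Distances are topological (node counts): branch lengths on such composite
trees do not represent time and are never required. All tie-breaks are
lexicographic by unit id, so runs are reproducible.

Cluster representatives (`cluster_value()`) are either the member mean
(`mode = "mean"`) or one member drawn uniformly (`mode = "random"`); the
resampling analysis (`resampled_paired_comparison()`) repeats the random
draw `k = 100` times, consuming one seeded RNG in iteration-major,
sorted-unit-id order, and reports the mean and standard error (sample SD /
$\sqrt{k}$) of the per-iteration exact p-values. Since the exact two-sided p
can never fall below $2/2^9$ with nine pairs, the resampled mean equals that
floor exactly when no iteration flips a pair's sign, and exceeds it
otherwise; the report counts flip iterations so deviations are diagnosable.

The histogram product (`acro_histogram()`) uses half-open bins of width 0.1
with the final bin closed at 1.0 — a plotting convention, stated because the
source material does not fix one.

## What a run reports

`run_report()` executes everything — strict loading, audit,
clustering, pairing, independence check, the species-level Mann–Whitney,
the cluster-mean paired test, the resampling, and the histograms — and
writes a JSON record (full precision, no timestamps, byte-identical under a
fixed seed) plus TSV histogram tables. On the packaged inputs the
cluster-mean differences are positive in all nine pairs, giving $S = 0$,
$p = 0.0039$; the species-level test gives $U_{\min} = 24.5$, $Z = -4.80$
against 18-vs-23 groups. A species-level U near 25 published for this
compilation assumed a 19th X1X2Y species that the printed table does not
contain, which is why the package validates its Mann–Whitney against a
brute-force all-pairs oracle rather than against that printed value.

## The drive simulator

The generator (`simulate_dataset()` and friends) exists to test the
pipeline, not to model mammalian population genetics. Its pieces:

- **Tree**: pure-birth (Yule) via `ape::rphylo`, default 48 tips, birth
  rate 1.
- **Karyotype state**: counts of acrocentric (A) and biarmed (B) autosome
  pairs, root default A = B = 10. Fusions (two acrocentric pairs → one
  biarmed) and fissions (reverse) conserve the autosomal arm count A + 2B;
  only 2n changes — the tests assert this invariant on every node.
- **Proposals**: Poisson along branches (rate `rearrange_rate`, default 1
  per unit length), type chosen proportional to availability, A(A−1) for
  fusions versus B for fissions; impossible proposals are skipped.
- **Drive**: a lineage carries one of two bias values (default mixture
  `c(0, 0)`; switching at 0.05 per unit length keeps regimes heritable but
  not frozen). A bias $d$ fixes fusions with probability
  $1/(1+e^{-2d})$ and fissions with $1/(1+e^{+2d})$ — the simplest
  symmetric monotone map from a signed bias to a probability, with $d = 0$
  recovering neutrality. This map is declared synthetic machinery; nothing
  quantitative about real drive strengths is implied.
- **Sex systems**: fusion proposals arrive at rate
  $\mu \cdot A/(A+B)$ (mutation bias toward acrocentric-rich karyotypes,
  default $\mu = 0.5$), X- or Y-type with probability 1/2. An X-fusion
  fixes with probability $1/(1+e^{-2d})$ (the biarmed neo-X must survive
  female meiosis); a Y-fusion fixes with probability 1/2 (male-limited,
  drive-free). The first fixed event sets the system permanently — systems
  are absorbing, matching the one-system-per-species structure of the real
  table — and consumes one acrocentric pair, which is deducted when the tip
  record is emitted (deducting at event time would only perturb later
  proposal weights marginally).

Emitted tables use the exact interchange schema with a biarmed sex-pair
convention (2n = 2(A+B)+2, NF = 2(A+2B)+2), so they reload under strict
validation; "simple" tips are excluded from the analysis table but retained
in the truth file.

### What the simulator does and does not emulate

It reproduces the features the analysis relies on: bimodal acrocentric
fractions under drive heterogeneity, monophyletic same-system clusters from
absorbing fixation, and a tunable association between fusion type and
karyotype composition. It ignores real population-genetic detail
(underdominance of fusion heterozygotes, effective population size,
inbreeding), rate variation among lineages, and any calibration of $d$
against measured transmission ratios. Passing calibration therefore shows
the *pipeline* is correct and the *test* holds its level under the model's
null — not that the biological hypothesis is true.

One structural asymmetry is worth knowing: because fusion proposals scale
as A(A−1) while fissions scale as B, fully acrocentric karyotypes are hard
to reach — fission proposals become vanishingly rare once A is large. Under
a strong drive mixture ($d = \pm 4$, `rearrange_rate = 24`) the pooled tip
fractions are clearly bimodal, with the biarm-rich mode at the extreme and
the acrocentric-rich mode near 0.7 rather than at 1.0.

### Calibration experiments and the problem sizes used

`type_i_error_experiment()` simulates no-drive null data (zero bias makes
every fixation probability 1/2, so no association is forced), re-drawing
until both systems are present, then runs clustering, automatic pairing,
and the mean-mode exact paired test. Because systems are absorbing, deep
fixation events capture whole clades: small trees yield only 1–3
independent pairs, and with fewer than 7 pairs the discrete exact test
cannot reject at $\alpha = 0.05$ at all (its smallest attainable two-sided
p is $2/2^n$). The calibration therefore runs at 600 tips with
$\mu = 0.35$, where the automatic pairing yields a median of about ten
pairs and the attainable test size sits near the nominal level; 1000
replicates take on the order of a minute. The measured rejection rate falls
within three Monte-Carlo standard errors of 0.05.

`sign_recovery_experiment()` measures how often the X1X2Y group's mean
acrocentric fraction exceeds the XY1Y2 group's (ties score 1/2, preserving
symmetry at zero effect). Over the drive grid $d \in \{0.5, 1.5, 3\}$ (96
tips, $\mu = 0.5$, `rearrange_rate = 8`, switch rate 0.1) recovery rises
monotonically toward 1, and sits near 1/2 at $d = 0$.

## A worked example

```{r example, eval = FALSE}
library(karyopairs)

tab   <- neosex_karyotypes()
tree  <- read_species_tree(neosex_fixture_path("tree"))
units <- find_system_clusters(tree, setNames(tab$system, tab$species_key))
pairs <- build_pairs(tree, units,
                     read_pair_config(neosex_fixture_path("pairs")))

group_comparison(tab)              # U = 24.5, Z = -4.80, p = 1.6e-06
paired_comparison(tab, tree, pairs)  # S = 0, p = 0.0039
resampled_paired_comparison(tab, tree, pairs, k = 100, seed = 7)
```

## Known limitations

- The packaged tree is a topological reconstruction from published
  composite phylogenies; branch lengths are absent by design, so methods
  requiring divergence times (e.g. Felsenstein contrasts) are out of scope.
- The nine-pair configuration is a documented reconstruction; the paired
  result $S = 0$ is robust to any family-consistent pairing because the
  group fraction distributions barely overlap, but users can supply their
  own configuration and the report names the pairing used.
- The exact signed-rank enumeration is capped (default $n \le 20$) for
  runtime; beyond it the normal approximation is labeled, never silent.
- The background 1170-species karyotype compilation referenced by the
  original analysis is accepted as a user-supplied table for histogram
  comparison but is not packaged.
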