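---
title: "Consistent signal transduction: model, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consistent signal transduction: model, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acst)
```

## The model

`acst` asks, pathway by pathway, whether the expression data show a
*sign-consistent regulatory cascade* — a connected set of transcription
factor → target edges along which the observed directions of change agree
with the annotated interaction signs — and whether that cascade sits near
the pathway's functional end.

The ingredients, for a pathway graph $G = (V, E)$ with edge signs
$r_{ij} \in \{-1, 0, +1\}$ and a two-group design:

1. **Local statistic.** Per gene, the signed Welch $t$ (tested minus
   control; unequal-variance form, $n-1$ sample variances). Its square is
   standardized across the *universe* — all genes of the analyzed catalog
   measured in the dataset — giving $z_g = (t_g^2 - \bar{t^2}) / s_{t^2}$.
   Squaring makes $z$ reward magnitude regardless of direction; the sign of
   $t$ is kept separately for the consistency test. Standardization exists
   for one reason: label permutations systematically yield smaller $t$
   statistics than the true labeling, and recomputing $z$ *inside every
   permutation* puts observed and null pathway scores on the same scale.

2. **Consistent subgraphs.** An edge is consistent iff
   $\mathrm{sign}(t_i)\,\mathrm{sign}(t_j)\,r_{ij} = +1$, evaluated on the
   raw (non-standardized) $t$, whose signs carry the real direction of
   change. The maximal consistent subgraphs are the weakly-connected
   components of the consistent-edge set. Maximality is preferred over
   best-scoring sub-pieces because a longer stretch of coherent
   transduction is stronger evidence of a functional change, even when a
   subset would score higher.

3. **Position weight.** Each subgraph $C$ scores
   $\gamma(C) = w(d)\sum_{g \in C} z_g$ with $d$ the directed node-count
   distance from $C$ to the leaves of $G$ (terminal effectors: in-degree
   $\ge 1$, out-degree $0$). The pathway's global statistic is
   $\sum_C \gamma(C)$, or $0$ when no edge is consistent.

4. **Inference.** A subject-sampling permutation null (group sizes
   preserved; gene–gene correlations intact), empirical p-value
   $(1 + \#\{b : S_b \ge S_{obs}\})/(B+1)$, and a resampling-based FDR
   point estimate (below).

### Assumptions

* Expression changes of *target genes* reflect transcription-factor
  activity; protein-level events (phosphorylation etc.) are deliberately
  not modeled — only gene-expression relations enter the graph. This
  trades sensitivity for specificity: pathways whose annotation has few
  gene–gene edges cannot be scored.
* Subjects are exchangeable under the null within the permutation scheme;
  each group needs at least 2 subjects for a Welch variance.
* The $t$ statistic is scale-free, so the matrix may be on any scale
  (log-intensities, abundances); no normalization is performed here, and
  upstream preprocessing (array normalization, probe→gene mapping,
  quality filtering) is out of scope.

## Tunable parameters

| parameter | default | units / domain | why this default |
|---|---|---|---|
| `B` | 1000 | permutations | resolves p down to ~0.001; doubling `B` halves the Monte-Carlo noise sd |
| `weight` | `"reciprocal"` | — | $w(d)=1/d$: $w(1)=1$, strictly decaying upstream; see below |
| `alpha` | 0.25 | FDR scale | the conventional screening cut for this family of pathway tests |
| `test_label` | (required) | — | fixes the sign convention: $t>0$ ⇔ higher in the tested group |
| `missing` | `"drop"` | — | the method assumes complete measurements; `"strict"` errors instead |

Generator defaults (`random_pathway`): 10 nodes, 12 edges, 45 % activating,
10 % neutral, the balance repressing — the scale and sign mix of the
gene-expression-relation skeleton of a typical curated signaling pathway,
where activation annotations moderately outnumber repression and a small
fraction of relations lack a direction. `simulate_expression` uses 10 + 10
subjects and unit Gaussian noise; planted cascades state their `effect` in
noise-sd units, so `effect = 2` means each cascade gene's group means differ
by two residual standard deviations — strong but realistic differential
expression. These are statements about the world being emulated, fixed
once, not tuning knobs.

## Numerical and design choices

**Weight form.** The direction of the position weight is fixed by the
method's rationale (cascades at the pathway end score more); its exact
functional form is an open design choice. We use $w(d) = 1/d$ — the
simplest form with $w(1) = 1$ and strict monotone decay, giving the exact
relation $\gamma(d+k) = \gamma(d)\,d/(d+k)$ that the acceptance suite
checks. An exponential alternative `exponential:λ`
($w(d) = e^{-\lambda(d-1)}$) is one flag away; both give $w(\infty) = 0$.

**Unreachable and leafless cases.** A subgraph with no directed route to
any leaf scores 0 (it is still reported): by the method's own logic it may
not induce a terminal response. A graph with *no* leaves at all (pure
cycles) would otherwise silently zero every subgraph, so there the fallback
$w = 1$ is applied with a warning.

**Leaf definition.** Out-degree 0 *and* in-degree ≥ 1; an isolated node is
not a leaf (it terminates nothing), and a single node with no consistent
incident edge is not a subgraph — a consistent *relation* needs an edge.

**Neutral edges.** $r = 0$ edges can never be consistent but stay in the
graph: distances and leaves are properties of the searched graph, not of
its consistent part. Removing them would silently shorten $d$.

**Zero statistics.** A variance-floored gene ($t = 0$ by the $10^{-12}$
floor on the Welch standard error) has sign 0 and can never participate in
a consistent edge: a null statistic carries no direction.

**p-value convention.** $(1 + \text{count})/(B + 1)$ counts the observed
labeling as one permutation: p is never 0, its floor is $1/(B+1)$ (≈ 0.001
at $B = 1000$), and the estimator is exactly valid (conservative under
ties) without continuity fudges.

**FDR estimator.** At each observed statistic used as threshold $c$:
$\widehat{V}(c) = B^{-1}\sum_b \#\{j : S_{jb} \ge c\}$ (null-expected
exceedances, pooled over pathways — appropriate for dependent tests) over
$R(c) = \#\{j : S^{obs}_j \ge c\} \ge 1$, capped at 1, then monotonized
step-up style: thresholds are processed in increasing statistic order and
the running minimum is taken, so the adjusted value is non-increasing in
the statistic and tied statistics share one value. Thresholding on the
statistic scale (not the p-value scale) is a deliberate choice; at fixed
$B$ the orderings agree except under ties.

**Determinism.** One seed governs a run; all $B$ permutations are drawn up
front from it, so results are independent of pathway iteration order and
byte-identical across repeats. Subgraphs are reported sorted by (score
descending, smallest node id) to pin the output order.

**Degenerate inputs.** A universe with all-equal $t^2$ standardizes to all
zeros with a warning; pathways with fewer than two measured genes are
skipped with a message rather than failing the run; restriction to the
measured universe never contracts edges through removed nodes — an
unmeasured middle gene genuinely breaks a cascade.

**KGML mapping.** Only `entry type="gene"` nodes and `GErel` relations are
read; subtype `expression` → $+1$, `repression` → $-1$, anything else
(including compound-mediated or missing subtypes) → $0$. Multi-gene entries
expand to one node per gene with edges replicated, because the local
statistic lives at gene level; expansion self-loops are dropped (a
self-relation degenerates to $\mathrm{sign}(t)^2 r$ and carries no
co-regulation information). Gene identifiers are opaque strings — mapping
platform probes to pathway identifiers is the caller's responsibility.

## What the synthetic generator does and does not establish

The generator plants a mean-shift cascade whose shift directions follow the
cumulative edge-sign products, in homoscedastic Gaussian noise with
independent genes. A green acceptance suite therefore establishes: exact
agreement of the subgraph engine with a brute-force enumeration oracle,
calibrated type-I error and p-value uniformity under an exchangeable null,
recovery of a strong planted cascade against decoys, and the stated
algebraic invariants (standardization moments, scale-freeness, weight
exactness, determinism).

It does *not* establish performance under correlated genes, heavy-tailed or
batch-confounded noise, cascades weaker than the planted effect, or
misannotated edge signs; nor does it validate any biological claim about
real pathway databases. Array-era preprocessing artifacts are explicitly
not emulated.

## Known limitations

* Pathways without gene-expression relations (most metabolic maps) cannot
  be analyzed — a property of the data type, accepted by design.
* The consistency criterion uses only signs; a cascade of large but
  slightly discordant changes scores zero. High specificity is bought with
  sensitivity.
* Distances treat every annotated edge as traversable; annotation gaps
  shorten or sever leaf routes and directly change $d$.
* The FDR point estimator is an estimate, not a proven-control procedure;
  with few pathways and small $B$ its granularity is coarse.
* Permutation resolution bounds the smallest p at $1/(B+1)$; with strong
  signals many pathways tie at the floor and ranking among them is
  uninformative.
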