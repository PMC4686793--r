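---
title: "Inside-outside dynamic programming: models, algebras and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inside-outside dynamic programming: models, algebras and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adpio)
```

## The idea

Many dynamic programs in computational biology come in complementary pairs.
An *inside* recursion evaluates sub-structures of the input -- prefixes of a
sequence read by an HMM, prefix-pair alignments, folded substrings of an RNA,
partial Hamiltonian paths through a vertex subset. An *outside* recursion
evaluates the complement of each sub-structure relative to the full input.
Neither alone gives ensemble information, but their product does: for a
sub-structure $A$ with inside value $Z(A)$ and outside value $Z(A^*)$, the
ratio $Z(A)\,Z(A^*)/Z$ is the probability that a structure drawn from the
Boltzmann ensemble contains $A$. This single pattern yields per-position
state posteriors for HMMs (forward-backward), match probabilities for
pairwise alignment, base-pair probabilities for RNA folding, and adjacency
and endpoint probabilities for ensembles of Hamiltonian paths.

The package separates, in the style of algebraic dynamic programming, three
independent layers:

* the **decomposition grammar** -- how an object splits into parts
  (`adp_grammar()`, with ready-made instances `grammar_hmm()`,
  `grammar_nw()`, `grammar_gotoh()`, `grammar_rna()`, `grammar_shp()`);
* the **evaluation algebra** -- how a decomposition is scored: counting
  ($+,\times$ over 1-weights), optimization ($\min/\max$, $+$), or the
  partition function ($+$, $\times$ over Boltzmann weights
  $e^{-E/RT}$);
* the **choice function** -- implicit in the algebra above.

Because the outside recursion is determined by the inside decomposition, it
is *derived mechanically*: for an inside production
$A \to \alpha B \beta$, the complement of $B$ consists of the complement of
$A$ plus the siblings of $B$, giving the outside production
$B^* \to \alpha A^* \beta$. `derive_outside()` implements exactly this rule,
plus the start/stop exchange (`S -> A` becomes the termination rule
`A* -> S*`; `A -> eps` becomes the outside start rule `eps* -> A*`).

```{r}
grammar_rules(grammar_rna())
grammar_rules(derive_outside(grammar_rna()))
```

## Boundaries and the axioms of decomposition

Objects may share material with their complement. The package records, per
symbol, what the boundary $\partial A$ of its objects is: empty (alignment
prefixes -- inside and outside scores simply add), a prefix end point (HMM
prefixes, where the scored terminal is a *transition* between adjacent
positions), the closing base pair of a helix (shared between $B$ and $B^*$
in the RNA grammar), or the distinguished endpoints of a punctuated vertex
set. Declaring the boundary kind per *symbol* (rather than per production)
was a genuinely open choice; per-symbol is simpler and no grammar in the
package needs per-production overlap rules, but the alternative would allow
the same nonterminal to overlap differently in different rules.

The covering axioms -- parts cover the object, interiors are disjoint,
interiors nest -- are statements about index semantics, not about grammar
syntax. They are therefore *not* checked statically; they are what the
oracle tests verify numerically: every engine is compared against exhaustive
enumeration of the objects it claims to sum over.

## Normalization

A grammar is *normalized* when start rules have a single nonterminal
right-hand side and terminal-only rules are exactly `A -> eps`
(`check_normalized()`). Normalization matters for one precise reason: the
outside transformation swaps the roles of start and stop. The inside start
rule `S -> A` (evaluation type: one variable) becomes the outside
termination `A* -> S*` (a seed), and the inside seed `A -> eps` becomes the
outside start rule `eps* -> A*` (one variable). Only in a normalized grammar
do all start rules have the single-variable type and all seeds the neutral
type, so the swap is type-safe and the inside evaluation algebra can be
reused unchanged on the outside grammar. All *body* rules keep their
attribute signature rule by rule -- e.g. the weight of the affine-gap rule
`D -> I (u-)` (gap opening) attaches to the outside rule `I* -> D* (u-)`
(gap closing). `normalize_grammar()` repairs non-normalized grammars by
introducing fresh symbols; `derive_outside()` rejects them by default
(naming the violating rules) because closure of normalization under the
transformation is only guaranteed for normalized input.

## The concrete engines

### Two-state CpG-island HMM

States `+` (island) and `-` (background); the probability that nucleotide
$b$ follows $a$ is a row-stochastic matrix per state, and $q_\pm$, $q_\mp$
are the per-step switch probabilities. The factor for a step uses the
*source* state's dinucleotide table and switch probability -- including the
asymmetric pairing of switch probability and emission table in the
cross-state factors; the convention is applied uniformly, so published
parameter tables for this model drop in unchanged.
Position 1 has no predecessor nucleotide; the engine keeps the boundary
values $P_0 = M_0 = 1$ and gives position 1 a per-state initial emission
weight, by default the column marginal of the corresponding dinucleotide
matrix (configurable, e.g. to forbid one start state). Posteriors are
normalized by the forward total so that $P(+) + P(-) = 1$ per position; the
raw inside-outside products (whose state-sum is constant across positions --
a useful self-test) are exposed by `hmm_joint_product()`. For inputs longer
than 64 nucleotides the recursions run in log space (logsumexp); below that
they run in plain arithmetic, which is exact for the test sizes.

### Pairwise alignment

`nw_inside_outside()` implements linear gap costs on prefix pairs; the
outside table indexes the complementary suffix pair ("the hole after
$(i,j)$", excluding positions $i$ and $j$ themselves). `gotoh_inside()` adds
affine gaps via the three last-column classes `M`, `D`, `I`; its
mechanically derived outside variant (`gotoh_outside()`) is the *gap-closing*
algorithm: outside states record how the alignment continues, so gap opening
on the inside corresponds to gap closing on the outside. Defaults are
match $+1$ / mismatch $-1$, gap open $-2$, gap extend $-1$, and Boltzmann
weights $e^{s/RT}$ with $RT = 1$ in partition mode; these are conventional
toy values (the decomposition, not the parameterization, is the point) and
everything is overridable in `scoring_scheme()`.

Two conventions are worth stating. First, the textbook affine-gap grammar
gives each of `M`, `D`, `I` its own epsilon rule, which would count the
empty alignment three times under `S -> M | D | I`; the engine assigns the
empty alignment to `M` only (`M[0,0] = 1`, `D = I = 0`), so totals count
alignments exactly and each nonempty alignment keeps its unique last-column
classification. Second, `match_posterior()` is the numeric form of the
formal rule `S -> M M*`: $P(i,j) = M_{ij} M^*_{ij} / Z$. The
inside-outside consistency check `antidiagonal_cut_sum()` sums complementary
splits across an anti-diagonal cut (cells on the cut plus match columns that
jump it) and reproduces $Z$ for every cut -- each alignment crosses such a
cut exactly once.

### Toy RNA folding

The folding grammar `S -> U; U -> cU | BU | eps; B -> cUc'` with the six
canonical pairs. The energy model is deliberately minimal: $E = 1$ per base
pair, $0$ per unpaired position (both overridable), so partition mode is a
two-parameter Boltzmann ensemble; nearest-neighbour loop energies are out of
scope. `min_hairpin` defaults to 0 to match the bare grammar (adjacent
positions may pair); a value of 3 gives physically plausible hairpins and is
a documented deviation from the bare decomposition when used.

The helix nonterminal `B` *contains its closing pair as boundary*, shared
with its outside complement `B*`. The pair's Boltzmann factor is charged on
the inside rule only, so `B[i,j] * Bstar[i,j] / Z` counts the pair exactly
once -- this is asserted against the enumeration oracle rather than assumed.
One index subtlety: the outside rule combining `B*` with the trailing `U` of
`U -> B U` must include the split in which that trailing `U` is empty
(`k = j`), otherwise inside and outside totals disagree; the engine includes
it and the equality `Ustar[n+1, n] = Z` (the context of the final empty
slot) is tested for every input.

Structure counting counts parses; for this grammar the parse-structure
correspondence is a bijection (each structure has a unique leftmost
decomposition), which is verified against `enumerate_structures()` on random
sequences rather than assumed.

### Dynamic programming over sets

The index type is the *punctuated set* $[i, A, j]$: a vertex subset with
distinguished endpoints. The single rule `A -> A v` splits one endpoint off;
on sets this yields $|A|$ decompositions rather than one -- the only
difference from string grammars. `held_karp()` solves the travelling
salesman problem exactly ($O(n^2 2^n)$); `shp_inside()` evaluates all
Hamiltonian paths per endpoint pair under min / count / partition algebras,
and `shp_outside()` grows the complement (`A* -> A* v`), which for paths is
itself a path sharing the boundary vertex. Combining inside and outside
across any fixed split cardinality reproduces the per-endpoint-pair
partition function -- tested exhaustively for all cardinalities.

Paths are undirected: symmetric input is required for the ensemble (and
enforced), states are keyed on unordered endpoint pairs, and `held_karp()`
alone accepts asymmetric matrices. Boltzmann weights are
$\exp(-\ell(\pi)/(RT))$ with $R = (n-1)\bar d$ ($\bar d$ the mean
off-diagonal dissimilarity over distinct unordered pairs -- identical to the
all-entries mean for symmetric input) so that $T$ is a unitless temperature:
$T \to 0$ concentrates all mass on the (co)optimal paths, $T \to \infty$
makes adjacencies uniform ($2/n$ per pair). The partition algebra runs
entirely in log space: at $T = 10^{-4}$, which the limit checks use, plain
Boltzmann factors underflow, while logsumexp is exact at any temperature.
The subset tables take $O(n^2 2^n)$ memory; the default cap is $n \le 16$
for the ensemble (about 134 MB of tables) and $n \le 20$ for Held-Karp
(which stores only $O(n\,2^n)$), both overridable. Early pruning of
disconnected punctuated sets (useful for sparse graphs) is not implemented:
the application domain is complete dissimilarity matrices.

`adjacency_posterior()` evaluates
$P(i \sim j \mid p,q) = \tfrac{1}{Z_{pq}} \sum_{A} Z([p,A,i])\; e^{-\alpha d_{ij}}\; Z([j, V\setminus A, q])$
with the membership conventions $p, i \in A$ and $j, q \notin A$ (both edge
orientations are summed), and marginalizes over endpoint pairs weighted by
$Z_{pq}/Z$. The normalizations $\sum_{p<q} P(\text{ends}=p,q) = 1$,
$\sum_p P(\text{end}=p) = 2$ and $\sum_{i<j} P(i \sim j) = n-1$ hold to
$10^{-9}$ and are tested.

### Gene-cluster application

Clusters of paralogous genes that arose by serial local duplication should
show genetic distance increasing monotonically with genomic distance -- the
Robinson property $d_{ik} \ge \max(d_{ij}, d_{jk})$ for genes in genomic
order, under which the shortest Hamiltonian path through the distance matrix
follows the gene order. Because single-domain distances are noisy, the
pipeline reports ensemble statistics rather than just the optimum:
`run_cluster_analysis()` builds distance matrices from aligned homeodomain
sequences (Hamming, and the BLOSUM45 transform
$d_{ab} = s(aa) + s(bb) - 2\,s(ab)$ using the published matrix shipped with
Biostrings; both metrics are reported side by side since either is
defensible), sets $R = (n-1)\bar d$, and evaluates adjacency and endpoint
posteriors at each requested temperature. Columns containing gaps or
non-standard residues are dropped pairwise for the BLOSUM metric (all three
terms of $d_{ab}$ restricted to the shared scorable columns); a strict mode
errors instead.

## The synthetic cluster generator

`synthesize_cluster()` emulates serial duplication: divergence increments
$u_k$ between adjacent genes are drawn once (uniform on $[2, 6]$ by default
-- for 60-column homeodomain-like alignments this places adjacent-gene
Hamming distances in the low single digits and the cluster diameter near but
below the alignment length, the regime where order recovery is non-trivial
but possible) and accumulated, so $d_{ij} = \sum_{k=i}^{j-1} u_k$. At
`noise = 0` the matrix is exactly additive, hence exactly Robinson. In
sequence mode each increment mutates that many *fresh* alignment positions,
so Hamming distances realize the additive matrix exactly; Gaussian matrix
noise or Poisson extra mutations perturb this.

What the generator does *not* emulate: back-mutation and saturation (real
homeodomain distances are not additive), rate variation across sites and
lineages, rearrangements after duplication, and correlated noise. Passing
tests on synthetic clusters therefore show that the machinery recovers
order and endpoints *when the Robinson signal is present*, not that real
clusters carry such a signal -- on real data the interesting output is
precisely where the posteriors deviate from the clean pattern.

## Numerical and testing choices

* Probabilities and partition functions are validated against exhaustive
  enumeration oracles (`enumerate_parses()` for string grammars,
  `enumerate_structures()` for RNA, `enumerate_hamiltonian_paths()` for
  sets) at tolerances between $10^{-9}$ and $10^{-12}$; the oracles share no
  code with the engines. Oracle sizes: sequences up to 10-12 nucleotides,
  alignments up to length 5, vertex sets up to $n = 9$ -- small enough that
  the complete test suite runs in well under a minute while still covering
  every recursion branch.
* `enumerate_parses()` handles ordered (string) tapes, one or two; set-like
  grammars use the dedicated path enumerator, which is what a generic
  subset-split parser would reduce to for the one set grammar shipped.
* Tie-breaking in optimizing backtraces is deterministic: smallest vertex
  index on ties, paths reported from their smaller endpoint, tours in a
  canonical orientation. Co-optimal solutions remain accessible through the
  count/partition algebras.
* Grammar productions are kept in lexicographic order after derivation so
  that grammar comparisons (and the JSON round trip) are deterministic.
* Float comparisons in tests always use tolerances, never string equality;
  TSV output rounds to 6 significant digits, JSON reports full precision.
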