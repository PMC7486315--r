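---
title: "Structured descriptions, keys, and delimitation matrices: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structured descriptions, keys, and delimitation matrices: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arenosae)
```

## The description model

A taxon description here is not prose but an ordered set of *descriptive
elements* (DEs).  Every DE names a **structure** (an organ or organ part
from a controlled vocabulary), a **property** of that structure, and one
**score**:

* a quantitative range with optional parenthetical extremes, as taxonomic
  accounts print them — `(8.0–)9.0–13.0(–14.0) mm` means a main range of
  9–13 mm with rarely observed extremes down to 8 and up to 14;
* a set of alternative qualitative states (`oblong` *or* `ellipsoid`);
* a relative comparison against another structure (an uppermost stem
  internode `obviously longer than` the next upper one); or
* an integer count range (`8–12 distinct internodes`).  Counts are printed
  as ranges in floras, so the package stores them as integer-bounded ranges
  with the reserved unit `"count"`; a scalar count is the degenerate
  `lo == hi` case.

DEs can carry *modifiers*: frequency (`usually`, `rarely`), temporal
(`at-anthesis`, `in-fruit`), and spatial (`in-lower-part`,
`upper-surface`).  Temporal and spatial modifiers define separate contexts
of the same slot, which is how "cylindrical at anthesis and clavate in
fruit" becomes two DEs on one calyx-shape slot.  At most one DE may occupy
a (slot, modifier-context) pair.

Two vocabulary layers keep descriptions comparable.  The **base ontology**
declares structures (a single-parent part-of tree, with synonyms resolved
at load time), properties with their kinds, states and units, and
*specifier definitions*.  A **description template** (a pro-forma ontology)
is an ordered selection of (structure, property) slots drawn from the base
ontology; its order is total and drives validation and rendering.  The
original base-ontology file behind the source database is not available, so
the packaged ontology is a reconstruction covering every term the packaged
descriptions use, and says so in its `provenance` field.

**Specifiers** single out one instance from a collection:
`internode[position=uppermost]`, `flower[order=first]/pedicel`.  The first
(alar) flower's pedicel is the conventional one to measure, because
pedicels keep growing for the life of the inflorescence; giving the path an
explicit `order=first` specifier makes that convention machine-checkable.
Calyx-tooth heteromorphism — three longer teeth differing from the two
shorter ones — is encoded the same way, as `tooth[class=shorter]` and
`tooth[class=longer]` slots, so both tooth classes can be described and
queried independently.

Absence of a slot always means *not recorded*, never *organ absent*
("Seeds unknown." simply leaves the seed slots out), and everything
downstream is three-valued because of it.

## Factoring and the section description

The section-level description holds features constant across the member
species; the per-species accounts then need not repeat them.
`intersect_constant()` computes such a parent bottom-up: a slot survives
only when every input records it and the scores agree — identically under
the `strict` policy, or up to an enclosing hull (flagged `"hull"`) for
quantitative slots under `enclosing`.  `factor_descriptions()` removes from
a child every DE identical to a parent DE; `expand_description()` merges
parent DEs back into the slots a child does not record, with the child
winning conflicts.  Expanding a factored child restores it exactly, and
factoring an expanded child restores the factored form; the test suite
checks both identities byte-for-byte under the canonical serialisation
(template-ordered elements, sorted keys and state sets).

Frequency modifiers participate in DE equality: "usually nocturnal" at the
section level is *not* the same element as an unqualified "nocturnal" in a
species, and factoring keeps them apart.

## Rendering

`format_quant()` emits the `(EL–)ML–MH(–EH) unit` pattern with an en dash
and one decimal for lengths; `parse_quant()` inverts it (accepting ASCII
hyphens and `10.0–30.0 × 2.0–4.0 mm` dimension pairs), and parse∘format is
the identity on valid ranges.  `render_description()` emits one phrase
group per template label, in slot order, merging adjacent length × width
slots into dimension pairs and joining temporal contexts with "and".  The
contract is deliberately *slot-wise phrase equality*, not full-sentence
byte equality with any printed account: published prose interleaves
free-text asides that structured data should not try to reproduce.  An
ASCII style (`render_style(ascii = TRUE)`) substitutes `-` and `x` for
terminals without the typographic glyphs.

## The key engine

A dichotomous key is a graph of numbered couplets, each with exactly two
leads; a lead is a conjunction of predicates and routes to another couplet
or ends at a taxon.  Structural invariants (unique ids, two leads, resolved
goto targets, acyclicity, reachability) are enforced at parse time.

Printed keys never say what "Anthophore > 6 mm" means for a taxon whose
anthophore is 5.0–6.0 mm, so the range-versus-threshold semantics are an
explicit `satisfaction_policy()`:

* `strict-range` — the whole main range must satisfy the comparison;
* `midpoint` — the midpoint of the main range must satisfy it;
* `overlap` — some point of the main range suffices.

These are nested (strict ⊆ midpoint ⊆ overlap for threshold predicates),
which the suite verifies property-style.  The default is **midpoint** with
**both-branches** unknown handling: several thresholds in the packaged key
sit exactly on range bounds of the packaged taxa (anthophore 3.0–5.0 mm
against "> 4 mm"), where strict semantics dead-ends; the midpoint keeps
evaluation deterministic, and when *no* lead of a couplet is true (a
false/unknown mix) both leads are explored and the outcome sets unioned, so
a taxon is never lost at a boundary.  A description with every slot unknown
therefore reaches all twelve terminals.  `state-in` predicates are true
when the recorded state set intersects the predicate's set (keys cite one
representative state against "A or B" descriptions), and relative
predicates treat `obviously-longer-than` as entailing `longer-than`.

Three clauses of the packaged key are stored as lead notes rather than
predicates, each flagged in the key document itself: distribution clauses
(descriptions carry no occurrence slots); the colour contrast "white or
pale pink" of couplet 1's second lead, which several taxa that must pass
through that lead contradict in their own accounts (their limbs are plainly
pink) — an inconsistency between the printed key and the printed
descriptions, not something evaluation should inherit; and "leaves not
fleshy" in couplet 9, since negated states are outside the comparator
vocabulary.  Its positive counterpart, "leaves fleshy", *is* a predicate
and is satisfied by a provenance-flagged supplemented element of subsp.
*maritima* — the one key character with no counterpart in any formal
account.  Couplet 8's bare "calyx teeth 1.5–2 mm" is encoded against the
shorter tooth class (the printed lead does not say which class it means;
the longer class of subsp. *cypria*, 2.0–2.5 mm, would contradict the lead
that diagnoses it).  Flowering time is likewise supplemented per species
from the section account's explicit list of the three diurnal taxa.

`check_key_consistency()` audits a key against the descriptions of all its
terminal taxa: membership (does each taxon's own description reach it?) and
discrimination (couplets where the sibling lead also admits the taxon).

## Posterior cluster similarity matrices

For species delimitation under the multispecies coalescent, a posterior
sample of ultrametric species trees is summarised by a co-clustering
matrix.  The pipeline: read the sample (NEXUS with translate tables and
BEAST-style bracketed annotations, or plain Newick); discard the first
`floor(fraction × N)` trees as burn-in (the floor makes the cut
reproducible bit-for-bit for any N; the conventional fraction is 10%);
partition each tree's tips at a *collapse height* ε, two tips sharing a
class iff their MRCA sits strictly below ε (ε approximates zero node
height — the study convention is `1e-4` — so boundary equality, a
measure-zero event, does not cluster); and average the resulting
co-membership indicators.  Entry (i, j) is then the posterior frequency
with which i and j belong to the same near-zero-height cluster.  Every tip
is its own minimal cluster: each specimen's assignment is what is under
test.

Ultrametricity is checked with a relative tolerance of `1e-8` of the root
height; failing trees are rejected with the offending tip named, never
silently repaired.  The implementation walks each tip upward to its highest
ancestor below ε (linear in tree size); the test suite compares it against
an independent O(n²) all-pairs MRCA-height oracle on random coalescent
trees.  For display, `sort_by_tree()` permutes the matrix to the
left-to-right tip order of the ladderized summary tree — smaller clades
first, larger last, ties by label.  The referenced plotting conventions do
not pin down a tip order, so ladderization is this package's documented
choice; it is idempotent and invariant to the incoming label order.

## Synthetic data: what it emulates and what it does not

`gen_descriptions()` builds a synthetic ontology with one organ per
character slot and draws taxa in which exactly
`round(constant_fraction × n_chars)` slots are identical everywhere and
every remaining slot differs somewhere — the regime the section/species
factoring is designed for, with the truth record returned for checking.

`gen_posterior()` emulates the *structure* of a species-tree posterior
around a known partition, not the coalescent process itself: per sample,
each tip is independently reassigned to a uniformly drawn other class with
probability *q*; tips of one realised class coalesce at heights uniform on
(0, `within_height`), class roots join at or above `between_height`.  The
defaults (`within_height = 2e-5`, `between_height = 1e-2`) bracket the
conventional ε of `1e-4` by two orders of magnitude on either side, so
collapse partitioning recovers the realised assignment exactly and
co-clustering probabilities have closed form (`flip_cocluster_prob()`):
`(1−q)² + q²/(C−1)` within a class, `2q(1−q)/(C−1) + q²(C−2)/(C−1)²`
between.  What passing these tests shows is that the counting and
thresholding machinery is exact; it says nothing about MCMC mixing,
gene-tree conflict, or model misspecification in real posteriors, which
the generator deliberately does not simulate.  Generators take an explicit
seed, save and restore the caller's RNG state, and are byte-reproducible
per seed.

## Problem sizes and numerical choices

The shipped tests run the parse/format identity on 1,000 random
one-decimal ranges; the factoring round-trip on the full fixture set plus
100 random parent/child pairs; the collapse oracle on 200 random
coalescent trees of up to 30 tips, with the collapse height drawn strictly
between two realised node heights so float ties cannot blur the
strict-inequality contract; and partition recovery on a 12-tip, 4-class
posterior of 400 samples at q = 0.1, where every matrix entry must sit
within three binomial standard errors of its analytic probability and
thresholding at 0.5 must reproduce the constructed partition.  These sizes
give the property suites real room to fail while keeping a default test
run near twenty seconds.

Unit conversions go through the registry (mm canonical, cm = 10 mm) before
any comparison; counts are unitless and never convert to lengths.
Canonical serialisation orders elements by template slot (then modifier
context), sorts state sets, and leaves numbers to the JSON writer
unchanged, which is what makes the round-trip tests byte-exact.

## Limitations

The ontology layer does no OWL/RDF reasoning and no term versioning; state
combinations are alternatives ("or") only — conjunctive state pairs are
flattened into separate DEs; descriptions are taxon-level, not
specimen-level; the key engine evaluates and audits given keys but does
not generate them; and no summary tree is inferred — `sort_by_tree()`
consumes one.  The reconstructed base ontology covers the packaged
descriptions, not the full vocabulary of the original database.
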