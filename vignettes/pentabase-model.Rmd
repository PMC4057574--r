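---
title: "An order-five edit algebra for nucleotide sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An order-five edit algebra for nucleotide sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pentabase)
```

## The problem and the model

Position-wise algebra on DNA breaks down the moment an insertion or deletion
shifts every downstream coordinate. `pentabase` restores the algebra by
adjoining a fifth, "empty" base **E** to {C, A, T/U, G}: an indel becomes a
substitution to or from E, and the five letters carry a sharply transitive
action of the cyclic group of order five.

Letters are indexed by phases m ∈ Z/5 (E = 0, C = 1, A = 2, T/U = 3, G = 4)
and the group Z₅ = {n, r, u, d, l} acts by adding the exponent of the
generator r: `X_m ∘ r^k = X_((m+k) mod 5)`. Three equivalent notations exist
and `z5()` parses all of them:

* **linear** — powers of r along a lattice row: u = r², d = r³, l = r⁴;
* **rotational** — rotations ω_k by 2πk/5 of the phasor diagram placing the
  five letters at the fifth roots of unity (`base_phasor()`);
* **wallpaper** — displacements `x[a,b] = r^a ● u^b` on the lattice whose
  cell at (x, y) holds the letter with index (x + 2y) mod 5
  (`grid_letter()`, `wallpaper_grid()`); the motif repeats by a knight's-move
  translation, each row cycles E-C-A-T-G, and the letters at (x, y) and
  (−x, −y) are complementary.

Every element is stored canonically as the exponent k ∈ 0..4; aliases are
print/parse forms only, which removes any possibility of representation
drift between the three notations. The rendering into rotational tokens is a
(trivially faithful) functor, and `check_functor_laws()` verifies
composition preservation exhaustively over all 25 component pairs.

One notational subtlety: in the u-generated representation the exponent
realising X_m is (3m) mod 5, forced by u = r² (2·3m ≡ m mod 5); this is what
`base_power(b, "u")` returns.

## Sequence vectors and E bookkeeping

A `seqvec` is a sparse map from 1-based place numbers to explicit letters
over an implicit infinite background of E's. The distinction between an
**explicit** E (a stored entry — tracked, deletable) and an **implicit** E
(no entry) is load-bearing:

* `braces()` ("{ }") demotes explicit E's to implicit without renumbering;
* `angle()` ("< >") deletes E's and renumbers 1..N — the conventional
  sequence;
* `insert_E()` / `delete_E()` shift downstream place numbers up/down;
* `n_bases()` counts real bases only and is invariant under all of the
  above, as is the conventional text — these invariants are enforced by
  property tests.

The infinite trailing tail of E's is never stored; the explicit text
rendering appends a fixed `|E...` marker instead. Place numbers are 1-based
throughout because every display convention in this formalism starts at 1.
`seq_reverse()` reverses over the span 1..max(place), mapping implicit gaps
symmetrically — the minimal extension consistent with the dense examples the
formalism is defined on — and flips the direction label. Equality testing is
direction-label-sensitive by default; `seq_equal()` exposes
`ignore_direction` and `ignore_explicit_E` because an operator application
can legitimately differ from a directly constructed target only in the
explicit/implicit status of E's.

## Operator vectors

An `opvec` stores only non-identity components (place → exponent 1..4);
composition and inversion are componentwise, so the operator vectors form an
Abelian group with the empty vector as identity. Two design choices matter:

* operators may act at implicit places, materialising an explicit base there
  (no mandatory pre-insertion step);
* a base mapped *to* E stays an explicit E — recombination depends on
  tracking such E's for later deletion.

`op_diff()` is strictly positional: it never aligns. Indel alignment is the
caller's job via `insert_E()` first, mirroring the two-step decomposition
(insert E's, then substitute) that the model prescribes. `diff`/`apply` are
mutually inverse, and `diff(a, c) = diff(a, b) ● diff(b, c)` exactly —
both identities are exercised on a thousand seeded random cases.

Complementation is the operator with component exponent (−2m) mod 5 at
every place holding index m; applying it agrees everywhere with the
letter-wise `complement_base()` oracle. `complement_seq()` flips the
direction label (the chemistry is antiparallel) but deliberately does **not**
reverse place order; compose with `seq_reverse()` when reversed coordinates
are wanted.

## Recombination

`recombine(s_c, seg_c, s_d, seg_d)` swaps two segments by the E-padding
construction: a block of E's the size of the *other* segment is inserted
immediately before the segment in the first sequence and immediately after
it in the second; one operator vector then writes the incoming bases into
the E block while erasing the outgoing segment to E's, and the second
operator realises the reverse exchange. Base content is conserved as a
multiset across the pair.

The celebrated inverse identity — the two operators are exact componentwise
inverses — holds precisely when the two segments start at the same place
number, so that the written block of one sequence occupies the same places
as the erased block of the other. The defining worked example (segments at
places 3–6 and 3–7 of a six- and seven-letter sequence) satisfies this, and
the property suite samples that aligned regime; for arbitrary segment
starts `recombine()` still returns the operators that produce the correct
swapped sequences on both sides, the inverse relation then holding
block-wise rather than place-wise. Zero-length segments are rejected rather
than guessed at, and segments must lie within the explicit span.

## The central-dogma chain as a category

`central_dogma()` chains four morphisms between the objects X (sense DNA),
Y (antisense DNA), Z (pre-mRNA) and Zs (spliced mRNA):

1. **ρ** complement (X → Y) — by default the transcript is the complement;
   a `complement = FALSE` flag transcribes the sense strand directly, since
   both options are admissible in the model;
2. **τ** transcription (Y → Z) — a pure alphabet relabel (index 3 renders U
   instead of T); it changes object, so it is represented as a relabel step
   and never as an operator vector — that is exactly why category language
   rather than group language is needed here;
3. **j** splicing (Z → Zs) — intron bases become explicit E's *in place*
   (coordinates given in the transcript's pre-mRNA place numbers, inclusive,
   1-based), so nothing renumbers until
4. **maturation** — the angle normalisation, after which
   `codon_partition()` groups letters into the three reading frames.

`morphism()`, `check_identity_laws()` and `check_associativity()` verify the
category laws by evaluation: exhaustively at the component level (the
component algebra is finite of order five, so exhaustiveness is available
and decisive) and on seeded samples at the sequence level. Where the
formalism's prose and its summary figure disagree on the typing of the
morphism h, the figure's typing (h : Z → Z) is followed. The negative
controls the checkers support (a corrupted identity, a permuted component
map, a mutated composition table) are ordinary function arguments, so a
failing report can be demonstrated and tested without private hooks.

Codon-to-amino-acid translation and reverse transcription are out of scope
by design.

## Numerical and interface choices

* **Determinism.** The only stochastic code is the fixture generator
  `random_seqvec()` (uniform letters, per-position explicit-E probability)
  and the sampled property suites; both take explicit seeds and apply them
  locally via `withr::with_seed`, leaving the caller's RNG untouched.
* **Problem sizes.** Property suites in the tests run 1000 seeded cases for
  the algebraic identities and 25–40 cases for the heavier sequence-level
  constructions, with sequence lengths up to 40; the component-level checks
  are exhaustive (25 pairs, 125 triples). These sizes make the whole suite
  run in well under a minute while the exhaustive layers are already
  complete proofs at the component level.
* **What the generator does not emulate.** Real genomes are not i.i.d.
  uniform over four letters, and real recombination respects homology; the
  generator probes the *algebraic* contracts (round trips, inverses,
  conservation), not biological realism, so passing tests certify the
  calculus, not any claim about real sequence statistics.
* **Interchange.** FASTA I/O goes through Biostrings with E as a literal
  letter (it participates in the arithmetic, unlike an alignment gap; a
  `dash_as_E` flag maps `-` to E on import for interop). The `evec` and
  `editlog` JSON sidecars serialise full place-number bookkeeping and
  operator vectors canonically, so round trips are byte-exact. Mixed T and U
  in one record is an error rather than a guess.
* **Figures.** The polygonal-line chart of a vector is defined as
  (place number, phase index) with E = 0 — deterministic and
  information-preserving; `orbit_path()` returns the points (implicit E's
  optionally included, off by default) and `plot_orbit()` the ggplot.

## Limitations

The model imposes no pairing constraints between strands (any letter may
face any other), place-number bookkeeping is the user's responsibility the
moment operators and indels are interleaved by hand, and the wallpaper
arrangement built here is one of several admissible letter placements — the
algebra is unchanged under relabellings such as swapping A with C and G
with T.
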