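# pentabase

An algebraic toolkit for DNA/RNA sequence editing over a five-letter
alphabet. The four bases C, A, T (U in RNA) and G are joined by an imaginary
"empty" base **E**, so that insertions and deletions — which ordinarily
break any position-wise algebra — become ordinary substitutions to and from
E. On the augmented alphabet every edit is a group action, every edit has an
exact inverse, and a whole editing history can be tracked, composed and
undone with place-number bookkeeping intact.

## The model

Index the letters by phases m ∈ Z/5: E = 0, C = 1, A = 2, T/U = 3, G = 4.
The cyclic group Z₅ = {n, r, u, d, l} acts on letters by

    X_m ∘ r^k = X_(m+k mod 5),   with u = r², d = r³, l = r⁴, identity n,

equivalently as rotations ω_m = e^(2πim/5) of a five-point phasor diagram, or
as displacements x[a,b] = r^a ● u^b on a wallpaper lattice where moving right
applies r and moving up applies u (canonical exponent (a + 2b) mod 5).

A sequence is a sparse **place-indexed vector**: a map from 1-based place
numbers to explicit letters over an implicit infinite background of E's. An
**operator vector** B assigns a group element to each place and acts
componentwise, `D ∘ B`. From this you get, for free:

- a positional `diff`/`apply` pair: `apply(a, diff(a, b)) = b`, with
  `diff(b, a) = diff(a, b)⁻¹`;
- complementation as the operator with exponent (−2m) mod 5 per component
  (A↔T, C↔G, E↔E), an involution;
- recombination of two sequences as paired E-padding plus two operator
  vectors that are componentwise inverses of each other;
- a central-dogma chain: complement → T→U relabel → intron-to-E splicing →
  maturation (delete E's, renumber) → codon partition, whose morphisms
  satisfy the category and functor laws the package can verify on demand.

## Worked example

```r
library(pentabase)

cd <- central_dogma(seqvec("TCATEAGCTGA"), introns = list(c(2, 4)))
cd
#> <central_dogma>
#>   dna       T1 C2 A3 T4 E5 A6 G7 C8 T9 G10 A11 |E...
#>   antisense A1 G2 T3 A4 E5 T6 C7 G8 A9 C10 T11 |E...
#>   pre_mrna  A1 G2 U3 A4 E5 U6 C7 G8 A9 C10 U11 |E...
#>   spliced   A1 E2 E3 E4 E5 U6 C7 G8 A9 C10 U11 |E...
#>   mature    A1 U2 C3 G4 A5 C6 U7 |E...
codon_partition(cd$mature, frame = 0)
#> [1] "AUC" "GAC" "U"
```

The sense strand (with one tracked explicit E at place 5) is complemented,
relabelled to RNA, the intron at transcript places 2–4 is erased to explicit
E's without renumbering, and maturation deletes all E's and renumbers,
yielding the mature message `AUCGACU` in three reading frames.

Recombination swaps two segments and returns the operator pair realising the
exchange:

```r
r <- recombine(seqvec("GETAGT"), c(3, 6), seqvec("ATAGCTA"), c(3, 7))
r
#> <recombination>
#>   out_c: G1 E2 A3 G4 C5 T6 A7 E8 E9 E10 E11 |E...
#>   out_d: A1 T2 E3 E4 E5 E6 E7 T8 A9 G10 T11 |E...
identical(op_inverse(r$op_c)$exponent, r$op_d$exponent)
#> [1] TRUE
```

A command-line interface covering the same verbs (`complement`,
`transcribe`, `splice`, `mature`, `dogma`, `diff`, `apply`, `recombine`,
`edit`, `grid`, `orbit`, `selfcheck`, `fixtures`) is installed at
`inst/cli/pentabase`; it reads and writes FASTA (E as a literal letter) and
the package's evec/editlog JSON formats.

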