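---
title: "Modelling and quantifying shufflon variant dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and quantifying shufflon variant dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shufflonr)
```

## The biological system

I-complex conjugative plasmids carry a type IVb pilus whose minor pilin,
PilV, acts as an adhesin that selects recipient cells during mating. The 3′
end of *pilV* sits inside a *shufflon*: a set of `n` invertible DNA
cassettes separated by *sfx* recombination sites. A dedicated tyrosine
recombinase (the shufflase, Rci) recombines pairs of inverted *sfx* sites,
inverting the cassettes between them singly or in contiguous groups. Each
cassette carries two convergent partial ORFs, one per strand, and whichever
ORF ends up fused in frame to the constant *pilV* 5′ region — the ORF read
off the cassette adjacent to the constant region, in its current
orientation — becomes the expressed C-terminal adhesin domain. The shufflon
is therefore a combinatorial switch over `2n` adhesin variants, and the
plasmid's conjugative host range changes as the locus is shuffled.

## The conformation model

A conformation is represented as a **signed permutation** of the cassette
ids: order encodes position relative to the constant region, sign encodes
orientation. One recombination event between the sites flanking positions
`i..j` reverses the block and flips every sign (`invert_block()`). The set
of reachable states is the closure of the identity arrangement under all
contiguous block reversals, computed by breadth-first search with a
visited set keyed on the canonical serialisation (`"1+,3-,2+,4-"`);
deterministic output order is obtained by sorting on the signed-integer
encoding. For `n >= 1` this closure is the full group of signed
permutations, of size `n!·2^n`:

```{r}
nrow(enumerate_conformations(4))
```

Two modelling choices deserve comment.

* **Reachability.** Which *sfx* pairs can actually recombine depends on
  their relative orientations, which published consensus figures do not
  resolve into a reachability graph. We allow every contiguous block
  reversal, which generates the full state space and matches the standard
  `n!·2^n` count (384 for four cassettes); the move set is configurable
  (`moves` argument of `enumerate_conformations()`) for stricter models.
* **Equality.** Conformations are compared element-wise. There is no
  quotient by global inversion because the constant *pilV* region fixes an
  absolute reference frame on the locus.

Partitioning all conformations by expressed variant is exactly uniform —
each of the `2n` variants is active in `(n−1)!·2^(n−1)` states — which the
test suite verifies against brute-force enumeration.

## Locus anatomy and coordinates

An *sfx* site is modelled as a 31-bp footprint: a nonconserved 12-bp left
arm, a perfectly conserved 7-bp core where the crossover occurs, and a
conserved 12-bp right arm whose positions 7–9 form a variable triplet
(repeat classes such as GTG/ATC/TCG, labelled e/f/g). Detection
(`find_sfx_sites()`) requires an exact core match plus a right-arm match at
non-wildcard positions with at most `max_mismatches` substitutions
(default 0), on both strands; the left arm is recorded but never matched.
The consensus letters are a configuration object (`sfx_consensus()`) whose
bundled default is **synthetic**: detection never hard-codes the letters of
any particular plasmid.

All coordinates in the package are 1-based and inclusive, the R and
Bioconductor convention. `build_locus()` segments a sequence so that the
constant 5′ region ends at (and includes) the first site core, cassettes
are the intervals strictly between consecutive cores — each therefore
starts with the upstream site's right arm and ends with the downstream
site's left arm — and the constant 3′ side (toward *rci*) begins after the
last core. The reading frame of the constant region comes from the
annotated *pilV* CDS start when one exists, otherwise from the
`constant5_hint` argument; it is never inferred by a longest-ORF heuristic.
Translation uses the bacterial genetic code (NCBI table 11) by default, and
reported variant lengths exclude the stop codon.

## Junction signatures and counting

Each variant is identified by a k-mer spanning the junction between the
constant *pilV* 3′ end and the adjacent cassette. The classic footprint
length is 39 bp; since only the total length is standard, the split is a
package decision: by default `c = 19` constant-side bases ending at the
core boundary (the 12 left-arm bases plus the 7-bp core — the left arm is
locus-specific and anchors the signature to the *pilV* junction) and
`k − c = 20` cassette-side bases, which carry all the discriminating
information. Both are configurable. If two signatures collide, or one
equals another's reverse complement, `k` grows symmetrically (one base per
side) until all are unique; an irreducible collision (identical cassette
prefixes longer than the available sequence) is an error naming the pair.
The test suite verifies, by exhaustive scan over all 384 conformation
sequences of a generated locus, that each signature occurs in exactly the
conformations expressing its variant.

Counting (`count_footprints()`) is intentionally primitive, mirroring how
such footprints are tallied straight from raw FASTQ: exact substring
matching of each signature against the read and its reverse complement, a
read counting at most once per variant. Reads matching two or more distinct
variants are tallied as ambiguous and excluded — with verified-unique
signatures these can only be chimeric or error-bearing reads. No quality or
length filtering is applied by default (an optional mean-quality cutoff
exists); a per-occurrence counting mode is available. Relative abundance is
the count divided by the total number of footprint-positive reads, so
frequencies sum to 1; an all-zero table is an explicit error rather than
silent zeros.

**Enrichment** between donor and transconjugant populations is reported as
`log2((f_trans + eps)/(f_donor + eps))`. No standard formula exists for
this quantity, so the log2 frequency ratio with a pseudocount is this
package's explicit definition; `eps` defaults to one read's worth of
frequency in the smaller sample (`1/min(total_positive)`), which bounds the
statistic for dropout variants while leaving well-measured frequencies
essentially untouched. **Conjugation frequencies** are transconjugants per
recipient CFU; zero transconjugants, or ratios below the limit of
detection, are reported *at* the limit with a censoring flag (defaults
1e-8, matching typical in vitro detection limits; 1e-5 is typical in vivo).

## The synthetic-data layer

`generate_locus()` builds a locus whose ground truth is fully known:

* a constant region of 345 codons (the TP114-like PilV N-terminus length),
  stop-free in frame, ending with the first site's left arm and core;
* `n = 4` cassettes by default, each with two convergent stop-terminated
  ORFs whose total lengths are drawn uniformly from 69–113 codons (the
  observed range of PilV C-termini), separated by `n + 1` planted sites
  with variable triplets cycling over GTG/ATC/TCG;
* the first cassette base falls on a codon boundary of the fused frame, so
  a variant ORF is simply the in-frame translation of its oriented cassette
  (its first four codons are encoded by the flanking arm, whose letters are
  chosen stop-free);
* background sequence is uniform-random (GC content configurable, default
  0.5) and resampled to avoid spurious core motifs; as a final guard the
  generator runs the package's own site detection and regenerates (still
  under the same seed stream) if the planted architecture is not recovered
  exactly.

`simulate_dynamics()` evolves `n_cells` independent cells for `n_steps`
steps; per step a cell inverts, with probability `inversion_prob`, one
uniformly chosen contiguous block. The move set is symmetric, so the chain's
stationary law is uniform over all conformations — the qualitative analogue
of an active shufflon expressing every variant — while `inversion_prob = 0`
keeps the population locked in its starting state, the shufflase-deletion
analogue. The real per-generation inversion rate is unknown (shufflase
levels appear to be very low in vivo), so `inversion_prob` is a free
parameter, not an estimate. Per-cell simulation was chosen over a
deterministic master equation because it matches the clonal-population
framing and gives the uniform stationary law as an independent test oracle.

`simulate_selection()` models transfer toward a given recipient as
multiplicative reweighting, `f·w / Σ f·w`, with non-negative
variant-specific compatibility weights. `simulate_reads()` draws each
read's source conformation multinomially, samples a uniform start and
strand on the full rearranged locus sequence, and applies independent
substitutions at `error_rate` (default 0.001; substitution-only — indels,
PCR bias and paired-end chimeras are out of scope). Base qualities are a
uniform high constant. Every simulator is a pure function of its inputs and
seed (`withr::with_seed`), so all outputs are byte-reproducible.

### What the generator does and does not emulate

The synthetic locus reproduces the *architecture* that the analysis depends
on — site structure, cassette geometry, reading frames, junction
uniqueness — with uniform-random sequence content. It does not emulate real
codon usage, homology between cassettes of related plasmids, amplicon
library structure (reads are shotgun-style over the whole locus, so only
the fraction of reads spanning the junction window is informative), indel
or quality-dependent errors. Passing tests therefore demonstrate
correctness of the combinatorics, detection, signature construction and
counting under a clean substitution-noise model — not robustness to every
artefact of real libraries. Homologous cassettes that share long prefixes
would trigger the signature-extension path or, at the extreme, an
irreducible-collision error rather than silent misassignment.

## Numerical and testing choices

Problem sizes used by the test suite were chosen to exercise the claims
with comfortable statistical margins at interactive runtimes: exhaustive
checks run at n = 3–4 (48–384 states); stochastic recovery tests use read
depths of 10⁴–10⁵ and compare observed frequencies to truth within 3
binomial (or delta-method multinomial, for log ratios) standard errors of
the realised footprint-positive read count. The enrichment-recovery
experiment uses 250-bp reads so that a larger fraction of simulated
molecules spans the junction window, mimicking junction-amplicon libraries.
Fixed seeds make every stochastic test deterministic.

Known limitations: no read alignment or mapping (exact matching only, with
an optional mismatch budget), no paired-end merging or UMI handling, no
replicate-level statistics beyond mean ± SD in the plots, and the
reachability question above — if a real shufflon's site orientations forbid
some block reversals, the uniform stationary law and the 384-state count
apply to the permissive move set only.
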