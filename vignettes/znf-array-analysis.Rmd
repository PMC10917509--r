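---
title: "Minisatellite zinc-finger array analysis: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minisatellite zinc-finger array analysis: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(znfarray)
```

## The problem

The DNA-binding specificity of the meiotic regulator PRDM9 is encoded by a
tandem array of C2H2 zinc fingers, itself encoded by a minisatellite of 84-bp
repeat units in exon 12. Each unit encodes one ~28-residue finger; the
residues at recognition-helix positions −1, +3 and +6 contact one 3-bp DNA
subsite and are hypervariable under positive selection. Arrays evolve by
within-unit point mutation and by recombination-driven gain and loss of whole
units (tandem duplication or "slippage", and unit insertion/deletion), which
defeats ordinary multiple-sequence alignment and standard nucleotide
substitution models. This package implements the repeat-aware toolchain such
alleles need: decomposition into units, a weighted repeat-unit edit distance,
BIONJ phylogenies, in-silico binding-motif construction and genome scanning —
plus a simulator that generates allele families with known history so that
every stage can be validated end to end.

## Repeat decomposition and zinc-finger anatomy

`decompose_minisatellite()` tiles an allele left to right into 84-bp units.
When the length is not a multiple of 84, segmentations containing shortened
units (84 minus an in-frame deletion, 9 nt by default) are enumerated and
scored by the total nucleotide edit distance of all units to the consensus of
the full-length units in that segmentation; ties prefer the leftmost
shortened unit. The only non-canonical unit observed in practice is a first
finger carrying a 9-nt in-frame deletion that removes three residues
including one zinc-coordinating cysteine, and the enumeration is exact for
such cases. Decomposition is lossless: concatenating the units always
reproduces the input byte for byte.

Contact residues are located structurally, not by fixed offsets.
`resolve_contact_positions()` finds the C2H2 signature
`C-x(2,4)-C-x(12)-H-x(3,5)-H` in the translated unit and anchors
recognition-helix numbering at the first zinc-coordinating histidine (helix
position +7); helix offset *p* then maps to amino-acid index `h1 − 7 + p`.
This makes 75-nt units and extended offset sets (−5, −2, +1) resolve
consistently, and cleanly fails on units that have lost a ligand.

Confidence filtering (`filter_repeats()`) defaults to pattern mode: a unit is
kept when its peptide matches the C2H2 signature. Profile mode scores units
against a user-supplied position-specific bit-score table and keeps those
strictly above 17.7 bits, the gathering threshold conventionally used for
this finger model; the package ships no trained profile because reproducing
an externally trained model is out of scope. Downstream distances and motifs
consume kept units by default, but `use_kept = FALSE` retains everything —
the right choice for simulator output, where every unit is a true repeat by
construction.

## The weighted repeat-unit edit distance

`array_distance()` is a global-alignment dynamic programme over *unit*
sequences. Substituting one unit for another costs the nucleotide Hamming
distance (Levenshtein when masked lengths differ, which only unequal-length
units force) times `w_mut = 1`. Deleting or inserting a whole unit costs
`w_indel = 3.5`, discounted to `w_slippage = 1.75` when the unit is identical
to an immediate neighbour in its own array — the signature of a tandem
duplication/slippage event. The defaults are the established weights for
this minisatellite. Design choices a user should know:

* **Slippage identity** requires an exact nucleotide match by default
  (`slippage_max_mismatch = 0`) and is always judged on the unmasked
  sequence, because duplication copies the physical unit; masking is a
  comparison-level operation. Runs of several identical inserted units are
  charged per unit, not per event.
* **Symmetry** holds because the gap discount is owner-relative (a unit's
  cost depends on its own neighbours). The distance satisfies non-negativity,
  identity and symmetry; the triangle inequality is *not* asserted — the
  slippage discount can break it.
* **Masking** (`mask = "contacts"`) removes the 9 contact-codon nucleotides
  of each unit, located per unit via the anchoring rule above, before
  comparison. Masked distance can never exceed unmasked distance. Units whose
  C2H2 pattern cannot be resolved are left unmasked rather than guessed at.
* The DP is verified against an exhaustive enumeration of all monotone edit
  scripts on small arrays in the test suite.

Masking is the mechanism behind the characteristic tree collapse: alleles
that differ only at contact codons have identically zero masked distance and
fall onto a single zero-length cluster in the masked tree, while remaining
separated in the full tree.

## BIONJ and rooting

`bionj_tree()` implements Gascuel's BIONJ (neighbor joining with
variance-weighted reduction) in double precision. On additive matrices the
output reproduces the input path lengths to ~1e-15, and the implementation
is cross-checked against an independent C implementation on noisy matrices
in the tests. Determinism is explicit: ties in the Q criterion are broken by
the lexicographically smallest pair of cluster labels, so all-zero matrices
agglomerate in label order. Negative branch-length estimates are clamped to
zero with the deficit moved to the sibling branch, standard NJ practice.
`root_on_outgroup()` inserts the root at the midpoint of the outgroup's
pendant edge (the natural uninformative choice on that edge), so unrooting
recovers the original tree exactly.

## From fingers to binding motifs

The per-finger specificity model is pluggable. The published approach uses an
externally trained polynomial-kernel SVM; that model is third-party
intellectual property and is *not* re-trained or bundled. Instead,
`predict_finger_pfm()` accepts (a) an externally computed 4×3 matrix (MEME or
JASPAR text via `read_meme()`/`read_jaspar()`), (b) any user function from
contact triplet to matrix, or (c) a deterministic built-in fallback: a
simplified recognition-code lookup mapping each contact residue to a base
preference (pseudocount 0.01, uniform for residues without a documented
preference). The fallback exists so that the downstream algebra — assembly,
comparison, scanning, overlap — is fully exercisable and testable; it is not
a substitute specificity model for biological inference.

`assemble_array_pwm()` concatenates per-finger matrices in N-to-C order and
reverse-complements the result, because the N-terminal finger reads the 3'
end of the site; assembling twice is an involution back to the forward
orientation, and the tests verify that a site planted for the assembled
matrix is found by the unreversed concatenation at the same locus on the
opposite strand.

`compare_motifs()` approximates a TomTom-style comparison with a permutation
null: the observed score is the best summed Pearson column correlation over
all offsets (≥ 6 aligned columns) and both orientations, and the p-value is
the add-one-corrected fraction of column-shuffled targets scoring *strictly*
better. Strict counting matters: zinc-finger arrays routinely contain
repeated fingers, hence repeated PWM columns, and a shuffle that permutes
identical columns ties the observed score. With ≥-counting a self-comparison
could then never attain the minimal p; with strict counting every motif's
self-comparison reaches `1/(n_shuffles + 1)`, the empirical analogue of the
"zero cannot be log-transformed" diagonal. `n_shuffles` below 100 is
rejected as statistically meaningless.

`score_threshold_from_pvalue()` computes the exact log-odds score
distribution under the zero-order background by dynamic programming over
columns, discretized to 1e-3 bits, and returns the smallest threshold with
tail probability ≤ p (default scan p = 1e-5; the choice between a p-value
and a raw-score cutoff is configurable because published practice varies).
`scan_genome()` scores both strands, skips windows containing non-ACGT
letters, reports minus-strand hits in forward half-open 0-based coordinates,
and applies a 1e-9-bit tolerance at the threshold to absorb floating-point
accumulation-order effects (negligible against the 1e-3-bit grid).
`intersect_hits()` counts hit pairs sharing ≥ 1 bp on the same chromosome,
strand-agnostic, plus a base-pair Jaccard on merged coverage; overlapping
hits of one motif on opposite strands are both reported, matching the
"each incident" convention.

## The simulator: what it emulates and what it does not

`simulate_allele_family()` draws a Yule (pure-birth) tree rescaled to unit
height, then evolves an ancestral array of 11 identical canonical 84-bp
units along it. Three event types act per branch with Poisson counts:
substitutions (`sub_rate = 2` per unit per unit branch length), tandem
duplications and unit deletions (`dup_rate = del_rate = 0.3` per array per
unit branch length). Substitution positions are uniform except at the 9
contact-codon nucleotides, which are hit 10× more often
(`contact_hypermut_factor`), emulating positive selection on the
hypervariable sites as an elevated rate. These rates are honest inventions —
no generative model accompanies the real data — chosen so that a family of 8
alleles accumulates tens of substitutions and a few unit-number changes, the
regime the real alleles display. The hypermutable positions are defined at
the canonical contact offsets (nt 37–39, 49–51, 58–60 of each 84-nt unit),
a generative convention that avoids re-resolving contacts on partially
mutated units.

Every applied event is logged (branch, type, unit, position, bases), and
`replay_event_log()` reproduces all leaves exactly from the ancestor — the
simulator's lossless-provenance invariant. `make_contact_only_variants()`
generates the masked-collapse fixture (variants differing from a base allele
only within contact codons, stop codons avoided, duplicates rejected), and
`plant_motif_genome()` plants motif consensi at recorded non-overlapping
positions and strands in i.i.d. background sequence.

The simulator does **not** emulate: recombination between alleles, biased
gene conversion and hotspot erosion, heterozygosity and read-level artefacts
of Sanger sequencing, within-unit indels, or realistic demography. Passing
tests therefore demonstrate the correctness of the algorithms under a clean
generative model, not the biological fidelity of any particular rate
setting.

## Validation conditions and problem sizes

The test suite validates each stage against independent oracles: exhaustive
edit-script enumeration for the distance DP (hundreds of random small
arrays), closed forms and additive matrices for BIONJ (4–10 taxa, branch
lengths ≥ 0.1), Monte-Carlo hit rates for threshold calibration (0.5–1 Mb of
i.i.d. background, agreement within 3 standard errors at p = 1e-3 and 1e-4),
all-pairs counting for interval overlap (1,000 random instances), and exact
direct summation for the binomial test. Topology recovery uses 50 simulated
8-leaf families at the default rates and requires a mean normalized
Robinson–Foulds distance ≤ 0.2 against the true trees; distances there are
computed over all units (`use_kept = FALSE`), the appropriate condition for
simulator output as discussed above. These sizes were chosen as the smallest
that make the statistical checks meaningful.

## Small utilities

Two closed-form laboratory utilities ride along with the pipeline.
`sperm_concentration()` converts paired 25-square Bürker-chamber counts into
million spermatozoa per ml using the chamber volume
0.02 × 0.02 × 0.01 × 25 = 1e-4 cm³ and the dilution factor (default 1:40).
`trd_binomial_test()` tests transmission-ratio distortion against the
Mendelian 50:50 expectation, either exactly (minimum-likelihood two-sided
binomial) or by the continuity-corrected normal approximation; the two agree
within 10% relative error near 50:50 for n ≥ 200.

## Known limitations

* The built-in recognition-code fallback is a coarse, position-independent
  caricature of finger specificity; use externally computed matrices for any
  biological claim.
* The distance is not a full metric (no triangle inequality), so methods
  requiring metricity should be applied with care; BIONJ does not.
* Segmentation enumeration is exact but bounded (it refuses pathologically
  ambiguous inputs rather than guessing).
* The motif comparison null (column shuffling) is not the analytic TomTom
  null; p-values are comparable within a run, not across tools.

```{r example, eval = FALSE}
# A complete run on simulated data:
fam <- simulate_allele_family(simulation_config(seed = 1))
write_fasta(fam$alleles, "alleles.fa")
res <- run_pipeline(list(alleles_fasta = "alleles.fa", outdir = "out",
                         run_motifs = TRUE, seed = 1))
res$dist_full
```
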