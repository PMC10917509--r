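# znfarray

Tools for analysing minisatellite alleles that encode C2H2 zinc-finger
arrays — the architecture of exon 12 of the mouse meiotic regulator *Prdm9*,
whose zinc-finger array determines where meiotic recombination hotspots
form and whose allelic incompatibilities drive hybrid sterility.

Such alleles are tandem arrays of 84-bp repeat units, each encoding one
~28-residue zinc finger. The residues at recognition-helix positions −1, +3
and +6 of each finger contact one 3-bp DNA subsite and are hypervariable.
Arrays evolve by point mutation *and* by gain/loss of whole units
(duplication/slippage), which breaks ordinary alignment-based phylogenetics.
`znfarray` provides the repeat-aware toolchain:

* **Decomposition & translation** — tile an allele into 84-bp units (exact
  handling of in-frame shortened units such as a 75-nt first finger),
  translate them, locate the DNA-contacting residues by anchoring on the
  C2H2 signature `C-x(2,4)-C-x(12)-H-x(3,5)-H`, and filter low-confidence
  repeats (pattern mode, or bit-score profiles with the strict >17.7 rule).
* **Weighted repeat-unit edit distance** — a global-alignment DP over unit
  sequences with the established costs
  `w_mut = 1` per nucleotide change, `w_indel = 3.5` per whole-unit
  insertion/deletion, and `w_slippage = 1.75` when the gained/lost unit is
  identical to an immediate neighbour (a tandem-duplication event):

  `d(A, B) = min over monotone edit scripts of
     Σ w_mut·Hamming(aᵢ, bⱼ) + Σ w_indel + Σ w_slippage`

  computed in full and with the 9 hypervariable contact-codon nucleotides of
  each unit masked out.
* **BIONJ phylogenies** — double-precision variance-weighted neighbor
  joining (exact on additive matrices), outgroup rooting at the pendant-edge
  midpoint, Newick/PHYLIP IO, Robinson–Foulds comparison.
* **Binding motifs** — per-finger 4×3 specificity matrices (pluggable
  predictor: external MEME/JASPAR matrices, your own function, or a built-in
  recognition-code fallback), reverse-complement assembly into a 4×3k array
  PWM, TomTom-style motif comparison with a permutation null, exact-DP
  p-value→score thresholds, two-strand genome scanning, BED output, and
  ≥1-bp interval-overlap quantification with base-pair Jaccard.
* **Simulator** — allele families evolved along Yule trees by substitution
  (10× hypermutable contact codons), tandem duplication and unit deletion,
  with a replayable event log; contact-only variant families; genomes with
  planted motif instances. Everything downstream is testable without any
  external data.
* **Utilities** — Bürker-chamber sperm-concentration conversion and the
  two-sided binomial transmission-ratio-distortion test (exact and normal).

## Worked example

```r
library(znfarray)

# simulate a family of 8 alleles with known history
fam <- simulate_allele_family(simulation_config(seed = 1))
lengths(fam$leaf_units)
#> allele_01 allele_02 allele_03 allele_04 allele_05 allele_06 allele_07 allele_08
#>        11        13        11        11        13        12        11        13

arrays <- lapply(names(fam$alleles), function(nm) znf_array(fam$alleles[[nm]], nm))
names(arrays) <- names(fam$alleles)
arrays$allele_01
#> znf_array 'allele_01': 11 unit(s), 7 kept
#>   unit lengths: 84 84 84 84 84 84 84 84 84 84 84
#>   contacts:     SNN --- SNK --- SNK --- SNK --- SNK SNK CNN
```

The contact triplets are the helix −1/+3/+6 residues of each finger; `---`
marks fingers whose C2H2 signature was destroyed (here by simulated
substitutions in the zinc-ligand codons), which pattern-mode filtering drops
(11 units, 7 kept).

```r
m <- distance_matrix(arrays, use_kept = FALSE)   # simulator units are all true repeats
round(m[1:4, 1:4], 2)
#>           allele_01 allele_02 allele_03 allele_04
#> allele_01      0.00     21.25        28        29
#> allele_02     21.25      0.00        32        33
#> allele_03     28.00     32.00         0         1
#> allele_04     29.00     33.00         1         0
```

`allele_03` and `allele_04` differ by a single substitution (distance 1);
the fractional distances are slippage events (multiples of 1.75) on top of
substitutions.

```r
tree <- bionj_tree(m)
normalized_rf(tree, fam$tree)     # recovery vs the true simulated tree
#> [1] 0.2

pwm <- assemble_array_pwm(arrays$allele_01)     # fallback recognition code
ncol(pwm)                                       # 3 columns per kept finger
#> [1] 21
score_threshold_from_pvalue(pwm, 1e-4)          # bits, exact tail DP
#> [1] 2.669
```

The two laboratory utilities:

```r
sperm_concentration(5, 5)    # paired 25-square counts -> million/ml
#> [1] 4
trd_binomial_test(10, 10)    # 10/10 transmissions, exact two-sided
#> [1] 0.001953125
```

An end-to-end run (`run_pipeline()`) takes a FASTA of alleles and writes the
allele table, full and contact-masked distance matrices (PHYLIP + TSV), both
rooted BIONJ trees (Newick), motif files (MEME + JASPAR), optional genome
scans (BED6) with overlap matrices, and a reproducibility manifest. A thin
command-line front end with the same stages as subcommands is installed at
`inst/cli/znfarray.R`.

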