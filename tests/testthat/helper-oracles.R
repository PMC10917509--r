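# Independent oracles and fixture builders, kept deliberately naive and
# separate from the package's implementation paths.

# codon map used to hand-build units in tests (same standard code, own copy)
.t_codons <- c(
  A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT", G = "GGT", H = "CAT",
  I = "ATT", K = "AAA", L = "CTG", M = "ATG", N = "AAT", P = "CCT", Q = "CAA",
  R = "CGT", S = "TCT", T = "ACT", V = "GTT", W = "TGG", Y = "TAT"
)

aa_to_nt <- function(aa) paste(.t_codons[strsplit(aa, "")[[1]]], collapse = "")

# canonical 28-mer used throughout the tests; contacts S/N/K at aa 12/16/19
canon_aa <- "TGEKCPECGKAFSQSSNLQKHQRTHTGE"

# canonical unit with the three contact residues replaced
unit_with_contacts <- function(contacts) {
  aa <- strsplit(canon_aa, "")[[1]]
  aa[c(13, 17, 20)] <- strsplit(contacts, "")[[1]]
  aa_to_nt(paste(aa, collapse = ""))
}

hamming_chr <- function(a, b) sum(charToRaw(a) != charToRaw(b))

# exhaustive minimum over all monotone edit scripts (no memoization; the
# recursion mirrors the problem statement, not the DP)
oracle_array_distance <- function(ua, ub, w = weight_scheme()) {
  gap_cost <- function(units, i) {
    n <- length(units)
    same <- function(j) {
      if (j < 1 || j > n) return(FALSE)
      d <- if (nchar(units[i]) == nchar(units[j])) hamming_chr(units[i], units[j])
           else as.integer(adist(units[i], units[j]))
      d <= w$slippage_max_mismatch
    }
    if (same(i - 1) || same(i + 1)) w$w_slippage else w$w_indel
  }
  da <- vapply(seq_along(ua), function(i) gap_cost(ua, i), 0)
  db <- vapply(seq_along(ub), function(j) gap_cost(ub, j), 0)
  subc <- function(a, b) {
    d <- if (nchar(a) == nchar(b)) hamming_chr(a, b) else as.integer(adist(a, b))
    w$w_mut * d
  }
  rec <- function(i, j) {
    if (i > length(ua) && j > length(ub)) return(0)
    best <- Inf
    if (i <= length(ua) && j <= length(ub))
      best <- min(best, subc(ua[i], ub[j]) + rec(i + 1, j + 1))
    if (i <= length(ua)) best <- min(best, da[i] + rec(i + 1, j))
    if (j <= length(ub)) best <- min(best, db[j] + rec(i, j + 1))
    best
  }
  rec(1, 1)
}

# random toy arrays over a 2-unit alphabet, <= 4 units each
random_toy_array <- function(alphabet = c("AAAAAA", "AACGTT")) {
  n <- sample(1:4, 1)
  sample(alphabet, n, replace = TRUE)
}

# all-pairs >=1 bp overlap count, quadratic on purpose
oracle_overlap_pairs <- function(a, b) {
  n <- 0L
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] == b$chrom[j] &&
        a$start[i] < b$end[j] && b$start[j] < a$end[i]) n <- n + 1L
  }
  n
}

random_hit_set <- function(n_max = 50, span = 500, chroms = c("c1", "c2")) {
  n <- sample(0:n_max, 1)
  if (n == 0) return(data.frame(chrom = character(0), start = integer(0),
                                end = integer(0), stringsAsFactors = FALSE))
  start <- sample.int(span, n, replace = TRUE) - 1L
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + sample(1:30, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# random tree with branch lengths >= 0.1 and its additive distance matrix
random_additive_case <- function(n) {
  tr <- ape::rtree(n, br = NULL)
  tr$edge.length <- runif(nrow(tr$edge), 0.1, 1)
  list(tree = tr, m = cophenetic(tr))
}

sim_arrays <- function(fam, ...) {
  arrays <- lapply(names(fam$alleles), function(nm) znf_array(fam$alleles[[nm]], nm, ...))
  names(arrays) <- names(fam$alleles)
  arrays
}
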