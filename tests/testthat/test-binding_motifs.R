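test_that("fallback finger prediction yields stochastic, deterministic columns", {
  f <- predict_finger_pfm("TDK")
  expect_equal(dim(f$pfm), c(4L, 3L))
  expect_equal(colSums(f$pfm), rep(1, 3), tolerance = 1e-9)
  expect_true(all(f$pfm >= 0))
  expect_identical(predict_finger_pfm("TDK"), f)
  expect_error(predict_finger_pfm("TBX"), "unknown residue")
})

test_that("external per-finger matrices pass through after a normalization check", {
  m <- matrix(c(0.7, 0.1, 0.1, 0.1,
                0.1, 0.7, 0.1, 0.1,
                0.1, 0.1, 0.7, 0.1), 4, 3)
  f <- predict_finger_pfm("AAA", predictor = m)
  expect_equal(unname(f$pfm), m)
  bad <- m; bad[1, 1] <- 0.9
  expect_error(predict_finger_pfm("AAA", predictor = bad), "sum to 1")
})

test_that("array PWM assembly reverse-complements the N-to-C concatenation", {
  # single finger whose subsite consensus is A,C,G (5'->3')
  m <- matrix(0.04, 4, 3, dimnames = list(c("A", "C", "G", "T"), NULL))
  m["A", 1] <- 0.88; m["C", 2] <- 0.88; m["G", 3] <- 0.88
  f <- predict_finger_pfm("AAA", predictor = m)
  pwm <- assemble_array_pwm(NULL, per_finger = list(f))
  expect_equal(ncol(pwm), 3L)
  expect_identical(pwm_consensus(pwm), "CGT")  # revcomp of "ACG"
  # k fingers -> width 3k
  a <- znf_array(strrep(znf_canonical_unit(), 4), "w")
  pwm4 <- assemble_array_pwm(a)
  expect_equal(ncol(pwm4), 12L)
  expect_equal(colSums(pwm4), rep(1, 12), tolerance = 1e-9)
  # reverse complement is an involution
  expect_equal(unname(unclass(revcomp_pwm(revcomp_pwm(pwm4)))),
               unname(unclass(pwm4)))
  expect_error(assemble_array_pwm(NULL, per_finger = list()), "empty")
})

test_that("motif self-comparison is optimal at offset 0 with minimal p", {
  a <- znf_array(paste0(unit_with_contacts("TDK"), unit_with_contacts("ASQ"),
                        unit_with_contacts("RNK"), znf_canonical_unit()), "self")
  pwm <- assemble_array_pwm(a)
  s <- compare_motifs(pwm, pwm, n_shuffles = 150, seed = 4)
  expect_equal(s$best_offset, 0L)
  expect_identical(s$best_orientation, "+")
  expect_equal(s$p_value, 1 / 151)
  expect_equal(s$neg_log10_p, -log10(1 / 151))
  # fixed seed -> identical p across runs
  expect_identical(compare_motifs(pwm, pwm, n_shuffles = 150, seed = 4)$p_value,
                   s$p_value)
  expect_error(compare_motifs(pwm, pwm, n_shuffles = 50), "at least 100")
})

test_that("motifs narrower than the minimum overlap yield the no-similarity marker", {
  m5 <- matrix(0.25, 4, 5, dimnames = list(c("A", "C", "G", "T"), NULL))
  p5 <- structure(m5, name = "w5", background = c(A = .25, C = .25, G = .25, T = .25),
                  class = c("array_pwm", "matrix", "array"))
  s <- compare_motifs(p5, p5, n_shuffles = 100, seed = 1, min_overlap = 6)
  expect_true(s$no_similarity)
  expect_true(is.na(s$p_value))
})

test_that("score thresholds follow the exact tail distribution", {
  a <- znf_array(strrep(znf_canonical_unit(), 3), "t")
  pwm <- assemble_array_pwm(a)
  # p = 1 admits every score, so the threshold is the minimum possible score
  lod <- log2(pmax(unclass(pwm), 1e-10) / 0.25)
  expect_equal(score_threshold_from_pvalue(pwm, 1), sum(apply(lod, 2, min)),
               tolerance = 2e-3)
  # a uniform PWM equal to background scores 0 everywhere
  u <- structure(matrix(0.25, 4, 8, dimnames = list(c("A", "C", "G", "T"), NULL)),
                 name = "u", background = c(A = .25, C = .25, G = .25, T = .25),
                 class = c("array_pwm", "matrix", "array"))
  expect_warning(thr <- score_threshold_from_pvalue(u, 1e-4), "maximum score")
  expect_equal(thr, 0)
})

test_that("threshold calibration matches empirical hit rates on background", {
  set.seed(8)
  m <- matrix(runif(48), 4, 12)
  m <- sweep(m, 2, colSums(m), "/")
  rownames(m) <- c("A", "C", "G", "T")
  pwm <- structure(m, name = "rand", background = c(A = .25, C = .25, G = .25, T = .25),
                   class = c("array_pwm", "matrix", "array"))
  bg <- c(A = .25, C = .25, G = .25, T = .25)
  gen <- setNames(paste(sample(c("A", "C", "G", "T"), 2e5, TRUE), collapse = ""), "c")
  p <- 1e-3
  thr <- score_threshold_from_pvalue(pwm, p, background = bg)
  hits <- scan_genome(pwm, gen, thr, background = bg)
  npos <- 2e5 - 12 + 1
  rate <- sum(hits$strand == "+") / npos
  expect_lt(abs(rate - p), 3 * sqrt(p * (1 - p) / npos))
})

test_that("planted sites are recovered on both strands at the max-score threshold", {
  a <- znf_array(paste0(unit_with_contacts("TDK"), unit_with_contacts("RNK"),
                        znf_canonical_unit()), "plant")
  pwm <- assemble_array_pwm(a)
  pg <- plant_motif_genome(list(plant = pwm), 30000, n_per_motif = 6, seed = 12)
  hits <- scan_genome(pwm, pg$genome, pwm_max_score(pwm, pg$background),
                      background = pg$background)
  expect_true(all(c("+", "-") %in% pg$truth$strand))  # seed gives both strands
  key <- function(df) paste(df$chrom, df$start, df$end, df$strand)
  expect_true(all(key(pg$truth) %in% key(hits)))
})

test_that("windows containing non-ACGT letters are skipped", {
  a <- znf_array(strrep(znf_canonical_unit(), 2), "n")
  pwm <- assemble_array_pwm(a)
  cons <- pwm_consensus(pwm)
  gen <- setNames(paste0(strrep("N", 10), cons, strrep("A", 10)), "c")
  hits <- scan_genome(pwm, gen, pwm_max_score(pwm), background = rep(0.25, 4))
  expect_equal(nrow(hits[hits$strand == "+", ]), 1L)
  expect_equal(hits$start[hits$strand == "+"], 10L)
  expect_error(scan_genome(pwm, setNames(character(0), character(0)), 0), "empty")
})

test_that("assembly orientation flips the strand on which a planted site scores", {
  a <- znf_array(paste0(unit_with_contacts("TDK"), unit_with_contacts("RNK"),
                        znf_canonical_unit()), "orient")
  pwm <- assemble_array_pwm(a)            # reverse-complement assembled
  fwd <- revcomp_pwm(pwm)                 # plain N->C concatenation
  cons <- pwm_consensus(pwm)
  gen <- setNames(paste0(strrep("A", 50), cons, strrep("A", 50)), "c")
  bg <- rep(0.25, 4)
  h1 <- scan_genome(pwm, gen, pwm_max_score(pwm), background = bg)
  h2 <- scan_genome(fwd, gen, pwm_max_score(fwd), background = bg)
  h1 <- h1[h1$start == 50, ]; h2 <- h2[h2$start == 50, ]
  expect_identical(h1$strand, "+")
  expect_identical(h2$strand, "-")        # same locus, opposite strand
})

test_that("hit intersection obeys the >=1 bp rule and matches brute force", {
  a <- data.frame(chrom = "c", start = 0L, end = 18L)
  b <- data.frame(chrom = "c", start = 17L, end = 35L)
  expect_equal(intersect_hits(a, b)$n_pairs, 1L)
  b2 <- data.frame(chrom = "c", start = 18L, end = 35L)
  expect_equal(intersect_hits(a, b2)$n_pairs, 0L)
  set.seed(13)
  for (i in 1:100) {
    x <- random_hit_set(); y <- random_hit_set()
    expect_equal(intersect_hits(x, y)$n_pairs, oracle_overlap_pairs(x, y),
                 info = paste("instance", i))
  }
})

test_that("identical hit sets give Jaccard 1; disjoint sets give 0", {
  a <- data.frame(chrom = "c", start = c(0L, 100L, 200L), end = c(10L, 110L, 210L))
  ov <- intersect_hits(a, a)
  expect_equal(ov$n_pairs, 3L)
  expect_equal(ov$jaccard, 1)
  b <- data.frame(chrom = "c", start = 500L, end = 510L)
  expect_equal(intersect_hits(a, b)$jaccard, 0)
})

test_that("overlap matrices are labelled, symmetric for Jaccard, zero for empty sets", {
  a <- data.frame(chrom = "c", start = c(0L, 50L), end = c(10L, 60L))
  b <- data.frame(chrom = "c", start = 5L, end = 15L)
  e <- data.frame(chrom = character(0), start = integer(0), end = integer(0))
  om <- overlap_matrix(list(a = a, b = b, empty = e))
  expect_equal(diag(om$jaccard), c(a = 1, b = 1, empty = 0))
  expect_equal(om$jaccard, t(om$jaccard))
  expect_true(all(om$counts[, "empty"] == 0) && all(om$counts["empty", ] == 0))
  set.seed(14)
  x <- random_hit_set(20); y <- random_hit_set(20)
  om2 <- overlap_matrix(list(x = x, y = y))
  expect_equal(om2$counts["x", "y"], om2$counts["y", "x"])  # equal widths not needed for these sizes
})

test_that("MEME and JASPAR motif files round-trip", {
  a1 <- znf_array(strrep(znf_canonical_unit(), 2), "m1")
  a2 <- znf_array(paste0(unit_with_contacts("TDK"), znf_canonical_unit()), "m2")
  pwms <- list(m1 = assemble_array_pwm(a1), m2 = assemble_array_pwm(a2))
  fm <- withr::local_tempfile(fileext = ".meme")
  fj <- withr::local_tempfile(fileext = ".jaspar")
  write_meme(pwms, fm); write_jaspar(pwms, fj)
  rm_ <- read_meme(fm); rj <- read_jaspar(fj)
  expect_identical(names(rm_), c("m1", "m2"))
  for (nm in names(pwms)) {
    expect_equal(unname(unclass(rm_[[nm]])), unname(unclass(pwms[[nm]])),
                 tolerance = 1e-5)
    expect_equal(unname(unclass(rj[[nm]])), unname(unclass(pwms[[nm]])),
                 tolerance = 1e-5)
  }
})

test_that("BED export uses 6 half-open 0-based columns and round-trips", {
  a <- znf_array(strrep(znf_canonical_unit(), 2), "bed")
  pwm <- assemble_array_pwm(a)
  pg <- plant_motif_genome(list(bed = pwm), 10000, n_per_motif = 3, seed = 9)
  hits <- scan_genome(pwm, pg$genome, pwm_max_score(pwm, pg$background),
                      background = pg$background)
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed(hits, f)
  cols <- strsplit(readLines(f)[1], "\t")[[1]]
  expect_length(cols, 6L)
  back <- read_bed(f)
  expect_equal(back$start, hits$start)
  expect_equal(back$end, hits$end)
  expect_equal(back$strand, hits$strand)
})
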