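.BASES <- c("A", "C", "G", "T")

# Simplified C2H2 recognition code: canonical residue -> base preferences for
# the position each contact residue reads. Residues without a documented
# preference fall through to a uniform column. Used only by the built-in
# fallback predictor; externally trained per-finger matrices override it.
.recognition_code <- list(
  R = c(G = 1),
  K = c(G = 0.5, T = 0.5),
  H = c(G = 1),
  N = c(A = 1),
  Q = c(A = 1),
  D = c(C = 1),
  E = c(C = 0.5, A = 0.5),
  S = c(G = 0.5, T = 0.5),
  T = c(A = 0.5, T = 0.5),
  V = c(A = 0.5, C = 0.5),
  L = c(T = 1),
  M = c(T = 1),
  W = c(T = 1),
  Y = c(T = 0.5, C = 0.5)
)

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Predict the 3-bp binding preference of one zinc finger
#'
#' The predictor is pluggable: supply a function mapping a 3-letter contact
#' string to a 4x3 column-stochastic matrix (e.g. wrapping an externally
#' trained specificity model), or a pre-computed 4x3 matrix (e.g. loaded with
#' [read_meme()]/[read_jaspar()]), which is checked for normalization and
#' returned verbatim. With `predictor = NULL` a deterministic built-in
#' recognition-code fallback is used: each contact residue independently sets
#' a base-preference column (pseudocount 0.01, uniform for residues without a
#' documented preference). Columns are ordered 5' to 3' of the finger's DNA
#' subsite, i.e. the residues at helix -1, +3 and +6 read the 3', middle and
#' 5' base respectively.
#'
#' @param contacts 3-letter upper-case amino-acid string (helix -1, +3, +6).
#' @param predictor `NULL`, a function, or a 4x3 numeric matrix.
#' @param pseudocount Smoothing mass added to every base in fallback mode.
#' @return A `finger_specificity` object: list with `contacts` and `pfm`
#'   (4x3 matrix, rows A,C,G,T, columns summing to 1).
#' @export
predict_finger_pfm <- function(contacts, predictor = NULL, pseudocount = 0.01) {
  stopifnot(is.character(contacts), length(contacts) == 1L, nchar(contacts) == 3L)
  res <- strsplit(toupper(contacts), "")[[1]]
  if (!all(res %in% .AA20))
    stop("unknown residue letter(s) in contacts '", contacts, "'")
  pfm <- if (is.function(predictor)) {
    predictor(contacts)
  } else if (is.matrix(predictor)) {
    predictor
  } else {
    # helix -1 reads the 3' base: reverse residue order across subsite columns
    vapply(rev(res), function(r) {
      w <- setNames(rep(pseudocount, 4L), .BASES)
      pref <- .recognition_code[[r]]
      if (!is.null(pref)) w[names(pref)] <- w[names(pref)] + pref
      else w[] <- w + 0.25
      w / sum(w)
    }, numeric(4L))
  }
  pfm <- as.matrix(pfm)
  if (!all(dim(pfm) == c(4L, 3L))) stop("per-finger PFM must be 4x3")
  if (any(pfm < 0) || any(abs(colSums(pfm) - 1) > 1e-6))
    stop("per-finger PFM columns must be non-negative and sum to 1")
  rownames(pfm) <- .BASES
  colnames(pfm) <- NULL
  structure(list(contacts = contacts, pfm = pfm), class = "finger_specificity")
}

#' Reverse-complement a position weight matrix
#'
#' Reverses column order and swaps the A/T and C/G rows; an involution.
#'
#' @param pwm 4 x w matrix with rows A,C,G,T.
#' @return The reverse-complemented matrix (attributes preserved).
#' @export
revcomp_pwm <- function(pwm) {
  out <- pwm[4:1, rev(seq_len(ncol(pwm))), drop = FALSE]
  rownames(out) <- .BASES
  attributes(out)[setdiff(names(attributes(pwm)), c("dim", "dimnames"))] <-
    attributes(pwm)[setdiff(names(attributes(pwm)), c("dim", "dimnames"))]
  out
}

#' Assemble an array-level PWM from per-finger specificities
#'
#' Concatenates the per-finger 3-column PFMs in N-to-C finger order and then
#' reverse-complements the concatenation, because the N-terminal finger of a
#' C2H2 array contacts the 3' end of the binding site. The result has width
#' 3k for k fingers.
#'
#' @param array A `znf_array`; fingers with unresolvable contacts (`"---"`)
#'   or excluded by the kept mask are skipped.
#' @param per_finger Optional list of `finger_specificity` objects (N-to-C)
#'   overriding prediction from the array's contacts.
#' @param predictor Passed to [predict_finger_pfm()] when predicting.
#' @param background Named base-frequency 4-vector (default uniform).
#' @return An `array_pwm`: 4 x 3k matrix with rows A,C,G,T and attributes
#'   `name`, `background`, `orientation = "revcomp"`.
#' @export
assemble_array_pwm <- function(array, per_finger = NULL, predictor = NULL,
                               background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  if (is.null(per_finger)) {
    stopifnot(inherits(array, "znf_array"))
    contacts <- array$contacts[array$kept & array$contacts != "---"]
    if (length(contacts) == 0L) stop("no fingers with resolvable contacts")
    per_finger <- lapply(contacts, predict_finger_pfm, predictor = predictor)
  }
  if (length(per_finger) == 0L) stop("empty finger list")
  mats <- lapply(per_finger, function(f) {
    if (inherits(f, "finger_specificity")) f$pfm else f
  })
  m <- do.call(cbind, mats)
  m <- m[4:1, rev(seq_len(ncol(m))), drop = FALSE]   # reverse complement
  rownames(m) <- .BASES
  structure(m,
            name = if (inherits(array, "znf_array")) array$name else attr(array, "name"),
            background = background, orientation = "revcomp",
            class = c("array_pwm", "matrix", "array"))
}

#' Consensus sequence of a PWM
#' @param pwm 4 x w matrix, rows A,C,G,T.
#' @return Character string of per-column argmax bases (ties to the
#'   alphabetically first base).
#' @export
pwm_consensus <- function(pwm) {
  paste(.BASES[apply(pwm, 2L, which.max)], collapse = "")
}

.pwm_lodds <- function(pwm, background = NULL) {
  bg <- background %||% attr(pwm, "background") %||% setNames(rep(0.25, 4L), .BASES)
  bg <- pmax(bg, 0.01); bg <- bg / sum(bg)
  log2(pmax(unclass(pwm), 1e-10) / bg)
}

#' Maximum attainable log-odds score of a PWM
#' @param pwm An `array_pwm` (or 4 x w matrix).
#' @param background Optional base-frequency vector overriding the PWM's own.
#' @return Score in bits.
#' @export
pwm_max_score <- function(pwm, background = NULL) {
  sum(apply(.pwm_lodds(pwm, background), 2L, max))
}

# Pearson column-correlation score for every admissible offset of t against q.
# Returns data.frame(offset, score); constant columns contribute 0.
.offset_scores <- function(q, t, min_overlap) {
  wq <- ncol(q); wt <- ncol(t)
  qc <- sweep(q, 2L, colMeans(q)); tc <- sweep(t, 2L, colMeans(t))
  nq <- sqrt(colSums(qc^2)); nt <- sqrt(colSums(tc^2))
  R <- crossprod(qc, tc)
  denom <- outer(nq, nt)
  R <- ifelse(denom > 0, R / denom, 0)
  offs <- (-(wt - 1L)):(wq - 1L)
  res <- lapply(offs, function(o) {
    j <- seq_len(wt)
    i <- o + j
    ok <- i >= 1L & i <= wq
    if (sum(ok) < min_overlap) return(NULL)
    data.frame(offset = o, score = sum(R[cbind(i[ok], j[ok])]))
  })
  do.call(rbind, res)
}

#' Compare two array PWMs with a permutation null
#'
#' Scores every relative column offset (with at least `min_overlap` aligned
#' columns) and both target orientations by the summed Pearson correlation of
#' aligned probability columns, then estimates a p-value against
#' `n_shuffles` column-shuffled targets. The p-value is the add-one-corrected
#' fraction of shuffled targets scoring strictly better than the observed
#' best, so its minimum is `1/(n_shuffles + 1)` (an empirical probability of
#' zero cannot be log-transformed). When no offset meets the minimum-overlap
#' rule the `no_similarity` marker is set.
#'
#' @param q,t Query and target `array_pwm` objects.
#' @param n_shuffles Number of column permutations (>= 100).
#' @param seed RNG seed for the permutations.
#' @param min_overlap Minimum aligned columns (default 6).
#' @return A `motif_similarity` list: `query`, `target`, `best_offset`,
#'   `best_orientation`, `score`, `p_value`, `neg_log10_p`, `no_similarity`.
#' @export
compare_motifs <- function(q, t, n_shuffles = 200L, seed = 1L, min_overlap = 6L) {
  if (n_shuffles < 100L) stop("n_shuffles must be at least 100")
  qm <- unclass(q); tm <- unclass(t)
  attributes(qm) <- attributes(qm)["dim"]; attributes(tm) <- attributes(tm)["dim"]
  best_of <- function(target) {
    parts <- list()
    fwd <- .offset_scores(qm, target, min_overlap)
    if (!is.null(fwd)) parts[[1L]] <- cbind(fwd, orientation = "+")
    rev <- .offset_scores(qm, revcomp_pwm(target), min_overlap)
    if (!is.null(rev)) parts[[length(parts) + 1L]] <- cbind(rev, orientation = "-")
    if (length(parts) == 0L) return(NULL)
    hits <- do.call(rbind, parts)
    hits[which.max(hits$score), , drop = FALSE]
  }
  obs <- best_of(tm)
  out <- list(query = attr(q, "name"), target = attr(t, "name"),
              best_offset = NA_integer_, best_orientation = NA_character_,
              score = NA_real_, p_value = NA_real_, neg_log10_p = NA_real_,
              no_similarity = TRUE)
  class(out) <- "motif_similarity"
  if (is.null(obs)) return(out)
  set.seed(seed)
  wt <- ncol(tm)
  exceed <- 0L
  for (s in seq_len(n_shuffles)) {
    sh <- best_of(tm[, sample.int(wt), drop = FALSE])
    if (!is.null(sh) && sh$score > obs$score) exceed <- exceed + 1L
  }
  p <- (1L + exceed) / (n_shuffles + 1L)
  out$best_offset <- obs$offset
  out$best_orientation <- obs$orientation
  out$score <- obs$score
  out$p_value <- p
  out$neg_log10_p <- -log10(p)
  out$no_similarity <- FALSE
  out
}

#' Log-odds score threshold for a target match p-value
#'
#' Computes the exact distribution of PWM log-odds scores under the
#' zero-order background model by dynamic programming over columns (scores
#' discretized to 1e-3 bits) and returns the smallest threshold whose tail
#' probability is at most `p`. If even the maximum score has tail
#' probability above `p`, the maximum score is returned with a warning.
#'
#' @param pwm An `array_pwm`.
#' @param p Target match probability, in (0, 1).
#' @param background Optional base-frequency vector overriding the PWM's own.
#' @return Threshold in bits.
#' @export
score_threshold_from_pvalue <- function(pwm, p, background = NULL) {
  stopifnot(p > 0, p <= 1)
  bg <- background %||% attr(pwm, "background") %||% setNames(rep(0.25, 4L), .BASES)
  bg <- pmax(bg, 0.01); bg <- bg / sum(bg)
  step <- 1e-3
  K <- round(.pwm_lodds(pwm, bg) / step)
  v <- 1; vmin <- 0L
  for (j in seq_len(ncol(K))) {
    kj <- K[, j]
    newmin <- vmin + min(kj)
    newlen <- length(v) + (max(kj) - min(kj))
    nv <- numeric(newlen)
    for (b in 1:4) {
      off <- kj[b] - min(kj)
      idx <- seq_along(v) + off
      nv[idx] <- nv[idx] + v * bg[b]
    }
    v <- nv; vmin <- newmin
  }
  tail_p <- rev(cumsum(rev(v)))
  i <- which(tail_p <= p)
  if (length(i) == 0L) {
    warning("requested p = ", p, " below the probability of the maximum score; ",
            "returning the maximum score")
    i <- max(which(v > 0))
  } else {
    i <- min(i)
  }
  (vmin + i - 1L) * step
}

#' Scan sequences for PWM matches above a score threshold
#'
#' Slides the PWM over both strands of every input sequence, scoring each
#' window by its log-odds against the background model. Windows containing
#' non-ACGT letters are skipped. Minus-strand hits are reported in forward
#' strand coordinates (0-based, half-open).
#'
#' @param pwm An `array_pwm`.
#' @param genome FASTA path, `Biostrings::DNAStringSet`, or named character
#'   vector of sequences.
#' @param threshold Minimum score in bits (e.g. from
#'   [score_threshold_from_pvalue()]).
#' @param background Optional base-frequency vector; default: estimated from
#'   the scanned sequence (zero-order, floored at 0.01 per base).
#' @return Data frame of hits: `chrom`, `start`, `end`, `strand`, `score`,
#'   `motif`, sorted by (chrom, start).
#' @export
scan_genome <- function(pwm, genome, threshold, background = NULL) {
  seqs <- .as_named_seqs(genome)
  if (length(seqs) == 0L) stop("empty FASTA / sequence set")
  w <- ncol(pwm)
  if (is.null(background)) {
    cnt <- setNames(numeric(4L), .BASES)
    for (s in seqs) {
      tb <- table(factor(strsplit(s, "")[[1]], levels = .BASES))
      cnt <- cnt + as.numeric(tb)
    }
    background <- pmax(cnt / max(sum(cnt), 1), 0.01)
    background <- background / sum(background)
  }
  lod_f <- .pwm_lodds(pwm, background)
  lod_r <- lod_f[4:1, rev(seq_len(w)), drop = FALSE]
  hits <- list()
  for (nm in names(seqs)) {
    v <- match(strsplit(toupper(seqs[[nm]]), "")[[1]], .BASES)
    Lp <- length(v) - w + 1L
    if (Lp < 1L) next
    for (strand in c("+", "-")) {
      lod <- if (strand == "+") lod_f else lod_r
      sc <- numeric(Lp)
      for (j in seq_len(w)) sc <- sc + lod[cbind(v[j:(j + Lp - 1L)], j)]
      # 1e-9-bit tolerance absorbs accumulation-order rounding; negligible
      # against the 1e-3-bit threshold grid
      keep <- which(!is.na(sc) & sc >= threshold - 1e-9)
      if (length(keep))
        hits[[length(hits) + 1L]] <- data.frame(
          chrom = nm, start = keep - 1L, end = keep - 1L + w,
          strand = strand, score = sc[keep],
          motif = attr(pwm, "name") %||% "pwm",
          stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0L)
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      strand = character(0), score = numeric(0),
                      motif = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  out <- out[order(out$chrom, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.as_named_seqs <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    set <- Biostrings::readDNAStringSet(genome)
    seqs <- as.list(toupper(as.character(set)))
    names(seqs) <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1L)
    seqs
  } else if (inherits(genome, "DNAStringSet")) {
    seqs <- as.list(as.character(genome))
    names(seqs) <- vapply(strsplit(names(genome), "\\s+"), `[`, "", 1L)
    seqs
  } else if (is.character(genome)) {
    if (is.null(names(genome))) stop("character genome input must be named")
    as.list(genome)
  } else stop("unsupported genome input")
}

#' Count overlapping hit pairs and base-pair Jaccard of two hit sets
#'
#' A pair is incident when two hits share at least 1 bp on the same
#' chromosome, regardless of strand. The Jaccard index is computed on merged
#' base-pair coverage.
#'
#' @param a,b Hit data frames as produced by [scan_genome()] (need columns
#'   `chrom`, `start`, `end`).
#' @return List with `n_pairs` and `jaccard`.
#' @export
intersect_hits <- function(a, b) {
  chroms_a <- unique(a$chrom); chroms_b <- unique(b$chrom)
  n_pairs <- 0L
  inter_bp <- 0; union_bp <- 0
  ir <- function(df) IRanges::IRanges(start = df$start + 1L, end = df$end)
  for (ch in union(chroms_a, chroms_b)) {
    ra <- ir(a[a$chrom == ch, , drop = FALSE])
    rb <- ir(b[b$chrom == ch, , drop = FALSE])
    n_pairs <- n_pairs + length(IRanges::findOverlaps(ra, rb, minoverlap = 1L))
    ma <- IRanges::reduce(ra); mb <- IRanges::reduce(rb)
    inter_bp <- inter_bp + sum(IRanges::width(IRanges::intersect(ma, mb)))
    union_bp <- union_bp + sum(IRanges::width(IRanges::reduce(c(ma, mb))))
  }
  list(n_pairs = n_pairs,
       jaccard = if (union_bp > 0) inter_bp / union_bp else 0)
}

#' Pairwise overlap matrices for a batch of hit sets
#'
#' @param hit_sets Named list of hit data frames.
#' @return List of two labelled matrices: `counts` (incident pairs) and
#'   `jaccard`.
#' @export
overlap_matrix <- function(hit_sets) {
  stopifnot(length(hit_sets) >= 2L, !is.null(names(hit_sets)))
  n <- length(hit_sets); nms <- names(hit_sets)
  counts <- matrix(0, n, n, dimnames = list(nms, nms))
  jacc <- matrix(0, n, n, dimnames = list(nms, nms))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      ov <- intersect_hits(hit_sets[[i]], hit_sets[[j]])
      counts[i, j] <- ov$n_pairs
      jacc[i, j] <- ov$jaccard
    }
  }
  list(counts = counts, jaccard = jacc)
}

#' Write genome-scan hits as BED6
#'
#' Columns: chrom, start, end, name (motif label), score (bits x 100,
#' rounded), strand; coordinates 0-based, half-open.
#'
#' @param hits Hit data frame from [scan_genome()].
#' @param path Output path.
#' @export
write_bed <- function(hits, path) {
  df <- data.frame(hits$chrom, hits$start, hits$end, hits$motif,
                   round(hits$score * 100), hits$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file of hits
#' @param path BED6 path written by [write_bed()].
#' @return Hit data frame (`score` back in bits).
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  data.frame(chrom = df[[1]], start = df[[2]], end = df[[3]],
             strand = df[[6]], score = df[[5]] / 100, motif = df[[4]],
             stringsAsFactors = FALSE)
}

#' Write PWMs in minimal MEME motif format
#' @param pwms Named list of `array_pwm` objects (or 4 x w matrices).
#' @param path Output path.
#' @param background Base frequencies recorded in the header.
#' @export
write_meme <- function(pwms, path, background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "",
               "Background letter frequencies",
               paste(sprintf("%s %.5f", .BASES, background), collapse = " "), ""), con)
  for (nm in names(pwms)) {
    m <- unclass(pwms[[nm]])
    writeLines(sprintf("MOTIF %s", nm), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                       ncol(m)), con)
    for (j in seq_len(ncol(m)))
      writeLines(paste(sprintf("%.6f", m[, j]), collapse = " "), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read PWMs from minimal MEME motif format
#' @param path MEME-format path.
#' @return Named list of `array_pwm` objects.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  idx <- grep("^MOTIF\\s+", lines)
  out <- list()
  for (i in idx) {
    nm <- sub("^MOTIF\\s+(\\S+).*$", "\\1", lines[i])
    hdr <- i + 1L
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr]))
    rows <- lines[(hdr + 1L):(hdr + w)]
    m <- t(vapply(strsplit(trimws(rows), "\\s+"),
                  function(r) as.numeric(r), numeric(4L)))
    m <- t(m)  # back to 4 x w
    rownames(m) <- .BASES
    out[[nm]] <- structure(m, name = nm,
                           background = setNames(rep(0.25, 4L), .BASES),
                           orientation = "revcomp",
                           class = c("array_pwm", "matrix", "array"))
  }
  out
}

#' Write PWMs in JASPAR text format
#' @param pwms Named list of `array_pwm` objects.
#' @param path Output path.
#' @export
write_jaspar <- function(pwms, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (nm in names(pwms)) {
    m <- unclass(pwms[[nm]])
    writeLines(sprintf(">%s", nm), con)
    for (b in seq_len(4L))
      writeLines(sprintf("%s [ %s ]", .BASES[b],
                         paste(sprintf("%.6f", m[b, ]), collapse = " ")), con)
  }
  invisible(path)
}

#' Read PWMs from JASPAR text format (columns renormalized to probabilities)
#' @param path JASPAR-format path.
#' @return Named list of `array_pwm` objects.
#' @export
read_jaspar <- function(path) {
  lines <- readLines(path)
  idx <- grep("^>", lines)
  out <- list()
  for (k in seq_along(idx)) {
    nm <- sub("^>\\s*(\\S+).*$", "\\1", lines[idx[k]])
    rows <- lines[idx[k] + 1:4]
    vals <- lapply(rows, function(r) {
      as.numeric(strsplit(trimws(gsub("^[ACGT]\\s*\\[|\\]\\s*$", "", r)), "\\s+")[[1]])
    })
    m <- do.call(rbind, vals)
    rownames(m) <- .BASES
    m <- sweep(m, 2L, colSums(m), "/")
    out[[nm]] <- structure(m, name = nm,
                           background = setNames(rep(0.25, 4L), .BASES),
                           orientation = "revcomp",
                           class = c("array_pwm", "matrix", "array"))
  }
  out
}
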