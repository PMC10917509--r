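#' Edit-cost weighting scheme for repeat-array distances
#'
#' The three event costs of the weighted minimum edit distance between
#' repeat-unit arrays: `w_mut` per nucleotide change within a unit (default
#' 1), `w_indel` per whole-unit insertion or deletion (default 3.5), and
#' `w_slippage` per tandem-duplication/slippage event, i.e. gain or loss of a
#' unit identical to an adjacent unit (default 1.75). `slippage_max_mismatch`
#' relaxes the identity requirement for the slippage discount to at most that
#' many nucleotide differences (default 0: exact match).
#'
#' @param w_mut,w_indel,w_slippage Positive event costs.
#' @param slippage_max_mismatch Non-negative integer.
#' @return A `weight_scheme` object.
#' @export
weight_scheme <- function(w_mut = 1, w_indel = 3.5, w_slippage = 1.75,
                          slippage_max_mismatch = 0L) {
  stopifnot(w_mut > 0, w_indel > 0, w_slippage > 0, slippage_max_mismatch >= 0)
  if (w_slippage > w_indel)
    stop("w_slippage must not exceed w_indel (slippage is the discounted event)")
  structure(list(w_mut = w_mut, w_indel = w_indel, w_slippage = w_slippage,
                 slippage_max_mismatch = as.integer(slippage_max_mismatch)),
            class = "weight_scheme")
}

# masked nucleotide strings for an array's kept units: contact codons removed
# per unit via resolve_contact_positions; units whose C2H2 pattern cannot be
# resolved are left unmasked.
.unit_strings <- function(x, mask = c("none", "contacts"), use_kept = TRUE) {
  mask <- match.arg(mask)
  if (is.character(x)) {                      # plain unit vector (toy/test use)
    units <- x
    aa <- NULL
  } else {
    stopifnot(inherits(x, "znf_array"))
    keep <- if (use_kept) x$kept else rep(TRUE, nrow(x$units))
    units <- x$units$nt[keep]
    aa <- x$units$aa[keep]
  }
  if (length(units) == 0L) stop("array has no kept units")
  if (mask == "contacts") {
    if (is.null(aa)) stop("contacts mask requires a znf_array (translated units)")
    units <- mapply(function(nt, a) {
      pos <- tryCatch(resolve_contact_positions(a), error = function(e) NULL)
      if (is.null(pos)) return(nt)
      paste(strsplit(nt, "")[[1]][-(pos$nt_idx + 1L)], collapse = "")
    }, units, aa, USE.NAMES = FALSE)
  }
  units
}

#' Nucleotide cost of substituting one repeat unit for another
#'
#' Hamming distance when the (possibly masked) units have equal length,
#' nucleotide-level Levenshtein distance otherwise (unequal lengths arise from
#' in-frame deletions such as a 75-nt first unit), multiplied by `w_mut`.
#'
#' @param a,b Unit nucleotide strings.
#' @param weights A [weight_scheme()].
#' @return Non-negative cost.
#' @export
unit_cost <- function(a, b, weights = weight_scheme()) {
  d <- if (nchar(a) == nchar(b)) .hamming(a, b) else as.integer(utils::adist(a, b))
  weights$w_mut * d
}

# per-unit deletion/insertion cost in its own array: slippage discount when
# the unit equals (within slippage_max_mismatch) its immediate left or right
# neighbour; identity is judged on unmasked sequence.
.gap_costs <- function(units, weights) {
  n <- length(units)
  vapply(seq_len(n), function(i) {
    near <- function(j) {
      if (j < 1L || j > n) return(FALSE)
      if (nchar(units[i]) != nchar(units[j]))
        return(as.integer(utils::adist(units[i], units[j])) <= weights$slippage_max_mismatch)
      .hamming(units[i], units[j]) <= weights$slippage_max_mismatch
    }
    if (near(i - 1L) || near(i + 1L)) weights$w_slippage else weights$w_indel
  }, 0)
}

#' Weighted minimum edit distance between two repeat-unit arrays
#'
#' Global alignment dynamic programme over the unit sequences of two alleles.
#' Substituting unit for unit costs [unit_cost()]; deleting a unit from the
#' first array (or inserting one from the second) costs `w_slippage` when that
#' unit is identical to an immediate neighbour in its own array (a tandem
#' duplication/slippage event) and `w_indel` otherwise. The slippage discount
#' being owner-relative keeps the distance symmetric.
#'
#' @param A,B `znf_array` objects, or plain character vectors of unit strings.
#' @param weights A [weight_scheme()].
#' @param mask `"none"` or `"contacts"` (drop the 9 contact-codon nucleotides
#'   of each unit before comparison; slippage identity stays unmasked).
#' @param use_kept Use only confidence-filtered units of a `znf_array`.
#' @return Non-negative distance.
#' @export
#' @examples
#' u <- znf_canonical_unit()
#' array_distance(c(u, u), c(u, u, u))  # one tandem duplication: 1.75
array_distance <- function(A, B, weights = weight_scheme(),
                           mask = c("none", "contacts"), use_kept = TRUE) {
  mask <- match.arg(mask)
  ua_raw <- .unit_strings(A, "none", use_kept)
  ub_raw <- .unit_strings(B, "none", use_kept)
  ua <- .unit_strings(A, mask, use_kept)
  ub <- .unit_strings(B, mask, use_kept)
  del_a <- .gap_costs(ua_raw, weights)
  ins_b <- .gap_costs(ub_raw, weights)
  n <- length(ua); m <- length(ub)
  D <- matrix(0, n + 1L, m + 1L)
  D[, 1L] <- c(0, cumsum(del_a))
  D[1L, ] <- c(0, cumsum(ins_b))
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      D[i + 1L, j + 1L] <- min(
        D[i, j] + unit_cost(ua[i], ub[j], weights),
        D[i, j + 1L] + del_a[i],
        D[i + 1L, j] + ins_b[j]
      )
    }
  }
  D[n + 1L, m + 1L]
}

#' Pairwise distance matrix over a set of alleles
#'
#' @param arrays Named list of `znf_array` objects (or character vectors of
#'   unit strings); names must be unique. At least 3 arrays.
#' @param weights A [weight_scheme()].
#' @param mask `"none"` or `"contacts"`.
#' @param use_kept Use only confidence-filtered units.
#' @return Symmetric numeric matrix with zero diagonal, labelled by allele
#'   name, with the mask recorded in the `"mask"` attribute.
#' @export
distance_matrix <- function(arrays, weights = weight_scheme(),
                            mask = c("none", "contacts"), use_kept = TRUE) {
  mask <- match.arg(mask)
  nms <- names(arrays)
  if (is.null(nms))
    nms <- vapply(arrays, function(a) if (inherits(a, "znf_array")) a$name else NA_character_, "")
  if (anyNA(nms)) stop("arrays must be named")
  if (length(arrays) < 3L) stop("need at least 3 arrays for a distance matrix")
  if (anyDuplicated(nms)) stop("duplicate allele names: ",
                               paste(unique(nms[duplicated(nms)]), collapse = ", "))
  n <- length(arrays)
  m <- matrix(0, n, n, dimnames = list(nms, nms))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- array_distance(arrays[[i]], arrays[[j]], weights, mask, use_kept)
      m[i, j] <- d
      m[j, i] <- d
    }
  }
  attr(m, "mask") <- mask
  m
}

#' Write a distance matrix in square PHYLIP format
#'
#' Six decimal places; labels are sanitized by replacing whitespace with
#' underscores (with a warning).
#'
#' @param m Labelled symmetric matrix.
#' @param path Output path.
#' @export
write_phylip <- function(m, path) {
  labs <- rownames(m)
  stopifnot(!is.null(labs), all(nchar(labs) <= 250L))
  if (any(grepl("\\s", labs))) {
    warning("whitespace in label(s) replaced by '_'")
    labs <- gsub("\\s+", "_", labs)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(m)), con)
  for (i in seq_len(nrow(m))) {
    writeLines(paste(formatC(labs[i], width = -12),
                     paste(sprintf("%.6f", m[i, ]), collapse = "  ")), con)
  }
  invisible(path)
}

#' Read a square PHYLIP distance matrix
#' @param path Input path.
#' @return Labelled symmetric matrix.
#' @export
read_phylip <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  rows <- strsplit(trimws(lines[1 + seq_len(n)]), "\\s+")
  labs <- vapply(rows, `[`, "", 1L)
  m <- t(vapply(rows, function(r) as.numeric(r[-1L]), numeric(n)))
  dimnames(m) <- list(labs, labs)
  m
}

#' Write a distance matrix as long-format TSV
#' @param m Labelled symmetric matrix (with a `"mask"` attribute, optional).
#' @param path Output path.
#' @export
write_distance_tsv <- function(m, path) {
  labs <- rownames(m)
  idx <- which(upper.tri(m), arr.ind = TRUE)
  df <- data.frame(
    allele_i = labs[idx[, 1L]],
    allele_j = labs[idx[, 2L]],
    distance = m[idx],
    mask_mode = attr(m, "mask") %||% "none",
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
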