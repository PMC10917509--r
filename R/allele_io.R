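# One codon per residue, used to back-translate the canonical unit.
.codon_table <- c(
  A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT", G = "GGT", H = "CAT",
  I = "ATT", K = "AAA", L = "CTG", M = "ATG", N = "AAT", P = "CCT", Q = "CAA",
  R = "CGT", S = "TCT", T = "ACT", V = "GTT", W = "TGG", Y = "TAT"
)

# 28-residue canonical C2H2 finger: C4..C7 ligands, recognition helix anchored
# by the first His at aa index 20 (0-based), second His at 24.
.canonical_aa <- "TGEKCPECGKAFSQSSNLQKHQRTHTGE"

# C2H2 signature used for pattern-mode confidence filtering and contact anchoring
.c2h2_pattern <- "C(.{2,4})C(.{12})H(.{3,5})H"

#' Canonical 84-bp zinc-finger repeat unit
#'
#' Returns the nucleotide sequence of the canonical C2H2 repeat unit used as
#' the ancestral state by the simulator and in examples. It encodes a
#' 28-residue finger with the two zinc-coordinating cysteines at amino-acid
#' indices 4 and 7 and histidines at 20 and 24 (0-based), so the
#' recognition-helix contact residues (-1, +3, +6) sit at amino-acid indices
#' 12, 16 and 19.
#'
#' @return An 84-character DNA string.
#' @export
#' @examples
#' nchar(znf_canonical_unit())
znf_canonical_unit <- function() {
  paste(.codon_table[strsplit(.canonical_aa, "")[[1]]], collapse = "")
}

#' Read minisatellite alleles from a FASTA file
#'
#' Reads a multi-record FASTA of nucleotide alleles. Sequences are upper-cased
#' and validated against the strict ACGT alphabet; IUPAC ambiguity codes are
#' rejected because the alleles these tools target are assembled, cloned
#' Sanger products with no residual ambiguity.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of DNA sequences, one per record, in file
#'   order, with the file path stored in the `"source"` attribute.
#' @export
read_allele_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    warning("empty FASTA file: ", path)
    out <- character(0)
    attr(out, "source") <- path
    return(out)
  }
  nms <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1L)
  dup <- nms[duplicated(nms)]
  if (length(dup)) stop("duplicate FASTA header(s): ", paste(unique(dup), collapse = ", "))
  seqs <- toupper(as.character(set))
  for (i in seq_along(seqs)) {
    bad <- regexpr("[^ACGT]", seqs[[i]])
    if (bad > 0L) {
      stop("non-ACGT character '", substr(seqs[[i]], bad, bad), "' in record '",
           nms[[i]], "' at position ", bad, " (ambiguity codes are rejected)")
    }
  }
  names(seqs) <- nms
  attr(seqs, "source") <- path
  seqs
}

#' Decompose an allele into minisatellite repeat units
#'
#' Tiles a nucleotide allele left to right into repeat units of canonical
#' length (84 bp). When the sequence length is not a multiple of the unit
#' length, segmentations containing shortened units (unit length minus an
#' allowed in-frame deletion) are enumerated and scored by the total
#' nucleotide edit distance of every unit to the consensus of the full-length
#' units in that segmentation; the best-scoring segmentation wins and ties go
#' to the segmentation whose shortened units are leftmost. This matches the
#' one non-canonical unit seen in practice: a first finger carrying a 9-nt
#' in-frame deletion.
#'
#' @param sequence DNA string (ACGT).
#' @param unit_len Canonical repeat-unit length in nucleotides (default 84).
#' @param allowed_deletion_nt Integer vector of in-frame deletion sizes
#'   (multiples of 3) that shortened units may carry; default 9.
#' @return A data frame with one row per unit: `index` (0-based), `nt`
#'   (unit sequence), `complete` (`TRUE` for full-length units), `aa`
#'   (`NA` until [translate_units()] is applied).
#' @export
decompose_minisatellite <- function(sequence, unit_len = 84L,
                                    allowed_deletion_nt = 9L) {
  stopifnot(is.character(sequence), length(sequence) == 1L, unit_len > 0L)
  if (length(allowed_deletion_nt) && any(allowed_deletion_nt %% 3L != 0L))
    stop("allowed_deletion_nt must be multiples of 3 (in-frame deletions)")
  L <- nchar(sequence)
  if (L < unit_len - max(c(allowed_deletion_nt, 0L)))
    stop("sequence of length ", L, " is shorter than one repeat unit")

  if (L %% unit_len == 0L) {
    starts <- seq(1L, L, by = unit_len)
    units <- substring(sequence, starts, starts + unit_len - 1L)
    return(.units_df(units, unit_len))
  }

  short_lens <- unique(unit_len - allowed_deletion_nt)
  short_lens <- short_lens[short_lens > 0L]
  combos <- .length_compositions(L, unit_len, short_lens, cap = 20000L)
  if (length(combos) == 0L)
    stop("no valid segmentation of sequence length ", L,
         " into units of length {", paste(c(unit_len, short_lens), collapse = ","),
         "}; remainder modulo ", unit_len, " is ", L %% unit_len)

  best <- NULL; best_score <- Inf; best_key <- NULL
  for (lens in combos) {
    ends <- cumsum(lens)
    units <- substring(sequence, c(1L, head(ends, -1L) + 1L), ends)
    full <- units[lens == unit_len]
    score <- if (length(full) == 0L) {
      Inf
    } else {
      cons <- .consensus(full)
      sum(vapply(units, function(u) {
        if (nchar(u) == nchar(cons)) .hamming(u, cons)
        else as.integer(utils::adist(u, cons))
      }, 0))
    }
    key <- which(lens != unit_len)  # short-unit positions; leftmost wins ties
    if (score < best_score ||
        (score == best_score && .lex_less(key, best_key))) {
      best <- lens; best_score <- score; best_key <- key
    }
  }
  ends <- cumsum(best)
  units <- substring(sequence, c(1L, head(ends, -1L) + 1L), ends)
  .units_df(units, unit_len)
}

.units_df <- function(units, unit_len) {
  data.frame(
    index = seq_along(units) - 1L,
    nt = units,
    complete = nchar(units) == unit_len,
    aa = NA_character_,
    stringsAsFactors = FALSE
  )
}

# all orderings of unit lengths summing to total; bounded enumeration
.length_compositions <- function(total, unit_len, short_lens, cap = 20000L) {
  out <- list()
  recurse <- function(remaining, acc) {
    if (length(out) > cap) stop("segmentation too ambiguous (> ", cap, " candidates)")
    if (remaining == 0L) { out[[length(out) + 1L]] <<- acc; return(invisible()) }
    for (l in c(unit_len, short_lens)) {
      if (l <= remaining) recurse(remaining - l, c(acc, l))
    }
  }
  recurse(total, integer(0))
  out
}

.consensus <- function(units) {
  m <- do.call(rbind, strsplit(units, ""))
  paste(apply(m, 2L, function(col) {
    tb <- table(factor(col, levels = c("A", "C", "G", "T")))
    names(tb)[which.max(tb)]  # ties resolved alphabetically (factor order)
  }), collapse = "")
}

.hamming <- function(a, b) sum(charToRaw(a) != charToRaw(b))

.lex_less <- function(a, b) {
  if (is.null(b)) return(TRUE)
  n <- min(length(a), length(b))
  if (n > 0L) for (i in seq_len(n)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  length(a) < length(b)
}

#' Conceptually translate repeat units into zinc-finger peptides
#'
#' Translates each unit in frame 0 with the standard genetic code. Units with
#' an internal stop codon are flagged `complete = FALSE` and their translation
#' is truncated at the stop, with a warning (not an error: such units can
#' still be carried through decomposition round trips).
#'
#' @param units Data frame from [decompose_minisatellite()].
#' @return The same data frame with the `aa` column populated.
#' @export
translate_units <- function(units) {
  stopifnot(is.data.frame(units), all(c("nt", "complete") %in% names(units)))
  if (any(nchar(units$nt) %% 3L != 0L))
    stop("unit length not divisible by 3; cannot translate in frame 0")
  aa <- as.character(Biostrings::translate(Biostrings::DNAStringSet(units$nt),
                                           no.init.codon = TRUE))
  names(aa) <- NULL
  stops <- regexpr("*", aa, fixed = TRUE)
  hit <- stops > 0L
  if (any(hit)) {
    warning("in-frame stop codon in unit(s) ",
            paste(units$index[hit], collapse = ", "),
            "; translation truncated and unit flagged incomplete")
    aa[hit] <- substr(aa[hit], 1L, stops[hit] - 1L)
    units$complete[hit] <- FALSE
  }
  units$aa <- aa
  units
}

#' Resolve DNA-contacting positions within a zinc-finger unit
#'
#' Locates the C2H2 signature `C-x(2,4)-C-x(12)-H-x(3,5)-H` in the translated
#' unit and anchors recognition-helix numbering at the first zinc-coordinating
#' histidine, which occupies helix position +7. Helix offset `p` then maps to
#' amino-acid index `h1 - 7 + p` (0-based). The default offsets (-1, +3, +6)
#' are the residues contacting the 3-bp DNA subsite; alternative or extended
#' offset sets (e.g. adding -5, -2, +1) are accepted.
#'
#' @param aa Translated unit peptide (single string).
#' @param helix_offsets Ordered integer helix offsets; default `c(-1, 3, 6)`.
#' @return A list with `helix_offsets`, `aa_idx` (0-based amino-acid indices)
#'   and `nt_idx` (0-based indices of the corresponding codon nucleotides,
#'   grouped in consecutive triples).
#' @export
resolve_contact_positions <- function(aa, helix_offsets = c(-1L, 3L, 6L)) {
  stopifnot(is.character(aa), length(aa) == 1L)
  m <- regexec(.c2h2_pattern, aa)[[1]]
  if (m[1] == -1L)
    stop("C2H2 pattern not found in unit peptide '", aa, "'")
  # capture 2 is the x(12) spacer; the His anchor follows it
  h1 <- (m[3] - 1L) + 12L                      # 0-based index of first His
  aa_idx <- h1 - 7L + as.integer(helix_offsets)
  if (any(aa_idx < 0L) || any(aa_idx >= nchar(aa)))
    stop("helix offset maps outside the unit (peptide length ", nchar(aa), ")")
  nt_idx <- as.integer(t(outer(3L * aa_idx, 0:2, "+")))
  list(helix_offsets = as.integer(helix_offsets), aa_idx = aa_idx, nt_idx = nt_idx)
}

#' Extract per-finger DNA-contact residue triplets
#'
#' @param array A `znf_array` object (see [znf_array()]).
#' @param helix_offsets Helix offsets passed to [resolve_contact_positions()].
#' @return Character vector of upper-case 3-letter contact strings, one per
#'   unit in array order; units where the C2H2 pattern cannot be resolved
#'   yield the placeholder `"---"`.
#' @export
extract_contacts <- function(array, helix_offsets = c(-1L, 3L, 6L)) {
  stopifnot(inherits(array, "znf_array"))
  vapply(array$units$aa, function(aa) {
    pos <- tryCatch(resolve_contact_positions(aa, helix_offsets),
                    error = function(e) NULL)
    if (is.null(pos)) return("---")
    toupper(paste(substring(aa, pos$aa_idx + 1L, pos$aa_idx + 1L), collapse = ""))
  }, "", USE.NAMES = FALSE)
}

#' Confidence model for zinc-finger repeat filtering
#'
#' In `pattern` mode a unit is kept when its peptide matches the C2H2
#' signature. In `profile` mode a position-specific scoring table (in bits)
#' is summed over the unit's residues and the unit is kept only when the
#' score is strictly above `threshold_bits` (default 17.7, the gathering
#' threshold conventionally used for this finger model).
#'
#' @param mode `"pattern"` (default) or `"profile"`.
#' @param threshold_bits Bit-score threshold for profile mode.
#' @param profile Numeric matrix of per-position, per-residue bit scores
#'   (rows = positions 1..28, columns named by amino-acid letters).
#' @return A `confidence_model` object.
#' @export
confidence_model <- function(mode = c("pattern", "profile"),
                             threshold_bits = 17.7, profile = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.finite(threshold_bits))
  if (mode == "profile" && is.null(profile))
    stop("profile mode requires a position-specific scoring table")
  structure(list(mode = mode, threshold_bits = threshold_bits, profile = profile),
            class = "confidence_model")
}

.profile_score <- function(aa, profile) {
  res <- strsplit(aa, "")[[1]]
  n <- min(length(res), nrow(profile))
  s <- 0
  for (i in seq_len(n)) {
    j <- match(res[i], colnames(profile))
    if (!is.na(j)) s <- s + profile[i, j]
  }
  s
}

#' Filter low-confidence repeats in a zinc-finger array
#'
#' Sets the array's `kept` mask according to a [confidence_model()]. Kept
#' units are the ones downstream distance and motif computations consume by
#' default.
#'
#' @param array A `znf_array`.
#' @param model A [confidence_model()].
#' @return The array with its `kept` mask updated.
#' @export
filter_repeats <- function(array, model = confidence_model()) {
  stopifnot(inherits(array, "znf_array"), inherits(model, "confidence_model"))
  if (any(is.na(array$units$aa))) stop("units must be translated before filtering")
  array$kept <- if (model$mode == "pattern") {
    grepl(.c2h2_pattern, array$units$aa)
  } else {
    vapply(array$units$aa, .profile_score, 0, profile = model$profile,
           USE.NAMES = FALSE) > model$threshold_bits
  }
  array
}

#' Build a zinc-finger array object from a nucleotide allele
#'
#' Runs decomposition, translation, contact extraction and confidence
#' filtering in one step, producing the central container consumed by the
#' distance, phylogeny and motif modules.
#'
#' @param sequence Allele DNA string (ACGT).
#' @param name Allele label.
#' @param unit_len,allowed_deletion_nt Passed to [decompose_minisatellite()].
#' @param model A [confidence_model()]; default pattern mode.
#' @param helix_offsets Contact helix offsets.
#' @return A `znf_array` object: list with `name`, `sequence`, `units`
#'   (data frame), `contacts` (3-letter strings) and `kept` (logical mask).
#' @export
#' @examples
#' a <- znf_array(strrep(znf_canonical_unit(), 3), "toy")
#' a$contacts
znf_array <- function(sequence, name, unit_len = 84L, allowed_deletion_nt = 9L,
                      model = confidence_model(), helix_offsets = c(-1L, 3L, 6L)) {
  units <- decompose_minisatellite(sequence, unit_len, allowed_deletion_nt)
  units <- translate_units(units)
  obj <- structure(
    list(name = name, sequence = sequence, units = units,
         contacts = NULL, kept = rep(TRUE, nrow(units))),
    class = "znf_array"
  )
  obj$contacts <- extract_contacts(obj, helix_offsets)
  filter_repeats(obj, model)
}

#' @export
print.znf_array <- function(x, ...) {
  cat("znf_array '", x$name, "': ", nrow(x$units), " unit(s), ",
      sum(x$kept), " kept\n", sep = "")
  cat("  unit lengths:", paste(nchar(x$units$nt), collapse = " "), "\n")
  cat("  contacts:    ", paste(x$contacts, collapse = " "), "\n")
  invisible(x)
}

#' Tabulate a set of zinc-finger arrays
#'
#' @param arrays List of `znf_array` objects.
#' @return Data frame with one row per allele: name, unit count, unit
#'   lengths, contact triplets and kept mask (comma-separated).
#' @export
allele_table <- function(arrays) {
  stopifnot(length(arrays) > 0L)
  do.call(rbind, lapply(arrays, function(a) {
    data.frame(
      name = a$name,
      n_units = nrow(a$units),
      unit_lengths = paste(nchar(a$units$nt), collapse = ","),
      contacts = paste(a$contacts, collapse = ","),
      kept = paste(as.integer(a$kept), collapse = ","),
      stringsAsFactors = FALSE
    )
  }))
}

#' Write the allele table as TSV
#' @param arrays List of `znf_array` objects.
#' @param path Output path.
#' @export
write_allele_table <- function(arrays, path) {
  utils::write.table(allele_table(arrays), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
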