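# 0-based nucleotide indices of the contact codons in the canonical 84-nt unit
# (amino acids 12, 16, 19 -> helix -1, +3, +6)
.canonical_contact_nt <- c(36:38, 48:50, 57:59)

#' Configuration for simulating a minisatellite allele family
#'
#' Alleles evolve along a Yule tree of unit height from an ancestral array of
#' identical canonical 84-bp units, by within-unit point mutation, whole-unit
#' tandem duplication (slippage) and whole-unit deletion. `sub_rate` is the
#' expected number of substitutions per unit per unit branch length;
#' `dup_rate` and `del_rate` are per array per unit branch length.
#' Substitution positions are uniform except that the 9 contact-codon
#' nucleotides of each unit are hit `contact_hypermut_factor` times more
#' often, emulating the elevated substitution pressure on the hypervariable
#' DNA-contacting residues.
#'
#' @param seed Integer RNG seed (mandatory).
#' @param n_leaves Number of alleles (>= 3).
#' @param ancestral_units Units in the ancestral array (>= 2; default 11).
#' @param unit_len Unit length (84).
#' @param sub_rate,dup_rate,del_rate Event rates (defaults 2, 0.3, 0.3).
#' @param contact_hypermut_factor Multiplier on `sub_rate` at contact
#'   nucleotides (default 10).
#' @return A `simulation_config` object.
#' @export
simulation_config <- function(seed, n_leaves = 8L, ancestral_units = 11L,
                              unit_len = 84L, sub_rate = 2, dup_rate = 0.3,
                              del_rate = 0.3, contact_hypermut_factor = 10) {
  stopifnot(n_leaves >= 3L, ancestral_units >= 2L,
            sub_rate >= 0, dup_rate >= 0, del_rate >= 0,
            contact_hypermut_factor >= 0)
  structure(list(seed = as.integer(seed), n_leaves = as.integer(n_leaves),
                 ancestral_units = as.integer(ancestral_units),
                 unit_len = as.integer(unit_len), sub_rate = sub_rate,
                 dup_rate = dup_rate, del_rate = del_rate,
                 contact_hypermut_factor = contact_hypermut_factor),
            class = "simulation_config")
}

#' Simulate an allele family with known evolutionary history
#'
#' Generates a Yule tree rescaled to unit height, evolves the ancestral array
#' along it, and records every applied event so that the leaves can be
#' reproduced exactly from the ancestor and the event log
#' ([replay_event_log()]). Fully reproducible from the seed.
#'
#' @param cfg A [simulation_config()].
#' @return A `simulated_family`: list with `config`, `tree` (true tree,
#'   `ape::phylo`), `alleles` (named character vector of leaf sequences),
#'   `leaf_units` (list of true unit vectors per leaf), `event_log`
#'   (data frame: branch = child node id, type, unit, pos, from, to, in
#'   applied order) and `ancestor_units`.
#' @export
simulate_allele_family <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  tree <- ape::rphylo(cfg$n_leaves, birth = 1, death = 0)
  tree$edge.length <- tree$edge.length / max(ape::node.depth.edgelength(tree))
  tree$tip.label <- sprintf("allele_%02d", seq_len(cfg$n_leaves))
  tree <- stats::reorder(tree, "cladewise")

  anc <- rep(znf_canonical_unit(), cfg$ancestral_units)
  states <- vector("list", max(tree$edge))
  states[[cfg$n_leaves + 1L]] <- anc
  log <- list()
  del_floor_hit <- FALSE

  for (e in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
    len <- tree$edge.length[e]
    units <- states[[parent]]
    n_sub <- stats::rpois(1L, cfg$sub_rate * length(units) * len)
    n_dup <- stats::rpois(1L, cfg$dup_rate * len)
    n_del <- stats::rpois(1L, cfg$del_rate * len)
    types <- rep(c("sub", "dup", "del"), c(n_sub, n_dup, n_del))
    if (length(types) > 1L) types <- sample(types)
    for (ty in types) {
      if (ty == "sub") {
        wts <- unlist(lapply(units, function(u) {
          w <- rep(1, nchar(u))
          if (nchar(u) == cfg$unit_len)
            w[.canonical_contact_nt + 1L] <- cfg$contact_hypermut_factor
          w
        }))
        g <- sample.int(length(wts), 1L, prob = wts)
        lens <- nchar(units)
        u <- findInterval(g - 1L, cumsum(lens), left.open = FALSE) + 1L
        pos <- g - c(0L, cumsum(lens))[u]
        old <- substr(units[u], pos, pos)
        new <- sample(setdiff(.BASES, old), 1L)
        substr(units[u], pos, pos) <- new
        log[[length(log) + 1L]] <- data.frame(
          branch = child, type = "sub", unit = u - 1L, pos = pos - 1L,
          from = old, to = new, stringsAsFactors = FALSE)
      } else if (ty == "dup") {
        u <- sample.int(length(units), 1L)
        units <- append(units, units[u], after = u)
        log[[length(log) + 1L]] <- data.frame(
          branch = child, type = "dup", unit = u - 1L, pos = NA_integer_,
          from = NA_character_, to = NA_character_, stringsAsFactors = FALSE)
      } else {
        if (length(units) <= 1L) { del_floor_hit <- TRUE; next }
        u <- sample.int(length(units), 1L)
        units <- units[-u]
        log[[length(log) + 1L]] <- data.frame(
          branch = child, type = "del", unit = u - 1L, pos = NA_integer_,
          from = NA_character_, to = NA_character_, stringsAsFactors = FALSE)
      }
    }
    states[[child]] <- units
  }
  if (del_floor_hit)
    warning("deletion event(s) skipped to keep at least one unit per array")

  leaf_units <- states[seq_len(cfg$n_leaves)]
  names(leaf_units) <- tree$tip.label
  alleles <- vapply(leaf_units, paste, "", collapse = "")
  event_log <- if (length(log)) do.call(rbind, log) else
    data.frame(branch = integer(0), type = character(0), unit = integer(0),
               pos = integer(0), from = character(0), to = character(0),
               stringsAsFactors = FALSE)
  structure(list(config = cfg, tree = tree, alleles = alleles,
                 leaf_units = leaf_units, event_log = event_log,
                 ancestor_units = anc),
            class = "simulated_family")
}

#' Replay a family's event log from the ancestor
#'
#' Reconstructs every leaf sequence by applying the logged events branch by
#' branch; equality with the simulated leaves is the simulator's lossless
#' provenance guarantee.
#'
#' @param family A `simulated_family`.
#' @return Named character vector of reconstructed leaf sequences.
#' @export
replay_event_log <- function(family) {
  tree <- family$tree
  n_tip <- length(tree$tip.label)
  states <- vector("list", max(tree$edge))
  states[[n_tip + 1L]] <- family$ancestor_units
  log <- family$event_log
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2L]
    units <- states[[tree$edge[e, 1L]]]
    ev <- log[log$branch == child, , drop = FALSE]
    for (k in seq_len(nrow(ev))) {
      u <- ev$unit[k] + 1L
      if (ev$type[k] == "sub") {
        substr(units[u], ev$pos[k] + 1L, ev$pos[k] + 1L) <- ev$to[k]
      } else if (ev$type[k] == "dup") {
        units <- append(units, units[u], after = u)
      } else {
        units <- units[-u]
      }
    }
    states[[child]] <- units
  }
  out <- vapply(states[seq_len(n_tip)], paste, "", collapse = "")
  names(out) <- tree$tip.label
  out
}

#' Generate alleles differing from a base allele only at contact codons
#'
#' Each variant carries 1-3 random nucleotide substitutions confined to the
#' contact-codon nucleotides (avoiding stop codons), so masked pairwise
#' distances are identically zero while unmasked distances are strictly
#' positive. Variants are guaranteed distinct from the base and each other.
#'
#' @param base Base allele DNA string (decomposable into canonical units).
#' @param n Number of variants.
#' @param seed RNG seed.
#' @param prefix Name prefix for the variants.
#' @return Named character vector of `n` variant sequences.
#' @export
make_contact_only_variants <- function(base, n, seed, prefix = "variant") {
  set.seed(seed)
  if (n == 0L) return(setNames(character(0), character(0)))
  units <- translate_units(decompose_minisatellite(base))
  starts <- c(0L, cumsum(nchar(units$nt)))
  # 0-based global start index of every resolvable contact codon
  codon_starts <- unlist(lapply(seq_len(nrow(units)), function(i) {
    pos <- tryCatch(resolve_contact_positions(units$aa[i]), error = function(e) NULL)
    if (is.null(pos)) return(integer(0))
    starts[i] + pos$nt_idx[c(1L, 4L, 7L)]
  }))
  if (length(codon_starts) == 0L) stop("base allele has no resolvable contact codons")
  seen <- base
  out <- character(n)
  for (v in seq_len(n)) {
    repeat {
      s <- base
      for (k in seq_len(sample(1:3, 1L))) {
        repeat {
          cs <- sample(codon_starts, 1L) + 1L          # codon start, 1-based
          g <- cs + sample(0:2, 1L)                    # position within codon
          old <- substr(s, g, g)
          new <- sample(setdiff(.BASES, old), 1L)
          cand <- s
          substr(cand, g, g) <- new
          codon <- substr(cand, cs, cs + 2L)
          if (!codon %in% c("TAA", "TAG", "TGA")) {
            s <- cand
            break
          }
        }
      }
      if (!s %in% seen) break
    }
    seen <- c(seen, s)
    out[v] <- s
  }
  names(out) <- sprintf("%s_%02d", prefix, seq_len(n))
  out
}

#' Plant motif consensus sites in an i.i.d. background genome
#'
#' @param pwms Named list of `array_pwm` objects.
#' @param genome_length Background length (>= 10x total planted width).
#' @param n_per_motif Copies planted per motif (default 5).
#' @param background Base frequencies of the background (default uniform).
#' @param seed RNG seed.
#' @param chrom Sequence name of the synthetic contig.
#' @return List with `genome` (named character vector of length 1), `truth`
#'   (BED-like data frame of planted intervals: chrom, start, end, strand,
#'   motif) and `background`.
#' @export
plant_motif_genome <- function(pwms, genome_length, n_per_motif = 5L,
                               background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                               seed = 1L, chrom = "chrS") {
  set.seed(seed)
  widths <- vapply(pwms, ncol, 0L)
  total <- sum(widths * n_per_motif)
  if (genome_length < 10L * total)
    stop("genome_length must be at least 10x the total planted width (", 10L * total, ")")
  seqv <- sample(.BASES, genome_length, replace = TRUE, prob = background)
  placed <- matrix(numeric(0), ncol = 2L)
  truth <- list()
  for (nm in names(pwms)) {
    cons <- pwm_consensus(pwms[[nm]])
    w <- nchar(cons)
    for (k in seq_len(n_per_motif)) {
      ok <- FALSE
      for (att in seq_len(1000L)) {
        s <- sample.int(genome_length - w + 1L, 1L)
        if (nrow(placed) == 0L ||
            all(s + w - 1L < placed[, 1L] | s > placed[, 2L])) {
          ok <- TRUE; break
        }
      }
      if (!ok) stop("could not place motif '", nm, "' without overlap after 1000 attempts")
      strand <- sample(c("+", "-"), 1L)
      ins <- if (strand == "+") cons else .revcomp_string(cons)
      seqv[s:(s + w - 1L)] <- strsplit(ins, "")[[1]]
      placed <- rbind(placed, c(s, s + w - 1L))
      truth[[length(truth) + 1L]] <- data.frame(
        chrom = chrom, start = s - 1L, end = s - 1L + w, strand = strand,
        motif = nm, stringsAsFactors = FALSE)
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               strand = character(0), motif = character(0), stringsAsFactors = FALSE)
  truth <- truth[order(truth$start), , drop = FALSE]
  rownames(truth) <- NULL
  list(genome = setNames(paste(seqv, collapse = ""), chrom),
       truth = truth, background = background)
}

.revcomp_string <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

#' Write named sequences as FASTA
#' @param seqs Named character vector of DNA sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write a family's event log as JSON lines
#' @param family A `simulated_family`.
#' @param path Output path.
#' @export
write_event_log <- function(family, path) {
  con <- file(path, "w"); on.exit(close(con))
  log <- family$event_log
  for (i in seq_len(nrow(log)))
    writeLines(jsonlite::toJSON(as.list(log[i, , drop = FALSE]),
                                auto_unbox = TRUE, na = "null"), con)
  invisible(path)
}
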