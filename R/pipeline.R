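#' Counting-chamber geometry for sperm concentration
#'
#' Defaults describe a Buerker chamber: 0.02 cm square side, 0.01 cm chamber
#' height, 25 squares counted, 1:40 dilution, giving a counted volume of
#' 0.02 * 0.02 * 0.01 * 25 = 0.0001 cm^3.
#'
#' @param square_side Square side in cm.
#' @param chamber_height Chamber height in cm.
#' @param n_squares Number of squares counted.
#' @param dilution Dilution factor.
#' @return A `chamber_spec` with a `volume_cm3` field.
#' @export
#' @examples
#' chamber_spec()$volume_cm3  # 1e-4
chamber_spec <- function(square_side = 0.02, chamber_height = 0.01,
                         n_squares = 25L, dilution = 40) {
  stopifnot(square_side > 0, chamber_height > 0, n_squares > 0, dilution > 0)
  structure(list(square_side = square_side, chamber_height = chamber_height,
                 n_squares = n_squares, dilution = dilution,
                 volume_cm3 = square_side^2 * chamber_height * n_squares),
            class = "chamber_spec")
}

#' Sperm concentration from paired chamber counts
#'
#' Adds the two replicate 25-square counts, divides by the counted volume
#' (1 cm^3 = 1 ml), applies the dilution factor and reports million per ml.
#'
#' @param count_a25,count_b25 Non-negative replicate counts.
#' @param chamber A [chamber_spec()].
#' @return Concentration in million per ml.
#' @export
#' @examples
#' sperm_concentration(5, 5)  # 4 million/ml
sperm_concentration <- function(count_a25, count_b25, chamber = chamber_spec()) {
  if (count_a25 < 0 || count_b25 < 0) stop("counts must be non-negative")
  (count_a25 + count_b25) / chamber$volume_cm3 * chamber$dilution / 1e6
}

#' Two-sided binomial test for transmission ratio distortion
#'
#' Tests deviation of `k` transmitted alleles out of `n` offspring from the
#' Mendelian 50:50 expectation. The exact method sums all outcomes no more
#' probable than the observed one (the minimum-likelihood two-sided test);
#' the normal method uses a continuity-corrected z approximation.
#'
#' @param k Offspring carrying the allele.
#' @param n Total offspring (>= 1).
#' @param method `"exact"` or `"normal"`.
#' @return Two-sided p-value.
#' @export
#' @examples
#' trd_binomial_test(10, 10)            # 2 * 0.5^10
#' trd_binomial_test(174, 200, "normal")
trd_binomial_test <- function(k, n, method = c("exact", "normal")) {
  method <- match.arg(method)
  if (n < 1L) stop("n must be at least 1")
  stopifnot(k >= 0, k <= n)
  if (method == "exact") {
    stats::binom.test(k, n, p = 0.5)$p.value
  } else {
    z <- (abs(k - n / 2) - 0.5) / sqrt(n / 4)
    min(1, 2 * stats::pnorm(-z))
  }
}

#' Run the full allele-analysis pipeline
#'
#' Reads alleles, decomposes and filters them, computes full and
#' contact-masked distance matrices, builds and (optionally) roots both BIONJ
#' trees, and optionally assembles binding motifs, scans a genome and
#' quantifies binding-site overlap. All outputs plus a manifest are written
#' to `outdir`; reruns with the same configuration and seed are
#' byte-identical.
#'
#' @param config Named list or path to a flat YAML file. Recognised keys:
#'   `alleles_fasta` (required), `outdir` (required), `outgroup`,
#'   `w_mut`, `w_indel`, `w_slippage`, `slippage_max_mismatch`,
#'   `run_motifs` (logical), `genome_fasta`, `scan_p` (default 1e-5),
#'   `n_shuffles` (default 200), `seed` (default 1), `quiet` (logical).
#' @return Invisibly, a list with the in-memory results and the manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  required <- c("alleles_fasta", "outdir")
  missing_keys <- setdiff(required, names(config))
  if (length(missing_keys)) stop("missing config key(s): ", paste(missing_keys, collapse = ", "))
  cfg <- utils::modifyList(
    list(outgroup = NULL, w_mut = 1, w_indel = 3.5, w_slippage = 1.75,
         slippage_max_mismatch = 0L, run_motifs = FALSE, genome_fasta = NULL,
         scan_p = 1e-5, n_shuffles = 200L, seed = 1L, quiet = FALSE),
    config)
  say <- function(...) if (!isTRUE(cfg$quiet))
    message(format(Sys.time(), "%H:%M:%S"), " [pipeline] ", ...)

  # --- validation before any compute ---
  if (!file.exists(cfg$alleles_fasta)) stop("alleles_fasta not found: ", cfg$alleles_fasta)
  if (!is.null(cfg$genome_fasta) && !file.exists(cfg$genome_fasta))
    stop("genome_fasta not found: ", cfg$genome_fasta)
  seqs <- read_allele_fasta(cfg$alleles_fasta)
  if (!is.null(cfg$outgroup) && !cfg$outgroup %in% names(seqs))
    stop("outgroup '", cfg$outgroup, "' not among alleles: ",
         paste(names(seqs), collapse = ", "))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$outdir, f)

  say("decompose: ", length(seqs), " allele(s), seed ", cfg$seed)
  arrays <- lapply(names(seqs), function(nm) {
    tryCatch(znf_array(seqs[[nm]], nm),
             error = function(e) stop("stage decompose failed for allele '",
                                      nm, "': ", conditionMessage(e)))
  })
  names(arrays) <- names(seqs)
  write_allele_table(arrays, out("alleles.tsv"))

  w <- weight_scheme(cfg$w_mut, cfg$w_indel, cfg$w_slippage, cfg$slippage_max_mismatch)
  say("distance matrices (full + contact-masked)")
  d_full <- distance_matrix(arrays, w, mask = "none")
  d_mask <- distance_matrix(arrays, w, mask = "contacts")
  write_phylip(d_full, out("dist_full.phy")); write_distance_tsv(d_full, out("dist_full.tsv"))
  write_phylip(d_mask, out("dist_masked.phy")); write_distance_tsv(d_mask, out("dist_masked.tsv"))

  say("BIONJ trees")
  trees <- lapply(list(full = d_full, masked = d_mask), function(m) {
    t <- bionj_tree(m)
    if (!is.null(cfg$outgroup)) t <- root_on_outgroup(t, cfg$outgroup)
    t
  })
  write_newick(trees$full, out("tree_full.nwk"))
  write_newick(trees$masked, out("tree_masked.nwk"))

  motifs <- NULL; hit_sets <- NULL; overlaps <- NULL
  if (isTRUE(cfg$run_motifs)) {
    say("binding motifs")
    motifs <- lapply(arrays, assemble_array_pwm)
    write_meme(motifs, out("motifs.meme"))
    write_jaspar(motifs, out("motifs.jaspar"))
    if (!is.null(cfg$genome_fasta)) {
      say("genome scan at p = ", cfg$scan_p)
      hit_sets <- lapply(motifs, function(p) {
        thr <- score_threshold_from_pvalue(p, cfg$scan_p)
        scan_genome(p, cfg$genome_fasta, thr)
      })
      for (nm in names(hit_sets))
        write_bed(hit_sets[[nm]], out(sprintf("scan_%s.bed", nm)))
      if (length(hit_sets) >= 2L) {
        overlaps <- overlap_matrix(hit_sets)
        utils::write.table(overlaps$counts, out("overlap_counts.tsv"),
                           sep = "\t", quote = FALSE)
        utils::write.table(overlaps$jaccard, out("overlap_jaccard.tsv"),
                           sep = "\t", quote = FALSE)
      }
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("znfarray")),
    inputs = list(alleles_fasta = cfg$alleles_fasta, genome_fasta = cfg$genome_fasta),
    parameters = cfg[c("w_mut", "w_indel", "w_slippage", "slippage_max_mismatch",
                       "outgroup", "run_motifs", "scan_p", "n_shuffles", "seed")],
    outputs = list.files(cfg$outdir)
  )
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              null = "null"), out("manifest.json"))
  say("done: ", length(manifest$outputs), " output file(s) in ", cfg$outdir)
  invisible(list(arrays = arrays, dist_full = d_full, dist_masked = d_mask,
                 trees = trees, motifs = motifs, hits = hit_sets,
                 overlaps = overlaps, manifest = manifest))
}
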