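#' BIONJ tree from a distance matrix
#'
#' Builds an unrooted BIONJ tree: neighbor joining with the variance-weighted
#' distance reduction of Gascuel's BIONJ, implemented in double precision so
#' that additive matrices are reproduced to numerical accuracy. The
#' agglomeration is deterministic: ties in the Q criterion are broken by the
#' lexicographically smallest pair of cluster labels (each cluster labelled by
#' its alphabetically first leaf), so zero-distance taxa join in label order.
#' Negative branch-length estimates, which NJ-family methods can produce on
#' non-additive input, are clamped to zero with the deficit transferred to
#' the sibling branch (standard practice); any residual negative length is
#' set to zero.
#'
#' @param m Labelled symmetric numeric matrix (e.g. from
#'   [distance_matrix()]), at least 3 labels.
#' @return An `ape::phylo` tree, unrooted.
#' @export
bionj_tree <- function(m) {
  stopifnot(is.matrix(m), nrow(m) >= 3L, !is.null(rownames(m)))
  if (anyNA(m) || any(!is.finite(m))) stop("distance matrix contains NA/NaN/Inf")
  if (max(abs(m - t(m))) > 1e-9) stop("distance matrix is not symmetric")
  if (any(abs(diag(m)) > 1e-12)) stop("distance matrix diagonal must be zero")
  tree <- .bionj(m)
  .clamp_negative_edges(tree)
}

# BIONJ agglomeration (Gascuel 1997, Mol Biol Evol 14:685-695). Clusters are
# carried as Newick fragments; variances start equal to the distances.
.bionj <- function(m) {
  labs <- rownames(m)
  n <- nrow(m)
  d <- unname(m)
  v <- d
  frag <- labs                      # Newick fragment per active cluster
  rep_lab <- labs                   # alphabetically first leaf per cluster
  fmt <- function(x) sprintf("%.17g", x)
  while (length(frag) > 3L) {
    r <- length(frag)
    S <- rowSums(d)
    Q <- (r - 2) * d - outer(S, S, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    pair_key <- vapply(seq_len(nrow(cand)), function(k) {
      p <- sort(c(rep_lab[cand[k, 1L]], rep_lab[cand[k, 2L]]))
      paste(p, collapse = "\r")
    }, "")
    sel <- cand[order(pair_key)[1L], ]
    i <- sel[[1L]]; j <- sel[[2L]]
    li <- d[i, j] / 2 + (S[i] - S[j]) / (2 * (r - 2))
    lj <- d[i, j] - li
    lambda <- if (v[i, j] > 0) {
      k <- setdiff(seq_len(r), c(i, j))
      min(1, max(0, 0.5 + sum(v[j, k] - v[i, k]) / (2 * (r - 2) * v[i, j])))
    } else 0.5
    k <- setdiff(seq_len(r), c(i, j))
    du <- lambda * (d[i, k] - li) + (1 - lambda) * (d[j, k] - lj)
    vu <- lambda * v[i, k] + (1 - lambda) * v[j, k] - lambda * (1 - lambda) * v[i, j]
    new_frag <- paste0("(", frag[i], ":", fmt(li), ",", frag[j], ":", fmt(lj), ")")
    new_rep <- min(rep_lab[i], rep_lab[j])
    d <- rbind(cbind(d[k, k, drop = FALSE], du), c(du, 0))
    v <- rbind(cbind(v[k, k, drop = FALSE], vu), c(vu, 0))
    frag <- c(frag[k], new_frag)
    rep_lab <- c(rep_lab[k], new_rep)
  }
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  txt <- paste0("(", frag[1], ":", fmt(la), ",", frag[2], ":", fmt(lb), ",",
                frag[3], ":", fmt(lc), ");")
  ape::read.tree(text = txt)
}

.clamp_negative_edges <- function(tree) {
  el <- tree$edge.length
  if (is.null(el) || all(el >= 0)) return(tree)
  edge <- tree$edge
  for (e in which(el < 0)) {
    deficit <- el[e]
    el[e] <- 0
    sib <- which(edge[, 1L] == edge[e, 1L])
    sib <- sib[sib != e]
    if (length(sib)) el[sib[1L]] <- el[sib[1L]] + deficit
  }
  el[el < 0] <- 0
  tree$edge.length <- el
  tree
}

#' Root a tree on an outgroup leaf
#'
#' Inserts the root at the midpoint of the outgroup's pendant edge; all other
#' relationships and branch lengths are preserved, so unrooting recovers the
#' original unrooted tree.
#'
#' @param tree An `ape::phylo` tree.
#' @param outgroup Tip label to root on.
#' @return A rooted `ape::phylo` tree.
#' @export
root_on_outgroup <- function(tree, outgroup) {
  stopifnot(inherits(tree, "phylo"))
  if (!outgroup %in% tree$tip.label)
    stop("outgroup '", outgroup, "' is not a leaf; available: ",
         paste(tree$tip.label, collapse = ", "))
  tip <- match(outgroup, tree$tip.label)
  pend <- tree$edge.length[which(tree$edge[, 2L] == tip)]
  rooted <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  root <- ape::Ntip(rooted) + 1L
  kids <- which(rooted$edge[, 1L] == root)
  out_tip <- match(outgroup, rooted$tip.label)
  e_out <- kids[rooted$edge[kids, 2L] == out_tip]
  e_other <- setdiff(kids, e_out)
  shift <- rooted$edge.length[e_out] - pend / 2
  rooted$edge.length[e_out] <- pend / 2
  rooted$edge.length[e_other[1L]] <- rooted$edge.length[e_other[1L]] + shift
  rooted
}

#' Write a tree in Newick format
#'
#' Branch lengths are rounded to 6 decimal places before serialization.
#'
#' @param tree An `ape::phylo` tree.
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.null(tree$edge.length))
    tree$edge.length <- round(tree$edge.length, 6L)
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a Newick tree
#'
#' @param path Input path.
#' @return An `ape::phylo` tree.
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  depth <- 0L
  for (i in seq_len(nchar(txt))) {
    ch <- substr(txt, i, i)
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("malformed Newick: unbalanced ')' at character ", i)
    }
  }
  if (depth != 0L)
    stop("malformed Newick: ", depth, " unclosed '(' (string length ", nchar(txt), ")")
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) stop("Newick parse error: ", conditionMessage(e)))
  if (is.null(tree)) stop("Newick parse error: no tree in ", path)
  tree
}

#' Robinson-Foulds distance between two trees
#'
#' Number of bipartitions present in exactly one of the two trees (the
#' unweighted, symmetric-difference RF distance).
#'
#' @param t1,t2 `ape::phylo` trees over the same leaf set.
#' @return Non-negative integer.
#' @export
robinson_foulds <- function(t1, t2) {
  stopifnot(inherits(t1, "phylo"), inherits(t2, "phylo"))
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("leaf sets differ: only in t1 {",
         paste(setdiff(t1$tip.label, t2$tip.label), collapse = ","),
         "}, only in t2 {",
         paste(setdiff(t2$tip.label, t1$tip.label), collapse = ","), "}")
  as.integer(phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2),
                               check.labels = TRUE))
}

#' Normalized Robinson-Foulds distance
#'
#' RF distance divided by its maximum `2 * (n - 3)` for `n` leaves.
#'
#' @inheritParams robinson_foulds
#' @return Value in `[0, 1]`.
#' @export
normalized_rf <- function(t1, t2) {
  n <- length(t1$tip.label)
  if (n <= 3L) return(0)
  robinson_foulds(t1, t2) / (2 * (n - 3L))
}
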