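# Neighbor joining (Saitou-Nei), Robinson-Foulds distance and clade tests.
#
# The joining rule is the classical Q-criterion; ties on Q are broken by
# lexicographic taxon-pair order (each internal node is keyed by the
# smallest leaf label it contains) so the reconstruction is deterministic.
# Negative branch-length estimates are clamped to zero with the deficit
# moved to the sister branch (Kuhner-Felsenstein convention), preserving
# the path length between the joined nodes.

#' Neighbor-joining tree from a distance matrix
#'
#' Classical agglomerative neighbor joining: iteratively join the pair
#' minimizing `Q(i, j) = (n - 2) d(i, j) - R(i) - R(j)`, compute the two
#' branch lengths from the standard two-point formulas, reduce the matrix,
#' and finish with the three-taxon closed form.  Consistent on additive
#' matrices: a tree-realizable input is reconstructed exactly.
#'
#' @param d symmetric distance matrix with a zero diagonal and taxon
#'   dimnames; at least 3 taxa.
#' @param clamp_negative clamp negative branch estimates to zero
#'   (Kuhner-Felsenstein); set `FALSE` to keep raw estimates.
#' @return an unrooted `ape::phylo` tree with branch lengths.
#' @examples
#' d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' neighbor_joining(d)   # branch lengths 1, 1, 3
#' @export
neighbor_joining <- function(d, clamp_negative = TRUE) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (nrow(d) < 3L) {
    stop("neighbor joining requires >= 3 taxa", call. = FALSE)
  }
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  }
  if (max(abs(d - t(d))) > 1e-9 || any(abs(diag(d)) > 1e-12) || any(d < 0)) {
    stop("distance matrix must be symmetric, nonnegative, zero diagonal",
         call. = FALSE)
  }

  labels <- rownames(d)
  newick <- as.list(labels)          # growing subtree fragments
  keys <- labels                     # lexicographic tie-break keys
  D <- d

  clamp_pair <- function(li, lj) {
    if (!clamp_negative) return(c(li, lj))
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    c(max(li, 0), max(lj, 0))
  }
  fmt <- function(x) sprintf("%.10g", x)

  while (nrow(D) > 3L) {
    n <- nrow(D)
    R <- rowSums(D)
    Q <- (n - 2) * D - outer(R, R, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    best <- NULL
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (Q[i, j] <= qmin + 1e-12) {
          key <- sort(c(keys[i], keys[j]))
          if (is.null(best) ||
              key[1L] < best$key[1L] ||
              (key[1L] == best$key[1L] && key[2L] < best$key[2L])) {
            best <- list(i = i, j = j, key = key)
          }
        }
      }
    }
    i <- best$i; j <- best$j
    li <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (n - 2))
    lj <- D[i, j] - li
    l <- clamp_pair(li, lj)
    merged <- sprintf("(%s:%s,%s:%s)", newick[[i]], fmt(l[1L]),
                      newick[[j]], fmt(l[2L]))
    others <- setdiff(seq_len(n), c(i, j))
    dn <- (D[i, others] + D[j, others] - D[i, j]) / 2

    D2 <- rbind(cbind(D[others, others, drop = FALSE], dn),
                c(dn, 0))
    newick <- c(newick[others], merged)
    keys <- c(keys[others], min(best$key))
    D <- D2
  }

  # three-point closed form
  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  if (clamp_negative) { la <- max(la, 0); lb <- max(lb, 0); lc <- max(lc, 0) }
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);", newick[[1L]], fmt(la),
                 newick[[2L]], fmt(lb), newick[[3L]], fmt(lc))
  ape::read.tree(text = txt)
}

# Non-trivial splits of an unrooted tree as canonical membership strings.
tree_splits <- function(tree) {
  ntip <- length(tree$tip.label)
  tips_sorted <- sort(tree$tip.label)
  tr <- ape::reorder.phylo(tree, "postorder")
  desc <- vector("list", ntip + tr$Nnode)
  for (i in seq_len(ntip)) desc[[i]] <- tree$tip.label[i]
  for (k in seq_len(nrow(tr$edge))) {
    p <- tr$edge[k, 1L]; ch <- tr$edge[k, 2L]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  splits <- character(0)
  for (k in seq_len(nrow(tr$edge))) {
    ch <- tr$edge[k, 2L]
    side <- desc[[ch]]
    if (length(side) <= 1L || length(side) >= ntip - 1L) next  # trivial
    membership <- tips_sorted %in% side
    if (membership[1L]) membership <- !membership   # canonical orientation
    splits <- c(splits, paste(as.integer(membership), collapse = ""))
  }
  unique(splits)
}

#' Robinson-Foulds distance between two unrooted trees
#'
#' Symmetric-difference count of non-trivial bipartitions; the trees must
#' share an identical leaf set.  Zero iff the topologies agree.
#'
#' @param tree1,tree2 `ape::phylo` trees.
#' @return nonnegative integer.
#' @export
robinson_foulds <- function(tree1, tree2) {
  if (!setequal(tree1$tip.label, tree2$tip.label)) {
    stop("trees must share a leaf set", call. = FALSE)
  }
  s1 <- tree_splits(ape::unroot(tree1))
  s2 <- tree_splits(ape::unroot(tree2))
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

#' Does an edge separate a focal group from an outgroup?
#'
#' TRUE iff some edge of the tree (equivalently, some bipartition, trivial
#' ones included) puts `focal` and all `partners` on one side and the whole
#' `outgroup` on the other.  Taxa outside both sets may fall on either side.
#'
#' @param tree `ape::phylo`.
#' @param focal single taxon id.
#' @param partners character vector of taxa expected with `focal`.
#' @param outgroup character vector of taxa expected apart from `focal`.
#' @return logical.
#' @export
clade_check <- function(tree, focal, partners, outgroup) {
  taxa <- tree$tip.label
  unknown <- setdiff(c(focal, partners, outgroup), taxa)
  if (length(unknown)) {
    stop("unknown taxa: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  S <- union(focal, partners)
  O <- unique(outgroup)
  if (length(intersect(S, O))) {
    stop("focal/partner and outgroup sets overlap", call. = FALSE)
  }
  ntip <- length(taxa)
  tr <- ape::reorder.phylo(ape::unroot(tree), "postorder")
  desc <- vector("list", ntip + tr$Nnode)
  for (i in seq_len(ntip)) desc[[i]] <- tree$tip.label[i]
  for (k in seq_len(nrow(tr$edge))) {
    p <- tr$edge[k, 1L]; ch <- tr$edge[k, 2L]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  for (k in seq_len(nrow(tr$edge))) {
    side <- desc[[tr$edge[k, 2L]]]
    other <- setdiff(taxa, side)
    if ((all(S %in% side) && all(O %in% other)) ||
        (all(S %in% other) && all(O %in% side))) {
      return(TRUE)
    }
  }
  FALSE
}
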