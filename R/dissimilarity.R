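#' Bray-Curtis dissimilarity between all samples
#'
#' `d(x, y) = 1 - 2 * sum(min(x, y)) / (sum(x) + sum(y))`, computed with
#' `vegan::vegdist`.
#'
#' @param counts taxa x samples matrix with positive sample totals
#'   (rarefied or otherwise depth-comparable).
#' @return symmetric matrix with sample labels; attribute `metric = "BC"`.
#' @export
bray_curtis <- function(counts) {
  if (any(colSums(counts) == 0))
    stop("zero-sum sample(s): ", paste(colnames(counts)[colSums(counts) == 0],
                                       collapse = ", "))
  m <- as.matrix(vegan::vegdist(t(counts), method = "bray"))
  attr(m, "metric") <- "BC"
  m
}

# per-branch abundance matrix: rows = edges of `tree`, cols = samples;
# entry = summed relative abundance of the leaves below that edge
branch_abundance <- function(counts, tree) {
  observed <- rownames(counts)[rowSums(counts > 0) > 0]
  miss <- setdiff(observed, tree$tip.label)
  if (length(miss))
    stop("taxa missing from tree: ", paste(miss, collapse = ", "))
  p <- sweep(counts, 2, colSums(counts), "/")
  tr <- stats::reorder(tree, "postorder")
  n_tip <- length(tr$tip.label)
  n_node <- n_tip + tr$Nnode
  A <- matrix(0, n_node, ncol(counts))
  shared <- intersect(tr$tip.label, rownames(p))
  A[match(shared, tr$tip.label), ] <- p[shared, , drop = FALSE]
  for (e in seq_len(nrow(tr$edge))) {
    A[tr$edge[e, 1], ] <- A[tr$edge[e, 1], ] + A[tr$edge[e, 2], ]
  }
  list(B = A[tr$edge[, 2], , drop = FALSE], L = tr$edge.length)
}

#' UniFrac dissimilarity between all samples
#'
#' Unweighted UniFrac is the branch length unique to one sample's
#' descendant set over the branch length with descendants in either
#' sample. Weighted UniFrac is
#' `sum(L * |p_x - p_y|) / sum(L * (p_x + p_y))` over branches, with
#' `p` the relative abundance descending from the branch; the normalized
#' variant (default) is bounded in \[0, 1\], `normalized = FALSE` returns
#' the raw numerator. Multifurcating trees are accepted.
#'
#' @param counts taxa x samples matrix.
#' @param tree rooted [ape::phylo] with branch lengths; all observed taxa
#'   must be leaves.
#' @param weighted abundance-weighted (TRUE) or presence/absence (FALSE).
#' @param normalized normalize the weighted variant to \[0, 1\].
#' @return symmetric matrix; attribute `metric` is `"WUniFrac"` or
#'   `"UWUniFrac"`.
#' @export
unifrac <- function(counts, tree, weighted = TRUE, normalized = TRUE) {
  if (any(colSums(counts) == 0)) stop("zero-sum sample(s)")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  ba <- branch_abundance(counts, tree)
  B <- ba$B; L <- ba$L
  S <- ncol(counts)
  d <- matrix(0, S, S, dimnames = list(colnames(counts), colnames(counts)))
  if (weighted) {
    for (i in seq_len(S - 1)) for (j in (i + 1):S) {
      num <- sum(L * abs(B[, i] - B[, j]))
      d[i, j] <- d[j, i] <- if (normalized) {
        den <- sum(L * (B[, i] + B[, j]))
        if (den > 0) num / den else 0
      } else num
    }
  } else {
    P <- B > 1e-12
    for (i in seq_len(S - 1)) for (j in (i + 1):S) {
      uni <- sum(L[xor(P[, i], P[, j])])
      tot <- sum(L[P[, i] | P[, j]])
      d[i, j] <- d[j, i] <- if (tot > 0) uni / tot else 0
    }
  }
  attr(d, "metric") <- if (weighted) "WUniFrac" else "UWUniFrac"
  d
}

#' All three dissimilarity matrices on a shared label order
#'
#' @param counts taxa x samples matrix (rarefied for comparability).
#' @param tree rooted tree for the UniFrac pair.
#' @return named list `BC`, `WUniFrac`, `UWUniFrac`.
#' @export
all_metrics <- function(counts, tree) {
  list(BC = bray_curtis(counts),
       WUniFrac = unifrac(counts, tree, weighted = TRUE),
       UWUniFrac = unifrac(counts, tree, weighted = FALSE))
}
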