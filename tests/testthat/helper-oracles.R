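# independent brute-force oracles and tiny fixture builders

`%||%` <- function(a, b) if (is.null(a)) b else a

tiny_tree <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

star_tree <- function() ape::read.tree(text = "(A:1,B:1,C:1);")

tiny_counts <- function() {
  m <- matrix(c(5L, 0L, 2L,
                0L, 3L, 1L,
                4L, 4L, 0L), nrow = 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("s1", "s2", "s3")))
  m
}

rand_rooted_tree <- function(n_tips, seed) {
  tr <- withr::with_seed(seed, ape::rtree(n_tips, rooted = TRUE))
  tr$tip.label <- paste0("T", seq_len(n_tips))
  tr
}

# tip labels below each edge's child node, aligned with tree$edge rows
edge_tip_sets <- function(tree) {
  po <- stats::reorder(tree, "postorder")
  n_tip <- length(po$tip.label)
  below <- vector("list", n_tip + po$Nnode)
  for (i in seq_len(n_tip)) below[[i]] <- po$tip.label[i]
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; c_ <- po$edge[e, 2]
    below[[p]] <- c(below[[p]], below[[c_]])
  }
  list(tree = po, sets = lapply(po$edge[, 2], function(nd) below[[nd]]))
}

brute_faith_pd <- function(x, tree) {
  # sum of branch lengths over edges with at least one observed descendant
  # (the union of root-to-observed-leaf paths on a rooted tree)
  et <- edge_tip_sets(tree)
  obs <- names(x)[x > 0]
  sum(et$tree$edge.length[vapply(et$sets, function(s) any(s %in% obs), logical(1))])
}

brute_unifrac_pair <- function(xa, xb, tree, weighted) {
  et <- edge_tip_sets(tree)
  L <- et$tree$edge.length
  pa <- xa / sum(xa); pb <- xb / sum(xb)
  Ba <- vapply(et$sets, function(s) sum(pa[s]), numeric(1))
  Bb <- vapply(et$sets, function(s) sum(pb[s]), numeric(1))
  if (weighted) {
    sum(L * abs(Ba - Bb)) / sum(L * (Ba + Bb))
  } else {
    ia <- Ba > 0; ib <- Bb > 0
    sum(L[xor(ia, ib)]) / sum(L[ia | ib])
  }
}

brute_permanova_ss <- function(d, meta, terms) {
  n <- nrow(d)
  A <- -0.5 * d^2
  J <- diag(n) - matrix(1 / n, n, n)
  G <- J %*% A %*% J
  X <- matrix(1, n, 1)
  hat <- function(X) X %*% MASS::ginv(crossprod(X)) %*% t(X)
  H_prev <- hat(X)
  ss <- numeric(length(terms)); names(ss) <- terms
  for (t_ in terms) {
    X <- cbind(X, stats::model.matrix(~ meta[[t_]])[, -1, drop = FALSE])
    H <- hat(X)
    ss[t_] <- sum(diag((H - H_prev) %*% G))
    H_prev <- H
  }
  list(ss = ss, total = sum(diag(G)),
       residual = sum(diag((diag(n) - H_prev) %*% G)))
}

# small metadata builder: k hosts x m samples each, dates spaced `gap` days
toy_metadata <- function(k = 3, m = 3, gap = 30, groups = NULL, seasons = NULL) {
  n <- k * m
  data.frame(
    sample_id = sprintf("s%02d", seq_len(n)),
    individual_id = rep(sprintf("I%d", seq_len(k)), each = m),
    age = rep(seq(7, 24, length.out = k), each = m),
    group = factor(groups %||% rep("G1", n)),
    season = factor(seasons %||% rep("wet", n)),
    gestation = 0,
    collection_date = as.Date("2020-01-01") + rep(seq_len(m) - 1, k) * gap,
    rainfall_30d = 100,
    stringsAsFactors = FALSE)
}

labeled_dist <- function(values, labels) {
  m <- as.matrix(values)
  dimnames(m) <- list(labels, labels)
  m
}

small_params <- function(...) {
  sim_params(n_individuals = 8, n_taxa = 30, samples_per_season = 2, ...)
}
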