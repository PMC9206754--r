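# internal helpers shared across modules

#' @importFrom stats sd
z_score <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("cannot z-transform a constant predictor")
  (x - mean(x)) / s
}

# upper-triangle (i < j) index pairs of an n x n matrix, as a 2-column matrix
upper_pairs <- function(n) {
  j <- rep.int(seq_len(n), seq_len(n) - 1L)
  i <- sequence(seq_len(n) - 1L)
  cbind(i = i, j = j)
}

# align a metadata data.frame to a vector of sample labels (bijective join)
align_metadata <- function(metadata, labels) {
  if (!all(labels %in% metadata$sample_id)) {
    missing <- setdiff(labels, metadata$sample_id)
    stop("samples absent from metadata: ", paste(utils::head(missing, 5), collapse = ", "))
  }
  metadata[match(labels, metadata$sample_id), , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# n x n_perm matrix of permutation maps, shuffling positions only within
# each block (blocks of size 1 stay fixed); draws from the current RNG
block_perm_matrix <- function(blocks, n, n_perm) {
  P <- matrix(rep.int(seq_len(n), n_perm), n, n_perm)
  for (pos in blocks) {
    b <- length(pos)
    if (b < 2) next
    K <- stats::runif(b * n_perm)
    # one grouped order call: sort keys within each permutation column
    o <- order(rep(seq_len(n_perm), each = b), K)
    ord <- o - (rep(seq_len(n_perm), each = b) - 1L) * b
    P[pos, ] <- matrix(pos[ord], b, n_perm)
  }
  P
}

# column-wise ranks of a matrix by one grouped order call; ties broken by
# first occurrence (use the same procedure on observed and permuted data)
col_ranks_first <- function(M) {
  m <- nrow(M); k <- ncol(M)
  o <- order(rep(seq_len(k), each = m), M)
  r <- integer(m * k)
  r[o] <- rep.int(seq_len(m), k)
  matrix(r, m, k)
}
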