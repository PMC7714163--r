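## Vectorized plug-in information profiles across many SNPs at once.
##
## The scan substrate is a complete-case integer matrix of genotypes
## (subjects x SNPs). For a fixed phenotype column (or pair of columns) the
## per-SNP contingency tables are assembled with dense crossproducts of
## genotype-level indicator matrices against phenotype one-hot matrices, so a
## whole permutation shuffle costs a handful of BLAS calls instead of one
## `table()` per SNP. Results are numerically identical to routing each tuple
## through `joint_from_samples()` + `mutual_information()` / `deltas()`
## (asserted in the test suite).

## One-hot encode integer codes 1..L into an n x L double matrix.
onehot <- function(idx, L) {
  n <- length(idx)
  m <- matrix(0, n, L)
  m[cbind(seq_len(n), idx)] <- 1
  m
}

## Precompute per-genotype-level indicator matrices and SNP margins.
## G: complete (no sentinel) integer matrix, subjects x SNPs.
geno_indicators <- function(G) {
  lv <- sort(unique(as.vector(G)))
  ind <- lapply(lv, function(v) (G == v) * 1)
  rowm <- vapply(ind, colSums, numeric(ncol(G)))
  if (is.null(dim(rowm))) rowm <- matrix(rowm, nrow = ncol(G))
  list(ind = ind, levels = lv, rowm = rowm, n = nrow(G),
       snp_names = colnames(G))
}

## H from a matrix of count margins (rows = SNPs): vectorized entropy in
## `base` units. n is the sample count.
h_from_counts <- function(M, n, base) {
  (n * log(n) - rowSums(xlogx(M))) / (n * log(base))
}

## Mutual information of every SNP with one phenotype vector.
## gi: geno_indicators(); y: integer codes (no sentinel), length n.
mi_profile <- function(gi, y, base = 2) {
  yl <- sort(unique(y))
  Y <- onehot(match(y, yl), length(yl))
  mi_profile_oh(gi, Y, base)
}

## Same, with the phenotype already one-hot encoded (fast path for shuffles).
mi_profile_oh <- function(gi, Y, base = 2) {
  n <- gi$n
  cells <- 0
  for (k in seq_along(gi$ind)) {
    cells <- cells + rowSums(xlogx(crossprod(gi$ind[[k]], Y)))
  }
  ycounts <- colSums(Y)
  ## MI = (1/n) [ sum c_ij ln c_ij - sum c_i. ln c_i. - sum c_.j ln c_.j + n ln n ]
  unname(cells - rowSums(xlogx(gi$rowm)) - sum(xlogx(ycounts)) + n * log(n)) /
    (n * log(base))
}

## Delta scores of every SNP against a fixed pair of phenotype columns.
## y1, y2: integer codes; returns per-SNP vectors for every measure.
## Variable order per triple: (SNP, y1, y2).
delta_profile <- function(gi, y1, y2, base = 2) {
  l1 <- sort(unique(y1)); l2 <- sort(unique(y2))
  delta_profile_oh(gi,
                   onehot(match(y1, l1), length(l1)),
                   onehot(match(y2, l2), length(l2)),
                   base)
}

delta_profile_oh <- function(gi, Y1, Y2, base = 2) {
  n <- gi$n
  L1 <- ncol(Y1); L2 <- ncol(Y2)
  ## column-wise Khatri-Rao product: one-hot of the (y1, y2) pair, y2 fastest
  Y12 <- matrix(0, n, L1 * L2)
  for (a in seq_len(L1)) {
    Y12[, (a - 1L) * L2 + seq_len(L2)] <- Y1[, a] * Y2
  }
  ## aggregation matrices marginalizing the (y1, y2) axis of the S x (L1*L2)
  ## count blocks
  A1 <- kronecker(diag(L1), matrix(1, L2, 1))  # sum over y2 -> y1 margin
  A2 <- kronecker(matrix(1, L1, 1), diag(L2))  # sum over y1 -> y2 margin
  cells <- 0; s1 <- 0; s2 <- 0
  for (k in seq_along(gi$ind)) {
    Ck <- crossprod(gi$ind[[k]], Y12)          # SNPs x (L1*L2)
    cells <- cells + rowSums(xlogx(Ck))
    s1 <- s1 + rowSums(xlogx(Ck %*% A1))
    s2 <- s2 + rowSums(xlogx(Ck %*% A2))
  }
  lb <- n * log(base)
  cells <- unname(cells); s1 <- unname(s1); s2 <- unname(s2)
  h_s <- unname(n * log(n) - rowSums(xlogx(gi$rowm))) / lb
  h_1 <- (n * log(n) - sum(xlogx(colSums(Y1)))) / lb
  h_2 <- (n * log(n) - sum(xlogx(colSums(Y2)))) / lb
  h_12 <- (n * log(n) - sum(xlogx(colSums(Y12)))) / lb
  h_s1 <- (n * log(n) - s1) / lb
  h_s2 <- (n * log(n) - s2) / lb
  h_s12 <- (n * log(n) - cells) / lb
  mi_s1 <- h_s + h_1 - h_s1
  mi_s2 <- h_s + h_2 - h_s2
  mi_12 <- h_1 + h_2 - h_12
  i3 <- h_s + h_1 + h_2 - h_s1 - h_s2 - h_12 + h_s12
  d_snp <- i3 - mi_12
  d_y1 <- i3 - mi_s2
  d_y2 <- i3 - mi_s1
  list(
    i3 = i3, delta_snp = d_snp, delta_y1 = d_y1, delta_y2 = d_y2,
    delta_sym = d_snp * d_y1 * d_y2,
    omega = h_s + h_1 + h_2 - h_s12,
    mi_s1 = mi_s1, mi_s2 = mi_s2, mi_12 = mi_12
  )
}
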