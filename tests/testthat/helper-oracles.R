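# Independent brute-force oracles. These deliberately avoid the package's
# entropy-difference formulas: every measure is a direct summation over the
# cells of the probability array, so agreement is a genuine two-route check.

o_entropy <- function(p, base = 2) {
  p <- p[p > 0]
  -sum(p * log(p)) / log(base)
}

# MI by direct sum over cells of a 2-d probability array
o_mi <- function(P, base = 2) {
  px <- rowSums(P); py <- colSums(P)
  tot <- 0
  for (i in seq_len(nrow(P))) for (j in seq_len(ncol(P))) {
    if (P[i, j] > 0) tot <- tot + P[i, j] * log(P[i, j] / (px[i] * py[j]))
  }
  tot / log(base)
}

# I(X;Y|Z) by direct conditional summation over a 3-d array (X, Y, Z)
o_cmi <- function(P, base = 2) {
  pz <- apply(P, 3, sum)
  tot <- 0
  for (k in seq_len(dim(P)[3])) {
    if (pz[k] == 0) next
    cond <- P[, , k] / pz[k]
    tot <- tot + pz[k] * o_mi(cond, base)
  }
  tot
}

# interaction information via its definition I(X,Y) - I(X,Y|Z)
o_i3 <- function(P, base = 2) {
  o_mi(apply(P, c(1, 2), sum), base) - o_cmi(P, base)
}

o_deltas <- function(P, base = 2) {
  i3 <- o_i3(P, base)
  mi_yz <- o_mi(apply(P, c(2, 3), sum), base)
  mi_xz <- o_mi(apply(P, c(1, 3), sum), base)
  mi_xy <- o_mi(apply(P, c(1, 2), sum), base)
  dx <- i3 - mi_yz; dy <- i3 - mi_xz; dz <- i3 - mi_xy
  omega <- o_entropy(apply(P, 1, sum), base) + o_entropy(apply(P, 2, sum), base) +
    o_entropy(apply(P, 3, sum), base) - o_entropy(as.vector(P), base)
  list(i3 = i3, delta_x = dx, delta_y = dy, delta_z = dz,
       delta_sym = dx * dy * dz, omega = omega,
       pairwise_mi = c(xy = mi_xy, xz = mi_xz, yz = mi_yz))
}

# random joint over given dims (positive cells, normalized)
random_joint <- function(dims) {
  p <- stats::rgamma(prod(dims), shape = 0.8)
  array(p / sum(p), dim = dims)
}

# exhaustive optimum for the missing-data subset selection
o_lp_brute <- function(M, tau) {
  n <- nrow(M); m <- ncol(M)
  best <- 0
  for (rmask in seq_len(2^n) - 1L) {
    rows <- which(bitwAnd(rmask, 2^(seq_len(n) - 1L)) > 0)
    if (!length(rows)) next
    for (cmask in seq_len(2^m) - 1L) {
      cols <- which(bitwAnd(cmask, 2^(seq_len(m) - 1L)) > 0)
      if (!length(cols)) next
      if (length(rows) + length(cols) <= best) next
      sub <- M[rows, cols, drop = FALSE]
      if (any(rowSums(!sub) == 0)) next
      if (any(colSums(sub) / length(rows) > tau + 1e-12)) next
      best <- length(rows) + length(cols)
    }
  }
  best
}

# small complete genotype matrix for scan tests
make_test_genotypes <- function(n = 120, S = 15, seed = 42, maf = NULL) {
  set.seed(seed)
  maf <- maf %||% runif(S, 0.2, 0.5)
  G <- sapply(maf, function(f) rbinom(n, 2, f))
  map <- data.frame(rsid = sprintf("rs%03d", seq_len(S)),
                    chr = as.character(rep(1:3, length.out = S)),
                    pos = seq_len(S) * 1000L,
                    major = "A", minor = "G",
                    stringsAsFactors = FALSE)
  genotype_matrix(G, map,
                  data.frame(subject_id = sprintf("S%03d", seq_len(n)),
                             sex = rep(c("male", "female"), length.out = n),
                             ethnicity = rep(1:2, length.out = n)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# absolute-tolerance comparison (information measures near zero make
# relative tolerances meaningless)
expect_abs_equal <- function(a, b, tol = 1e-12) {
  testthat::expect_lt(max(abs(a - b)), tol)
}
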