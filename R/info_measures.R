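## Exact plug-in information measures on small discrete alphabets.
##
## All measures are computed from a `joint_distribution`, an array of cell
## probabilities (optionally backed by counts). Estimation is plain
## maximum-likelihood ("plug-in"): permutation nulls downstream absorb the
## estimator bias, so no bias correction is applied here.

#' Joint distribution over discrete variables
#'
#' Container for an empirical or exact joint probability mass function over
#' one, two or three (or more) discrete variables. All information measures in
#' the package operate on this class.
#'
#' @param x numeric array (or vector for a single variable) of cell
#'   probabilities or counts. Dimensions are the variable alphabets.
#' @param counts logical; if `TRUE`, `x` holds counts and is normalized,
#'   with `n_samples` taken as `sum(x)`.
#' @param n_samples number of samples behind the distribution (`NA` for exact
#'   constructions).
#' @return An object of class `joint_distribution` with fields `prob`
#'   (probability array), `n_samples`, and `alphabet_sizes`.
#' @examples
#' jd <- joint_distribution(matrix(c(.4, .1, .1, .4), 2))
#' mutual_information(jd)
#' @export
joint_distribution <- function(x, counts = FALSE, n_samples = NA_integer_) {
  if (!is.numeric(x)) stop("`x` must be numeric", call. = FALSE)
  arr <- if (is.null(dim(x))) array(x, dim = length(x)) else as.array(x)
  if (any(!is.finite(arr))) stop("non-finite cell values", call. = FALSE)
  if (any(arr < 0)) stop("negative frequency in joint distribution", call. = FALSE)
  if (counts) {
    if (any(abs(arr - round(arr)) > 1e-9)) {
      stop("counts must be non-negative integers", call. = FALSE)
    }
    n_samples <- sum(arr)
    if (n_samples <= 0) stop("empty count table", call. = FALSE)
    arr <- arr / n_samples
  } else {
    tot <- sum(arr)
    if (abs(tot - 1) > 1e-9) {
      stop(sprintf("frequencies must sum to 1 (got %.12g)", tot), call. = FALSE)
    }
    arr <- arr / tot
  }
  structure(
    list(prob = arr, n_samples = n_samples, alphabet_sizes = dim(arr)),
    class = "joint_distribution"
  )
}

#' @export
print.joint_distribution <- function(x, ...) {
  cat(sprintf(
    "<joint_distribution> %s alphabet, n_samples = %s\n",
    paste(x$alphabet_sizes, collapse = " x "),
    ifelse(is.na(x$n_samples), "exact", x$n_samples)
  ))
  invisible(x)
}

n_vars <- function(jd) length(jd$alphabet_sizes)

check_jd <- function(jd, arity = NULL) {
  if (!inherits(jd, "joint_distribution")) {
    stop("expected a `joint_distribution`", call. = FALSE)
  }
  if (!is.null(arity) && n_vars(jd) != arity) {
    stop(sprintf("expected a %d-variable joint, got %d variables",
                 arity, n_vars(jd)), call. = FALSE)
  }
  invisible(jd)
}

#' Empirical joint distribution from coded sample columns
#'
#' Builds the plug-in joint distribution of one or more integer-coded
#' variables. Rows carrying the missing-value sentinel in any column are
#' excluded (complete-case), and `n_samples` reflects the retained rows.
#'
#' @param columns a data.frame, matrix, or list of equal-length integer
#'   vectors.
#' @param missing_sentinel code marking missing values (default `-2`).
#' @return a [joint_distribution] whose dimensions follow the sorted observed
#'   alphabet of each column (attribute `levels`).
#' @export
joint_from_samples <- function(columns, missing_sentinel = -2L) {
  if (is.matrix(columns)) columns <- as.data.frame(columns)
  if (is.data.frame(columns)) columns <- as.list(columns)
  if (!is.list(columns) || length(columns) == 0L) {
    stop("`columns` must be a non-empty list/data.frame/matrix", call. = FALSE)
  }
  n <- unique(vapply(columns, length, 1L))
  if (length(n) != 1L) stop("columns must have equal length", call. = FALSE)
  keep <- Reduce(`&`, lapply(columns, function(v) v != missing_sentinel & !is.na(v)))
  if (!any(keep)) stop("no rows remain after removing missing values", call. = FALSE)
  cols <- lapply(columns, function(v) v[keep])
  lvls <- lapply(cols, function(v) sort(unique(v)))
  dims <- vapply(lvls, length, 1L)
  idx <- mapply(function(v, l) match(v, l), cols, lvls, SIMPLIFY = FALSE)
  cell <- idx[[1]]
  if (length(idx) > 1L) {
    mult <- 1L
    for (k in 2:length(idx)) {
      mult <- mult * dims[[k - 1L]]
      cell <- cell + (idx[[k]] - 1L) * mult
    }
  }
  counts <- tabulate(cell, nbins = prod(dims))
  jd <- joint_distribution(array(counts, dim = dims), counts = TRUE)
  attr(jd, "levels") <- lvls
  jd
}

#' Marginal of a joint distribution
#'
#' @param jd a [joint_distribution].
#' @param vars integer indices of the variables to keep.
#' @export
marginal_distribution <- function(jd, vars) {
  check_jd(jd)
  if (any(vars < 1 | vars > n_vars(jd))) stop("variable index out of range", call. = FALSE)
  p <- apply(jd$prob, vars, sum)
  joint_distribution(p, n_samples = jd$n_samples)
}

#' Shannon entropy
#'
#' Entropy of a probability vector or of the full joint distribution, with the
#' convention 0 log 0 = 0.
#'
#' @param x a [joint_distribution] or a numeric probability vector.
#' @param base logarithm base; 2 (bits, default) or `exp(1)` (nats).
#' @return entropy in units determined by `base`.
#' @examples
#' entropy(c(0.25, 0.75))
#' @export
entropy <- function(x, base = 2) {
  p <- if (inherits(x, "joint_distribution")) x$prob else {
    if (!is.numeric(x)) stop("`x` must be numeric or a joint_distribution", call. = FALSE)
    if (any(x < 0)) stop("negative frequency", call. = FALSE)
    if (abs(sum(x) - 1) > 1e-9) stop("probabilities must sum to 1", call. = FALSE)
    x
  }
  -sum(xlogx(p)) / log(base)
}

## Entropy of the marginal over `vars`, in nats times 1 (internal).
h_marg <- function(jd, vars, base) {
  -sum(xlogx(apply(jd$prob, vars, sum))) / log(base)
}

#' Mutual information of a two-variable joint
#'
#' I(X,Y) = H(X) + H(Y) - H(X,Y), the general model-free pairwise dependence
#' measure used by all pairwise scans.
#'
#' @inheritParams entropy
#' @param jd a two-variable [joint_distribution].
#' @return mutual information (bits by default); non-negative and symmetric.
#' @export
mutual_information <- function(jd, base = 2) {
  check_jd(jd, arity = 2L)
  h_marg(jd, 1, base) + h_marg(jd, 2, base) - entropy(jd, base)
}

#' Interaction information of a three-variable joint
#'
#' I(X,Y,Z) = I(X,Y) - I(X,Y|Z), the three-variable generalization of mutual
#' information. Negative values indicate synergy (the XOR case reaches -1 bit
#' on uniform binary inputs); positive values indicate redundancy. Invariant
#' under permutation of the three variables.
#'
#' @inheritParams entropy
#' @param jd a three-variable [joint_distribution].
#' @export
interaction_information <- function(jd, base = 2) {
  check_jd(jd, arity = 3L)
  h_marg(jd, 1, base) + h_marg(jd, 2, base) + h_marg(jd, 3, base) -
    h_marg(jd, c(1, 2), base) - h_marg(jd, c(1, 3), base) - h_marg(jd, c(2, 3), base) +
    entropy(jd, base)
}

#' Conditional mutual information I(X;Y|Z)
#'
#' @inheritParams interaction_information
#' @param given index (1, 2 or 3) of the conditioning variable.
#' @export
conditional_mutual_information <- function(jd, given = 3L, base = 2) {
  check_jd(jd, arity = 3L)
  others <- setdiff(1:3, given)
  h_marg(jd, c(others[1], given), base) + h_marg(jd, c(others[2], given), base) -
    h_marg(jd, given, base) - entropy(jd, base)
}

#' Delta dependency scores of a three-variable joint
#'
#' Computes the full set of three-variable dependency measures: interaction
#' information, the three asymmetric deltas, the symmetric delta, the
#' multi-information (total correlation), and the three pairwise mutual
#' informations.
#'
#' The asymmetric delta for target X is `delta_x = I(X,Y,Z) - I(Y,Z)`, which
#' equals `-I(Y;Z|X)` and is therefore always <= 0 on exact distributions. The
#' symmetric delta is the product `delta_x * delta_y * delta_z` (bits cubed,
#' <= 0); it is zero whenever any one variable is independent of the other
#' two, and large in magnitude for collectively interdependent triples such as
#' XOR, which carries no pairwise dependence at all. The asymmetric deltas
#' satisfy `delta_x = I(X,Y) + I(X,Z) - omega` where `omega` is the
#' multi-information `sum(H(marginals)) - H(joint)`.
#'
#' @inheritParams interaction_information
#' @return an object of class `delta_scores`: list with `i3`, `delta_x`,
#'   `delta_y`, `delta_z`, `delta_sym`, `omega`, `pairwise_mi` (named xy, xz,
#'   yz).
#' @examples
#' # the XOR joint: no pairwise dependence, strong three-way dependence
#' p <- array(0, c(2, 2, 2))
#' p[1, 1, 1] <- p[1, 2, 2] <- p[2, 1, 2] <- p[2, 2, 1] <- 0.25
#' deltas(joint_distribution(p))
#' @export
deltas <- function(jd, base = 2) {
  check_jd(jd, arity = 3L)
  hx <- h_marg(jd, 1, base); hy <- h_marg(jd, 2, base); hz <- h_marg(jd, 3, base)
  hxy <- h_marg(jd, c(1, 2), base)
  hxz <- h_marg(jd, c(1, 3), base)
  hyz <- h_marg(jd, c(2, 3), base)
  hxyz <- entropy(jd, base)
  mi_xy <- hx + hy - hxy
  mi_xz <- hx + hz - hxz
  mi_yz <- hy + hz - hyz
  i3 <- hx + hy + hz - hxy - hxz - hyz + hxyz
  d_x <- i3 - mi_yz
  d_y <- i3 - mi_xz
  d_z <- i3 - mi_xy
  omega <- hx + hy + hz - hxyz
  structure(
    list(
      i3 = i3, delta_x = d_x, delta_y = d_y, delta_z = d_z,
      delta_sym = d_x * d_y * d_z, omega = omega,
      pairwise_mi = c(xy = mi_xy, xz = mi_xz, yz = mi_yz)
    ),
    class = "delta_scores"
  )
}

#' @export
print.delta_scores <- function(x, digits = 4, ...) {
  cat("<delta_scores>\n")
  cat(sprintf("  I3        : %+0.*f\n", digits, x$i3))
  cat(sprintf("  deltas    : X %+0.*f  Y %+0.*f  Z %+0.*f\n",
              digits, x$delta_x, digits, x$delta_y, digits, x$delta_z))
  cat(sprintf("  delta_sym : %+0.*f\n", digits, x$delta_sym))
  cat(sprintf("  omega     : %0.*f\n", digits, x$omega))
  cat(sprintf("  pairwise  : xy %0.*f  xz %0.*f  yz %0.*f\n",
              digits, x$pairwise_mi[["xy"]], digits, x$pairwise_mi[["xz"]],
              digits, x$pairwise_mi[["yz"]]))
  invisible(x)
}
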