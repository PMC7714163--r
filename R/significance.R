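## Permutation significance, confounding adjustment, stratified profiling.
##
## P-values follow the pooled permutation strategy: shuffle the phenotype
## side of the data (breaking genotype-phenotype links while preserving all
## linkage between SNPs), recompute every tuple score with the identical
## estimator, and pool all randomized scores into one null. The pooled
## p-value of an observed score is the fraction of the pooled null at least
## as extreme; the family-wise error rate uses the distribution of the
## per-shuffle absolute maximum score. Extremeness is |score| throughout:
## mutual information is non-negative and three-variable deltas are ranked
## by absolute value.

new_null_distribution <- function(pooled_scores, per_shuffle_max, n_shuffles,
                                  n_tuples, scheme) {
  stopifnot(length(pooled_scores) == n_shuffles * n_tuples,
            length(per_shuffle_max) == n_shuffles)
  structure(
    list(pooled_sorted = sort(abs(pooled_scores)),
         per_shuffle_max = per_shuffle_max,
         n_shuffles = n_shuffles, n_tuples = n_tuples, scheme = scheme),
    class = "null_distribution"
  )
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("<null_distribution> %d shuffles x %d tuples (%s)\n",
              x$n_shuffles, x$n_tuples, x$scheme))
  invisible(x)
}

permute_data <- function(data, scheme, n) {
  if (scheme == "permute_phenotype") {
    perm <- sample.int(n)
    data$phenotypes <- data$phenotypes[perm, , drop = FALSE]
  } else if (scheme == "permute_both_phenotypes_independently") {
    data$phenotypes <- data$phenotypes[sample.int(n), , drop = FALSE]
    data$phenotypes2 <- data$phenotypes2[sample.int(n), , drop = FALSE]
  } else {
    stop(sprintf("unknown scheme: %s", scheme), call. = FALSE)
  }
  data
}

#' Pooled permutation null distribution
#'
#' Repeatedly shuffles the phenotype side of `data` and recomputes all tuple
#' scores with `score_fn`, pooling every randomized score. Two schemes are
#' supported: `"permute_phenotype"` (pairwise scans: phenotype rows are
#' shuffled as a block, genotype linkage preserved) and
#' `"permute_both_phenotypes_independently"` (three-way scans: the two
#' phenotype blocks get independent permutations, also breaking their mutual
#' link).
#'
#' @param score_fn function of `data` returning the numeric vector of all
#'   tuple scores; must be the identical estimator used for the observed
#'   scan.
#' @param data list with element `phenotypes` (data.frame/matrix) and, for
#'   the three-way scheme, `phenotypes2`; any other elements (e.g. genotypes)
#'   pass through untouched.
#' @param n_shuffles number of shuffles (default 1000).
#' @param scheme permutation scheme (see above).
#' @param seed RNG seed; fixed seed gives a bit-identical null.
#' @return a `null_distribution` with the pooled scores and per-shuffle
#'   absolute maxima.
#' @export
permutation_null <- function(score_fn, data, n_shuffles = 1000,
                             scheme = c("permute_phenotype",
                                        "permute_both_phenotypes_independently"),
                             seed = 1L) {
  scheme <- match.arg(scheme)
  n <- nrow(data$phenotypes)
  obs <- score_fn(data)
  n_tuples <- length(obs)
  pooled <- numeric(n_shuffles * n_tuples)
  per_max <- numeric(n_shuffles)
  with_seed(seed, {
    for (s in seq_len(n_shuffles)) {
      sc <- score_fn(permute_data(data, scheme, n))
      if (length(sc) != n_tuples) stop("score_fn returned inconsistent tuple count", call. = FALSE)
      pooled[(s - 1L) * n_tuples + seq_len(n_tuples)] <- sc
      per_max[s] <- max(abs(sc))
    }
  })
  new_null_distribution(pooled, per_max, n_shuffles, n_tuples, scheme)
}

#' Pooled permutation p-value
#'
#' p = (number of pooled null scores at least as extreme as the observed
#' score) / (n_tuples * n_shuffles). Extremeness is |score|. An observed
#' score exceeding every null score is reported at the attainable floor
#' 1/(n_tuples * n_shuffles) with attribute `"at_floor"` set.
#'
#' @param observed numeric vector of observed scores.
#' @param null a `null_distribution`.
#' @return p-values in (0, 1]; logical attribute `at_floor` marks values
#'   reported at the floor.
#' @export
pooled_pvalue <- function(observed, null) {
  stopifnot(inherits(null, "null_distribution"))
  N <- length(null$pooled_sorted)
  if (!N) stop("empty null distribution", call. = FALSE)
  cnt <- N - findInterval(abs(observed), null$pooled_sorted, left.open = TRUE)
  at_floor <- cnt == 0L
  p <- pmax(cnt, 1L) / N
  attr(p, "at_floor") <- at_floor
  p
}

#' Family-wise error rate from per-shuffle maxima
#'
#' Fraction of shuffles whose absolute maximum randomized score is at least
#' as extreme as the observed score. Always at least the pooled p-value of
#' the same score on the same null.
#'
#' @inheritParams pooled_pvalue
#' @return FWER values in [0, 1].
#' @export
fwer <- function(observed, null) {
  stopifnot(inherits(null, "null_distribution"))
  mx <- sort(null$per_shuffle_max)
  (length(mx) - findInterval(abs(observed), mx, left.open = TRUE)) / length(mx)
}

#' Ethnicity labels with group priors
#'
#' @param groups integer vector of group memberships in {1, 2}, one per
#'   subject.
#' @param priors optional group priors `c(P1, P2)` summing to 1; empirical
#'   frequencies by default.
#' @export
ethnicity_labels <- function(groups, priors = NULL) {
  groups <- as.integer(groups)
  if (!all(groups %in% c(1L, 2L))) stop_field("groups", "must be coded 1 or 2")
  if (is.null(priors)) {
    priors <- as.numeric(table(factor(groups, levels = 1:2)) / length(groups))
  }
  if (length(priors) != 2 || abs(sum(priors) - 1) > 1e-9) {
    stop_field("priors", "must be two proportions summing to 1")
  }
  structure(list(groups = groups, priors = priors), class = "ethnicity_labels")
}

#' Ethnicity-adjusted mutual information
#'
#' Mutual information between a SNP and a phenotype with the phenotype
#' conditional standardized over ethnicity:
#' `pi(b|s) = sum_i P(eps_i) p(b|s, eps_i)` (prior-weighted, so `pi(.|s)` is
#' a proper distribution and the measure reduces exactly to the unadjusted MI
#' when the conditional does not depend on the group). The adjusted MI is
#' `sum_s p(s) sum_b pi(b|s) log(pi(b|s) / p(b))` with `p(s)` and `p(b)` the
#' pooled empirical marginals. A (genotype, group) cell with no subjects
#' falls back to the group-free conditional `p(b|s)` and is flagged.
#'
#' @param snp integer genotype codes (missing as sentinel).
#' @param phenotype integer phenotype codes (missing as sentinel).
#' @param eth an [ethnicity_labels] aligned with the subjects.
#' @param base logarithm base (default 2, bits).
#' @param literal if `TRUE`, uses the unweighted sum
#'   `pi(b|s) = sum_i p(b|s, eps_i)` (a non-normalized standardization kept
#'   for comparison only).
#' @param missing_sentinel missing-value code.
#' @return adjusted MI; attribute `"zero_cells"` counts (genotype, group)
#'   cells that fell back to the pooled conditional.
#' @export
adjusted_mutual_information <- function(snp, phenotype, eth, base = 2,
                                        literal = FALSE, missing_sentinel = -2L) {
  stopifnot(inherits(eth, "ethnicity_labels"))
  keep <- snp != missing_sentinel & phenotype != missing_sentinel &
    !is.na(snp) & !is.na(phenotype)
  s <- snp[keep]; b <- phenotype[keep]; g <- eth$groups[keep]
  if (!length(s)) stop("no complete cases", call. = FALSE)
  sv <- sort(unique(s)); bv <- sort(unique(b))
  p_s <- as.numeric(table(factor(s, levels = sv))) / length(s)
  p_b <- as.numeric(table(factor(b, levels = bv))) / length(b)
  zero_cells <- 0L
  total <- 0
  for (si in seq_along(sv)) {
    in_s <- s == sv[si]
    pi_bs <- numeric(length(bv))
    for (gi in 1:2) {
      in_sg <- in_s & g == gi
      if (!any(in_sg)) {
        zero_cells <- zero_cells + 1L
        cond <- as.numeric(table(factor(b[in_s], levels = bv))) / sum(in_s)
      } else {
        cond <- as.numeric(table(factor(b[in_sg], levels = bv))) / sum(in_sg)
      }
      w <- if (literal) 1 else eth$priors[gi]
      pi_bs <- pi_bs + w * cond
    }
    nz <- pi_bs > 0
    total <- total + p_s[si] *
      sum(pi_bs[nz] * (log(pi_bs[nz]) - log(p_b[nz]))) / log(base)
  }
  attr(total, "zero_cells") <- zero_cells
  total
}

#' Pairwise Kolmogorov-Smirnov comparison of stratified distributions
#'
#' Two-sample K-S statistic and p-value for every pair of strata (e.g. a
#' numeric phenotype stratified by genotype, or by the level of a second
#' phenotype). The reported p-value tests the hypothesis that the two
#' stratum distributions are the same.
#'
#' @param values numeric vector.
#' @param strata stratum label per value; at least two non-empty strata, each
#'   with at least 2 values.
#' @return list with `statistic` and `p_value` (symmetric matrices with one
#'   row/column per stratum) and `n` (stratum sizes).
#' @export
ks_stratified <- function(values, strata) {
  keep <- !is.na(values) & !is.na(strata)
  values <- values[keep]; strata <- strata[keep]
  lv <- sort(unique(strata))
  if (length(lv) < 2) stop("need at least 2 non-empty strata", call. = FALSE)
  sizes <- vapply(lv, function(l) sum(strata == l), 1L)
  if (any(sizes < 2)) {
    stop(sprintf("stratum with < 2 values: %s",
                 paste(lv[sizes < 2], collapse = ", ")), call. = FALSE)
  }
  k <- length(lv)
  D <- matrix(0, k, k, dimnames = list(lv, lv))
  P <- matrix(1, k, k, dimnames = list(lv, lv))
  for (a in seq_len(k - 1)) {
    for (b in (a + 1):k) {
      ks <- suppressWarnings(
        stats::ks.test(values[strata == lv[a]], values[strata == lv[b]],
                       exact = FALSE)
      )
      D[a, b] <- D[b, a] <- unname(ks$statistic)
      P[a, b] <- P[b, a] <- ks$p.value
    }
  }
  list(statistic = D, p_value = P, n = stats::setNames(sizes, lv))
}
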