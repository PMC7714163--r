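## Genotype and phenotype preprocessing.
##
## The genotype pipeline mirrors the six-step filter used upstream of the
## dependency scans: (1) constant SNPs out, (2) perfectly correlated SNPs
## collapsed to one representative, (3) high-missingness SNPs out, (4) SNP
## pairs with high mutual information collapsed, (5) near-constant SNPs out,
## (6) X/Y SNPs split off for the sex-stratified analysis. Numeric phenotypes
## are binned into four data-driven intervals; categorical phenotypes are
## screened for alphabet size and near-constancy. Missing-data subset
## selection maximizes subjects + variables under a per-variable missingness
## cap.

chr_order <- function(chr) {
  match(as.character(chr), c(as.character(1:22), "X", "Y", "XY", "MT"))
}

## union-find over 1..n
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}
uf_groups <- function(parent) {
  roots <- vapply(seq_along(parent), function(i) uf_find(parent, i), 1L)
  split(seq_along(parent), roots)
}

## single-linkage grouping from a 2-column pair matrix; returns groups of
## size >= 2 as index vectors
link_pairs <- function(n, pairs) {
  parent <- uf_new(n)
  if (nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      ra <- uf_find(parent, pairs[k, 1]); rb <- uf_find(parent, pairs[k, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  Filter(function(g) length(g) > 1L, uf_groups(parent))
}

## pairs of columns of G that are identical on every subject where both are
## observed (and share at least one such subject)
identical_pairs <- function(G, sentinel = -2L, block = 2000L) {
  S <- ncol(G)
  obs <- (G != sentinel) * 1
  lv <- setdiff(sort(unique(as.vector(G))), sentinel)
  pairs <- matrix(integer(0), 0, 2)
  for (start in seq(1L, S, by = block)) {
    cols <- start:min(start + block - 1L, S)
    both <- crossprod(obs, obs[, cols, drop = FALSE])
    agree <- 0
    for (v in lv) {
      Iv <- (G == v) * 1
      agree <- agree + crossprod(Iv, Iv[, cols, drop = FALSE])
    }
    hit <- which(agree == both & both >= 1, arr.ind = TRUE)
    hit[, 2] <- cols[hit[, 2]]
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    pairs <- rbind(pairs, hit)
  }
  pairs
}

pick_representative <- function(idx, map) {
  idx[order(chr_order(map$chr[idx]), map$pos[idx])][1]
}

#' Collapse SNPs with high pairwise mutual information
#'
#' Computes plug-in mutual information between SNP pairs on
#' pairwise-complete subjects and collapses single-linkage clusters of pairs
#' exceeding the threshold, keeping one representative per cluster (lowest
#' chromosome, then position). Since MI(X,Y) <= min(H(X), H(Y)), only SNPs
#' whose own entropy exceeds the threshold can participate, which keeps the
#' pair search small.
#'
#' @param g a [genotype_matrix].
#' @param threshold MI threshold (default 1.2, in `base` units).
#' @param base logarithm base for the MI (default 2, bits).
#' @return list with `genotypes` (collapsed [genotype_matrix]) and `groups`
#'   (named list mapping each representative rsID to the rsIDs of its
#'   collapsed members).
#' @export
collapse_by_mi <- function(g, threshold = 1.2, base = 2) {
  if (threshold <= 0) stop_field("threshold", "must be positive")
  G <- g$genotypes
  S <- ncol(G)
  h <- apply(G, 2, function(v) {
    v <- v[v != g$missing_sentinel]
    if (!length(v)) return(0)
    entropy(tabulate(v + 1L, 3L) / length(v), base = base)
  })
  cand <- which(h > threshold)
  pairs <- matrix(integer(0), 0, 2)
  if (length(cand) > 1) {
    for (a in seq_len(length(cand) - 1)) {
      for (b in (a + 1):length(cand)) {
        i <- cand[a]; j <- cand[b]
        jd <- tryCatch(
          joint_from_samples(list(G[, i], G[, j]), g$missing_sentinel),
          error = function(e) NULL
        )
        if (!is.null(jd) && mutual_information(jd, base = base) > threshold) {
          pairs <- rbind(pairs, c(i, j))
        }
      }
    }
  }
  groups_idx <- link_pairs(S, pairs)
  drop <- integer(0)
  groups <- list()
  for (grp in groups_idx) {
    rep_i <- pick_representative(grp, g$map)
    groups[[g$map$rsid[rep_i]]] <- g$map$rsid[setdiff(grp, rep_i)]
    drop <- c(drop, setdiff(grp, rep_i))
  }
  keep <- setdiff(seq_len(S), drop)
  list(genotypes = subset_genotypes(g, snps = keep), groups = groups)
}

#' Preprocess a genotype matrix
#'
#' Applies, in order: (1) removal of constant SNPs; (2) collapsing of
#' perfectly correlated SNPs (identical on pairwise-complete subjects),
#' keeping one representative; (3) removal of SNPs with more than
#' `missing_threshold` missing values; (4) mutual-information collapsing (see
#' [collapse_by_mi()]); (5) removal of near-constant SNPs (one genotype in
#' more than `near_constant` of observed subjects); (6) separation of X/Y
#' (incl. pseudoautosomal) SNPs into their own matrix for the sex-stratified
#' scans.
#'
#' @param g a [genotype_matrix] coded 0/1/2/-2.
#' @param config list overriding `missing_threshold` (0.25), `mi_threshold`
#'   (1.2), `near_constant` (0.95), `mi_base` (2).
#' @return list with `genotypes` (autosomal, filtered), `xy` (sex-chromosome
#'   [genotype_matrix] or NULL), and `report` (a `preprocess_report`).
#' @export
preprocess_genotypes <- function(g, config = list()) {
  cfg <- utils::modifyList(
    list(missing_threshold = 0.25, mi_threshold = 1.2, near_constant = 0.95,
         mi_base = 2),
    config
  )
  stopifnot(inherits(g, "genotype_matrix"))
  sentinel <- g$missing_sentinel
  input_snps <- g$map$rsid
  steps <- c(constant = 0L, collapsed_identical = 0L, high_missing = 0L,
             collapsed_mi = 0L, near_constant = 0L, moved_xy = 0L)
  removed <- list()

  ## step 1: constant SNPs (no variation among observed genotypes)
  n_distinct <- apply(g$genotypes, 2, function(v) length(unique(v[v != sentinel])))
  const <- which(n_distinct <= 1L)
  steps["constant"] <- length(const)
  removed$constant <- g$map$rsid[const]
  if (length(const)) g <- subset_genotypes(g, snps = setdiff(seq_len(ncol(g$genotypes)), const))

  ## step 2: perfectly correlated SNPs collapsed
  pairs <- identical_pairs(g$genotypes, sentinel)
  groups_ident <- list()
  drop <- integer(0)
  for (grp in link_pairs(ncol(g$genotypes), pairs)) {
    rep_i <- pick_representative(grp, g$map)
    groups_ident[[g$map$rsid[rep_i]]] <- g$map$rsid[setdiff(grp, rep_i)]
    drop <- c(drop, setdiff(grp, rep_i))
  }
  steps["collapsed_identical"] <- length(drop)
  if (length(drop)) g <- subset_genotypes(g, snps = setdiff(seq_len(ncol(g$genotypes)), drop))

  ## step 3: high missingness
  miss_frac <- colMeans(g$genotypes == sentinel)
  high <- which(miss_frac > cfg$missing_threshold)
  steps["high_missing"] <- length(high)
  removed$high_missing <- g$map$rsid[high]
  if (length(high)) g <- subset_genotypes(g, snps = setdiff(seq_len(ncol(g$genotypes)), high))

  ## step 4: MI collapsing
  mi_res <- collapse_by_mi(g, threshold = cfg$mi_threshold, base = cfg$mi_base)
  steps["collapsed_mi"] <- ncol(g$genotypes) - ncol(mi_res$genotypes$genotypes)
  g <- mi_res$genotypes

  ## step 5: near-constant SNPs
  near <- which(apply(g$genotypes, 2, function(v) {
    v <- v[v != sentinel]
    max(tabulate(v + 1L, 3L)) / length(v)
  }) > cfg$near_constant)
  steps["near_constant"] <- length(near)
  removed$near_constant <- g$map$rsid[near]
  if (length(near)) g <- subset_genotypes(g, snps = setdiff(seq_len(ncol(g$genotypes)), near))

  ## step 6: move X/Y (incl. pseudoautosomal) SNPs to a separate matrix
  sl <- if ("sex_linked" %in% names(g$map)) g$map$sex_linked else FALSE
  xy_idx <- which(g$map$chr %in% c("X", "Y", "XY") | sl)
  steps["moved_xy"] <- length(xy_idx)
  xy <- if (length(xy_idx)) subset_genotypes(g, snps = xy_idx) else NULL
  if (length(xy_idx)) g <- subset_genotypes(g, snps = setdiff(seq_len(ncol(g$genotypes)), xy_idx))

  report <- structure(
    list(steps = steps,
         collapsed_identical = groups_ident,
         collapsed_mi = mi_res$groups,
         removed = removed,
         input_snps = input_snps,
         retained_snps = g$map$rsid,
         xy_snps = if (is.null(xy)) character(0) else xy$map$rsid,
         retained_subjects = rownames(g$genotypes) %||% seq_len(nrow(g$genotypes))),
    class = "preprocess_report"
  )
  list(genotypes = g, xy = xy, report = report)
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat("<preprocess_report>\n")
  for (nm in names(x$steps)) cat(sprintf("  %-20s %d\n", nm, x$steps[[nm]]))
  cat(sprintf("  retained             %d (+ %d X/Y)\n",
              length(x$retained_snps), length(x$xy_snps)))
  invisible(x)
}

#' Discretize a numeric phenotype into four bins
#'
#' Bin boundaries are (-Inf, l], (l, mu], (mu, r], (r, Inf) where mu is the
#' mean of the observed values, l the median of values <= mu and r the median
#' of values > mu. Values equal to mu land in bin 2. Missing values are
#' preserved as the sentinel.
#'
#' @param values numeric vector.
#' @param missing_sentinel sentinel marking missing entries (also honours
#'   `NA`).
#' @return integer codes in 1..4, with missing entries as the sentinel.
#' @export
discretize_numeric <- function(values, missing_sentinel = -2L) {
  obs_mask <- !is.na(values) & values != missing_sentinel
  v <- values[obs_mask]
  if (length(unique(v)) < 4L) {
    stop("need at least 4 distinct non-missing values to form 4 bins", call. = FALSE)
  }
  mu <- mean(v)
  l <- stats::median(v[v <= mu])
  r <- stats::median(v[v > mu])
  codes <- rep.int(as.integer(missing_sentinel), length(values))
  w <- values[obs_mask]
  codes[obs_mask] <- 1L + (w > l) + (w > mu) + (w > r)
  codes
}

#' Screen categorical phenotypes
#'
#' Drops variables with more than `max_categories` distinct observed values
#' (too many levels weaken dependency detection) and variables where one
#' value covers more than `near_constant` of observed subjects.
#'
#' @param table data.frame of integer-coded categorical phenotypes.
#' @param max_categories maximum alphabet size retained (default 10).
#' @param near_constant constancy threshold (default 0.95).
#' @param missing_sentinel missing-value code.
#' @return the screened data.frame; dropped variables and reasons in
#'   attribute `"screen_report"`.
#' @export
screen_categorical <- function(table, max_categories = 10, near_constant = 0.95,
                               missing_sentinel = -2L) {
  drop <- character(0); reason <- character(0)
  for (nm in names(table)) {
    v <- table[[nm]]
    v <- v[!is.na(v) & v != missing_sentinel]
    k <- length(unique(v))
    if (k > max_categories) {
      drop <- c(drop, nm); reason <- c(reason, "too_many_categories")
    } else if (length(v) && max(table(v)) / length(v) > near_constant) {
      drop <- c(drop, nm); reason <- c(reason, "near_constant")
    }
  }
  out <- table[setdiff(names(table), drop)]
  attr(out, "screen_report") <- data.frame(variable = drop, reason = reason,
                                           stringsAsFactors = FALSE)
  out
}

lp_feasible <- function(M, rows, cols, tau) {
  if (!length(rows) || !length(cols)) return(FALSE)
  sub <- M[rows, cols, drop = FALSE]
  if (any(rowSums(!sub) == 0)) return(FALSE)       # a row entirely missing
  all(colSums(sub) / length(rows) <= tau + 1e-12)  # per-variable missing cap
}

lp_greedy <- function(M, tau) {
  rows <- seq_len(nrow(M)); cols <- seq_len(ncol(M))
  repeat {
    changed <- FALSE
    if (length(rows) && length(cols)) {
      keep_r <- rowSums(!M[rows, cols, drop = FALSE]) > 0
      if (!all(keep_r)) { rows <- rows[keep_r]; changed <- TRUE }
    }
    if (length(rows) && length(cols)) {
      frac <- colSums(M[rows, cols, drop = FALSE]) / length(rows)
      if (any(frac > tau + 1e-12)) {
        cols <- cols[-which.max(frac)]
        changed <- TRUE
      }
    }
    if (!changed || !length(rows) || !length(cols)) break
  }
  list(rows = rows, cols = cols)
}

#' Select an optimal low-missingness subject/variable subset
#'
#' Maximizes the number of kept subjects plus kept variables subject to:
#' every kept subject has at least one non-missing value among the kept
#' variables, and every kept variable has a missing fraction (over kept
#' subjects) at most `tau`. Solved exactly by branch-and-bound enumeration
#' when the instance is small; otherwise by alternating row/column
#' elimination, whose solution the exact search always weakly dominates.
#'
#' @param table data.frame or matrix with missing values coded as the
#'   sentinel.
#' @param tau per-variable missing-fraction cap in [0, 1].
#' @param missing_sentinel missing-value code.
#' @param exact_limit enumerate exhaustively when
#'   `2^nrow * 2^ncol <= exact_limit`.
#' @return object of class `lp_selection`: `kept_subjects`, `kept_variables`
#'   (integer index sets), `tau`, `objective`.
#' @export
select_subset_lp <- function(table, tau, missing_sentinel = -2L,
                             exact_limit = 2^18) {
  if (tau < 0 || tau > 1) stop_field("tau", "must be in [0, 1]")
  M <- as.matrix(table) == missing_sentinel  # TRUE = missing
  n <- nrow(M); m <- ncol(M)
  if (!n || !m) stop("empty table", call. = FALSE)
  greedy <- lp_greedy(M, tau)
  best <- if (lp_feasible(M, greedy$rows, greedy$cols, tau)) greedy else list(rows = integer(0), cols = integer(0))
  if (2^n * 2^m <= exact_limit) {
    ## exhaustive over column subsets (decreasing size), exact row subproblem
    ## by enumeration with pruning against the incumbent
    col_subsets <- lapply(seq_len(2^m) - 1L, function(mask) which(bitwAnd(mask, 2^(seq_len(m) - 1L)) > 0))
    col_subsets <- col_subsets[order(-vapply(col_subsets, length, 1L))]
    for (cols in col_subsets) {
      if (!length(cols)) next
      if (length(cols) + n <= length(best$rows) + length(best$cols)) next
      cand <- which(rowSums(!M[, cols, drop = FALSE]) > 0)
      if (lp_feasible(M, cand, cols, tau)) {
        if (length(cand) + length(cols) > length(best$rows) + length(best$cols)) {
          best <- list(rows = cand, cols = cols)
        }
        next
      }
      ## enumerate row subsets of the candidates, largest first
      nr <- length(cand)
      if (!nr || nr > 16L) next
      bits <- 2^(seq_len(nr) - 1L)
      masks <- seq_len(2^nr) - 1L
      sizes <- vapply(masks, function(x) sum(bitwAnd(x, bits) > 0), numeric(1))
      for (mask in masks[order(-sizes)]) {
        rows <- cand[bitwAnd(mask, bits) > 0]
        if (length(rows) + length(cols) <= length(best$rows) + length(best$cols)) break
        if (lp_feasible(M, rows, cols, tau)) {
          best <- list(rows = rows, cols = cols)
          break
        }
      }
    }
  }
  if (!length(best$rows) || !length(best$cols)) {
    stop("no feasible nonempty selection", call. = FALSE)
  }
  structure(
    list(kept_subjects = sort(best$rows), kept_variables = sort(best$cols),
         tau = tau, objective = length(best$rows) + length(best$cols)),
    class = "lp_selection"
  )
}

#' @export
print.lp_selection <- function(x, ...) {
  cat(sprintf("<lp_selection> %d subjects + %d variables = %d (tau = %g)\n",
              length(x$kept_subjects), length(x$kept_variables), x$objective, x$tau))
  invisible(x)
}

#' Linkage-disequilibrium partners of candidate SNPs
#'
#' Genotype-correlation r-squared between each candidate SNP and every other
#' SNP within a base-pair window on the same chromosome, computed on
#' pairwise-complete subjects.
#'
#' @param g a [genotype_matrix].
#' @param candidate_snps rsIDs present in `g`.
#' @param window_bp search window around the candidate position.
#' @param r2_threshold report partners with r^2 at or above this value.
#' @return data.frame with columns `candidate`, `partner`, `r2`.
#' @export
ld_r2 <- function(g, candidate_snps, window_bp = 250000, r2_threshold = 0.8) {
  missing_cand <- setdiff(candidate_snps, g$map$rsid)
  if (length(missing_cand)) {
    stop(sprintf("candidate SNP(s) absent from matrix: %s",
                 paste(missing_cand, collapse = ", ")), call. = FALSE)
  }
  G <- g$genotypes
  G[G == g$missing_sentinel] <- NA_integer_
  out <- list()
  for (cand in candidate_snps) {
    ci <- match(cand, g$map$rsid)
    near <- which(g$map$chr == g$map$chr[ci] &
                    abs(g$map$pos - g$map$pos[ci]) <= window_bp &
                    seq_len(ncol(G)) != ci)
    for (j in near) {
      r <- suppressWarnings(stats::cor(G[, ci], G[, j],
                                       use = "pairwise.complete.obs"))
      if (!is.na(r) && r^2 >= r2_threshold) {
        out[[length(out) + 1L]] <- data.frame(
          candidate = cand, partner = g$map$rsid[j], r2 = r^2,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(out)) {
    return(data.frame(candidate = character(0), partner = character(0),
                      r2 = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
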