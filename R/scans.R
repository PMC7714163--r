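## Dependency scan orchestration.
##
## Every scan (i) computes its complete-case subject set first, so all
## tuples of a scan share one N, (ii) scores all tuples with the plug-in
## estimators, (iii) builds a pooled permutation null with the identical
## estimator, and (iv) reports rows ranked by p-value with deterministic
## tie-breaking (then |score| descending, then identifier).

#' Permutation-null configuration for scans
#'
#' @param n_shuffles number of shuffles (default 1000).
#' @param seed RNG seed for the shuffles.
#' @export
null_config <- function(n_shuffles = 1000, seed = 1L) {
  stopifnot(is_count(n_shuffles))
  list(n_shuffles = as.integer(n_shuffles), seed = as.integer(seed))
}

new_scan_result <- function(df, kind, n_subjects, null = NULL, extra = list()) {
  attr(df, "kind") <- kind
  attr(df, "n_subjects") <- n_subjects
  attr(df, "null") <- null
  for (nm in names(extra)) attr(df, nm) <- extra[[nm]]
  class(df) <- c("scan_result", "data.frame")
  df
}

#' @export
print.scan_result <- function(x, n = 10, ...) {
  cat(sprintf("<scan_result: %s> %d tuples, N = %d subjects\n",
              attr(x, "kind"), nrow(x), attr(x, "n_subjects")))
  print.data.frame(utils::head(x, n))
  if (nrow(x) > n) cat(sprintf("... %d more rows\n", nrow(x) - n))
  invisible(x)
}

rank_scan <- function(df, id_cols) {
  id <- do.call(paste, c(unname(df[id_cols]), sep = "\r"))
  df <- df[order(df$p_value, -abs(df$score), id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

## complete-case subject mask over one or more phenotype tables
complete_rows <- function(..., sentinel = -2L) {
  tabs <- list(...)
  masks <- lapply(tabs, function(tb) {
    if (is.null(tb)) return(NULL)
    Reduce(`&`, lapply(as.data.frame(tb), function(v) !is.na(v) & v != sentinel))
  })
  Reduce(`&`, Filter(Negate(is.null), masks))
}

## restrict genotypes to complete-case subjects and SNPs with no missing
## values there; returns the integer matrix + dropped SNP ids
complete_genotypes <- function(g, subject_mask) {
  G <- g$genotypes[subject_mask, , drop = FALSE]
  ok <- colSums(G == g$missing_sentinel) == 0L
  list(G = G[, ok, drop = FALSE], dropped = colnames(G)[!ok])
}

## fast MI between two integer code vectors (no missing)
mi_codes <- function(cx, cy, Lx, Ly, base = 2) {
  n <- length(cx)
  cnt <- tabulate((cx - 1L) * Ly + cy, Lx * Ly)
  (sum(xlogx(cnt)) - sum(xlogx(tabulate(cx, Lx))) -
     sum(xlogx(tabulate(cy, Ly))) + n * log(n)) / (n * log(base))
}

## delta scores of a coded triple (no missing); returns list like deltas()
delta_codes <- function(cx, cy, cz, Lx, Ly, Lz, base = 2) {
  n <- length(cx)
  h <- function(cnt) (n * log(n) - sum(xlogx(cnt))) / (n * log(base))
  hx <- h(tabulate(cx, Lx)); hy <- h(tabulate(cy, Ly)); hz <- h(tabulate(cz, Lz))
  hxy <- h(tabulate((cx - 1L) * Ly + cy, Lx * Ly))
  hxz <- h(tabulate((cx - 1L) * Lz + cz, Lx * Lz))
  hyz <- h(tabulate((cy - 1L) * Lz + cz, Ly * Lz))
  hxyz <- h(tabulate(((cx - 1L) * Ly + cy - 1L) * Lz + cz, Lx * Ly * Lz))
  i3 <- hx + hy + hz - hxy - hxz - hyz + hxyz
  list(i3 = i3,
       delta_x = i3 - (hy + hz - hyz),
       delta_y = i3 - (hx + hz - hxz),
       delta_z = i3 - (hx + hy - hxy),
       omega = hx + hy + hz - hxyz,
       mi_xy = hx + hy - hxy, mi_xz = hx + hz - hxz, mi_yz = hy + hz - hyz)
}

recode <- function(v) {
  lv <- sort(unique(v))
  list(codes = match(v, lv), L = length(lv))
}

#' Pairwise SNP-phenotype dependency scan
#'
#' Mutual information between every SNP and every phenotype on the shared
#' complete-case subject set, with pooled permutation p-values and FWER. The
#' permutation scheme shuffles the phenotype rows as a block, preserving all
#' linkage between SNPs (and between phenotypes).
#'
#' @param g a [genotype_matrix]; SNPs with missing values on the
#'   complete-case subjects are dropped (recorded in attribute
#'   `dropped_snps`).
#' @param phenotypes data.frame of integer-coded (discretized) phenotypes;
#'   missing as sentinel.
#' @param null_cfg a [null_config].
#' @param cutoff p-value cutoff used to set the `flagged` column (defaults to
#'   the Bayley-scan convention 2.7e-6; use 8e-6 for growth phenotypes).
#' @param base logarithm base for MI.
#' @return a `scan_result` data.frame: `snp`, `phenotype`, `score` (MI),
#'   `p_value`, `fwer`, `flagged`, sorted by p-value.
#' @export
scan_pairwise <- function(g, phenotypes, null_cfg = null_config(),
                          cutoff = 2.7e-6, base = 2) {
  phenotypes <- as.data.frame(phenotypes)
  mask <- complete_rows(phenotypes, sentinel = g$missing_sentinel)
  if (!any(mask)) stop("no complete-case subjects", call. = FALSE)
  cg <- complete_genotypes(g, mask)
  if (!ncol(cg$G)) stop("no SNPs without missing values", call. = FALSE)
  P <- phenotypes[mask, , drop = FALSE]
  n <- nrow(P)
  gi <- geno_indicators(cg$G)
  Ys <- lapply(P, function(v) {
    lv <- sort(unique(v))
    onehot(match(v, lv), length(lv))
  })
  obs <- vapply(Ys, function(Y) mi_profile_oh(gi, Y, base), numeric(ncol(cg$G)))
  if (is.null(dim(obs))) obs <- matrix(obs, nrow = ncol(cg$G))
  n_tuples <- length(obs)
  pooled <- numeric(null_cfg$n_shuffles * n_tuples)
  per_max <- numeric(null_cfg$n_shuffles)
  with_seed(null_cfg$seed, {
    for (s in seq_len(null_cfg$n_shuffles)) {
      perm <- sample.int(n)
      sc <- vapply(Ys, function(Y) mi_profile_oh(gi, Y[perm, , drop = FALSE], base),
                   numeric(ncol(cg$G)))
      pooled[(s - 1L) * n_tuples + seq_len(n_tuples)] <- sc
      per_max[s] <- max(abs(sc))
    }
  })
  null <- new_null_distribution(pooled, per_max, null_cfg$n_shuffles, n_tuples,
                                "permute_phenotype")
  df <- data.frame(
    snp = rep(colnames(cg$G), times = ncol(P)),
    phenotype = rep(names(P), each = ncol(cg$G)),
    score = as.vector(obs),
    stringsAsFactors = FALSE
  )
  df$p_value <- as.numeric(pooled_pvalue(df$score, null))
  df$fwer <- fwer(df$score, null)
  df$flagged <- df$p_value < cutoff
  df <- rank_scan(df, c("snp", "phenotype"))
  new_scan_result(df, "pairwise", n, null,
                  extra = list(dropped_snps = cg$dropped, cutoff = cutoff))
}

#' Phenotype-phenotype dependency scan
#'
#' Mutual information for every phenotype pair and the symmetric delta for
#' every phenotype triple over one table of discretized phenotypes
#' (neurodevelopmental composites and growth parameters alike). The null
#' permutes every column independently, breaking all links.
#'
#' @param phenotypes data.frame of integer-coded phenotypes.
#' @param null_cfg a [null_config].
#' @param base logarithm base.
#' @return list with `pairs` and `triples` scan_results.
#' @export
scan_phenotype_dependencies <- function(phenotypes, null_cfg = null_config(),
                                        base = 2) {
  phenotypes <- as.data.frame(phenotypes)
  mask <- complete_rows(phenotypes)
  P <- phenotypes[mask, , drop = FALSE]
  n <- nrow(P)
  if (!n) stop("no complete-case subjects", call. = FALSE)
  rc <- lapply(P, recode)
  nm <- names(P)
  k <- length(nm)
  pair_idx <- utils::combn(k, 2)
  trip_idx <- if (k >= 3) utils::combn(k, 3) else matrix(integer(0), 3, 0)
  score_pairs <- function(rc) {
    apply(pair_idx, 2, function(ij) {
      mi_codes(rc[[ij[1]]]$codes, rc[[ij[2]]]$codes,
               rc[[ij[1]]]$L, rc[[ij[2]]]$L, base)
    })
  }
  score_trips <- function(rc) {
    if (!ncol(trip_idx)) return(numeric(0))
    apply(trip_idx, 2, function(ijk) {
      d <- delta_codes(rc[[ijk[1]]]$codes, rc[[ijk[2]]]$codes, rc[[ijk[3]]]$codes,
                       rc[[ijk[1]]]$L, rc[[ijk[2]]]$L, rc[[ijk[3]]]$L, base)
      d$delta_x * d$delta_y * d$delta_z
    })
  }
  obs_p <- score_pairs(rc)
  obs_t <- score_trips(rc)
  np <- length(obs_p); nt <- length(obs_t)
  pooled_p <- numeric(null_cfg$n_shuffles * np)
  pooled_t <- numeric(null_cfg$n_shuffles * max(nt, 1))
  max_p <- numeric(null_cfg$n_shuffles); max_t <- numeric(null_cfg$n_shuffles)
  with_seed(null_cfg$seed, {
    for (s in seq_len(null_cfg$n_shuffles)) {
      rcs <- lapply(rc, function(x) list(codes = x$codes[sample.int(n)], L = x$L))
      sp <- score_pairs(rcs)
      pooled_p[(s - 1L) * np + seq_len(np)] <- sp
      max_p[s] <- max(abs(sp))
      if (nt) {
        st <- score_trips(rcs)
        pooled_t[(s - 1L) * nt + seq_len(nt)] <- st
        max_t[s] <- max(abs(st))
      }
    }
  })
  null_p <- new_null_distribution(pooled_p, max_p, null_cfg$n_shuffles, np,
                                  "permute_each_column")
  dfp <- data.frame(var1 = nm[pair_idx[1, ]], var2 = nm[pair_idx[2, ]],
                    score = obs_p, stringsAsFactors = FALSE)
  dfp$p_value <- as.numeric(pooled_pvalue(dfp$score, null_p))
  dfp$fwer <- fwer(dfp$score, null_p)
  pairs <- new_scan_result(rank_scan(dfp, c("var1", "var2")),
                           "phenotype_pairs", n, null_p)
  triples <- NULL
  if (nt) {
    null_t <- new_null_distribution(pooled_t, max_t, null_cfg$n_shuffles, nt,
                                    "permute_each_column")
    dft <- data.frame(var1 = nm[trip_idx[1, ]], var2 = nm[trip_idx[2, ]],
                      var3 = nm[trip_idx[3, ]], score = obs_t,
                      stringsAsFactors = FALSE)
    dft$p_value <- as.numeric(pooled_pvalue(dft$score, null_t))
    dft$fwer <- fwer(dft$score, null_t)
    triples <- new_scan_result(rank_scan(dft, c("var1", "var2", "var3")),
                               "phenotype_triples", n, null_t)
  }
  list(pairs = pairs, triples = triples)
}

## shared engine for the three-way SNP x phenotype x phenotype scans
threeway_engine <- function(g, bayley, growth, null_cfg, base, score_pick) {
  bayley <- as.data.frame(bayley); growth <- as.data.frame(growth)
  if (length(intersect(names(bayley), names(growth)))) {
    stop("phenotype sets overlap", call. = FALSE)
  }
  mask <- complete_rows(bayley, growth, sentinel = g$missing_sentinel)
  if (!any(mask)) stop("no complete-case subjects", call. = FALSE)
  cg <- complete_genotypes(g, mask)
  if (!ncol(cg$G)) stop("no SNPs without missing values", call. = FALSE)
  B <- bayley[mask, , drop = FALSE]; R <- growth[mask, , drop = FALSE]
  n <- nrow(B)
  gi <- geno_indicators(cg$G)
  oh <- function(v) { lv <- sort(unique(v)); onehot(match(v, lv), length(lv)) }
  YB <- lapply(B, oh); YR <- lapply(R, oh)
  S <- ncol(cg$G)
  grid <- expand.grid(b = seq_along(YB), r = seq_along(YR))
  score_all <- function(permB = NULL, permR = NULL) {
    out <- matrix(0, S, nrow(grid))
    for (q in seq_len(nrow(grid))) {
      Y1 <- YB[[grid$b[q]]]; Y2 <- YR[[grid$r[q]]]
      if (!is.null(permB)) Y1 <- Y1[permB, , drop = FALSE]
      if (!is.null(permR)) Y2 <- Y2[permR, , drop = FALSE]
      out[, q] <- score_pick(delta_profile_oh(gi, Y1, Y2, base))
    }
    out
  }
  obs <- score_all()
  n_tuples <- length(obs)
  pooled <- numeric(null_cfg$n_shuffles * n_tuples)
  per_max <- numeric(null_cfg$n_shuffles)
  with_seed(null_cfg$seed, {
    for (s in seq_len(null_cfg$n_shuffles)) {
      sc <- score_all(sample.int(n), sample.int(n))
      pooled[(s - 1L) * n_tuples + seq_len(n_tuples)] <- sc
      per_max[s] <- max(abs(sc))
    }
  })
  null <- new_null_distribution(pooled, per_max, null_cfg$n_shuffles, n_tuples,
                                "permute_both_phenotypes_independently")
  df <- data.frame(
    snp = rep(colnames(cg$G), times = nrow(grid)),
    bayley_phenotype = rep(names(B)[grid$b], each = S),
    growth_phenotype = rep(names(R)[grid$r], each = S),
    score = as.vector(obs),
    stringsAsFactors = FALSE
  )
  df$p_value <- as.numeric(pooled_pvalue(df$score, null))
  df$fwer <- fwer(df$score, null)
  list(df = df, null = null, n = n, dropped = cg$dropped)
}

#' Three-way pleiotropy scan (SNP x Bayley x growth)
#'
#' Symmetric delta for every (SNP, Bayley phenotype, growth phenotype)
#' triple. The permutation null permutes the Bayley block and the growth
#' block independently, breaking genotype-phenotype and
#' phenotype-phenotype links while preserving SNP linkage. Scores are ranked
#' by |delta_sym|.
#'
#' @inheritParams scan_pairwise
#' @param bayley,growth disjoint data.frames of discretized phenotypes.
#' @param cutoff report threshold on the pooled p-value (default 3.2e-6).
#' @param pairwise optional pairwise `scan_result` for the same cohort; adds
#'   a `pairwise_significant` column marking SNPs that any pairwise tuple
#'   flags below `pairwise_cutoff` (pleiotropic candidates are typically NOT
#'   found by any pairwise dependence).
#' @param pairwise_cutoff cutoff used with `pairwise` (default 2.7e-6).
#' @return a `scan_result`: `snp`, `bayley_phenotype`, `growth_phenotype`,
#'   `score` (delta_sym, bits^3), `p_value`, `fwer`, `flagged`.
#' @export
scan_threeway <- function(g, bayley, growth, null_cfg = null_config(),
                          cutoff = 3.2e-6, pairwise = NULL,
                          pairwise_cutoff = 2.7e-6, base = 2) {
  eng <- threeway_engine(g, bayley, growth, null_cfg, base,
                         function(d) d$delta_sym)
  df <- eng$df
  df$flagged <- df$p_value < cutoff
  if (!is.null(pairwise)) {
    sig_snps <- unique(pairwise$snp[pairwise$p_value < pairwise_cutoff])
    df$pairwise_significant <- df$snp %in% sig_snps
  }
  df <- rank_scan(df, c("snp", "bayley_phenotype", "growth_phenotype"))
  new_scan_result(df, "threeway", eng$n, eng$null,
                  extra = list(dropped_snps = eng$dropped, cutoff = cutoff))
}

#' Asymmetric-delta scan
#'
#' Ranks (SNP, Bayley, growth) triples by one asymmetric delta: the delta
#' specific to the growth phenotype, the Bayley phenotype, or the SNP. Each
#' target gets its own permutation null under the same two-block scheme as
#' the symmetric scan.
#'
#' @inheritParams scan_threeway
#' @param target which variable's asymmetric delta to score.
#' @export
scan_asymmetric <- function(g, bayley, growth,
                            target = c("growth", "bayley", "snp"),
                            null_cfg = null_config(), base = 2) {
  target <- match.arg(target)
  pick <- switch(target,
                 snp = function(d) d$delta_snp,
                 bayley = function(d) d$delta_y1,
                 growth = function(d) d$delta_y2)
  eng <- threeway_engine(g, bayley, growth, null_cfg, base, pick)
  df <- rank_scan(eng$df, c("snp", "bayley_phenotype", "growth_phenotype"))
  new_scan_result(df, paste0("asymmetric_", target), eng$n, eng$null,
                  extra = list(dropped_snps = eng$dropped))
}

#' SNP-SNP interaction scan
#'
#' Symmetric delta over (anchor SNP, partner SNP, phenotype) triples for each
#' anchor locus already implicated by a single-locus effect, against all
#' other SNPs. The null permutes the phenotype only, preserving all SNP-SNP
#' linkage.
#'
#' @inheritParams scan_pairwise
#' @param anchor_snps rsIDs of implicated loci present in `g`.
#' @param phenotype single integer-coded phenotype vector (or one-column
#'   data.frame).
#' @return a `scan_result`: `anchor`, `partner`, `score` (delta_sym),
#'   `p_value`, `fwer`.
#' @export
scan_snp_interaction <- function(g, anchor_snps, phenotype,
                                 null_cfg = null_config(), base = 2) {
  if (is.data.frame(phenotype)) phenotype <- phenotype[[1]]
  missing_anchor <- setdiff(anchor_snps, g$map$rsid)
  if (length(missing_anchor)) {
    stop(sprintf("anchor(s) absent from matrix: %s",
                 paste(missing_anchor, collapse = ", ")), call. = FALSE)
  }
  mask <- !is.na(phenotype) & phenotype != g$missing_sentinel
  cg <- complete_genotypes(g, mask)
  keep_snps <- colnames(cg$G)
  anchors <- intersect(anchor_snps, keep_snps)
  if (!length(anchors)) stop("no anchor survives complete-case filtering", call. = FALSE)
  y <- phenotype[mask]
  n <- length(y)
  ly <- sort(unique(y)); Y <- onehot(match(y, ly), length(ly))
  obs_list <- list(); id_list <- list()
  gis <- list()
  for (a in anchors) {
    others <- setdiff(keep_snps, a)
    gi <- geno_indicators(cg$G[, others, drop = FALSE])
    av <- cg$G[, a]
    la <- sort(unique(av)); A <- onehot(match(av, la), length(la))
    gis[[a]] <- list(gi = gi, A = A, others = others)
    d <- delta_profile_oh(gi, A, Y, base)
    obs_list[[a]] <- d$delta_sym
    id_list[[a]] <- others
  }
  obs <- unlist(obs_list, use.names = FALSE)
  n_tuples <- length(obs)
  pooled <- numeric(null_cfg$n_shuffles * n_tuples)
  per_max <- numeric(null_cfg$n_shuffles)
  with_seed(null_cfg$seed, {
    for (s in seq_len(null_cfg$n_shuffles)) {
      Yp <- Y[sample.int(n), , drop = FALSE]
      sc <- unlist(lapply(gis, function(x) {
        delta_profile_oh(x$gi, x$A, Yp, base)$delta_sym
      }), use.names = FALSE)
      pooled[(s - 1L) * n_tuples + seq_len(n_tuples)] <- sc
      per_max[s] <- max(abs(sc))
    }
  })
  null <- new_null_distribution(pooled, per_max, null_cfg$n_shuffles, n_tuples,
                                "permute_phenotype")
  df <- data.frame(
    anchor = rep(anchors, times = vapply(id_list, length, 1L)),
    partner = unlist(id_list, use.names = FALSE),
    score = obs, stringsAsFactors = FALSE
  )
  df$p_value <- as.numeric(pooled_pvalue(df$score, null))
  df$fwer <- fwer(df$score, null)
  df <- rank_scan(df, c("anchor", "partner"))
  new_scan_result(df, "snp_interaction", n, null,
                  extra = list(dropped_snps = cg$dropped))
}

#' Sex-stratified X/Y scans
#'
#' Runs the pairwise and three-way scans separately within each sex on the
#' X/Y (incl. pseudoautosomal) SNP matrix: male haploid coding and female
#' diploid coding are never mixed in one scan, and each stratum reports its
#' own complete-case N.
#'
#' @inheritParams scan_threeway
#' @param g_xy the sex-chromosome [genotype_matrix] (e.g. the `xy` element of
#'   [preprocess_genotypes()]); its `subjects` metadata must carry `sex`.
#' @param sex optional explicit sex labels (`"male"`/`"female"`), overriding
#'   `g_xy$subjects$sex`.
#' @return a `scan_result` with columns `sex`, `kind`, `snp`,
#'   `bayley_phenotype`, `growth_phenotype`, `score`, `p_value`, `fwer`, `n`.
#' @export
scan_sex_stratified <- function(g_xy, bayley, growth, sex = NULL,
                                null_cfg = null_config(), base = 2) {
  sex <- sex %||% g_xy$subjects$sex
  if (is.null(sex)) stop("sex labels required", call. = FALSE)
  out <- list()
  for (sx in c("male", "female")) {
    rows <- which(sex == sx)
    if (!length(rows)) stop(sprintf("empty sex stratum: %s", sx), call. = FALSE)
    gs <- subset_genotypes(g_xy, subjects = rows)
    bs <- as.data.frame(bayley)[rows, , drop = FALSE]
    rs <- as.data.frame(growth)[rows, , drop = FALSE]
    pw <- scan_pairwise(gs, cbind(bs, rs), null_cfg = null_cfg, base = base)
    in_b <- pw$phenotype %in% names(bs)
    pw_df <- data.frame(
      sex = sx, kind = "pairwise", snp = pw$snp,
      bayley_phenotype = ifelse(in_b, pw$phenotype, NA_character_),
      growth_phenotype = ifelse(in_b, NA_character_, pw$phenotype),
      score = pw$score, p_value = pw$p_value, fwer = pw$fwer,
      n = attr(pw, "n_subjects"), stringsAsFactors = FALSE
    )
    tw <- scan_threeway(gs, bs, rs, null_cfg = null_cfg, base = base)
    tw_df <- data.frame(
      sex = sx, kind = "threeway", snp = tw$snp,
      bayley_phenotype = tw$bayley_phenotype,
      growth_phenotype = tw$growth_phenotype,
      score = tw$score, p_value = tw$p_value, fwer = tw$fwer,
      n = attr(tw, "n_subjects"), stringsAsFactors = FALSE
    )
    out[[sx]] <- rbind(pw_df, tw_df)
  }
  df <- do.call(rbind, out)
  df <- df[order(df$p_value, -abs(df$score), df$snp), , drop = FALSE]
  rownames(df) <- NULL
  new_scan_result(df, "sex_stratified", NA_integer_)
}

#' Annotate scan results with the nearest gene
#'
#' Adds a `gene` column by nearest midpoint distance using a user-supplied
#' gene BED file (chrom, start, end, name). SNPs on chromosomes absent from
#' the BED get an empty label. Requires the optional \pkg{rtracklayer} /
#' \pkg{GenomicRanges} packages.
#'
#' @param result a `scan_result` with an `snp` column.
#' @param g the [genotype_matrix] the scan used (for SNP positions).
#' @param gene_bed path to a BED file of gene spans.
#' @export
annotate_nearest_gene <- function(result, g, gene_bed) {
  if (!requireNamespace("rtracklayer", quietly = TRUE) ||
      !requireNamespace("GenomicRanges", quietly = TRUE)) {
    stop("gene annotation requires rtracklayer and GenomicRanges", call. = FALSE)
  }
  genes <- rtracklayer::import(gene_bed, format = "BED")
  mid <- (GenomicRanges::start(genes) + GenomicRanges::end(genes)) / 2
  gene_chr <- as.character(GenomicRanges::seqnames(genes))
  gene_name <- genes$name
  idx <- match(result$snp, g$map$rsid)
  result$gene <- vapply(seq_along(idx), function(k) {
    i <- idx[k]
    if (is.na(i)) return("")
    sel <- gene_chr == as.character(g$map$chr[i])
    if (!any(sel)) return("")
    j <- which.min(abs(mid[sel] - g$map$pos[i]))
    gene_name[sel][j]
  }, "")
  result
}
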