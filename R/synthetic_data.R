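## Synthetic cohort generator.
##
## Downstream stages (preprocessing, growth modelling, dependency scans,
## permutation significance) are exercised on generated cohorts that emulate
## the statistical structure the analysis assumes: biallelic SNPs in
## Hardy-Weinberg equilibrium with group-specific allele frequencies across
## two ethnicity groups, haploid-coded sex-chromosome SNPs in males,
## Bayley-like ordinal composites, Gompertz-type growth trajectories, uniform
## missingness, and (optionally) planted additive pairwise and XOR-style
## pleiotropic effects.

#' Specification of a synthetic cohort
#'
#' @param n_subjects number of subjects.
#' @param n_snps number of SNPs.
#' @param maf_range minor-allele-frequency range, within (0, 0.5]; per-SNP
#'   MAFs are drawn uniformly from this interval.
#' @param ethnicity_fractions proportions of the two ethnicity groups; must
#'   sum to 1.
#' @param ethnicity_af_delta allele-frequency offset between the two groups
#'   applied to each confounded SNP (group 1 gets +delta/2, group 2 -delta/2,
#'   clamped to (0.01, 0.99)).
#' @param confounded_fraction fraction of autosomal SNPs carrying the
#'   group-specific allele-frequency offset.
#' @param ethnicity_pheno_shift group-level mean shift (in latent-score SD
#'   units) added to numeric phenotypes of group 1; 0 (default) yields a
#'   cohort with no genotype-phenotype dependence, the global-null world used
#'   for calibration.
#' @param missing_rate per-entry genotype missingness probability in [0, 1).
#' @param sex_fraction_male fraction of male subjects.
#' @param x_snp_fraction fraction of SNPs placed on the X chromosome (coded
#'   haploid {0, 2} in males).
#' @param seed RNG seed; a fixed seed makes every generator byte-identical.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 1000, n_snps = 5000,
                        maf_range = c(0.05, 0.5),
                        ethnicity_fractions = c(0.6, 0.4),
                        ethnicity_af_delta = 0.1,
                        confounded_fraction = 0,
                        ethnicity_pheno_shift = 0,
                        missing_rate = 0.05,
                        sex_fraction_male = 0.5,
                        x_snp_fraction = 0.03,
                        seed = 1L) {
  if (!is_count(n_subjects)) stop_field("n_subjects", "must be a positive integer")
  if (!is_count(n_snps)) stop_field("n_snps", "must be a positive integer")
  if (length(maf_range) != 2 || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2]) {
    stop_field("maf_range", "must be an increasing pair within (0, 0.5]")
  }
  if (length(ethnicity_fractions) != 2 || any(ethnicity_fractions < 0) ||
      abs(sum(ethnicity_fractions) - 1) > 1e-9) {
    stop_field("ethnicity_fractions", "must be 2 proportions summing to 1")
  }
  if (ethnicity_af_delta < 0 || ethnicity_af_delta >= 1) {
    stop_field("ethnicity_af_delta", "must be in [0, 1)")
  }
  if (confounded_fraction < 0 || confounded_fraction > 1) {
    stop_field("confounded_fraction", "must be in [0, 1]")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop_field("missing_rate", "must be in [0, 1)")
  }
  if (sex_fraction_male < 0 || sex_fraction_male > 1) {
    stop_field("sex_fraction_male", "must be in [0, 1]")
  }
  if (x_snp_fraction < 0 || x_snp_fraction > 1) {
    stop_field("x_snp_fraction", "must be in [0, 1]")
  }
  structure(
    list(n_subjects = as.integer(n_subjects), n_snps = as.integer(n_snps),
         maf_range = maf_range, ethnicity_fractions = ethnicity_fractions,
         ethnicity_af_delta = ethnicity_af_delta,
         confounded_fraction = confounded_fraction,
         ethnicity_pheno_shift = ethnicity_pheno_shift,
         missing_rate = missing_rate,
         sex_fraction_male = sex_fraction_male,
         x_snp_fraction = x_snp_fraction, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' A planted genotype-phenotype effect
#'
#' @param kind `"additive_pairwise"` (one phenotype, mean shifted by
#'   minor-allele count), `"xor_pleiotropic"` (two phenotypes tied to a
#'   dichotomized SNP through a noisy XOR with null pairwise marginals), or
#'   `"null"`.
#' @param snp_index column index of the target SNP.
#' @param phenotype_names one name (additive) or exactly two (XOR).
#' @param effect_size shift per minor allele (additive, latent-SD units) or
#'   penetrance in [0, 1] (XOR).
#' @export
planted_effect <- function(kind = c("additive_pairwise", "xor_pleiotropic", "null"),
                           snp_index, phenotype_names, effect_size) {
  kind <- match.arg(kind)
  n_ph <- length(phenotype_names)
  if (kind == "additive_pairwise" && n_ph != 1L) {
    stop_field("phenotype_names", "additive_pairwise names exactly 1 phenotype")
  }
  if (kind == "xor_pleiotropic" && n_ph != 2L) {
    stop_field("phenotype_names", "xor_pleiotropic names exactly 2 phenotypes")
  }
  if (kind == "xor_pleiotropic" && (effect_size < 0 || effect_size > 1)) {
    stop_field("effect_size", "XOR penetrance must be in [0, 1]")
  }
  structure(list(kind = kind, snp_index = as.integer(snp_index),
                 phenotype_names = phenotype_names, effect_size = effect_size),
            class = "planted_effect")
}

#' Genotype matrix with SNP map
#'
#' @param genotypes integer matrix, subjects x SNPs, coded 0/1/2 minor-allele
#'   counts with -2 for missing.
#' @param map data.frame with columns `rsid`, `chr`, `pos`, `major`, `minor`
#'   (one row per SNP, hg19-style 1-based positions).
#' @param subjects optional data.frame with `subject_id`, `sex`, `ethnicity`.
#' @export
genotype_matrix <- function(genotypes, map, subjects = NULL) {
  genotypes <- as.matrix(genotypes)
  bad <- setdiff(unique(as.vector(genotypes)), c(-2L, 0L, 1L, 2L))
  if (length(bad)) {
    stop(sprintf("unknown genotype code(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  storage.mode(genotypes) <- "integer"
  if (nrow(map) != ncol(genotypes)) stop("map rows must match SNP columns", call. = FALSE)
  need <- c("rsid", "chr", "pos", "major", "minor")
  if (!all(need %in% names(map))) {
    stop(sprintf("map must contain columns: %s", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  colnames(genotypes) <- map$rsid
  if (!is.null(subjects)) rownames(genotypes) <- subjects$subject_id
  structure(list(genotypes = genotypes, map = map, subjects = subjects,
                 missing_sentinel = -2L),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d subjects x %d SNPs (%.1f%% missing)\n",
              nrow(x$genotypes), ncol(x$genotypes),
              100 * mean(x$genotypes == x$missing_sentinel)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$genotypes)

subset_genotypes <- function(g, subjects = NULL, snps = NULL) {
  gm <- g$genotypes
  map <- g$map
  sub <- g$subjects
  if (!is.null(snps)) {
    gm <- gm[, snps, drop = FALSE]
    map <- map[snps, , drop = FALSE]
  }
  if (!is.null(subjects)) {
    gm <- gm[subjects, , drop = FALSE]
    if (!is.null(sub)) sub <- sub[subjects, , drop = FALSE]
  }
  genotype_matrix(gm, map, sub)
}

#' Simulate a genotype matrix under Hardy-Weinberg equilibrium
#'
#' Each autosomal SNP draws genotypes as Binomial(2, f) minor-allele counts at
#' its (possibly ethnicity-specific) allele frequency f; X-chromosome SNPs are
#' haploid-coded {0, 2} in males. Missing entries are set to the sentinel -2
#' uniformly at `missing_rate`. The SNP map carries synthetic rsIDs, 1-based
#' positions, and chromosome labels (X SNPs flagged).
#'
#' @param spec a [cohort_spec].
#' @return a [genotype_matrix]; its `map` has a logical column `sex_linked`
#'   and `confounded`, and `subjects` holds sex and ethnicity labels.
#' @export
simulate_genotypes <- function(spec) {
  if (!inherits(spec, "cohort_spec")) stop("`spec` must be a cohort_spec", call. = FALSE)
  with_seed(spec$seed, {
    n <- spec$n_subjects; S <- spec$n_snps
    sex <- ifelse(stats::runif(n) < spec$sex_fraction_male, "male", "female")
    eth <- ifelse(stats::runif(n) < spec$ethnicity_fractions[1], 1L, 2L)
    maf <- stats::runif(S, spec$maf_range[1], spec$maf_range[2])
    n_x <- round(spec$x_snp_fraction * S)
    is_x <- c(rep(TRUE, n_x), rep(FALSE, S - n_x))
    n_conf <- round(spec$confounded_fraction * (S - n_x))
    confounded <- !is_x & (cumsum(!is_x) <= n_conf)
    f1 <- pmin(pmax(maf + ifelse(confounded, spec$ethnicity_af_delta / 2, 0), 0.01), 0.99)
    f2 <- pmin(pmax(maf - ifelse(confounded, spec$ethnicity_af_delta / 2, 0), 0.01), 0.99)
    ## per-subject allele frequency: group 1 uses f1, group 2 uses f2
    G <- matrix(0L, n, S)
    for (grp in 1:2) {
      rows <- which(eth == grp)
      if (!length(rows)) next
      f <- if (grp == 1) f1 else f2
      draw <- matrix(
        stats::rbinom(length(rows) * S, 2L, rep(f, each = length(rows))),
        nrow = length(rows)
      )
      G[rows, ] <- draw
    }
    ## X SNPs: males haploid, coded 0 or 2 by a single allele draw
    if (n_x > 0) {
      males <- which(sex == "male")
      if (length(males)) {
        for (grp in 1:2) {
          rows <- intersect(males, which(eth == grp))
          if (!length(rows)) next
          f <- if (grp == 1) f1[is_x] else f2[is_x]
          hap <- matrix(
            stats::rbinom(length(rows) * n_x, 1L, rep(f, each = length(rows))),
            nrow = length(rows)
          )
          G[rows, which(is_x)] <- 2L * hap
        }
      }
    }
    if (spec$missing_rate > 0) {
      G[stats::runif(length(G)) < spec$missing_rate] <- -2L
    }
    chr <- ifelse(is_x, "X", as.character(1L + (seq_len(S) %% 22L)))
    bases <- c("A", "C", "G", "T")
    major <- sample(bases, S, replace = TRUE)
    minor <- vapply(major, function(b) sample(setdiff(bases, b), 1L), "")
    map <- data.frame(
      rsid = sprintf("rs%07d", seq_len(S)),
      chr = chr,
      pos = as.integer(seq_len(S) * 1000L + sample(0:999, S, replace = TRUE)),
      major = major, minor = minor,
      maf = maf, sex_linked = is_x, confounded = confounded,
      stringsAsFactors = FALSE
    )
    subjects <- data.frame(
      subject_id = sprintf("S%04d", seq_len(n)),
      sex = sex, ethnicity = eth, stringsAsFactors = FALSE
    )
    genotype_matrix(G, map, subjects)
  })
}

#' Simulate correlated Bayley-like ordinal composites
#'
#' Five (by default) ordinal scales generated from an equicorrelated Gaussian
#' copula and cut into equiprobable levels. The continuous latent scores are
#' kept as attribute `"latent"` so effects can be planted on the numeric scale
#' before binning.
#'
#' @param n_subjects number of subjects.
#' @param n_scales number of composite scales.
#' @param n_levels ordinal alphabet size per scale.
#' @param rho latent inter-scale correlation in [0, 1).
#' @param seed RNG seed.
#' @param scale_names optional column names.
#' @return data.frame of integer codes 1..n_levels with attribute `latent`
#'   (numeric matrix of the underlying scores).
#' @export
simulate_bayley <- function(n_subjects, n_scales = 5, n_levels = 4, rho = 0.3,
                            seed = 1L, scale_names = NULL) {
  if (rho < 0 || rho > 1) stop_field("rho", "must be in [0, 1]")
  with_seed(seed, {
    common <- stats::rnorm(n_subjects)
    lat <- sqrt(rho) * matrix(common, n_subjects, n_scales) +
      sqrt(1 - rho) * matrix(stats::rnorm(n_subjects * n_scales), n_subjects)
    cuts <- stats::qnorm(seq_len(n_levels - 1) / n_levels)
    codes <- apply(lat, 2, function(v) findInterval(v, cuts) + 1L)
    nm <- scale_names %||%
      c("Cognitive", "Language", "Motor", "Adaptive", "SocialEmotional",
        sprintf("Scale%02d", seq_len(max(0, n_scales - 5)) + 5L))[seq_len(n_scales)]
    out <- as.data.frame(codes)
    names(out) <- nm
    colnames(lat) <- nm
    attr(out, "latent") <- lat
    out
  })
}

#' Plant an additive pairwise SNP effect on a numeric phenotype
#'
#' Shifts the named numeric phenotype by `effect_size` times the minor-allele
#' count, before any discretization. Subjects with a missing genotype are left
#' unshifted. `effect_size = 0` returns the input untouched.
#'
#' @param g a [genotype_matrix].
#' @param pheno data.frame with at least one numeric column, or a discrete
#'   table carrying a `"latent"` attribute (as produced by
#'   [simulate_bayley()]), in which case the latent matrix is shifted and
#'   re-binned into the same number of levels.
#' @param effect a [planted_effect] of kind `"additive_pairwise"`.
#' @export
plant_additive_effect <- function(g, pheno, effect) {
  stopifnot(inherits(effect, "planted_effect"))
  if (effect$kind != "additive_pairwise") stop("effect kind must be additive_pairwise", call. = FALSE)
  nm <- effect$phenotype_names
  lat <- attr(pheno, "latent")
  if (!nm %in% names(pheno) && !(!is.null(lat) && nm %in% colnames(lat))) {
    stop(sprintf("unknown phenotype name: %s", nm), call. = FALSE)
  }
  if (effect$effect_size == 0) return(pheno)
  geno <- g$genotypes[, effect$snp_index]
  dose <- ifelse(geno == g$missing_sentinel, 0, geno)
  if (!is.null(lat) && nm %in% colnames(lat)) {
    ## shift on the latent scale, re-bin into equiprobable levels
    n_levels <- max(pheno[[nm]])
    lat[, nm] <- lat[, nm] + effect$effect_size * dose
    cuts <- stats::quantile(lat[, nm], probs = seq_len(n_levels - 1) / n_levels)
    pheno[[nm]] <- findInterval(lat[, nm], cuts) + 1L
    attr(pheno, "latent") <- lat
    pheno
  } else if (is.numeric(pheno[[nm]])) {
    pheno[[nm]] <- pheno[[nm]] + effect$effect_size * dose
    pheno
  } else {
    stop(sprintf("phenotype `%s` is not numeric and has no latent scores", nm),
         call. = FALSE)
  }
}

#' Exact noisy-XOR joint distribution
#'
#' The exact 2x2x2 joint of (dichotomized SNP, phenotype 1, phenotype 2) under
#' the planted pleiotropy construction: P1 ~ Bernoulli(q_p1) independent of
#' the SNP indicator D ~ Bernoulli(q_snp); with probability `penetrance`,
#' P2 = P1 XOR D, otherwise P2 ~ Bernoulli(1/2) independently. At penetrance
#' 1 with P1 balanced, both genotype-phenotype pairs carry exactly zero
#' mutual information for any q_snp; with uniform inputs (q_snp = 1/2) all
#' three pairwise MIs vanish and the symmetric delta is -1 bit^3.
#'
#' @param penetrance XOR penetrance in [0, 1].
#' @param q_snp P(D = 1).
#' @param q_p1 P(P1 = 1).
#' @return a three-variable [joint_distribution] in (D, P1, P2) order.
#' @export
xor_joint_distribution <- function(penetrance = 1, q_snp = 0.5, q_p1 = 0.5) {
  if (penetrance < 0 || penetrance > 1) stop_field("penetrance", "must be in [0, 1]")
  p <- array(0, c(2, 2, 2))
  for (d in 0:1) for (a in 0:1) for (b in 0:1) {
    pd <- ifelse(d == 1, q_snp, 1 - q_snp)
    pa <- ifelse(a == 1, q_p1, 1 - q_p1)
    pb <- penetrance * as.numeric(b == bitwXor(a, d)) + (1 - penetrance) * 0.5
    p[d + 1, a + 1, b + 1] <- pd * pa * pb
  }
  joint_distribution(p)
}

#' Plant an XOR-style pleiotropic effect
#'
#' Rewires two binary (or binarized) phenotypes so that their joint
#' distribution with the dichotomized SNP ({0} vs {1, 2} minor-allele count)
#' follows a noisy XOR with the given penetrance: the first phenotype is kept
#' (binarized) and, with probability `effect_size`, the second is set to
#' `P1 XOR D`; otherwise it is redrawn as a fair coin. The construction leaves
#' all three pairwise dependencies null (exactly so at penetrance 1 when P1 is
#' balanced) while creating a strong three-way dependence.
#'
#' @inheritParams plant_additive_effect
#' @param effect a [planted_effect] of kind `"xor_pleiotropic"`; its
#'   `effect_size` is the penetrance.
#' @param seed RNG seed for the noisy branch.
#' @return `pheno` with the two named columns binary-coded 0/1.
#' @export
plant_xor_pleiotropy <- function(g, pheno, effect, seed = 1L) {
  stopifnot(inherits(effect, "planted_effect"))
  if (effect$kind != "xor_pleiotropic") stop("effect kind must be xor_pleiotropic", call. = FALSE)
  nms <- effect$phenotype_names
  if (!all(nms %in% names(pheno))) {
    stop(sprintf("unknown phenotype name(s): %s",
                 paste(setdiff(nms, names(pheno)), collapse = ", ")), call. = FALSE)
  }
  geno <- g$genotypes[, effect$snp_index]
  if (any(geno == g$missing_sentinel)) {
    ## dichotomization needs observed genotypes; missing entries propagate
    d <- ifelse(geno == g$missing_sentinel, NA_integer_, as.integer(geno > 0))
  } else {
    d <- as.integer(geno > 0)
  }
  binarize <- function(v, nm) {
    u <- sort(unique(v[!is.na(v) & v != -2L]))
    if (length(u) == 2L) return(as.integer(v == u[2]))
    if (is.numeric(v) && length(u) > 2L) {
      ## cut at the value giving the most balanced split (null pairwise
      ## marginals of the XOR construction need P(p1 = 1) close to 1/2)
      frac_above <- vapply(u, function(c) mean(v > c, na.rm = TRUE), 1)
      cut <- u[which.min(abs(frac_above - 0.5))]
      return(as.integer(v > cut))
    }
    stop(sprintf("phenotype `%s` is not reducible to binary", nm), call. = FALSE)
  }
  p1 <- binarize(pheno[[nms[1]]], nms[1])
  with_seed(seed, {
    n <- length(p1)
    noisy <- stats::runif(n) >= effect$effect_size
    p2 <- ifelse(noisy, stats::rbinom(n, 1L, 0.5), bitwXor(p1, d))
    p2[is.na(d) & !noisy] <- -2L
    pheno[[nms[1]]] <- p1
    pheno[[nms[2]]] <- as.integer(p2)
  })
  pheno
}

#' Simulate a full cohort
#'
#' Convenience wrapper producing every substrate the pipeline consumes:
#' genotypes, discrete Bayley-like phenotypes, numeric growth phenotypes
#' (true per-subject Gompertz deviations), and subject metadata. Planted
#' effects are applied in order.
#'
#' @param spec a [cohort_spec].
#' @param effects list of [planted_effect]s.
#' @param growth_params a [growth_population_params] for the growth
#'   phenotype deviations.
#' @param n_levels Bayley ordinal alphabet size.
#' @param rho latent Bayley inter-scale correlation.
#' @return list with `genotypes` ([genotype_matrix]), `bayley` (discrete
#'   data.frame), `growth` (numeric data.frame linf/alpha/lambda),
#'   `growth_discrete` (4-bin codes), `subjects`.
#' @export
simulate_cohort <- function(spec, effects = list(),
                            growth_params = growth_population_params(),
                            n_levels = 4, rho = 0.3) {
  g <- simulate_genotypes(spec)
  bay <- simulate_bayley(spec$n_subjects, n_levels = n_levels, rho = rho,
                         seed = spec$seed + 1L)
  grow <- with_seed(spec$seed + 2L, {
    data.frame(
      linf = growth_params$linf + stats::rnorm(spec$n_subjects, 0, sqrt(growth_params$var_linf)),
      alpha = growth_params$alpha + stats::rnorm(spec$n_subjects, 0, sqrt(growth_params$var_alpha)),
      lambda = growth_params$lambda + stats::rnorm(spec$n_subjects, 0, sqrt(growth_params$var_lambda))
    )
  })
  if (spec$ethnicity_pheno_shift != 0) {
    shift <- ifelse(g$subjects$ethnicity == 1L, spec$ethnicity_pheno_shift, 0)
    lat <- attr(bay, "latent")
    lat <- lat + shift
    cuts <- stats::qnorm(seq_len(n_levels - 1) / n_levels)
    for (j in seq_along(bay)) bay[[j]] <- findInterval(lat[, j], cuts) + 1L
    attr(bay, "latent") <- lat
    grow$linf <- grow$linf + shift * sqrt(growth_params$var_linf)
  }
  for (ef in effects) {
    in_bay <- all(ef$phenotype_names %in% names(bay))
    in_grow <- all(ef$phenotype_names %in% names(grow))
    if (ef$kind == "additive_pairwise") {
      if (in_bay) bay <- plant_additive_effect(g, bay, ef)
      else if (in_grow) grow <- plant_additive_effect(g, grow, ef)
      else stop(sprintf("unknown phenotype name: %s", ef$phenotype_names), call. = FALSE)
    } else if (ef$kind == "xor_pleiotropic") {
      if (in_bay) {
        bay <- plant_xor_pleiotropy(g, bay, ef, seed = spec$seed + 3L)
      } else {
        ## one Bayley + one growth target: operate on the combined table
        comb <- cbind(bay, grow)
        comb <- plant_xor_pleiotropy(g, comb, ef, seed = spec$seed + 3L)
        bay[names(bay)] <- comb[names(bay)]
        grow[names(grow)] <- comb[names(grow)]
      }
    }
  }
  growth_discrete <- as.data.frame(lapply(grow, function(v) {
    if (length(unique(v)) <= 2L) as.integer(v) else discretize_numeric(v)
  }))
  list(genotypes = g, bayley = bay, growth = grow,
       growth_discrete = growth_discrete, subjects = g$subjects)
}
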