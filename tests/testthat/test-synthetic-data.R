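test_that("cohort_spec validates fields by name", {
  expect_error(cohort_spec(n_subjects = 0), "n_subjects")
  expect_error(cohort_spec(maf_range = c(0, 0.5)), "maf_range")
  expect_error(cohort_spec(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(cohort_spec(ethnicity_fractions = c(0.5, 0.6)), "ethnicity_fractions")
  expect_error(cohort_spec(missing_rate = 1), "missing_rate")
  expect_error(cohort_spec(sex_fraction_male = 1.2), "sex_fraction_male")
  expect_error(simulate_genotypes(list()), "cohort_spec")
})

test_that("genotype frequencies follow Hardy-Weinberg at known MAF", {
  n <- 4000
  spec <- cohort_spec(n_subjects = n, n_snps = 30, maf_range = c(0.5, 0.5),
                      missing_rate = 0, x_snp_fraction = 0, seed = 3)
  g <- simulate_genotypes(spec)
  # expected (0.25, 0.5, 0.25); each genotype count within 3 binomial SDs
  for (code in 0:2) {
    p <- ifelse(code == 1L, 0.5, 0.25)
    frac <- colMeans(g$genotypes == code)
    expect_true(all(abs(frac - p) < 3 * sqrt(p * (1 - p) / n)))
  }
})

test_that("missingness rate and sentinel are honoured", {
  spec <- cohort_spec(n_subjects = 800, n_snps = 50, missing_rate = 0.1, seed = 4)
  g <- simulate_genotypes(spec)
  frac <- mean(g$genotypes == -2L)
  expect_lt(abs(frac - 0.1), 3 * sqrt(0.1 * 0.9 / length(g$genotypes)))
  spec0 <- cohort_spec(n_subjects = 200, n_snps = 20, missing_rate = 0, seed = 4)
  expect_false(any(simulate_genotypes(spec0)$genotypes == -2L))
})

test_that("generators are byte-identical under a fixed seed", {
  spec <- cohort_spec(n_subjects = 150, n_snps = 40, seed = 9,
                      confounded_fraction = 0.2)
  expect_identical(simulate_genotypes(spec), simulate_genotypes(spec))
  expect_identical(simulate_cohort(spec), simulate_cohort(spec))
  expect_identical(simulate_bayley(100, seed = 5), simulate_bayley(100, seed = 5))
  pars <- growth_population_params()
  expect_identical(simulate_growth_trajectories(pars, 20, seed = 8),
                   simulate_growth_trajectories(pars, 20, seed = 8))
})

test_that("X SNPs are haploid-coded in males and flagged in the map", {
  spec <- cohort_spec(n_subjects = 300, n_snps = 100, x_snp_fraction = 0.1,
                      missing_rate = 0, seed = 12)
  g <- simulate_genotypes(spec)
  xi <- which(g$map$sex_linked)
  expect_length(xi, 10)
  expect_true(all(g$map$chr[xi] == "X"))
  males <- g$subjects$sex == "male"
  expect_true(all(g$genotypes[males, xi] %in% c(0L, 2L)))
  expect_true(any(g$genotypes[!males, xi] == 1L))
})

test_that("confounded SNPs carry the group allele-frequency offset", {
  spec <- cohort_spec(n_subjects = 3000, n_snps = 60, maf_range = c(0.3, 0.4),
                      confounded_fraction = 0.5, ethnicity_af_delta = 0.2,
                      missing_rate = 0, x_snp_fraction = 0, seed = 21)
  g <- simulate_genotypes(spec)
  af <- function(rows, j) mean(g$genotypes[rows, j]) / 2
  g1 <- g$subjects$ethnicity == 1L
  conf <- which(g$map$confounded)
  rest <- which(!g$map$confounded)
  d_conf <- mean(vapply(conf, function(j) af(g1, j) - af(!g1, j), 1))
  d_rest <- mean(vapply(rest, function(j) af(g1, j) - af(!g1, j), 1))
  expect_gt(d_conf, 0.15)
  expect_lt(abs(d_rest), 0.03)
})

test_that("Bayley composites: correlation extremes behave as expected", {
  # perfect correlation: scales identical, MI equals the marginal entropy
  b1 <- simulate_bayley(2000, n_scales = 2, n_levels = 4, rho = 1, seed = 6)
  expect_identical(b1[[1]], b1[[2]])
  jd <- joint_from_samples(b1)
  expect_equal(mutual_information(jd),
               entropy(marginal_distribution(jd, 1)), tolerance = 1e-12)
  # zero correlation: mean pairwise MI is at the plug-in bias level
  n <- 2000
  b0 <- simulate_bayley(n, n_scales = 5, n_levels = 4, rho = 0, seed = 6)
  bias <- (4 - 1) * (4 - 1) / (2 * n * log(2))
  mis <- apply(utils::combn(5, 2), 2, function(ij) {
    mutual_information(joint_from_samples(b0[ij]))
  })
  expect_gt(mean(mis), bias / 2)
  expect_lt(mean(mis), bias * 2)
})

test_that("planted additive effect: no-op at zero, monotone in effect size", {
  spec <- cohort_spec(n_subjects = 600, n_snps = 20, maf_range = c(0.3, 0.4),
                      missing_rate = 0, x_snp_fraction = 0, seed = 31)
  co <- simulate_cohort(spec)
  ef0 <- planted_effect("additive_pairwise", 3, "linf", 0)
  expect_identical(plant_additive_effect(co$genotypes, co$growth, ef0), co$growth)
  mi_at <- vapply(c(0, 0.5, 1, 2), function(es) {
    grow <- plant_additive_effect(co$genotypes, co$growth,
                                  planted_effect("additive_pairwise", 3, "linf", es))
    mutual_information(joint_from_samples(list(co$genotypes$genotypes[, 3],
                                               discretize_numeric(grow$linf))))
  }, 1)
  expect_true(all(diff(mi_at) > 0))
  expect_error(
    plant_additive_effect(co$genotypes, co$growth,
                          planted_effect("additive_pairwise", 3, "nope", 1)),
    "unknown phenotype"
  )
})

test_that("planted_effect validates its arity rules", {
  expect_error(planted_effect("additive_pairwise", 1, c("a", "b"), 1), "exactly 1")
  expect_error(planted_effect("xor_pleiotropic", 1, "a", 1), "exactly 2")
  expect_error(planted_effect("xor_pleiotropic", 1, c("a", "b"), 2), "penetrance")
})

test_that("planted XOR: exact joint signatures at the penetrance extremes", {
  d1 <- deltas(xor_joint_distribution(1, 0.5, 0.5))
  expect_equal(unname(d1$pairwise_mi), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(d1$delta_sym, -1)
  d0 <- deltas(xor_joint_distribution(0, 0.4, 0.3))
  expect_equal(d0$delta_sym, 0, tolerance = 1e-12)
  expect_equal(d0$omega, 0, tolerance = 1e-12)
  # the two genotype-phenotype pairs stay null for any SNP frequency at
  # penetrance 1 (the phenotype-phenotype pair needs a balanced SNP)
  dq <- deltas(xor_joint_distribution(1, q_snp = 0.7, q_p1 = 0.5))
  expect_equal(dq$pairwise_mi[["xy"]], 0, tolerance = 1e-12)
  expect_equal(dq$pairwise_mi[["xz"]], 0, tolerance = 1e-12)
  expect_gt(dq$pairwise_mi[["yz"]], 0)
  expect_lt(dq$delta_sym, -0.1)
})

test_that("planted XOR on sampled data: strong three-way, null pairwise", {
  spec <- cohort_spec(n_subjects = 1500, n_snps = 10, maf_range = c(0.28, 0.32),
                      missing_rate = 0, x_snp_fraction = 0, seed = 33)
  co <- simulate_cohort(spec)
  ef <- planted_effect("xor_pleiotropic", 2, c("Cognitive", "Motor"), 1)
  bay <- plant_xor_pleiotropy(co$genotypes, co$bayley, ef, seed = 34)
  expect_true(all(bay$Cognitive %in% 0:1) && all(bay$Motor %in% 0:1))
  snp <- co$genotypes$genotypes[, 2]
  d <- deltas(joint_from_samples(list(snp, bay$Cognitive, bay$Motor)))
  expect_lt(d$delta_sym, -0.1)
  expect_true(all(d$pairwise_mi < 0.01))
  expect_error(
    plant_xor_pleiotropy(co$genotypes, data.frame(a = letters[1:10], b = 1:10),
                         planted_effect("xor_pleiotropic", 1, c("a", "b"), 1)),
    "not reducible to binary"
  )
})

test_that("growth trajectory simulation respects its contracts", {
  pars0 <- growth_population_params(var_linf = 0, var_alpha = 0, var_lambda = 0,
                                    var_resid = 0)
  obs <- simulate_growth_trajectories(pars0, 25, seed = 41)
  expect_equal(obs$hc_cm, predict_growth(obs$time_weeks, pars0), tolerance = 1e-12)
  counts <- table(obs$subject_id)
  expect_true(all(counts >= 2 & counts <= 18))
  expect_true(all(obs$time_weeks >= 8 & obs$time_weeks <= 290))
  # subject random effects are centred: sample mean of L_i within 3 SE
  pars <- growth_population_params()
  n <- 400
  obs2 <- simulate_growth_trajectories(pars, n, seed = 42)
  eff <- attr(obs2, "true_effects")
  expect_lt(abs(mean(eff$linf)), 3 * sqrt(pars$var_linf / n))
  expect_error(growth_population_params(var_linf = -1), "variance")
})
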