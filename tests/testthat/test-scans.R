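make_scan_cohort <- function(seed = 71, n = 400, S = 40) {
  spec <- cohort_spec(n_subjects = n, n_snps = S, maf_range = c(0.2, 0.45),
                      missing_rate = 0, x_snp_fraction = 0, seed = seed)
  simulate_cohort(spec)
}

test_that("scan_pairwise ranks a strong planted additive SNP first", {
  co <- make_scan_cohort()
  idx <- order(abs(co$genotypes$map$maf - 0.3))[1]
  grow <- plant_additive_effect(
    co$genotypes, co$growth,
    planted_effect("additive_pairwise", idx, "linf", 1.2)
  )
  gd <- as.data.frame(lapply(grow, discretize_numeric))
  res <- scan_pairwise(co$genotypes, cbind(co$bayley, gd),
                       null_config(60, 2), cutoff = 1e-3)
  expect_s3_class(res, "scan_result")
  expect_equal(attr(res, "n_subjects"), 400)
  expect_equal(res$snp[1], co$genotypes$map$rsid[idx])
  expect_equal(res$phenotype[1], "linf")
  expect_true(res$flagged[1])
  expect_true(all(diff(res$p_value) >= 0))
  expect_equal(nrow(res), 40 * 8)
  # identical configuration is bit-for-bit reproducible
  res2 <- scan_pairwise(co$genotypes, cbind(co$bayley, gd),
                        null_config(60, 2), cutoff = 1e-3)
  expect_identical(as.data.frame(res), as.data.frame(res2))
})

test_that("scan_pairwise enforces complete-case contracts", {
  co <- make_scan_cohort(seed = 72, n = 100, S = 10)
  ph <- co$bayley
  ph$Cognitive[1:10] <- -2L
  g <- co$genotypes
  g$genotypes[15, 3] <- -2L  # subject 15 survives; SNP 3 must be dropped
  res <- scan_pairwise(g, ph, null_config(10, 1))
  expect_equal(attr(res, "n_subjects"), 90)
  expect_true(g$map$rsid[3] %in% attr(res, "dropped_snps"))
  expect_false(g$map$rsid[3] %in% res$snp)
  ph_all <- ph; ph_all$Motor <- rep(-2L, 100)
  expect_error(scan_pairwise(g, ph_all, null_config(5, 1)), "no complete-case")
})

test_that("scan_phenotype_dependencies surfaces duplicated and planted triples", {
  set.seed(73)
  n <- 300
  ph <- data.frame(a = sample(1:4, n, TRUE), b = sample(1:4, n, TRUE),
                   c = sample(1:4, n, TRUE))
  ph$dup <- ph$a
  # a planted XOR among phenotypes: three-way structure without pairwise
  x <- sample(0:1, n, TRUE); y <- sample(0:1, n, TRUE)
  ph$x <- x; ph$y <- y; ph$z <- bitwXor(x, y)
  res <- scan_phenotype_dependencies(ph, null_config(80, 4))
  expect_equal(sort(unlist(res$pairs[1, c("var1", "var2")], use.names = FALSE)),
               c("a", "dup"))
  top_triple <- sort(unlist(res$triples[1, c("var1", "var2", "var3")],
                            use.names = FALSE))
  expect_equal(top_triple, c("x", "y", "z"))
  expect_lt(res$triples$score[1], -0.9)
})

test_that("scan_threeway finds planted pleiotropy and flags pairwise status", {
  co <- make_scan_cohort(seed = 74)
  idx <- order(abs(co$genotypes$map$maf - 0.3))[1]
  rsid <- co$genotypes$map$rsid[idx]
  comb <- cbind(co$bayley, co$growth)
  comb <- plant_xor_pleiotropy(
    co$genotypes, comb,
    planted_effect("xor_pleiotropic", idx, c("Adaptive", "lambda"), 1), seed = 75
  )
  bay <- comb[names(co$bayley)]
  gd <- as.data.frame(lapply(comb[names(co$growth)], function(v) {
    if (length(unique(v)) <= 2) as.integer(v) else discretize_numeric(v)
  }))
  pw <- scan_pairwise(co$genotypes, cbind(bay, gd), null_config(60, 6))
  tw <- scan_threeway(co$genotypes, bay, gd, null_config(40, 7),
                      pairwise = pw, pairwise_cutoff = 2.7e-6)
  expect_equal(tw$snp[1], rsid)
  expect_equal(tw$bayley_phenotype[1], "Adaptive")
  expect_equal(tw$growth_phenotype[1], "lambda")
  expect_false(tw$pairwise_significant[1])
  expect_error(scan_threeway(co$genotypes, bay, bay, null_config(5, 1)), "overlap")
})

test_that("a constant SNP scores exactly zero in every triple", {
  co <- make_scan_cohort(seed = 76, n = 150, S = 8)
  g <- co$genotypes
  g$genotypes[, 5] <- 1L
  g$genotypes[1, 5] <- 0L  # nearly-constant column stays in; truly constant next
  g$genotypes[, 6] <- 2L
  tw <- scan_threeway(g, co$bayley[, 1:2], co$growth_discrete["linf"],
                      null_config(10, 8))
  expect_true(all(abs(tw$score[tw$snp == g$map$rsid[6]]) < 1e-12))
})

test_that("scan_asymmetric targets coincide on a symmetric planted effect", {
  co <- make_scan_cohort(seed = 77, n = 500, S = 20)
  idx <- order(abs(co$genotypes$map$maf - 0.3))[1]
  comb <- cbind(co$bayley["Adaptive"], co$growth["lambda"])
  comb <- plant_xor_pleiotropy(
    co$genotypes, comb,
    planted_effect("xor_pleiotropic", idx, c("Adaptive", "lambda"), 1), seed = 78
  )
  bay <- comb["Adaptive"]; gd <- data.frame(lambda = as.integer(comb$lambda))
  ranks <- vapply(c("growth", "bayley", "snp"), function(tg) {
    res <- scan_asymmetric(co$genotypes, bay, gd, target = tg,
                           null_cfg = null_config(20, 9))
    match(co$genotypes$map$rsid[idx], res$snp)
  }, 1L)
  expect_true(all(ranks == 1L))
})

test_that("scan_snp_interaction recovers an epistatic partner", {
  set.seed(79)
  n <- 600
  g <- make_test_genotypes(n = n, S = 12, seed = 80,
                           maf = rep(0.3, 12))
  d1 <- as.integer(g$genotypes[, 2] > 0)
  d2 <- as.integer(g$genotypes[, 7] > 0)
  pheno <- bitwXor(d1, d2) + 1L
  anchor <- g$map$rsid[2]
  res <- scan_snp_interaction(g, anchor, pheno, null_config(30, 10))
  expect_false(anchor %in% res$partner)
  expect_equal(res$partner[1], g$map$rsid[7])
  expect_equal(nrow(res), 11)
  expect_error(scan_snp_interaction(g, "rs999", pheno), "absent")
})

test_that("sex-stratified scans keep strata separate and report N", {
  spec <- cohort_spec(n_subjects = 300, n_snps = 40, x_snp_fraction = 1,
                      missing_rate = 0, seed = 81)
  g <- simulate_genotypes(spec)  # all X SNPs: male haploid codes
  co <- simulate_cohort(cohort_spec(n_subjects = 300, n_snps = 5,
                                    missing_rate = 0, seed = 81))
  bay <- co$bayley
  gd <- co$growth_discrete
  # plant a female-only effect on one X SNP
  fem <- g$subjects$sex == "female"
  idx <- 4
  grow <- co$growth
  grow$linf[fem] <- grow$linf[fem] +
    1.5 * ifelse(g$genotypes[fem, idx] > 0, g$genotypes[fem, idx], 0)
  gd$linf <- discretize_numeric(grow$linf)
  res <- scan_sex_stratified(g, bay, gd, null_cfg = null_config(40, 11))
  expect_setequal(unique(res$sex), c("male", "female"))
  # N equals the stratum complete-case count
  expect_equal(unique(res$n[res$sex == "male"]), sum(!fem))
  expect_equal(unique(res$n[res$sex == "female"]), sum(fem))
  f_pair <- res[res$sex == "female" & res$kind == "pairwise" &
                  !is.na(res$growth_phenotype) & res$growth_phenotype == "linf", ]
  m_pair <- res[res$sex == "male" & res$kind == "pairwise" &
                  !is.na(res$growth_phenotype) & res$growth_phenotype == "linf", ]
  rsid <- g$map$rsid[idx]
  expect_lt(f_pair$p_value[f_pair$snp == rsid],
            0.01)
  expect_gt(m_pair$p_value[m_pair$snp == rsid], 0.01)
  expect_error(scan_sex_stratified(g, bay, gd, sex = rep("male", 300)),
               "empty sex stratum")
})
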