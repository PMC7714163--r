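# fixture with exactly known per-step composition
make_preprocess_fixture <- function(n = 200, seed = 77) {
  set.seed(seed)
  cols <- list(
    normal1 = rbinom(n, 2, 0.3),
    normal2 = rbinom(n, 2, 0.4),
    constant = rep(1L, n),                       # step 1
    dup_a = NULL, dup_b = NULL,                  # step 2 (identical pair)
    high_missing = {v <- rbinom(n, 2, 0.3); v[seq_len(ceiling(0.3 * n))] <- -2L; v},
    near_constant = {v <- rep(0L, n); v[1:4] <- 1L; v},  # step 5 (2% variation)
    x_snp = rbinom(n, 2, 0.3)                    # step 6
  )
  base_col <- rbinom(n, 2, 0.45)
  cols$dup_a <- base_col
  cols$dup_b <- base_col
  G <- do.call(cbind, cols)
  map <- data.frame(
    rsid = names(cols), chr = c("1", "2", "3", "4", "5", "6", "7", "X"),
    pos = 1:8 * 1000L, major = "A", minor = "C",
    sex_linked = c(rep(FALSE, 7), TRUE), stringsAsFactors = FALSE
  )
  genotype_matrix(G, map)
}

test_that("preprocess_genotypes removes/collapses exactly as constructed", {
  g <- make_preprocess_fixture()
  res <- preprocess_genotypes(g)
  st <- res$report$steps
  expect_equal(unname(st["constant"]), 1L)
  expect_equal(unname(st["collapsed_identical"]), 1L)
  expect_equal(unname(st["high_missing"]), 1L)
  expect_equal(unname(st["collapsed_mi"]), 0L)
  expect_equal(unname(st["near_constant"]), 1L)
  expect_equal(unname(st["moved_xy"]), 1L)
  expect_setequal(res$genotypes$map$rsid, c("normal1", "normal2", "dup_a"))
  expect_equal(res$xy$map$rsid, "x_snp")
  # the duplicated pair keeps the lower-position representative
  expect_equal(names(res$report$collapsed_identical), "dup_a")
  expect_equal(res$report$collapsed_identical$dup_a, "dup_b")
})

test_that("every input SNP is accounted for exactly once", {
  g <- make_preprocess_fixture()
  res <- preprocess_genotypes(g)
  rep <- res$report
  accounted <- c(rep$retained_snps, rep$xy_snps,
                 unlist(rep$removed, use.names = FALSE),
                 unlist(rep$collapsed_identical, use.names = FALSE),
                 unlist(rep$collapsed_mi, use.names = FALSE))
  expect_setequal(accounted, rep$input_snps)
  expect_equal(length(accounted), length(rep$input_snps))
  expect_equal(sum(rep$steps), length(rep$input_snps) - length(rep$retained_snps))
})

test_that("preprocessing is idempotent", {
  g <- make_preprocess_fixture()
  once <- preprocess_genotypes(g)
  twice <- preprocess_genotypes(once$genotypes)
  expect_identical(once$genotypes$genotypes, twice$genotypes$genotypes)
  expect_true(all(twice$report$steps == 0))
})

test_that("collapse_by_mi merges only high-MI clusters", {
  set.seed(5)
  n <- 400
  v <- sample(0:2, n, TRUE, prob = c(1, 1, 1) / 3)  # H close to log2(3) > 1.2
  G <- cbind(a = v, b = v, c = sample(0:2, n, TRUE, prob = c(1, 1, 1) / 3),
             d = rbinom(n, 2, 0.2))
  map <- data.frame(rsid = colnames(G), chr = "1", pos = 1:4 * 100L,
                    major = "A", minor = "C", stringsAsFactors = FALSE)
  g <- genotype_matrix(G, map)
  res <- collapse_by_mi(g, threshold = 1.2)
  expect_setequal(res$genotypes$map$rsid, c("a", "c", "d"))
  expect_equal(res$groups$a, "b")
  # an effectively infinite threshold is the identity transform
  expect_equal(ncol(collapse_by_mi(g, threshold = 100)$genotypes$genotypes), 4)
  expect_error(collapse_by_mi(g, threshold = 0), "threshold")
})

test_that("discretize_numeric implements the four-bin boundary rule", {
  expect_equal(discretize_numeric(1:8), rep(1:4, each = 2))
  # mu = 4.5, l = 2.5, r = 6.5; a value exactly at the mean falls in bin 2
  expect_equal(discretize_numeric(c(1:8, 4.5))[9], 2L)
  # near-quartile occupancy on a symmetric sample
  set.seed(8)
  v <- rnorm(8000)
  counts <- tabulate(discretize_numeric(v), 4)
  expect_true(all(abs(counts - 2000) < 3 * sqrt(2000)))
  # missing preserved; alphabet confined to 1..4
  x <- c(rnorm(50), -2, NA)
  cd <- discretize_numeric(x)
  expect_equal(cd[51], -2L)
  expect_equal(cd[52], -2L)
  expect_true(all(cd[1:50] %in% 1:4))
  expect_error(discretize_numeric(rep(3, 10)), "4 distinct")
})

test_that("screen_categorical drops by alphabet size and near-constancy", {
  tb <- data.frame(
    many = rep(1:11, length.out = 100),        # 11 categories
    const96 = c(rep(1L, 96), rep(2L, 4)),      # 96% one value
    ten = rep(1:10, length.out = 100),         # boundary: retained
    ok = rep(1:3, length.out = 100)
  )
  out <- screen_categorical(tb)
  expect_setequal(names(out), c("ten", "ok"))
  rep <- attr(out, "screen_report")
  expect_setequal(rep$variable, c("many", "const96"))
  expect_equal(rep$reason[rep$variable == "many"], "too_many_categories")
})

test_that("LP subset selection: trivial, tau = 0, and brute-force equivalence", {
  M <- matrix(1L, 5, 4)
  sel <- select_subset_lp(M, tau = 0.5)
  expect_equal(sel$objective, 9)
  set.seed(14)
  for (rep in 1:25) {
    n <- sample(2:6, 1); m <- sample(2:6, 1)
    tab <- matrix(sample(c(1L, -2L), n * m, TRUE, prob = c(0.7, 0.3)), n, m)
    for (tau in c(0, 0.3, 0.6)) {
      brute <- o_lp_brute(tab == -2L, tau)
      got <- tryCatch(select_subset_lp(tab, tau), error = function(e) NULL)
      if (is.null(got)) {
        expect_equal(brute, 0)
      } else {
        expect_equal(got$objective, brute)
        sub <- tab[got$kept_subjects, got$kept_variables, drop = FALSE]
        expect_true(all(rowSums(sub != -2L) >= 1))
        expect_true(all(colMeans(sub == -2L) <= tau + 1e-12))
        if (tau == 0) expect_false(any(sub == -2L))
      }
    }
  }
  expect_error(select_subset_lp(matrix(-2L, 3, 3), 0), "no feasible")
  expect_error(select_subset_lp(matrix(1L, 2, 2), tau = 1.5), "tau")
})

test_that("ld_r2 finds duplicated columns and validates candidates", {
  set.seed(23)
  n <- 300
  a <- rbinom(n, 2, 0.4)
  G <- cbind(a = a, b = a, c = rbinom(n, 2, 0.4))
  G[1:5, 2] <- -2L  # pairwise-complete handling
  map <- data.frame(rsid = c("a", "b", "c"), chr = "1",
                    pos = c(1000L, 2000L, 3000L), major = "A", minor = "C",
                    stringsAsFactors = FALSE)
  g <- genotype_matrix(G, map)
  hits <- ld_r2(g, "a", window_bp = 10000, r2_threshold = 0.8)
  expect_equal(hits$partner, "b")
  expect_equal(hits$r2, 1, tolerance = 1e-12)
  all_r2 <- ld_r2(g, "a", window_bp = 10000, r2_threshold = 0)
  expect_lt(all_r2$r2[all_r2$partner == "c"], 0.1)
  expect_error(ld_r2(g, "zz"), "absent")
})
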