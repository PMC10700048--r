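test_that("exact HWE p-values: extreme cases and enumeration spot checks", {
  expect_lt(hwe_exact_pvalue(50, 0, 50), 1e-6)   # total heterozygote deficit
  expect_gt(hwe_exact_pvalue(25, 50, 25), 0.5)   # modal configuration
  expect_equal(hwe_exact_pvalue(3, 5, 2), hwe_p_oracle(3, 5, 2))
  set.seed(61)
  for (i in 1:40) {
    n <- sample(2:30, 1)
    naa <- sample(0:n, 1)
    nab <- sample(0:(n - naa), 1)
    nbb <- n - naa - nab
    expect_equal(hwe_exact_pvalue(naa, nab, nbb),
                 hwe_p_oracle(naa, nab, nbb), tolerance = 1e-9)
  }
})

test_that("individual-missingness filter removes rates at or above threshold", {
  set.seed(62)
  L <- 100
  G <- matrix(sample(0:2, 4 * L, replace = TRUE), 4, L)
  rates <- c(0.10, 0.29, 0.31, 0.50)
  for (i in 1:4) G[i, seq_len(L * rates[i])] <- NA
  g <- genotype_matrix(G, rep("A", 4))
  out <- filter_individual_missing(g, 0.30)
  expect_equal(nrow(out$geno), 2)
  expect_identical(rownames(out$geno), c("IND1", "IND2"))
  expect_error(filter_individual_missing(g, 0.05), "all individuals")
})

test_that("MAF filter keeps only loci strictly above the threshold", {
  set.seed(63)
  n <- 50
  mafs <- c(runif(17, 0.005, 0.045), runif(83, 0.08, 0.5))
  G <- sapply(mafs, function(p) {
    repeat {
      x <- stats::rbinom(n, 2, p)
      f <- sum(x) / (2 * n)
      f <- min(f, 1 - f)
      hit <- if (p <= 0.05) f <= 0.05 else f > 0.05
      if (hit) return(x)
    }
  })
  g <- genotype_matrix(G, rep(c("A", "B"), each = 25))
  out <- filter_maf(g, 0.05)
  expect_equal(ncol(out$geno), 83)
  expect_identical(colnames(out$geno), colnames(g$geno)[-(1:17)])
})

test_that("biallelic filter drops multi-allelic loci flagged from VCF input", {
  G <- matrix(sample(0:2, 40, replace = TRUE), 4, 10)
  g <- genotype_matrix(G, rep("A", 4), n_alleles = c(rep(2L, 6), 3L,
                                                     rep(2L, 3)))
  out <- filter_biallelic(g)
  expect_equal(ncol(out$geno), 9)
  g2 <- genotype_matrix(G, rep("A", 4))
  expect_identical(filter_biallelic(g2)$geno, g2$geno)
})

test_that("HWE filter removes planted violators", {
  set.seed(64)
  n <- 60
  G <- sapply(1:50, function(l) stats::rbinom(n, 2, runif(1, 0.2, 0.8)))
  # replace any chance violator, then plant 5 hard ones
  for (l in 1:50) {
    while (hwe_exact_pvalue(sum(G[, l] == 0), sum(G[, l] == 1),
                            sum(G[, l] == 2)) <= 0.01)
      G[, l] <- stats::rbinom(n, 2, 0.5)
  }
  planted <- 1:5
  for (l in planted) G[, l] <- sample(c(0L, 2L), n, replace = TRUE)
  g <- genotype_matrix(G, rep(c("A", "B"), each = 30))
  out <- filter_hwe(g, 0.01)
  expect_equal(ncol(out$geno), 45)
  expect_false(any(colnames(g$geno)[planted] %in% colnames(out$geno)))
})

test_that("F_ST outlier filter removes exactly the planted loci", {
  set.seed(65)
  n_per <- 30
  grp <- rep(c("A", "B", "C"), each = n_per)
  G <- sapply(1:40, function(l) stats::rbinom(3 * n_per, 2, 0.5))
  planted <- c(3, 17, 31)
  for (l in planted) {
    p <- ifelse(grp == "A", 0.95, 0.05)
    G[, l] <- stats::rbinom(3 * n_per, 2, p)
  }
  mono <- 40  # globally monomorphic: undefined theta, kept
  G[, mono] <- 0L
  g <- genotype_matrix(G, grp)
  th <- vapply(seq_len(40), function(l)
    wc_fst_locus(split(g$geno[, l], g$groups)), numeric(1))
  out <- filter_fst_outliers(g, 0.1)
  expect_identical(colnames(out$geno),
                   colnames(g$geno)[is.na(th) | th <= 0.1])
  expect_true(all(!colnames(g$geno)[planted] %in% colnames(out$geno)))
  expect_true(colnames(g$geno)[mono] %in% colnames(out$geno))
  # inverted mode keeps the high-theta loci
  inv <- filter_fst_outliers(g, 0.1, mode = "remove_below")
  expect_true(all(colnames(g$geno)[planted] %in% colnames(inv$geno)))
})

test_that("LD pruning collapses correlated blocks deterministically", {
  set.seed(66)
  n <- 80
  base <- stats::rbinom(n, 2, 0.5)
  G <- cbind(base, base,  # exact duplicate pair
             sapply(1:6, function(i) stats::rbinom(n, 2, 0.5)))
  colnames(G) <- paste0("L", 1:8)
  g <- genotype_matrix(G, rep("A", n))
  out <- ld_prune(g, 0.8)
  expect_equal(sum(c("L1", "L2") %in% colnames(out$geno)), 1)
  # equal missingness and MAF: the later locus is removed
  expect_true("L1" %in% colnames(out$geno))
  # a three-locus near-identical block leaves one survivor
  blk <- stats::rbinom(n, 2, 0.5)
  B <- cbind(blk, blk, blk,
             sapply(1:3, function(i) stats::rbinom(n, 2, 0.5)))
  colnames(B) <- paste0("M", 1:6)
  gb <- genotype_matrix(B, rep("A", n))
  outb <- ld_prune(gb, 0.8)
  expect_equal(sum(paste0("M", 1:3) %in% colnames(outb$geno)), 1)
  # independent loci untouched
  set.seed(67)
  ind <- sapply(1:10, function(i) stats::rbinom(n, 2, 0.5))
  gi <- genotype_matrix(ind, rep("A", n))
  expect_equal(ncol(ld_prune(gi, 0.8)$geno), 10)
})

test_that("complete-case selection reproduces known survivor counts", {
  set.seed(68)
  G <- matrix(sample(0:2, 20 * 1897, replace = TRUE), 20, 1897)
  miss <- sample(1897, 1897 - 693)
  for (l in miss) G[sample(20, 1), l] <- NA
  g <- genotype_matrix(G, rep(c("A", "B"), each = 10))
  out <- complete_case(g)
  expect_equal(ncol(out$geno), 693)
})

test_that("filters are idempotent and the cascade report telescopes", {
  raw <- make_raw(seed = 70, n_loci = 600)
  g <- raw$geno
  for (f in list(filter_biallelic,
                 function(x) filter_individual_missing(x, 0.30),
                 function(x) filter_maf(x, 0.05),
                 function(x) filter_fst_outliers(x, 0.1),
                 complete_case)) {
    once <- f(g)
    expect_identical(f(once)$geno, once$geno)
  }
  res <- run_cascade(g, complete = TRUE)
  rep <- res$report
  expect_equal(rep$loci_in[-1], rep$loci_out[-nrow(rep)])
  expect_equal(rep$ind_in[-1], rep$ind_out[-nrow(rep)])
  expect_equal(rep$loci_out[nrow(rep)], ncol(res$geno$geno))
  # planted violations are gone
  expect_false(any(raw$planted$triallelic %in% colnames(res$geno$geno)))
  expect_false(any(raw$planted$low_maf %in% colnames(res$geno$geno)))
  expect_false(any(raw$planted$hwe %in% colnames(res$geno$geno)))
  expect_true(all(!is.na(res$geno$geno)))
})

test_that("a clean raw matrix passes the cascade nearly untouched", {
  clean <- make_raw(seed = 71, n_loci = 400,
                    frac = list(triallelic = 0, low_maf = 0, hwe = 0,
                                high_fst = 0, dup = 0, miss_mean = 0,
                                n_bad_ind = 0))
  expect_true(all(!is.na(clean$geno$geno)))
  res <- run_cascade(clean$geno, complete = TRUE)
  expect_equal(nrow(res$geno$geno), nrow(clean$geno$geno))
  # the deterministic stages are exact identities on clean data
  rep <- res$report
  for (st in c("biallelic", "ind_missing", "maf", "ld", "complete_case"))
    expect_equal(rep$loci_out[rep$stage == st], rep$loci_in[rep$stage == st])
  # the statistical tests (HWE, F_ST) may claim a few chance casualties
  expect_gte(ncol(res$geno$geno), 0.90 * 400)
})

test_that("make_raw is reproducible and records its planted sets", {
  a <- make_raw(seed = 72, n_loci = 300)
  b <- make_raw(seed = 72, n_loci = 300)
  expect_identical(a$geno$geno, b$geno$geno)
  expect_identical(a$planted, b$planted)
  g <- a$geno
  out <- filter_maf(g, 0.05)
  expect_false(any(a$planted$low_maf %in% colnames(out$geno)))
})
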