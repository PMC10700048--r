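# Independent oracles used across the suite.  These deliberately re-derive
# each quantity from first principles (scalar loops, direct factorial
# formulas) rather than calling the package's vectorized paths.

# single-deme scenario over one group, for coalescent null checks
one_deme_scenario <- function(N_symbol = "N1") {
  scenario(99, demes = "A", sizes = c(A = N_symbol), events = list(),
           description = "single panmictic deme")
}

two_deme_scenario <- function() {
  scenario(98, demes = c("A", "B"), sizes = c(A = "N1", B = "N2"),
           events = list(ev_merge("t1", "B", "A", new_size = "NA")),
           description = "two demes splitting at t1")
}

# Weir & Cockerham (1984) two-group theta, transcribed independently from
# the variance-component formulas (r = 2), working from genotype vectors
wc_fst_oracle <- function(g1, g2) {
  g1 <- g1[!is.na(g1)]; g2 <- g2[!is.na(g2)]
  n1 <- length(g1); n2 <- length(g2)
  p1 <- sum(g1) / (2 * n1); p2 <- sum(g2) / (2 * n2)
  h1 <- sum(g1 == 1) / n1; h2 <- sum(g2 == 1) / n2
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
                        (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  if (a + b + cc == 0) return(NA_real_)
  a / (a + b + cc)
}

# exact HWE p-value by direct factorial enumeration (Levene-Haldane
# conditional distribution), computed with plain factorial() products
hwe_p_oracle <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  na_ <- 2 * n_aa + n_ab
  nb_ <- 2 * n_bb + n_ab
  hs <- seq(na_ %% 2, min(na_, nb_), by = 2)
  pr <- vapply(hs, function(h) {
    naa <- (na_ - h) / 2
    nbb <- (nb_ - h) / 2
    factorial(n) / (factorial(naa) * factorial(h) * factorial(nbb)) *
      2^h * factorial(na_) * factorial(nb_) / factorial(2 * n)
  }, numeric(1))
  pobs <- pr[match(n_ab, hs)]
  sum(pr[pr <= pobs * (1 + 1e-9)])
}

# naive per-locus-loop summary statistics: scalar arithmetic only
naive_sumstats <- function(g, trios = NULL) {
  grp <- g$groups
  gn <- levels(grp)
  if (is.null(trios) && all(c("LOWER-CENTRAL", "UPPER-CENTRAL",
                              "SOUTHERN") %in% gn))
    trios <- list(c(admixed = "LOWER-CENTRAL", parent1 = "UPPER-CENTRAL",
                    parent2 = "SOUTHERN"))
  if (is.null(trios)) trios <- list()
  L <- ncol(g$geno)
  freq <- function(gi, l) {
    x <- g$geno[grp == gi, l]
    x <- x[!is.na(x)]
    sum(x) / (2 * length(x))
  }
  out <- c()
  for (gi in gn) {
    vals <- c()
    for (l in seq_len(L)) {
      x <- g$geno[grp == gi, l]
      x <- x[!is.na(x)]
      ncop <- 2 * length(x)
      if (ncop < 2) next
      p <- sum(x) / ncop
      vals <- c(vals, ncop / (ncop - 1) * (1 - p^2 - (1 - p)^2))
    }
    out[paste0("HD.", gi)] <- mean(vals)
  }
  prs <- utils::combn(gn, 2)
  for (k in seq_len(ncol(prs))) {
    g1n <- prs[1, k]; g2n <- prs[2, k]
    fst <- nei <- c()
    for (l in seq_len(L)) {
      th <- wc_fst_oracle(g$geno[grp == g1n, l], g$geno[grp == g2n, l])
      if (is.finite(th) && abs(th) > 1e-12) fst <- c(fst, th)
      p1 <- freq(g1n, l); p2 <- freq(g2n, l)
      jx <- p1^2 + (1 - p1)^2; jy <- p2^2 + (1 - p2)^2
      jxy <- p1 * p2 + (1 - p1) * (1 - p2)
      if (jxy > 0) {
        D <- -log(jxy / sqrt(jx * jy))
        if (is.finite(D) && abs(D) > 1e-12) nei <- c(nei, D)
      }
    }
    out[paste0("FST.", g1n, "~", g2n)] <- mean(fst)
    out[paste0("NEI.", g1n, "~", g2n)] <- mean(nei)
  }
  for (tr in trios) {
    vals <- c()
    for (l in seq_len(L)) {
      pa <- freq(tr[["admixed"]], l)
      p1 <- freq(tr[["parent1"]], l)
      p2 <- freq(tr[["parent2"]], l)
      if (p1 == p2) next
      f <- (pa - p2) / (p1 - p2)
      if (is.finite(f) && abs(f) > 1e-12) vals <- c(vals, f)
    }
    out[paste0("ADM.", tr[["admixed"]], "~", tr[["parent1"]], "~",
               tr[["parent2"]])] <- mean(vals)
  }
  out
}

# hand-rolled reference table around externally supplied stats/params,
# for oracle tests that need no simulation
make_toy_ref <- function(stats, scenario_vec, params = NULL,
                         priors = prior_spec(), scenarios = NULL) {
  ids <- sort(unique(scenario_vec))
  if (is.null(scenarios))
    scenarios <- lapply(ids, function(i) {
      sc <- builtin_scenarios()[[1]]
      sc$id <- i
      sc
    })
  if (is.null(params))
    params <- matrix(NA_real_, nrow(stats), 11,
                     dimnames = list(NULL, c("NA", paste0("N", 1:5),
                                             paste0("t", 1:4), "ra")))
  structure(list(stats = stats, params = params,
                 scenario = scenario_vec,
                 meta = list(scenarios = scenarios, priors = priors,
                             groups = default_groups(), n_loci = NA,
                             trios = list(), seed = NULL,
                             per_scenario = table(scenario_vec))),
            class = "ref_table")
}

# brute-force direct-approach oracle: explicit standardize/sort/count
direct_pp_oracle <- function(ref, observed, k) {
  sds <- apply(ref$stats, 2, sd)
  keep <- sds > 0
  Z <- sweep(ref$stats[, keep, drop = FALSE], 2, sds[keep], "/")
  zo <- as.numeric(observed)[keep] / sds[keep]
  d <- apply(Z, 1, function(r) sqrt(sum((r - zo)^2)))
  sel <- order(d)[seq_len(k)]
  ids <- sort(unique(ref$scenario))
  vapply(ids, function(i) mean(ref$scenario[sel] == i), numeric(1))
}
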