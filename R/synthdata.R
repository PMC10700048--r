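# Synthetic data with known truth: a stand-in "observed" dataset with the
# study structure (124 individuals, five groups pooled from nine
# subpopulations, 693 complete-case SNPs), a raw matrix with planted QC
# violations, and a tiny hand-checkable worked example.  All outputs are
# regenerable bit-identically from their truth records.

#' Truth parameters of the synthetic observed dataset
#'
#' Posterior-mean point values of the reference analysis under the
#' registry's Scenario 1: effective sizes `NA = 5.98e5`, `N1 = 3440`,
#' `N2 = 2710`, `N3 = 2600`, `N4 = 681`, `N5 = 365` diploids; split times
#' `t4 = 1260`, `t3 = 629`, `t2 = 351`, `t1 = 261` generations.
#'
#' @return Named numeric vector.
#' @export
truth_parameters <- function() {
  c("NA" = 5.98e5, N1 = 3440, N2 = 2710, N3 = 2600, N4 = 681, N5 = 365,
    t1 = 261, t2 = 351, t3 = 629, t4 = 1260)
}

# nine subpopulation labels (12-15 individuals each) nested in the five
# groups; purely a labelling of the sampling design
subpop_labels <- function(groups) {
  plan <- list(
    "SOUTHERN" = c(BA_a = 14, BA_b = 14),
    "LOWER-CENTRAL" = c(OC = 14, YD_x = 14, YD = 13),
    "UPPER-CENTRAL" = c(GS_a = 13, GS_b = 14),
    "EASTERN" = c(AD = 14),
    "NORTHERN" = c(YJ = 14))
  labs <- character(0)
  for (g in names(groups)) {
    sizes <- plan[[g]]
    if (is.null(sizes) || sum(sizes) != groups[[g]])
      sizes <- setNames(groups[[g]], paste0(substr(g, 1, 2), "1"))
    labs <- c(labs, rep(names(sizes), times = sizes))
  }
  labs
}

#' Generate the synthetic observed dataset
#'
#' Simulates Scenario 1 at the truth parameters ([truth_parameters()]):
#' 693 unlinked SNP loci, no missing data, default 124-individual
#' five-group configuration.  The returned truth record is sufficient to
#' regenerate the dataset bit-identically.
#'
#' @param seed Integer seed.
#' @param n_loci Number of loci (default 693).
#' @param groups A [group_config()] (default [default_groups()]).
#' @return `list(geno = geno_matrix, truth = truth record)`; the genotype
#'   matrix carries a `subpop` attribute with the nine source-population
#'   labels.
#' @export
make_observed <- function(seed = 1, n_loci = 693, groups = default_groups()) {
  set.seed(seed)
  sc <- builtin_scenarios()[[1]]
  draw <- truth_parameters()
  g <- simulate_dataset(sc, draw, groups, n_loci)
  attr(g, "subpop") <- subpop_labels(groups)
  truth <- list(scenario = 1, draw = as.list(draw), seed = seed,
                groups = as.list(setNames(as.integer(groups),
                                          names(groups))),
                n_loci = n_loci)
  list(geno = g, truth = truth)
}

#' Write / read a truth record sidecar
#' @param truth Truth record from [make_observed()].
#' @param path JSON path.
#' @return `read_truth_record()` returns the record as a list.
#' @export
write_truth_record <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_truth_record
#' @export
read_truth_record <- function(path) jsonlite::read_json(path)

#' Generate a raw genotype matrix with planted QC violations
#'
#' Base loci are drawn from a hierarchical-frequency model (per-locus
#' ancestral frequency, per-group beta-distributed deviation, HWE
#' genotypes).  Configured fractions of loci are then planted as:
#' low-MAF, HWE-violating (heterozygote deficits), high-differentiation
#' (F_ST outliers), duplicated/correlated blocks; triallelic sites are
#' flagged via the `n_alleles` slot; per-individual missingness is
#' beta-distributed with a few high-missingness individuals.  Every
#' planted set is recorded for survivor-count bookkeeping.
#'
#' @param seed Integer seed.
#' @param n_loci Total locus count (default 5000).
#' @param groups A [group_config()].
#' @param frac Named list of planted fractions (`triallelic`, `low_maf`,
#'   `hwe`, `high_fst`, `dup`) and missingness controls (`miss_mean`,
#'   `n_bad_ind`).  Set all fractions and missingness to zero for a clean
#'   matrix.
#' @return `list(geno =, planted =)` with `planted` a list of locus-id
#'   vectors per violation class (plus `bad_individuals`).
#' @export
make_raw <- function(seed = 1, n_loci = 5000, groups = default_groups(),
                     frac = list()) {
  set.seed(seed)
  # miss_mean is the mean per-genotype missing rate of ordinary
  # individuals; ~0.01 leaves roughly a third of loci fully observed in a
  # 124-individual matrix, matching the yield of a typical GBS study
  frac <- modifyList(list(triallelic = 0.01, low_maf = 0.10, hwe = 0.03,
                          high_fst = 0.03, dup = 0.04, miss_mean = 0.01,
                          n_bad_ind = 3), frac)
  n_ind <- sum(groups)
  grp <- factor(rep(names(groups), times = groups), levels = names(groups))
  ids <- paste0("IND", seq_len(n_ind))

  # base: mild structure, common alleles
  p0 <- stats::rbeta(n_loci, 1.2, 1.2) * 0.8 + 0.1
  G <- matrix(0L, n_ind, n_loci)
  for (gname in names(groups)) {
    rows <- which(grp == gname)
    a <- p0 * 40; b <- (1 - p0) * 40  # weak differentiation
    pg <- stats::rbeta(n_loci, a, b)
    G[rows, ] <- matrix(stats::rbinom(length(rows) * n_loci, 2,
                                      rep(pg, each = length(rows))),
                        length(rows), n_loci)
  }

  n_pick <- function(f) max(0L, round(f * n_loci))
  avail <- seq_len(n_loci)
  take <- function(k) {
    sel <- sort(sample(avail, k))
    avail <<- setdiff(avail, sel)
    sel
  }

  tri <- take(n_pick(frac$triallelic))
  low <- take(n_pick(frac$low_maf))
  for (l in low) {
    p <- runif(1, 0.001, 0.03)
    repeat {  # keep the realized MAF safely below the 5% threshold
      x <- stats::rbinom(n_ind, 2, p)
      if (sum(x) / (2 * n_ind) <= 0.045) break
    }
    G[, l] <- x
  }
  hw <- take(n_pick(frac$hwe))
  for (l in hw) {  # strong heterozygote deficit at intermediate frequency
    G[, l] <- sample(c(0L, 2L), n_ind, replace = TRUE)
  }
  hf <- take(n_pick(frac$high_fst))
  for (l in hf) {  # near-fixed differences between group blocks
    hi <- names(groups)[seq_len(ceiling(length(groups) / 2))]
    p_hi <- runif(1, 0.85, 0.99); p_lo <- runif(1, 0.01, 0.15)
    pr <- ifelse(grp %in% hi, p_hi, p_lo)
    G[, l] <- stats::rbinom(n_ind, 2, pr)
  }
  dup <- take(n_pick(frac$dup))
  dup_src <- integer(0)
  if (length(dup)) {
    dup_src <- sample(avail, length(dup), replace = TRUE)
    for (i in seq_along(dup)) {
      G[, dup[i]] <- G[, dup_src[i]]
      flip <- sample(n_ind, max(0L, round(0.02 * n_ind)))
      G[flip, dup[i]] <- stats::rbinom(length(flip), 2, 0.5)
    }
  }

  # missingness: beta-distributed per-individual rates, a few bad apples
  if (frac$miss_mean > 0) {
    rate <- stats::rbeta(n_ind, 2, 2 / frac$miss_mean - 2)
    bad <- integer(0)
    if (frac$n_bad_ind > 0) {
      bad <- sample(n_ind, frac$n_bad_ind)
      rate[bad] <- runif(length(bad), 0.35, 0.6)
    }
    for (i in seq_len(n_ind)) {
      nm <- stats::rbinom(1, n_loci, rate[i])
      if (nm > 0) G[i, sample(n_loci, nm)] <- NA_integer_
    }
  } else bad <- integer(0)

  rownames(G) <- ids
  colnames(G) <- paste0("L", seq_len(n_loci))
  n_alleles <- rep(2L, n_loci)
  n_alleles[tri] <- 3L
  gm <- genotype_matrix(G, grp, n_alleles = n_alleles)
  planted <- list(triallelic = colnames(G)[tri],
                  low_maf = colnames(G)[low],
                  hwe = colnames(G)[hw],
                  high_fst = colnames(G)[hf],
                  dup = colnames(G)[dup],
                  dup_source = colnames(G)[dup_src],
                  bad_individuals = ids[bad])
  list(geno = gm, planted = planted)
}

#' Tiny hand-checkable worked example
#'
#' Three groups (A, B, C) of four individuals and six loci, constructed so
#' the summary statistics can be verified by hand: locus 1 has allele
#' counts (2, 2)-style configurations in group A, locus 2 is identical in
#' all groups (zero Nei distance), and the rest exercise the non-zero-mean
#' rules.
#'
#' @return A [genotype_matrix()] (12 x 6).
#' @export
make_worked_example <- function() {
  # rows: 4 individuals per group A, B, C; entries are derived-allele counts.
  # Locus 1 in group A has two missing genotypes, so its allele counts are
  # (2, 2) over 4 gene copies: gene diversity 4/3 * (1 - 1/2) = 2/3.
  A <- rbind(c(1, 1, 2, 0, 1, 0),
             c(1, 1, 2, 0, 1, 0),
             c(NA, 1, 2, 0, 0, 1),
             c(NA, 1, 2, 0, 0, 1))
  B <- rbind(c(2, 1, 0, 0, 1, 1),
             c(2, 1, 0, 0, 1, 1),
             c(2, 1, 0, 0, 1, 0),
             c(1, 1, 0, 0, 0, 0))
  C <- rbind(c(0, 1, 1, 1, 2, 1),
             c(0, 1, 1, 1, 2, 1),
             c(1, 1, 1, 1, 2, 0),
             c(0, 1, 1, 0, 1, 0))
  G <- rbind(A, B, C)
  rownames(G) <- paste0(rep(c("A", "B", "C"), each = 4), 1:4)
  colnames(G) <- paste0("L", 1:6)
  genotype_matrix(G, rep(c("A", "B", "C"), each = 4))
}
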