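# DIYABC-style summary statistics for grouped biallelic SNP data.
# Single-sample statistics are averaged over the complete locus
# distribution; two- and three-sample statistics over loci whose per-locus
# value is defined and non-zero.

#' Per-locus gene diversity (expected heterozygosity)
#'
#' Nei's unbiased gene diversity `H = n/(n-1) * (1 - sum(p^2))` from
#' allele counts at one locus in one group, with `n` the number of
#' non-missing gene copies.
#'
#' @param counts Integer vector of allele counts (any number of alleles).
#' @return Diversity in `[0, 1]`; monomorphic loci give 0.
#' @export
gene_diversity_locus <- function(counts) {
  n <- sum(counts)
  if (n < 2) stop("gene diversity needs at least 2 gene copies")
  p <- counts / n
  n / (n - 1) * (1 - sum(p^2))
}

# Weir & Cockerham (1984) variance components for r groups at one locus.
# Inputs are per-group vectors: n (non-missing diploid individuals),
# p (counted-allele frequency), h (observed heterozygote frequency).
wc_components <- function(n, p, h) {
  r <- length(n)
  nbar <- mean(n)
  if (nbar <= 1 || any(n < 1)) return(c(a = NA_real_, b = NA_real_, cc = NA_real_))
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c(a = a, b = b, cc = hbar / 2)
}

#' Weir-Cockerham theta at one locus
#'
#' The 1984 variance-components estimator `theta = a / (a + b + c)` of
#' F_ST, from observed genotype vectors (codes 0/1/2, `NA` = missing).
#' With two groups this is the pairwise estimator; with more it is the
#' global multi-group form.  Heterozygote frequencies are taken from the
#' observed genotype counts, not from HWE expectations.
#'
#' @param ... Two or more integer genotype vectors, one per group.
#' @return theta, or `NA` when `a + b + c = 0` (locus monomorphic across
#'   the pooled groups) — never silently 0.
#' @export
wc_fst_locus <- function(...) {
  gl <- list(...)
  if (length(gl) == 1L && is.list(gl[[1]])) gl <- gl[[1]]
  stopifnot(length(gl) >= 2)
  n <- p <- h <- numeric(length(gl))
  for (i in seq_along(gl)) {
    x <- gl[[i]][!is.na(gl[[i]])]
    if (length(x) < 1) return(NA_real_)
    n[i] <- length(x)
    p[i] <- sum(x) / (2 * length(x))
    h[i] <- mean(x == 1)
  }
  comp <- wc_components(n, p, h)
  den <- sum(comp)
  if (!is.finite(den) || den == 0) return(NA_real_)
  unname(comp["a"] / den)
}

#' Nei's (1972) standard genetic distance at one locus
#'
#' `D = -ln(J_xy / sqrt(J_x * J_y))` with `J_x = sum(p_x^2)`,
#' `J_y = sum(p_y^2)`, `J_xy = sum(p_x * p_y)`.
#'
#' @param p_x,p_y Allele-frequency vectors (same allele order).
#' @return Distance, or `NA` when `J_xy = 0` (no shared alleles, D
#'   infinite).
#' @export
nei_distance_locus <- function(p_x, p_y) {
  jx <- sum(p_x^2); jy <- sum(p_y^2); jxy <- sum(p_x * p_y)
  if (jxy <= 0) return(NA_real_)
  -log(jxy / sqrt(jx * jy))
}

#' Three-sample admixture estimate at one locus
#'
#' `f = (p_admixed - p_parent2) / (p_parent1 - p_parent2)`: the
#' frequency-based estimate of the contribution of parent 1 to the admixed
#' group.  Not clipped to `[0, 1]`.
#'
#' @param p_admixed,p_parent1,p_parent2 Counted-allele frequencies.
#' @return Estimate, or `NA` when the parental frequencies coincide.
#' @export
admixture_estimate_locus <- function(p_admixed, p_parent1, p_parent2) {
  den <- p_parent1 - p_parent2
  if (den == 0) return(NA_real_)
  (p_admixed - p_parent2) / den
}

# default three-sample configuration: the lower-central deme as admixed,
# the trunk (upper-central) and basal southern demes as parents
default_trios <- function(group_names) {
  need <- c("LOWER-CENTRAL", "UPPER-CENTRAL", "SOUTHERN")
  if (all(need %in% group_names))
    list(c(admixed = "LOWER-CENTRAL", parent1 = "UPPER-CENTRAL",
           parent2 = "SOUTHERN"))
  else list()
}

#' Names of the summary-statistic components
#'
#' @param group_names Ordered group names.
#' @param trios List of named character triplets
#'   (`admixed`, `parent1`, `parent2`); `NULL` means the default single
#'   trio when the five standard groups are present.
#' @return Character vector of component names in pipeline order: per-group
#'   mean gene diversity, per-pair mean F_ST, per-pair mean Nei distance,
#'   per-trio mean admixture estimate.
#' @export
sumstat_names <- function(group_names, trios = NULL) {
  if (is.null(trios)) trios <- default_trios(group_names)
  pairs <- utils::combn(group_names, 2)
  c(paste0("HD.", group_names),
    paste0("FST.", pairs[1, ], "~", pairs[2, ]),
    paste0("NEI.", pairs[1, ], "~", pairs[2, ]),
    vapply(trios, function(tr)
      paste0("ADM.", tr[["admixed"]], "~", tr[["parent1"]], "~",
             tr[["parent2"]]), character(1)))
}

#' Compute the summary-statistic vector
#'
#' Single-sample means are over the complete locus distribution
#' (monomorphic-in-group loci contribute 0; loci with fewer than two
#' non-missing gene copies in a group are excluded from that group's
#' mean).  Two- and three-sample means are over loci whose per-locus value
#' is defined AND non-zero (values within 1e-12 of zero count as zero,
#' so the rule is stable under allele relabelling); negative theta values
#' are non-zero and are retained.  With five groups and the default single trio the vector has
#' 5 + 10 + 10 + 1 = 26 components.
#'
#' @param g A [genotype_matrix()].
#' @param trios See [sumstat_names()].
#' @return Named numeric vector of class `sumstat_vector`; attribute
#'   `n_contrib` records the number of contributing loci per component.
#' @export
compute_sumstats <- function(g, trios = NULL) {
  grp <- g$groups
  gn <- levels(grp)
  if (length(gn) < 2) stop("need at least two groups")
  if (ncol(g$geno) < 1) stop("need at least one locus")
  if (is.null(trios)) trios <- default_trios(gn)

  geno <- g$geno
  M <- !is.na(geno)
  g0 <- geno; g0[!M] <- 0L
  der <- rowsum(g0, grp)                       # groups x loci derived copies
  nind <- rowsum(M + 0L, grp)                  # non-missing individuals
  het <- rowsum((geno == 1L & M) + 0L, grp)    # observed heterozygotes
  ncop <- 2 * nind
  p <- der / ncop                              # NaN where ncop = 0
  hfreq <- het / nind

  nm <- sumstat_names(gn, trios)
  out <- setNames(numeric(length(nm)), nm)
  ncontrib <- setNames(integer(length(nm)), nm)

  # gene diversities: complete distribution
  H <- ncop / (ncop - 1) * 2 * p * (1 - p)
  for (i in seq_along(gn)) {
    def <- ncop[i, ] >= 2
    key <- paste0("HD.", gn[i])
    if (!any(def)) stop("empty contributing set for ", key)
    out[key] <- mean(H[i, def])
    ncontrib[key] <- sum(def)
  }

  nonzero_mean <- function(vals, key) {
    use <- is.finite(vals) & abs(vals) > 1e-12
    if (!any(use)) stop("empty contributing set for ", key)
    ncontrib[key] <<- sum(use)
    out[key] <<- mean(vals[use])
  }

  pairs <- utils::combn(seq_along(gn), 2)
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    n1 <- nind[i, ]; n2 <- nind[j, ]
    p1 <- p[i, ]; p2 <- p[j, ]
    h1 <- hfreq[i, ]; h2 <- hfreq[j, ]
    nbar <- (n1 + n2) / 2
    nc <- 2 * nbar - (n1^2 + n2^2) / (2 * nbar)
    pbar <- (n1 * p1 + n2 * p2) / (2 * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar
    hbar <- (n1 * h1 + n2 * h2) / (2 * nbar)
    a <- nbar / nc *
      (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
    b <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - s2 / 2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    theta <- a / (a + b + cc)
    theta[!is.finite(theta)] <- NA_real_
    theta[n1 < 1 | n2 < 1 | nbar <= 1] <- NA_real_
    nonzero_mean(theta, paste0("FST.", gn[i], "~", gn[j]))

    jx <- p1^2 + (1 - p1)^2
    jy <- p2^2 + (1 - p2)^2
    jxy <- p1 * p2 + (1 - p1) * (1 - p2)
    D <- -log(jxy / sqrt(jx * jy))
    D[!is.finite(D) | jxy <= 0] <- NA_real_
    D[ncop[i, ] < 2 | ncop[j, ] < 2] <- NA_real_
    nonzero_mean(D, paste0("NEI.", gn[i], "~", gn[j]))
  }

  for (tr in trios) {
    ia <- match(tr[["admixed"]], gn)
    i1 <- match(tr[["parent1"]], gn)
    i2 <- match(tr[["parent2"]], gn)
    if (anyNA(c(ia, i1, i2))) stop("trio references unknown group")
    den <- p[i1, ] - p[i2, ]
    f <- (p[ia, ] - p[i2, ]) / den
    f[den == 0 | !is.finite(f)] <- NA_real_
    nonzero_mean(f, paste0("ADM.", tr[["admixed"]], "~", tr[["parent1"]],
                           "~", tr[["parent2"]]))
  }

  structure(out, n_contrib = ncontrib, groups = gn, class = "sumstat_vector")
}

#' Serialize / read a summary-statistic vector as a one-row table
#'
#' @param s A `sumstat_vector`.
#' @param path File path (tab-delimited, stable header).
#' @return `read_sumstats()` returns the named numeric vector.
#' @export
write_sumstats <- function(s, path) {
  df <- as.data.frame(t(unclass(s)), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  setNames(as.numeric(df[1, ]), colnames(df))
}
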