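# SNP quality-control filter cascade: biallelic -> individual missingness
# -> MAF -> exact HWE -> F_ST outliers -> LD pruning, with complete-case
# selection applied separately for the ABC input.

new_filter_report <- function() {
  data.frame(stage = character(0), threshold = character(0),
             ind_in = integer(0), ind_out = integer(0),
             loci_in = integer(0), loci_out = integer(0),
             stringsAsFactors = FALSE)
}

add_stage <- function(report, stage, threshold, g_in, g_out, removed) {
  row <- data.frame(stage = stage, threshold = as.character(threshold),
                    ind_in = nrow(g_in$geno), ind_out = nrow(g_out$geno),
                    loci_in = ncol(g_in$geno), loci_out = ncol(g_out$geno),
                    stringsAsFactors = FALSE)
  rep2 <- rbind(report, row)
  rem <- attr(report, "removed") %||% list()
  rem[[stage]] <- removed
  attr(rep2, "removed") <- rem
  rep2
}

#' SNP filters
#'
#' Individual stages of the QC cascade.  Each takes and returns a
#' [genotype_matrix()]; each is idempotent.
#'
#' * `filter_biallelic()`: drop loci with more than two observed alleles
#'   (relevant to VCF input; simulated data are biallelic by
#'   construction).
#' * `filter_individual_missing()`: drop individuals whose missing
#'   fraction is `>= max_rate` (i.e. keep rates strictly below the
#'   threshold).
#' * `filter_maf()`: drop loci whose pooled non-missing minor-allele
#'   frequency is `<= min_maf` (keep MAF strictly above it).
#' * `filter_hwe()`: drop loci whose pooled-sample exact
#'   Hardy-Weinberg p-value is `<= alpha`; per-group mode tests each group
#'   and drops the locus if any group fails.
#' * `filter_fst_outliers()`: per-locus global multi-group
#'   Weir-Cockerham theta; under `mode = "remove_above"` loci with
#'   `theta > threshold` are dropped (undefined theta is not an outlier);
#'   `"remove_below"` inverts the rule.
#' * `ld_prune()`: greedy all-pairs pruning on the squared composite
#'   genotype correlation (codes 0/1/2, pairwise-complete); while any
#'   surviving pair has `r^2 >= r2_threshold`, the strongest pair is
#'   resolved by removing the member with higher missingness (ties: lower
#'   MAF, then the later locus).
#' * `complete_case()`: keep only loci with no missing genotypes.
#'
#' @param g A [genotype_matrix()].
#' @param max_rate,min_maf,alpha,threshold,r2_threshold Stage thresholds.
#' @param per_group Logical; test HWE within each group instead of the
#'   pooled sample.
#' @param mode F_ST filter direction.
#' @return A filtered `geno_matrix`.
#' @name snp_filters
NULL

#' @rdname snp_filters
#' @export
filter_biallelic <- function(g) {
  subset_geno(g, loci = which(g$n_alleles <= 2L))
}

#' @rdname snp_filters
#' @export
filter_individual_missing <- function(g, max_rate = 0.30) {
  rate <- rowMeans(is.na(g$geno))
  keep <- which(rate < max_rate)
  if (!length(keep)) stop("all individuals exceed the missingness threshold")
  subset_geno(g, ind = keep)
}

pooled_maf <- function(g) {
  der <- colSums(g$geno, na.rm = TRUE)
  ncop <- 2 * colSums(!is.na(g$geno))
  p <- der / ncop
  pmin(p, 1 - p)
}

#' @rdname snp_filters
#' @export
filter_maf <- function(g, min_maf = 0.05) {
  subset_geno(g, loci = which(pooled_maf(g) > min_maf))
}

#' Exact Hardy-Weinberg test for one biallelic locus
#'
#' Two-sided exact test conditional on the observed allele counts: the
#' p-value sums, over all heterozygote counts consistent with the allele
#' counts, the probabilities (under the Levene-Haldane conditional
#' distribution) that do not exceed that of the observed configuration.
#'
#' @param n_aa,n_ab,n_bb Genotype counts (reference homozygote,
#'   heterozygote, alternate homozygote).
#' @return Exact p-value in `(0, 1]`.
#' @export
hwe_exact_pvalue <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (n == 0) return(1)
  na_ <- 2 * n_aa + n_ab   # copies of allele a
  nb_ <- 2 * n_bb + n_ab
  hs <- seq(na_ %% 2, min(na_, nb_), by = 2)  # feasible het counts
  logp <- lgamma(n + 1) - lgamma((na_ - hs) / 2 + 1) - lgamma(hs + 1) -
    lgamma((nb_ - hs) / 2 + 1) + hs * log(2) +
    lgamma(na_ + 1) + lgamma(nb_ + 1) - lgamma(2 * n + 1)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  pobs <- pr[match(n_ab, hs)]
  sum(pr[pr <= pobs * (1 + 1e-9)])
}

locus_hwe_p <- function(geno_col) {
  x <- geno_col[!is.na(geno_col)]
  hwe_exact_pvalue(sum(x == 0), sum(x == 1), sum(x == 2))
}

#' @rdname snp_filters
#' @export
filter_hwe <- function(g, alpha = 0.01, per_group = FALSE) {
  if (!per_group) {
    p <- apply(g$geno, 2, locus_hwe_p)
  } else {
    p <- apply(g$geno, 2, function(col) {
      min(vapply(split(col, g$groups), locus_hwe_p, numeric(1)))
    })
  }
  subset_geno(g, loci = which(p > alpha))
}

locus_global_theta <- function(g) {
  gn <- levels(g$groups)
  vapply(seq_len(ncol(g$geno)), function(l) {
    wc_fst_locus(split(g$geno[, l], g$groups))
  }, numeric(1))
}

#' @rdname snp_filters
#' @export
filter_fst_outliers <- function(g, threshold = 0.1,
                                mode = c("remove_above", "remove_below")) {
  mode <- match.arg(mode)
  th <- locus_global_theta(g)
  drop <- if (mode == "remove_above") !is.na(th) & th > threshold
          else !is.na(th) & th < threshold
  subset_geno(g, loci = which(!drop))
}

#' @rdname snp_filters
#' @export
ld_prune <- function(g, r2_threshold = 0.8) {
  L <- ncol(g$geno)
  if (L < 2) return(g)
  r2 <- suppressWarnings(cor(g$geno, use = "pairwise.complete.obs"))^2
  diag(r2) <- 0
  r2[is.na(r2)] <- 0
  miss <- colMeans(is.na(g$geno))
  maf <- pooled_maf(g)
  alive <- rep(TRUE, L)
  repeat {
    r2a <- r2
    r2a[!alive, ] <- 0
    r2a[, !alive] <- 0
    m <- max(r2a)
    if (m < r2_threshold) break
    hit <- which(r2a == m, arr.ind = TRUE)
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    i <- hit[1, 1]; j <- hit[1, 2]
    # remove higher missingness; ties -> lower MAF; ties -> later locus
    drop <- if (miss[i] != miss[j]) {
      if (miss[i] > miss[j]) i else j
    } else if (maf[i] != maf[j]) {
      if (maf[i] < maf[j]) i else j
    } else j
    alive[drop] <- FALSE
  }
  subset_geno(g, loci = which(alive))
}

#' @rdname snp_filters
#' @export
complete_case <- function(g) {
  subset_geno(g, loci = which(colSums(is.na(g$geno)) == 0))
}

#' Run the QC filter cascade
#'
#' Applies, in order: biallelic, individual missingness, MAF, exact HWE,
#' F_ST outlier removal, LD pruning.  Complete-case selection is a
#' separate final step (enabled by `complete = TRUE`) used to prepare the
#' ABC input.
#'
#' @param g A [genotype_matrix()].
#' @param max_ind_missing,min_maf,hwe_alpha,fst_threshold,ld_r2 Stage
#'   thresholds (defaults: 0.30, 0.05, 0.01, 0.1, 0.8).
#' @param fst_mode,hwe_per_group See [snp_filters].
#' @param complete Apply [complete_case()] at the end.
#' @return `list(geno =, report =)`; the report telescopes — stage `k`'s
#'   output counts equal stage `k + 1`'s input counts — and carries the
#'   removed ids in its `removed` attribute.
#' @export
run_cascade <- function(g, max_ind_missing = 0.30, min_maf = 0.05,
                        hwe_alpha = 0.01, fst_threshold = 0.1,
                        fst_mode = "remove_above", hwe_per_group = FALSE,
                        ld_r2 = 0.8, complete = FALSE) {
  rep <- new_filter_report()
  step <- function(rep, name, thr, gi, go) {
    removed <- setdiff(colnames(gi$geno), colnames(go$geno))
    if (nrow(go$geno) < nrow(gi$geno))
      removed <- c(removed, setdiff(rownames(gi$geno), rownames(go$geno)))
    add_stage(rep, name, thr, gi, go, removed)
  }
  g1 <- filter_biallelic(g)
  rep <- step(rep, "biallelic", "<=2 alleles", g, g1)
  g2 <- filter_individual_missing(g1, max_ind_missing)
  rep <- step(rep, "ind_missing", max_ind_missing, g1, g2)
  g3 <- filter_maf(g2, min_maf)
  rep <- step(rep, "maf", min_maf, g2, g3)
  g4 <- filter_hwe(g3, hwe_alpha, per_group = hwe_per_group)
  rep <- step(rep, "hwe", hwe_alpha, g3, g4)
  g5 <- filter_fst_outliers(g4, fst_threshold, mode = fst_mode)
  rep <- step(rep, "fst", fst_threshold, g4, g5)
  g6 <- ld_prune(g5, ld_r2)
  rep <- step(rep, "ld", ld_r2, g5, g6)
  if (complete) {
    g7 <- complete_case(g6)
    rep <- step(rep, "complete_case", "no missing", g6, g7)
    g6 <- g7
  }
  list(geno = g6, report = rep)
}
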