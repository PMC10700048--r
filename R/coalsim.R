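#' Group configuration
#'
#' Ordered sampled groups and their diploid sample counts.  The order is
#' fixed for the whole pipeline: deme indexing, genotype-matrix row blocks
#' and summary-statistic component order all follow it.
#'
#' @param sizes Named integer vector of diploid counts per group.
#' @return Object of class `group_config` (a named integer vector).
#' @export
group_config <- function(sizes) {
  stopifnot(!is.null(names(sizes)), all(nzchar(names(sizes))),
            !anyDuplicated(names(sizes)), all(sizes >= 1))
  structure(as.integer(round(sizes)), names = names(sizes),
            class = "group_config")
}

#' Default five-group sampling configuration
#'
#' 124 diploid individuals: SOUTHERN 28, LOWER-CENTRAL 41, UPPER-CENTRAL
#' 27, EASTERN 14, NORTHERN 14 — the pooled five genetic units of the
#' nine-population sampling design emulated by [make_observed()].
#'
#' @return A [group_config()].
#' @export
default_groups <- function() {
  group_config(c("SOUTHERN" = 28, "LOWER-CENTRAL" = 41,
                 "UPPER-CENTRAL" = 27, "EASTERN" = 14, "NORTHERN" = 14))
}

# instantiate a scenario with a parameter draw against a group config;
# returns the numeric event encoding shared by the R and C++ engines
compile_scenario <- function(sc, draw, groups) {
  v <- validate_scenario(sc)
  if (length(v)) stop("invalid scenario: ", paste(v, collapse = "; "))
  if (!all(sc$demes %in% names(groups)))
    stop("group config lacks demes: ",
         paste(setdiff(sc$demes, names(groups)), collapse = ", "))
  need <- scenario_params(sc)
  miss <- setdiff(need, names(draw))
  if (length(miss))
    stop("draw lacks parameters: ", paste(miss, collapse = ", "))
  ss <- 2L * unname(groups[sc$demes])  # gene copies per deme
  N0 <- unname(draw[unname(sc$sizes)])
  di <- function(x) match(x, sc$demes)
  ev <- lapply(sc$events, function(e) {
    if (e$kind == "merge") {
      list(time = unname(draw[[e$time]]), kind = 0L,
           a = di(e$source), b = di(e$dest), c = 1L, rate = 0,
           newsize = if (is.null(e$new_size)) -1 else unname(draw[[e$new_size]]))
    } else {
      list(time = unname(draw[[e$time]]), kind = 1L,
           a = di(e$admixed), b = di(e$parent1), c = di(e$parent2),
           rate = unname(draw[[e$rate]]), newsize = -1)
    }
  })
  ev <- ev[order(vapply(ev, `[[`, 0, "time"))]
  g <- function(f, what) vapply(ev, `[[`, f, what)
  list(sample_sizes = ss, deme_sizes = N0,
       ev_time = g(0, "time"), ev_kind = g(0L, "kind"),
       ev_a = g(0L, "a") - 1L, ev_b = g(0L, "b") - 1L,
       ev_c = g(0L, "c") - 1L, ev_rate = g(0, "rate"),
       ev_newsize = g(0, "newsize"))
}

# pure-R coalescent engine, mirroring the compiled core; used as the
# slow cross-check route and to expose full genealogies
r_sim_genealogy <- function(sample_sizes, deme_sizes, ev_time, ev_kind,
                            ev_a, ev_b, ev_c, ev_rate, ev_newsize) {
  ss <- sample_sizes
  N <- deme_sizes
  n <- sum(ss)
  nn <- 2L * n - 1L
  ntime <- numeric(nn)
  parent <- integer(nn)  # 0 = root
  lin <- vector("list", length(ss))
  idx <- 0L
  for (d in seq_along(ss)) {
    lin[[d]] <- idx + seq_len(ss[d])
    idx <- idx + ss[d]
  }
  next_node <- n + 1L
  total <- n
  ei <- 1L
  nev <- length(ev_time)
  t <- 0
  while (total > 1L) {
    tmin <- Inf; dmin <- -1L
    for (d in seq_along(lin)) {
      k <- length(lin[[d]])
      if (k >= 2L) {
        if (!(N[d] > 0)) stop("lineages present in a deme with no positive size")
        w <- stats::rexp(1, rate = k * (k - 1) / (4 * N[d]))
        if (t + w < tmin) { tmin <- t + w; dmin <- d }
      }
    }
    tev <- if (ei <= nev) ev_time[ei] else Inf
    if (tev <= tmin) {
      if (!is.finite(tev))
        stop("lineages stranded in disconnected demes: no common ancestor")
      t <- tev
      a <- ev_a[ei] + 1L; b <- ev_b[ei] + 1L
      if (ev_kind[ei] == 0L) {
        lin[[b]] <- c(lin[[b]], lin[[a]])
        lin[[a]] <- integer(0)
        if (ev_newsize[ei] > 0) N[b] <- ev_newsize[ei]
      } else {
        cc <- ev_c[ei] + 1L
        to1 <- runif(length(lin[[a]])) < ev_rate[ei]
        lin[[b]] <- c(lin[[b]], lin[[a]][to1])
        lin[[cc]] <- c(lin[[cc]], lin[[a]][!to1])
        lin[[a]] <- integer(0)
      }
      ei <- ei + 1L
    } else {
      t <- tmin
      k <- length(lin[[dmin]])
      pair <- sample.int(k, 2L)
      p <- next_node; next_node <- next_node + 1L
      ntime[p] <- t
      parent[lin[[dmin]][pair]] <- p
      lin[[dmin]] <- c(lin[[dmin]][-pair], p)
      total <- total - 1L
    }
  }
  bl <- ntime[parent[parent > 0L]] - ntime[parent > 0L]
  structure(list(n_leaves = n, times = ntime, parent = parent,
                 total_length = sum(bl)),
            class = "genealogy")
}

#' Simulate a single-locus genealogy under a scenario
#'
#' Backward-time coalescent with piecewise-constant deme sizes: within a
#' deme of diploid size N each lineage pair coalesces at rate 1/(2N) per
#' generation (exponential waiting times); merge events move all lineages
#' of the source deme into the destination; admixture events route each
#' lineage of the admixed deme to parent 1 with probability `ra`, else to
#' parent 2.  Above the final event the remaining lineages coalesce in the
#' ancestral deme.
#'
#' @param sc A validated `scenario`.
#' @param draw Named parameter draw (see [sample_prior()]).
#' @param groups A [group_config()] covering the scenario's demes.
#' @param engine `"cpp"` (compiled, default) or `"r"` (pure-R reference
#'   implementation of the same algorithm).
#' @return A `genealogy`: leaf count, node times (generations; leaves at
#'   0), parent pointers (0 = root) and total branch length.  Leaves are
#'   ordered by deme block, two consecutive gene copies per individual.
#' @export
simulate_genealogy <- function(sc, draw, groups, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  cmp <- compile_scenario(sc, draw, groups)
  if (engine == "cpp") {
    g <- sim_genealogy_cpp(cmp$sample_sizes, cmp$deme_sizes, cmp$ev_time,
                           cmp$ev_kind, cmp$ev_a, cmp$ev_b, cmp$ev_c,
                           cmp$ev_rate, cmp$ev_newsize)
    structure(g, class = "genealogy")
  } else {
    do.call(r_sim_genealogy, cmp[c("sample_sizes", "deme_sizes", "ev_time",
                                   "ev_kind", "ev_a", "ev_b", "ev_c",
                                   "ev_rate", "ev_newsize")])
  }
}

#' Place one mutation uniformly on a genealogy
#'
#' The mutation point is drawn uniformly over total branch length (the
#' root carries no branch), so every locus is polymorphic in the pooled
#' sample by construction.  Gene copies descending from the mutated branch
#' carry the derived allele.
#'
#' @param gen A `genealogy`.
#' @return Integer 0/1 vector of derived-allele indicators per leaf.
#' @export
place_mutation <- function(gen) {
  n <- gen$n_leaves
  if (n < 2) stop("genealogy needs at least two leaves")
  par <- gen$parent
  nn <- length(par)
  has_par <- par > 0L
  bl <- numeric(nn)
  bl[has_par] <- gen$times[par[has_par]] - gen$times[has_par]
  u <- runif(1, 0, sum(bl))
  cs <- cumsum(bl)
  bsel <- which(u < cs)[1]
  if (is.na(bsel)) bsel <- max(which(has_par))
  # internal nodes are created in increasing time order, so every child has
  # a smaller index than its parent: one descending sweep marks the subtree
  below <- logical(nn)
  below[bsel] <- TRUE
  for (v in rev(seq_len(nn))) {
    if (below[v] && v > n) below[par == v] <- TRUE
  }
  as.integer(below[seq_len(n)])
}

#' Simulate a multilocus diploid SNP dataset
#'
#' Loci are independent: each is a fresh genealogy with a single uniform
#' mutation.  Consecutive gene copies within a deme are paired into
#' diploid individuals.  No missing data are produced.
#'
#' @inheritParams simulate_genealogy
#' @param n_loci Number of independent SNP loci.
#' @param min_maf Optional pooled minor-allele-frequency rejection
#'   threshold applied to simulated loci; `0` (default) disables it,
#'   matching a simulator run with the frequency criterion left at its
#'   default.
#' @return A [genotype_matrix()] of 0/1/2 derived-allele counts,
#'   individuals x loci.
#' @export
simulate_dataset <- function(sc, draw, groups, n_loci,
                             engine = c("cpp", "r"), min_maf = 0) {
  engine <- match.arg(engine)
  stopifnot(n_loci >= 1)
  cmp <- compile_scenario(sc, draw, groups)
  grp <- factor(rep(sc$demes, times = unname(groups[sc$demes])),
                levels = sc$demes)
  ids <- unlist(lapply(sc$demes, function(d)
    paste0(gsub("[^A-Za-z0-9]", "_", d), "_", seq_len(groups[[d]]))))
  if (engine == "cpp") {
    G <- sim_dataset_cpp(as.integer(n_loci), cmp$sample_sizes,
                         cmp$deme_sizes, cmp$ev_time, cmp$ev_kind,
                         cmp$ev_a, cmp$ev_b, cmp$ev_c, cmp$ev_rate,
                         cmp$ev_newsize, min_maf)
  } else {
    n_ind <- sum(cmp$sample_sizes) %/% 2L
    G <- matrix(0L, n_ind, n_loci)
    for (l in seq_len(n_loci)) {
      repeat {
        gen <- do.call(r_sim_genealogy,
                       cmp[c("sample_sizes", "deme_sizes", "ev_time",
                             "ev_kind", "ev_a", "ev_b", "ev_c", "ev_rate",
                             "ev_newsize")])
        der <- place_mutation(gen)
        f <- mean(der)
        if (min_maf <= 0 || min(f, 1 - f) > min_maf) break
      }
      G[, l] <- der[c(TRUE, FALSE)] + der[c(FALSE, TRUE)]
    }
  }
  dimnames(G) <- list(ids, paste0("L", seq_len(n_loci)))
  genotype_matrix(G, grp)
}

#' Genotype matrix container
#'
#' Individuals x loci biallelic genotype codes (0/1/2 copies of the
#' counted allele, `NA` = missing) with a per-individual group assignment
#' and optional per-locus observed allele counts (for multi-allelic sites
#' read from VCF before filtering).
#'
#' @param geno Integer matrix, individuals x loci, values in
#'   `{0, 1, 2, NA}`.
#' @param groups Factor (or character) of group labels, one per row.
#' @param n_alleles Optional integer vector of observed allele counts per
#'   locus (default 2).
#' @return Object of class `geno_matrix`.
#' @export
genotype_matrix <- function(geno, groups, n_alleles = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  ok <- geno %in% c(0L, 1L, 2L) | is.na(geno)
  if (!all(ok)) stop("genotype codes must be 0, 1, 2 or NA")
  groups <- if (is.factor(groups)) groups else factor(groups, levels = unique(groups))
  if (length(groups) != nrow(geno))
    stop("group assignment length must equal the number of individuals")
  if (is.null(rownames(geno)) && nrow(geno) > 0)
    rownames(geno) <- paste0("IND", seq_len(nrow(geno)))
  if (is.null(colnames(geno)) && ncol(geno) > 0)
    colnames(geno) <- paste0("L", seq_len(ncol(geno)))
  n_alleles <- if (is.null(n_alleles)) rep(2L, ncol(geno)) else as.integer(n_alleles)
  stopifnot(length(n_alleles) == ncol(geno))
  structure(list(geno = geno, groups = groups, n_alleles = n_alleles),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("<geno_matrix> ", nrow(x$geno), " individuals x ", ncol(x$geno),
      " loci\n", sep = "")
  cat("  groups:", paste0(levels(x$groups), " (",
                          tabulate(x$groups, nlevels(x$groups)), ")",
                          collapse = ", "), "\n")
  mis <- mean(is.na(x$geno))
  cat(sprintf("  missing: %.2f%%\n", 100 * mis))
  invisible(x)
}

# subset helper used by the QC cascade
subset_geno <- function(g, ind = NULL, loci = NULL) {
  keep_i <- if (is.null(ind)) seq_len(nrow(g$geno)) else ind
  keep_l <- if (is.null(loci)) seq_len(ncol(g$geno)) else loci
  genotype_matrix(g$geno[keep_i, keep_l, drop = FALSE],
                  droplevels(g$groups[keep_i]),
                  g$n_alleles[keep_l])
}
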