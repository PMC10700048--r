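# ABC machinery: reference tables, scenario choice (direct k-NN and
# logistic regression on discriminant scores), prior error rates,
# local-linear posterior estimation with logit transforms, time
# recalibration, and posterior-predictive model checking.

#' Build a prior-predictive reference table
#'
#' For each scenario: draw parameters from the prior, simulate a dataset
#' of `n_loci` unlinked SNPs for the given group configuration, and record
#' the summary-statistic vector.  Rows carry full provenance (scenario id
#' and parameter draw); tables built in batches can be concatenated with
#' [combine_reference_tables()].
#'
#' @param scenarios List of validated `scenario` objects.
#' @param priors A [prior_spec()].
#' @param groups A [group_config()].
#' @param n_loci Loci per simulated dataset.
#' @param n_per_scenario Simulations per scenario.
#' @param seed Optional integer seed (`set.seed`) for the whole build.
#' @param trios Three-sample statistic configuration (see
#'   [sumstat_names()]).
#' @return An object of class `ref_table` with elements `stats` (n x S
#'   matrix), `params` (n x 11 matrix, `NA` for parameters a scenario does
#'   not use), `scenario` (integer vector) and `meta`.
#' @export
build_reference_table <- function(scenarios, priors, groups, n_loci,
                                  n_per_scenario, seed = NULL,
                                  trios = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(trios)) trios <- default_trios(names(groups))
  n_total <- length(scenarios) * n_per_scenario
  n_degenerate <- 0L
  snames <- sumstat_names(names(groups), trios)
  stats <- matrix(NA_real_, n_total, length(snames),
                  dimnames = list(NULL, snames))
  params <- matrix(NA_real_, n_total, length(.param_order),
                   dimnames = list(NULL, .param_order))
  scen <- integer(n_total)
  row <- 0L
  for (sc in scenarios) {
    v <- validate_scenario(sc)
    if (length(v)) stop("invalid scenario ", sc$id, ": ",
                        paste(v, collapse = "; "))
    for (i in seq_len(n_per_scenario)) {
      row <- row + 1L
      tries <- 0L
      repeat {
        draw <- sample_prior(sc, priors)
        g <- simulate_dataset(sc, draw, groups, n_loci)
        s <- tryCatch(compute_sumstats(g, trios = trios),
                      error = function(e) NULL)
        if (!is.null(s)) break
        # degenerate draw (some statistic has an empty contributing
        # set); redraw rather than abort the build
        tries <- tries + 1L
        n_degenerate <- n_degenerate + 1L
        if (tries >= 100L)
          stop("reference row ", row, " (scenario ", sc$id,
               "): 100 consecutive degenerate draws")
      }
      stats[row, ] <- as.numeric(s)
      params[row, names(draw)] <- draw
      scen[row] <- sc$id
    }
  }
  if (n_degenerate > 0L)
    warning(n_degenerate, " degenerate prior draw(s) were resampled")
  structure(list(stats = stats, params = params, scenario = scen,
                 meta = list(scenarios = scenarios, priors = priors,
                             groups = groups, n_loci = n_loci,
                             trios = trios, seed = seed,
                             per_scenario = table(scen))),
            class = "ref_table")
}

#' @export
print.ref_table <- function(x, ...) {
  cat("<ref_table> ", nrow(x$stats), " rows x ", ncol(x$stats),
      " summary statistics; scenarios: ",
      paste(names(x$meta$per_scenario), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Concatenate reference tables built in batches
#'
#' @param ... `ref_table` objects sharing one statistic header and group
#'   configuration.
#' @return A single `ref_table`.
#' @export
combine_reference_tables <- function(...) {
  tabs <- list(...)
  h <- colnames(tabs[[1]]$stats)
  for (t in tabs)
    if (!identical(colnames(t$stats), h))
      stop("reference tables have different statistic headers")
  out <- tabs[[1]]
  out$stats <- do.call(rbind, lapply(tabs, `[[`, "stats"))
  out$params <- do.call(rbind, lapply(tabs, `[[`, "params"))
  out$scenario <- unlist(lapply(tabs, `[[`, "scenario"))
  out$meta$per_scenario <- table(out$scenario)
  out
}

#' Persist / load a reference table
#'
#' The table body is a tab-delimited file (scenario id, the 11 parameter
#' columns, then the statistic columns); metadata (priors, groups, loci,
#' scenario definitions) go to a JSON sidecar at `paste0(path, ".meta.json")`.
#'
#' @param ref A `ref_table`.
#' @param path Body file path.
#' @return `read_reference_table()` returns the `ref_table`.
#' @export
write_reference_table <- function(ref, path) {
  body <- data.frame(scenario = ref$scenario, ref$params, ref$stats,
                     check.names = FALSE)
  utils::write.table(body, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  meta <- ref$meta
  sidecar <- paste0(path, ".meta.json")
  write_scenario_config(meta$scenarios, meta$priors, sidecar)
  extra <- list(groups = as.list(setNames(as.integer(meta$groups),
                                          names(meta$groups))),
                n_loci = meta$n_loci, trios = meta$trios,
                seed = meta$seed)
  cfg <- jsonlite::read_json(sidecar)
  cfg$extra <- extra
  jsonlite::write_json(cfg, sidecar, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_reference_table
#' @export
read_reference_table <- function(path) {
  body <- utils::read.delim(path, check.names = FALSE)
  sidecar <- paste0(path, ".meta.json")
  cfg <- read_scenario_config(sidecar)
  raw <- jsonlite::read_json(sidecar)
  groups <- group_config(setNames(as.integer(unlist(raw$extra$groups)),
                                  names(raw$extra$groups)))
  trios <- lapply(raw$extra$trios, function(tr)
    setNames(as.character(unlist(tr)), names(tr)))
  pcols <- intersect(.param_order, colnames(body))
  scols <- setdiff(colnames(body), c("scenario", pcols))
  structure(list(stats = as.matrix(body[, scols, drop = FALSE]),
                 params = as.matrix(body[, pcols, drop = FALSE]),
                 scenario = body$scenario,
                 meta = list(scenarios = cfg$scenarios, priors = cfg$priors,
                             groups = groups,
                             n_loci = raw$extra$n_loci, trios = trios,
                             seed = raw$extra$seed,
                             per_scenario = table(body$scenario))),
            class = "ref_table")
}

# standardize reference stats by their table standard deviation (MAD
# behind a flag); zero-variance columns are dropped with a warning
std_stats <- function(ref, observed, robust = FALSE) {
  s <- if (robust) apply(ref$stats, 2, stats::mad) else apply(ref$stats, 2, sd)
  keep <- is.finite(s) & s > 0
  if (!all(keep))
    warning("dropping zero-variance statistic columns: ",
            paste(colnames(ref$stats)[!keep], collapse = ", "))
  obs <- as.numeric(observed)[match(colnames(ref$stats), names(observed))]
  if (anyNA(obs)) {
    if (is.null(names(observed)) &&
        length(observed) == ncol(ref$stats)) obs <- as.numeric(observed)
    else stop("observed statistics do not match the reference header")
  }
  Z <- sweep(ref$stats[, keep, drop = FALSE], 2, s[keep], "/")
  zobs <- obs[keep] / s[keep]
  list(Z = Z, zobs = zobs, keep = keep, scale = s)
}

euclid_to_obs <- function(Z, zobs) {
  sqrt(colSums((t(Z) - zobs)^2))
}

scenario_ids <- function(ref) {
  vapply(ref$meta$scenarios, `[[`, numeric(1), "id")
}

#' Scenario choice: direct approach
#'
#' Posterior probability of each scenario as its share of the `k`
#' reference rows nearest the observed statistics, after standardizing
#' every statistic by its reference-table standard deviation (Euclidean
#' distance; ties at the k-th distance broken by row order).  95% CIs are
#' Clopper-Pearson intervals on the nearest-neighbour counts.
#'
#' @param ref A `ref_table`.
#' @param observed A `sumstat_vector` (or named numeric matching the
#'   table's header).
#' @param k Number of nearest reference rows (default 500).
#' @param robust Standardize by MAD instead of SD.
#' @return Object of class `model_choice`: a data frame with one row per
#'   scenario (`scenario`, `pp`, `ci_lower`, `ci_upper`).
#' @export
direct_pp <- function(ref, observed, k = 500, robust = FALSE) {
  stopifnot(k >= 1, k <= nrow(ref$stats))
  st <- std_stats(ref, observed, robust)
  d <- euclid_to_obs(st$Z, st$zobs)
  sel <- order(d)[seq_len(k)]
  ids <- scenario_ids(ref)
  cnt <- vapply(ids, function(i) sum(ref$scenario[sel] == i), numeric(1))
  pp <- cnt / k
  lo <- ifelse(cnt == 0, 0, qbeta(0.025, cnt, k - cnt + 1))
  hi <- ifelse(cnt == k, 1, qbeta(0.975, cnt + 1, k - cnt))
  structure(data.frame(scenario = ids, pp = pp, ci_lower = lo,
                       ci_upper = hi),
            method = "direct", k = k, class = c("model_choice",
                                                "data.frame"))
}

#' @export
print.model_choice <- function(x, ...) {
  cat("<model_choice: ", attr(x, "method"), ">\n", sep = "")
  print.data.frame(format(as.data.frame(x), digits = 4), row.names = FALSE)
  invisible(x)
}

# manual ridge-regularized LDA fallback for singular within-class fits
ridge_lda_scores <- function(Z, lab, zobs) {
  cls <- levels(lab)
  mu <- rowsum(Z, lab) / as.vector(table(lab))
  W <- matrix(0, ncol(Z), ncol(Z))
  for (cl in cls) {
    Zi <- Z[lab == cl, , drop = FALSE]
    if (nrow(Zi) > 1) W <- W + crossprod(scale(Zi, scale = FALSE))
  }
  W <- W / max(1, nrow(Z) - length(cls))
  W <- W + diag(1e-6 * mean(diag(W)) + 1e-12, ncol(Z))
  gm <- colMeans(Z)
  B <- crossprod(sweep(mu, 2, gm) * sqrt(as.vector(table(lab))))
  ev <- eigen(solve(W, B))
  naxes <- min(length(cls) - 1, ncol(Z))
  A <- Re(ev$vectors[, seq_len(naxes), drop = FALSE])
  list(scores = Z %*% A, obs = drop(rbind(zobs) %*% A))
}

#' Scenario choice: logistic-regression approach
#'
#' Selects the fraction of reference rows closest to the observed
#' statistics, replaces the statistics by linear-discriminant scores
#' fitted on that subset, and fits a multinomial logistic regression of
#' scenario label on the scores, weighting rows by an Epanechnikov kernel
#' of their distance scaled to the subset maximum.  The posterior
#' probabilities are the fitted class probabilities at the observed
#' point's scores; 95% CIs come from the asymptotic covariance of the
#' regression coefficients via the delta method.
#'
#' @inheritParams direct_pp
#' @param fraction Fraction of the table to retain (default 0.01).
#' @return A `model_choice` data frame over all scenarios in the table
#'   (scenarios absent from the selected subset get probability 0).
#' @export
logistic_pp <- function(ref, observed, fraction = 0.01, robust = FALSE) {
  st <- std_stats(ref, observed, robust)
  d <- euclid_to_obs(st$Z, st$zobs)
  m <- max(2L, ceiling(fraction * nrow(ref$stats)))
  sel <- order(d)[seq_len(m)]
  ids <- scenario_ids(ref)
  labs_all <- ref$scenario[sel]
  present <- sort(unique(labs_all))
  res <- data.frame(scenario = ids, pp = 0, ci_lower = 0, ci_upper = 0)
  if (length(present) < 2) {
    warning("selected subset contains a single scenario; returning PP = 1")
    res$pp[res$scenario == present] <- 1
    res$ci_lower[res$scenario == present] <- 1
    res$ci_upper[res$scenario == present] <- 1
    return(structure(res, method = "logistic", fraction = fraction,
                     class = c("model_choice", "data.frame")))
  }
  lab <- factor(labs_all, levels = present)
  Zs <- st$Z[sel, , drop = FALSE]
  sds <- apply(Zs, 2, sd)
  use <- is.finite(sds) & sds > 1e-10
  Zs <- Zs[, use, drop = FALSE]
  zo <- st$zobs[use]
  proj <- tryCatch({
    fit <- MASS::lda(Zs, grouping = lab)
    list(scores = predict(fit, Zs)$x,
         obs = drop(predict(fit, rbind(zo))$x))
  }, error = function(e) ridge_lda_scores(Zs, lab, zo))
  dm <- max(d[sel])
  w <- if (dm > 0) 1 - (d[sel] / dm)^2 else rep(1, m)
  w <- pmax(w, 1e-8)
  sco <- as.data.frame(proj$scores)
  names(sco) <- paste0("LD", seq_len(ncol(sco)))
  dat <- cbind(lab = lab, sco)
  fit <- nnet::multinom(lab ~ ., data = dat, weights = w, trace = FALSE,
                        Hess = TRUE, maxit = 500)
  newd <- as.data.frame(rbind(proj$obs))
  names(newd) <- names(sco)
  xobs <- c(1, as.numeric(proj$obs))
  K <- length(present)
  prob_fun <- function(theta) {
    B <- matrix(theta, nrow = K - 1, byrow = TRUE)
    eta <- c(0, as.numeric(B %*% xobs))
    e <- exp(eta - max(eta))
    e / sum(e)
  }
  cf <- coef(fit)
  theta <- if (is.matrix(cf)) as.vector(t(cf)) else as.numeric(cf)
  p <- prob_fun(theta)
  V <- tryCatch(vcov(fit), error = function(e) NULL)
  se <- rep(NA_real_, K)
  if (!is.null(V) && nrow(V) == length(theta)) {
    J <- matrix(0, K, length(theta))
    for (j in seq_along(theta)) {
      h <- 1e-5 * (1 + abs(theta[j]))
      tp <- theta; tp[j] <- tp[j] + h
      tm <- theta; tm[j] <- tm[j] - h
      J[, j] <- (prob_fun(tp) - prob_fun(tm)) / (2 * h)
    }
    se <- sqrt(pmax(0, diag(J %*% V %*% t(J))))
  }
  idx <- match(present, ids)
  res$pp[idx] <- p
  res$ci_lower[idx] <- pmax(0, p - 1.96 * se)
  res$ci_upper[idx] <- pmin(1, p + 1.96 * se)
  res$pp <- res$pp / sum(res$pp)
  structure(res, method = "logistic", fraction = fraction,
            class = c("model_choice", "data.frame"))
}

#' Prior error rate from pseudo-observed datasets
#'
#' Simulates `n_pods` fresh datasets from the prior under a known true
#' scenario, runs the chosen model-choice method against the reference
#' table for each, and reports the fraction of pods in which the true
#' scenario does not attain the strictly highest posterior probability
#' (ties count as errors).
#'
#' @param ref A `ref_table` (its metadata supplies scenarios, priors,
#'   groups and locus count for the pods).
#' @param true_scenario Scenario id that generates the pods.
#' @param n_pods Number of pseudo-observed datasets.
#' @param method `"direct"` or `"logistic"`.
#' @param k,fraction Method tuning (see [direct_pp()], [logistic_pp()]).
#' @param seed Optional `set.seed` value.
#' @return Object of class `prior_error`: true scenario, method, pod
#'   count, error rate, and the table of winning scenarios.
#' @export
prior_error_rate <- function(ref, true_scenario, n_pods = 1000,
                             method = c("direct", "logistic"), k = 500,
                             fraction = 0.01, seed = NULL) {
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  meta <- ref$meta
  ids <- scenario_ids(ref)
  sc <- meta$scenarios[[match(true_scenario, ids)]]
  winners <- integer(n_pods)
  errors <- logical(n_pods)
  for (i in seq_len(n_pods)) {
    tries <- 0L
    repeat {  # degenerate pods are resampled, as in the table build
      draw <- sample_prior(sc, meta$priors)
      g <- simulate_dataset(sc, draw, meta$groups, meta$n_loci)
      s <- tryCatch(compute_sumstats(g, trios = meta$trios),
                    error = function(e) NULL)
      if (!is.null(s)) break
      tries <- tries + 1L
      if (tries >= 100L) stop("100 consecutive degenerate pod draws")
    }
    mc <- if (method == "direct")
      suppressWarnings(direct_pp(ref, s, k = k))
    else suppressWarnings(logistic_pp(ref, s, fraction = fraction))
    top <- mc$pp == max(mc$pp)
    winners[i] <- mc$scenario[which(top)[1]]
    errors[i] <- sum(top) > 1 || mc$scenario[which.max(mc$pp)] != true_scenario
  }
  structure(list(true_scenario = true_scenario, method = method,
                 n_pods = n_pods, error_rate = mean(errors),
                 winners = table(factor(winners, levels = ids))),
            class = "prior_error")
}

#' @export
print.prior_error <- function(x, ...) {
  cat("<prior_error> true scenario ", x$true_scenario, ", ", x$method,
      " approach, ", x$n_pods, " pods\n", sep = "")
  cat(sprintf("  error rate: %.3f\n", x$error_rate))
  print(x$winners)
  invisible(x)
}

#' Statistic subsets for estimation and model checking
#'
#' The shipped split of the summary-statistic vector: parameter
#' estimation uses the gene-diversity and F_ST components; the
#' "less biased" model check uses the complementary Nei-distance and
#' admixture components, so goodness-of-fit is not judged with the same
#' statistics that drove the fit.
#'
#' @param stat_names Full statistic header (e.g.
#'   `colnames(ref$stats)` or `sumstat_names(...)`).
#' @return Character vector of component names.
#' @export
estimation_stats <- function(stat_names) {
  grep("^(HD|FST)\\.", stat_names, value = TRUE)
}

#' @rdname estimation_stats
#' @export
checking_stats <- function(stat_names) {
  grep("^(NEI|ADM)\\.", stat_names, value = TRUE)
}

# GCV-selected ridge solution of the weighted local-linear system;
# returns the slope matrix (p x q) for centered X and Y
ridge_slopes <- function(X, Y, w, lambdas = c(0, 10^seq(-4, 3, by = 0.5))) {
  sw <- sqrt(w)
  Xw <- X * sw
  Yw <- Y * sw
  sv <- svd(Xw)
  n <- nrow(X)
  best <- NULL
  bestg <- Inf
  for (lam in lambdas) {
    dl <- sv$d / (sv$d^2 + lam)
    beta <- sv$v %*% (dl * crossprod(sv$u, Yw))
    df <- sum(sv$d^2 / (sv$d^2 + lam))
    rss <- colSums((Yw - Xw %*% beta)^2)
    g <- sum(rss) / (n * max(1e-8, 1 - (df + 1) / n)^2)
    if (g < bestg) { bestg <- g; best <- beta }
  }
  best
}

#' Posterior parameter estimation by local-linear regression
#'
#' Among the reference rows of one scenario, selects the fraction closest
#' to the observed statistics, maps every parameter to
#' `logit((theta - a) / (b - a))` against its prior bounds, regresses the
#' transformed parameters on the standardized statistics (weighted
#' local-linear fit, Epanechnikov kernel with bandwidth equal to the
#' largest accepted distance), forms adjusted draws as fitted value at the
#' observed point plus residuals, back-transforms, and summarizes with
#' kernel-weighted mean, median, mode (Gaussian KDE, Silverman bandwidth)
#' and quantiles.
#'
#' @inheritParams direct_pp
#' @param scenario_id Scenario whose rows are used.
#' @param fraction Fraction of that scenario's rows accepted.
#' @param min_rows Minimum acceptable accepted-set size (default 50).
#' @param stat_subset Statistic names used for both the distance and the
#'   regression; `NULL` (default) uses the full vector.  The shipped
#'   pipeline passes [estimation_stats()] here and reserves
#'   [checking_stats()] for [model_check()].
#' @param method `"loclinear"` (default): ordinary weighted least
#'   squares; `"ridge"`: GCV-selected ridge shrinkage of the same fit,
#'   for ill-conditioned statistic sets; `"rejection"`: no regression
#'   adjustment.
#' @return Object of class `posterior_estimate` with a `summary` data
#'   frame (mean, median, mode, quantiles 0.025/0.05/0.5/0.95/0.975 per
#'   parameter), the adjusted `draws`, kernel `weights`, and the
#'   transform record.
#' @export
estimate_parameters <- function(ref, observed, scenario_id,
                                fraction = 0.01, min_rows = 50,
                                stat_subset = NULL,
                                method = c("loclinear", "ridge",
                                           "rejection"),
                                robust = FALSE) {
  method <- match.arg(method)
  rows <- which(ref$scenario == scenario_id)
  if (!length(rows)) stop("no reference rows for scenario ", scenario_id)
  ref_use <- ref
  if (!is.null(stat_subset)) {
    cols <- intersect(stat_subset, colnames(ref$stats))
    if (!length(cols)) stop("stat_subset matches no statistic columns")
    ref_use$stats <- ref$stats[, cols, drop = FALSE]
  }
  st <- std_stats(ref_use, observed, robust)
  d <- euclid_to_obs(st$Z[rows, , drop = FALSE], st$zobs)
  m <- max(1L, ceiling(fraction * length(rows)))
  if (m < min_rows)
    stop("insufficient acceptance: fraction yields ", m, " rows (< ",
         min_rows, ")")
  sel <- rows[order(d)[seq_len(m)]]
  dsel <- sort(d)[seq_len(m)]
  dm <- max(dsel)
  w <- if (dm > 0) 1 - (dsel / dm)^2 else rep(1, m)
  w <- pmax(w, 1e-8)

  sc <- ref$meta$scenarios[[match(scenario_id, scenario_ids(ref))]]
  pars <- scenario_params(sc)
  priors <- ref$meta$priors
  bounds <- lapply(pars, function(p) prior_bounds_for(priors, p))
  names(bounds) <- pars

  Y <- sapply(pars, function(p)
    bounded_logit(ref$params[sel, p], bounds[[p]][1], bounds[[p]][2]))
  Y <- matrix(Y, nrow = m, dimnames = list(NULL, pars))
  X <- sweep(st$Z[sel, , drop = FALSE], 2, st$zobs)  # centered at observed
  xsd <- apply(X, 2, sd)
  X <- X[, is.finite(xsd) & xsd > 1e-12, drop = FALSE]
  if (method != "rejection" && ncol(X) > 0 && m > ncol(X) + 1) {
    if (method == "loclinear") {
      fit <- lm.wfit(cbind(`(Intercept)` = 1, X), Y, w)
      beta <- fit$coefficients
      beta[is.na(beta)] <- 0
      slope <- beta[-1, , drop = FALSE]
    } else {
      xbar <- apply(X, 2, function(col) weighted.mean(col, w))
      ybar <- apply(Y, 2, function(col) weighted.mean(col, w))
      slope <- ridge_slopes(sweep(X, 2, xbar), sweep(Y, 2, ybar), w)
    }
    adj <- Y - X %*% slope
  } else {
    adj <- Y
  }
  draws <- sapply(pars, function(p)
    bounded_inv_logit(adj[, p], bounds[[p]][1], bounds[[p]][2]))
  draws <- matrix(draws, nrow = m, dimnames = list(NULL, pars))

  qs <- c(0.025, 0.05, 0.5, 0.95, 0.975)
  summ <- do.call(rbind, lapply(pars, function(p) {
    x <- draws[, p]
    q <- weighted_quantile(x, w, qs)
    data.frame(parameter = p,
               mean = weighted.mean(x, w),
               median = q[3],
               mode = weighted_mode(x, w),
               q025 = q[1], q05 = q[2], q50 = q[3], q95 = q[4],
               q975 = q[5], stringsAsFactors = FALSE)
  }))
  structure(list(summary = summ, draws = draws, weights = w,
                 acceptance_fraction = fraction, scenario = scenario_id,
                 transform = bounds, method = method,
                 stat_subset = stat_subset),
            class = "posterior_estimate")
}

#' @export
print.posterior_estimate <- function(x, ...) {
  cat("<posterior_estimate> scenario ", x$scenario, ", ",
      nrow(x$draws), " adjusted draws\n", sep = "")
  print(format(x$summary, digits = 4), row.names = FALSE)
  invisible(x)
}

#' Recalibrate divergence times into calendar years
#'
#' Multiplies a divergence time in generations by the species' generation
#' time (central value and range): central `t * gen_time`, low
#' `t * gen_range[1]`, high `t * gen_range[2]`.  Exact arithmetic; applies
#' to means and quantiles alike.
#'
#' @param t_gen Non-negative time(s) in generations.
#' @param gen_time Generation time in years (default 8).
#' @param gen_range Generation-time range (default `c(6, 10)`).
#' @return For scalar input a named vector `(years, years_low,
#'   years_high)`; for vector input a matrix with those columns.
#' @export
recalibrate_time <- function(t_gen, gen_time = 8, gen_range = c(6, 10)) {
  if (any(t_gen < 0)) stop("divergence times must be non-negative")
  out <- cbind(years = t_gen * gen_time,
               years_low = t_gen * gen_range[1],
               years_high = t_gen * gen_range[2])
  if (length(t_gen) == 1L) out[1, ] else out
}

#' Posterior-predictive model checking
#'
#' Draws parameter vectors from the adjusted posterior sample, simulates
#' datasets and their summary statistics, and locates the observed vector
#' in statistic space: a PCA fitted on the prior-predictive (reference)
#' statistics gives the coordinates of the prior cloud, the posterior
#' cloud and the observed point; each statistic also gets a
#' posterior-predictive tail probability (the smaller of the two
#' one-sided empirical tails).  Passing a `stat_subset` disjoint from the
#' statistics used for estimation gives the less-biased variant of the
#' check.
#'
#' @param ref A `ref_table`.
#' @param posterior A `posterior_estimate` from [estimate_parameters()].
#' @param observed The observed `sumstat_vector`.
#' @param n_posterior_sims Number of posterior-predictive simulations.
#' @param stat_subset Optional character vector of statistic names to
#'   restrict the check to.
#' @return Object of class `abc_model_check`: PC scores for the prior
#'   cloud, posterior cloud and observed point; PC variance proportions;
#'   per-statistic tail probabilities.
#' @export
model_check <- function(ref, posterior, observed, n_posterior_sims = 100,
                        stat_subset = NULL) {
  meta <- ref$meta
  cols <- stat_subset %||% colnames(ref$stats)
  cols <- intersect(cols, colnames(ref$stats))
  if (!length(cols)) stop("empty statistic subset")
  sc <- meta$scenarios[[match(posterior$scenario, scenario_ids(ref))]]
  idx <- sample.int(nrow(posterior$draws), n_posterior_sims, replace = TRUE,
                    prob = posterior$weights)
  sims <- matrix(NA_real_, n_posterior_sims, ncol(ref$stats),
                 dimnames = list(NULL, colnames(ref$stats)))
  for (i in seq_len(n_posterior_sims)) {
    tries <- 0L
    repeat {  # resample degenerate posterior draws
      draw <- posterior$draws[idx[i], ]
      g <- simulate_dataset(sc, draw, meta$groups, meta$n_loci)
      s <- tryCatch(compute_sumstats(g, trios = meta$trios),
                    error = function(e) NULL)
      if (!is.null(s)) break
      idx[i] <- sample.int(nrow(posterior$draws), 1,
                           prob = posterior$weights)
      tries <- tries + 1L
      if (tries >= 100L)
        stop("100 consecutive degenerate posterior-predictive draws")
    }
    sims[i, ] <- as.numeric(s)
  }
  ssd <- apply(ref$stats[, cols, drop = FALSE], 2, sd)
  cols <- cols[is.finite(ssd) & ssd > 0]
  pca <- prcomp(ref$stats[, cols, drop = FALSE], center = TRUE,
                scale. = TRUE)
  obs <- as.numeric(observed)[match(cols, names(observed))]
  tail_probs <- vapply(seq_along(cols), function(j) {
    s <- sims[, cols[j]]
    min(mean(s <= obs[j]), mean(s >= obs[j]))
  }, numeric(1))
  names(tail_probs) <- cols
  structure(list(
    prior_scores = pca$x,
    posterior_scores = predict(pca, sims[, cols, drop = FALSE]),
    observed_score = drop(predict(pca, rbind(setNames(obs, cols)))),
    var_prop = pca$sdev^2 / sum(pca$sdev^2),
    tail_probs = tail_probs,
    stats_used = cols),
    class = "abc_model_check")
}

#' @export
print.abc_model_check <- function(x, ...) {
  cat("<abc_model_check> ", nrow(x$posterior_scores),
      " posterior-predictive simulations, ", length(x$stats_used),
      " statistics\n", sep = "")
  cat(sprintf("  PC1 %.1f%%, PC2 %.1f%% of variance\n",
              100 * x$var_prop[1], 100 * x$var_prop[2]))
  cat(sprintf("  smallest tail probability: %.4f (%s)\n",
              min(x$tail_probs), names(which.min(x$tail_probs))))
  invisible(x)
}
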