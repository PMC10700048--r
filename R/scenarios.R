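#' Prior specification for demographic parameters
#'
#' Uniform prior bounds for the three parameter families used by the
#' demographic scenarios: effective population sizes (`N*`, diploid
#' individuals), divergence/admixture times (`t*`, generations), and
#' admixture rates (`ra`).  Times are constrained by a chain of strict
#' inequalities (default `t1 < t2 < t3 < t4`), enforced at sampling time by
#' joint rejection.
#'
#' @param n_bounds Lower/upper bounds for effective sizes.  Default
#'   `c(10, 6e5)`.
#' @param t_bounds Lower/upper bounds for event times in generations.
#'   Default `c(10, 1e3)`.
#' @param ra_bounds Lower/upper bounds for the admixture rate.  Default
#'   `c(1e-3, 0.999)`.
#' @param ordering Character vector of time symbols in increasing order;
#'   adjacent symbols are constrained by strict `<`.
#' @return An object of class `prior_spec`.
#' @seealso [estimation_priors()] for the prior used by the shipped
#'   parameter-recovery analyses.
#' @export
prior_spec <- function(n_bounds = c(10, 6e5), t_bounds = c(10, 1e3),
                       ra_bounds = c(1e-3, 0.999),
                       ordering = c("t1", "t2", "t3", "t4")) {
  for (b in list(n_bounds, t_bounds, ra_bounds)) {
    stopifnot(length(b) == 2, is.numeric(b))
    if (!(b[1] < b[2])) stop("prior bounds must satisfy lower < upper")
  }
  if (!all(grepl("^t[0-9]+$", ordering)))
    stop("ordering may refer only to time symbols (t1, t2, ...)")
  structure(list(n_bounds = as.numeric(n_bounds),
                 t_bounds = as.numeric(t_bounds),
                 ra_bounds = as.numeric(ra_bounds),
                 ordering = ordering),
            class = "prior_spec")
}

#' Prior used for posterior estimation runs
#'
#' Identical to [prior_spec()] defaults except that the divergence-time
#' bound is widened to `c(10, 2e3)` generations.  The widened bound is
#' required for internal consistency of the shipped truth parameters: the
#' oldest-split posterior mean of the reference analysis (1.26e3
#' generations) lies above the narrow default time bound, so a recovery
#' analysis under the narrow prior would place the truth outside prior
#' support.  See the methods vignette for discussion.
#'
#' @return A `prior_spec`.
#' @export
estimation_priors <- function() prior_spec(t_bounds = c(10, 2e3))

#' Prior bounds for one parameter symbol
#'
#' Size symbols (`NA`, `N1`...) map to `n_bounds`, time symbols (`t1`...)
#' to `t_bounds`, and `ra` to `ra_bounds`.
#'
#' @param priors A [prior_spec()].
#' @param param Parameter symbol.
#' @return Numeric vector `c(lower, upper)`.
#' @export
prior_bounds_for <- function(priors, param) {
  if (param == "ra") return(priors$ra_bounds)
  if (grepl("^t", param)) return(priors$t_bounds)
  priors$n_bounds  # "NA", "N1".."N5"
}

#' Demographic events
#'
#' Events are instantaneous, looking backward in time.  A merge moves every
#' lineage of `source` into `dest` (forward in time: `source` splits off
#' from `dest`); optionally the destination deme takes a new size symbol
#' from the event onward (used to give the final ancestor its own size).
#' An admixture moves each lineage of `admixed` independently to `parent1`
#' with probability `rate`, else to `parent2` (forward in time: `admixed`
#' is founded as a mixture of the two parents).
#'
#' @param time Time symbol, e.g. `"t1"`.
#' @param source,dest Deme names for a merge.
#' @param new_size Optional size symbol taken by `dest` above the event.
#' @param admixed,parent1,parent2 Deme names for an admixture.
#' @param rate Admixture-rate symbol, default `"ra"`.
#' @return A list describing the event.
#' @name demog_events
NULL

#' @rdname demog_events
#' @export
ev_merge <- function(time, source, dest, new_size = NULL) {
  list(time = time, kind = "merge", source = source, dest = dest,
       new_size = new_size)
}

#' @rdname demog_events
#' @export
ev_admixture <- function(time, admixed, parent1, parent2, rate = "ra") {
  list(time = time, kind = "admixture", admixed = admixed,
       parent1 = parent1, parent2 = parent2, rate = rate)
}

#' Construct a demographic scenario
#'
#' A scenario is an ordered set of sampled demes with size symbols, plus a
#' list of [demog_events] at symbolic times.  Event times, once
#' instantiated from the prior, must be non-decreasing along the list; the
#' event sequence must leave exactly one ancestral deme.
#'
#' @param id Integer or label identifying the scenario.
#' @param demes Character vector of sampled deme names (order fixed for the
#'   whole pipeline).
#' @param sizes Named character vector mapping each deme to its size
#'   symbol.
#' @param events List of events from [ev_merge()] / [ev_admixture()].
#' @param description Free-text description.
#' @return An object of class `scenario`.
#' @export
scenario <- function(id, demes, sizes, events, description = "") {
  stopifnot(is.character(demes), !anyDuplicated(demes))
  stopifnot(all(demes %in% names(sizes)))
  structure(list(id = id, demes = demes, sizes = sizes[demes],
                 events = events, description = description),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat("<scenario ", x$id, "> ", x$description, "\n", sep = "")
  cat("  demes:", paste0(x$demes, " (", x$sizes, ")", collapse = ", "), "\n")
  for (e in x$events) {
    if (e$kind == "merge") {
      cat("  ", e$time, ": merge ", e$source, " -> ", e$dest,
          if (!is.null(e$new_size)) paste0(" [size -> ", e$new_size, "]"),
          "\n", sep = "")
    } else {
      cat("  ", e$time, ": ", e$admixed, " admixed from ", e$parent1,
          " (", e$rate, ") / ", e$parent2, "\n", sep = "")
    }
  }
  invisible(x)
}

# all parameter symbols a scenario uses, in canonical order
#' Parameter symbols used by a scenario
#' @param sc A `scenario`.
#' @return Character vector of symbols in canonical order.
#' @export
scenario_params <- function(sc) {
  syms <- unname(sc$sizes)
  for (e in sc$events) {
    syms <- c(syms, e$time)
    if (e$kind == "merge") {
      if (!is.null(e$new_size)) syms <- c(syms, e$new_size)
    } else {
      syms <- c(syms, e$rate)
    }
  }
  syms <- unique(syms)
  ord <- match(syms, .param_order)
  c(syms[order(ord, na.last = TRUE)])
}

# deme that remains after the last event
#' Trunk deme of a scenario (the deme left after the final event)
#' @param sc A `scenario`.
#' @return Deme name.
#' @export
scenario_trunk <- function(sc) {
  alive <- sc$demes
  for (e in sc$events) {
    if (e$kind == "merge") alive <- setdiff(alive, e$source)
    else alive <- setdiff(alive, e$admixed)
  }
  if (length(alive) != 1L) return(NA_character_)
  alive
}

#' Validate a scenario's structural invariants
#'
#' Checks that every event references demes alive at its time, that event
#' times (in canonical symbol order) never decrease along the list, and
#' that the event sequence reduces the deme set to a single common
#' ancestor.
#'
#' @param sc A `scenario`.
#' @return Character vector of violations; empty when the scenario is
#'   valid.
#' @export
validate_scenario <- function(sc) {
  bad <- character(0)
  alive <- sc$demes
  last_t <- 0L
  tidx <- function(s) {
    i <- suppressWarnings(as.integer(sub("^t", "", s)))
    if (is.na(i)) -1L else i
  }
  for (e in sc$events) {
    ti <- tidx(e$time)
    if (ti < 0) bad <- c(bad, paste0("bad time symbol: ", e$time))
    if (ti < last_t)
      bad <- c(bad, paste0("event times decrease at ", e$time))
    last_t <- max(last_t, ti)
    refs <- if (e$kind == "merge") c(e$source, e$dest)
            else c(e$admixed, e$parent1, e$parent2)
    unknown <- setdiff(refs, sc$demes)
    if (length(unknown))
      bad <- c(bad, paste0("unknown deme: ", paste(unknown, collapse = ", ")))
    dead <- setdiff(intersect(refs, sc$demes), alive)
    if (length(dead))
      bad <- c(bad, paste0("deme no longer exists at ", e$time, ": ",
                           paste(dead, collapse = ", ")))
    gone <- if (e$kind == "merge") e$source else e$admixed
    alive <- setdiff(alive, gone)
  }
  if (length(alive) != 1L)
    bad <- c(bad, paste0("no common ancestor: ", length(alive),
                         " demes remain after the last event"))
  bad
}

#' Built-in eight-scenario registry
#'
#' The shipped divergence/admixture models for a five-deme system
#' (SOUTHERN, LOWER-CENTRAL, UPPER-CENTRAL, EASTERN, NORTHERN).  Scenarios
#' 1-4 use the UPPER-CENTRAL deme as the trunk from which the others
#' split; 5-8 mirror them with the LOWER-CENTRAL deme as trunk.  Within
#' each block: the first model has the eastern split older than the
#' northern one, the second swaps that order, and the third/fourth repeat
#' the pair with the non-trunk central deme founded by admixture between
#' the trunk and the southern deme (rate `ra`) instead of a clean split.
#' Scenario 1 is the registry's reference model: splits at `t1`
#' (LOWER-CENTRAL), `t2` (NORTHERN), `t3` (EASTERN), and `t4` (SOUTHERN
#' versus the ancestor of size `NA`).
#'
#' Topologies of scenarios 3-8 are provisional defaults: they are chosen to
#' complete a plausible model family (and the 11-parameter union) and can
#' be replaced wholesale via [read_scenario_config()].
#'
#' @return List of eight validated `scenario` objects.
#' @export
builtin_scenarios <- function() {
  S <- "SOUTHERN"; LC <- "LOWER-CENTRAL"; UC <- "UPPER-CENTRAL"
  E <- "EASTERN"; N <- "NORTHERN"
  demes <- c(S, LC, UC, E, N)
  sizes <- setNames(c("N1", "N2", "N3", "N4", "N5"), demes)
  mk <- function(id, events, desc) scenario(id, demes, sizes, events, desc)
  split4 <- function(trunk) ev_merge("t4", S, trunk, new_size = "NA")
  sc <- list(
    mk(1, list(ev_merge("t1", LC, UC), ev_merge("t2", N, UC),
               ev_merge("t3", E, UC), split4(UC)),
       "upper-central trunk; eastern split older than northern"),
    mk(2, list(ev_merge("t1", LC, UC), ev_merge("t2", E, UC),
               ev_merge("t3", N, UC), split4(UC)),
       "upper-central trunk; northern split older than eastern"),
    mk(3, list(ev_admixture("t1", LC, UC, S), ev_merge("t2", N, UC),
               ev_merge("t3", E, UC), split4(UC)),
       "as scenario 1 but lower-central founded by admixture"),
    mk(4, list(ev_admixture("t1", LC, UC, S), ev_merge("t2", E, UC),
               ev_merge("t3", N, UC), split4(UC)),
       "as scenario 2 but lower-central founded by admixture"),
    mk(5, list(ev_merge("t1", UC, LC), ev_merge("t2", N, LC),
               ev_merge("t3", E, LC), split4(LC)),
       "lower-central trunk; eastern split older than northern"),
    mk(6, list(ev_merge("t1", UC, LC), ev_merge("t2", E, LC),
               ev_merge("t3", N, LC), split4(LC)),
       "lower-central trunk; northern split older than eastern"),
    mk(7, list(ev_admixture("t1", UC, LC, S), ev_merge("t2", N, LC),
               ev_merge("t3", E, LC), split4(LC)),
       "as scenario 5 but upper-central founded by admixture"),
    mk(8, list(ev_admixture("t1", UC, LC, S), ev_merge("t2", E, LC),
               ev_merge("t3", N, LC), split4(LC)),
       "as scenario 6 but upper-central founded by admixture"))
  for (s in sc) {
    v <- validate_scenario(s)
    if (length(v)) stop("internal: invalid builtin scenario ", s$id, ": ",
                        paste(v, collapse = "; "))
  }
  sc
}

#' Sample parameter draws from the prior
#'
#' Each parameter a scenario uses is drawn uniformly within its bounds.
#' The time-ordering chain of the prior is enforced by joint rejection:
#' all times are redrawn together until the chain holds, which leaves the
#' draw exactly uniform on the order-constrained region.  Reproducible
#' under `set.seed()`.
#'
#' @param sc A validated `scenario`.
#' @param priors A [prior_spec()].
#' @param n Number of draws.
#' @return For `n = 1` a named numeric vector; otherwise an `n` x p matrix
#'   with one column per parameter symbol.
#' @export
sample_prior <- function(sc, priors = prior_spec(), n = 1) {
  params <- scenario_params(sc)
  tsyms <- intersect(priors$ordering, params)
  out <- matrix(NA_real_, n, length(params),
                dimnames = list(NULL, params))
  for (p in setdiff(params, tsyms)) {
    b <- prior_bounds_for(priors, p)
    out[, p] <- runif(n, b[1], b[2])
  }
  if (length(tsyms)) {
    tb <- priors$t_bounds
    need <- rep(TRUE, n)
    tm <- matrix(NA_real_, n, length(tsyms))
    guard <- 0L
    while (any(need)) {
      k <- sum(need)
      cand <- matrix(runif(k * length(tsyms), tb[1], tb[2]), k)
      ok <- if (ncol(cand) > 1) {
        rowSums(cand[, -1, drop = FALSE] >
                  cand[, -ncol(cand), drop = FALSE]) == ncol(cand) - 1
      } else rep(TRUE, k)
      tm[which(need)[ok], ] <- cand[ok, , drop = FALSE]
      need[which(need)[ok]] <- FALSE
      guard <- guard + 1L
      if (guard > 1e6) stop("time-ordering constraint appears unsatisfiable")
    }
    out[, tsyms] <- tm
  }
  if (n == 1) out[1, ] else out
}

#' Read and write scenario/prior configurations
#'
#' Scenario sets and priors round-trip through a JSON configuration so
#' that alternative topologies can be supplied without code changes.
#'
#' @param scenarios List of `scenario` objects.
#' @param priors A `prior_spec`.
#' @param path File path.
#' @return `read_scenario_config()` returns `list(scenarios =, priors =)`.
#' @export
write_scenario_config <- function(scenarios, priors, path) {
  enc_event <- function(e) e[!vapply(e, is.null, logical(1))]
  cfg <- list(
    priors = list(n_bounds = priors$n_bounds, t_bounds = priors$t_bounds,
                  ra_bounds = priors$ra_bounds, ordering = priors$ordering),
    scenarios = lapply(scenarios, function(s) list(
      id = s$id, demes = s$demes, sizes = as.list(s$sizes),
      events = lapply(s$events, enc_event), description = s$description)))
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_scenario_config
#' @export
read_scenario_config <- function(path) {
  cfg <- jsonlite::read_json(path)
  priors <- prior_spec(
    n_bounds = as.numeric(cfg$priors$n_bounds),
    t_bounds = as.numeric(cfg$priors$t_bounds),
    ra_bounds = as.numeric(cfg$priors$ra_bounds),
    ordering = as.character(unlist(cfg$priors$ordering)))
  scens <- lapply(cfg$scenarios, function(s) {
    demes <- as.character(unlist(s$demes))
    sizes <- setNames(as.character(unlist(s$sizes)), names(s$sizes))
    events <- lapply(s$events, function(e) {
      if (e$kind == "merge")
        ev_merge(e$time, e$source, e$dest, e$new_size %||% NULL)
      else
        ev_admixture(e$time, e$admixed, e$parent1, e$parent2, e$rate)
    })
    scenario(s$id, demes, sizes, events, s$description %||% "")
  })
  list(scenarios = scens, priors = priors)
}
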