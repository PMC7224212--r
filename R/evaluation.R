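#' Monte-Carlo bias and precision of the reconstruction
#'
#' Repeats the full pipeline — fresh Gaussian noise on the ideal
#' displacements (boundary pixels included), smoothing, inversion,
#' normalization to mean relative stiffness 0.5 — and summarizes the
#' per-element replicate distribution. Bias is the root-mean-square error of
#' the replicate-mean map against the normalized truth; precision is the
#' pooled (RMS over elements) across-replicate standard deviation. A
#' per-replicate RMSE variant of bias is reported alongside
#' (`bias_per_replicate`).
#'
#' @param case a phantom bundle from [end_to_end_case()] /
#'   [generate_displacements()] with a noise-free field.
#' @param noise_sigma Gaussian noise SD in mm (default 0.1, the
#'   experimental displacement-noise level).
#' @param n_replicates number of noise replicates (`>= 2`; 100 for full
#'   studies, fewer for desk-scale runs).
#' @param seed master seed; replicate seeds are drawn from it, so the whole
#'   experiment is reproducible.
#' @param smoothing `"lowess"` (default), `"gaussian"` or `"none"`.
#' @param smooth_window LOWESS window in pixels (default 150).
#' @param smooth_sigma Gaussian smoothing SD in pixels (default 2).
#' @param settings [optimizer_settings()] for the inversions.
#' @return An object of class `monte_carlo_result`: `bias`, `precision`,
#'   `bias_per_replicate`, `bias_map` and `sd_map` (per element),
#'   `rho_mean`, `truth` (normalized), `n_replicates`, `n_failed`,
#'   `not_converged`, `seeds`, `labels`.
#' @export
monte_carlo <- function(case, noise_sigma = 0.1, n_replicates = 30L,
                        seed = 1L, smoothing = c("lowess", "gaussian",
                                                 "none"),
                        smooth_window = 150L, smooth_sigma = 2,
                        settings = optimizer_settings()) {
  smoothing <- match.arg(smoothing)
  n_replicates <- as.integer(n_replicates)
  if (n_replicates < 2L) stop("`n_replicates` must be >= 2")
  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_replicates)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                 envir = globalenv())
  mesh <- case$mesh
  truth_n <- normalize_relative_stiffness(case$truth$rho)
  maps <- matrix(NA_real_, nrow(mesh$elements), n_replicates)
  failed <- integer(0); not_conv <- integer(0)
  for (i in seq_len(n_replicates)) {
    res <- tryCatch({
      fld <- add_noise(case$field, noise_spec(sigma = noise_sigma,
                                              seed = rep_seeds[i]))
      fld <- switch(smoothing,
                    lowess = smooth_lowess(fld, smooth_window),
                    gaussian = smooth_gaussian(fld, smooth_sigma),
                    none = fld)
      interp <- interpolate_to_mesh(fld, mesh)
      prob <- inverse_problem(mesh, interp$values, weights = interp$weights,
                              settings = settings)
      run_inversion(prob)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, i)
      next
    }
    if (!res$state$converged) not_conv <- c(not_conv, i)
    maps[, i] <- normalize_relative_stiffness(res$material$rho)
  }
  ok <- setdiff(seq_len(n_replicates), failed)
  if (length(ok) < 2L) stop("fewer than 2 replicates succeeded")
  mu <- rowMeans(maps[, ok, drop = FALSE])
  sk <- apply(maps[, ok, drop = FALSE], 1L, stats::sd)
  bias_map <- mu - truth_n
  per_rep_rmse <- apply(maps[, ok, drop = FALSE], 2L,
                        function(m) sqrt(mean((m - truth_n)^2)))
  structure(list(
    n_replicates = length(ok),
    bias = sqrt(mean(bias_map^2)),
    precision = sqrt(mean(sk^2)),
    precision_rmse_sd = stats::sd(per_rep_rmse),
    bias_per_replicate = mean(per_rep_rmse),
    bias_map = bias_map, sd_map = sk, rho_mean = mu, truth = truth_n,
    n_failed = length(failed), not_converged = not_conv,
    seeds = rep_seeds, labels = case$truth$labels,
    noise_sigma = noise_sigma, smoothing = smoothing),
    class = "monte_carlo_result")
}

#' @export
print.monte_carlo_result <- function(x, ...) {
  cat("<monte_carlo_result> ", x$n_replicates, " replicates (sigma ",
      x$noise_sigma, " mm, ", x$smoothing, " smoothing)\n",
      "  bias (RMS of replicate-mean error): ", format(x$bias, digits = 3),
      "\n  precision (pooled across-replicate SD): ",
      format(x$precision, digits = 3), "\n", sep = "")
  if (x$n_failed > 0) cat("  failed replicates:", x$n_failed, "\n")
  invisible(x)
}

#' Cotter systematic fractional factor screening
#'
#' Two-level sensitivity design requiring `2m + 2` runs for `m` factors: one
#' all-low run, m runs with a single factor high, m runs with a single
#' factor low (from all-high), and one all-high run. For each factor the
#' odd- and even-order contrasts are
#' `Co = ((y_hi_all - y_lo_j) + (y_hi_j - y_lo_all)) / 4` and
#' `Ce = ((y_hi_all - y_lo_j) - (y_hi_j - y_lo_all)) / 4`, and the
#' importance measure is `M = |Co| + |Ce|`; factors are returned ranked by
#' `M`. On a purely additive response `M` is proportional to the absolute
#' effect coefficients.
#'
#' @param factors named list: each entry is `list(low = , high = )` (any
#'   type the response function understands).
#' @param response function taking a named list of factor settings and
#'   returning one scalar (larger = worse, by convention).
#' @return data frame with columns `factor`, `C_odd`, `C_even`, `M`,
#'   sorted by decreasing `M`; attribute `"runs"` holds the design and the
#'   observed responses.
#' @export
cotter_sensitivity <- function(factors, response) {
  m <- length(factors)
  if (m < 2) stop("need at least 2 factors")
  if (is.null(names(factors)) || any(names(factors) == ""))
    stop("factors must be named")
  for (nm in names(factors)) {
    f <- factors[[nm]]
    if (identical(f$low, f$high))
      stop("factor '", nm, "' has identical low and high settings")
  }
  level_row <- function(high_mask) {
    s <- lapply(seq_len(m), function(j)
      if (high_mask[j]) factors[[j]]$high else factors[[j]]$low)
    names(s) <- names(factors)
    s
  }
  design <- vector("list", 2 * m + 2)
  design[[1]] <- rep(FALSE, m)
  for (j in seq_len(m)) {                 # single factor high
    v <- rep(FALSE, m); v[j] <- TRUE
    design[[1 + j]] <- v
  }
  for (j in seq_len(m)) {                 # single factor low
    v <- rep(TRUE, m); v[j] <- FALSE
    design[[1 + m + j]] <- v
  }
  design[[2 * m + 2]] <- rep(TRUE, m)
  y <- vapply(design, function(d) as.numeric(response(level_row(d))),
              numeric(1))
  co <- ce <- numeric(m)
  for (j in seq_len(m)) {
    d_hi <- y[2 * m + 2] - y[1 + m + j]   # effect of raising j, others high
    d_lo <- y[1 + j] - y[1]               # effect of raising j, others low
    co[j] <- (d_hi + d_lo) / 4
    ce[j] <- (d_hi - d_lo) / 4
  }
  out <- data.frame(factor = names(factors), C_odd = co, C_even = ce,
                    M = abs(co) + abs(ce))
  out <- out[order(-out$M), ]
  rownames(out) <- NULL
  runs <- data.frame(run = seq_along(design),
                     t(vapply(design, function(d) as.integer(d),
                              integer(m))))
  names(runs)[-1] <- names(factors)
  runs$response <- y
  attr(out, "runs") <- runs
  out
}

#' Default factor grid for pipeline sensitivity screening
#'
#' The two-level settings screened on the bilayer case: raw-data noise SD
#' (0.02 vs 0.2 mm), smoothing technique (LOWESS vs Gaussian), Poisson's
#' ratio (0.3 vs 0.49), sensitivity-filter radius (1x vs 4x element size),
#' mesh density (0.3 vs 0.6 mm elements) and iteration budget (30 vs 100).
#'
#' @return named list of `list(low, high)` factor settings.
#' @export
cotter_default_factors <- function() {
  list(noise_sigma = list(low = 0.02, high = 0.2),
       smoothing = list(low = "lowess", high = "gaussian"),
       nu = list(low = 0.3, high = 0.49),
       filter_factor = list(low = 1, high = 4),
       mesh_density = list(low = 0.3, high = 0.6),
       iterations = list(low = 30L, high = 100L))
}

#' Factor screening of the full elastography pipeline
#'
#' Runs [cotter_sensitivity()] with the response defined as the absolute
#' error of the recovered top:bottom layer-mean stiffness ratio of the
#' bilayer phantom (scale-free, one scalar per run). Each run regenerates
#' the phantom at the run's mesh density, adds noise at the run's level,
#' smooths with the run's technique and inverts with the run's optimizer
#' settings.
#'
#' @param factors factor grid (default [cotter_default_factors()]).
#' @param seed seed for the per-run noise draws.
#' @param spacing_default mesh density (mm) used when the grid does not vary
#'   it.
#' @return the ranked data frame of [cotter_sensitivity()].
#' @export
cotter_elastography <- function(factors = cotter_default_factors(),
                                seed = 1L, spacing_default = 0.3) {
  run_id <- 0L
  response <- function(s) {
    run_id <<- run_id + 1L
    spacing <- if (!is.null(s$mesh_density)) s$mesh_density else
      spacing_default
    case <- end_to_end_case("bilayer2d", spacing = spacing)
    fld <- add_noise(case$field,
                     noise_spec(sigma = if (!is.null(s$noise_sigma))
                       s$noise_sigma else 0.1, seed = seed + run_id))
    if (!is.null(s$smoothing)) {
      npix <- sum(fld$mask)
      fld <- if (s$smoothing == "lowess")
        smooth_lowess(fld, min(150L, npix)) else smooth_gaussian(fld, 2)
    }
    st <- optimizer_settings(
      max_iterations = if (!is.null(s$iterations)) s$iterations else 100L,
      filter_radius_factor = if (!is.null(s$filter_factor))
        s$filter_factor else 1)
    interp <- interpolate_to_mesh(fld, case$mesh)
    mat <- material_field(rho = rep(0.5, nrow(case$mesh$elements)),
                          nu = if (!is.null(s$nu)) s$nu else 0.49)
    prob <- inverse_problem(case$mesh, interp$values,
                            weights = interp$weights, material = mat,
                            settings = st)
    inv <- run_inversion(prob)
    rr <- region_ratio(inv$material$rho, case$truth$labels)
    truth_rr <- region_ratio(case$truth$rho, case$truth$labels)
    abs(rr$ratios["top", "bottom"] - truth_rr$ratios["top", "bottom"])
  }
  cotter_sensitivity(factors, response)
}

# "a:b = 1:x" ratio formatting with the smaller mean scaled to 1
format_region_ratio <- function(means, a, b) {
  if (means[b] >= means[a])
    sprintf("%s:%s = 1:%.1f", a, b, means[b] / means[a])
  else
    sprintf("%s:%s = 1:%.1f", b, a, means[a] / means[b])
}

#' Consolidated machine- and human-readable report
#'
#' Writes a JSON file (round-trippable with [jsonlite::read_json()]) and a
#' plain-text summary of whatever results are supplied: region ratios,
#' Monte-Carlo bias/precision, factor rankings and convergence traces.
#' Empty input produces an empty (but valid) report.
#'
#' @param path_prefix output prefix; writes `<prefix>.json` and
#'   `<prefix>.txt`.
#' @param ratios optional result of [region_ratio()].
#' @param monte_carlo optional [monte_carlo()] result.
#' @param cotter optional [cotter_sensitivity()] ranking.
#' @param history optional optimization history data frame.
#' @return invisibly, the JSON path.
#' @export
report <- function(path_prefix, ratios = NULL, monte_carlo = NULL,
                   cotter = NULL, history = NULL) {
  obj <- list()
  txt <- character(0)
  if (!is.null(ratios)) {
    obj$region_means <- as.list(ratios$means)
    obj$region_ratios <- as.data.frame(as.table(ratios$ratios))
    names(obj$region_ratios) <- c("numerator", "denominator", "ratio")
    nm <- names(ratios$means)
    for (i in seq_along(nm)[-1])
      txt <- c(txt, format_region_ratio(ratios$means, nm[1], nm[i]))
  }
  if (!is.null(monte_carlo)) {
    obj$monte_carlo <- list(n_replicates = monte_carlo$n_replicates,
                            bias = monte_carlo$bias,
                            precision = monte_carlo$precision,
                            bias_per_replicate =
                              monte_carlo$bias_per_replicate,
                            n_failed = monte_carlo$n_failed)
    txt <- c(txt, sprintf("Monte Carlo (%d replicates): bias %.3f, precision %.3f",
                          monte_carlo$n_replicates, monte_carlo$bias,
                          monte_carlo$precision))
  }
  if (!is.null(cotter)) {
    obj$cotter <- cotter
    txt <- c(txt, paste("Factor ranking:",
                        paste(cotter$factor, collapse = " > ")))
  }
  if (!is.null(history)) obj$convergence <- history
  json_path <- paste0(path_prefix, ".json")
  jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  writeLines(txt, paste0(path_prefix, ".txt"))
  invisible(json_path)
}
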