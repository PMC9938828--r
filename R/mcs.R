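#' Stochastic input specifications
#'
#' Constructors for the distribution families the Monte Carlo engine
#' samples from:
#'
#' * `dist_fixed(value)` — a degenerate (constant) input.
#' * `dist_normal(mean, sd, min)` — Gaussian, optionally left-truncated
#'   (rejection sampling); used for the water intake rate, truncated at 0.
#' * `dist_lognormal(mean, sd)` — log-normal parameterised by its
#'   *arithmetic* mean and sd through moment matching
#'   (`sdlog^2 = log(1 + (sd/mean)^2)`, `meanlog = log(mean) - sdlog^2/2`),
#'   so sample moments converge to the given ones; used for concentrations
#'   and body weight.
#' * `dist_triangular(min, mode, max)` — inverse-CDF sampling; used for the
#'   exposure frequency.
#' * `dist_mixture(components, weights)` — a finite mixture of specs, used
#'   to pool the two seasonal concentration distributions.
#'
#' @param value,mean,sd,min,mode,max family parameters; `sd >= 0`,
#'   `min <= mode <= max`.
#' @param components list of distribution specs.
#' @param weights mixture weights, recycled to equal weights when `NULL`.
#' @return a `dist_spec` object.
#' @name dist_spec
NULL

new_dist <- function(family, ...) {
  structure(list(family = family, ...), class = "dist_spec")
}

#' @rdname dist_spec
#' @export
dist_fixed <- function(value) {
  assert_number(value, "value")
  new_dist("fixed", value = value)
}

#' @rdname dist_spec
#' @export
dist_normal <- function(mean, sd, min = -Inf) {
  assert_number(mean, "mean")
  assert_number(sd, "sd", 0)
  new_dist("normal", mean = mean, sd = sd, min = min)
}

#' @rdname dist_spec
#' @export
dist_lognormal <- function(mean, sd) {
  assert_number(mean, "mean", 0, strict = TRUE)
  assert_number(sd, "sd", 0)
  if (sd == 0) return(dist_fixed(mean))
  sdlog <- sqrt(log(1 + (sd / mean)^2))
  new_dist("lognormal", mean = mean, sd = sd,
           meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' @rdname dist_spec
#' @export
dist_triangular <- function(min, mode, max) {
  for (v in c("min", "mode", "max")) assert_number(get(v), v)
  if (!(min <= mode && mode <= max)) {
    stop("triangular spec needs min <= mode <= max", call. = FALSE)
  }
  new_dist("triangular", min = min, mode = mode, max = max)
}

#' @rdname dist_spec
#' @export
dist_mixture <- function(components, weights = NULL) {
  if (!length(components) ||
      !all(vapply(components, inherits, logical(1), "dist_spec"))) {
    stop("components must be a nonempty list of dist_spec objects",
         call. = FALSE)
  }
  if (is.null(weights)) weights <- rep(1, length(components))
  if (length(weights) != length(components) || any(weights < 0) ||
      sum(weights) <= 0) {
    stop("weights must be nonnegative with a positive sum and match the ",
         "number of components", call. = FALSE)
  }
  new_dist("mixture", components = components, weights = weights / sum(weights))
}

#' @export
print.dist_spec <- function(x, ...) {
  pars <- x[setdiff(names(x), c("family", "components", "weights"))]
  cat(sprintf("<dist_spec: %s> %s\n", x$family,
              paste(names(pars), signif(unlist(pars), 4),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Draw from a distribution spec
#'
#' @param spec a [dist_spec] object.
#' @param n number of draws.
#' @return numeric vector of length `n`; deterministic given the RNG state.
#' @examples
#' set.seed(1)
#' mean(draw_dist(dist_triangular(180, 345, 365), 1e4))
#' @export
draw_dist <- function(spec, n) {
  if (!inherits(spec, "dist_spec")) {
    stop("`spec` must be a dist_spec", call. = FALSE)
  }
  switch(spec$family,
    fixed = rep(spec$value, n),
    normal = {
      if (is.finite(spec$min)) {
        out <- numeric(0)
        # rejection: loop is cheap as long as min is in the far tail
        while (length(out) < n) {
          cand <- stats::rnorm(n, spec$mean, spec$sd)
          out <- c(out, cand[cand >= spec$min])
        }
        out[seq_len(n)]
      } else {
        stats::rnorm(n, spec$mean, spec$sd)
      }
    },
    lognormal = stats::rlnorm(n, spec$meanlog, spec$sdlog),
    triangular = {
      u <- stats::runif(n)
      rng <- spec$max - spec$min
      if (rng == 0) return(rep(spec$min, n))
      fc <- (spec$mode - spec$min) / rng
      ifelse(u < fc,
             spec$min + sqrt(u * rng * (spec$mode - spec$min)),
             spec$max - sqrt((1 - u) * rng * (spec$max - spec$mode)))
    },
    mixture = {
      idx <- sample.int(length(spec$components), n, replace = TRUE,
                        prob = spec$weights)
      out <- numeric(n)
      for (j in seq_along(spec$components)) {
        take <- idx == j
        if (any(take)) out[take] <- draw_dist(spec$components[[j]], sum(take))
      }
      out
    },
    stop("unknown distribution family: ", spec$family, call. = FALSE)
  )
}

#' Monte Carlo configuration
#'
#' @param n_iter number of repetitions (default 10000).
#' @param seed root RNG seed; each input derives an independent child
#'   stream from it, so adding an input does not perturb the others' draws.
#'   A random root is drawn from the session RNG when `NULL`.
#' @param percentiles percentiles to report, in (0, 100).
#' @return an `mcs_config` list.
#' @export
mcs_config <- function(n_iter = 10000, seed = NULL, percentiles = c(5, 95)) {
  assert_number(n_iter, "n_iter", 1)
  if (any(percentiles <= 0 | percentiles >= 100)) {
    stop("percentiles must lie strictly between 0 and 100", call. = FALSE)
  }
  if (is.null(seed)) seed <- sample.int(1073741823L, 1)
  structure(list(n_iter = as.integer(n_iter), seed = as.integer(seed),
                 percentiles = percentiles),
            class = "mcs_config")
}

#' Look up a model input by name
#'
#' Helper for model functions passed to [run_mcs()]: retrieves one named
#' input vector from the sampled draws and fails with the missing input's
#' name instead of propagating a `NULL`.
#'
#' @param x named list of input draw vectors.
#' @param name input name.
#' @return the draw vector.
#' @export
mcs_input <- function(x, name) {
  v <- x[[name]]
  if (is.null(v)) {
    stop("no distribution spec supplied for model input `", name, "`",
         call. = FALSE)
  }
  v
}

#' Run a Monte Carlo uncertainty analysis
#'
#' Samples every input independently from its distribution spec (one child
#' RNG stream per input, all derived from the root seed), evaluates the
#' model on the joint draws, and reports the mean, the requested
#' percentiles, and the rank-correlation contribution-to-variance
#' sensitivity of the output to each varying input. Identical seed and
#' configuration yield a bit-identical result.
#'
#' @param model function taking the named list of input vectors and
#'   returning one output draw per repetition; use [mcs_input()] for lookups
#'   so missing specs are reported by name.
#' @param specs named list of [dist_spec] objects, one per model input.
#' @param config an [mcs_config()].
#' @param output_name label for the output (e.g. `"HI"` or `"CR"`).
#' @return an `mcs_result`: `draws`, `inputs`, `mean`, `percentiles`,
#'   `sensitivity` (signed %, `NA` when the output does not vary), plus the
#'   `config` used.
#' @examples
#' specs <- list(X = dist_normal(10, 2), a = dist_fixed(3))
#' res <- run_mcs(function(x) mcs_input(x, "a") * mcs_input(x, "X"),
#'                specs, mcs_config(n_iter = 1000, seed = 42))
#' res$mean
#' @export
run_mcs <- function(model, specs, config = mcs_config(),
                    output_name = "output") {
  if (!length(specs) || is.null(names(specs)) || any(names(specs) == "")) {
    stop("`specs` must be a nonempty named list", call. = FALSE)
  }
  if (!all(vapply(specs, inherits, logical(1), "dist_spec"))) {
    stop("every element of `specs` must be a dist_spec", call. = FALSE)
  }
  n <- config$n_iter
  inputs <- lapply(names(specs), function(nm) {
    set.seed(child_seed(config$seed, nm))
    draw_dist(specs[[nm]], n)
  })
  names(inputs) <- names(specs)
  draws <- model(inputs)
  if (length(draws) != n || !is.numeric(draws)) {
    stop("model must return one numeric draw per repetition", call. = FALSE)
  }
  sens <- if (length(unique(draws)) > 1L) {
    sensitivity_contribution(inputs, draws)
  } else {
    stats::setNames(rep(NA_real_, length(inputs)), names(inputs))
  }
  structure(
    list(output = output_name,
         draws = draws,
         inputs = inputs,
         mean = mean(draws),
         percentiles = stats::quantile(draws, config$percentiles / 100),
         sensitivity = sens,
         config = config),
    class = "mcs_result"
  )
}

#' @export
print.mcs_result <- function(x, ...) {
  cat(sprintf("<mcs_result: %s> %d repetitions (seed %d)\n",
              x$output, x$config$n_iter, x$config$seed))
  cat(sprintf("  mean %.4g; percentiles: %s\n", x$mean,
              paste(names(x$percentiles), signif(x$percentiles, 4),
                    sep = " = ", collapse = ", ")))
  s <- x$sensitivity[!is.na(x$sensitivity) & x$sensitivity != 0]
  if (length(s)) {
    s <- s[order(-abs(s))]
    cat("  sensitivity (%):",
        paste(names(s), sprintf("%+.1f", s), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Contribution-to-variance sensitivity
#'
#' Attributes output uncertainty to each stochastic input through Spearman
#' rank correlations: for input j, `rho_j = spearman(input_j, output)` and
#' `contribution_j = sign(rho_j) * rho_j^2 / sum(rho_k^2) * 100`, the signed
#' normalised squared rank correlation. Constant (fixed) inputs contribute
#' 0 by definition; the absolute contributions of the varying inputs sum
#' to 100.
#'
#' @param inputs named list of input draw vectors.
#' @param output output draw vector of equal length, with at least two
#'   distinct values.
#' @return named vector of signed percentage contributions.
#' @export
sensitivity_contribution <- function(inputs, output) {
  if (!length(inputs)) stop("no inputs supplied", call. = FALSE)
  if (any(vapply(inputs, length, integer(1)) != length(output))) {
    stop("inputs and output must have equal lengths", call. = FALSE)
  }
  if (length(unique(output)) < 2L) {
    stop("output is constant: no variance to attribute", call. = FALSE)
  }
  varying <- vapply(inputs, function(v) length(unique(v)) > 1L, logical(1))
  rho <- vapply(inputs, function(v) {
    if (length(unique(v)) > 1L) {
      stats::cor(v, output, method = "spearman")
    } else 0
  }, numeric(1))
  denom <- sum(rho^2)
  contrib <- if (denom > 0) sign(rho) * rho^2 / denom * 100 else rho
  stats::setNames(contrib, names(inputs))
}

# Concentration spec for one metal: seasonal moment-matched lognormal, or
# the equal-weight two-season mixture when season = "pooled".
concentration_spec <- function(reference, metal, season) {
  pick <- function(s) {
    row <- reference[reference$metal == metal & reference$season == s, ]
    if (nrow(row) != 1L) {
      stop("reference summary lacks ", metal, " in season ", s,
           call. = FALSE)
    }
    dist_lognormal(row$mean, row$sd)
  }
  if (identical(season, "pooled")) {
    dist_mixture(lapply(SEASONS, pick))
  } else {
    pick(match_season(season))
  }
}

#' Input specifications for the risk Monte Carlo
#'
#' Builds the named spec list of the hazard-index or carcinogenic-risk
#' chain, following the conventional family assignment: concentrations
#' log-normal (moment-matched to the seasonal reference statistics; pooled
#' over the two seasons by default), intake rate normal (truncated at 0),
#' exposure frequency triangular over the profile's EF range, body weight
#' log-normal, and ED, AT, RfD/TDI and SF fixed. No coefficient of
#' variation is reported for IR and BW by the underlying survey, so both
#' default to 20% — explicit, overridable assumptions.
#'
#' @param profile an [exposure_profile()].
#' @param metals metal registry (toxicological columns only are used).
#' @param reference seasonal concentration statistics
#'   (see [reference_summary()]).
#' @param season `"pooled"` (the default: equal-weight season mixture),
#'   `"winter"` or `"summer"`.
#' @param ir_cv,bw_cv assumed coefficients of variation of the intake rate
#'   and body weight.
#' @param metal for `cr_specs`, the carcinogenic metal (must carry a slope
#'   factor).
#' @return named list of [dist_spec] objects.
#' @name risk_specs
#' @export
hi_specs <- function(profile, metals = default_metals(),
                     reference = reference_summary(), season = "pooled",
                     ir_cv = 0.2, bw_cv = 0.2) {
  reg <- metals[metals$agency == metals$agency[1], ]
  specs <- list(
    IR = dist_normal(profile$ir, ir_cv * profile$ir, min = 0),
    EF = dist_triangular(profile$ef[["min"]], profile$ef[["mode"]],
                         profile$ef[["max"]]),
    ED = dist_fixed(profile$ed),
    BW = dist_lognormal(profile$bw, bw_cv * profile$bw),
    f = dist_fixed(profile$f)
  )
  for (i in seq_len(nrow(reg))) {
    m <- reg$metal[i]
    specs[[paste0("C_", m)]] <- concentration_spec(reference, m, season)
    dose <- if (!is.na(reg$rfd[i])) reg$rfd[i] else reg$tdi[i]
    if (is.na(dose)) {
      stop("neither rfd nor tdi configured for metal ", m, call. = FALSE)
    }
    specs[[paste0("RfD_", m)]] <- dist_fixed(dose)
  }
  specs
}

#' @rdname risk_specs
#' @export
cr_specs <- function(profile, metals = default_metals(),
                     reference = reference_summary(), season = "pooled",
                     metal = "Pb", ir_cv = 0.2, bw_cv = 0.2) {
  reg <- metals[metals$agency == metals$agency[1], ]
  row <- reg[reg$metal == metal, ]
  if (nrow(row) != 1L || is.na(row$sf)) {
    stop("metal ", metal, " carries no slope factor", call. = FALSE)
  }
  list(
    IR = dist_normal(profile$ir, ir_cv * profile$ir, min = 0),
    EF = dist_triangular(profile$ef[["min"]], profile$ef[["mode"]],
                         profile$ef[["max"]]),
    ED = dist_fixed(profile$ed),
    BW = dist_lognormal(profile$bw, bw_cv * profile$bw),
    f = dist_fixed(profile$f),
    AT = dist_fixed(profile$lifetime_years * 365),
    C = concentration_spec(reference, metal, season),
    SF = dist_fixed(row$sf)
  )
}

#' Risk model functions for the Monte Carlo engine
#'
#' `hi_model(metal_names)` returns the hazard-index model
#' `HI = sum_m C_m * IR * EF / (f * BW * 365 * RfD_m)` (the noncarcinogenic
#' averaging time `ED * 365` cancels ED); `cr_model()` returns the
#' carcinogenic-risk model `CR = C * IR * EF * ED * SF / (f * BW * AT)`.
#' Both read their inputs via [mcs_input()].
#'
#' @param metal_names metals entering the hazard index.
#' @return a model function for [run_mcs()].
#' @name risk_models
#' @export
hi_model <- function(metal_names) {
  force(metal_names)
  function(x) {
    ir <- mcs_input(x, "IR")
    ef <- mcs_input(x, "EF")
    ed <- mcs_input(x, "ED")
    f <- mcs_input(x, "f")
    bw <- mcs_input(x, "BW")
    # per-metal HQ with the same operation order as cdi()/hq(), so fixed
    # specs collapse to the deterministic hazard index bit-exactly
    hqs <- vapply(metal_names, function(m) {
      mcs_input(x, paste0("C_", m)) * ir * ef * ed / (f * bw * (ed * 365)) /
        mcs_input(x, paste0("RfD_", m))
    }, numeric(length(ir)))
    rowSums(matrix(hqs, nrow = length(ir)))
  }
}

#' @rdname risk_models
#' @export
cr_model <- function() {
  function(x) {
    cdi_c <- mcs_input(x, "C") * mcs_input(x, "IR") * mcs_input(x, "EF") *
      mcs_input(x, "ED") /
      (mcs_input(x, "f") * mcs_input(x, "BW") * mcs_input(x, "AT"))
    cdi_c * mcs_input(x, "SF")
  }
}

#' Monte Carlo hazard index / carcinogenic risk for a receptor group
#'
#' Convenience wrappers assembling the default specs and model and running
#' the engine.
#'
#' @param group `"children"` or `"adults"` (any name in `profiles`).
#' @param config an [mcs_config()].
#' @param profiles named list of exposure profiles.
#' @param metals metal registry.
#' @param reference seasonal concentration statistics.
#' @param season `"pooled"`, `"winter"` or `"summer"`.
#' @param metal carcinogenic metal for `run_cr_mcs`.
#' @param ... passed on to [hi_specs()] / [cr_specs()] (e.g. `ir_cv`,
#'   `bw_cv`).
#' @return an `mcs_result`.
#' @examples
#' res <- run_hi_mcs("children", mcs_config(n_iter = 2000, seed = 7))
#' res
#' @name run_risk_mcs
#' @export
run_hi_mcs <- function(group = "children", config = mcs_config(),
                       profiles = default_profiles(),
                       metals = default_metals(),
                       reference = reference_summary(),
                       season = "pooled", ...) {
  profile <- profiles[[group]]
  if (is.null(profile)) stop("unknown group: ", group, call. = FALSE)
  reg <- metals[metals$agency == metals$agency[1], ]
  specs <- hi_specs(profile, metals, reference, season, ...)
  run_mcs(hi_model(reg$metal), specs, config,
          output_name = paste0("HI_", group))
}

#' @rdname run_risk_mcs
#' @export
run_cr_mcs <- function(group = "children", config = mcs_config(),
                       profiles = default_profiles(),
                       metals = default_metals(),
                       reference = reference_summary(),
                       season = "pooled", metal = "Pb", ...) {
  profile <- profiles[[group]]
  if (is.null(profile)) stop("unknown group: ", group, call. = FALSE)
  specs <- cr_specs(profile, metals, reference, season, metal, ...)
  run_mcs(cr_model(), specs, config,
          output_name = paste0("CR_", metal, "_", group))
}
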