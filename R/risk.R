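#' Chronic daily intake through drinking-water ingestion
#'
#' `CDI = C * IR * EF * ED / (f * BW * AT)` in mg/kg/day, with the averaging
#' time `AT = ED * 365` days for the noncarcinogenic endpoint (so ED
#' cancels) and `AT = lifetime_years * 365` days for the carcinogenic
#' endpoint. The conversion coefficient `f = 1000` turns ug/L into mg/L.
#'
#' Point estimates use the modal exposure frequency (345 days/year in the
#' default profiles); `ef` stays an explicit argument so other points of the
#' triangular EF range can be evaluated.
#'
#' @param conc concentration C (ug/L), `>= 0`; vectorised.
#' @param profile an [exposure_profile()].
#' @param endpoint `"noncarcinogenic"` or `"carcinogenic"`.
#' @param ef exposure frequency (days/year), within the profile's EF range.
#' @return chronic daily intake (mg/kg/day).
#' @examples
#' cdi(2.28, default_profiles()$children) # Mn, child, winter mean
#' @export
cdi <- function(conc, profile, endpoint = c("noncarcinogenic", "carcinogenic"),
                ef = profile$ef[["mode"]]) {
  endpoint <- match.arg(endpoint)
  if (!inherits(profile, "exposure_profile")) {
    stop("`profile` must be an exposure_profile", call. = FALSE)
  }
  if (any(!is.finite(conc) | conc < 0)) {
    stop("concentration must be finite and >= 0", call. = FALSE)
  }
  assert_number(ef, "ef", 0, strict = TRUE)
  if (ef < profile$ef[["min"]] || ef > profile$ef[["max"]]) {
    stop(sprintf("ef = %g outside the profile's EF range [%g, %g]",
                 ef, profile$ef[["min"]], profile$ef[["max"]]), call. = FALSE)
  }
  at_days <- if (endpoint == "noncarcinogenic") {
    profile$ed * 365
  } else {
    if (profile$lifetime_years <= 0) {
      stop("carcinogenic endpoint needs a positive lifetime_years",
           call. = FALSE)
    }
    profile$lifetime_years * 365
  }
  conc * profile$ir * ef * profile$ed / (profile$f * profile$bw * at_days)
}

#' Hazard quotient
#'
#' `HQ = CDI / RfD` (or the tolerable daily intake when the metal carries a
#' TDI instead of an RfD, as Pb does here). `HQ < 1` denotes an acceptable
#' noncarcinogenic risk.
#'
#' @param cdi chronic daily intake (mg/kg/day).
#' @param rfd reference dose (mg/kg/day), or `NA`.
#' @param tdi tolerable daily intake (mg/kg/day), or `NA`.
#' @param metal optional metal name used in error messages.
#' @return hazard quotient (dimensionless).
#' @export
hq <- function(cdi, rfd = NA, tdi = NA, metal = NULL) {
  dose <- if (!is.na(rfd)) rfd else tdi
  if (is.na(dose)) {
    stop("neither rfd nor tdi configured",
         if (!is.null(metal)) paste0(" for metal ", metal) else "",
         call. = FALSE)
  }
  if (dose <= 0) stop("safe dose must be > 0", call. = FALSE)
  if (any(cdi < 0)) stop("CDI must be >= 0", call. = FALSE)
  cdi / dose
}

#' Hazard index
#'
#' The integrated noncarcinogenic risk: the sum of the per-metal hazard
#' quotients. `HI < 1` denotes acceptable combined risk.
#'
#' @param hqs numeric vector of hazard quotients, nonempty.
#' @return hazard index (dimensionless).
#' @export
hi <- function(hqs) {
  if (!length(hqs)) {
    stop("hazard index is undefined for an empty set of quotients",
         call. = FALSE)
  }
  if (any(!is.finite(hqs) | hqs < 0)) {
    stop("hazard quotients must be finite and >= 0", call. = FALSE)
  }
  sum(hqs)
}

#' Carcinogenic risk
#'
#' `CR = CDI * SF`: the lifetime excess cancer probability under the linear
#' dose-response model, where CDI is the carcinogenic-endpoint intake
#' (lifetime averaging) and SF the slope factor (kg day/mg).
#'
#' @param cdi carcinogenic-endpoint chronic daily intake (mg/kg/day).
#' @param sf slope factor (kg day/mg), `> 0`.
#' @return carcinogenic risk (dimensionless probability), vectorised.
#' @export
cr <- function(cdi, sf) {
  if (is.na(sf)) stop("slope factor absent", call. = FALSE)
  assert_number(sf, "sf", 0, strict = TRUE)
  if (any(cdi < 0)) stop("CDI must be >= 0", call. = FALSE)
  cdi * sf
}

#' Classify a carcinogenic risk value
#'
#' USEPA bands: `< 1e-6` negligible, `1e-6`-`1e-4` within the threshold
#' range, `> 1e-4` potent.
#'
#' @param x carcinogenic risk, `>= 0`.
#' @return one of `"negligible"`, `"threshold"`, `"potent"`, vectorised.
#' @export
classify_cr <- function(x) {
  if (any(!is.finite(x) | x < 0)) {
    stop("CR must be finite and >= 0", call. = FALSE)
  }
  ifelse(x > 1e-4, "potent", ifelse(x >= 1e-6, "threshold", "negligible"))
}

#' Deterministic health-risk assessment
#'
#' Evaluates the ingestion risk chain (CDI, HQ, HI, CR) at seasonal mean
#' concentrations for each receptor group: per group x season x metal the
#' noncarcinogenic intake and hazard quotient; per group x season the hazard
#' index; and for every metal carrying a slope factor the carcinogenic
#' intake and risk at the seasonal mean, minimum and maximum concentrations.
#'
#' @param summary tibble with columns `metal`, `season`, `mean` and (for the
#'   cancer block's range endpoints, optional) `min`, `max`.
#' @param metals metal registry; toxicological columns (`rfd`/`tdi`/`sf`)
#'   are agency-independent, so the first agency's rows are used.
#' @param profiles named list of [exposure_profile()]s.
#' @param ef exposure frequency (days/year) of the point estimates.
#' @return list of tibbles `doses` (CDI, HQ per metal), `hazard` (HI and its
#'   acceptability per group x season, plus the winter+summer sum per group)
#'   and `cancer` (CR at mean/min/max with its band).
#' @examples
#' risk <- compute_risk(reference_summary())
#' risk$hazard
#' @export
compute_risk <- function(summary, metals = default_metals(),
                         profiles = default_profiles(),
                         ef = NULL) {
  reg <- metals[metals$agency == metals$agency[1], ]
  doses <- list()
  hazard <- list()
  cancer <- list()
  for (g in names(profiles)) {
    profile <- profiles[[g]]
    ef_g <- if (is.null(ef)) profile$ef[["mode"]] else ef
    for (season in unique(summary$season)) {
      sub <- summary[summary$season == season, ]
      idx <- match(reg$metal, sub$metal)
      if (anyNA(idx)) {
        stop("summary lacks season ", season, " means for: ",
             paste(reg$metal[is.na(idx)], collapse = ", "), call. = FALSE)
      }
      conc <- sub$mean[idx]
      d <- cdi(conc, profile, "noncarcinogenic", ef = ef_g)
      q <- mapply(hq, d, reg$rfd, reg$tdi, reg$metal)
      doses[[length(doses) + 1L]] <- tibble::tibble(
        group = g, season = season, metal = reg$metal,
        conc = conc, cdi = d, hq = q
      )
      h <- hi(q)
      hazard[[length(hazard) + 1L]] <- tibble::tibble(
        group = g, season = season, hi = h,
        hi_class = ifelse(h > 1, "unacceptable", "acceptable")
      )
      carc <- reg[!is.na(reg$sf), ]
      for (i in seq_len(nrow(carc))) {
        m <- carc$metal[i]
        row <- sub[idx[match(m, reg$metal)], ]
        at <- c(mean = row$mean,
                min = if ("min" %in% names(row)) row$min else NA_real_,
                max = if ("max" %in% names(row)) row$max else NA_real_)
        at <- at[!is.na(at)]
        d_c <- cdi(unname(at), profile, "carcinogenic", ef = ef_g)
        r <- cr(d_c, carc$sf[i])
        cancer[[length(cancer) + 1L]] <- tibble::tibble(
          group = g, season = season, metal = m,
          statistic = names(at), conc = unname(at),
          cdi = d_c, cr = r, cr_class = classify_cr(r)
        )
      }
    }
  }
  hazard <- do.call(rbind, hazard)
  sums <- lapply(split(hazard, hazard$group), function(x) {
    tibble::tibble(group = x$group[1], season = "winter+summer",
                   hi = sum(x$hi),
                   hi_class = ifelse(sum(x$hi) > 1, "unacceptable",
                                     "acceptable"))
  })
  hazard <- rbind(hazard, do.call(rbind, unname(sums)))
  list(doses = do.call(rbind, doses),
       hazard = hazard,
       cancer = do.call(rbind, cancer))
}
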