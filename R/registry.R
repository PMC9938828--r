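#' Metal registry: regulatory and toxicological constants
#'
#' Reads a YAML registry of per-metal constants into a long tibble with one
#' row per metal x agency: the permissible standard `standard` (ug/L), the
#' ideal concentration `ideal` (ug/L) used by the HPI sub-index, the
#' noncarcinogenic safe dose (`rfd` or `tdi`, mg/kg/day; exactly one of the
#' two per metal) and the carcinogenic slope factor `sf` (kg day/mg, `NA`
#' for metals without one).
#'
#' The packaged default registry covers Pb, Hg, Mn and Fe with EPA and WHO
#' standards (Pb 15/10, Hg 2/6, Mn 50/400, Fe 300/300 ug/L), ideal values of
#' 0 except Mn (100 ug/L), RfDs of 0.0003 (Hg), 0.14 (Mn) and 0.7 (Fe),
#' Pb's TDI of 0.0035 mg/kg/day and Pb's slope factor of 0.0085 kg day/mg.
#' Other agencies or metals are drop-in through a user YAML file of the same
#' layout.
#'
#' @param path path to a metals YAML file; the packaged defaults when `NULL`.
#' @return tibble with columns `metal`, `agency`, `standard`, `ideal`,
#'   `rfd`, `tdi`, `sf`.
#' @examples
#' default_metals()
#' @export
read_metal_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "metals.yaml", package = "ptewater")
  }
  if (!file.exists(path)) {
    stop("metal configuration file not found: ", path, call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$metals) || !length(cfg$metals)) {
    stop("metal configuration has no `metals` entries: ", path, call. = FALSE)
  }
  rows <- lapply(names(cfg$metals), function(m) {
    spec <- cfg$metals[[m]]
    if (is.null(spec$standards) || !length(spec$standards)) {
      stop("metal ", m, " has no `standards` entries", call. = FALSE)
    }
    has_rfd <- !is.null(spec$rfd)
    has_tdi <- !is.null(spec$tdi)
    if (has_rfd && has_tdi) {
      stop("metal ", m, " declares both rfd and tdi; exactly one is allowed",
           call. = FALSE)
    }
    tibble::tibble(
      metal = m,
      agency = names(spec$standards),
      standard = as.numeric(unlist(spec$standards)),
      ideal = if (is.null(spec$ideal)) 0 else as.numeric(spec$ideal),
      rfd = if (has_rfd) as.numeric(spec$rfd) else NA_real_,
      tdi = if (has_tdi) as.numeric(spec$tdi) else NA_real_,
      sf = if (is.null(spec$sf)) NA_real_ else as.numeric(spec$sf)
    )
  })
  out <- do.call(rbind, rows)
  validate_metals(out)
  out
}

#' @rdname read_metal_config
#' @export
default_metals <- function() {
  read_metal_config(NULL)
}

validate_metals <- function(metals) {
  stopifnot(is.data.frame(metals))
  needed <- c("metal", "agency", "standard", "ideal", "rfd", "tdi", "sf")
  missing <- setdiff(needed, names(metals))
  if (length(missing)) {
    stop("metal registry lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(metals$standard) | metals$standard <= 0)) {
    stop("every agency standard S_i must be finite and > 0", call. = FALSE)
  }
  if (any(metals$standard == metals$ideal)) {
    bad <- metals$metal[metals$standard == metals$ideal]
    stop("standard equals ideal value (sub-index undefined) for: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  if (any(!is.na(metals$rfd) & !is.na(metals$tdi))) {
    stop("a metal may carry rfd or tdi, not both", call. = FALSE)
  }
  invisible(metals)
}

# One registry row for a metal under an agency.
metal_row <- function(metals, metal, agency) {
  row <- metals[metals$metal == metal & metals$agency == agency, ]
  if (nrow(row) != 1L) {
    stop("no unique registry entry for metal ", metal, " under agency ",
         agency, call. = FALSE)
  }
  row
}

#' Receptor exposure profiles
#'
#' Reads receptor-group exposure parameters for the drinking-water ingestion
#' dose equation: intake rate `ir` (L/day), exposure frequency `ef`
#' (days/year, a triangular min/mode/max), exposure duration `ed` (years),
#' body weight `bw` (kg), unit conversion `f` (1000, ug to mg) and the
#' carcinogenic averaging lifetime `lifetime_years` (70 y). The packaged
#' defaults hold the child profile (IR 1.25 L/day, ED 6 y, BW 10.64 kg) and
#' the adult profile (IR 1.95 L/day, ED 50 y, BW 61.68 kg), both with EF
#' triangular 180/345/365 days/year.
#'
#' @param path path to an exposure YAML file; the packaged defaults when
#'   `NULL`.
#' @return named list of `exposure_profile` objects.
#' @examples
#' default_profiles()$children
#' @export
read_exposure_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "exposure.yaml", package = "ptewater")
  }
  if (!file.exists(path)) {
    stop("exposure configuration file not found: ", path, call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$profiles) || !length(cfg$profiles)) {
    stop("exposure configuration has no `profiles` entries: ", path,
         call. = FALSE)
  }
  profiles <- lapply(names(cfg$profiles), function(g) {
    p <- cfg$profiles[[g]]
    exposure_profile(
      group = g, ir = p$ir,
      ef_min = p$ef$min, ef_mode = p$ef$mode, ef_max = p$ef$max,
      ed = p$ed, bw = p$bw,
      f = if (is.null(p$f)) 1000 else p$f,
      lifetime_years = if (is.null(p$lifetime_years)) 70 else p$lifetime_years
    )
  })
  names(profiles) <- names(cfg$profiles)
  profiles
}

#' @rdname read_exposure_config
#' @export
default_profiles <- function() {
  read_exposure_config(NULL)
}

#' Construct an exposure profile
#'
#' @param group receptor label, e.g. `"children"` or `"adults"`.
#' @param ir water intake rate (L/day).
#' @param ef_min,ef_mode,ef_max exposure frequency triangular parameters
#'   (days/year), `0 < min <= mode <= max <= 365`.
#' @param ed exposure duration (years).
#' @param bw body weight (kg).
#' @param f unit conversion coefficient (1000 converts ug to mg).
#' @param lifetime_years carcinogenic averaging lifetime (years).
#' @return an `exposure_profile` list.
#' @export
exposure_profile <- function(group, ir, ef_min, ef_mode, ef_max, ed, bw,
                             f = 1000, lifetime_years = 70) {
  assert_number(ir, "ir", 0, strict = TRUE)
  assert_number(ed, "ed", 0, strict = TRUE)
  assert_number(bw, "bw", 0, strict = TRUE)
  assert_number(f, "f", 0, strict = TRUE)
  assert_number(lifetime_years, "lifetime_years", 0, strict = TRUE)
  for (v in c("ef_min", "ef_mode", "ef_max")) {
    assert_number(get(v), v, 0, strict = TRUE)
  }
  if (!(ef_min <= ef_mode && ef_mode <= ef_max && ef_max <= 365)) {
    stop("exposure frequency must satisfy 0 < min <= mode <= max <= 365",
         call. = FALSE)
  }
  structure(
    list(group = group, ir = ir,
         ef = c(min = ef_min, mode = ef_mode, max = ef_max),
         ed = ed, bw = bw, f = f, lifetime_years = lifetime_years),
    class = "exposure_profile"
  )
}

#' @export
print.exposure_profile <- function(x, ...) {
  cat(sprintf(
    "<exposure_profile: %s> IR %.2f L/day, EF %g/%g/%g d/y, ED %g y, BW %.2f kg\n",
    x$group, x$ir, x$ef[["min"]], x$ef[["mode"]], x$ef[["max"]], x$ed, x$bw))
  invisible(x)
}

#' Reference seasonal concentration statistics
#'
#' The packaged per-metal, per-season summary statistics (n, mean, sd, min,
#' max, all concentrations in ug/L) of the two-season urban tap-water survey
#' that this package's defaults emulate: 45 winter and 45 summer samples for
#' each of Pb, Hg, Mn and Fe. These moments parameterise the synthetic-sample
#' generator and serve as the mean-concentration input of the index and risk
#' stages.
#'
#' @param path optional CSV with columns `metal`, `season`, `n`, `mean`,
#'   `sd`, `min`, `max`; the packaged reference when `NULL`.
#' @return tibble of seasonal summary statistics.
#' @examples
#' reference_summary()
#' @export
reference_summary <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "seasonal_reference.csv",
                        package = "ptewater")
  }
  if (!file.exists(path)) {
    stop("reference summary file not found: ", path, call. = FALSE)
  }
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("metal", "season", "mean", "sd")
  missing <- setdiff(needed, names(out))
  if (length(missing)) {
    stop("reference summary lacks columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(out)
}
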