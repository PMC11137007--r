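#' Load a model configuration from a JSON file
#'
#' The configuration has three sections. `rates` holds one sub-section per
#' rate (`p`, `h`, `b`) plus the scalar `u`; each rate is either
#' `{"family": "constant", "level": x}` or
#' `{"family": "exp_cosine", "a1": x, "b1": x, "scale": x, "sign": +/-1}`.
#' `season` holds `T`, `L0`, `s_max`, `n_steps`; `solver` (optional) holds
#' [solver_settings()] fields. Unknown keys anywhere are rejected with the
#' offending key path. An omitted `s_max` defaults to a non-binding cap
#' ([nonbinding_smax()]) with a warning.
#'
#' @param path Path to a JSON configuration file.
#' @return A list with `rates`, `params`, `settings`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  check_keys(cfg, c("rates", "season", "solver"), "")
  if (is.null(cfg$rates) || is.null(cfg$season)) {
    stop("configuration must contain 'rates' and 'season' sections")
  }
  check_keys(cfg$rates, c("p", "h", "b", "u"), "rates")
  for (nm in c("p", "h", "b")) {
    if (is.null(cfg$rates[[nm]])) stop("missing rate section: rates.", nm)
  }
  u <- cfg$rates$u
  if (is.null(u)) u <- 0
  if (!is.numeric(u) || length(u) != 1L || u < 0) {
    stop("invalid value at rates.u: must be a non-negative number")
  }
  check_keys(cfg$season, c("T", "L0", "s_max", "n_steps"), "season")
  Tn <- cfg$season$T %||% 1
  rates <- rate_set(parse_rate(cfg$rates$p, "rates.p", Tn),
                    parse_rate(cfg$rates$h, "rates.h", Tn),
                    parse_rate(cfg$rates$b, "rates.b", Tn), u = u)
  s_max <- cfg$season$s_max
  if (is.null(s_max)) {
    s_max <- nonbinding_smax(rates, Tn)
    warning(sprintf(
      "season.s_max not given; defaulting to a non-binding cap %.4g", s_max))
  }
  n_steps <- cfg$season$n_steps %||% 20000L
  params <- season_params(T = Tn, L0 = cfg$season$L0 %||% 1,
                          s_max = s_max, n_steps = n_steps)
  sv <- cfg$solver
  if (is.null(sv)) sv <- list()
  check_keys(sv, c("integrator", "n_steps", "rel_tol", "control_tol"),
             "solver")
  settings <- solver_settings(
    integrator = sv$integrator %||% "fixed_rk4",
    n_steps = sv$n_steps %||% n_steps,
    rel_tol = sv$rel_tol %||% 1e-8,
    control_tol = sv$control_tol %||% 1e-8)
  list(rates = rates, params = params, settings = settings)
}

#' @rdname load_config
#' @param rates,params The configuration to serialise.
#' @param settings Optional [solver_settings()] to include.
#' @export
write_config <- function(rates, params, path, settings = NULL) {
  stopifnot(inherits(rates, "iso_rateset"), inherits(params, "iso_season"))
  rate_spec <- function(r) {
    if (r$family == "constant") {
      list(family = "constant", level = r$level)
    } else {
      list(family = "exp_cosine", a1 = r$a1, b1 = r$b1, scale = r$scale,
           sign = r$sign)
    }
  }
  cfg <- list(
    rates = list(p = rate_spec(rates$p), h = rate_spec(rates$h),
                 b = rate_spec(rates$b_eff), u = rates$u),
    season = list(T = params$T, L0 = params$L0, s_max = params$s_max,
                  n_steps = params$n_steps))
  if (!is.null(settings)) {
    cfg$solver <- list(integrator = settings$integrator,
                       n_steps = settings$n_steps,
                       rel_tol = settings$rel_tol,
                       control_tol = settings$control_tol)
  }
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra)) {
    stop(sprintf("unknown configuration key%s: %s",
                 if (nchar(where)) paste0(" under '", where, "'") else "",
                 paste(extra, collapse = ", ")))
  }
  invisible(x)
}

parse_rate <- function(spec, where, Tn) {
  if (is.null(spec$family)) stop("missing 'family' at ", where)
  if (identical(spec$family, "constant")) {
    check_keys(spec, c("family", "level"), where)
    if (is.null(spec$level)) stop("missing 'level' at ", where)
    rate_constant(spec$level, period = Tn)
  } else if (identical(spec$family, "exp_cosine")) {
    check_keys(spec, c("family", "a1", "b1", "scale", "sign"), where)
    if (is.null(spec$a1) || is.null(spec$b1)) {
      stop("exp_cosine rate needs 'a1' and 'b1' at ", where)
    }
    rate_exp_cosine(spec$a1, spec$b1, scale = spec$scale %||% 1,
                    sign = spec$sign %||% -1, period = Tn)
  } else {
    stop(sprintf("unknown rate family '%s' at %s", spec$family, where))
  }
}

#' Export / import a solved trajectory as a delimited table
#'
#' Writes a tab-separated table with columns `t`, `L`, `lambda`, `s`, `p`,
#' `h`, `b`, `hamiltonian`, one row per grid point, at 17 significant
#' digits so that doubles round-trip bit-exactly. [import_trajectory()]
#' reads the table back and re-validates the control bounds.
#'
#' @param trajectory An `iso_trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_trajectory <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "iso_trajectory"))
  df <- data.frame(t = trajectory$t_grid, L = trajectory$L,
                   lambda = trajectory$lam, s = trajectory$s,
                   p = trajectory$p_vals, h = trajectory$h_vals,
                   b = trajectory$b_vals, hamiltonian = trajectory$H_vals)
  txt <- vapply(df, function(col) sprintf("%.17g", col),
                character(nrow(df)))
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot open '", path, "' for writing: ", conditionMessage(e))
  })
  on.exit(close(con))
  writeLines(paste(colnames(df), collapse = "\t"), con)
  writeLines(apply(txt, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' @rdname export_trajectory
#' @param s_max If given, re-validate that the `s` column lies in
#'   `[0, s_max]`.
#' @return `import_trajectory()`: a `data.frame` with the eight columns.
#' @export
import_trajectory <- function(path, s_max = NULL) {
  df <- utils::read.delim(path, header = TRUE, colClasses = "numeric")
  need <- c("t", "L", "lambda", "s", "p", "h", "b", "hamiltonian")
  if (!identical(colnames(df), need)) {
    stop("unexpected trajectory columns: ", paste(colnames(df), collapse = ", "))
  }
  if (any(df$s < 0)) stop("imported schedule has negative production rates")
  if (!is.null(s_max) && any(df$s > s_max + 1e-12)) {
    stop("imported schedule exceeds s_max")
  }
  df
}

#' Flat summary of a solved trajectory
#'
#' Collects the scalar diagnostics of a solved season into one list,
#' suitable for JSON export: the objective, switching/phase boundary
#' times, the phase sequence, initial and peak production, the
#' season-integrated heat stress, peak timing (where defined), and the
#' surviving leaf fraction.
#'
#' @param trajectory An `iso_trajectory`.
#' @return A named list of scalars (plus the phase-sequence string).
#' @export
summarize_trajectory <- function(trajectory) {
  stopifnot(inherits(trajectory, "iso_trajectory"))
  ph <- classify_phases(trajectory)
  n <- length(trajectory$t_grid)
  shift <- tryCatch(peak_shift(trajectory), error = function(e) NA_real_)
  list(
    phi = trajectory$phi,
    t_s = ph$t_s,
    t_phase1_end = ph$t_phase1_end,
    phases = paste(ph$sequence, collapse = "->"),
    s0 = trajectory$s[1L],
    s_peak = max(trajectory$s),
    t_s_peak = quad_peak(trajectory$t_grid, trajectory$s),
    peak_shift = shift,
    H_total = total_heat_stress(trajectory$rates$h, trajectory$params$T),
    lam0 = trajectory$lam[1L],
    L_final_frac = trajectory$L[n] / trajectory$params$L0,
    s_max = trajectory$params$s_max,
    n_steps = trajectory$settings$n_steps)
}
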