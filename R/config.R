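config_defaults <- function(p, alpha = 0.05, beta = 1, gamma = 30000) {
  list(p = p, alpha = alpha, beta = beta, gamma = gamma, c = 0.5, l = 0,
       variant = "ocd", modified_grid = FALSE, seed = 1,
       T_diag = NA_real_, T_off = NA_real_)
}

known_config_keys <- c("p", "alpha", "beta", "gamma", "c", "l", "variant",
                       "modified_grid", "seed", "T_diag", "T_off",
                       "input", "output", "n_reps", "horizon", "s",
                       "vartheta", "z", "shape", "rho", "n_runs")

#' Load a run configuration
#'
#' Reads a flat YAML mapping, rejects unknown keys, and fills everything
#' not supplied from the practical defaults (given `p`, and optionally
#' `alpha`, `beta`, `gamma`). Values in `overrides` (e.g. parsed
#' command-line flags) take precedence over the file.
#'
#' @param path YAML file path, or `NULL` to build purely from
#'   `overrides`.
#' @param overrides named list of overriding values.
#' @return named list of class `ocd_config` with every default resolved.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  bad <- setdiff(names(cfg), known_config_keys)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(names(overrides), known_config_keys)
  if (length(bad))
    stop("unknown override key(s): ", paste(bad, collapse = ", "))
  cfg[names(overrides)] <- overrides
  if (is.null(cfg$p)) stop("configuration must at least supply 'p'")
  base <- config_defaults(cfg$p,
                          alpha = cfg$alpha %||% 0.05,
                          beta = cfg$beta %||% 1,
                          gamma = cfg$gamma %||% 30000)
  keep <- setdiff(names(cfg), names(base))
  out <- c(base, cfg[keep])
  out[names(base)] <- ifelse_null(cfg[names(base)], base)
  structure(out, class = "ocd_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

ifelse_null <- function(vals, defaults) {
  out <- defaults
  for (nm in names(defaults)) if (!is.null(vals[[nm]])) out[[nm]] <- vals[[nm]]
  out
}

#' Write a configuration back to YAML
#'
#' Round-trips through [load_config()] unchanged.
#'
#' @param cfg an `ocd_config`.
#' @param path output YAML path.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Generate the deterministic toy fixtures
#'
#' Writes, under `dir`: two toy streams with a known changepoint
#' (`stream_p2.tsv`: p = 2, z = 20, theta = (3, 0); `stream_p5.tsv`:
#' p = 5, z = 50, a 2-sparse change), a synthetic weekly panel
#' (`panel.csv`, first column `date`), and a small cached calibration
#' (`thresholds.yaml`, p = 5, gamma = 200). Byte-identical under the same
#' seed; a different seed changes content but not schema.
#'
#' @param dir output directory (created if missing).
#' @param seed master seed.
#' @return invisibly, the paths written.
#' @export
make_fixtures <- function(dir, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "stream_p2.tsv")
  m <- stream_model(2, 20, c(3, 0), seed = split_seed(seed, 1L))
  write_stream(generate_stream(m, 60), p1)
  p2 <- file.path(dir, "stream_p5.tsv")
  m <- stream_model(5, 50, c(2, -2, 0, 0, 0), seed = split_seed(seed, 2L))
  write_stream(generate_stream(m, 150), p2)
  p3 <- file.path(dir, "panel.csv")
  pan <- synth_weekly_panel(n_regions = 6, n_weeks = 120,
                            seed = split_seed(seed, 3L))
  utils::write.csv(data.frame(date = pan$dates, pan$counts), p3,
                   row.names = FALSE)
  p4 <- file.path(dir, "thresholds.yaml")
  g <- scale_grid(5, 1)
  tn <- default_tuning(5, beta = 1, gamma = 200)
  tn <- calibrate_thresholds(5, 200, tn, g, n_runs = 10,
                             seed = split_seed(seed, 4L))
  yaml::write_yaml(list(p = 5L, gamma = 200L, beta = 1,
                        T_diag = tn$T_diag, T_off = tn$T_off), p4)
  invisible(c(p1, p2, p3, p4))
}
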