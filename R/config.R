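#' Read and write run configurations
#'
#' Plain-text (YAML) run configuration with sections `environment`, `herd`,
#' `founders`, `scheme`, `goals`, `link`, a master `seed`, an output
#' directory and a scale `preset` (`"paper"` or `"desk"`; the desk preset
#' shrinks counts but never alters model constants). Parsing and serializing
#' round-trip exactly. Unknown keys raise a configuration error naming the
#' key.
#'
#' @param path File path.
#' @return A list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) cfg_error(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  validate_run_config(raw)
}

#' @rdname read_run_config
#' @param config A `run_config` (or plain list).
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname read_run_config
#' @param x A raw list to validate.
#' @export
validate_run_config <- function(x) {
  allowed <- c("seed", "out_dir", "preset", "environment", "herd",
               "founders", "scheme", "goals", "link")
  bad <- setdiff(names(x), allowed)
  if (length(bad)) {
    cfg_error(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")))
  }
  if (is.null(x$seed)) cfg_error("config must set a seed")
  x$preset <- x$preset %||% "desk"
  if (!x$preset %in% c("desk", "paper")) {
    cfg_error(sprintf("unknown preset '%s'", x$preset))
  }
  x$out_dir <- x$out_dir %||% "."
  structure(x, class = "run_config")
}

#' Default run configuration
#' @param preset Scale preset.
#' @param seed Master seed.
#' @return A `run_config`.
#' @export
default_run_config <- function(preset = "desk", seed = 1) {
  validate_run_config(list(
    seed = seed, out_dir = ".", preset = preset,
    environment = list(scenario = "MS", n_years = 12),
    herd = list(),
    founders = if (preset == "paper") {
      list(n_sires = 200, daughters_per_sire = 100)
    } else {
      list(n_sires = 50, daughters_per_sire = 20)
    },
    scheme = list(),
    goals = "Base",
    link = list(horizons = c(10, 20, 30), n_cows = 2000)
  ))
}

#' Write a plain run log
#'
#' Records the seed, package version, timestamp and a digest-free dump of
#' the configuration next to each pipeline artifact.
#'
#' @param config A `run_config`.
#' @param path Log file path.
#' @param extra Optional named character vector of extra fields.
#' @return `path`, invisibly.
#' @export
write_run_log <- function(config, path, extra = NULL) {
  lines <- c(
    sprintf("lactgain %s", as.character(utils::packageVersion("lactgain"))),
    sprintf("date: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("seed: %s", config$seed),
    sprintf("preset: %s", config$preset),
    if (!is.null(extra)) sprintf("%s: %s", names(extra), extra),
    "config:",
    paste0("  ", strsplit(yaml::as.yaml(unclass(config)), "\n")[[1]])
  )
  writeLines(lines, path)
  invisible(path)
}
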