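# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Commercial ("half-up") rounding, as used for the displayed relative-risk
#' reduction percentages and table entries. Base R's `round()` rounds half to
#' even, which can differ at exact .5 boundaries.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (may be negative).
#' @return Numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(c(0.5, 1.5, 2.5))
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Assert that `df` has all of `cols`; abort naming the offender and the caller.
check_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ), class = "walkdiab_validation_error")
  }
  invisible(df)
}

stop_validation <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "walkdiab_validation_error")
}

stop_degenerate <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "walkdiab_degenerate_error")
}

stop_config <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "walkdiab_config_error")
}

# Read a JSON or YAML configuration file by extension.
read_config_file <- function(path) {
  if (!file.exists(path)) {
    stop_config("configuration file does not exist: %s", path)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop_config("reading YAML configuration requires the 'yaml' package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}
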