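#' Load a run configuration from a YAML file
#'
#' The configuration file has sections `gating` (fields of
#' [gate_config()]), `instrument` (fields of [instrument_model()]),
#' `protocol` (`n_profile`, `n_sort`, `concentration`), `axes`
#' (`fluorescence`, `backscatter` channel names), `paths` (free-form) and a
#' global `seed`. Missing fields fall back to the package defaults;
#' unknown fields are rejected to catch typos.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return A list with elements `gating` (a `gate_config`), `instrument`
#'   (an `instrument_model`), `protocol`, `axes` (an `axis_mapping`),
#'   `paths` and `seed`.
#' @export
load_config <- function(path = NULL) {
  user <- if (is.null(path)) list() else {
    if (!file.exists(path)) {
      sg_stop("sortgate_error_io", sprintf("config file not found: %s", path))
    }
    yaml::read_yaml(path) %||% list()
  }
  known <- c("gating", "instrument", "protocol", "axes", "paths", "seed")
  unknown <- setdiff(names(user), known)
  if (length(unknown)) {
    sg_stop("sortgate_error_invalid_config",
            sprintf("unknown config section '%s'", unknown[1]))
  }
  section <- function(name, builder) {
    args <- user[[name]] %||% list()
    extra <- setdiff(names(args), names(formals(builder)))
    if (length(extra)) {
      sg_stop("sortgate_error_invalid_config",
              sprintf("unknown field '%s' in config section '%s'", extra[1], name))
    }
    do.call(builder, args)
  }
  protocol <- utils::modifyList(
    list(n_profile = 10000, n_sort = 1200, concentration = 2e6),
    user$protocol %||% list())
  list(gating = section("gating", gate_config),
       instrument = section("instrument", instrument_model),
       protocol = protocol,
       axes = do.call(axis_mapping, user$axes %||% list()),
       paths = user$paths %||% list(),
       seed = as.integer(user$seed %||% 1L))
}
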