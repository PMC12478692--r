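#' Default run configuration
#'
#' Every tunable of the pipeline in one flat list: contact threshold,
#' Laplacian kind, band fractions `(p, q)` (defaults 0.01 and 0.03, the
#' main-results setting), super-node count `s`, attention width `c`, feature
#' width `d`, contextual width `e`, descriptor padding `max_len`, one-hot
#' fusion flag, optimizer settings and seed.
#'
#' @return Named list of configuration values.
#' @export
default_config <- function() {
  list(
    contact_threshold = 10.0,
    laplacian = "normalized",
    p = 0.01, q = 0.03,
    s = 8L, c = 64L, d = 128L, e = 32L,
    max_len = 1024L,
    use_onehot = TRUE,
    epochs = 20L, batch_size = 16L, lr = 1e-3, patience = Inf,
    seed = 1L
  )
}

#' Validate and complete a configuration
#'
#' Unknown keys are an error (listing them); missing keys fall back to
#' [default_config()]; the band constraint `0 < p < q < 1` and basic
#' positivity constraints are enforced.
#'
#' @param config Partial configuration list (possibly from a YAML file).
#' @return Completed configuration list.
#' @export
validate_config <- function(config = list()) {
  defaults <- default_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, config)
  if (!(cfg$p > 0 && cfg$q < 1 && cfg$p < cfg$q)) {
    stop("config violates constraint 0 < p < q < 1")
  }
  if (cfg$s < 1) stop("config violates constraint s >= 1")
  if (cfg$contact_threshold <= 0) stop("contact_threshold must be positive")
  for (k in c("s", "c", "d", "e", "max_len", "epochs", "batch_size", "seed")) {
    cfg[[k]] <- as.integer(cfg[[k]])
  }
  cfg
}

#' Read a configuration from YAML
#'
#' @param path YAML file path; keys as in [default_config()].
#' @return Validated configuration list.
#' @export
read_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

#' Write the resolved configuration snapshot of a run
#'
#' @param config Configuration list.
#' @param path Output YAML path.
#' @return Invisibly, the path.
#' @export
write_config <- function(config, path) {
  cfg <- config
  cfg$patience <- if (is.finite(cfg$patience)) cfg$patience else "Inf"
  yaml::write_yaml(cfg, path)
  invisible(path)
}
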