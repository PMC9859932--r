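#' Pipeline configuration
#'
#' A single flat key-value list holding every tunable threshold of the
#' pipeline, serializable to YAML and logged verbatim at the start of every
#' CLI run.
#'
#' @return A named list of defaults.
#' @export
default_config <- function() {
  list(
    normalization = "rpm_log2",   # reference convention; queries use rpm_ln
    mito_prefix = "MT-",
    qc_mito_ceiling = 0.10,
    alpha = 0.01,
    max_cond = 3,
    test_kind = "fisher_z",
    min_class_cells = 30,
    msa_floor = 0.6,
    loading_floor = 0.5,
    communality_floor = 0.5,
    top_n = 1000,
    n_perm = 100,
    percentile = 0.95,
    k_min = 2,
    k_max = 15,
    n_init = 10,
    ring_digits = 4,
    seed = 1
  )
}

validate_config <- function(cfg) {
  def <- default_config()
  unknown <- setdiff(names(cfg), names(def))
  if (length(unknown)) stop_("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(def, cfg)
  in01 <- function(key) {
    v <- cfg[[key]]
    if (!is.numeric(v) || v <= 0 || v >= 1) stop_("config '", key, "' must be in (0, 1)")
  }
  in01("alpha"); in01("percentile")
  for (key in c("msa_floor", "loading_floor", "communality_floor", "qc_mito_ceiling")) {
    v <- cfg[[key]]
    if (!is.numeric(v) || v < 0 || v > 1) stop_("config '", key, "' must be in [0, 1]")
  }
  for (key in c("max_cond", "min_class_cells", "top_n", "n_perm", "k_min",
                "k_max", "n_init", "ring_digits", "seed")) {
    v <- cfg[[key]]
    if (!is.numeric(v) || v < 0) stop_("config '", key, "' must be non-negative")
  }
  if (cfg$k_min < 2 || cfg$k_max < cfg$k_min) stop_("invalid k range")
  if (!cfg$normalization %in% c("rpm_log2", "rpm_ln", "rpm", "none"))
    stop_("unknown normalization mode: ", cfg$normalization)
  if (!cfg$test_kind %in% c("fisher_z", "chi2"))
    stop_("unknown test kind: ", cfg$test_kind)
  cfg
}

#' @rdname default_config
#' @param path YAML file path.
#' @export
read_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

#' @rdname default_config
#' @param cfg a config list (missing keys are filled with defaults).
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(validate_config(cfg), path)
  invisible(path)
}
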