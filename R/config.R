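#' Default analysis configuration
#'
#' One layered configuration drives the command-line interface and is
#' embedded into every serialized report: file values override these
#' defaults, command-line flags override the file.
#'
#' @return named list of all tunable parameters with their defaults.
#' @export
dm_defaults <- function() {
  list(
    target_edge = 1.0,        # remeshing target edge length (A)
    leaflet_cutoff = 15,      # anchor proximity cutoff for leaflets (A)
    k_neighbors = 12,         # normal-estimation neighbourhood
    pbc_margin = 10,          # periodic ghost margin (A)
    grid_factor = 0.5,        # reconstruction cell / mean anchor spacing
    sigma_factor = 1.0,       # splat kernel width / mean anchor spacing
    smooth_iter = 8,          # CVT relaxation iterations
    deep_threshold = 4.5,     # shallow/deep depth split (A)
    bin_width = 5,            # area histogram bin width (A^2)
    a_min_floor = 15,         # smallest admissible fit lower bound (A^2)
    min_count = 5,            # upper-bound signal-to-noise guard
    min_bins = 8,             # minimum usable bins per window
    a0 = 50,                  # mixture superposition reference area (A^2)
    contact_cutoff = 11,      # lipid contact cutoff (A)
    n_bins_domains = NULL,    # curvature bins (NULL: ~10 A wide)
    angle_threshold = 2       # flat-domain turning threshold (degrees)
  )
}

#' Merge configuration layers
#'
#' @param config_file optional YAML file with a flat key-value mapping.
#' @param overrides named list of explicit values (e.g. parsed flags).
#' @return the effective configuration list.
#' @export
dm_config <- function(config_file = NULL, overrides = list()) {
  cfg <- dm_defaults()
  if (!is.null(config_file)) {
    file_cfg <- yaml::read_yaml(config_file)
    unknown <- setdiff(names(file_cfg), names(cfg))
    if (length(unknown)) {
      warning("unknown config key(s) ignored: ",
              paste(unknown, collapse = ", "))
    }
    cfg[intersect(names(file_cfg), names(cfg))] <-
      file_cfg[intersect(names(file_cfg), names(cfg))]
  }
  cfg[names(overrides)] <- overrides
  cfg
}
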