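# Run configuration: a nested key-value tree mirroring every module's
# parameters, with strict validation (unknown keys are rejected) so a run
# manifest pins every knob.

#' Default run configuration
#'
#' @return Nested list of all tunable parameters with their defaults.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    dict = list(n_words = 64L, patch_size = 4L, stride = 4L),
    lda = list(n_iter = 500L, burn_in = 200L, thin = 10L, alpha = NULL,
               beta = 0.01),
    ms = list(thr = 0.1, s_thr = 0.5, max_iter = 100L, min_size = 20L),
    msbs = list(C = 1.5, hr_init = 40, hr_min = 2, tol = 1,
                jump_factor = 1),
    rect = list(r1 = 8L, r2 = 8L),
    slic = list(n_segments = 64L, compactness = 10, n_iter = 10L),
    pipeline = list(K = 2L, fg_rule = "excess_green", topic_id = NULL,
                    beta_prime = 0.2, alpha_threshold = 0.8,
                    gamma_l = 0.5, gamma_h = 2, d0 = 30, high_q = 0.85,
                    low_frac = 0.5, min_distance = 5, dilation_radius = 5,
                    bimodality = 0.2)
  )
}

merge_config <- function(base, override, path = "") {
  for (key in names(override)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(base)) stop("unknown config key: ", full)
    if (is.list(base[[key]]) && !is.null(base[[key]])) {
      if (!is.list(override[[key]]))
        stop("config key ", full, " must be a section")
      base[[key]] <- merge_config(base[[key]], override[[key]], full)
    } else {
      base[key] <- override[key]
    }
  }
  base
}

#' Load a YAML configuration over the defaults
#'
#' @param path YAML file; NULL returns the defaults.
#' @return Validated nested config list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- merge_config(cfg, user)
  }
  cfg
}

config_to_msbs <- function(cfg) {
  msbs_config(C = cfg$msbs$C, hr_init = cfg$msbs$hr_init,
              hr_min = cfg$msbs$hr_min, tol = cfg$msbs$tol,
              jump_factor = cfg$msbs$jump_factor, thr = cfg$ms$thr,
              s_thr = cfg$ms$s_thr, max_iter = cfg$ms$max_iter,
              min_size = cfg$ms$min_size, n_words = cfg$dict$n_words,
              patch_size = cfg$dict$patch_size, stride = cfg$dict$stride,
              n_iter = cfg$lda$n_iter, burn_in = cfg$lda$burn_in,
              thin = cfg$lda$thin, alpha = cfg$lda$alpha,
              beta = cfg$lda$beta)
}
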