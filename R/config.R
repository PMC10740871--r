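#' Resolve a run configuration
#'
#' Normalizes a configuration list (typically read from YAML) into fully
#' resolved component objects: model [channel_config] (preset name or
#' explicit widths), [supervision_config], [train_config], evaluation
#' parameters, data-generation parameters and the global seed. Unknown
#' fields are rejected so typos fail loudly.
#'
#' @param cfg a named list (see `load_run_config`).
#' @return A list of class `run_config` with elements `model`, `supervision`,
#'   `training`, `evaluation`, `data`, `out_dir`, `seed`.
#' @export
resolve_run_config <- function(cfg) {
  known <- c("model", "supervision", "training", "evaluation", "data",
             "out_dir", "seed")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)

  model <- cfg$model
  model_cfg <- if (is.null(model)) {
    preset_config("dse")
  } else if (is.character(model)) {
    preset_config(model)
  } else {
    channel_config(model$stem_width, unlist(model$encoder_widths),
                   unlist(model$decoder_widths))
  }
  sup <- do.call(supervision_config, as.list(cfg$supervision))
  tcf <- do.call(train_config,
                 utils::modifyList(list(seed = derive_seed(seed, "train")),
                                   as.list(cfg$training)))
  ev <- utils::modifyList(list(window_s = 5, step_s = 0.1,
                               band_lo_bpm = 40, band_hi_bpm = 180),
                          as.list(cfg$evaluation))
  dat <- utils::modifyList(list(n_clips = 30L, duration_s = 128 / 30, fs = 30,
                                hr_range = c(50, 150)),
                           as.list(cfg$data))
  structure(list(model = model_cfg, supervision = sup, training = tcf,
                 evaluation = ev, data = dat,
                 out_dir = if (is.null(cfg$out_dir)) "." else cfg$out_dir,
                 seed = seed),
            class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' `load_run_config` reads and resolves; `save_run_config` serializes the
#' resolved configuration so a run can be reproduced from its output
#' directory. Load -> save -> load is idempotent.
#'
#' @param path YAML file path.
#' @return `load_run_config`: a `run_config`.
#' @export
load_run_config <- function(path) {
  resolve_run_config(yaml::read_yaml(path))
}

#' @rdname load_run_config
#' @param rc a `run_config`.
#' @export
save_run_config <- function(rc, path) {
  stopifnot(inherits(rc, "run_config"))
  lst <- list(
    model = list(stem_width = rc$model$stem_width,
                 encoder_widths = rc$model$encoder_widths,
                 decoder_widths = rc$model$decoder_widths),
    supervision = unclass(rc$supervision),
    training = unclass(rc$training),
    evaluation = rc$evaluation,
    data = rc$data,
    out_dir = rc$out_dir,
    seed = rc$seed)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' Derive a component seed from the global seed
#'
#' One global seed fans out deterministically to per-component seeds, so a
#' module tested in isolation matches the end-to-end run. Results stay
#' within the 32-bit integer range.
#'
#' @param seed global integer seed.
#' @param component component name (e.g. `"data"`, `"train"`, `"weights"`).
#' @return An integer seed.
#' @export
derive_seed <- function(seed, component) {
  h <- sum(utf8ToInt(component) * seq_along(utf8ToInt(component)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}
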