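#' Run a configured synthesis-and-analysis pipeline stage
#'
#' Thin orchestration layer over the package's functions: generates the
#' configured synthetic inputs, runs the corresponding analysis stage and
#' the cohort statistics, and writes results plus a provenance manifest
#' (stage, parameters, seed, package version) into the output directory.
#' All randomness flows from the config seed.
#'
#' @param config a list, or path to a YAML file, with fields
#'   \describe{
#'     \item{stage}{`"cohort"`, `"biometry"` or `"calibration"`.}
#'     \item{seed}{integer seed.}
#'     \item{params}{stage-specific parameter list (see Details).}
#'   }
#'   Unknown top-level keys are rejected.
#' @param out_dir output directory (created if needed); `NULL` skips
#'   writing.
#' @details Stage parameters: `cohort` accepts any [cohort_spec()]
#'   arguments plus `ages`/`effects` vectors for a multi-age design;
#'   `biometry` accepts [eye_phantom_spec()] arguments plus `n` (number of
#'   phantoms); `calibration` accepts `lens_powers`, `factor`,
#'   `n_replicates`, `noise_sd`.
#' @return The stage result (report data.frame or list), invisibly
#'   augmented with the manifest.
#' @examples
#' run_pipeline(list(stage = "calibration", seed = 1,
#'                   params = list(factor = 1.924)))$factor
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  allowed <- c("stage", "seed", "params", "verbosity")
  extra <- setdiff(names(config), allowed)
  if (length(extra)) {
    stop_spec("unknown config key(s): ", paste(extra, collapse = ", "))
  }
  stage <- match.arg(config$stage, c("cohort", "biometry", "calibration"))
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  params <- if (is.null(config$params)) list() else config$params

  result <- switch(stage,
    cohort = pipeline_cohort(params, seed),
    biometry = pipeline_biometry(params, seed),
    calibration = pipeline_calibration(params, seed))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    tab <- if (is.data.frame(result)) result else {
      scalars <- result[vapply(result, function(x)
        is.numeric(x) && length(x) == 1L, logical(1))]
      as.data.frame(scalars)
    }
    write_results(tab, file.path(out_dir, paste0(stage, "_results")))
    manifest <- list(stage = stage, seed = seed, params = params,
                     package = "zfocular",
                     version = as.character(utils::packageVersion("zfocular")))
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  }
  invisible(result)
}

pipeline_cohort <- function(params, seed) {
  ages <- if (is.null(params$ages)) "1.5 mpf" else params$ages
  effects <- if (is.null(params$effects)) {
    rep(if (is.null(params$effect)) -47 else params$effect, length(ages))
  } else params$effects
  spec_args <- params[setdiff(names(params), c("ages", "effects", "effect"))]
  tabs <- lapply(seq_along(ages), function(k) {
    args <- spec_args
    args$effect <- effects[k]
    args$age_label <- ages[k]
    args$seed <- seed + k - 1L
    generate_cohort(do.call(cohort_spec, args))
  })
  crosssectional_report(do.call(rbind, tabs))
}

pipeline_biometry <- function(params, seed) {
  n <- if (is.null(params$n)) 5L else as.integer(params$n)
  spec_args <- params[setdiff(names(params), "n")]
  rows <- lapply(seq_len(n), function(k) {
    args <- spec_args
    args$seed <- seed + k - 1L
    b <- generate_bscan(do.call(eye_phantom_spec, args))
    bio <- compute_biometry(segment_axial_boundaries(b))
    data.frame(phantom = k, axial_length_um = bio$axial_length_um,
               truth_axial_um = sum(b$truth$physical_um))
  })
  do.call(rbind, rows)
}

pipeline_calibration <- function(params, seed) {
  powers <- if (is.null(params$lens_powers)) c(-6, -2, 0, 4, 10) else
    as.numeric(params$lens_powers)
  factor <- if (is.null(params$factor)) 1.924 else params$factor
  n_rep <- if (is.null(params$n_replicates)) 1L else as.integer(params$n_replicates)
  noise <- if (is.null(params$noise_sd)) 0 else params$noise_sd
  slopes <- lapply(seq_along(powers), function(k) {
    vapply(seq_len(n_rep), function(r) {
      p <- generate_pupil_profile(powers[k], factor, noise_sd = noise,
                                  seed = seed + k * 1000L + r)
      estimate_slope(p)$slope
    }, numeric(1))
  })
  calibrate(powers, slopes)
}
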