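# Composable, serializable preprocessing pipelines. Steps are identified by
# canonical registry names (crop, despike_wh, savgol, gaussian, asls, aspls,
# normalize, subtract_bg, plus user-registered steps); pipelines serialize to
# JSON by step name and fully resolved parameters only -- no code is ever
# embedded, so shared protocols cannot execute arbitrary serialized code.

.step_registry <- new.env(parent = emptyenv())

.register_builtin_steps <- function() {
  reg <- function(name, fn, defaults) {
    assign(name, list(fn = fn, defaults = defaults), envir = .step_registry)
  }
  reg("crop",
    function(x, p) crop_spectra(x, p$min_wn, p$max_wn),
    list(min_wn = 700, max_wn = 1800)
  )
  reg("despike_wh",
    function(x, p) despike_whitaker_hayes(x, p$z_threshold, p$window),
    list(z_threshold = 6.5, window = 5L)
  )
  reg("savgol",
    function(x, p) denoise_savgol(x, p$polyorder, p$window),
    list(polyorder = 3L, window = 7L)
  )
  reg("gaussian",
    function(x, p) denoise_gaussian(x, p$sigma_bands),
    list(sigma_bands = 1)
  )
  reg("asls",
    function(x, p) baseline_asls(x, p$lambda, p$p, p$max_iter, p$tol),
    list(lambda = 1e5, p = 0.01, max_iter = 30L, tol = 1e-3)
  )
  reg("aspls",
    function(x, p) baseline_aspls(x, p$lambda, p$max_iter, p$tol),
    list(lambda = 1e5, max_iter = 30L, tol = 1e-3)
  )
  reg("normalize",
    function(x, p) normalize_spectra(x, p$mode),
    list(mode = "minmax_global")
  )
  reg("subtract_bg",
    function(x, p) subtract_background(x, as.numeric(p$background)),
    list(background = numeric(0))
  )
}

.onLoad <- function(libname, pkgname) {
  .register_builtin_steps()
}

#' Register a custom preprocessing step
#'
#' Registered steps become usable inside pipelines and pipeline JSON under
#' their name. The step function must map a `spectral_container` to a
#' `spectral_container`.
#'
#' @param name Step identifier (must be unused).
#' @param fn Function `(container, params)` returning a container; `params`
#'   is a named list.
#' @param defaults Named list of default parameters.
#' @return `name`, invisibly.
#' @export
register_step <- function(name, fn, defaults = list()) {
  if (exists(name, envir = .step_registry, inherits = FALSE)) {
    stop(sprintf("step '%s' is already registered", name), call. = FALSE)
  }
  if (!is.function(fn)) stop("fn must be a function", call. = FALSE)
  assign(name, list(fn = fn, defaults = defaults), envir = .step_registry)
  invisible(name)
}

#' List registered step names
#' @return Character vector of registered preprocessing step names.
#' @export
list_steps <- function() sort(ls(.step_registry))

.get_step <- function(name) {
  if (!exists(name, envir = .step_registry, inherits = FALSE)) {
    stop(sprintf(
      "unknown step '%s'; registered steps: %s",
      name, paste(list_steps(), collapse = ", ")
    ), call. = FALSE)
  }
  get(name, envir = .step_registry, inherits = FALSE)
}

#' Construct a pipeline step
#'
#' Defaults of the registered step are expanded immediately, so a step (and
#' any pipeline built from it) is always fully concrete.
#'
#' @param step Registered step name.
#' @param params Named list of parameter overrides.
#' @return A `pipeline_step` object.
#' @export
pipeline_step <- function(step, params = list()) {
  entry <- .get_step(step)
  full <- utils::modifyList(entry$defaults, as.list(params))
  structure(list(step = step, params = full), class = "pipeline_step")
}

#' Construct a preprocessing pipeline
#'
#' An ordered list of named steps applied left to right; a pipeline behaves
#' exactly like a single container -> container method and can be saved,
#' reused and shared as JSON.
#'
#' @param steps List of [pipeline_step()] objects (at least one).
#' @param name Pipeline name.
#' @return A `spectral_pipeline` object.
#' @export
pipeline <- function(steps, name = "pipeline") {
  if (length(steps) < 1L) stop("a pipeline needs at least one step", call. = FALSE)
  steps <- lapply(steps, function(s) {
    if (!inherits(s, "pipeline_step")) {
      stop("steps must be pipeline_step objects", call. = FALSE)
    }
    s
  })
  structure(
    list(name = name, steps = steps, format_version = "1"),
    class = "spectral_pipeline"
  )
}

#' @export
print.spectral_pipeline <- function(x, ...) {
  cat(sprintf("<spectral_pipeline '%s': %d steps>\n", x$name, length(x$steps)))
  for (i in seq_along(x$steps)) {
    s <- x$steps[[i]]
    ps <- vapply(s$params, function(v) paste(format(v), collapse = ","), "")
    cat(sprintf(
      "  %d. %s(%s)\n", i, s$step,
      paste(names(s$params), ps, sep = "=", collapse = ", ")
    ))
  }
  invisible(x)
}

#' Apply a pipeline to a container
#'
#' Strict left-to-right composition, identical to chaining the step
#' operations manually. A per-step log (step name, parameters, input/output
#' shapes, wall time) is attached to the result as attribute
#' `"pipeline_log"`.
#'
#' @param p A `spectral_pipeline`.
#' @param x A `spectral_container`.
#' @param verbose Print each log record as it is emitted.
#' @return The processed container.
#' @export
pipeline_apply <- function(p, x, verbose = FALSE) {
  if (!inherits(p, "spectral_pipeline")) {
    stop("expected a spectral_pipeline", call. = FALSE)
  }
  .assert_container(x)
  log <- vector("list", length(p$steps))
  for (i in seq_along(p$steps)) {
    s <- p$steps[[i]]
    entry <- .get_step(s$step)
    shape_in <- c(spatial_shape(x), n_bands(x))
    t0 <- proc.time()[["elapsed"]]
    x <- tryCatch(
      entry$fn(x, s$params),
      error = function(e) {
        stop(sprintf("pipeline step %d ('%s') failed: %s",
                     i, s$step, conditionMessage(e)), call. = FALSE)
      }
    )
    elapsed <- proc.time()[["elapsed"]] - t0
    log[[i]] <- list(
      step = s$step, params = s$params,
      shape_in = shape_in, shape_out = c(spatial_shape(x), n_bands(x)),
      seconds = elapsed
    )
    if (verbose) {
      message(sprintf(
        "[%d/%d] %s: %s -> %s (%.3fs)", i, length(p$steps), s$step,
        paste(shape_in, collapse = "x"),
        paste(log[[i]]$shape_out, collapse = "x"), elapsed
      ))
    }
  }
  attr(x, "pipeline_log") <- log
  x
}

.pipeline_as_list <- function(p) {
  list(
    format_version = p$format_version,
    name = p$name,
    steps = lapply(p$steps, function(s) {
      params <- if (length(s$params)) {
        s$params[order(names(s$params))]
      } else {
        structure(list(), names = character(0)) # serializes as {}
      }
      list(step = s$step, params = params)
    })
  )
}

#' Save a pipeline as JSON
#'
#' The schema is
#' `{"format_version":"1","name":...,"steps":[{"step":...,"params":{...}}]}`
#' with canonically ordered parameter keys, so saved protocols diff cleanly
#' and are fully concrete (all defaults expanded).
#'
#' @param p A `spectral_pipeline`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
pipeline_save <- function(p, path) {
  if (!inherits(p, "spectral_pipeline")) {
    stop("expected a spectral_pipeline", call. = FALSE)
  }
  for (s in p$steps) .get_step(s$step) # refuse to save unknown steps
  # digits = I(17): doubles must survive the JSON round trip bit-exactly
  jsonlite::write_json(.pipeline_as_list(p), path,
    auto_unbox = TRUE, digits = I(17), pretty = TRUE
  )
  invisible(path)
}

#' Load a pipeline from JSON
#'
#' Every step name must be registered in the current session (custom steps
#' are matched by name only and must be re-registered before loading).
#'
#' @param path Path to pipeline JSON.
#' @return A `spectral_pipeline`.
#' @export
pipeline_load <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format_version, "1")) {
    stop(sprintf("incompatible pipeline format_version '%s'",
                 obj$format_version %||% "<missing>"), call. = FALSE)
  }
  steps <- lapply(obj$steps, function(s) {
    .get_step(s$step)
    params <- lapply(s$params, function(v) {
      if (is.list(v)) as.numeric(unlist(v)) else v
    })
    # integers arrive as integer-valued doubles from JSON; harmless downstream
    structure(list(step = s$step, params = params), class = "pipeline_step")
  })
  pipeline(steps, name = obj$name %||% "pipeline")
}

#' Retrieve a named built-in preprocessing protocol
#'
#' Two fully specified protocols are shipped:
#' \describe{
#'   \item{`cell_phenotyping`}{crop to 700-1800 cm^-1, cosmic-ray removal,
#'     Savitzky-Golay denoising (order 3, window 7), ASLS baseline
#'     correction, global min-max normalization -- the protocol used for
#'     cell-phenotyping unmixing workflows.}
#'   \item{`pipeline_I`}{crop to 700-1800 cm^-1, cosmic-ray removal, Gaussian
#'     denoising, ASLS baseline correction, per-spectrum area-under-curve
#'     normalization -- a representative throughput-profiling protocol.}
#' }
#'
#' @param name Protocol name.
#' @return A `spectral_pipeline`.
#' @export
get_protocol <- function(name) {
  protocols <- list(
    cell_phenotyping = function() pipeline(list(
      pipeline_step("crop", list(min_wn = 700, max_wn = 1800)),
      pipeline_step("despike_wh"),
      pipeline_step("savgol", list(polyorder = 3L, window = 7L)),
      pipeline_step("asls"),
      pipeline_step("normalize", list(mode = "minmax_global"))
    ), name = "cell_phenotyping"),
    pipeline_I = function() pipeline(list(
      pipeline_step("crop", list(min_wn = 700, max_wn = 1800)),
      pipeline_step("despike_wh"),
      pipeline_step("gaussian"),
      pipeline_step("asls"),
      pipeline_step("normalize", list(mode = "auc_pixel"))
    ), name = "pipeline_I")
  )
  if (!name %in% names(protocols)) {
    stop(sprintf(
      "unknown protocol '%s'; available: %s",
      name, paste(names(protocols), collapse = ", ")
    ), call. = FALSE)
  }
  protocols[[name]]()
}
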