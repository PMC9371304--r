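#' Model parameters for the astrocytic compartment
#'
#' Loads the model parameter set from a structured JSON file (flat keys, one
#' entry per rate constant, concentration or count, each with units and a
#' `calibrated` flag) and returns it as an `astro_params` object: a named
#' numeric list with the per-key metadata attached as an attribute.
#'
#' All concentrations are in uM, times in seconds, first-order rates in 1/s
#' and second-order rates in 1/uM/s.
#'
#' @param file Path to a parameter JSON file. Defaults to the versioned file
#'   shipped with the package.
#' @param ... Named numeric overrides applied on top of the file values,
#'   e.g. `astro_parameters(n_ip3r = 20)`.
#' @return An object of class `astro_params`.
#' @export
#' @examples
#' p <- astro_parameters()
#' p$k_mglur
astro_parameters <- function(file = NULL, ...) {
  if (is.null(file)) {
    file <- system.file("extdata", "default_parameters.json",
                        package = "gliosim", mustWork = TRUE)
  }
  raw <- jsonlite::read_json(file, simplifyVector = FALSE)
  entries <- raw$params
  p <- lapply(entries, function(e) as.numeric(e$value))
  meta <- data.frame(
    name = names(entries),
    unit = vapply(entries, function(e) as.character(e$unit), ""),
    calibrated = vapply(entries, function(e) isTRUE(e$calibrated), TRUE),
    desc = vapply(entries, function(e) as.character(e$desc), ""),
    stringsAsFactors = FALSE, row.names = NULL
  )
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    for (nm in names(overrides)) p[[nm]] <- as.numeric(overrides[[nm]])
  }
  structure(p, meta = meta, version = raw$meta$version,
            class = "astro_params")
}

#' Validate a parameter set
#'
#' Checks the structural invariants of the model parameters: strictly
#' positive rates, concentrations and volumes; integer channel count >= 1;
#' ER/cytosol volume ratio in (0, 1]; vesicle counts and docking capacity
#' consistent.
#'
#' @param params An `astro_params` object.
#' @return `params`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_parameters <- function(params) {
  stopifnot(inherits(params, "astro_params"))
  num <- unlist(params)
  nonneg_ok <- c("glu_base", "v_pm_leak")   # may legitimately be zero
  pos <- num[!names(num) %in% nonneg_ok]
  if (any(!is.finite(num))) stop("non-finite parameter value")
  if (any(pos <= 0)) {
    stop("parameters must be strictly positive: ",
         paste(names(pos)[pos <= 0], collapse = ", "))
  }
  if (any(num[nonneg_ok] < 0)) stop("negative leak/baseline parameter")
  if (params$n_ip3r < 1 || params$n_ip3r != round(params$n_ip3r))
    stop("n_ip3r must be an integer >= 1")
  if (params$er_cyt_ratio <= 0 || params$er_cyt_ratio > 1)
    stop("er_cyt_ratio must lie in (0, 1]")
  for (nm in c("n_docked", "n_mobile", "docked_max", "n_subunits",
               "syt4_sites", "syt7_sites")) {
    if (params[[nm]] != round(params[[nm]]) || params[[nm]] < 0)
      stop(nm, " must be a non-negative integer")
  }
  if (params$n_docked > params$docked_max)
    stop("n_docked cannot exceed docked_max")
  if (abs(params$syt4_koff / params$syt4_kon - 22) > 22 * 0.5)
    warning("Syt4 off/on ratio far from the nominal 22 uM")
  if (abs(params$syt7_koff / params$syt7_kon - 15) > 15 * 0.5)
    warning("Syt7 per-site off/on ratio far from the nominal 15 uM")
  invisible(params)
}

#' @export
print.astro_params <- function(x, ...) {
  meta <- attr(x, "meta")
  cat("Astrocytic compartment model parameters (",
      length(x), " values, file version ",
      attr(x, "version"), ")\n", sep = "")
  df <- data.frame(value = unlist(x),
                   unit = meta$unit[match(names(x), meta$name)],
                   calibrated = meta$calibrated[match(names(x), meta$name)])
  print(df, ...)
  invisible(x)
}

#' Write a parameter set back to JSON
#'
#' @param params An `astro_params` object.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_parameters <- function(params, file) {
  stopifnot(inherits(params, "astro_params"))
  meta <- attr(params, "meta")
  entries <- lapply(names(params), function(nm) {
    i <- match(nm, meta$name)
    list(value = params[[nm]], unit = meta$unit[i],
         calibrated = meta$calibrated[i], desc = meta$desc[i])
  })
  names(entries) <- names(params)
  out <- list(meta = list(version = attr(params, "version"),
                          note = "exported parameter set"),
              params = entries)
  jsonlite::write_json(out, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}
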