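#' Write / read curves as annotated CSV
#'
#' Curves are stored as two-column CSV (`time_s` plus `conc_mmol_per_L` or
#' `si_au`) preceded by `#`-prefixed metadata lines (curve class, location,
#' baseline length, and any extra provenance fields such as the config
#' hash and seed). Round trips are lossless to full double precision.
#'
#' @param curve A [concentration_curve()] or [signal_curve()].
#' @param path File path.
#' @param metadata Named list of extra provenance fields for the header.
#' @return `write_curve` returns `path` invisibly; `read_curve` returns
#'   the reconstructed curve.
#' @export
write_curve <- function(curve, path, metadata = list()) {
  stopifnot(inherits(curve, "phantom_curve"))
  meta <- c(list(class = class(curve)[1L], location = curve$location),
            if (!is.null(curve$baseline_n)) list(baseline_n = curve$baseline_n),
            metadata)
  hdr <- sprintf("# %s: %s", names(meta), vapply(meta, format, ""))
  df <- as.data.frame(curve)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(names(df), collapse = ","), con)
  writeLines(paste(sprintf("%.17g", df[[1L]]), sprintf("%.17g", df[[2L]]),
                   sep = ","), con)
  invisible(path)
}

#' @rdname write_curve
#' @export
read_curve <- function(path) {
  lines <- readLines(path)
  is_meta <- grepl("^#", lines)
  meta <- list()
  for (ln in lines[is_meta]) {
    m <- regmatches(ln, regexec("^#\\s*([^:]+):\\s*(.*)$", ln))[[1L]]
    if (length(m) == 3L) meta[[trimws(m[2L])]] <- trimws(m[3L])
  }
  body <- lines[!is_meta]
  if (length(body) < 2L) {
    stop(sprintf("malformed curve file '%s': no data rows", path),
         call. = FALSE)
  }
  df <- utils::read.csv(text = body)
  if (!"time_s" %in% names(df) || ncol(df) < 2L) {
    stop(sprintf("malformed curve file '%s': expected columns time_s,<value>",
                 path), call. = FALSE)
  }
  vals <- df[[setdiff(names(df), "time_s")[1L]]]
  loc <- meta$location %||% "unknown"
  if (identical(meta$class, "signal_curve") || "si_au" %in% names(df)) {
    signal_curve(df$time_s, vals, roi = loc,
                 baseline_n = as.integer(meta$baseline_n %||% 0L))
  } else {
    concentration_curve(df$time_s, vals, location = loc)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bundle a complete run configuration
#'
#' Collects everything needed to reproduce a simulation run: circuit,
#' injection protocol, sequence, signal model, noise level and seed, under
#' a versioned schema id.
#'
#' @param circuit A [circuit_config()].
#' @param protocol An [injection_protocol()].
#' @param seq A [sequence_params()].
#' @param model A [signal_model_params()].
#' @param sigma Noise SD in au.
#' @param seed Integer seed.
#' @return A `run_config` list.
#' @export
run_config <- function(circuit, protocol, seq = sequence_params(),
                       model = signal_model_params(), sigma = 0, seed = 1L) {
  structure(list(schema = "perfusiontwin/run_config/1",
                 circuit = circuit, protocol = protocol, sequence = seq,
                 model = model, sigma = sigma, seed = seed),
            class = "run_config")
}

#' Serialise / deserialise a run configuration as JSON
#'
#' `read_config` validates the file and reports missing fields by name.
#'
#' @param config A [run_config()].
#' @param path File path.
#' @return `write_config` returns `path` invisibly; `read_config` the
#'   validated `run_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  jsonlite::write_json(strip_classes(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

strip_classes <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, strip_classes)
    attributes(x) <- list(names = names(x))
  }
  x
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) {
                    stop(sprintf("malformed config file '%s': %s", path,
                                 conditionMessage(e)), call. = FALSE)
                  })
  need <- function(obj, fields, where) {
    missing <- setdiff(fields, names(obj))
    if (length(missing) > 0L) {
      stop(sprintf("config schema error in '%s': missing field(s) %s in %s",
                   path, paste(missing, collapse = ", "), where),
           call. = FALSE)
    }
  }
  need(raw, c("schema", "circuit", "protocol", "sequence", "model",
              "sigma", "seed"), "run_config")
  need(raw$circuit, c("cascade", "coronary", "cardiac_output",
                      "perfusion_flow_right", "perfusion_flow_left",
                      "distribution_volume", "mode"), "circuit")
  need(raw$protocol, c("dose", "body_weight", "agent_concentration",
                       "injection_rate", "flush_volume",
                       "prebolus_fraction"), "protocol")
  casc <- lapply(seq_len(nrow(raw$circuit$cascade)), function(i) {
    r <- raw$circuit$cascade[i, ]
    compartment(r$name, r$volume, r$kind)
  })
  cor <- raw$circuit$coronary
  circuit <- circuit_config(
    cardiac_output = raw$circuit$cardiac_output,
    perfusion_flow_right = raw$circuit$perfusion_flow_right,
    perfusion_flow_left = raw$circuit$perfusion_flow_left,
    cascade = casc,
    coronary = compartment(cor$name, cor$volume, cor$kind),
    distribution_volume = raw$circuit$distribution_volume,
    mode = raw$circuit$mode,
    tube_dispersion_n = raw$circuit$tube_dispersion_n %||% 1L)
  protocol <- do.call(injection_protocol, raw$protocol)
  seqp <- do.call(sequence_params, raw$sequence)
  model <- do.call(signal_model_params, raw$model[c("r1", "R10", "scale")])
  run_config(circuit, protocol, seqp, model, sigma = raw$sigma,
             seed = raw$seed)
}

#' Stable hash of a configuration
#'
#' MD5 of the canonical JSON serialisation, used to stamp output artifacts
#' with the configuration that produced them.
#'
#' @param config Any serialisable object (typically a [run_config()]).
#' @return Hex string.
#' @export
config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(strip_classes(unclass(config)), tf, auto_unbox = TRUE,
                       digits = NA, null = "null")
  unname(tools::md5sum(tf))
}

#' Write a quantification result as JSON
#'
#' Emits the fitted Fermi parameters, the perfusion estimate, residual and
#' convergence flag together with the provenance fields (seed, config
#' hash).
#'
#' @param result A `fermi_fit` from [fit_fermi()].
#' @param path File path.
#' @param seed Seed used for the acquisition, if any.
#' @param config A [run_config()] (hashed into the output), optional.
#' @return `path`, invisibly.
#' @export
write_result <- function(result, path, seed = NULL, config = NULL) {
  stopifnot(inherits(result, "fermi_fit"))
  out <- list(
    schema = "perfusiontwin/fermi_result/1",
    params = result$params[c("F", "k", "tau_d", "tau_0")],
    perfusion_ml_ml_min = result$perfusion,
    residual_rms_au = result$residual_rms,
    converged = result$converged,
    n_iter = result$n_iter,
    seed = seed,
    config_hash = if (!is.null(config)) config_hash(config) else NULL
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Export an image stack as text frames with a JSON sidecar
#'
#' Each frame is written as a plain CSV matrix; geometry, timing and ROI
#' layout go into `stack.json`. (A deliberately simple, text-only format:
#' nothing downstream needs DICOM/NIfTI/PNG.)
#'
#' @param stack A `phantom_image_stack`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_image_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "phantom_image_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(stack$frames)) {
    utils::write.table(stack$frames[[i]],
                       file.path(dir, sprintf("frame_%04d.csv", i)),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  side <- list(schema = "perfusiontwin/image_stack/1",
               n_frames = length(stack$frames),
               shape = stack$layout$shape,
               pixel_size_mm = stack$layout$pixel_size_mm,
               times_s = stack$times,
               background = stack$background, sigma = stack$sigma,
               rois = stack$layout$rois)
  jsonlite::write_json(side, file.path(dir, "stack.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
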