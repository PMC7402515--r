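#' Write and read spike times as plain text
#'
#' One spike time (seconds) per line.
#'
#' @param spikes A \code{\link{spike_train}} or numeric times (s).
#' @param path Output file.
#' @export
write_spike_times <- function(spikes, path) {
  t <- if (inherits(spikes, "spike_train")) spikes$times else
    as.numeric(spikes)
  writeLines(formatC(t, format = "g", digits = 17), path)
  invisible(path)
}

#' @rdname write_spike_times
#' @param duration Recording duration (s) for the reconstructed train.
#' @return \code{read_spike_times}: a \code{\link{spike_train}}.
#' @export
read_spike_times <- function(path, duration) {
  t <- as.numeric(readLines(path))
  spike_train(t, duration)
}

#' Write a gain curve as CSV
#'
#' Columns: \code{f}, \code{gain}, \code{gain_sd}, \code{phase},
#' \code{n_spikes}.
#'
#' @param curve A \code{\link{gain_curve}}.
#' @param path Output file.
#' @export
write_gain_curve <- function(curve, path) {
  write.csv(curve[, c("f", "gain", "gain_sd", "phase", "n_spikes")],
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gain_curve
#' @export
read_gain_curve <- function(path) {
  out <- read.csv(path)
  class(out) <- c("gain_curve", "data.frame")
  out
}

#' Serialize a ball-and-stick model to JSON
#'
#' Captures geometry, densities, kinetics and AIS distance with full
#' numeric precision so that \code{model_from_json(model_to_json(m))}
#' reconstructs a bit-identical model.
#'
#' @param model A \code{\link{bas_model}}.
#' @param path Optional output file; when NULL the JSON string is returned.
#' @return JSON string (invisibly, when written to a file).
#' @export
model_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "bas_model"))
  payload <- list(
    geometry = unclass(model$geometry)[c(
      "axon_diameter", "axon_length", "n_axon_compartments",
      "soma_diameter", "axial_resistivity", "specific_capacitance")],
    densities = unclass(model$densities),
    kinetics = as.list(unclass(model$kinetics)),
    ais_distance = model$ais_distance)
  js <- jsonlite::toJSON(payload, digits = I(17), auto_unbox = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @rdname model_to_json
#' @param json JSON string or path to a JSON file.
#' @return \code{model_from_json}: the reconstructed \code{bas_model}.
#' @export
model_from_json <- function(json) {
  if (length(json) == 1 && file.exists(json)) json <- readLines(json)
  p <- jsonlite::fromJSON(paste(json, collapse = "\n"))
  kin <- structure(unlist(p$kinetics), class = "channel_kinetics")
  bas_model(do.call(cable_geometry, p$geometry),
            do.call(channel_densities, p$densities),
            ais_distance = p$ais_distance, kinetics = kin)
}

#' Write and read an eIF parameter table as CSV
#'
#' Columns \code{d}, \code{tau_m}, \code{E_L}, \code{V_T}, \code{Delta_T}
#' (extra columns are preserved).
#'
#' @param table Data frame as returned by \code{\link{run_reduction_sweep}}
#'   or \code{\link{eif_reference_params}}.
#' @param path File path.
#' @export
write_eif_table <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_eif_table
#' @export
read_eif_table <- function(path) {
  tab <- read.csv(path)
  need <- c("d", "tau_m", "E_L", "V_T", "Delta_T")
  if (!all(need %in% names(tab)))
    stop("eIF table must have columns ", paste(need, collapse = ", "))
  tab
}

#' Export a spike template as two-column plain text
#'
#' Columns: channel index and spike time (ms), whitespace separated.
#'
#' @param template A \code{\link{spike_template}}.
#' @param path File path.
#' @export
write_template <- function(template, path) {
  ch <- rep(seq_along(template$times), lengths(template$times))
  t <- unlist(template$times)
  writeLines(paste(ch, formatC(t, format = "g", digits = 17)), path)
  invisible(path)
}

#' Write an experiment result table and accompanying JSON fit report
#'
#' @param result A \code{sweep_result} from \code{\link{run_gain_sweep}}.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_sweep_result <- function(result, dir) {
  stopifnot(inherits(result, "sweep_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(result$records, file.path(dir, "sweep_records.csv"),
            row.names = FALSE)
  for (d in names(result$gain_curves))
    write_gain_curve(result$gain_curves[[d]],
                     file.path(dir, sprintf("gain_curve_d%s.csv", d)))
  report <- list(manifest = result$manifest)
  if (!is.null(result$logistic))
    report$logistic <- result$logistic[c("a", "k", "d0", "b", "residual")]
  writeLines(jsonlite::toJSON(report, digits = NA, auto_unbox = TRUE,
                              pretty = TRUE),
             file.path(dir, "fit_report.json"))
  invisible(dir)
}
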