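# File schemas: trace CSV, histogram/bound-fraction CSV, results JSON,
# experiment config JSON (validated), plain-text image export.

#' Write molecule traces to a CSV file
#'
#' Schema: `frame_index, time_s, excitation, I_D, I_A, molecule_id`.
#' @param traces list of `molecule_trace` (or one trace).
#' @param file destination.
#' @export
write_trace_csv <- function(traces, file) {
  if (inherits(traces, "molecule_trace")) traces <- list(traces)
  rows <- lapply(traces, function(tr) {
    data.frame(frame_index = tr$frame, time_s = tr$time,
               excitation = tr$excitation,
               I_D = round(tr$I_D, 3), I_A = round(tr$I_A, 3),
               molecule_id = attr(tr, "molecule_id") %||% NA)
  })
  utils::write.csv(do.call(rbind, rows), file, row.names = FALSE,
                   quote = FALSE)
  invisible(file)
}

#' Read molecule traces from a trace CSV
#'
#' Inverse of [write_trace_csv()]. Corrupt rows (non-numeric intensities,
#' missing fields) are skipped with a warning reporting the count.
#'
#' @param file path to a trace CSV.
#' @param frame_time frame integration time, s.
#' @param optics optional [optics_model()] attached to the traces (used
#'   for intensity floors downstream).
#' @return list of `molecule_trace`.
#' @export
read_trace_csv <- function(file, frame_time = 0.050,
                           optics = optics_model()) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE,
                        colClasses = c(excitation = "character"))
  need <- c("frame_index", "time_s", "excitation", "I_D", "I_A",
            "molecule_id")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop("trace CSV is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  suppressWarnings({
    df$I_D <- as.numeric(df$I_D)
    df$I_A <- as.numeric(df$I_A)
    df$time_s <- as.numeric(df$time_s)
  })
  bad <- !stats::complete.cases(df[, c("time_s", "I_D", "I_A")]) |
    !df$excitation %in% c("G", "R", "dark")
  if (any(bad)) {
    warning(sum(bad), " corrupt row(s) skipped in ", file, call. = FALSE)
    df <- df[!bad, , drop = FALSE]
  }
  if (nrow(df) == 0L) stop("no usable rows in ", file, call. = FALSE)
  lapply(split(df, df$molecule_id), function(d) {
    tr <- data.frame(frame = d$frame_index, time = d$time_s,
                     excitation = d$excitation, I_D = d$I_D, I_A = d$I_A,
                     stringsAsFactors = FALSE)
    attr(tr, "frame_time") <- frame_time
    attr(tr, "optics") <- optics
    attr(tr, "molecule_id") <- d$molecule_id[1L]
    attr(tr, "flow_start") <- 0
    class(tr) <- c("molecule_trace", "data.frame")
    tr
  })
}

#' Write a FRET histogram as CSV (bin_center, density)
#' @param hist a `fret_histogram`.
#' @param file destination.
#' @export
write_histogram_csv <- function(hist, file) {
  utils::write.csv(data.frame(bin_center = hist$bin_center,
                              density = hist$density),
                   file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Write a bound-fraction series as CSV
#' @param bfs a `bound_fraction_series`.
#' @param file destination.
#' @export
write_bound_fraction_csv <- function(bfs, file) {
  utils::write.csv(data.frame(time_s = bfs$time, fraction = bfs$fraction,
                              n_molecules = bfs$n_molecules),
                   file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Write an image as a plain-text matrix (TSV of counts)
#'
#' Plain-text stand-in for binary image stacks so outputs stay
#' text-reviewable; one file per frame.
#' @param image numeric matrix.
#' @param file destination.
#' @export
write_image_txt <- function(image, file) {
  utils::write.table(round(image, 1), file, row.names = FALSE,
                     col.names = FALSE, sep = "\t")
  invisible(file)
}

#' Write an analysis-results list as JSON
#' @param results named list.
#' @param file destination.
#' @export
write_results_json <- function(results, file) {
  jsonlite::write_json(results, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(file)
}

config_schema <- function() {
  list(
    preset = function(v) is.character(v) && length(v) == 1L &&
      v %in% names(smfret_presets()),
    n_molecules = function(v) is.numeric(v) && v >= 1,
    seed = function(v) is.numeric(v) && v >= 0,
    out_dir = function(v) is.character(v) && length(v) == 1L
  )
}

#' Validate an experiment configuration
#'
#' Required fields: `preset` (a known preset name), `n_molecules`,
#' `seed`, `out_dir`. Optional: `conc_nM` (concentration in nM, the
#' units experiment tables are written in; converted to molar
#' internally), `horizon_s`, `flow_start_s`. Errors name the offending
#' field.
#'
#' @param config named list (e.g. parsed from JSON).
#' @return the validated config with defaults filled in and `conc`
#'   (molar) derived from `conc_nM`.
#' @export
validate_config <- function(config) {
  schema <- config_schema()
  for (field in names(schema)) {
    if (is.null(config[[field]])) {
      stop("config is missing required field '", field, "'", call. = FALSE)
    }
    if (!schema[[field]](config[[field]])) {
      stop("config field '", field, "' is invalid", call. = FALSE)
    }
  }
  config$n_molecules <- as.integer(config$n_molecules)
  if (config$n_molecules < 1L) {
    stop("config field 'n_molecules' is invalid", call. = FALSE)
  }
  pr <- preset(config$preset)
  if (!is.null(config$conc_nM)) {
    if (!is.numeric(config$conc_nM) || any(config$conc_nM < 0)) {
      stop("config field 'conc_nM' is invalid", call. = FALSE)
    }
    config$conc <- config$conc_nM * 1e-9
  } else {
    config$conc <- pr$conc %||% pr$conc_grid[1L]
  }
  config$horizon_s <- config$horizon_s %||% pr$horizon %||% 600
  config$flow_start_s <- config$flow_start_s %||% pr$flow_start %||% 0
  config
}

#' Read and validate a JSON experiment config
#' @param file path to a JSON config.
#' @export
read_config <- function(file) {
  validate_config(jsonlite::read_json(file, simplifyVector = TRUE))
}

# stable short hash of a config (for manifests): djb2 over the
# serialized representation; output location is not part of the
# experiment identity
config_hash <- function(config) {
  config <- config[setdiff(names(config), "out_dir")]
  s <- jsonlite::toJSON(config[order(names(config))], auto_unbox = TRUE)
  h <- 5381
  for (b in utf8ToInt(as.character(s))) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", as.integer(h))
}
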