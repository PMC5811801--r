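#' Read a time series from CSV/TSV
#'
#' Accepts the two-column dialect (`time_s`, `value`, with header; the rate
#' is inferred from the time stamps) or a single-column file accompanied by
#' a YAML/JSON sidecar header (same path with `.yaml`/`.json` appended)
#' providing `rate` and optionally `start`, `units`, `channel`.
#'
#' @param path CSV/TSV file path.
#' @param channel Channel label to attach (default from sidecar or "").
#' @return An [scr_ts].
#' @export
read_timeseries_csv <- function(path, channel = NULL) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep)
  if (ncol(df) >= 2) {
    dt <- diff(df[[1]])
    if (length(dt) < 1 || any(dt <= 0)) {
      stop("read_timeseries_csv: need increasing time stamps", call. = FALSE)
    }
    scr_ts(df[[2]], rate = 1 / stats::median(dt), start = df[[1]][1],
           channel = channel %||% "")
  } else {
    side <- NULL
    for (ext in c(".yaml", ".json")) {
      sp <- paste0(path, ext)
      if (file.exists(sp)) {
        side <- if (ext == ".yaml") yaml::read_yaml(sp)
                else jsonlite::read_json(sp, simplifyVector = TRUE)
        break
      }
    }
    if (is.null(side) || is.null(side$rate)) {
      stop("read_timeseries_csv: single-column file needs a sidecar with 'rate'",
           call. = FALSE)
    }
    scr_ts(df[[1]], rate = side$rate, start = side$start %||% 0,
           units = side$units %||% "", channel = channel %||% side$channel %||% "")
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a time series as two-column CSV
#'
#' @param ts An [scr_ts].
#' @param path Output path.
#' @export
write_timeseries_csv <- function(ts, path) {
  utils::write.csv(as.data.frame(ts), path, row.names = FALSE)
  invisible(path)
}

#' Read an event schedule from CSV
#'
#' Expects columns `onset_s`, `event_type`, `subject`, `repetition` and
#' optionally `epoch_id`.
#'
#' @param path CSV file path.
#' @return An [event_schedule].
#' @export
read_events_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("onset_s", "event_type", "subject", "repetition")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("read_events_csv: missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  event_schedule(df$onset_s, df$event_type, df$subject, df$repetition,
                 epoch_id = df$epoch_id)
}

#' Write an event schedule as CSV
#'
#' @param events An [event_schedule].
#' @param path Output path.
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(as.data.frame(events), path, row.names = FALSE)
  invisible(path)
}

#' Read or write model parameters (YAML or JSON)
#'
#' Serializes [scrf_params] (`theta1`..`theta4`) or [burst_params] (`A`,
#' `mu`, `sigma`, `c`) losslessly; the format is chosen from the file
#' extension.
#'
#' @param params A parameter object.
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return `read_params()` returns the parameter object; `write_params()`
#'   the path, invisibly.
#' @export
write_params <- function(params, path) {
  lst <- unclass(params)
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(lst, path)
  else jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  lst <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  if (all(c("theta1", "theta2", "theta3") %in% names(lst))) {
    scrf_params(lst$theta1, lst$theta2, lst$theta3, lst$theta4 %||% 0)
  } else if (all(c("A", "mu", "sigma") %in% names(lst))) {
    burst_params(lst$A, lst$mu, lst$sigma, lst$c %||% 0)
  } else {
    stop("read_params: unrecognized parameter file", call. = FALSE)
  }
}

#' Write a pipeline report as JSON
#'
#' @param report A run report (list) from [run_exp1_pipeline()] or
#'   [run_exp2_pipeline()].
#' @param path Output path.
#' @export
write_report_json <- function(report, path) {
  strip <- function(x) {
    if (inherits(x, c("scr_ts", "scr_epoch"))) {
      list(n = length(x$values), rate = x$rate)
    } else if (inherits(x, "scr_fit")) {
      list(params = unclass(x$params), gain = x$gain, r2 = x$r2,
           converged = x$converged)
    } else if (is.list(x)) {
      lapply(x, strip)
    } else x
  }
  jsonlite::write_json(strip(report), path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, na = "null")
  invisible(path)
}
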