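SART_COLS <- c("participant", "trial", "stimulus", "response", "rt",
               "probe_response")

#' Read a SART trial/probe dataset
#'
#' Reads the package's CSV dialect: UTF-8, dot decimal, times in seconds,
#' 1-based trial indices, columns `participant`, `trial`, `stimulus`
#' (`go`/`nogo`), `response` (`go`/`withheld`), `rt` (empty for withheld
#' trials and probe rows) and `probe_response` (1-4, empty for trial rows).
#' Trial rows and probe rows share the table; a probe row records the
#' Likert response to the thought probe following that trial index.
#' Malformed rows are rejected with their line numbers.
#'
#' @param path Path to a CSV file.
#' @return A validated tibble of trial and probe records.
#' @export
read_sart <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "mindrace_io_error")
  }
  hdr <- names(readr::read_csv(path, n_max = 0,
                               show_col_types = FALSE, col_types = readr::cols()))
  missing <- setdiff(SART_COLS, hdr)
  if (length(missing) > 0) {
    abort(paste0("Missing required columns: ", paste(missing, collapse = ", ")),
          class = "mindrace_io_error")
  }
  data <- readr::read_csv(
    path,
    col_types = readr::cols(
      participant = readr::col_integer(),
      trial = readr::col_integer(),
      stimulus = readr::col_character(),
      response = readr::col_character(),
      rt = readr::col_double(),
      probe_response = readr::col_integer()
    )
  )
  validate_sart(data[SART_COLS])
}

#' Validate a SART dataset
#'
#' Enforces the record invariants: trial rows have a stimulus in
#' `{go, nogo}` and a response in `{go, withheld}`, a positive RT exactly
#' when the response is go; probe rows carry only a Likert response in 1-4;
#' trial indices are unique within participant. Violations are reported
#' with (1-based, header-inclusive) line numbers.
#'
#' @param data A data frame in the SART dialect.
#' @return The validated tibble, invisibly classed as before.
#' @export
validate_sart <- function(data) {
  data <- tibble::as_tibble(data)
  line <- seq_len(nrow(data)) + 1L  # 1-based with header line
  is_probe <- !is.na(data$probe_response)
  is_trial <- !is.na(data$stimulus) | !is.na(data$response)
  problems <- character()
  add <- function(msg, bad) {
    if (any(bad)) {
      c(problems,
        sprintf("%s (lines %s)", msg,
                paste(utils::head(line[bad], 5), collapse = ", ")))
    } else problems
  }
  problems <- add("row is neither a trial nor a probe", !is_probe & !is_trial)
  problems <- add("row mixes trial and probe fields", is_probe & is_trial)
  problems <- add("unknown stimulus",
                  is_trial & !data$stimulus %in% c("go", "nogo"))
  problems <- add("unknown response",
                  is_trial & !data$response %in% c("go", "withheld"))
  problems <- add("rt present on withheld trial",
                  is_trial & !is.na(data$response) &
                    data$response == "withheld" & !is.na(data$rt))
  problems <- add("go response without positive rt",
                  is_trial & !is.na(data$response) & data$response == "go" &
                    (is.na(data$rt) | data$rt <= 0))
  problems <- add("probe_response outside 1..4",
                  is_probe & !data$probe_response %in% 1:4)
  problems <- add("missing participant id", is.na(data$participant))
  if (length(problems) > 0) {
    abort(paste0("Malformed SART data:\n  ",
                 paste(problems, collapse = "\n  ")),
          class = "mindrace_data_error")
  }
  dup <- data[is_trial, ] |>
    dplyr::count(.data$participant, .data$trial) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort("Duplicate trial indices within participant.",
          class = "mindrace_data_error")
  }
  data
}

#' Write a SART dataset
#'
#' @param data A tibble in the SART dialect (validated before writing).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sart <- function(data, path) {
  data <- validate_sart(data)
  readr::write_csv(data, path, na = "")
  invisible(path)
}

#' Remove exceptionally slow responses
#'
#' Removes go-response trials with RT above `cutoff` (1.5 s by default,
#' which is exceptionally slow in the SART). Withheld trials and probe rows
#' are never removed, and no likelihood renormalization is applied; the
#' removal mirrors the data-cleaning step of the larger experiment.
#'
#' @param data A SART tibble.
#' @param cutoff RT cutoff in seconds, `> 0`.
#' @return A list with `data` (the filtered tibble) and `report` (a one-row
#'   tibble: `n_removed`, `n_trials`, `pct_removed` rounded to 2 decimals).
#' @examples
#' # removal percentage is reported to two decimals, as in "0.24% of trials"
#' @export
filter_slow_trials <- function(data, cutoff = 1.5) {
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff <= 0) {
    abort("`cutoff` must be a positive number of seconds.",
          class = "mindrace_domain_error")
  }
  data <- tibble::as_tibble(data)
  is_trial <- !is.na(data$stimulus)
  slow <- is_trial & !is.na(data$rt) & data$rt > cutoff
  n_trials <- sum(is_trial)
  report <- tibble::tibble(
    n_removed = sum(slow),
    n_trials = n_trials,
    pct_removed = round(100 * sum(slow) / n_trials, 2)
  )
  list(data = data[!slow, , drop = FALSE], report = report)
}

#' Split a SART tibble into trial and probe records
#'
#' @param data A SART tibble.
#' @return `sart_trials()`: the trial rows; `sart_probes()`: the probe rows
#'   with columns `participant`, `trial`, `response`.
#' @export
sart_trials <- function(data) {
  dplyr::filter(tibble::as_tibble(data), !is.na(.data$stimulus)) |>
    dplyr::select("participant", "trial", "stimulus", "response", "rt")
}

#' @rdname sart_trials
#' @export
sart_probes <- function(data) {
  dplyr::filter(tibble::as_tibble(data), !is.na(.data$probe_response)) |>
    dplyr::transmute(.data$participant, .data$trial,
                     response = as.integer(.data$probe_response))
}
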