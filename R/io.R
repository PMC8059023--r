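#' Read and write pipeline files
#'
#' Plain-text interchange for the pipeline's tabular objects:
#' speed profiles as 2-column CSV (`time_s`, `speed_mps`), test records as
#' 3-column CSV (`time_s`, `speed_mps`, `hr_bpm`), validation tables as the
#' tidy CSV produced by [cross_validate()], and fitted models as JSON
#' (`{order, gain_bpm_per_mps, time_constants_s}`).
#'
#' @param data Object to write.
#' @param path File path.
#' @return Readers return tibbles (or an [tf_model()] for
#'   `read_model_json()`); writers return `data` invisibly.
#' @name hrdyn-io
NULL

#' @rdname hrdyn-io
#' @export
write_speed_profile <- function(data, path) {
  readr::write_csv(data[c("time_s", "speed_mps")], path)
  invisible(data)
}

#' @rdname hrdyn-io
#' @export
read_speed_profile <- function(path) {
  out <- readr::read_csv(path, col_types = readr::cols(
    time_s = readr::col_double(), speed_mps = readr::col_double()
  ))
  lv <- sort(unique(out$speed_mps))
  if (length(lv) == 2L) {
    attr(out, "mean_speed") <- mean(lv)
    attr(out, "half_amplitude") <- diff(lv) / 2
  }
  out
}

#' @rdname hrdyn-io
#' @export
write_test_record <- function(data, path) {
  readr::write_csv(data[c("time_s", "speed_mps", "hr_bpm")], path)
  invisible(data)
}

#' @rdname hrdyn-io
#' @param participant,session Labels attached to the record on reading.
#' @export
read_test_record <- function(path, participant = NA_character_,
                             session = NA_character_) {
  out <- readr::read_csv(path, col_types = readr::cols(
    time_s = readr::col_double(), speed_mps = readr::col_double(),
    hr_bpm = readr::col_double()
  ))
  tibble::tibble(participant = participant, session = session, out)
}

#' @rdname hrdyn-io
#' @export
write_validation_records <- function(data, path) {
  readr::write_csv(data, path)
  invisible(data)
}

#' @rdname hrdyn-io
#' @export
read_validation_records <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname hrdyn-io
#' @param model An [tf_model()] or `hr_tf_fit`.
#' @export
write_model_json <- function(model, path) {
  if (inherits(model, "hr_tf_fit")) model <- model$model
  stopifnot(inherits(model, "hr_tf"))
  jsonlite::write_json(
    list(
      order = model$order,
      gain_bpm_per_mps = model$gain,
      time_constants_s = model$time_constants
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(model)
}

#' @rdname hrdyn-io
#' @export
read_model_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  tf_model(x$gain_bpm_per_mps, x$time_constants_s)
}
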