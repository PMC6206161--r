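
LEARNING_COLS <- c("subject_id", "experiment", "session", "trial", "context_id",
                   "valence", "magnitude", "information", "option_left",
                   "option_right", "choice", "outcome_chosen", "outcome_unchosen")
TRANSFER_COLS <- c("subject_id", "trial", "option_a", "option_b", "choice")

#' Write learning / transfer trial tables to CSV
#'
#' Comma-separated, UTF-8, header row; a missing counterfactual outcome
#' (partial-feedback trial) is written as an empty field.
#'
#' @param x a trial tibble in the package schema.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_learning_trials <- function(x, path) {
  stopifnot(all(LEARNING_COLS %in% names(x)))
  readr::write_csv(x[, LEARNING_COLS], path, na = "")
  invisible(path)
}

#' @rdname write_learning_trials
#' @export
write_transfer_trials <- function(x, path) {
  stopifnot(all(TRANSFER_COLS %in% names(x)))
  readr::write_csv(x[, TRANSFER_COLS], path, na = "")
  invisible(path)
}

io_fail <- function(path, rows, msg) {
  stop(sprintf("%s: %s (line%s %s)", path, msg,
               if (length(rows) > 1) "s" else "",
               paste(utils::head(rows + 1L, 5), collapse = ", ")),
       call. = FALSE)
}

#' Read and validate a learning-trials CSV
#'
#' Validates the schema on read and reports violations with file line
#' numbers: required columns, choice labels, outcome values, and the
#' partial/complete feedback contract (`outcome_unchosen` must be present
#' exactly on complete-information rows). Rows are normalized to
#' subject/session/trial order.
#'
#' @param path CSV file in the [write_learning_trials()] schema.
#' @return a validated tibble.
#' @export
read_learning_trials <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  # column presence is validated explicitly below; silence readr's own
  # complaint about parsers for absent columns
  x <- suppressWarnings(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                    col_types = readr::cols(
                      subject_id = "c", experiment = "i", session = "i",
                      trial = "i", context_id = "c", valence = "c",
                      magnitude = "d", information = "c",
                      option_left = "c", option_right = "c", choice = "c",
                      outcome_chosen = "d", outcome_unchosen = "d")))
  missing <- setdiff(LEARNING_COLS, names(x))
  if (length(missing) > 0)
    stop(path, ": missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  if (nrow(x) == 0) stop(path, ": no trials", call. = FALSE)

  bad <- which(!x$choice %in% c("left", "right"))
  if (length(bad)) io_fail(path, bad, "choice must be 'left' or 'right'")
  bad <- which(!x$valence %in% c("reward", "loss"))
  if (length(bad)) io_fail(path, bad, "valence must be 'reward' or 'loss'")
  bad <- which(!x$information %in% c("partial", "complete"))
  if (length(bad)) io_fail(path, bad, "information must be 'partial' or 'complete'")
  bad <- which(is.na(x$outcome_chosen))
  if (length(bad)) io_fail(path, bad, "outcome_chosen must be numeric")
  bad <- which(x$information == "partial" & !is.na(x$outcome_unchosen))
  if (length(bad)) io_fail(path, bad, "outcome_unchosen present on a partial-feedback row")
  bad <- which(x$information == "complete" & is.na(x$outcome_unchosen))
  if (length(bad)) io_fail(path, bad, "outcome_unchosen missing on a complete-feedback row")

  x[order(x$subject_id, x$session, x$trial), ]
}

#' Read and validate a transfer-trials CSV
#'
#' @param path CSV file in the [write_transfer_trials()] schema.
#' @return a validated tibble, ordered by subject and trial. Transfer rows
#'   carry no outcome fields: the phase is feedback-free by design.
#' @export
read_transfer_trials <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(
                         subject_id = "c", trial = "i", option_a = "c",
                         option_b = "c", choice = "c"))
  missing <- setdiff(TRANSFER_COLS, names(x))
  if (length(missing) > 0)
    stop(path, ": missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  if (nrow(x) == 0) stop(path, ": no trials", call. = FALSE)
  bad <- which(!x$choice %in% c("a", "b"))
  if (length(bad)) io_fail(path, bad, "choice must be 'a' or 'b'")
  bad <- which(x$option_a == x$option_b)
  if (length(bad)) io_fail(path, bad, "option_a and option_b must differ")
  x[order(x$subject_id, x$trial), ]
}

#' Serialize / restore a cohort configuration
#'
#' JSON round-trip of a [cohort_config()] so that generated artifacts can
#' embed the exact configuration (priors, seed, sizes) that produced them.
#'
#' @param config a [cohort_config()].
#' @param path JSON file.
#' @return `write_cohort_config` returns `path` invisibly;
#'   `read_cohort_config` returns a `cohort_config`.
#' @export
write_cohort_config <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  x <- jsonlite::fromJSON(readLines(path), simplifyVector = TRUE)
  cohort_config(n_exp1 = x$n_exp1, n_exp2 = x$n_exp2, model = x$model,
                priors = x$priors, seed = x$seed, outcome_mode = x$outcome_mode)
}
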