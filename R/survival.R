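#' Dichotomize survival data at the median survival time
#'
#' Converts per-subject survival records into a binary long/short survival
#' outcome so survival cohorts can enter two-class biomarker discovery.
#' The median is computed once over all input times. Subjects surviving at
#' least to the median (event observed or not) are labeled `"long"`;
#' subjects with an observed event before the median are labeled
#' `"short"`; subjects censored before the median are uninformative and
#' are removed.
#'
#' @param data A data frame with one row per subject.
#' @param time Column of nonnegative survival/follow-up times.
#' @param event Column of event indicators (`TRUE`/1 = event observed,
#'   `FALSE`/0 = censored).
#' @return The input tibble with two added columns: `retained` (logical)
#'   and `outcome` (`"long"`, `"short"`, or `NA` for removed subjects).
#'   The positive class for downstream discovery is `"long"`.
#'
#' @examples
#' d <- data.frame(time = c(1, 2, 3, 4), event = c(1, 1, 1, 1))
#' dichotomize_survival(d)
#' @export
dichotomize_survival <- function(data, time = "time", event = "event") {
  stopifnot(is.data.frame(data))
  time_col <- .col_name(rlang::enquo(time), data, default = "time")
  event_col <- .col_name(rlang::enquo(event), data, default = "event")
  times <- data[[time_col]]
  events <- as.logical(data[[event_col]])
  if (is.null(times) || is.null(events)) {
    stop("time/event columns not found", call. = FALSE)
  }
  stopifnot(is.numeric(times), !anyNA(times), !anyNA(events))
  if (any(times < 0)) stop("survival times must be nonnegative", call. = FALSE)

  med <- stats::median(times)
  long <- times >= med                 # tie at the median counts as long
  retained <- long | events            # censored before the median: removed
  outcome <- rep(NA_character_, length(times))
  outcome[long] <- "long"
  outcome[!long & events] <- "short"
  if (!any(retained)) stop("all subjects removed by censoring", call. = FALSE)

  dplyr::mutate(tibble::as_tibble(data),
                retained = retained, outcome = outcome)
}
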