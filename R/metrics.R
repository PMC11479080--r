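#' Accuracy from recall and false alarm rate
#'
#' The detection accuracy summary used throughout:
#' `accuracy = (recall + (100 - FAR)) / 2`, all in percent.
#'
#' @param recall Recall in percent.
#' @param far False alarm rate in percent.
#' @return Accuracy in percent.
#' @export
eq2_accuracy <- function(recall, far) (recall + (100 - far)) / 2

#' Reference detection-performance tables
#'
#' Per-subject offline classification and online detection performance of an
#' eight-operator emergency-detection study, used as arithmetic reference
#' values (accuracy must equal `eq2_accuracy(recall, far)` to printed
#' precision) and as the benchmark context for the synthetic experiments.
#'
#' @param which `"offline"` or `"online"`.
#' @return Data frame with subject, accuracy, recall, far (and
#'   `response_time_ms` for the online table), percentages as printed.
#' @export
reference_performance <- function(which = c("offline", "online")) {
  which <- match.arg(which)
  f <- system.file("extdata", paste0(which, "_performance.csv"),
                   package = "emergeeg")
  if (f == "") f <- file.path("inst", "extdata",
                              paste0(which, "_performance.csv"))
  utils::read.csv(f, stringsAsFactors = FALSE)
}

#' Recompute the reference tables' accuracy arithmetic
#'
#' Recomputes each row's accuracy from its (recall, FAR) pair and the column
#' means, and compares them with the printed values at printed precision.
#' Per-row comparisons allow 0.015 (the printed recall/FAR are themselves
#' rounded to two decimals, which can move the recomputed accuracy by up to
#' one unit in the last printed digit); column means are exact to rounding.
#'
#' @return Data frame of checks with columns `check`, `expected`,
#'   `recomputed`, `pass`.
#' @export
check_reference_arithmetic <- function() {
  rows <- list()
  add <- function(check, expected, recomputed, tol)
    rows[[length(rows) + 1]] <<- data.frame(
      check = check, expected = expected, recomputed = recomputed,
      pass = abs(expected - recomputed) <= tol + 1e-9)
  for (which in c("offline", "online")) {
    tab <- reference_performance(which)
    for (i in seq_len(nrow(tab)))
      add(sprintf("%s subject %s accuracy", which, tab$subject[i]),
          tab$accuracy[i], eq2_accuracy(tab$recall[i], tab$far[i]), 0.015)
    add(sprintf("%s mean accuracy", which),
        if (which == "offline") 74.29 else 88.81,
        round(mean(tab$accuracy), 2), 0.005)
    add(sprintf("%s mean recall", which),
        if (which == "offline") 73.34 else 90.31,
        round(mean(tab$recall), 2), 0.005)
  }
  do.call(rbind, rows)
}
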