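## Data-flow audit: every model fit performed by the prediction
## orchestrators can be logged with the test-line phenotype cells that
## entered it, so leakage (a test-line phenotype at a predicted time point
## inside a fit) is checkable rather than assumed. Only the documented
## allowances — the initial state / designated secondary time point — may
## expose test-line cells.

the_audit <- new.env(parent = emptyenv())
the_audit$active <- FALSE
the_audit$log <- list()

#' Audit the data flow of prediction runs
#'
#' `audit_start()` begins recording one entry per model fit executed by the
#' `run_*` orchestrators; `audit_stop()` ends recording and returns the
#' log; [audit_leakage()] checks a log for test-line phenotype cells at
#' predicted time points that entered any fit outside the documented
#' secondary-trait allowances.
#'
#' @return `audit_start()` nothing; `audit_stop()` the log invisibly.
#' @export
audit_start <- function() {
  the_audit$log <- list()
  the_audit$active <- TRUE
  invisible(NULL)
}

#' @rdname audit_start
#' @export
audit_stop <- function() {
  the_audit$active <- FALSE
  invisible(the_audit$log)
}

audit_active <- function() isTRUE(the_audit$active)

# Record one model fit (internal). `entered_test_cells` is a data.frame
# with columns line, time (time-point indices) of test-line phenotype cells
# used by the fit; `allowed_times` are the time indices at which test-line
# cells are a documented allowance for this fit.
audit_record <- function(scenario, iteration, fold, model_id, test_lines,
                         predicted_times, entered_test_cells = NULL,
                         allowed_times = integer(0)) {
  if (!audit_active()) return(invisible(NULL))
  if (is.null(entered_test_cells)) {
    entered_test_cells <- data.frame(line = character(0), time = integer(0))
  }
  the_audit$log[[length(the_audit$log) + 1L]] <- list(
    scenario = scenario, iteration = iteration, fold = fold,
    model_id = model_id, test_lines = test_lines,
    predicted_times = predicted_times,
    entered_test_cells = entered_test_cells,
    allowed_times = allowed_times
  )
  invisible(NULL)
}

#' @param log an audit log (default: the one collected since
#'   [audit_start()]).
#' @return `audit_leakage()`: data.frame of violations (scenario, model,
#'   line, time); zero rows means no leakage.
#' @rdname audit_start
#' @export
audit_leakage <- function(log = the_audit$log) {
  out <- lapply(log, function(e) {
    cells <- e$entered_test_cells
    if (!nrow(cells)) return(NULL)
    bad <- cells$line %in% e$test_lines &
      cells$time %in% e$predicted_times &
      !(cells$time %in% e$allowed_times)
    if (!any(bad)) return(NULL)
    data.frame(scenario = e$scenario, model_id = e$model_id,
               iteration = e$iteration, fold = e$fold,
               line = cells$line[bad], time = cells$time[bad])
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(scenario = character(0), model_id = character(0),
                      iteration = integer(0), fold = integer(0),
                      line = character(0), time = integer(0))
  }
  out
}
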