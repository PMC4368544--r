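#' Read a trial-level consumption table
#'
#' Canonical interchange layout: one row per subject with columns
#' `subject_id`, optionally `excluded` (logical; pilot subjects without the
#' on-screen mean-relief display), and `trial_1..trial_T` holding raw
#' consumption in milligrams.  CSV is the canonical format; `.xlsx` files are
#' accepted when the readxl package is available.  Validation is strict:
#' wrong column counts, non-numeric cells and out-of-range milligram values
#' raise errors naming the offending row/column.
#'
#' @param file Path to a `.csv` or `.xlsx` file.
#' @param cfg A [task_config()].
#' @return A data.frame of class `consumption_table` with columns
#'   `subject_id`, `excluded`, `trial_1..trial_T`.
#' @export
read_consumption_table <- function(file, cfg = task_config()) {
  if (grepl("\\.xlsx?$", file, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading .xlsx requires the readxl package; convert to CSV")
    }
    tab <- as.data.frame(readxl::read_excel(file))
  } else {
    tab <- read.csv(file, check.names = TRUE)
  }
  if (!"subject_id" %in% names(tab)) stop("missing subject_id column")
  if (!"excluded" %in% names(tab)) tab$excluded <- FALSE
  tab$excluded <- as.logical(tab$excluded)
  trial_cols <- grep("^trial_", names(tab), value = TRUE)
  if (length(trial_cols) != cfg$n_trials) {
    stop("expected ", cfg$n_trials, " trial columns, found ",
         length(trial_cols))
  }
  trial_cols <- paste0("trial_", seq_len(cfg$n_trials))
  if (!all(trial_cols %in% names(tab))) stop("trial columns not contiguous 1..T")
  cap_mg <- cfg$max_per_trial_units * cfg$unit_mg
  for (j in trial_cols) {
    v <- tab[[j]]
    if (!is.numeric(v)) stop("non-numeric consumption in column ", j)
    bad <- which(is.na(v) | v < 0 | v > cap_mg)
    if (length(bad)) {
      stop("consumption out of range [0, ", cap_mg, "] mg in column ", j,
           ", row ", bad[1], " (subject ", tab$subject_id[bad[1]], ")")
    }
  }
  out <- tab[c("subject_id", "excluded", trial_cols)]
  class(out) <- c("consumption_table", "data.frame")
  out
}

#' @rdname read_consumption_table
#' @param tab A `consumption_table` (or compatible data.frame / cohort
#'   `table`).
#' @export
write_consumption_table <- function(tab, file) {
  write.csv(tab, file, row.names = FALSE)
  invisible(file)
}

#' Milligram matrix and rounded paths from a consumption table
#'
#' @param tab A `consumption_table`.
#' @param include_excluded Keep subjects flagged as excluded?
#' @param cfg A [task_config()].
#' @return `consumption_matrix`: subjects x trials matrix of mg with subject
#'   ids as rownames. `consumption_paths`: list of [round_and_correct()]ed
#'   [consumption_path()]s.
#' @export
consumption_matrix <- function(tab, include_excluded = FALSE,
                               cfg = task_config()) {
  keep <- if (include_excluded) rep(TRUE, nrow(tab)) else !tab$excluded
  m <- as.matrix(tab[keep, paste0("trial_", seq_len(cfg$n_trials))])
  rownames(m) <- tab$subject_id[keep]
  dimnames(m)[[2]] <- NULL
  m
}

#' @rdname consumption_matrix
#' @export
consumption_paths <- function(tab, include_excluded = FALSE,
                              cfg = task_config()) {
  m <- consumption_matrix(tab, include_excluded, cfg)
  lapply(seq_len(nrow(m)), function(i) {
    round_and_correct(m[i, ], cfg, subject_id = rownames(m)[i])
  })
}

#' Read a table of anticipation-discounting estimates
#'
#' Per-subject, per-frame parameters from one-off binary intertemporal
#' choices: `alpha`, `gamma_p` (pain discounting) and `gamma_d` (dread
#' discounting), plus the sooner-choice frequency.  The column layout is
#' configurable through `column_map` for externally produced spreadsheets.
#' Subjects with missing (non-estimable) parameters are retained with `NA`
#' values; [lookup_discount()] reports them as unavailable rather than
#' erroring.
#'
#' @param file Path to a `.csv` or `.xlsx` file.
#' @param column_map Named character vector mapping canonical names
#'   (`subject_id`, `frame`, `alpha`, `gamma_p`, `gamma_d`, `sooner_freq`)
#'   to the file's column names.
#' @return A data.frame of class `discount_table`.
#' @export
read_discount_table <- function(file, column_map = NULL) {
  if (grepl("\\.xlsx?$", file, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading .xlsx requires the readxl package; convert to CSV")
    }
    tab <- as.data.frame(readxl::read_excel(file))
  } else {
    tab <- read.csv(file)
  }
  canon <- c("subject_id", "frame", "alpha", "gamma_p", "gamma_d",
             "sooner_freq")
  if (!is.null(column_map)) {
    for (nm in names(column_map)) {
      names(tab)[names(tab) == column_map[[nm]]] <- nm
    }
  }
  missing_cols <- setdiff(canon, names(tab))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  tab <- tab[canon]
  if (!all(tab$frame %in% c("pain", "relief"))) {
    stop("frame must be 'pain' or 'relief'")
  }
  ok <- !is.na(tab$alpha)
  if (any(tab$alpha[ok] < 0) ||
      any(tab$gamma_p[ok] <= 0 | tab$gamma_p[ok] > 1) ||
      any(tab$gamma_d[ok] <= 0 | tab$gamma_d[ok] > 1)) {
    stop("discount parameters outside valid ranges")
  }
  if (any(!is.na(tab$sooner_freq) &
          (tab$sooner_freq < 0 | tab$sooner_freq > 1))) {
    stop("sooner_freq must lie in [0, 1]")
  }
  class(tab) <- c("discount_table", "data.frame")
  tab
}

#' @rdname read_discount_table
#' @param tab A `discount_table`.
#' @export
write_discount_table <- function(tab, file) {
  write.csv(tab, file, row.names = FALSE)
  invisible(file)
}

#' Look up one subject's discounting parameters
#'
#' Maps the binary-choice estimates onto the consumption model's discount
#' parameters: `gamma_c = gamma_p` (discounting of relief equated with
#' discounting of pain) and `gamma_a = gamma_d`.  The `relief` frame is the
#' default, matching the frame of the consumption task.
#'
#' @param tab A `discount_table`.
#' @param subject_id Subject to look up.
#' @param frame `"relief"` (default) or `"pain"`.
#' @return A [discount_params()], or `NULL` if the subject is absent or the
#'   parameters were not estimable.
#' @export
lookup_discount <- function(tab, subject_id, frame = c("relief", "pain")) {
  frame <- match.arg(frame)
  row <- tab[tab$subject_id == subject_id & tab$frame == frame, ]
  if (nrow(row) == 0 || is.na(row$alpha[1])) return(NULL)
  discount_params(alpha = row$alpha[1], gamma_c = row$gamma_p[1],
                  gamma_a = row$gamma_d[1])
}

#' Write fit results and a group summary
#'
#' @param fits A list of `fit_result`s.
#' @param file Output path (CSV for fits, JSON for the summary).
#' @return The path, invisibly.
#' @export
write_fit_results <- function(fits, file) {
  write.csv(fits_as_data_frame(fits), file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_fit_results
#' @param summaries Named list of [group_bic()] results (one per model).
#' @export
write_group_summary <- function(summaries, file) {
  jsonlite::write_json(summaries, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
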