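#' Trial dataset container
#'
#' Pairs a long-format longitudinal table (square-root CD4 by visit) with a
#' one-row-per-subject survival table, validated together. All times are in
#' months.
#'
#' @param longitudinal data.frame with columns `subject_id`, `time`
#'   (months since randomisation) and `y` (square-root CD4, cells^0.5/mm^1.5).
#' @param survival data.frame with columns `subject_id`, `time` (event or
#'   censoring time, months), `event` (1 = died, 0 = censored), `arm`
#'   (1 = combined integrated therapy), `age` (years) and `gender`
#'   (1 = women).
#' @param meta optional list of metadata (e.g. `t_max`, generating
#'   parameters, seed); `t_max` defaults to the maximum survival time.
#' @return object of class `trial_dataset`.
#' @export
trial_dataset <- function(longitudinal, survival, meta = list()) {
  need_l <- c("subject_id", "time", "y")
  need_s <- c("subject_id", "time", "event", "arm", "age", "gender")
  miss_l <- setdiff(need_l, names(longitudinal))
  miss_s <- setdiff(need_s, names(survival))
  if (length(miss_l)) stop("longitudinal table missing columns: ",
                           paste(miss_l, collapse = ", "))
  if (length(miss_s)) stop("survival table missing columns: ",
                           paste(miss_s, collapse = ", "))
  longitudinal <- as.data.frame(longitudinal)[need_l]
  survival <- as.data.frame(survival)[need_s]
  if (anyDuplicated(survival$subject_id))
    stop("duplicated subject ids in the survival table")
  only_l <- setdiff(longitudinal$subject_id, survival$subject_id)
  only_s <- setdiff(survival$subject_id, longitudinal$subject_id)
  if (length(only_l)) stop("subjects only in the longitudinal table: ",
                           paste(utils::head(only_l, 5L), collapse = ", "))
  if (length(only_s)) stop("subjects with no measurements: ",
                           paste(utils::head(only_s, 5L), collapse = ", "))
  if (any(!is.finite(longitudinal$y)))
    stop("non-finite longitudinal measurements")
  if (any(survival$time < 0)) stop("negative survival times")
  if (!all(survival$event %in% c(0, 1))) stop("event must be 0/1")
  Tmap <- survival$time[match(longitudinal$subject_id, survival$subject_id)]
  late <- longitudinal$time > Tmap + 1e-8
  if (any(late))
    stop("measurements after the event/censoring time for subjects: ",
         paste(unique(utils::head(longitudinal$subject_id[late], 5L)),
               collapse = ", "))
  if (is.null(meta$t_max)) meta$t_max <- max(survival$time)
  structure(list(longitudinal = longitudinal, survival = survival,
                 meta = meta), class = "trial_dataset")
}

#' @export
print.trial_dataset <- function(x, ...) {
  cat("Trial dataset: ", nrow(x$survival), " subjects, ",
      nrow(x$longitudinal), " CD4 measurements\n",
      "  deaths: ", sum(x$survival$event), " (",
      round(100 * mean(x$survival$event), 1), "%), follow-up <= ",
      round(max(x$survival$time), 1), " months\n", sep = "")
  invisible(x)
}

#' Read and write trial datasets as CSV
#'
#' `read_trial_dataset()` parses the two CSV files and validates every
#' dataset invariant; with `sqrt_transform = TRUE` the longitudinal response
#' column is taken to be raw CD4 counts and is square-root transformed on
#' read. `write_trial_dataset()` writes the paired tables (and metadata as
#' JSON-like dput text).
#'
#' @param long_path,surv_path CSV paths. The longitudinal file needs columns
#'   `subject_id,time_months,sqrt_cd4` (or `cd4` with `sqrt_transform`);
#'   the survival file `subject_id,time_months,event,arm,age,gender`.
#' @param sqrt_transform if `TRUE`, apply `sqrt()` to the response on read.
#' @return a [trial_dataset()].
#' @export
read_trial_dataset <- function(long_path, surv_path, sqrt_transform = FALSE) {
  long <- utils::read.csv(long_path)
  surv <- utils::read.csv(surv_path)
  ycol <- if (sqrt_transform) {
    if (!"cd4" %in% names(long)) stop("sqrt_transform needs a 'cd4' column")
    sqrt(long$cd4)
  } else {
    if (!"sqrt_cd4" %in% names(long)) stop("expected a 'sqrt_cd4' column")
    long$sqrt_cd4
  }
  if (!"time_months" %in% names(long) || !"time_months" %in% names(surv))
    stop("both files need a 'time_months' column")
  trial_dataset(
    data.frame(subject_id = long$subject_id, time = long$time_months,
               y = ycol),
    data.frame(subject_id = surv$subject_id, time = surv$time_months,
               event = surv$event, arm = surv$arm, age = surv$age,
               gender = surv$gender)
  )
}

#' @rdname read_trial_dataset
#' @param dataset a [trial_dataset()].
#' @param dir output directory (created if needed); writes `long.csv`,
#'   `surv.csv` and `meta.txt`.
#' @export
write_trial_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "trial_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  long <- data.frame(subject_id = dataset$longitudinal$subject_id,
                     time_months = dataset$longitudinal$time,
                     sqrt_cd4 = dataset$longitudinal$y)
  surv <- data.frame(subject_id = dataset$survival$subject_id,
                     time_months = dataset$survival$time,
                     event = dataset$survival$event,
                     arm = dataset$survival$arm,
                     age = dataset$survival$age,
                     gender = dataset$survival$gender)
  utils::write.csv(long, file.path(dir, "long.csv"), row.names = FALSE)
  utils::write.csv(surv, file.path(dir, "surv.csv"), row.names = FALSE)
  dput(dataset$meta, file.path(dir, "meta.txt"))
  invisible(file.path(dir, c("long.csv", "surv.csv", "meta.txt")))
}

# cheap content fingerprint used to refuse comparing fits on different data
.dataset_fingerprint <- function(dataset) {
  s <- dataset$survival; l <- dataset$longitudinal
  paste(nrow(s), nrow(l),
        format(sum(s$time) + sum(s$event) + sum(l$y) + sum(l$time),
               digits = 15),
        sep = "|")
}
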