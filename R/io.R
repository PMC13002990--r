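#' Read or write observation tables as CSV
#'
#' The CSV schema is `study_id, experiment_id, observable, time_min, value,
#' sem, n`. Reading validates the header, observable names, numeric fields
#' and SEM positivity, reporting offending row numbers. The write/read round
#' trip is lossless.
#'
#' @param path CSV path.
#' @param experiments optional named list of `list(schedule, anthro)` keyed by
#'   experiment id; when supplied a full [markerDataset()] is returned,
#'   otherwise the validated observation table.
#' @return `readDataset()`: a [markerDataset()] or a data.frame of
#'   observations.
#' @export
readDataset <- function(path, experiments = NULL) {
  obs <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("study_id", "experiment_id", "observable", "time_min", "value", "sem")
  miss <- setdiff(req, names(obs))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (!"n" %in% names(obs)) obs$n <- NA_real_
  for (col in c("time_min", "value", "sem")) {
    v <- suppressWarnings(as.numeric(obs[[col]]))
    bad <- which(is.na(v) & !is.na(obs[[col]]))
    if (length(bad)) stop("malformed numbers in column '", col, "', row(s) ",
                          paste(bad, collapse = ", "))
    obs[[col]] <- v
  }
  bad <- which(!obs$observable %in% observableNames())
  if (length(bad)) stop("unknown observable in row(s) ",
                        paste(bad, collapse = ", "),
                        "; allowed: ", paste(observableNames(), collapse = ", "))
  bad <- which(!is.finite(obs$sem) | obs$sem <= 0)
  if (length(bad)) stop("non-positive SEM in row(s) ", paste(bad, collapse = ", "))
  if (is.null(experiments)) return(obs)
  markerDataset(obs, experiments)
}

#' @rdname readDataset
#' @param dataset a [markerDataset()] or an observation data.frame.
#' @export
writeDataset <- function(dataset, path) {
  obs <- if (inherits(dataset, "markerDataset")) dataset$observations else dataset
  utils::write.csv(obs, path, row.names = FALSE)
  invisible(path)
}

#' Read or write a subject description as JSON
#'
#' Subject files use the model's input naming: `sex` (1 = male, 0 = female,
#' or the words), `weight` (kg), `height` (m), `age` (years).
#'
#' @param path JSON path.
#' @param anthro an [anthropometrics()] object.
#' @return `readSubject()` returns an [anthropometrics()] object.
#' @export
readSubject <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sex <- x$sex
  if (is.numeric(sex)) sex <- if (sex == 1) "male" else "female"
  anthropometrics(sex, x$weight, x$height, x$age)
}

#' @rdname readSubject
#' @export
writeSubject <- function(anthro, path) {
  jsonlite::write_json(
    list(sex = if (anthro$sex == "male") 1 else 0, weight = anthro$weight,
         height = anthro$height, age = anthro$age),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
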