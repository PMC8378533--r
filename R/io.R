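#' Read and write the cohort and panel tables as CSV
#'
#' Plain-text interchange for the two core tables. The cohort CSV has
#' columns `person_id, sex, start_age_c, smoker, srh, event, time`; the
#' panel CSV has `person_id, occasion, age_c, domain, score`; the latent
#' (truth) CSV has `person_id, domain, u0, u1`.
#'
#' @param x Data frame to write.
#' @param path File path.
#' @return Writers return `path` invisibly; readers return a data.frame.
#' @export
write_cohort_csv <- function(x, path) {
  need <- c("person_id", "sex", "start_age_c", "smoker", "srh", "event",
            "time")
  stopifnot(all(need %in% names(x)))
  utils::write.csv(x[need], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("person_id", "sex", "start_age_c", "smoker", "srh", "event",
            "time")
  if (!all(need %in% names(x)))
    stop("cohort CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  x
}

#' @rdname write_cohort_csv
#' @export
write_panel_csv <- function(x, path) {
  need <- c("person_id", "occasion", "age_c", "domain", "score")
  stopifnot(all(need %in% names(x)))
  utils::write.csv(x[need], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_panel_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("person_id", "occasion", "age_c", "domain", "score")
  if (!all(need %in% names(x)))
    stop("panel CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  x
}

#' @rdname write_cohort_csv
#' @export
write_latent_csv <- function(x, path) {
  need <- c("person_id", "domain", "u0", "u1")
  stopifnot(all(need %in% names(x)))
  utils::write.csv(x[need], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
write_scores_csv <- function(x, path) {
  stopifnot(all(c("person_id", "u0_hat") %in% names(x)))
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Write a posterior summary to JSON or CSV
#'
#' @param summary A [posterior_summary()] (or a fit, whose summary is used).
#' @param path Output path; format chosen by extension (`.json` or `.csv`).
#' @return `path`, invisibly.
#' @export
write_posterior <- function(summary, path) {
  s <- get_summary(summary)
  if (grepl("\\.json$", path))
    jsonlite::write_json(as.data.frame(s), path, auto_unbox = TRUE,
                         digits = NA)
  else utils::write.csv(as.data.frame(s), path, row.names = FALSE)
  invisible(path)
}
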