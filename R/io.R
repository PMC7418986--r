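#' Read an age-at-harvest CSV
#'
#' Expects columns `year, sex, age, count`; validates sexes, non-negative
#' counts, the 0-30 age range, key uniqueness, and that the year span has no
#' gaps.
#'
#' @param path CSV file path.
#' @return Validated data frame `(year, sex, age, count)`.
#' @export
read_age_harvest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_columns(df, c("year", "sex", "age", "count"), path)
  .validate_age_harvest(df, allow_fractional = TRUE)
  span <- sort(unique(df$year))
  gaps <- setdiff(seq(span[1], span[length(span)]), span)
  if (length(gaps) > 0) {
    stop("harvest file ", path, ": no records for year ", gaps[1])
  }
  df
}

#' Read the yearly complaints/kills CSV
#'
#' Expects columns `year, complaints_onsite, complaints_phone,
#' nuisance_kills`; `complaints_phone` may be `NA` in masked years.
#'
#' @param path CSV file path.
#' @return Validated data frame.
#' @export
read_yearly <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_columns(df, c("year", "complaints_onsite", "complaints_phone",
                         "nuisance_kills"), path)
  for (col in c("complaints_onsite", "nuisance_kills")) {
    bad <- which(is.na(df[[col]]) | df[[col]] < 0)
    if (length(bad) > 0) {
      stop(path, ": invalid ", col, " in row ", bad[1])
    }
  }
  bad <- which(!is.na(df$complaints_phone) & df$complaints_phone < 0)
  if (length(bad) > 0) stop(path, ": negative phone count in row ", bad[1])
  if (anyDuplicated(df$year)) stop(path, ": duplicate year")
  df[order(df$year), ]
}

#' Read the food-survey CSV
#'
#' Expects columns `year, species, respondent, abundance, production` with
#' integer 0-4 scores.
#'
#' @param path CSV file path.
#' @return Validated data frame.
#' @export
read_food_survey <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_columns(df, c("year", "species", "respondent", "abundance",
                         "production"), path)
  .validate_food_survey(df)
  df
}

#' Read a study-data workbook (XLSX)
#'
#' Reads one sheet per table from an XLSX deposit. Sheet names are supplied
#' through `mapping` since deposit layouts vary; each sheet must carry the
#' same columns as the corresponding CSV reader expects.
#'
#' @param path XLSX file path.
#' @param mapping Named list with elements `age_harvest`, `yearly`,
#'   `food_survey` giving the sheet name (or index) for each table; omit an
#'   element to skip that table.
#' @return Named list of validated data frames.
#' @export
read_study_workbook <- function(path,
                                mapping = list(age_harvest = "age_harvest",
                                               yearly = "yearly",
                                               food_survey = "food_survey")) {
  if (!requireNamespace("readxl", quietly = TRUE)) {
    stop("reading XLSX requires the readxl package")
  }
  out <- list()
  if (!is.null(mapping$age_harvest)) {
    df <- as.data.frame(readxl::read_excel(path, sheet = mapping$age_harvest))
    .require_columns(df, c("year", "sex", "age", "count"), path)
    .validate_age_harvest(df, allow_fractional = TRUE)
    out$age_harvest <- df
  }
  if (!is.null(mapping$yearly)) {
    df <- as.data.frame(readxl::read_excel(path, sheet = mapping$yearly))
    .require_columns(df, c("year", "complaints_onsite", "complaints_phone",
                           "nuisance_kills"), path)
    out$yearly <- df
  }
  if (!is.null(mapping$food_survey)) {
    df <- as.data.frame(readxl::read_excel(path, sheet = mapping$food_survey))
    .validate_food_survey(df)
    out$food_survey <- df
  }
  out
}

#' Write the simulated/observed tables as CSVs
#'
#' @param observed An `observed_data` object.
#' @param dir Output directory (created if absent).
#' @param truth Optional `sim_truth`; if given, individual fates are written
#'   to `truth.csv`.
#' @return Invisibly, the paths written.
#' @export
write_observed <- function(observed, dir, truth = NULL) {
  stopifnot(inherits(observed, "observed_data"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(age_harvest = file.path(dir, "age_harvest.csv"),
             yearly = file.path(dir, "yearly.csv"),
             food_survey = file.path(dir, "food_survey.csv"))
  utils::write.csv(observed$age_harvest, paths["age_harvest"],
                   row.names = FALSE)
  utils::write.csv(observed$yearly, paths["yearly"], row.names = FALSE)
  utils::write.csv(observed$food_survey, paths["food_survey"],
                   row.names = FALSE)
  if (!is.null(truth)) {
    paths <- c(paths, truth = file.path(dir, "truth.csv"))
    utils::write.csv(truth$individuals, paths["truth"], row.names = FALSE)
  }
  invisible(paths)
}

.require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  extra <- setdiff(names(df), cols)
  if (length(missing) > 0) {
    stop(path, ": missing column(s) ", paste(missing, collapse = ", "),
         if (length(extra) > 0)
           paste0("; unexpected column(s) ", paste(extra, collapse = ", ")))
  }
  invisible(df)
}
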