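#' Read a battery configuration from YAML or JSON
#'
#' The config document has a `battery` name, a `bands` block with
#' `pass_max` and `borderline_max`, an optional `missing_policy`, and a
#' `components` list whose entries carry `name`, `direction`, `cuts` (three
#' numbers, increasing severity), `valid_range`, and optional `units` /
#' `granularity`. The packaged default (`system.file("extdata",
#' "ei5_battery.yaml", package = "eindex")`) is the standard EI-5 battery.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file, or the string
#'   `"default"` for the packaged EI-5 config.
#' @return A validated [battery_config()].
#' @export
read_battery_config <- function(path) {
  if (identical(path, "default"))
    path <- system.file("extdata", "ei5_battery.yaml", package = "eindex")
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  else yaml::read_yaml(path)
  battery_from_list(doc)
}

battery_from_list <- function(doc) {
  if (is.null(doc$components) || !length(doc$components))
    stop("config has no components", call. = FALSE)
  comps <- lapply(doc$components, function(cm) {
    for (fld in c("name", "direction", "cuts", "valid_range"))
      if (is.null(cm[[fld]]))
        stop(sprintf("component '%s': missing field '%s'",
                     if (is.null(cm$name)) "<unnamed>" else cm$name, fld),
             call. = FALSE)
    component_spec(cm$name, cm$direction, unlist(cm$cuts),
                   unlist(cm$valid_range),
                   units = if (is.null(cm$units)) "raw" else cm$units,
                   granularity = cm$granularity)
  })
  bands <- doc$bands
  if (is.null(bands$pass_max) || is.null(bands$borderline_max))
    stop("config must declare bands$pass_max and bands$borderline_max",
         call. = FALSE)
  battery_config(comps, pass_max = bands$pass_max,
                 borderline_max = bands$borderline_max,
                 name = if (is.null(doc$battery)) "battery" else doc$battery,
                 missing_policy = if (is.null(doc$missing_policy)) "error"
                                  else doc$missing_policy)
}

#' Write a battery configuration to YAML or JSON
#'
#' Inverse of [read_battery_config()]: the round trip reproduces identical
#' recoding.
#'
#' @param battery A [battery_config()].
#' @param path Output path; format chosen by extension (`.json` vs YAML).
#' @return `path`, invisibly.
#' @export
write_battery_config <- function(battery, path) {
  stopifnot(inherits(battery, "battery_config"))
  doc <- list(
    battery = battery$name,
    bands = list(pass_max = battery$pass_max,
                 borderline_max = battery$borderline_max),
    missing_policy = battery$missing_policy,
    components = lapply(unname(battery$components), function(s) {
      out <- list(name = s$name, direction = s$direction, cuts = s$cuts,
                  valid_range = s$valid_range, units = s$units)
      if (!is.null(s$granularity)) out$granularity <- s$granularity
      out
    }))
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(doc, path)
  invisible(path)
}

#' Read a cohort CSV
#'
#' Reads an examinee-per-row table. Component and criterion columns can be
#' renamed via `column_map` (names = canonical, values = file columns);
#' unknown columns are kept as covariates. `0/1` criterion flag columns are
#' coerced to logical; percent columns may carry a `%` suffix, which is
#' stripped. Missing scores pass through as `NA` — the battery's
#' `missing_policy` decides their fate at scoring time, not at read time.
#'
#' @param path CSV path with a header row.
#' @param column_map Optional named character vector renaming file columns
#'   to canonical names.
#' @return Data frame.
#' @export
read_cohort_csv <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(column_map)) {
    absent <- setdiff(unname(column_map), names(df))
    if (length(absent))
      stop("mapped column(s) not in file: ", paste(absent, collapse = ", "),
           call. = FALSE)
    for (canon in names(column_map))
      names(df)[names(df) == column_map[[canon]]] <- canon
  }
  for (cn in grep("_fail$", names(df), value = TRUE))
    df[[cn]] <- as.logical(df[[cn]])
  for (cn in intersect(c("wmt_ir", "wmt_dr", "wmt_cns"), names(df)))
    if (is.character(df[[cn]]))
      df[[cn]] <- as.numeric(sub("%$", "", trimws(df[[cn]])))
  df
}

#' Write a scored cohort to CSV
#'
#' @param scored Output of [score_cohort()].
#' @param path Destination CSV.
#' @return `path`, invisibly.
#' @export
write_scored_cohort <- function(scored, path) {
  utils::write.csv(scored, path, row.names = FALSE)
  invisible(path)
}
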