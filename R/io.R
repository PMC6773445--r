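#' Write and read cohorts as tidy CSV
#'
#' Cohorts are stored long: one row per embryo, time point and quantity,
#' with a nullable `region` column for regional wall thickness. Regional
#' thickness columns `h_medial`/`h_lateral`/`h_poles` map to quantity `h`
#' with `region` set; all other quantities have an empty region.
#'
#' @param cohort A `morpho_cohort` tibble.
#' @param path File path.
#' @return `write_cohort_csv()` returns `path` invisibly;
#'   `read_cohort_csv()` returns a `morpho_cohort` tibble.
#' @export
write_cohort_csv <- function(cohort, path) {
  long <- cohort_to_long(cohort)
  utils::write.csv(long, path, row.names = FALSE, na = "")
  invisible(path)
}

cohort_to_long <- function(cohort) {
  check_columns(cohort, c("embryo_id", "t"), "cohort")
  id_cols <- intersect(c("embryo_id", "side", "t"), names(cohort))
  long <- tidyr::pivot_longer(
    tibble::as_tibble(cohort),
    cols = -dplyr::all_of(id_cols),
    names_to = "quantity", values_to = "value"
  )
  long$region <- ifelse(
    grepl("^h_", long$quantity), sub("^h_", "", long$quantity), NA_character_
  )
  long$quantity <- ifelse(grepl("^h_", long$quantity), "h", long$quantity)
  names(long)[names(long) == "t"] <- "t_hpf"
  long
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(long, c("embryo_id", "t_hpf", "quantity", "value"), "cohort csv")
  long$quantity <- ifelse(
    long$quantity == "h" & !is.na(long$region) & long$region != "",
    paste0("h_", long$region), long$quantity
  )
  id_cols <- intersect(c("embryo_id", "side", "t_hpf"), names(long))
  wide <- tidyr::pivot_wider(
    tibble::as_tibble(long[, c(id_cols, "quantity", "value")]),
    names_from = "quantity", values_from = "value"
  )
  names(wide)[names(wide) == "t_hpf"] <- "t"
  new_morpho_cohort(wide)
}

#' Write an event log as JSON lines
#'
#' One JSON object per line with fields `t`, `kind` and `params`.
#'
#' @param events Tibble with columns `t`, `kind`, `params` (list column).
#' @param path File path.
#' @export
write_events_json <- function(events, path) {
  lines <- purrr::pmap_chr(events, function(t, kind, params, ...) {
    jsonlite::toJSON(list(t = t, kind = kind, params = params), auto_unbox = TRUE)
  })
  writeLines(lines, path)
  invisible(path)
}
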