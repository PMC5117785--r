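#' Table containers for the audit analysis
#'
#' Four light S3 containers (classed data.frames) carry the aggregate inputs:
#' \describe{
#'   \item{case_count_table}{cases by age band x stage x screening category;
#'     counts may be fractional (percent-derived and after reallocation).
#'     Unknown-stage rows carry \code{stage = "unknown"} and \code{category = NA}.}
#'   \item{or_table}{odds ratios vs the never-screened referent, with 95\% CI
#'     and the standard error of the log OR; referent rows are exactly 1.}
#'   \item{fatality_table}{\eqn{\rho} = 1 - 5-year relative survival, in [0,1],
#'     by age band x stage.}
#'   \item{observed_deaths}{annual observed deaths by age-at-death band plus an
#'     \code{all_ages} row.}
#' }
#'
#' @param x a data.frame with the columns listed under each constructor
#' @return the validated, classed data.frame
#' @name tables
NULL

stop_missing_cols <- function(x, cols, what) {
  miss <- setdiff(cols, names(x))
  if (length(miss))
    stop(what, ": missing column(s) ", paste(miss, collapse = ", "))
}

#' @rdname tables
#' @details \code{case_count_table}: columns \code{age_band}, \code{stage},
#'   \code{category}, \code{count} (non-negative).
#' @export
case_count_table <- function(x) {
  stop_missing_cols(x, c("age_band", "stage", "category", "count"),
                    "case_count_table")
  x$count <- as.numeric(x$count)
  bad <- !(x$stage %in% stage_levels(include_unknown = TRUE))
  if (any(bad)) stop("case_count_table: unknown stage code ",
                     paste(unique(x$stage[bad]), collapse = ", "))
  bad <- !is.na(x$category) & !(x$category %in% category_levels())
  if (any(bad)) stop("case_count_table: unknown category ",
                     paste(unique(x$category[bad]), collapse = ", "))
  if (any(x$count < 0)) stop("case_count_table: negative count")
  structure(as.data.frame(x), class = c("case_count_table", "data.frame"))
}

#' @rdname tables
#' @details \code{or_table}: columns \code{age_band}, \code{stage},
#'   \code{category}, \code{or}, \code{lo}, \code{hi}, \code{se_log}. Referent
#'   (\code{not_screened}) rows must have \code{or = 1} exactly; elsewhere
#'   \code{lo <= or <= hi}.
#' @export
or_table <- function(x) {
  stop_missing_cols(x, c("age_band", "stage", "category", "or", "lo", "hi",
                         "se_log"), "or_table")
  ref <- x$category == "not_screened"
  if (any(x$or[ref] != 1)) stop("or_table: referent odds ratios must equal 1")
  if (any(x$or <= 0, na.rm = TRUE)) stop("or_table: odds ratios must be positive")
  ok <- is.na(x$lo) | is.na(x$hi) | (x$lo <= x$or + 1e-9 & x$or <= x$hi + 1e-9)
  if (!all(ok)) stop("or_table: interval does not bracket the estimate")
  structure(as.data.frame(x), class = c("or_table", "data.frame"))
}

#' @rdname tables
#' @details \code{fatality_table}: columns \code{age_band}, \code{stage},
#'   \code{rho} in [0, 1] (relative survival above 100\% is clipped to
#'   \code{rho = 0} upstream).
#' @export
fatality_table <- function(x) {
  stop_missing_cols(x, c("age_band", "stage", "rho"), "fatality_table")
  x$rho <- as.numeric(x$rho)
  if (any(x$rho < 0 | x$rho > 1)) stop("fatality_table: rho outside [0, 1]")
  structure(as.data.frame(x), class = c("fatality_table", "data.frame"))
}

#' @rdname tables
#' @details \code{observed_deaths}: columns \code{death_band}, \code{deaths}
#'   and optionally \code{role} (\code{"band"}, \code{"covered"} for a printed
#'   subtotal of the covered bands, \code{"total"}). Without a \code{role}
#'   column, \code{all_ages} is the total and everything else a band. The
#'   total must be at least the sum of the bands.
#' @export
observed_deaths <- function(x) {
  stop_missing_cols(x, c("death_band", "deaths"), "observed_deaths")
  if (is.null(x$role))
    x$role <- ifelse(x$death_band == "all_ages", "total", "band")
  if (sum(x$role == "total") != 1)
    stop("observed_deaths: exactly one total (all_ages) row required")
  tot <- x$deaths[x$role == "total"]
  if (tot < sum(x$deaths[x$role == "band"]) - 1e-9)
    stop("observed_deaths: all-ages total below the sum of the listed bands")
  structure(as.data.frame(x), class = c("observed_deaths", "data.frame"))
}

#' Write an analysis table to CSV
#'
#' Plain CSV, full double precision (\code{>= 15} significant digits), so that
#' \code{read_table(write_table(x))} reproduces every cell.
#'
#' @param x a table from [tables]
#' @param path output file path
#' @return \code{path}, invisibly
#' @export
write_table <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

read_csv_plain <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read analysis tables from CSV
#'
#' Each reader validates through the matching constructor in [tables].
#'
#' @param path a CSV written by [write_table()] (or following the same schema)
#' @return the classed table
#' @export
read_case_counts <- function(path) case_count_table(read_csv_plain(path))

#' @rdname read_case_counts
#' @export
read_or_table <- function(path) or_table(read_csv_plain(path))

#' @rdname read_case_counts
#' @export
read_fatality_table <- function(path) fatality_table(read_csv_plain(path))

#' @rdname read_case_counts
#' @export
read_observed_deaths <- function(path) observed_deaths(read_csv_plain(path))

#' Load a packaged fixture set
#'
#' The \code{"england_audit"} fixture transcribes the published audit tables:
#' stage x age x screening-category case counts and odds ratios, the raked
#' age x stage 5-year case-fatality table, observed annual deaths by
#' age-at-death band, and the published mortality projection (relative 5-year
#' mortality under no screening / universal regular screening, with the
#' estimated death columns). Percent-derived counts are kept fractional,
#' normalised so each (band, stage) cell block sums to its printed stage
#' total; the standard error of each log OR is reconstructed from the printed
#' CI as \code{(log hi - log lo) / (2 * 1.96)}.
#'
#' @param name fixture identifier; currently \code{"england_audit"}
#' @return a list with elements \code{counts}, \code{ors}, \code{fatality},
#'   \code{deaths} and \code{projection}
#' @examples
#' fx <- load_fixture_tables()
#' subset(fx$fatality, age_band == "50-64" & stage == "2")$rho  # 0.512
#' @export
load_fixture_tables <- function(name = "england_audit") {
  dir <- system.file("extdata", name, package = "screenimpact")
  if (dir == "" || !dir.exists(dir)) stop("unknown fixture: ", name)
  list(counts     = read_case_counts(file.path(dir, "counts.csv")),
       ors        = read_or_table(file.path(dir, "ors.csv")),
       fatality   = read_fatality_table(file.path(dir, "fatality.csv")),
       deaths     = read_observed_deaths(file.path(dir, "deaths.csv")),
       projection = read_csv_plain(file.path(dir, "projection.csv")))
}

#' @export
print.case_count_table <- function(x, ...) {
  staged <- x$stage != "unknown"
  cat("<case_count_table> ", sum(x$count), " cases (",
      round(sum(x$count[staged]), 1), " staged) in ",
      length(unique(x$age_band)), " age band(s)\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 8))
  if (nrow(x) > 8) cat("... ", nrow(x) - 8, " more rows\n")
  invisible(x)
}

#' @export
print.or_table <- function(x, ...) {
  cat("<or_table> ", nrow(x), " cells, bands: ",
      paste(unique(x$age_band), collapse = ", "), "\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 8))
  if (nrow(x) > 8) cat("... ", nrow(x) - 8, " more rows\n")
  invisible(x)
}

# single-cell lookup used across the estimators
table_cell <- function(tab, col, ...) {
  keys <- list(...)
  sel <- rep(TRUE, nrow(tab))
  for (k in names(keys)) sel <- sel & tab[[k]] == keys[[k]]
  v <- tab[[col]][sel]
  if (length(v) == 0) return(NA_real_)
  if (length(v) > 1) stop("ambiguous table cell lookup")
  v
}
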