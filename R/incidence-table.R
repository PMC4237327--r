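#' Age-grouped incidence table
#'
#' Validating constructor for registry-style age-binned incidence data:
#' half-open age bins `[age_lo, age_hi)` with a mean incidence per
#' 100,000 person-years in each bin. The final bin may be open-ended
#' (`age_hi = Inf`, written as e.g. `"85+"` on disk); it is closed at
#' the simulation horizon when compared to model curves.
#'
#' @param data A data frame with numeric columns `age_lo`, `age_hi`,
#'   `rate_per_100k_py`.
#' @param source Character tag recording where the table came from
#'   (default `"user"`).
#' @return A tibble of class `incidence_table`, sorted by `age_lo`.
#' @examples
#' incidence_table(data.frame(
#'   age_lo = c(0, 20), age_hi = c(20, Inf), rate_per_100k_py = c(2, 10)
#' ))
#' @export
incidence_table <- function(data, source = "user") {
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  required <- c("age_lo", "age_hi", "rate_per_100k_py")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols)) {
    abort(sprintf("`data` is missing required columns: %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  tab <- as_tibble(data)[required]
  if (nrow(tab) == 0L) abort("incidence table must have at least one bin.")
  for (col in required) {
    bad <- which(!is.finite(tab[[col]]) &
                   !(col == "age_hi" & is.infinite(tab[[col]])))
    if (length(bad)) {
      abort(sprintf("row %d: `%s` is not a finite number.", bad[1], col))
    }
  }
  tab <- dplyr::arrange(tab, .data$age_lo)
  bad <- which(tab$age_lo >= tab$age_hi)
  if (length(bad)) {
    abort(sprintf("row %d: age_lo must be below age_hi.", bad[1]))
  }
  bad <- which(tab$rate_per_100k_py < 0)
  if (length(bad)) {
    abort(sprintf("row %d: negative incidence rate.", bad[1]))
  }
  if (nrow(tab) > 1L) {
    if (any(is.infinite(tab$age_hi[-nrow(tab)]))) {
      abort("only the final bin may be open-ended.")
    }
    overlap <- which(tab$age_lo[-1] < tab$age_hi[-nrow(tab)])
    if (length(overlap)) {
      abort(sprintf("row %d: age bins overlap.", overlap[1] + 1L))
    }
  }
  structure(tab, class = c("incidence_table", class(tab)),
            source = source)
}

#' Read an age-grouped incidence table from delimited text
#'
#' Expects a comma-separated file with header
#' `age_lo, age_hi, rate_per_100k_py`. A trailing `+` in the final bin's
#' `age_hi` (e.g. `85+`) marks an open-ended bin and is stored as `Inf`.
#'
#' @param path File to read.
#' @param source Source tag (default: the file path).
#' @return An `incidence_table` tibble.
#' @export
read_incidence_table <- function(path, source = path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  required <- c("age_lo", "age_hi", "rate_per_100k_py")
  if (!all(required %in% names(raw))) {
    abort(sprintf(
      "malformed header in %s: expected columns %s.",
      path, paste(required, collapse = ", ")))
  }
  parse_num <- function(x, col) {
    out <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(out))
    if (length(bad)) {
      abort(sprintf("row %d: cannot parse `%s` value \"%s\".",
                    bad[1], col, x[bad[1]]))
    }
    out
  }
  hi_raw <- raw$age_hi
  open_ended <- grepl("\\+$", hi_raw)
  if (any(open_ended & seq_along(hi_raw) != length(hi_raw))) {
    abort(sprintf("row %d: only the final bin may use the \"+\" dialect.",
                  which(open_ended)[1]))
  }
  hi <- numeric(length(hi_raw))
  hi[!open_ended] <- parse_num(hi_raw[!open_ended], "age_hi")
  hi[open_ended] <- Inf
  tab <- tibble(
    age_lo = parse_num(raw$age_lo, "age_lo"),
    age_hi = hi,
    rate_per_100k_py = parse_num(raw$rate_per_100k_py, "rate_per_100k_py")
  )
  if (any(open_ended)) {
    lo_open <- tab$age_lo[length(hi_raw)]
    if (tab$age_lo[which(open_ended)] < lo_open) {
      abort("open-ended bin must be the final bin.")
    }
  }
  incidence_table(tab, source = source)
}

#' Write an age-grouped incidence table as delimited text
#'
#' Inverse of [read_incidence_table()]: an open-ended final bin is
#' written back in the `85+` dialect, so `read(write(x))` reproduces
#' `x` exactly.
#'
#' @param table An `incidence_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_incidence_table <- function(table, path) {
  stopifnot(inherits(table, "incidence_table"))
  hi <- ifelse(is.infinite(table$age_hi),
               paste0(format(table$age_lo, trim = TRUE), "+"),
               format(table$age_hi, trim = TRUE, digits = 15))
  out <- tibble(
    age_lo = table$age_lo, age_hi = hi,
    rate_per_100k_py = table$rate_per_100k_py
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' Bin-average a model incidence curve over table age groups
#'
#' Time-averages the continuous model incidence over each age bin of an
#' observed table (trapezoidal integral divided by bin width), producing
#' the model-side quantity comparable to a registry's mean incidence per
#' age group. An open-ended final bin is closed at the grid horizon.
#'
#' @param table An `incidence_table`.
#' @param curves An `nsc_curves` tibble whose grid spans every bin.
#' @param column Curve column to average (default `"incidence"`).
#' @return The table with an added `model_rate` column.
#' @export
bin_average_incidence <- function(table, curves, column = "incidence") {
  stopifnot(inherits(table, "incidence_table"),
            inherits(curves, "nsc_curves"))
  t <- curves$t
  y <- curves[[column]]
  if (is.null(y)) abort(sprintf("no column `%s` in curves.", column))
  t_max <- t[length(t)]
  lo <- table$age_lo
  hi <- pmin(table$age_hi, t_max)
  if (any(lo < t[1]) || any(lo >= t_max)) {
    abort("age bins fall outside the simulated age grid.")
  }
  avg <- purrr::map2_dbl(lo, hi, function(a, b) {
    sel <- which(t >= a - 1e-12 & t <= b + 1e-12)
    ts <- t[sel]
    ys <- y[sel]
    # trapezoid over the grid slice, divided by the covered width
    sum(diff(ts) * (head(ys, -1) + tail(ys, -1)) / 2) / (ts[length(ts)] - ts[1])
  })
  dplyr::mutate(table, model_rate = avg)
}
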