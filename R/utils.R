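#' @keywords internal
"_PACKAGE"

KJ_PER_KCAL <- 4.184

#' Convert kilojoules to kilocalories
#'
#' Energy is carried internally in kJ (1 kcal = 4.184 kJ); descriptive output
#' is reported in kcal to match dietary-survey convention.
#'
#' @param kj Numeric vector of energies in kJ.
#' @return Numeric vector in kcal.
#' @export
kj_to_kcal <- function(kj) kj / KJ_PER_KCAL

#' Convert kilocalories to kilojoules
#' @param kcal Numeric vector of energies in kcal.
#' @return Numeric vector in kJ.
#' @export
kcal_to_kj <- function(kcal) kcal * KJ_PER_KCAL

# Fail with a schema error naming the first missing column.
require_cols <- function(df, cols, table_name) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("schema error in %s table: missing column(s) %s",
                 table_name, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

# Read a delimited table if given a path, pass data.frames through.
as_table <- function(x, table_name) {
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) {
      stop(sprintf("%s table not readable: %s", table_name, x), call. = FALSE)
    }
    x <- utils::read.csv(x, stringsAsFactors = FALSE,
                         colClasses = NA, check.names = FALSE)
  }
  if (!is.data.frame(x)) {
    stop(sprintf("%s table must be a data.frame or a CSV path", table_name),
         call. = FALSE)
  }
  as.data.frame(x, stringsAsFactors = FALSE)
}

# Food codes are 8-digit strings; numeric input is zero-padded.
normalize_food_code <- function(code) {
  if (is.numeric(code)) code <- sprintf("%08d", code)
  code <- as.character(code)
  bad <- !grepl("^[0-9]{8}$", code)
  if (any(bad)) {
    stop(sprintf("invalid food code(s), expected 8 digits: %s",
                 paste(utils::head(unique(code[bad]), 5L), collapse = ", ")),
         call. = FALSE)
  }
  code
}

log_msg <- function(quiet, fmt, ...) {
  if (!isTRUE(quiet)) message(sprintf(fmt, ...))
  invisible(NULL)
}
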