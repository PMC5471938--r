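# Classed conditions driving the CLI exit-code contract:
#   lbd_input_error  -> exit 1 (bad input data, unknown CUIs, failed queries)
#   lbd_config_error -> exit 2 (bad configuration / parameters)
# Anything else surfacing from a run maps to exit 3 (internal error).

stopInput <- function(fmt, ...) {
  stop(structure(
    class = c("lbd_input_error", "lbd_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

stopConfig <- function(fmt, ...) {
  stop(structure(
    class = c("lbd_config_error", "lbd_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

#' Normalize dates to ISO-8601 days
#'
#' Accepts `YYYY-MM-DD` or bare `YYYY` (mapped to January 1st of that year,
#' so year-only corpora still carry a total order for timeslicing).
#' Unparseable values become `NA`.
#'
#' @param x character vector of date strings.
#' @return a `Date` vector, `NA` where unparseable.
#' @keywords internal
normalizeDate <- function(x) {
  x <- trimws(as.character(x))
  out <- rep(as.Date(NA), length(x))
  isYear <- grepl("^[0-9]{4}$", x)
  if (any(isYear))
    out[isYear] <- as.Date(paste0(x[isYear], "-01-01"))
  isFull <- grepl("^[0-9]{4}-[0-9]{2}-[0-9]{2}$", x)
  if (any(isFull))
    out[isFull] <- suppressWarnings(as.Date(x[isFull], format = "%Y-%m-%d"))
  out
}

isValidCui <- function(x) grepl("^C[0-9]+$", x)

# Canonical unordered representation: (smaller CUI, larger CUI).
orderPair <- function(a, b) {
  swap <- a > b
  tmp <- a[swap]
  a[swap] <- b[swap]
  b[swap] <- tmp
  list(a = a, b = b)
}

pairKey <- function(a, b) {
  p <- orderPair(a, b)
  paste(p$a, p$b, sep = "\r")
}

emptyFilterLog <- function() {
  data.frame(step = character(), detail = character(),
             n_before = integer(), n_after = integer(),
             stringsAsFactors = FALSE)
}
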