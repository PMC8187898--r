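#' 2x2 carrier table
#'
#' The atom every statistic in the package consumes: carriers and totals of a
#' marker among cases and among controls. Non-carriers are implied
#' (\code{b = case_total - a}, \code{d = control_total - c}). Totals count
#' only individuals with known carrier status, so denominators may differ
#' between markers typed at different loci.
#'
#' @param case_carriers Number of case carriers (\code{a}).
#' @param case_total Number of cases with known status.
#' @param control_carriers Number of control carriers (\code{c}).
#' @param control_total Number of controls with known status.
#' @return An object of class \code{carrier_table} with elements
#'   \code{a, b, c, d, case_total, control_total}.
#' @examples
#' carrier_table(8, 51, 1, 94)
#' @export
carrier_table <- function(case_carriers, case_total,
                          control_carriers, control_total) {
  vals <- c(case_carriers, case_total, control_carriers, control_total)
  if (any(is.na(vals)) || any(vals < 0) || any(vals != round(vals))) {
    stop("carrier table cells must be non-negative integers", call. = FALSE)
  }
  if (case_total <= 0 || control_total <= 0) {
    stop("carrier table totals must be positive", call. = FALSE)
  }
  if (case_carriers > case_total || control_carriers > control_total) {
    stop("carriers cannot exceed the group total", call. = FALSE)
  }
  structure(
    list(a = as.integer(case_carriers),
         b = as.integer(case_total - case_carriers),
         c = as.integer(control_carriers),
         d = as.integer(control_total - control_carriers),
         case_total = as.integer(case_total),
         control_total = as.integer(control_total)),
    class = "carrier_table"
  )
}

#' @export
print.carrier_table <- function(x, ...) {
  cat(sprintf("carrier table: cases %d/%d (%.2f%%), controls %d/%d (%.2f%%)\n",
              x$a, x$case_total, 100 * x$a / x$case_total,
              x$c, x$control_total, 100 * x$c / x$control_total))
  invisible(x)
}

#' @export
as.matrix.carrier_table <- function(x, ...) {
  matrix(c(x$a, x$b, x$c, x$d), nrow = 2, byrow = TRUE,
         dimnames = list(group = c("case", "control"),
                         status = c("carrier", "non-carrier")))
}

as_carrier_table <- function(x) {
  if (inherits(x, "carrier_table")) return(x)
  if (is.numeric(x) && length(x) == 4L) {
    return(carrier_table(x[1L], x[2L], x[3L], x[4L]))
  }
  stop("cannot interpret input as a carrier table", call. = FALSE)
}
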