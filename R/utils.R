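# Shared constants and low-level helpers.

SEGMENT_IDS <- c("Lb", "T1", "T2", "T3", paste0("A", 1:8))
ELIGIBLE_SEGMENTS <- c("T2", "T3", paste0("A", 1:6))
CENTRAL_SEGMENTS <- c("A2", "A3", "A4")
COMPARTMENT_TYPES <- c("stripe", "interstripe")
SIDES <- c("upper", "lower")
EVENT_SOURCES <- c("mixer_cell", "posterior_intercalating_cell")
INTERFACE_STAGES <- c("pre_fusion", "en_face", "post_fusion")
INTENSITY_STAGES <- c("pre_fusion", "en_face", "interlocked")
INTENSITY_MARKERS <- c("ecadherin", "actin", "myosin", "bazooka", "vinculin")
SNAPSHOT_STAGES <- c("closure", "post_closure")

#' Signal a dataset validation failure
#'
#' Throws a condition of class `fusefid_validation_error` whose message names
#' the offending table, row and column when known.
#' @keywords internal
abort_validation <- function(message, file = NULL, row = NULL, column = NULL) {
  loc <- c(
    if (!is.null(file)) paste0("table ", file),
    if (!is.null(row)) paste0("row ", paste(row, collapse = ",")),
    if (!is.null(column)) paste0("column ", column)
  )
  msg <- if (length(loc)) paste0(message, " [", paste(loc, collapse = ", "), "]") else message
  cond <- structure(
    class = c("fusefid_validation_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}

# Decimal strings that parse back to exactly the same double.
# Guarantees lossless TSV round trips and byte-stable output for a fixed
# seed. Vectorized: 15 significant digits round-trip almost all measured
# values (which are stored at 4 decimals); the rare remainder fall back
# to 16/17 digits.
format_roundtrip <- function(x) {
  out <- rep("NA", length(x))
  ok <- which(!is.na(x))
  if (!length(ok)) return(out)
  s <- sprintf("%.15g", x[ok])
  for (d in 16:17) {
    todo <- as.numeric(s) != x[ok]
    if (!any(todo)) break
    s[todo] <- sprintf("%.*g", d, x[ok][todo])
  }
  out[ok] <- s
  out
}

# Deterministic TSV writer: UTF-8, tab-delimited, header row, "NA" missing.
write_tsv_table <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    col <- out[[j]]
    if (is.double(col)) {
      out[[j]] <- format_roundtrip(col)
    } else if (is.logical(col) || is.integer(col)) {
      out[[j]] <- ifelse(is.na(col), "NA", as.character(col))
    } else {
      col <- as.character(col)
      out[[j]] <- ifelse(is.na(col), "NA", col)
    }
  }
  utils::write.table(out, path,
    sep = "\t", quote = FALSE, row.names = FALSE,
    na = "NA", eol = "\n"
  )
  invisible(path)
}

read_tsv_table <- function(path, col_classes) {
  df <- utils::read.delim(path,
    sep = "\t", header = TRUE, na.strings = "NA",
    stringsAsFactors = FALSE, colClasses = NA, check.names = FALSE
  )
  missing_cols <- setdiff(names(col_classes), names(df))
  if (length(missing_cols)) {
    abort_validation(
      paste0("missing required column(s): ", paste(missing_cols, collapse = ", ")),
      file = basename(path)
    )
  }
  df <- df[names(col_classes)]
  for (nm in names(col_classes)) {
    cls <- col_classes[[nm]]
    df[[nm]] <- switch(cls,
      character = as.character(df[[nm]]),
      numeric = as.numeric(df[[nm]]),
      integer = {
        v <- df[[nm]]
        if (is.logical(v)) v <- as.integer(v)
        as.integer(v)
      },
      logical = as.logical(df[[nm]]),
      df[[nm]]
    )
  }
  df
}

is_wholenumber <- function(x, tol = 1e-9) {
  !is.na(x) & abs(x - round(x)) < tol
}
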