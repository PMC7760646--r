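#' Write / read a trial dataset as NONMEM-style CSV
#'
#' Datasets travel as plain CSV with one row per dosing or observation event:
#' columns ID, TIME, AMT, RATE, DV, MDV, EVID, DOSE plus covariates; missing
#' values are written as `.` in the NONMEM tradition. Numeric values are
#' written with full double precision so a write/read round trip is lossless.
#'
#' @param data a `nimo_trial` data frame (or compatible).
#' @param path CSV file path.
#' @return `write_dataset` returns `path` invisibly; `read_dataset` returns
#'   a `nimo_trial` data frame.
#' @export
write_dataset <- function(data, path) {
  out <- as.data.frame(data)
  chr <- lapply(out, function(col) {
    if (is.numeric(col)) {
      s <- formatC(col, digits = 17, format = "g")
      s[is.na(col)] <- "."
      trimws(s)
    } else {
      as.character(col)
    }
  })
  chr <- as.data.frame(chr, stringsAsFactors = FALSE)
  utils::write.csv(chr, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.required_columns <- c("ID", "TIME", "AMT", "RATE", "DV", "MDV", "EVID",
                       "DOSE")

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  raw <- utils::read.csv(path, na.strings = c(".", "NA"),
                         stringsAsFactors = FALSE)
  missing_cols <- setdiff(.required_columns, names(raw))
  if (length(missing_cols)) {
    stop("dataset file is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (nm in names(raw)) {
    if (!is.numeric(raw[[nm]])) {
      suppressWarnings(num <- as.numeric(raw[[nm]]))
      if (all(is.na(num) == is.na(raw[[nm]]))) raw[[nm]] <- num
    }
  }
  raw$MDV <- as.integer(raw$MDV)
  raw$EVID <- as.integer(raw$EVID)
  obs <- raw$EVID == 0L & raw$MDV == 0L
  if (any(obs & (is.na(raw$DV) | raw$DV < 0))) {
    stop("negative or missing DV on observation rows")
  }
  for (id in unique(raw$ID)) {
    tt <- raw$TIME[raw$ID == id & obs]
    if (is.unsorted(tt)) {
      stop("non-monotone observation times for subject ", id)
    }
  }
  class(raw) <- c("nimo_trial", "data.frame")
  raw
}

# Short content fingerprint used to refuse comparisons/diagnostics across
# different datasets.
data_hash <- function(data) {
  obs <- data$EVID == 0L & data$MDV == 0L
  sprintf("n%d-o%d-%.12g-%.12g-%.12g",
          length(unique(data$ID)), sum(obs),
          sum(data$TIME, na.rm = TRUE),
          sum(data$DV[obs]),
          sum(data$DV[obs] * data$TIME[obs]))
}
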