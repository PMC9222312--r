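#' Write an ECG record as delimited text
#'
#' Versioned plain-text format: comment header lines (`# key=value`, with the
#' sampling rate, amplitude units and any beat annotations), then
#' tab-separated columns.  Simulated records keep their ground-truth parts as
#' extra columns; plain records write `time_s` and `x` only.
#'
#' @param record an [af_record] or list with `x`, `fs` and optionally
#'   `annotations`.
#' @param path output file path.
#' @param units amplitude unit label written to the header (default "uV").
#' @return `path`, invisibly.
#' @export
write_record <- function(record, path, units = "uV") {
  x <- record$x; fs <- record$fs
  stopifnot(is.numeric(x), is.numeric(fs))
  cols <- list(time_s = (seq_along(x) - 1) / fs, x = x)
  for (nm in c("fwave_truth", "ventricular", "noise")) {
    if (!is.null(record[[nm]])) cols[[nm]] <- record[[nm]]
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# fwaver_record v1",
               sprintf("# fs=%.10g", fs),
               sprintf("# units=%s", units)), con)
  ann <- record$annotations
  if (!is.null(ann) && nrow(ann) > 0) {
    writeLines(sprintf("# beat %d %s", ann$sample, ann$type), con)
  }
  df <- as.data.frame(cols)
  writeLines(paste(names(df), collapse = "\t"), con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read an ECG record written by [write_record()]
#'
#' @param path file path.
#' @return list with `x`, `fs`, `units`, `annotations` and any ground-truth
#'   columns present; class `af_record` when the file carries a ground-truth
#'   F-wave, otherwise `ecg_record`.
#' @export
read_record <- function(path) {
  lines <- readLines(path)
  hd <- grep("^#", lines, value = TRUE)
  if (!length(hd) || !startsWith(hd[1], "# fwaver_record")) {
    stop("not an fwaver record file (missing '# fwaver_record' header)")
  }
  get_field <- function(key) {
    m <- grep(sprintf("^# %s=", key), hd, value = TRUE)
    if (!length(m)) stop(sprintf("record header is missing the '%s' field", key))
    sub(sprintf("^# %s=", key), "", m[1])
  }
  fs <- as.numeric(get_field("fs"))
  units <- get_field("units")
  beats <- grep("^# beat ", hd, value = TRUE)
  ann <- if (length(beats)) {
    parts <- strsplit(sub("^# beat ", "", beats), " ")
    data.frame(sample = as.integer(vapply(parts, `[`, "", 1)),
               type = vapply(parts, `[`, "", 2), stringsAsFactors = FALSE)
  } else NULL
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  df <- utils::read.table(text = body, header = TRUE, sep = "\t")
  rec <- c(list(x = df$x, fs = fs, units = units, annotations = ann),
           df[setdiff(names(df), c("time_s", "x"))])
  class(rec) <- if (!is.null(rec$fwave_truth)) "af_record" else "ecg_record"
  rec
}
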