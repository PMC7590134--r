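#' @title Readers for delimited IMU recordings and corpus assembly
#' @description
#' Two text dialects are understood: the package's own fixed-width CSV (see
#' [write_fixed_csv()]) and gait-database-style whitespace/tab-delimited
#' files with `#`-prefixed metadata lines, an optional column-name header
#' row, and one column per sensor axis (36 data columns for six 6-axis
#' IMUs, plus an optional trailing activity-label column).
#' @name io
NULL

#' Read a delimited IMU recording
#'
#' @param path file path.
#' @param dialect `"auto"` (default), `"fixed_csv"`, or `"gait_db"`.
#'   `"auto"` treats a file whose first non-empty line starts with `#` or a
#'   non-numeric header as `"gait_db"`, otherwise `"fixed_csv"`.
#' @param keep regular expression selecting data columns by header name for
#'   the `gait_db` dialect (default accelerometer + gyroscope prefixes);
#'   ignored when the file has no header row.
#' @return a list of integer channel vectors (named when a header row is
#'   present), with attribute `"meta"` holding the `#` metadata lines.
#' @export
read_imu_delimited <- function(path, dialect = c("auto", "fixed_csv", "gait_db"),
                               keep = "^(acc|gyro)") {
  dialect <- match.arg(dialect)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty file: ", path)
  meta <- grep("^#", lines, value = TRUE)
  body <- grep("^#", lines, value = TRUE, invert = TRUE)
  if (!length(body)) stop("no data rows in ", path)
  if (dialect == "auto") {
    first <- strsplit(trimws(body[1]), ",")[[1]]
    comma_numeric <- length(first) > 0 && all(grepl("^[+-]?[0-9]+$", first))
    dialect <- if (length(meta) || !comma_numeric) "gait_db" else "fixed_csv"
  }
  if (dialect == "fixed_csv") {
    channels <- read_fixed_csv(charToRaw(paste0(paste(body, collapse = "\n"), "\n")))
    names(channels) <- NULL
    if (length(meta)) attr(channels, "meta") <- meta
    return(channels)
  }
  toks <- strsplit(trimws(body), "[,\t ]+")
  widths <- lengths(toks)
  header <- NULL
  if (!all(grepl("^[+-]?[0-9]+$", toks[[1]]))) {
    header <- toks[[1]]
    toks <- toks[-1]
    widths <- widths[-1]
  }
  if (!length(toks)) stop("no data rows in ", path)
  if (length(unique(widths)) != 1) {
    stop(sprintf("ragged rows in %s: row %d has %d fields, expected %d",
                 path, which(widths != widths[1])[1] + length(header != 0),
                 widths[which(widths != widths[1])[1]], widths[1]))
  }
  ncol <- widths[1]
  flat <- unlist(toks, use.names = FALSE)
  bad <- which(!grepl("^[+-]?[0-9]+$", flat))
  if (length(bad)) {
    stop(sprintf("non-integer cell %s at row %d, column %d of %s",
                 flat[bad[1]], (bad[1] - 1) %/% ncol + 1,
                 (bad[1] - 1) %% ncol + 1, path))
  }
  vals <- as.numeric(flat)
  oob <- which(vals < -32768 | vals > 32767)
  if (length(oob)) {
    stop(sprintf("value %g at row %d, column %d of %s outside 16-bit signed range",
                 vals[oob[1]], (oob[1] - 1) %/% ncol + 1,
                 (oob[1] - 1) %% ncol + 1, path))
  }
  mat <- matrix(as.integer(vals), ncol = ncol, byrow = TRUE)
  channels <- lapply(seq_len(ncol), function(j) mat[, j])
  if (!is.null(header)) {
    names(channels) <- header
    channels <- channels[grepl(keep, header)]
    if (!length(channels)) stop("no columns matching ", keep, " in ", path)
  }
  if (length(meta)) attr(channels, "meta") <- meta
  channels
}

#' Assemble a corpus of test cases from a directory of recordings
#'
#' Scans `root` for gait-database-style files, parses subject / activity /
#' trial tags from each filename, splits each file's channels into one test
#' case per body segment (six channels each: the 3 accelerometer + 3
#' gyroscope axes whose column names contain the segment token), and skips
#' files on the exclusion list (e.g. recordings with known corrupted
#' gyroscope streams). Unparseable filenames are skipped with a warning.
#'
#' @param root directory to scan.
#' @param exclude character vector of file names (basenames) to skip.
#' @param pattern filename regex with three capture groups:
#'   activity, subject, trial. The default matches the
#'   `<prefix>_<activity>_<subject>_<trial>.txt` scheme used by public gait
#'   databases.
#' @param segments segment tokens expected inside column names.
#' @return list of test cases in the [synth_corpus()] shape: `meta`
#'   (subject, activity, trial, segment) plus `channels` (6 equal-length
#'   integer vectors).
#' @export
build_corpus <- function(root, exclude = character(),
                         pattern = "^.*_v[0-9]+_([a-z_]+?)_([0-9]+)_([0-9]+)\\.txt$",
                         segments = c("rf", "lf", "rs", "ls", "rt", "lt")) {
  files <- list.files(root, pattern = "\\.txt$", full.names = TRUE)
  files <- files[!(basename(files) %in% exclude)]
  cases <- list()
  for (f in files) {
    m <- regmatches(basename(f), regexec(pattern, basename(f)))[[1]]
    if (length(m) != 4) {
      warning("skipping unparseable filename: ", basename(f))
      next
    }
    channels <- read_imu_delimited(f, dialect = "gait_db")
    nm <- names(channels)
    if (is.null(nm)) stop("corpus files need a column-name header row: ", f)
    for (seg in segments) {
      sel <- grepl(paste0("(^|_)", seg, "(_|$)"), nm)
      if (sum(sel) != 6) next   # segment absent from this recording
      cases[[length(cases) + 1L]] <- list(
        meta = list(subject = as.integer(m[3]), activity = m[2],
                    trial = as.integer(m[4]), segment = seg),
        channels = channels[sel])
    }
  }
  cases
}
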