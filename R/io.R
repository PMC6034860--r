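# Text chromatogram import/export.
#
# Three plain-text dialects are supported:
#  * plain_tsv      -- two tab-separated numeric columns (time, intensity),
#                      no header.
#  * chromeleon_txt -- "key: value" metadata lines until a line starting with
#                      "Chromatogram Data", then tab-separated data lines with
#                      either "time<TAB>intensity" or "time<TAB>step<TAB>
#                      intensity" fields.
#  * empower_arw    -- two tab-separated header lines (field names, then field
#                      values, including a SampleName field), followed by one
#                      "time<TAB>intensity" pair per line.
# Vendor dialects accept decimal commas and normalise them to points. Vendor
# export layouts vary by instrument configuration; these two are declared,
# documented approximations that the fixture writers reproduce exactly.

.num <- function(x, path, lineno, allow_comma = FALSE) {
  if (allow_comma) x <- gsub(",", ".", x, fixed = TRUE)
  v <- suppressWarnings(as.numeric(x))
  if (any(is.na(v))) {
    stop(sprintf("%s: cannot parse numeric value on line %d",
                 basename(path), lineno[which(is.na(v))[1]]), call. = FALSE)
  }
  v
}

.split_fields <- function(lines) strsplit(lines, "\t", fixed = TRUE)

.parse_pairs <- function(lines, linenos, path, allow_comma = FALSE,
                         allow_step = FALSE) {
  fields <- .split_fields(lines)
  nf <- lengths(fields)
  ok_n <- if (allow_step) nf %in% c(2L, 3L) else nf == 2L
  if (any(!ok_n)) {
    stop(sprintf("%s: malformed data line %d (expected %s tab-separated fields)",
                 basename(path), linenos[which(!ok_n)[1]],
                 if (allow_step) "2 or 3" else "2"), call. = FALSE)
  }
  tcol <- vapply(fields, `[`, "", 1L)
  icol <- vapply(seq_along(fields), function(i) fields[[i]][nf[i]], "")
  list(time = .num(tcol, path, linenos, allow_comma),
       intensity = .num(icol, path, linenos, allow_comma))
}

.detect_dialect <- function(path, lines) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "arw") return("empower_arw")
  if (any(startsWith(lines, "Chromatogram Data"))) return("chromeleon_txt")
  first <- lines[nzchar(trimws(lines))][1]
  if (is.na(first)) {
    stop(sprintf("%s: empty file", basename(path)), call. = FALSE)
  }
  f1 <- strsplit(first, "\t", fixed = TRUE)[[1]]
  if (length(f1) >= 2L &&
      !anyNA(suppressWarnings(as.numeric(f1[c(1L, length(f1))])))) {
    return("plain_tsv")
  }
  if (grepl(":", first, fixed = TRUE)) return("chromeleon_txt")
  if (length(f1) >= 2L) return("empower_arw")
  stop(sprintf("%s: cannot infer chromatogram dialect", basename(path)),
       call. = FALSE)
}

#' Read a chromatogram from a text export
#'
#' Parses one of the supported plain-text chromatogram dialects into a
#' [chromatogram()]. In `"auto"` mode the dialect is inferred from the file
#' extension (`.arw` implies the Empower-style dialect) and otherwise from the
#' content (a `"Chromatogram Data"` marker implies the Chromeleon-style
#' dialect; a leading numeric pair implies plain TSV).
#'
#' @param path Path to the file.
#' @param dialect `"auto"` (default), `"plain_tsv"`, `"chromeleon_txt"` or
#'   `"empower_arw"`.
#' @return A [chromatogram()]. The sample id is the file stem unless an
#'   Empower-style header provides a `SampleName` field.
#' @export
read_chromatogram <- function(path, dialect = c("auto", "plain_tsv",
                                                "chromeleon_txt",
                                                "empower_arw")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  if (dialect == "auto") dialect <- .detect_dialect(path, lines)
  stem <- tools::file_path_sans_ext(basename(path))
  sample_id <- stem

  keep <- nzchar(trimws(lines))
  if (dialect == "plain_tsv") {
    idx <- which(keep)
    if (length(idx) == 0L) {
      stop(sprintf("%s: empty data block", basename(path)), call. = FALSE)
    }
    p <- .parse_pairs(lines[idx], idx, path)
  } else if (dialect == "chromeleon_txt") {
    marker <- which(startsWith(lines, "Chromatogram Data"))
    if (length(marker) == 0L) {
      stop(sprintf("%s: no 'Chromatogram Data' section found", basename(path)),
           call. = FALSE)
    }
    idx <- which(keep & seq_along(lines) > marker[1])
    if (length(idx) == 0L) {
      stop(sprintf("%s: empty data block", basename(path)), call. = FALSE)
    }
    p <- .parse_pairs(lines[idx], idx, path, allow_comma = TRUE,
                      allow_step = TRUE)
  } else { # empower_arw
    idx <- which(keep)
    if (length(idx) < 3L) {
      stop(sprintf("%s: empty data block", basename(path)), call. = FALSE)
    }
    hdr_names <- strsplit(lines[idx[1]], "\t", fixed = TRUE)[[1]]
    hdr_vals <- strsplit(lines[idx[2]], "\t", fixed = TRUE)[[1]]
    hdr_names <- gsub('^"|"$', "", hdr_names)
    hdr_vals <- gsub('^"|"$', "", hdr_vals)
    hit <- which(tolower(hdr_names) == "samplename")
    if (length(hit) == 1L && hit <= length(hdr_vals) &&
        nzchar(hdr_vals[hit])) {
      sample_id <- hdr_vals[hit]
    }
    didx <- idx[-c(1L, 2L)]
    p <- .parse_pairs(lines[didx], didx, path, allow_comma = TRUE)
  }

  if (any(diff(p$time) <= 0)) {
    stop(sprintf("%s: time values are not strictly increasing",
                 basename(path)), call. = FALSE)
  }
  chromatogram(p$time, p$intensity, sample_id = sample_id,
               source_path = path, dialect = dialect)
}

#' Write a chromatogram as plain TSV
#'
#' Writes two tab-separated columns (time, intensity) at 12 significant
#' digits, so that [read_chromatogram()] round-trips the vectors to well
#' below 1e-9 relative error.
#'
#' @param chrom A [chromatogram()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chromatogram <- function(chrom, path) {
  stopifnot(inherits(chrom, "chromatogram"))
  lines <- sprintf("%.12g\t%.12g", chrom$time, chrom$intensity)
  writeLines(lines, path)
  invisible(path)
}

#' Read a peak list
#'
#' Reads a tab-separated peak list with three fields per line: peak name,
#' expected retention time and retention-time half-window. Lines starting
#' with `#` and blank lines are ignored.
#'
#' @param path Path to the peak-list file.
#' @return A [peak_list()] (possibly empty), rows in file order.
#' @export
read_peak_list <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  idx <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  if (length(idx) == 0L) return(peak_list(character(), numeric(), numeric()))
  fields <- .split_fields(lines[idx])
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop(sprintf("%s: line %d has fewer than 3 tab-separated fields",
                 basename(path), idx[which(nf < 3L)[1]]), call. = FALSE)
  }
  nm <- vapply(fields, `[`, "", 1L)
  tr <- .num(vapply(fields, `[`, "", 2L), path, idx)
  w <- .num(vapply(fields, `[`, "", 3L), path, idx)
  peak_list(nm, tr, w)
}

#' Write a peak list
#'
#' @param peaks A [peak_list()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peak_list <- function(peaks, path) {
  stopifnot(inherits(peaks, "peak_list"))
  writeLines(sprintf("%s\t%.12g\t%.12g", peaks$name, peaks$tr, peaks$window),
             path)
  invisible(path)
}

#' Write a chromatogram in a vendor-style dialect
#'
#' Fixture writers for the two vendor-style dialects; primarily used to
#' exercise the parsers and to export synthetic data in a realistic layout.
#'
#' @param chrom A [chromatogram()].
#' @param path Output path.
#' @param dialect `"plain_tsv"`, `"chromeleon_txt"` or `"empower_arw"`.
#' @return `path`, invisibly.
#' @export
write_chromatogram_dialect <- function(chrom, path,
                                       dialect = c("plain_tsv",
                                                   "chromeleon_txt",
                                                   "empower_arw")) {
  stopifnot(inherits(chrom, "chromatogram"))
  dialect <- match.arg(dialect)
  if (dialect == "plain_tsv") return(write_chromatogram(chrom, path))
  if (dialect == "chromeleon_txt") {
    hdr <- c(
      sprintf("Injection Information: %s", chrom$sample_id),
      "Detector: FLD",
      "Signal Unit: EU",
      "Time Unit: min",
      "Chromatogram Data:")
    data <- sprintf("%.12g\t%.12g", chrom$time, chrom$intensity)
    writeLines(c(hdr, data), path)
  } else {
    hdr <- c(paste(c("\"SampleName\"", "\"Channel\""), collapse = "\t"),
             paste(c(sprintf("\"%s\"", chrom$sample_id), "\"FLR\""),
                   collapse = "\t"))
    data <- sprintf("%.12g\t%.12g", chrom$time, chrom$intensity)
    writeLines(c(hdr, data), path)
  }
  invisible(path)
}
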