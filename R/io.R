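# Comma-separated, UTF-8, "." decimal, mandatory header row throughout.

check_numeric_cols <- function(df, cols, path) {
  for (cl in cols) {
    v <- df[[cl]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))))[1]
      stop("non-numeric cell in ", path, " at row ", bad %||% 1,
           ", column '", cl, "'")
    }
    if (anyNA(v)) {
      stop("missing value in ", path, " at row ", which(is.na(v))[1],
           ", column '", cl, "'")
    }
    if (any(v < 0)) {
      stop("negative value in ", path, " at row ", which(v < 0)[1],
           ", column '", cl, "'")
    }
  }
  invisible(df)
}

#' Read / write a linkage census table
#'
#' Census CSVs carry one row per sample with the header
#' `sample,t_fruf,b21_fruf,b26_fruf,di_fruf,t_glcp,i_glcp`; values may be
#' integer counts or molar percentages.
#'
#' @param path file path.
#' @return data.frame with a `sample` column and the six class columns.
#' @export
read_census_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("sample", LINKAGE_CLASSES)
  missing <- setdiff(need, names(df))
  unknown <- setdiff(names(df), need)
  if (length(missing) || length(unknown)) {
    stop("census CSV schema mismatch in ", path,
         if (length(missing)) paste0("; missing: ",
                                     paste(missing, collapse = ", ")),
         if (length(unknown)) paste0("; unknown: ",
                                     paste(unknown, collapse = ", ")))
  }
  check_numeric_cols(df, LINKAGE_CLASSES, path)
  df[need]
}

#' @rdname read_census_csv
#' @param df data.frame with columns `sample` and the six linkage classes.
#' @export
write_census_csv <- function(df, path) {
  need <- c("sample", LINKAGE_CLASSES)
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("cannot write census CSV; missing column(s): ",
         paste(missing, collapse = ", "))
  }
  utils::write.csv(df[need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# header dialects accepted by read_linkage_csv
PCT_HEADER <- c(t_fruf_pct = "t_fruf", b21_pct = "b21_fruf",
                b26_pct = "b26_fruf", di_pct = "di_fruf",
                t_glcp_pct = "t_glcp", i_glcp_pct = "i_glcp")
RATIO_HEADER <- c(t_fruf_ratio = "t_fruf", b21_ratio = "b21_fruf",
                  b26_ratio = "b26_fruf", di_ratio = "di_fruf",
                  glcp_ratio = "glcp")

#' Read a linkage table in percentage or ratio form
#'
#' Accepts three header dialects: the plain census header
#' (`t_fruf`, ..., `i_glcp`), the percentage header (`t_fruf_pct`,
#' `b21_pct`, `b26_pct`, `di_pct`, `t_glcp_pct`, `i_glcp_pct`) or the
#' pre-normalized ratio header (`t_fruf_ratio`, `b21_ratio`, `b26_ratio`,
#' `di_ratio`, `glcp_ratio`). Column names are canonicalized on return, so
#' the result feeds [infer_linkage_table()] directly.
#'
#' @param path file path.
#' @return data.frame with `sample` plus either the six class columns
#'   (percent/count input) or the five ratio columns.
#' @export
read_linkage_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"sample" %in% names(df)) stop("missing 'sample' column in ", path)
  other <- setdiff(names(df), "sample")
  dialect <- if (all(LINKAGE_CLASSES %in% other)) {
    stats::setNames(LINKAGE_CLASSES, LINKAGE_CLASSES)
  } else if (all(names(PCT_HEADER) %in% other)) {
    PCT_HEADER
  } else if (all(names(RATIO_HEADER) %in% other)) {
    RATIO_HEADER
  } else {
    stop("unrecognized linkage CSV header in ", path, ": ",
         paste(other, collapse = ", "),
         "; expected the census, _pct or _ratio column sets")
  }
  extra <- setdiff(other, names(dialect))
  if (length(extra)) {
    stop("unknown column(s) in ", path, ": ", paste(extra, collapse = ", "))
  }
  check_numeric_cols(df, names(dialect), path)
  out <- df[c("sample", names(dialect))]
  names(out) <- c("sample", unname(dialect))
  out
}

#' Read / write PMAA spectra in MSP text format
#'
#' The dialect: `Name:` opens an entry, arbitrary `Key: value` header lines
#' are kept as metadata (unknown keys are ignored by consumers), `Num Peaks:`
#' announces the peak count, and each following line is one `m/z intensity`
#' pair. Entries are separated by blank lines.
#'
#' @param path file path.
#' @return list of [pmaa_spectrum()] objects.
#' @export
read_msp <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  spectra <- list()
  i <- 1
  n <- length(lines)
  while (i <= n) {
    if (!grepl("^Name:", lines[i])) {
      i <- i + 1
      next
    }
    meta <- list(Name = trimws(sub("^Name:", "", lines[i])))
    i <- i + 1
    npeaks <- NULL
    while (i <= n && nzchar(trimws(lines[i])) &&
           grepl("^[A-Za-z][A-Za-z ]*:", lines[i])) {
      key <- trimws(sub(":.*$", "", lines[i]))
      val <- trimws(sub("^[^:]*:", "", lines[i]))
      if (tolower(key) == "num peaks") {
        npeaks <- as.integer(val)
        i <- i + 1
        break
      }
      meta[[key]] <- val
      i <- i + 1
    }
    if (is.null(npeaks)) stop("entry '", meta$Name, "' lacks a Num Peaks line")
    mz <- numeric(npeaks)
    intensity <- numeric(npeaks)
    for (j in seq_len(npeaks)) {
      parts <- strsplit(trimws(lines[i]), "[[:space:];]+")[[1]]
      if (length(parts) < 2) {
        stop("malformed peak line ", i, " in ", path, ": '", lines[i], "'")
      }
      mz[j] <- as.numeric(parts[1])
      intensity[j] <- as.numeric(parts[2])
      i <- i + 1
    }
    spectra[[length(spectra) + 1]] <-
      pmaa_spectrum(mz, intensity, name = meta$Name,
                    metadata = meta[setdiff(names(meta), "Name")])
  }
  if (!length(spectra)) stop("no spectra found in ", path)
  spectra
}

#' @rdname read_msp
#' @param spectra list of [pmaa_spectrum()] objects.
#' @export
write_msp <- function(spectra, path) {
  if (inherits(spectra, "pmaa_spectrum")) spectra <- list(spectra)
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    writeLines(paste0("Name: ", s$name %||% "spectrum"), con)
    for (key in names(s$metadata)) {
      writeLines(paste0(key, ": ", s$metadata[[key]]), con)
    }
    writeLines(paste0("Num Peaks: ", length(s$mz)), con)
    writeLines(sprintf("%d %g", s$mz, s$intensity), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read / write an HPTLC band table
#'
#' Band CSVs have a `sample` column, an optional `label` class column, and
#' one `rf_<value>` intensity column per band (e.g. `rf_0.062`).
#'
#' @param path file path.
#' @return data.frame; Rf values parsed from the column names are kept in
#'   attribute `"rf_values"`.
#' @export
read_band_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"sample" %in% names(df)) stop("missing 'sample' column in ", path)
  rf_cols <- grep("^rf_", names(df), value = TRUE)
  if (!length(rf_cols)) stop("no rf_* band columns in ", path)
  unknown <- setdiff(names(df), c("sample", "label", rf_cols))
  if (length(unknown)) {
    stop("unknown column(s) in ", path, ": ", paste(unknown, collapse = ", "))
  }
  rf <- as.numeric(sub("^rf_", "", rf_cols))
  if (anyNA(rf) || any(rf <= 0 | rf >= 1)) {
    stop("band columns must be named rf_<value> with value in (0,1)")
  }
  check_numeric_cols(df, rf_cols, path)
  attr(df, "rf_values") <- rf
  df
}

#' @rdname read_band_csv
#' @param df band table data.frame (`sample`, optional `label`, `rf_*`).
#' @export
write_band_csv <- function(df, path) {
  if (!"sample" %in% names(df)) stop("band table needs a 'sample' column")
  if (!any(grepl("^rf_", names(df)))) {
    stop("band table needs at least one rf_* column")
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an analysis report as JSON
#'
#' @param x named list of results (numbers, vectors, tables).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
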