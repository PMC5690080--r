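#' Convert a raw gantry angle to the rotation from the horizontal axis
#'
#' Scans are driven in machine gantry coordinates (the horizontal beam is
#' at gantry 270 or 90 degrees); the math core works with the rotation
#' beta from the horizontal central axis. \code{beta = |gantry - base|},
#' with the scanned half recorded: angles above the base scan the upper
#' half, below it the lower half.
#'
#' @param gantry_deg Raw gantry angle(s), degrees.
#' @param base Gantry angle of the horizontal central axis (default 270).
#' @return A data frame with columns \code{beta} (degrees, in
#'   \code{[0, 90)}) and \code{half} (\code{"upper"} or \code{"lower"}).
#' @examples
#' gantry_to_beta(270:290)
#' @export
gantry_to_beta <- function(gantry_deg, base = 270) {
  stopifnot(is.numeric(gantry_deg), is.numeric(base), length(base) == 1L)
  beta <- abs(gantry_deg - base)
  if (any(beta >= 90))
    stop("gantry angle maps outside [0, 90) degrees from the central axis")
  data.frame(beta = beta,
             half = ifelse(gantry_deg >= base, "upper", "lower"))
}

# Metadata keys recognized in profile CSV comment headers.
.meta_keys <- c("setup", "chamber", "f", "e", "d", "ssd", "half",
                "normalization", "normalized")

#' Read a profile scan CSV
#'
#' The scan dialect is CSV with leading comment lines \code{# key: value}
#' carrying metadata (setup, chamber, f, e, d, half, ...), then a header
#' row and data rows. A moving-gantry scan has columns
#' \code{gantry_deg} (or \code{beta}), \code{reading_plus},
#' \code{reading_minus}; a moving-detector scan has \code{x_cm} (or
#' \code{x}) instead of the angle. A single-polarity file (only
#' \code{reading_plus}, or a plain \code{reading} column) is accepted
#' with a warning.
#'
#' @param path Path to the CSV file.
#' @param gantry_base Base gantry angle used to reduce raw
#'   \code{gantry_deg} values to beta (ignored for detector scans and for
#'   files that already carry \code{beta}).
#' @return A list with \code{data} (the scan data frame, coordinate
#'   column named \code{beta} or \code{x}), \code{setup}, \code{meta}
#'   (named list of metadata), and \code{geom} (a
#'   \code{\link{beam_geometry}} when f, e, d are all present, else NULL).
#' @export
read_profile_csv <- function(path, gantry_base = 270) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  is_meta <- grepl("^\\s*#", lines)
  meta <- list()
  for (ln in lines[is_meta]) {
    m <- regmatches(ln, regexec("^\\s*#\\s*([A-Za-z_]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) == 3L) {
      key <- tolower(m[2]); val <- trimws(m[3])
      num <- suppressWarnings(as.numeric(val))
      meta[[key]] <- if (!is.na(num)) num else val
    }
  }
  dat <- utils::read.csv(textConnection(lines[!is_meta]),
                         strip.white = TRUE)
  names(dat) <- tolower(names(dat))

  coord <- intersect(c("gantry_deg", "beta", "x_cm", "x"), names(dat))
  if (length(coord) == 0L)
    stop("profile CSV must have a coordinate column: ",
         "gantry_deg/beta (moving_gantry) or x_cm/x (moving_detector)")
  coord <- coord[1]
  setup <- if (coord %in% c("gantry_deg", "beta")) "moving_gantry" else "moving_detector"
  if (!is.null(meta$setup) && !identical(meta$setup, setup))
    stop(sprintf("metadata declares setup '%s' but columns are the %s dialect",
                 meta$setup, setup))

  if (coord == "gantry_deg") {
    conv <- gantry_to_beta(dat$gantry_deg, base = gantry_base)
    dat$beta <- conv$beta
    if (is.null(meta$half)) meta$half <- unique(conv$half)[1]
    dat$gantry_deg <- NULL
  } else if (coord == "x_cm") {
    names(dat)[names(dat) == "x_cm"] <- "x"
  }
  cc <- if (setup == "moving_gantry") "beta" else "x"
  bad <- which(diff(dat[[cc]]) <= 0)
  if (length(bad))
    stop(sprintf("coordinates not strictly increasing at data row %d of %s",
                 bad[1] + 1L, path))

  if (!any(c("reading", "reading_plus", "relative_reading", "value_percent",
             "value") %in% names(dat)))
    stop("profile CSV has no reading column (reading_plus/reading_minus, ",
         "reading, relative_reading or value_percent)")
  if ("reading_plus" %in% names(dat) && !"reading_minus" %in% names(dat))
    warning("file has a single polarity only; polarity averaging will be skipped")

  geom <- if (all(c("f", "e", "d") %in% names(meta)))
    beam_geometry(meta$f, meta$e, meta$d) else NULL
  list(data = dat, setup = setup, meta = meta, geom = geom)
}

#' Write a scan or profile to CSV
#'
#' Writes the comment-metadata dialect read by
#' \code{\link{read_profile_csv}}. Numbers are serialized at full
#' precision (15 significant digits) so that write-then-read round trips
#' are lossless at working precision.
#'
#' @param x A data frame (scan) or a \code{\link{beam_profile}}.
#' @param path Output path.
#' @param meta Named list of metadata written as \code{# key: value}
#'   comment lines; for a \code{beam_profile} the object's own metadata
#'   are merged in.
#' @return \code{path}, invisibly.
#' @export
write_profile_csv <- function(x, path, meta = list()) {
  if (inherits(x, "beam_profile")) {
    auto <- list(setup = x$setup, chamber = x$chamber, half = x$half,
                 normalized = tolower(as.character(x$normalized)))
    if (!is.null(x$geom)) auto <- c(auto, list(f = x$geom$f, e = x$geom$e, d = x$geom$d))
    meta <- utils::modifyList(auto, meta)
    dat <- x$data
    names(dat)[names(dat) == "x"] <- "x_cm"
    if (x$normalized) names(dat)[names(dat) == "value"] <- "value_percent"
    if (!is.null(x$breakdown))
      dat <- cbind(dat, x$breakdown[, c("c_isq", "c_att", "c_obl")])
  } else {
    stopifnot(is.data.frame(x))
    dat <- x
    names(dat)[names(dat) == "x"] <- "x_cm"
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (key in names(meta))
    writeLines(sprintf("# %s: %s", key, format(meta[[key]], digits = 15)), con)
  num <- vapply(dat, is.numeric, logical(1))
  dat[num] <- lapply(dat[num], function(v) format(v, digits = 15, trim = TRUE))
  utils::write.csv(dat, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read or write a run configuration
#'
#' Run configurations are plain YAML: geometry (f, e, d), chamber,
#' response preset or calibration file, setup kind, gantry base angle,
#' scan design, seed, output paths. \code{write_run_config} then
#' \code{read_run_config} returns an identical structure.
#'
#' @param path YAML file path.
#' @return For \code{read_run_config}, a named list with defaults filled
#'   in (\code{gantry_base = 270}, \code{seed = 1}).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$gantry_base)) cfg$gantry_base <- 270
  if (is.null(cfg$seed)) cfg$seed <- 1L
  cfg
}

#' @rdname read_run_config
#' @param config Named list to serialize.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
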