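#' Construct a rheometer loading record
#'
#' Holds the time/force/displacement series of one mechanical protocol run
#' together with the sample geometry needed for stress--strain conversion.
#' Stress and strain are filled in by [to_stress_strain()]. Compression is
#' reported as positive force, displacement, stress and strain magnitudes.
#'
#' @param time_s strictly increasing time in seconds.
#' @param force_N compressive force in newtons.
#' @param displacement_mm compressive displacement in millimetres, relative
#'   to the post-preload height.
#' @param sample_diameter_mm assumed constant sample diameter (default 4).
#' @param sample_height_mm post-preload sample height, measured from the
#'   static tomogram.
#' @param protocol optional [protocol_spec()] describing the run.
#' @return An object of class `LoadingRecord`.
#' @export
loading_record <- function(time_s, force_N, displacement_mm,
                           sample_diameter_mm = 4,
                           sample_height_mm = NA_real_,
                           protocol = NULL) {
  n <- length(time_s)
  if (length(force_N) != n || length(displacement_mm) != n) {
    stop("time, force and displacement must have equal length")
  }
  if (n >= 2 && any(diff(time_s) <= 0)) {
    stop("time must be strictly increasing")
  }
  structure(
    list(time_s = as.numeric(time_s), force_N = as.numeric(force_N),
         displacement_mm = as.numeric(displacement_mm),
         sample_diameter_mm = sample_diameter_mm,
         sample_height_mm = sample_height_mm,
         stress_MPa = NULL, strain_frac = NULL,
         protocol = protocol),
    class = "LoadingRecord"
  )
}

#' @export
print.LoadingRecord <- function(x, ...) {
  cat(sprintf(
    "LoadingRecord: %d samples over %.1f s, d = %g mm, h = %g mm%s\n",
    length(x$time_s), diff(range(x$time_s)), x$sample_diameter_mm,
    x$sample_height_mm,
    if (is.null(x$stress_MPa)) "" else " (stress/strain derived)"))
  invisible(x)
}

#' Read a rheometer force--displacement export
#'
#' Reads a delimited text table, maps columns to time/force/displacement by
#' name, drops rows with non-finite entries (reported via a warning), and
#' returns a [loading_record()].
#'
#' @param path delimited text file with a header row.
#' @param column_map named character vector mapping the roles `time`,
#'   `force`, `displacement` to column names in the file.
#' @param sep field separator (default `","`).
#' @param sample_diameter_mm,sample_height_mm sample geometry.
#' @param units named list giving the multiplicative factor from file units
#'   to SI-derived record units (s, N, mm); default assumes the file is
#'   already in s / N / mm.
#' @return A `LoadingRecord`.
#' @export
read_loading_table <- function(path,
                               column_map = c(time = "time_s",
                                              force = "force_N",
                                              displacement = "displacement_mm"),
                               sep = ",",
                               sample_diameter_mm = 4,
                               sample_height_mm = NA_real_,
                               units = list(time = 1, force = 1,
                                            displacement = 1)) {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("time", "force", "displacement")
  for (role in need) {
    if (!(column_map[[role]] %in% names(tab))) {
      stop("mapped column for `", role, "` (", column_map[[role]],
           ") not found in ", path)
    }
  }
  t <- tab[[column_map[["time"]]]] * units$time
  f <- tab[[column_map[["force"]]]] * units$force
  d <- tab[[column_map[["displacement"]]]] * units$displacement
  keep <- is.finite(t) & is.finite(f) & is.finite(d)
  if (any(!keep)) {
    warning(sum(!keep), " row(s) with non-finite entries dropped")
  }
  loading_record(t[keep], f[keep], d[keep],
                 sample_diameter_mm = sample_diameter_mm,
                 sample_height_mm = sample_height_mm)
}

#' Write a loading record as a CSV table
#'
#' @param rec a `LoadingRecord`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_loading_table <- function(rec, path) {
  stopifnot(inherits(rec, "LoadingRecord"))
  tab <- data.frame(time_s = rec$time_s, force_N = rec$force_N,
                    displacement_mm = rec$displacement_mm)
  utils::write.table(tab, path, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
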