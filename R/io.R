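#' Read and write package file formats
#'
#' CSV (with header rows, full double precision) is the universal
#' interchange; TIFF (16-bit integer) is supported for image-like data
#' (carpets, vesicle images). All CSV round-trips are lossless at 64-bit
#' float precision.
#'
#' * trace CSV: columns `time_s`, `intensity`
#' * curve CSV: columns `lag_s`, `G` (optional `sem`)
#' * carpet CSV: one row per pixel, metadata in `#`-prefixed header lines
#' * transit CSV: column `transit_ms` (optional `group`)
#' * fit JSON: any fit object's parameters
#'
#' @param trace,curve,carpet,times,x object to write.
#' @param path file path.
#' @param dt sampling interval override when reading a trace whose time
#'   column is absent.
#' @name lipidfcs-io
NULL

fmt_num <- function(x) formatC(x, format = "g", digits = 17)

#' @rdname lipidfcs-io
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "intensity_trace"))
  v <- trace$values
  if (is.matrix(v)) stop("write one spot per trace file", call. = FALSE)
  df <- data.frame(time_s = fmt_num(seq_along(v) * trace$dt),
                   intensity = fmt_num(v))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

require_cols <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop("malformed file ", path, ": missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
}

#' @rdname lipidfcs-io
#' @export
read_trace <- function(path, dt = NULL) {
  df <- read.csv(path)
  require_cols(df, c("time_s", "intensity"), path)
  if (is.null(dt)) dt <- df$time_s[2] - df$time_s[1]
  intensity_trace(df$intensity, dt, meta = list(source = path))
}

#' @rdname lipidfcs-io
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "fcs_curve"))
  df <- data.frame(lag_s = fmt_num(curve$lag), G = fmt_num(curve$G))
  if (!is.null(curve$sem)) df$sem <- fmt_num(curve$sem)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname lipidfcs-io
#' @export
read_curve <- function(path) {
  df <- read.csv(path)
  require_cols(df, c("lag_s", "G"), path)
  fcs_curve(df$lag_s, df$G, sem = df$sem)
}

#' @rdname lipidfcs-io
#' @export
write_carpet <- function(carpet, path) {
  stopifnot(inherits(carpet, "sfcs_carpet"))
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    M <- carpet$intensities
    if (max(abs(M - round(M))) > 1e-9 || max(M) > 65535)
      stop("TIFF carpets are 16-bit integer counts; use CSV for ",
           "non-integer intensities", call. = FALSE)
    tiff::writeTIFF(round(M) / 65535, path, bits.per.sample = 16L)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(sprintf("# scan_frequency_hz: %s", fmt_num(carpet$scan_frequency)),
                 sprintf("# pixel_size_nm: %s", fmt_num(carpet$pixel_size))),
               con)
    write.table(matrix(fmt_num(carpet$intensities), nrow(carpet$intensities)),
                con, row.names = FALSE, col.names = FALSE, sep = ",",
                quote = FALSE)
  }
  invisible(path)
}

#' @rdname lipidfcs-io
#' @param scan_frequency,pixel_size metadata needed when reading TIFF
#'   carpets (CSV carpets carry them in header comments).
#' @export
read_carpet <- function(path, scan_frequency = NULL, pixel_size = NULL) {
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (is.null(scan_frequency) || is.null(pixel_size))
      stop("TIFF carpets need scan_frequency and pixel_size", call. = FALSE)
    M <- round(tiff::readTIFF(path) * 65535)
    return(sfcs_carpet(M, scan_frequency, pixel_size))
  }
  hdr <- readLines(path, n = 10)
  meta <- hdr[startsWith(hdr, "#")]
  get_meta <- function(key) {
    ln <- grep(paste0("^# ", key, ":"), meta, value = TRUE)
    if (!length(ln)) return(NULL)
    as.numeric(sub(".*: *", "", ln[1]))
  }
  sf <- if (!is.null(scan_frequency)) scan_frequency else
    get_meta("scan_frequency_hz")
  px <- if (!is.null(pixel_size)) pixel_size else get_meta("pixel_size_nm")
  if (is.null(sf) || is.null(px))
    stop("malformed file ", path, ": no scan_frequency_hz/pixel_size_nm ",
         "header and none supplied", call. = FALSE)
  M <- as.matrix(read.csv(path, header = FALSE, comment.char = "#"))
  dimnames(M) <- NULL
  sfcs_carpet(M, sf, px)
}

#' @rdname lipidfcs-io
#' @param group optional group labels written alongside transit times.
#' @export
write_transit <- function(times, path, group = NULL) {
  df <- data.frame(transit_ms = fmt_num(as.numeric(times)))
  if (!is.null(group)) df$group <- group
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname lipidfcs-io
#' @export
read_transit <- function(path) {
  df <- read.csv(path)
  require_cols(df, "transit_ms", path)
  out <- df$transit_ms
  if (!is.null(df$group)) attr(out, "group") <- df$group
  out
}

#' @rdname lipidfcs-io
#' @export
write_fit_json <- function(x, path) {
  payload <- if (inherits(x, "fcs_fit")) {
    list(kind = "fcs_fit", par = as.list(coef(x)), converged = x$converged,
         N = x$N, D = x$D, cpm = x$cpm, ssr = x$ssr, spec = x$spec)
  } else if (inherits(x, "transit_fit")) {
    list(kind = "transit_fit", model = x$model, mu = x$mu, sigma = x$sigma,
         B = x$B, e_mu = x$e_mu, loglik = x$loglik, bic = x$bic, n = x$n,
         delta_bic = x$delta_bic)
  } else if (inherits(x, "partition_result")) {
    list(kind = "partition_result", percent_lo = x$percent_lo,
         preference = x$preference, I_lo = x$I_lo, I_ld = x$I_ld)
  } else stop("unsupported object for fit JSON", call. = FALSE)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname lipidfcs-io
#' @export
read_fit_json <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)

#' @rdname lipidfcs-io
#' @param image numeric matrix to write as 16-bit TIFF (integer values up to
#'   65535) or CSV.
#' @export
write_image <- function(image, path) {
  image <- as.matrix(image)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (max(abs(image - round(image))) > 1e-9 || max(image) > 65535 ||
        min(image) < 0)
      stop("TIFF images are written as 16-bit integers; rescale first or ",
           "use CSV", call. = FALSE)
    tiff::writeTIFF(round(image) / 65535, path, bits.per.sample = 16L)
  } else {
    write.table(matrix(fmt_num(image), nrow(image)), path,
                row.names = FALSE, col.names = FALSE, sep = ",", quote = FALSE)
  }
  invisible(path)
}

#' @rdname lipidfcs-io
#' @export
read_image <- function(path) {
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    M <- tiff::readTIFF(path)
    if (length(dim(M)) == 3) M <- M[, , 1]
    return(round(M * 65535))
  }
  M <- as.matrix(read.csv(path, header = FALSE, comment.char = "#"))
  dimnames(M) <- NULL
  storage.mode(M) <- "double"
  M
}
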