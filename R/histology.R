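#' Harmonic mean of vascular canal diameters
#'
#' `HMC = n / sum(1/x_i)` over the `n` minimum diameters of the primary
#' vascular canals traced in one thin section. The harmonic mean is dominated
#' by the smallest canals, which is the desired behaviour when the quantity of
#' interest is the narrowest bore erythrocytes must squeeze through.
#'
#' @param diameters Numeric vector of canal diameters (micrometres), all
#'   strictly positive, length at least 1.
#' @return The harmonic mean, a single number in micrometres.
#' @examples
#' harmonic_mean(c(1, 2, 4))  # 3 / (1 + 1/2 + 1/4) = 1.714286
#' @export
harmonic_mean <- function(diameters) {
  if (length(diameters) == 0L) stop("no measurements")
  if (!is.numeric(diameters) || anyNA(diameters) || any(diameters <= 0)) {
    bad <- which(!is.finite(diameters) | diameters <= 0)[1L]
    stop("diameters must be positive; entry ", bad, " is ",
         diameters[bad])
  }
  length(diameters) / sum(1 / diameters)
}

#' One thin section's canal measurements
#'
#' @param specimen_id Text identifier of the thin section.
#' @param taxon Taxon name (may contain the extinct dagger, UTF-8).
#' @param diameters Positive canal diameters in micrometres.
#' @return A `canal_measurements` object.
#' @export
canal_measurements <- function(specimen_id, taxon, diameters) {
  stopifnot(is.character(specimen_id), length(specimen_id) == 1L, nzchar(specimen_id),
            is.character(taxon), length(taxon) == 1L)
  if (length(diameters) == 0L) stop("no measurements")
  if (!is.numeric(diameters) || anyNA(diameters) || any(diameters <= 0)) {
    bad <- which(!is.finite(diameters) | diameters <= 0)[1L]
    stop("diameters must be positive; entry ", bad, " of specimen ",
         specimen_id, " is ", diameters[bad])
  }
  structure(list(specimen_id = specimen_id, taxon = taxon,
                 diameters = as.numeric(diameters)),
            class = "canal_measurements")
}

#' @export
print.canal_measurements <- function(x, ...) {
  cat(sprintf("<canal_measurements> %s (%s): n = %d canals, HMC = %.3f um\n",
              x$specimen_id, x$taxon, length(x$diameters),
              harmonic_mean(x$diameters)))
  invisible(x)
}

#' Read a canal-diameter measurement table
#'
#' Expects delimited text (TSV or CSV, auto-detected from the header line
#' unless `sep` is given) with columns `specimen_id`, `taxon`, `diameter_um`
#' and one row per traced canal. Rows are grouped by `specimen_id` in file
#' order.
#'
#' @param path Path to the file, UTF-8.
#' @param sep Field separator; `NULL` (default) auto-detects `\t` vs `,`.
#' @return A list of [canal_measurements()], one per distinct specimen.
#' @export
read_measurements <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- first_noncomment_line(path)
  if (is.null(sep)) sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          encoding = "UTF-8", comment.char = "#",
                          colClasses = "character")
  need <- c("specimen_id", "taxon", "diameter_um")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  d <- suppressWarnings(as.numeric(df$diameter_um))
  if (anyNA(d)) {
    bad <- which(is.na(d))[1L]
    stop("unparseable diameter at data row ", bad, ": '", df$diameter_um[bad], "'")
  }
  if (any(d <= 0)) {
    bad <- which(d <= 0)[1L]
    stop("non-positive diameter at data row ", bad, ": ", d[bad])
  }
  df$diameter_um <- d
  as_canal_measurements(df)
}

#' Group a long-format measurement data.frame into per-specimen sets
#'
#' @param df Data.frame with columns `specimen_id`, `taxon`, `diameter_um`
#'   (one row per canal), e.g. from [simulate_measurements()].
#' @return A list of [canal_measurements()], one per distinct specimen, in
#'   first-appearance order.
#' @export
as_canal_measurements <- function(df) {
  stopifnot(all(c("specimen_id", "taxon", "diameter_um") %in% names(df)))
  ids <- unique(df$specimen_id)
  lapply(ids, function(id) {
    rows <- df$specimen_id == id
    taxa <- unique(df$taxon[rows])
    if (length(taxa) != 1L) {
      stop("specimen ", id, " maps to several taxa: ", paste(taxa, collapse = ", "))
    }
    canal_measurements(id, taxa, df$diameter_um[rows])
  })
}

#' Build per-specimen records: HMC, probability of endothermy, status
#'
#' The rows of the package's principal results table: per thin section the
#' harmonic mean canal diameter, the logistic probability of endothermy, and
#' the inferred binary status.
#'
#' @param measurements A list of [canal_measurements()] (or a single one).
#' @param model A [logistic_model()].
#' @return A data.frame with class `specimen_records` and columns
#'   `taxon`, `specimen_id`, `hmc_um`, `p_end`, `status`.
#' @export
specimen_records <- function(measurements, model = logistic_model()) {
  if (inherits(measurements, "canal_measurements")) measurements <- list(measurements)
  stopifnot(length(measurements) >= 1L,
            all(vapply(measurements, inherits, TRUE, "canal_measurements")))
  hmc <- vapply(measurements, function(m) harmonic_mean(m$diameters), 0)
  p <- predict_pend(hmc, model)
  out <- data.frame(
    taxon = vapply(measurements, `[[`, "", "taxon"),
    specimen_id = vapply(measurements, `[[`, "", "specimen_id"),
    hmc_um = hmc,
    p_end = p,
    status = classify(p, model),
    stringsAsFactors = FALSE
  )
  class(out) <- c("specimen_records", "data.frame")
  out
}

#' Write specimen records to a tab-separated table
#'
#' `hmc_um` and `p_end` are written with 17 significant digits so that a
#' read/write round trip through [read_specimen_table()] is bit-exact; a
#' display column `p_end_3sf` carries the 3-significant-figure formatting
#' used in print.
#'
#' @param records A `specimen_records` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_specimen_table <- function(records, path) {
  stopifnot(inherits(records, "specimen_records"))
  out <- data.frame(
    taxon = records$taxon,
    specimen_id = records$specimen_id,
    hmc_um = sprintf("%.17g", records$hmc_um),
    p_end = sprintf("%.17g", records$p_end),
    p_end_3sf = format_sig(records$p_end, 3L),
    status = records$status,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read back a specimen table written by [write_specimen_table()]
#' @param path Path to the TSV.
#' @return A `specimen_records` data.frame.
#' @export
read_specimen_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          encoding = "UTF-8")
  out <- data.frame(
    taxon = df$taxon, specimen_id = df$specimen_id,
    hmc_um = as.numeric(df$hmc_um), p_end = as.numeric(df$p_end),
    status = df$status, stringsAsFactors = FALSE
  )
  class(out) <- c("specimen_records", "data.frame")
  out
}

#' Scientific-notation significant-figure formatting (e.g. "8.35e-04")
#' @param x numbers; @param digits significant figures.
#' @keywords internal
format_sig <- function(x, digits = 3L) {
  formatC(x, digits = digits - 1L, format = "e")
}

# header line used for separator sniffing, skipping '#' comment lines
first_noncomment_line <- function(path) {
  con <- file(path, open = "r", encoding = "UTF-8")
  on.exit(close(con))
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L) return("")
    if (!startsWith(trimws(ln), "#")) return(ln)
  }
}
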