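#' Assemble a QA session report
#'
#' Bundles the structural and/or temporal metrics of one QA session with
#' provenance (input paths, package version, configuration hash,
#' timestamp). Either block may be absent.
#'
#' @param structural A `structural_metrics` object or `NULL`.
#' @param temporal A `temporal_metrics` object or `NULL`.
#' @param input Character vector of input paths, for provenance.
#' @param config Optional list of configuration values; serialized
#'   canonically and hashed into the provenance block.
#' @param timestamp Logical; record the wall-clock time. Disable for
#'   byte-identical reports across reruns.
#' @return An object of class `qa_report`.
#' @export
qa_report <- function(structural = NULL, temporal = NULL, input = character(),
                      config = NULL, timestamp = TRUE) {
  if (!is.null(structural)) stopifnot(inherits(structural, "structural_metrics"))
  if (!is.null(temporal)) stopifnot(inherits(temporal, "temporal_metrics"))
  provenance <- list(
    input = as.character(input),
    software = "phantomqa",
    version = as.character(packageVersion("phantomqa")),
    config_hash = .config_hash(config),
    timestamp = if (timestamp) format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z") else NULL
  )
  structure(list(structural = structural, temporal = temporal,
                 provenance = provenance),
            class = "qa_report")
}

# Stable hash of a canonical JSON serialization (djb2 over bytes; no
# cryptographic requirement, only change detection).
.config_hash <- function(config) {
  if (is.null(config)) return(NA_character_)
  json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = I(17))
  bytes <- utf8ToInt(as.character(json))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", h)
}

# Scalar fields serialized for each metrics block.
.structural_scalar_fields <- c(
  "s_mean", "s_min", "s_max", "s_fe1", "s_fe2", "s_pe1", "s_pe2",
  "sd1", "sd2", "psg_percent", "psg_permille", "piu",
  "snr1", "snr2", "snr_ratio", "snr_ratio_ok", "slice_used", "pe_axis")
.temporal_scalar_fields <- c(
  "sfnr_summary", "fluctuation_percent", "fluctuation_permille",
  "drift_percent", "rdc", "n_volumes", "slice_used")

.report_to_list <- function(report) {
  st <- report$structural
  tm <- report$temporal
  list(
    structural = if (is.null(st)) NULL else st[.structural_scalar_fields],
    temporal = if (is.null(tm)) NULL else c(
      tm[.temporal_scalar_fields],
      list(weisskoff = tm$weisskoff[c("side_lengths", "sd_actual",
                                      "roi_means", "sd_theoretical",
                                      "rdc", "n_volumes")])),
    provenance = report$provenance
  )
}

#' Write a QA report to disk
#'
#' JSON is the canonical form: all scalar metrics (and the Weisskoff curve
#' vectors) are written at full precision, so [read_report()] reproduces
#' them bit-exactly; pixel images are not serialized. The CSV form flattens
#' the scalar metrics of one or more reports into one row per session.
#'
#' @param report A [qa_report()], or for CSV a list of reports.
#' @param path Output path.
#' @param format `"json"` (single report) or `"csv"` (one row per report).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (format == "json") {
    stopifnot(inherits(report, "qa_report"))
    jsonlite::write_json(.report_to_list(report), path, auto_unbox = TRUE,
                         digits = I(17), null = "null", pretty = TRUE)
  } else {
    reports <- if (inherits(report, "qa_report")) list(report) else report
    utils::write.csv(reports_to_table(reports), path, row.names = FALSE)
  }
  invisible(path)
}

#' Read a JSON QA report
#'
#' @param path Path written by [write_report()].
#' @return A list with `structural`, `temporal` (scalar metrics and
#'   Weisskoff vectors) and `provenance`; scalar values are bit-exact
#'   copies of the written ones.
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x, class = "qa_report_data")
}

#' Flatten QA reports into a session table
#'
#' @param reports List of [qa_report()] objects (or lists read by
#'   [read_report()]).
#' @return A data.frame with one row per session and one column per scalar
#'   metric (`structural_*`, `temporal_*`).
#' @export
reports_to_table <- function(reports) {
  row_of <- function(r) {
    st <- r$structural
    tm <- r$temporal
    vals <- c(
      if (!is.null(st)) stats::setNames(
        lapply(.structural_scalar_fields, function(f) st[[f]]),
        paste0("structural_", .structural_scalar_fields)),
      if (!is.null(tm)) stats::setNames(
        lapply(.temporal_scalar_fields, function(f) tm[[f]]),
        paste0("temporal_", .temporal_scalar_fields)))
    as.data.frame(vals, stringsAsFactors = FALSE)
  }
  do.call(rbind, lapply(reports, row_of))
}
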