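#' Read and write pulling curves
#'
#' Curves are stored as headered delimited text (comma or tab, detected
#' automatically) with columns `pos_nm`, `force_pN` and optionally
#' `time_s`, plus a JSON sidecar (`<path>.json`) recording the curve kind,
#' sample rate and units. `write_curve()` then `read_curve()` round-trips
#' exactly.
#'
#' @param path Path of the delimited text file.
#' @param kind Override the curve kind (otherwise from the sidecar;
#'   defaults to `"FEC"` if no sidecar is found).
#' @param sample_rate Override the sample rate, Hz.
#' @return `read_curve()`: a [pulling_curve()].
#' @export
read_curve <- function(path, kind = NULL, sample_rate = NULL) {
  if (!file.exists(path)) stop("read_curve: no such file: ", path)
  lines <- readLines(path)
  if (length(lines) < 2) stop("read_curve: file has no data rows")
  sep <- if (grepl("\t", lines[1])) "\t" else ","
  header <- trimws(strsplit(lines[1], sep, fixed = TRUE)[[1]])
  need <- c("pos_nm", "force_pN")
  if (!all(need %in% header))
    stop("read_curve: missing column(s): ",
         paste(setdiff(need, header), collapse = ", "))
  body <- strsplit(lines[-1], sep, fixed = TRUE)
  nf <- lengths(body)
  if (any(nf != length(header)))
    stop("read_curve: malformed row ", which(nf != length(header))[1] + 1L,
         " (expected ", length(header), " fields)")
  mat <- suppressWarnings(
    vapply(body, function(r) as.numeric(r), numeric(length(header))))
  mat <- matrix(mat, nrow = length(header))
  bad <- which(apply(mat, 2, function(col) any(!is.finite(col))))
  if (length(bad))
    stop("read_curve: non-numeric or non-finite value in row ", bad[1] + 1L)
  rownames(mat) <- header
  meta <- list()
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar))
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  kind <- kind %||% meta$kind %||% "FEC"
  sample_rate <- sample_rate %||% meta$sample_rate %||% 200
  pulling_curve(mat["pos_nm", ], mat["force_pN", ],
                time = if ("time_s" %in% header) mat["time_s", ],
                kind = kind, sample_rate = sample_rate)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_curve
#' @param curve A [pulling_curve()].
#' @param sep Field separator, `","` or `"\t"`.
#' @param metadata Optional named list merged into the sidecar.
#' @return `write_curve()`: the path, invisibly.
#' @export
write_curve <- function(curve, path, sep = ",", metadata = list()) {
  stopifnot(inherits(curve, "pulling_curve"))
  df <- data.frame(pos_nm = curve$position, force_pN = curve$force)
  if (!is.null(curve$time)) df$time_s <- curve$time
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  sidecar <- c(list(kind = curve_kind(curve),
                    sample_rate = sample_rate(curve),
                    units = list(position = "nm", force = "pN", time = "s",
                                 concentration = "mM")),
               metadata)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a fit report
#'
#' Serialises one or more fit results to a CSV table and a JSON document
#' (same basename, `.json` extension) with a deterministic column order:
#' `label`, `model`, `parameter`, `estimate`, `std_error`. The two formats
#' carry identical values.
#'
#' @param results A `fec_fit`, a (optionally named) list of them, or a data
#'   frame already in report layout.
#' @param path Output CSV path.
#' @return The report data frame, invisibly.
#' @export
write_report <- function(results, path) {
  if (inherits(results, "fec_fit")) results <- list(results)
  if (is.data.frame(results)) {
    df <- results
  } else {
    if (length(results) == 0) stop("write_report: empty results")
    stopifnot(all(vapply(results, inherits, logical(1), "fec_fit")))
    labels <- names(results) %||% as.character(seq_along(results))
    labels[labels == ""] <- as.character(which(labels == ""))
    df <- do.call(rbind, Map(function(fit, lab) {
      data.frame(label = lab, model = fit$model,
                 parameter = names(fit$estimate),
                 estimate = unname(fit$estimate),
                 std_error = unname(fit$se))
    }, results, labels))
    rownames(df) <- NULL
  }
  if (nrow(df) == 0) stop("write_report: empty results")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(df, sub("\\.[^.]+$", ".json", path),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE)
  invisible(df)
}

#' Published elastic-parameter tables
#'
#' The per-salt fitted parameter tables packaged with saltfec as
#' tab-separated fixtures: WLC persistence/contour lengths for NaCl and
#' MgCl2, Ex-FJC Kuhn lengths and stretch moduli, thick-chain geometry at
#' low NaCl, and the secondary-structure sigmoid parameters. Concentrations
#' are nominal (add 9 mM buffer background for the monovalent series where
#' an effective concentration is needed).
#'
#' @return A named list of data frames: `wlc_nacl`, `wlc_mgcl2`,
#'   `exfjc_nacl`, `exfjc_mgcl2`, `tc_nacl`, `ss_sigmoid`.
#' @examples
#' salt_tables()$wlc_nacl
#' @export
salt_tables <- function() {
  dir <- system.file("extdata", package = "saltfec")
  rd <- function(f) utils::read.delim(file.path(dir, f))
  list(wlc_nacl    = rd("table_wlc_nacl.tsv"),
       wlc_mgcl2   = rd("table_wlc_mgcl2.tsv"),
       exfjc_nacl  = rd("table_exfjc_nacl.tsv"),
       exfjc_mgcl2 = rd("table_exfjc_mgcl2.tsv"),
       tc_nacl     = rd("table_tc_nacl.tsv"),
       ss_sigmoid  = rd("table_ss_sigmoid.tsv"))
}
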