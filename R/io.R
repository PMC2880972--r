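# Readers and writers: tab-separated flux tables ('.' decimal separator,
# header required) and JSON model-parameter files. Numeric columns survive
# a write/read round trip at better than 12 significant digits.

#' Write a flux dataset or regime curve as TSV
#'
#' Tab-delimited, '.' decimal separator, header line, no row names; the
#' unit tag and conversion context travel in a JSON sidecar
#' (`<path>.json`) so the table itself stays a plain flux table.
#'
#' @param d a [flux_dataset()] or any data.frame (e.g. an [atp_curve()]
#'   table).
#' @param path output path.
#' @param sidecar write the unit sidecar for `flux_dataset` inputs
#'   (default TRUE).
#' @return `path`, invisibly.
#' @export
write_flux_tsv <- function(d, path, sidecar = TRUE) {
  out <- as.data.frame(d)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) format(x, digits = 15, trim = TRUE,
                                                  scientific = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     dec = ".")
  if (sidecar && inherits(d, "flux_dataset")) {
    meta <- list(unit_tag = attr(d, "unit_tag"), context = attr(d, "context"))
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Read a flux dataset from TSV
#'
#' Expects header columns `glucose_uptake`, `lactate_excretion` and
#' optionally `oxidized_glucose`. The unit tag and context come from the
#' arguments, or from a JSON sidecar (`<path>.json`) when present and not
#' overridden.
#'
#' @param path TSV path.
#' @param unit_tag,context unit system; when NULL, taken from the sidecar
#'   if one exists, else `"mM_per_min"`.
#' @return A [flux_dataset()].
#' @export
read_flux_tsv <- function(path, unit_tag = NULL, context = NULL) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, dec = ".")
  req <- c("glucose_uptake", "lactate_excretion")
  miss <- setdiff(req, names(tab))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  side <- paste0(path, ".json")
  if ((is.null(unit_tag) || is.null(context)) && file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (is.null(unit_tag)) unit_tag <- meta$unit_tag
    if (is.null(context)) context <- as.list(meta$context)
  }
  flux_dataset(glucose_uptake = tab$glucose_uptake,
               lactate_excretion = tab$lactate_excretion,
               oxidized_glucose = tab$oxidized_glucose,
               unit_tag = if (is.null(unit_tag)) "mM_per_min" else unit_tag,
               context = if (is.null(context)) list() else context)
}

#' Write a crowding model as JSON
#'
#' Keys `a_G`, `a_L`, `a_M` (min/mM) and `phi_ATP` (dimensionless).
#'
#' @param m a [crowding_model()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_crowding_model <- function(m, path) {
  stopifnot(inherits(m, "crowding_model"))
  jsonlite::write_json(unclass(m), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a crowding model from JSON
#'
#' Accepts either the four derived keys (`a_G`, `a_L`, `a_M`, `phi_ATP`)
#' or a raw-input form with per-pathway blocks `glycolysis`, `ldh`, `mito`
#' (each `{v, r, s}`) plus `phi` (`{lo, hi}`), in which case the
#' coefficients are derived via [estimate_crowding_parameters()].
#'
#' @param path JSON path.
#' @return A [crowding_model()].
#' @export
read_crowding_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(obj$a_G)) {
    crowding_model(a_G = obj$a_G, a_L = obj$a_L, a_M = obj$a_M,
                   phi_ATP = obj$phi_ATP)
  } else if (!is.null(obj$glycolysis)) {
    est <- estimate_crowding_parameters(
      glycolysis = as.list(obj$glycolysis), ldh = as.list(obj$ldh),
      mito = as.list(obj$mito),
      phi = phi_range(obj$phi$lo, obj$phi$hi))
    est$model
  } else {
    stop("unrecognized model JSON: need a_G/a_L/a_M/phi_ATP or raw blocks",
         call. = FALSE)
  }
}
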