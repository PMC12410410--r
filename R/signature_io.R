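SIGNATURE_FORMAT_VERSION <- 1L

#' Serialize a trained signature to JSON
#'
#' The signature file is a JSON document carrying the human-readable fields
#' (format version, adaptive coefficient, pair table with directions,
#' p-values and importances, class order, classifier kind, seed) plus an
#' exact binary payload of the fitted model (base64-encoded R
#' serialization), so that `read_signature(write_signature(sig))` reproduces
#' predictions bit-for-bit.
#'
#' @param sig An `aigps_signature`.
#' @param path Output path (conventionally `.json`).
#' @return `path`, invisibly.
#' @export
write_signature <- function(sig, path) {
  stopifnot(inherits(sig, "aigps_signature"))
  doc <- list(
    format_version = SIGNATURE_FORMAT_VERSION,
    coefficient_a = sig$coefficient_a,
    classifier = sig$method,
    class_order = sig$class_order,
    seed = sig$seed,
    pairs = sig$pairs,
    gene_stats = if (is.null(sig$gene_stats)) NULL else
      list(sd = as.list(sig$gene_stats$sd), n = sig$gene_stats$n,
           cohort = sig$gene_stats$cohort),
    payload = jsonlite::base64_enc(serialize(sig, NULL, version = 2L)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a trained signature from JSON
#'
#' Restores the exact fitted object from the file's binary payload after
#' validating the format version and checking that the payload is consistent
#' with the document's pair table.
#'
#' @param path Path written by [write_signature()].
#' @return An `aigps_signature`.
#' @export
read_signature <- function(path) {
  if (!file.exists(path)) stop("signature file not found: ", path,
                               call. = FALSE)
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("corrupted signature file: ",
                                           conditionMessage(e), call. = FALSE))
  ver <- doc$format_version
  if (is.null(ver) || !identical(as.integer(ver), SIGNATURE_FORMAT_VERSION)) {
    stop("unsupported signature format version: ",
         if (is.null(ver)) "missing" else ver,
         " (this build reads version ", SIGNATURE_FORMAT_VERSION, ")",
         call. = FALSE)
  }
  sig <- tryCatch(unserialize(jsonlite::base64_dec(doc$payload)),
                  error = function(e) stop("corrupted signature payload",
                                           call. = FALSE))
  if (!inherits(sig, "aigps_signature") ||
      nrow(sig$pairs) != length(doc$pairs)) {
    stop("corrupted signature file: payload does not match pair table",
         call. = FALSE)
  }
  sig
}
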