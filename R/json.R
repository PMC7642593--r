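#' Serialize a profile to JSON
#'
#' Profiles interchange as JSON objects
#' `{"basis": ..., "amounts": {"<nutrient_id>": number, ...}}` with full
#' precision (no display rounding).
#'
#' @param x a [nutrient_profile()].
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return `path` invisibly, or a JSON string.
#' @export
profile_to_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "nutrient_profile"))
  obj <- list(basis = x$basis, amounts = as.list(x$amounts))
  if (is.null(path))
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname profile_to_json
#' @param json JSON string or file path to read.
#' @param panel a [nutrient_panel()].
#' @export
profile_from_json <- function(json, panel = nutrient_panel()) {
  obj <- jsonlite::fromJSON(json)
  nutrient_profile(unlist(obj$amounts), basis = obj$basis, panel = panel)
}
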