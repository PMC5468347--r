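# JSON serialization of trained models. Linear payloads are stored as plain
# coefficient tables; kernel/forest payloads are stored as an opaque
# base64-encoded R serialization.

MODEL_SCHEMA_VERSION <- 1L

#' Write a trained model to JSON
#'
#' @param model a `trained_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  payload <- model$payload
  if (payload$type == "linear") {
    pay <- list(type = "linear", family = payload$family,
                coef = as.list(payload$coef), intercept = payload$intercept)
  } else {
    pay <- list(type = payload$type, family = payload$family,
                blob = jsonlite::base64_enc(serialize(payload, NULL)))
  }
  obj <- list(
    schema_version = MODEL_SCHEMA_VERSION,
    features = model$features,
    center = as.list(model$center),
    scale = as.list(model$scale),
    payload = pay,
    threshold = model$threshold,
    performance = model$performance,
    signature_alternates = model$signature_alternates,
    provenance = model$provenance,
    encoder = if (!is.null(model$encoder)) {
      enc <- model$encoder
      enc$energy_P <- if (!is.null(enc$energy_P)) unclass(enc$energy_P)
      enc
    }
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a trained model from JSON
#'
#' @param path path to a model file written by [write_model()].
#' @return a `trained_model`.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(as.integer(obj$schema_version), MODEL_SCHEMA_VERSION)) {
    stop("unsupported model schema version: ", obj$schema_version)
  }
  if (identical(obj$payload$type, "linear")) {
    payload <- list(type = "linear", family = obj$payload$family,
                    coef = unlist(obj$payload$coef),
                    intercept = obj$payload$intercept)
    if (is.null(payload$coef)) {
      payload$coef <- stats::setNames(numeric(0), character(0))
    }
  } else {
    payload <- unserialize(jsonlite::base64_dec(obj$payload$blob))
  }
  enc <- obj$encoder
  if (!is.null(enc) && !is.null(enc$energy_P)) {
    m <- enc$energy_P
    if (!is.matrix(m)) m <- do.call(rbind, lapply(m, unlist))
    dimnames(m) <- list(AA_STANDARD, AA_STANDARD)
    enc$energy_P <- m
  }
  structure(list(
    features = as.character(obj$features),
    center = unlist(obj$center)[as.character(obj$features)],
    scale = unlist(obj$scale)[as.character(obj$features)],
    payload = payload,
    threshold = obj$threshold,
    performance = obj$performance,
    signature_alternates = obj$signature_alternates,
    provenance = obj$provenance,
    encoder = enc
  ), class = "trained_model")
}
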