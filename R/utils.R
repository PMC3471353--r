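# Shared vocabulary IRIs and small helpers.

NS_RDF  <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
NS_RDFS <- "http://www.w3.org/2000/01/rdf-schema#"
NS_OWL  <- "http://www.w3.org/2002/07/owl#"
NS_SKOS <- "http://www.w3.org/2004/02/skos/core#"
NS_DC   <- "http://purl.org/dc/elements/1.1/"
NS_DCT  <- "http://purl.org/dc/terms/"
NS_XSD  <- "http://www.w3.org/2001/XMLSchema#"

IRI_RDF_TYPE <- paste0(NS_RDF, "type")

#' Default annotation properties treated as term labels
#' @return Character vector of absolute property IRIs.
#' @export
default_label_properties <- function() {
  c(paste0(NS_RDFS, "label"),
    paste0(NS_SKOS, "prefLabel"),
    paste0(NS_DC, "title"),
    paste0(NS_DCT, "title"))
}

#' Default annotation properties treated as term descriptions
#' @return Character vector of absolute property IRIs.
#' @export
default_description_properties <- function() {
  c(paste0(NS_RDFS, "comment"),
    paste0(NS_DC, "description"),
    paste0(NS_DCT, "description"),
    paste0(NS_SKOS, "definition"))
}

# Local name of an IRI: everything after the last '#', '/' or ':'.
iri_local_name <- function(iri) {
  out <- sub(".*[#/:]", "", iri)
  ifelse(nzchar(out), out, iri)
}

is_absolute_iri <- function(x) {
  is.character(x) & nzchar(x) & grepl("^[A-Za-z][A-Za-z0-9+.-]*:", x)
}

# Case-insensitive fold used by all matching; R's tolower handles the
# Latin-1/Latin Extended range the fixtures use.
casefold_q <- function(x) tolower(x)

# Run an expression with a fixed RNG seed without disturbing the caller's
# RNG state.
with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

empty_pairs <- function() {
  data.frame(text = character(), lang = character(), stringsAsFactors = FALSE)
}

# Bind (text, lang) pairs dropping exact duplicates, preserving first-seen order.
merge_pairs <- function(a, b) {
  out <- rbind(a, b)
  if (nrow(out) == 0) return(empty_pairs())
  out <- out[!duplicated(paste0(out$text, "\r", out$lang)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
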