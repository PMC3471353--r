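# Minimal RDF document reader: Turtle and RDF/XML, returning a flat triple
# table. Covers the subset of both syntaxes used by ontology documents that
# declare properties, classes and individuals and annotate them with
# language-tagged literals. No RDF toolkit ships with this R stack, so the
# reader lives here; RDF/XML goes through xml2.

#' Read an RDF document into a triple table
#'
#' Parses a Turtle (`.ttl`) or RDF/XML (`.owl`, `.rdf`, `.xml`) document and
#' returns its triples in a flat data frame. The syntax is chosen from the
#' file extension, or sniffed from the content when `text` is given or the
#' extension is unknown.
#'
#' @param path Path to a local file, or a `file://` IRI.
#' @param text Document content as a single string (alternative to `path`).
#' @param format One of `"auto"`, `"turtle"`, `"rdfxml"`.
#' @return A data frame with columns `subject`, `predicate`, `object`
#'   (character), `is_literal` (logical) and `lang` (character, `""` when
#'   untagged or not a literal).
#' @export
read_rdf <- function(path = NULL, text = NULL, format = "auto") {
  stopifnot(xor(is.null(path), is.null(text)))
  src <- path %||% "<text>"
  if (!is.null(path)) {
    path <- sub("^file://", "", path)
    if (!file.exists(path)) {
      stop("cannot read RDF document: ", src, call. = FALSE)
    }
    text <- paste(readLines(path, encoding = "UTF-8", warn = FALSE),
                  collapse = "\n")
  }
  if (format == "auto") {
    format <- guess_rdf_format(src, text)
  }
  tryCatch(
    switch(format,
      turtle = parse_turtle(text),
      rdfxml = parse_rdfxml(text),
      stop("unknown RDF format: ", format)
    ),
    error = function(e) {
      stop("failed to parse RDF document ", src, ": ", conditionMessage(e),
           call. = FALSE)
    }
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

guess_rdf_format <- function(src, text) {
  ext <- tolower(sub(".*\\.", "", src))
  if (ext %in% c("ttl", "turtle", "n3", "nt")) return("turtle")
  if (ext %in% c("owl", "rdf", "xml")) return("rdfxml")
  if (grepl("^\\s*(<\\?xml|<rdf:RDF|<!--)", text)) "rdfxml" else "turtle"
}

empty_triples <- function() {
  data.frame(subject = character(), predicate = character(),
             object = character(), is_literal = logical(),
             lang = character(), stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------
# Turtle

# Lexer: IRIREF, PNAME, STRING (with optional @lang / ^^datatype), 'a',
# punctuation, @prefix/@base directives. Comments run # to end of line.
ttl_scan <- function(text) {
  toks <- list()
  n <- nchar(text)
  i <- 1L
  push <- function(type, value) toks[[length(toks) + 1L]] <<- list(type = type, value = value)
  while (i <= n) {
    rest <- substr(text, i, n)
    ws <- regmatches(rest, regexpr("^\\s+", rest))
    if (length(ws) == 1) { i <- i + nchar(ws); next }
    ch <- substr(text, i, i)
    if (ch == "#") {
      nl <- regexpr("\n", substr(text, i, n))
      i <- if (nl < 0) n + 1L else i + nl
      next
    }
    m <- regmatches(rest, regexpr("^<[^<>\"{}|^`\\\\ ]*>", rest))
    if (length(m) == 1) {
      push("iri", substr(m, 2, nchar(m) - 1)); i <- i + nchar(m); next
    }
    m <- regmatches(rest, regexpr('^"(?:[^"\\\\]|\\\\.)*"', rest))
    if (length(m) == 1) {
      i <- i + nchar(m)
      val <- ttl_unescape(substr(m, 2, nchar(m) - 1))
      lang <- ""
      rest2 <- substr(text, i, n)
      lm <- regmatches(rest2, regexpr("^@[A-Za-z]+(-[A-Za-z0-9]+)*", rest2))
      if (length(lm) == 1) {
        lang <- substr(lm, 2, nchar(lm)); i <- i + nchar(lm)
      } else {
        dm <- regmatches(rest2, regexpr("^\\^\\^(<[^>]*>|[A-Za-z_][\\w.-]*:[\\w.-]*)", rest2))
        if (length(dm) == 1) i <- i + nchar(dm)  # datatype recorded nowhere
      }
      push("literal", c(val, lang)); next
    }
    m <- regmatches(rest, regexpr("^@(prefix|base)\\b", rest, ignore.case = TRUE))
    if (length(m) == 1) {
      push("directive", tolower(substr(m, 2, nchar(m)))); i <- i + nchar(m); next
    }
    m <- regmatches(rest, regexpr("^(PREFIX|BASE)\\b", rest, ignore.case = TRUE))
    if (length(m) == 1) {
      push("directive", tolower(m)); i <- i + nchar(m); next
    }
    if (ch %in% c(".", ";", ",", "[", "]", "(", ")")) {
      push("punct", ch); i <- i + 1L; next
    }
    m <- regmatches(rest, regexpr("^[A-Za-z_][A-Za-z0-9_.-]*:[A-Za-z0-9_.-]*|^:[A-Za-z0-9_.-]*", rest))
    if (length(m) == 1) {
      m <- sub("\\.$", "", m)  # trailing dot is statement punctuation
      push("pname", m); i <- i + nchar(m); next
    }
    if (grepl("^a([\\s.;,]|$)", rest, perl = TRUE)) {
      push("a", "a"); i <- i + 1L; next
    }
    m <- regmatches(rest, regexpr("^[+-]?[0-9]+(\\.[0-9]+)?([eE][+-]?[0-9]+)?", rest))
    if (length(m) == 1) {
      push("literal", c(m, "")); i <- i + nchar(m); next
    }
    m <- regmatches(rest, regexpr("^(true|false)\\b", rest))
    if (length(m) == 1) {
      push("literal", c(m, "")); i <- i + nchar(m); next
    }
    stop("unexpected character '", ch, "' at offset ", i - 1L)
  }
  toks
}

ttl_unescape <- function(s) {
  if (!grepl("\\\\", s)) return(s)
  s <- gsub('\\\\"', '"', s)
  s <- gsub("\\\\n", "\n", s)
  s <- gsub("\\\\t", "\t", s)
  s <- gsub("\\\\r", "\r", s)
  gsub("\\\\\\\\", "\\\\", s)
}

parse_turtle <- function(text) {
  toks <- ttl_scan(text)
  prefixes <- character()
  rows <- list()
  i <- 1L
  n <- length(toks)
  peek <- function() if (i <= n) toks[[i]] else NULL
  take <- function() { t <- toks[[i]]; i <<- i + 1L; t }
  expect <- function(type) {
    t <- peek()
    if (is.null(t) || t$type != type) {
      stop("expected ", type, " near token ", i)
    }
    take()
  }
  resolve <- function(tok) {
    if (tok$type == "iri") return(tok$value)
    if (tok$type == "a") return(IRI_RDF_TYPE)
    if (tok$type == "pname") {
      colon <- regexpr(":", tok$value, fixed = TRUE)
      pfx <- substr(tok$value, 1, colon - 1)
      local <- substr(tok$value, colon + 1, nchar(tok$value))
      if (!pfx %in% names(prefixes)) stop("undeclared prefix '", pfx, ":'")
      return(paste0(prefixes[[pfx]], local))
    }
    stop("expected IRI or prefixed name, got ", tok$type)
  }
  emit <- function(s, p, o) {
    if (o$type == "literal") {
      rows[[length(rows) + 1L]] <<- data.frame(
        subject = s, predicate = p, object = o$value[1],
        is_literal = TRUE, lang = o$value[2], stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <<- data.frame(
        subject = s, predicate = p, object = resolve(o),
        is_literal = FALSE, lang = "", stringsAsFactors = FALSE)
    }
  }
  while (i <= n) {
    t <- peek()
    if (t$type == "directive") {
      take()
      if (t$value == "prefix") {
        pn <- expect("pname")
        if (!grepl(":$", pn$value)) stop("malformed prefix declaration")
        iri <- expect("iri")
        prefixes[[sub(":$", "", pn$value)]] <- iri$value
      } else {
        expect("iri")  # @base: accepted, relative IRIs unsupported
      }
      if (!is.null(peek()) && peek()$type == "punct" && peek()$value == ".") take()
      next
    }
    subj <- resolve(take())
    repeat {
      pred <- resolve(take())
      repeat {
        emit(subj, pred, take())
        t2 <- peek()
        if (!is.null(t2) && t2$type == "punct" && t2$value == ",") { take(); next }
        break
      }
      t2 <- peek()
      if (!is.null(t2) && t2$type == "punct" && t2$value == ";") {
        take()
        t3 <- peek()
        # tolerate trailing ';' before '.'
        if (!is.null(t3) && t3$type == "punct" && t3$value == ".") break
        next
      }
      break
    }
    t2 <- peek()
    if (is.null(t2) || t2$type != "punct" || t2$value != ".") {
      stop("expected '.' terminating statement near token ", i)
    }
    take()
  }
  if (length(rows) == 0) return(empty_triples())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# ---------------------------------------------------------------------------
# RDF/XML

parse_rdfxml <- function(text) {
  doc <- xml2::read_xml(text)
  ns <- xml2::xml_ns(doc)
  rows <- list()
  for (node in xml2::xml_children(doc)) {
    rows <- c(rows, rdfxml_node(node, ns))
  }
  if (length(rows) == 0) return(empty_triples())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

rdfxml_expand <- function(qname, ns) {
  colon <- regexpr(":", qname, fixed = TRUE)
  if (colon < 0) stop("unprefixed XML element '", qname, "'")
  pfx <- substr(qname, 1, colon - 1)
  local <- substr(qname, colon + 1, nchar(qname))
  base <- unname(ns[[pfx]])
  if (is.null(base)) stop("unknown XML namespace prefix '", pfx, "'")
  paste0(base, local)
}

# Fetch an attribute by qualified name; xml2 may report it with or without
# its namespace prefix depending on how the document declares it.
rdfxml_attr <- function(node, name) {
  at <- xml2::xml_attrs(node)
  local <- sub(".*:", "", name)
  hit <- which(names(at) == name | names(at) == local)
  if (length(hit) > 0) unname(at[[hit[1]]]) else NA_character_
}

rdfxml_lang <- function(node) {
  cur <- node
  repeat {
    if (inherits(cur, "xml_missing") || length(cur) == 0) return("")
    lang <- rdfxml_attr(cur, "xml:lang")
    if (!is.na(lang)) return(lang)
    parent <- tryCatch(xml2::xml_parent(cur), error = function(e) NULL)
    if (is.null(parent)) return("")
    cur <- parent
  }
}

rdfxml_node <- function(node, ns) {
  rows <- list()
  about <- rdfxml_attr(node, "rdf:about")
  if (is.na(about)) about <- rdfxml_attr(node, "rdf:ID")
  if (is.na(about)) return(rows)
  elem <- rdfxml_expand(xml2::xml_name(node, ns), ns)
  row <- function(p, o, lit, lang) {
    data.frame(subject = about, predicate = p, object = o,
               is_literal = lit, lang = lang, stringsAsFactors = FALSE)
  }
  if (elem != paste0(NS_RDF, "Description")) {
    rows[[length(rows) + 1L]] <- row(IRI_RDF_TYPE, elem, FALSE, "")
  }
  for (child in xml2::xml_children(node)) {
    pred <- rdfxml_expand(xml2::xml_name(child, ns), ns)
    res <- rdfxml_attr(child, "rdf:resource")
    if (!is.na(res)) {
      rows[[length(rows) + 1L]] <- row(pred, res, FALSE, "")
    } else if (length(xml2::xml_children(child)) == 0) {
      rows[[length(rows) + 1L]] <-
        row(pred, xml2::xml_text(child), TRUE, rdfxml_lang(child))
    }
    # nested node elements (rdf:parseType etc.) are outside the subset
  }
  rows
}
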