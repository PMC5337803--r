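# OWL → gazetteer conversion. The sentiment pipeline uses an ontology only
# as a term source: class labels plus any annotation property whose local
# name contains "synonym". Axioms, object properties and the class hierarchy
# are ignored by design.

#' Convert an OWL ontology into a flat gazetteer term list
#'
#' Extracts, for every resource with an IRI, its `rdfs:label` values and the
#' values of any annotation property whose local name contains "synonym"
#' (case-insensitive; covers e.g. `hasExactSynonym`, `hasRelatedSynonym`).
#' RDF/XML is parsed with \pkg{xml2}; Turtle input goes through a small
#' built-in reader covering the prefix/semicolon/comma triple subset that
#' label and synonym annotations use.
#'
#' @param path OWL file, RDF/XML (`.owl`, `.rdf`, `.xml`) or Turtle
#'   (`.ttl`); anything else is sniffed (leading `<?xml` or `<rdf:RDF` means
#'   RDF/XML).
#' @param out optional path; when given, the result is also written as a
#'   gazetteer TSV.
#' @return data.frame with `concept_id` (the IRI) and `term`, one row per
#'   label/synonym.
#' @export
owl_to_gazetteer <- function(path, out = NULL) {
  if (!file.exists(path)) stop("ontology file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  is_xml <- if (ext %in% c("owl", "rdf", "xml")) {
    TRUE
  } else if (ext == "ttl") {
    FALSE
  } else {
    head_txt <- paste(readLines(path, n = 5L, warn = FALSE), collapse = " ")
    grepl("<\\?xml|<rdf:RDF", head_txt)
  }
  terms <- if (is_xml) owl_terms_rdfxml(path) else owl_terms_turtle(path)
  if (!nrow(terms)) stop("zero terms extractable from ontology: ", path)
  terms <- unique(terms)
  rownames(terms) <- NULL
  if (!is.null(out)) write_gazetteer_tsv(terms, out)
  terms
}

owl_terms_rdfxml <- function(path) {
  doc <- xml2::read_xml(path)
  nodes <- xml2::xml_find_all(doc, "//*[@rdf:about or @rdf:ID]")
  rows <- list()
  for (node in nodes) {
    attrs <- xml2::xml_attrs(node)
    hit <- grepl("(^|:)(about|ID)$", names(attrs))
    if (!any(hit)) next
    iri <- unname(attrs[hit][[1L]])
    if (is.na(iri) || !nzchar(iri)) next
    for (child in xml2::xml_children(node)) {
      local <- xml2::xml_name(child)  # prefix already stripped
      if (identical(local, "label") || grepl("synonym", local, ignore.case = TRUE)) {
        value <- trimws(xml2::xml_text(child))
        if (nzchar(value)) {
          rows[[length(rows) + 1L]] <- data.frame(
            concept_id = iri, term = value, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(concept_id = character(), term = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

# --- minimal Turtle reader -------------------------------------------------
# Supports: @prefix / PREFIX declarations, IRIs in <>, prefixed names,
# "literal" objects with optional @lang or ^^type, statement separators
# '.', predicate lists with ';', object lists with ','. Blank nodes and
# multi-line literals are not needed for label/synonym extraction and are
# skipped.

ttl_tokenize <- function(text) {
  tokens <- list()
  i <- 1L
  n <- nchar(text)
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  ws <- c(" ", "\t", "\n", "\r")
  name_stop <- c(ws, ";", ",")
  while (i <= n) {
    ch <- chars[[i]]
    if (ch %in% ws) { i <- i + 1L; next }
    if (ch == "#") {  # comment to end of line
      while (i <= n && chars[[i]] != "\n") i <- i + 1L
      next
    }
    if (ch == "<") {
      j <- i
      while (j <= n && chars[[j]] != ">") j <- j + 1L
      tokens[[length(tokens) + 1L]] <- list(type = "iri",
                                            value = substr(text, i + 1L, j - 1L))
      i <- j + 1L
      next
    }
    if (ch == "\"") {
      j <- i + 1L
      val <- character()
      while (j <= n) {
        cj <- chars[[j]]
        if (cj == "\\" && j < n) {
          nxt <- chars[[j + 1L]]
          val <- c(val, switch(nxt, n = "\n", t = "\t", r = "\r", nxt))
          j <- j + 2L
        } else if (cj == "\"") {
          break
        } else {
          val <- c(val, cj)
          j <- j + 1L
        }
      }
      i <- j + 1L
      # swallow @lang or ^^<type> suffix
      while (i <= n && !chars[[i]] %in% c(name_stop, ".")) i <- i + 1L
      tokens[[length(tokens) + 1L]] <- list(type = "literal",
                                            value = paste(val, collapse = ""))
      next
    }
    if (ch %in% c(".", ";", ",")) {
      tokens[[length(tokens) + 1L]] <- list(type = "punct", value = ch)
      i <- i + 1L
      next
    }
    j <- i
    while (j <= n && !chars[[j]] %in% name_stop &&
           !(chars[[j]] == "." && (j == n || chars[[j + 1L]] %in% ws))) {
      j <- j + 1L
    }
    tokens[[length(tokens) + 1L]] <- list(type = "name",
                                          value = substr(text, i, j - 1L))
    i <- j
  }
  tokens
}

owl_terms_turtle <- function(path) {
  text <- paste(readLines(path, encoding = "UTF-8", warn = FALSE),
                collapse = "\n")
  tokens <- ttl_tokenize(text)
  prefixes <- list()
  rows <- list()
  expand <- function(tok) {
    if (tok$type == "iri") return(tok$value)
    v <- tok$value
    colon <- regexpr(":", v, fixed = TRUE)
    if (colon == -1L) return(v)
    pfx <- substr(v, 1L, colon)
    local <- substr(v, colon + 1L, nchar(v))
    base <- prefixes[[pfx]]
    if (is.null(base)) v else paste0(base, local)
  }
  i <- 1L
  subject <- NULL
  predicate <- NULL
  while (i <= length(tokens)) {
    tok <- tokens[[i]]
    if (tok$type == "name" && tolower(tok$value) %in% c("@prefix", "prefix")) {
      if (i + 2L <= length(tokens)) {
        prefixes[[tokens[[i + 1L]]$value]] <- tokens[[i + 2L]]$value
      }
      i <- i + 3L
      if (i <= length(tokens) && tokens[[i]]$type == "punct" &&
          tokens[[i]]$value == ".") i <- i + 1L
      subject <- NULL
      next
    }
    if (tok$type == "punct") {
      if (tok$value == ".") { subject <- NULL; predicate <- NULL }
      if (tok$value == ";") predicate <- NULL
      i <- i + 1L
      next
    }
    if (is.null(subject)) {
      subject <- expand(tok)
    } else if (is.null(predicate)) {
      predicate <- expand(tok)
      if (tok$type == "name" && tok$value == "a") predicate <- "rdf:type"
    } else {
      local <- sub(".*[/#:]", "", predicate)
      if (tok$type == "literal" &&
          (identical(local, "label") ||
             grepl("synonym", local, ignore.case = TRUE))) {
        rows[[length(rows) + 1L]] <- data.frame(
          concept_id = subject, term = tok$value, stringsAsFactors = FALSE)
      }
      # predicate kept as-is: comma-separated object lists reuse it,
      # ';' and '.' punctuation above reset it
    }
    i <- i + 1L
  }
  if (!length(rows)) {
    return(data.frame(concept_id = character(), term = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
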