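# RDF triple view and canonical Turtle I/O.
#
# The KB serializes to standard OWL-RDF: classes as owl:Class nodes with
# rdfs:label / definition-source annotations, asserted parents as
# rdfs:subClassOf edges, and the pattern expressions as owl:Restriction /
# owl:intersectionOf / owl:unionOf blank-node structures. Age intervals are
# datatype facet restrictions (xsd:minInclusive / xsd:maxInclusive) on
# xsd:decimal; occurrences are owl:hasValue decimals. Output is canonical
# (fixed prefix block, sorted subjects/predicates/objects), so identical KBs
# serialize byte-identically.
#
# No RDF library ships with this R stack, so the writer and the reader for
# this Turtle subset are implemented here.

TTL_PREFIXES <- c(
  obo  = "http://purl.obolibrary.org/obo/",
  owl  = "http://www.w3.org/2002/07/owl#",
  rdf  = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
  rdfs = "http://www.w3.org/2000/01/rdf-schema#",
  xsd  = "http://www.w3.org/2001/XMLSchema#"
)

node_iri <- function(curie) list(kind = "iri", value = curie)
node_blank <- function(id) list(kind = "blank", value = id)
node_lit <- function(value, dt = NA_character_)
  list(kind = "literal", value = as.character(value), dt = dt)

new_triple_view <- function(triples) structure(list(triples = triples),
                                               class = "vae_triples")

#' @export
print.vae_triples <- function(x, ...) {
  cat(sprintf("<vae_triples> %d triples\n", length(x$triples)))
  invisible(x)
}

#' Render a knowledge base as an RDF triple view
#'
#' @param kb A `vae_kb`.
#' @return A `vae_triples` object: a list of (subject, predicate, object)
#'   triples over IRI, blank-node, and typed-literal nodes.
#' @export
to_triples <- function(kb) {
  st <- new.env(parent = emptyenv())
  st$triples <- list()
  st$n_blank <- 0L
  add <- function(s, p, o) st$triples[[length(st$triples) + 1L]] <-
    list(s = s, p = p, o = o)
  fresh_blank <- function() {
    st$n_blank <- st$n_blank + 1L
    node_blank(sprintf("_:b%d", st$n_blank))
  }
  rdf_list <- function(nodes) {
    if (!length(nodes)) return(node_iri("rdf:nil"))
    head <- fresh_blank()
    cur <- head
    for (i in seq_along(nodes)) {
      add(cur, node_iri("rdf:first"), nodes[[i]])
      nxt <- if (i < length(nodes)) fresh_blank() else node_iri("rdf:nil")
      add(cur, node_iri("rdf:rest"), nxt)
      cur <- nxt
    }
    head
  }
  expr_node <- function(e) {
    switch(e$type,
      named = node_iri(paste0("obo:", e$id)),
      and = {
        b <- fresh_blank()
        add(b, node_iri("rdf:type"), node_iri("owl:Class"))
        add(b, node_iri("owl:intersectionOf"),
            rdf_list(lapply(e$args, expr_node)))
        b
      },
      or = {
        b <- fresh_blank()
        add(b, node_iri("rdf:type"), node_iri("owl:Class"))
        add(b, node_iri("owl:unionOf"), rdf_list(lapply(e$args, expr_node)))
        b
      },
      some = {
        b <- fresh_blank()
        add(b, node_iri("rdf:type"), node_iri("owl:Restriction"))
        add(b, node_iri("owl:onProperty"), node_iri(paste0("obo:", e$property)))
        add(b, node_iri("owl:someValuesFrom"), expr_node(e$filler))
        b
      },
      interval = {
        d <- fresh_blank()
        add(d, node_iri("rdf:type"), node_iri("rdfs:Datatype"))
        add(d, node_iri("owl:onDatatype"), node_iri("xsd:decimal"))
        facets <- list()
        fmin <- fresh_blank()
        add(fmin, node_iri("xsd:minInclusive"),
            node_lit(format_decimal(e$min), "xsd:decimal"))
        facets[[1L]] <- fmin
        if (is.finite(e$max)) {
          fmax <- fresh_blank()
          add(fmax, node_iri("xsd:maxInclusive"),
              node_lit(format_decimal(e$max), "xsd:decimal"))
          facets[[2L]] <- fmax
        }
        add(d, node_iri("owl:withRestrictions"), rdf_list(facets))
        b <- fresh_blank()
        add(b, node_iri("rdf:type"), node_iri("owl:Restriction"))
        add(b, node_iri("owl:onProperty"), node_iri(paste0("obo:", e$property)))
        add(b, node_iri("owl:someValuesFrom"), d)
        b
      },
      value = {
        b <- fresh_blank()
        add(b, node_iri("rdf:type"), node_iri("owl:Restriction"))
        add(b, node_iri("owl:onProperty"), node_iri(paste0("obo:", e$property)))
        add(b, node_iri("owl:hasValue"),
            node_lit(format_decimal(e$value), "xsd:decimal"))
        b
      },
      vaekb_abort("parse", sprintf("unknown expression type %s", e$type))
    )
  }

  for (pid in sort(names(kb$properties))) {
    p <- kb$properties[[pid]]
    s <- node_iri(paste0("obo:", pid))
    add(s, node_iri("rdf:type"),
        node_iri(switch(p$kind,
                        object = "owl:ObjectProperty",
                        datatype = "owl:DatatypeProperty",
                        "owl:AnnotationProperty")))
    add(s, node_iri("rdfs:label"), node_lit(p$label))
  }
  for (cid in sort(names(kb$classes))) {
    cls <- kb$classes[[cid]]
    s <- node_iri(paste0("obo:", cid))
    add(s, node_iri("rdf:type"), node_iri("owl:Class"))
    add(s, node_iri("rdfs:label"), node_lit(cls$label))
    if (!is.null(cls$definition))
      add(s, node_iri("obo:IAO_0000115"), node_lit(cls$definition))
    if (!is.null(cls$definition_source))
      add(s, node_iri("obo:IAO_0000119"), node_lit(cls$definition_source))
    for (par in sort(cls$parents))
      add(s, node_iri("rdfs:subClassOf"), node_iri(paste0("obo:", par)))
    if (!is.null(cls$expression)) {
      pred <- if (identical(cls$style, "equivalent")) "owl:equivalentClass"
              else "rdfs:subClassOf"
      add(s, node_iri(pred), expr_node(cls$expression))
    }
  }
  new_triple_view(st$triples)
}

# ---------------------------------------------------------------------------
# canonical writer

ttl_escape <- function(s) {
  s <- gsub("\\", "\\\\", s, fixed = TRUE)
  s <- gsub("\"", "\\\"", s, fixed = TRUE)
  s <- gsub("\n", "\\n", s, fixed = TRUE)
  s
}

render_iri <- function(curie) {
  if (grepl("^[A-Za-z][A-Za-z0-9]*:", curie) &&
      sub(":.*$", "", curie) %in% names(TTL_PREFIXES)) curie
  else paste0("<", curie, ">")
}

render_literal <- function(node) {
  base <- paste0("\"", ttl_escape(node$value), "\"")
  if (!is.na(node$dt)) paste0(base, "^^", render_iri(node$dt)) else base
}

#' Write a triple view (or a KB) as canonical Turtle
#'
#' Output is deterministic: fixed prefix block, named subjects sorted, blank
#' structures inlined with `[...]` / `(...)` syntax, predicates and objects
#' sorted (`rdf:type` first). Writing the same KB twice produces identical
#' bytes.
#'
#' @param view A `vae_triples` view from [to_triples()], or a `vae_kb`
#'   (converted automatically).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_turtle <- function(view, path) {
  if (inherits(view, "vae_kb")) view <- to_triples(view)
  triples <- view$triples
  by_subject <- list()
  obj_refs <- integer() # blank id -> number of times used as object
  for (t in triples) {
    skey <- t$s$value
    by_subject[[skey]] <- c(by_subject[[skey]], list(t))
    if (t$o$kind == "blank")
      obj_refs[t$o$value] <- sum(obj_refs[t$o$value], 1, na.rm = TRUE)
  }
  blank_ids <- unique(vapply(triples, function(t)
    if (t$s$kind == "blank") t$s$value else NA_character_, character(1)))
  blank_ids <- blank_ids[!is.na(blank_ids)]
  inlineable <- blank_ids[vapply(blank_ids, function(b)
    isTRUE(obj_refs[b] == 1), logical(1))]

  is_list_node <- function(skey) {
    ts <- by_subject[[skey]]
    !is.null(ts) && length(ts) == 2L &&
      setequal(vapply(ts, function(t) t$p$value, character(1)),
               c("rdf:first", "rdf:rest"))
  }
  render_obj <- function(node, depth) {
    if (node$kind == "iri") return(render_iri(node$value))
    if (node$kind == "literal") return(render_literal(node))
    b <- node$value
    if (!(b %in% inlineable)) return(b) # shared blank: keep the label
    if (is_list_node(b)) {
      items <- character()
      cur <- b
      repeat {
        ts <- by_subject[[cur]]
        first <- ts[[which(vapply(ts, function(t) t$p$value, character(1)) ==
                             "rdf:first")]]$o
        rest <- ts[[which(vapply(ts, function(t) t$p$value, character(1)) ==
                            "rdf:rest")]]$o
        items <- c(items, render_obj(first, depth + 1L))
        if (rest$kind == "iri" && rest$value == "rdf:nil") break
        cur <- rest$value
      }
      return(paste0("( ", paste(items, collapse = " "), " )"))
    }
    ts <- by_subject[[b]]
    ts <- ts[order_po(ts)]
    inner <- vapply(ts, function(t)
      paste(render_iri(t$p$value), render_obj(t$o, depth + 1L)), character(1))
    paste0("[ ", paste(inner, collapse = " ; "), " ]")
  }
  order_po <- function(ts) {
    p <- vapply(ts, function(t) t$p$value, character(1))
    o <- vapply(ts, function(t)
      if (t$o$kind == "literal") t$o$value else t$o$value, character(1))
    prank <- ifelse(p == "rdf:type", paste0("0", p), paste0("1", p))
    order(prank, o, method = "radix")
  }
  consumed <- new.env(parent = emptyenv())
  mark_consumed <- function(b) {
    consumed[[b]] <- TRUE
    for (t in by_subject[[b]])
      if (t$o$kind == "blank" && t$o$value %in% inlineable)
        mark_consumed(t$o$value)
  }
  for (b in inlineable) mark_consumed(b) # all inlined blanks never top-level?
  # top-level subjects: named IRIs plus blank nodes that are not inlined
  named_subjects <- sort(unique(vapply(triples, function(t)
    if (t$s$kind == "iri") t$s$value else NA_character_, character(1))))
  named_subjects <- named_subjects[!is.na(named_subjects)]
  floating <- setdiff(blank_ids, inlineable)

  lines <- c(
    vapply(names(TTL_PREFIXES), function(p)
      sprintf("@prefix %s: <%s> .", p, TTL_PREFIXES[[p]]), character(1)),
    ""
  )
  emit_subject <- function(skey, label) {
    ts <- by_subject[[skey]]
    ts <- ts[order_po(ts)]
    body <- vapply(ts, function(t)
      paste(render_iri(t$p$value), render_obj(t$o, 1L)), character(1))
    c(paste0(label, " ", body[1L],
             if (length(body) > 1L) " ;" else " ."),
      if (length(body) > 1L)
        paste0("    ", body[-1L],
               c(rep(" ;", length(body) - 2L), " .")))
  }
  for (skey in named_subjects)
    lines <- c(lines, emit_subject(skey, render_iri(skey)), "")
  for (skey in sort(floating))
    lines <- c(lines, emit_subject(skey, skey), "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# reader

ttl_tokenize <- function(text) {
  tokens <- list(); i <- 1L; n <- nchar(text)
  push <- function(type, value)
    tokens[[length(tokens) + 1L]] <<- list(type = type, value = value)
  line <- 1L
  while (i <= n) {
    ch <- substr(text, i, i)
    if (ch == "\n") { line <- line + 1L; i <- i + 1L; next }
    if (grepl("[[:space:]]", ch)) { i <- i + 1L; next }
    if (ch == "#") { while (i <= n && substr(text, i, i) != "\n") i <- i + 1L; next }
    if (ch %in% c(".", ";", ",", "[", "]", "(", ")")) {
      push("punct", ch); i <- i + 1L; next
    }
    rest <- substr(text, i, n)
    if (ch == "<") {
      m <- regmatches(rest, regexpr("^<[^>]*>", rest))
      if (!length(m)) vaekb_abort("parse",
                                  sprintf("line %d: unterminated IRI", line))
      push("iri", substr(m, 2L, nchar(m) - 1L)); i <- i + nchar(m); next
    }
    if (ch == "\"") {
      m <- regmatches(rest, regexpr('^"(\\\\.|[^"\\\\])*"', rest))
      if (!length(m)) vaekb_abort("parse",
                                  sprintf("line %d: unterminated string", line))
      raw <- substr(m, 2L, nchar(m) - 1L)
      val <- gsub("\\\\n", "\n", raw)
      val <- gsub('\\\\"', '"', val)
      val <- gsub("\\\\\\\\", "\\\\", val)
      i <- i + nchar(m)
      dt <- NA_character_
      if (substr(text, i, i + 1L) == "^^") {
        i <- i + 2L
        rest2 <- substr(text, i, n)
        m2 <- regmatches(rest2, regexpr("^(<[^>]*>|[A-Za-z][A-Za-z0-9_]*:[A-Za-z0-9_]+)",
                                        rest2))
        if (!length(m2)) vaekb_abort("parse",
                                     sprintf("line %d: bad datatype", line))
        dt <- if (startsWith(m2, "<")) substr(m2, 2L, nchar(m2) - 1L) else m2
        i <- i + nchar(m2)
      }
      push("literal", list(value = val, dt = dt)); next
    }
    m <- regmatches(rest, regexpr("^@prefix", rest))
    if (length(m)) { push("at_prefix", m); i <- i + nchar(m); next }
    m <- regmatches(rest, regexpr("^_:[A-Za-z0-9]+", rest))
    if (length(m)) { push("blank", m); i <- i + nchar(m); next }
    m <- regmatches(rest, regexpr("^[+-]?[0-9]+(\\.[0-9]+)?", rest))
    if (length(m)) {
      push("number", m); i <- i + nchar(m); next
    }
    m <- regmatches(rest,
                    regexpr("^[A-Za-z][A-Za-z0-9_.-]*:[A-Za-z0-9_.-]*", rest))
    if (length(m)) { push("pname", m); i <- i + nchar(m); next }
    m <- regmatches(rest, regexpr("^[A-Za-z][A-Za-z0-9_]*", rest))
    if (length(m)) { push("word", m); i <- i + nchar(m); next }
    vaekb_abort("parse", sprintf("line %d: unexpected character '%s'", line, ch))
  }
  tokens
}

#' Read a Turtle file into a triple view
#'
#' Supports the Turtle subset this package writes, plus the common standard
#' forms: `@prefix` declarations, prefixed names and full IRIs, the `a`
#' keyword, `;` / `,` predicate-object lists, `[...]` blank nodes, `(...)`
#' collections, plain and `^^`-typed string literals, and bare numbers.
#'
#' @param path Turtle file path.
#' @return A `vae_triples` view; blank nodes get fresh local ids.
#' @export
read_turtle <- function(path) {
  text <- paste(readLines(path, encoding = "UTF-8", warn = FALSE),
                collapse = "\n")
  toks <- ttl_tokenize(text)
  st <- new.env(parent = emptyenv())
  st$pos <- 1L
  st$prefixes <- character()
  st$triples <- list()
  st$n_blank <- 0L
  peek <- function() if (st$pos <= length(toks)) toks[[st$pos]] else NULL
  fail <- function(msg) vaekb_abort("parse", sprintf("turtle parse: %s", msg))
  advance <- function() {
    if (st$pos > length(toks)) fail("unexpected end of input")
    t <- toks[[st$pos]]; st$pos <- st$pos + 1L; t
  }
  add <- function(s, p, o) st$triples[[length(st$triples) + 1L]] <-
    list(s = s, p = p, o = o)
  fresh_blank <- function() {
    st$n_blank <- st$n_blank + 1L
    node_blank(sprintf("_:r%d", st$n_blank))
  }
  curie_or_iri <- function(full) {
    for (p in names(TTL_PREFIXES))
      if (startsWith(full, TTL_PREFIXES[[p]]))
        return(paste0(p, ":", substring(full, nchar(TTL_PREFIXES[[p]]) + 1L)))
    for (p in names(st$prefixes))
      if (startsWith(full, st$prefixes[[p]]))
        return(paste0(p, ":", substring(full, nchar(st$prefixes[[p]]) + 1L)))
    full
  }
  resolve_pname <- function(pn) {
    pfx <- sub(":.*$", "", pn)
    if (pfx %in% names(TTL_PREFIXES)) return(pn)
    if (pfx %in% names(st$prefixes))
      return(curie_or_iri(paste0(st$prefixes[[pfx]], sub("^[^:]*:", "", pn))))
    fail(sprintf("undeclared prefix '%s'", pfx))
  }
  parse_node <- function(tok) {
    if (tok$type == "iri") return(node_iri(curie_or_iri(tok$value)))
    if (tok$type == "pname") return(node_iri(resolve_pname(tok$value)))
    if (tok$type == "blank") return(node_blank(paste0(tok$value, "#in")))
    if (tok$type == "word" && tok$value == "a") return(node_iri("rdf:type"))
    if (tok$type == "literal")
      return(node_lit(tok$value$value,
                      if (is.na(tok$value$dt)) NA_character_
                      else curie_or_iri(tok$value$dt)))
    if (tok$type == "number") {
      dt <- if (grepl(".", tok$value, fixed = TRUE)) "xsd:decimal"
            else "xsd:integer"
      return(node_lit(tok$value, dt))
    }
    if (tok$type == "punct" && tok$value == "[") return(parse_blank_body())
    if (tok$type == "punct" && tok$value == "(") return(parse_collection())
    fail(sprintf("unexpected token '%s'", paste(tok$value, collapse = "")))
  }
  parse_object <- function() parse_node(advance())
  parse_blank_body <- function() {
    b <- fresh_blank()
    repeat {
      t <- peek()
      if (is.null(t)) fail("unterminated blank node")
      if (t$type == "punct" && t$value == "]") { advance(); break }
      pred <- parse_node(advance())
      repeat {
        add(b, pred, parse_object())
        t2 <- peek()
        if (!is.null(t2) && t2$type == "punct" && t2$value == ",") advance()
        else break
      }
      t2 <- peek()
      if (!is.null(t2) && t2$type == "punct" && t2$value == ";") advance()
    }
    b
  }
  parse_collection <- function() {
    items <- list()
    repeat {
      t <- peek()
      if (is.null(t)) fail("unterminated collection")
      if (t$type == "punct" && t$value == ")") { advance(); break }
      items[[length(items) + 1L]] <- parse_object()
    }
    if (!length(items)) return(node_iri("rdf:nil"))
    head <- fresh_blank(); cur <- head
    for (i in seq_along(items)) {
      add(cur, node_iri("rdf:first"), items[[i]])
      nxt <- if (i < length(items)) fresh_blank() else node_iri("rdf:nil")
      add(cur, node_iri("rdf:rest"), nxt)
      cur <- nxt
    }
    head
  }
  while (!is.null(peek())) {
    t <- peek()
    if (t$type == "at_prefix") {
      advance()
      pn <- advance()
      if (pn$type != "pname" && !(pn$type == "word")) fail("bad @prefix")
      pfx <- sub(":$", "", pn$value)
      iri <- advance()
      if (iri$type != "iri") fail("bad @prefix IRI")
      dot <- advance()
      if (!(dot$type == "punct" && dot$value == ".")) fail("@prefix missing '.'")
      st$prefixes[[pfx]] <- iri$value
      next
    }
    subj_tok <- advance()
    subj <- if (subj_tok$type == "punct" && subj_tok$value == "[")
      parse_blank_body() else parse_node(subj_tok)
    repeat {
      pred <- parse_node(advance())
      repeat {
        add(subj, pred, parse_object())
        t2 <- peek()
        if (!is.null(t2) && t2$type == "punct" && t2$value == ",") advance()
        else break
      }
      t2 <- peek()
      if (!is.null(t2) && t2$type == "punct" && t2$value == ";") {
        advance()
        t3 <- peek()
        if (!is.null(t3) && t3$type == "punct" && t3$value == ".") {
          advance(); break
        }
        next
      }
      if (!is.null(t2) && t2$type == "punct" && t2$value == ".") {
        advance(); break
      }
      if (is.null(t2)) break
      fail("expected '.', ';' or ',' after object")
    }
  }
  new_triple_view(st$triples)
}

# ---------------------------------------------------------------------------
# isomorphism up to blank-node renaming (blank structures are rooted/acyclic)

canonical_triple_lines <- function(view) {
  triples <- view$triples
  by_subject <- list()
  for (t in triples)
    if (t$s$kind == "blank")
      by_subject[[t$s$value]] <- c(by_subject[[t$s$value]], list(t))
  hash_cache <- new.env(parent = emptyenv())
  node_key <- function(node) {
    if (node$kind == "iri") return(paste0("<", node$value, ">"))
    if (node$kind == "literal")
      return(paste0("\"", node$value, "\"",
                    if (!is.na(node$dt)) paste0("^^", node$dt) else ""))
    b <- node$value
    hit <- hash_cache[[b]]
    if (!is.null(hit)) return(hit)
    ts <- by_subject[[b]]
    inner <- sort(vapply(ts, function(t)
      paste0(node_key(t$p), "=", node_key(t$o)), character(1)))
    key <- paste0("[", paste(inner, collapse = "|"), "]")
    hash_cache[[b]] <- key
    key
  }
  lines <- vapply(triples, function(t)
    paste(node_key(t$s), node_key(t$p), node_key(t$o)), character(1))
  sort(lines)
}

#' Test two triple views for isomorphism
#'
#' Equality of the triple multisets up to blank-node renaming (blank
#' structures are rooted and acyclic, so structural hashing is canonical).
#'
#' @param a,b `vae_triples` views.
#' @return `TRUE` or `FALSE`.
#' @export
triples_isomorphic <- function(a, b) {
  identical(canonical_triple_lines(a), canonical_triple_lines(b))
}
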