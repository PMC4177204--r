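# Analyses over a compiled KB: per-vaccine AE-variety ranking, AE frequency
# across vaccines, age-stratified occurrence summaries, the global maximum
# occurrence, and a small SPARQL-like matcher over the KB's triple view.

# half-up rounding to one decimal; reproduces e.g. 34/63 -> 54.0, 19/63 -> 30.2
round_half_up1 <- function(x) floor(x * 10 + 0.5) / 10

#' Count adverse-event varieties per vaccine
#'
#' One row per vaccine-specific `'... vaccine adverse event'` parent with the
#' number of distinct leaf VAE classes under it, descending by count, ties
#' broken alphabetically by label.
#'
#' Two modes must agree on well-formed KBs: `"structural"` counts compiled
#' associations per vaccine; `"label-convention"` replays the naming-rule
#' query (leaf labels contain `"associated"` and `"AE"`; parent labels contain
#' `"adverse event"`) over direct subclass edges.
#'
#' @param kb A compiled `vae_kb`.
#' @param mode `"structural"` or `"label-convention"`.
#' @return Data frame with columns `id`, `label`, `n_vae`.
#' @export
count_vae_per_vaccine <- function(kb, mode = c("structural", "label-convention")) {
  mode <- match.arg(mode)
  if (mode == "structural") {
    if (!length(kb$associations))
      return(data.frame(id = character(), label = character(),
                        n_vae = integer(), stringsAsFactors = FALSE))
    vacc <- vapply(kb$associations, function(a) a$vaccine, character(1))
    counts <- table(vacc)
    label <- vapply(names(counts), function(v)
      paste(kb$classes[[v]]$label, "vaccine adverse event"), character(1))
    id <- vapply(label, function(l) {
      cls <- kb_class(kb, l)
      if (is.null(cls)) NA_character_ else cls$id
    }, character(1))
    out <- data.frame(id = id, label = label,
                      n_vae = as.integer(counts),
                      stringsAsFactors = FALSE, row.names = NULL)
  } else {
    rows <- list()
    for (cid in names(kb$classes)) {
      cls <- kb$classes[[cid]]
      if (!grepl("associated", cls$label) || !grepl("AE", cls$label)) next
      for (p in cls$parents) {
        plabel <- kb$classes[[p]]$label
        if (grepl("adverse event", plabel))
          rows[[length(rows) + 1L]] <- c(p, plabel)
      }
    }
    if (!length(rows))
      return(data.frame(id = character(), label = character(),
                        n_vae = integer(), stringsAsFactors = FALSE))
    m <- do.call(rbind, rows)
    counts <- table(m[, 1])
    out <- data.frame(id = names(counts),
                      label = vapply(names(counts), function(p)
                        kb$classes[[p]]$label, character(1)),
                      n_vae = as.integer(counts),
                      stringsAsFactors = FALSE, row.names = NULL)
  }
  out <- out[order(-out$n_vae, out$label, method = "radix"), ]
  rownames(out) <- NULL
  out
}

#' Adverse-event frequency across vaccines
#'
#' For each distinct adverse-event term, the number of vaccines reporting an
#' association with it, and that count as a percent of all vaccines in the KB
#' (half-up to one decimal), descending by count.
#'
#' @param kb A compiled `vae_kb` with at least one vaccine.
#' @return Data frame with columns `ae`, `ae_label`, `n_vaccines`, `percent`.
#' @export
ae_frequency <- function(kb) {
  if (!length(kb$associations))
    vaekb_abort("empty_kb", "no vaccines in the knowledge base")
  vacc <- vapply(kb$associations, function(a) a$vaccine, character(1))
  ae <- vapply(kb$associations, function(a) a$ae, character(1))
  total <- length(unique(vacc))
  counts <- vapply(split(vacc, ae), function(v) length(unique(v)), integer(1))
  out <- data.frame(
    ae = names(counts),
    ae_label = vapply(names(counts), function(a) kb$classes[[a]]$label,
                      character(1)),
    n_vaccines = as.integer(counts),
    percent = round_half_up1(100 * counts / total),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out <- out[order(-out$n_vaccines, out$ae_label, method = "radix"), ]
  rownames(out) <- NULL
  out
}

# flatten (vaccine, ae, group) entries
assoc_entries <- function(kb) {
  rows <- list()
  for (a in kb$associations) for (g in a$groups)
    rows[[length(rows) + 1L]] <- data.frame(
      vaccine = a$vaccine, vaccine_label = a$vaccine_label,
      ae = a$ae, ae_label = a$ae_label,
      min = g$min, max = g$max, category = g$category,
      occurrence = g$occurrence, stringsAsFactors = FALSE)
  if (!length(rows))
    return(data.frame(vaccine = character(), vaccine_label = character(),
                      ae = character(), ae_label = character(),
                      min = numeric(), max = numeric(),
                      category = character(), occurrence = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows); rownames(out) <- NULL; out
}

#' Age-stratified occurrence summary
#'
#' Counts (vaccine, AE, age-group) entries and their mean occurrence per age
#' category (`senior` entries are folded into `adult` for the three-way
#' comparison) or per distinct age interval. The returned table carries the
#' attribute `child_gt_adult`: whether the mean child occurrence exceeds the
#' mean adult occurrence.
#'
#' @param kb A compiled `vae_kb`.
#' @param group_by `"category"` or `"interval"`.
#' @return Data frame with columns `group`, `n`, `mean_occurrence`.
#' @export
occurrence_by_age <- function(kb, group_by = c("category", "interval")) {
  group_by <- match.arg(group_by)
  e <- assoc_entries(kb)
  if (group_by == "category") {
    cat3 <- ifelse(e$category == "senior", "adult", e$category)
    lev <- c("child", "adult", "child-adult")
    out <- data.frame(
      group = lev,
      n = vapply(lev, function(l) sum(cat3 == l), integer(1)),
      mean_occurrence = vapply(lev, function(l) {
        v <- e$occurrence[cat3 == l]
        if (length(v)) mean(v) else NA_real_
      }, numeric(1)),
      stringsAsFactors = FALSE, row.names = NULL
    )
    ch <- out$mean_occurrence[out$group == "child"]
    ad <- out$mean_occurrence[out$group == "adult"]
    attr(out, "child_gt_adult") <-
      if (is.na(ch) || is.na(ad)) NA else ch > ad
  } else {
    key <- sprintf("%s-%s", format_decimal(e$min), format_decimal(e$max))
    lev <- unique(key[order(e$min, e$max)])
    out <- data.frame(
      group = lev,
      n = vapply(lev, function(l) sum(key == l), integer(1)),
      mean_occurrence = vapply(lev, function(l) mean(e$occurrence[key == l]),
                               numeric(1)),
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  out
}

#' Globally maximal occurrence entry
#'
#' @param kb A compiled `vae_kb` with at least one association.
#' @return One-row data frame `vaccine`, `vaccine_label`, `ae`, `ae_label`,
#'   `min`, `max`, `occurrence`; ties broken by (vaccine label, AE label).
#' @export
max_occurrence <- function(kb) {
  e <- assoc_entries(kb)
  if (!nrow(e)) vaekb_abort("empty_kb", "no associations in the knowledge base")
  e <- e[order(-e$occurrence, e$vaccine_label, e$ae_label, method = "radix"), ]
  out <- e[1L, c("vaccine", "vaccine_label", "ae", "ae_label",
                 "min", "max", "occurrence")]
  rownames(out) <- NULL
  out
}

# ---------------------------------------------------------------------------
# sparql_lite — a matcher for the query shape used over the KB's triple view.
# Supports: SELECT with plain variables and (COUNT(?x) AS ?n); basic graph
# patterns over rdfs:subClassOf (direct), rdfs:subClassOf* (reflexive-
# transitive closure) and rdfs:label; FILTER regex(?v, "re") (case-sensitive
# substring regex); GROUP BY; ORDER BY DESC/ASC; LIMIT.

OBO_BASE <- "http://purl.obolibrary.org/obo/"

# named-node projection of the triple view: subjects/objects as obo: CURIEs,
# labels as plain strings
kb_named_triples <- function(kb) {
  s <- character(); p <- character(); o <- character()
  for (cid in names(kb$classes)) {
    cls <- kb$classes[[cid]]
    s <- c(s, paste0("obo:", cid)); p <- c(p, "rdfs:label")
    o <- c(o, cls$label)
    for (par in cls$parents) {
      s <- c(s, paste0("obo:", cid)); p <- c(p, "rdfs:subClassOf")
      o <- c(o, paste0("obo:", par))
    }
  }
  data.frame(s = s, p = p, o = o, stringsAsFactors = FALSE)
}

sparql_tokenize <- function(q) {
  tokens <- list(); i <- 1L; n <- nchar(q)
  push <- function(type, value, pos)
    tokens[[length(tokens) + 1L]] <<- list(type = type, value = value, pos = pos)
  while (i <= n) {
    ch <- substr(q, i, i)
    if (grepl("[[:space:]]", ch)) { i <- i + 1L; next }
    if (ch == "#") { while (i <= n && substr(q, i, i) != "\n") i <- i + 1L; next }
    if (ch %in% c("{", "}", "(", ")", ".", ",", "*")) {
      push("punct", ch, i); i <- i + 1L; next
    }
    if (ch == "?") {
      m <- regmatches(substr(q, i, n), regexpr("^\\?[A-Za-z_][A-Za-z0-9_]*",
                                               substr(q, i, n)))
      if (!length(m)) vaekb_abort("query_parse",
                                  sprintf("bad variable at position %d", i))
      push("var", m, i); i <- i + nchar(m); next
    }
    if (ch == "<") {
      j <- regexpr(">", substr(q, i, n), fixed = TRUE)
      if (j < 0) vaekb_abort("query_parse",
                             sprintf("unterminated IRI at position %d", i))
      iri <- substr(q, i + 1L, i + j - 2L)
      push("iri", iri, i); i <- i + j; next
    }
    if (ch == "\"") {
      rest <- substr(q, i, n)
      m <- regmatches(rest, regexpr('^"(\\\\.|[^"\\\\])*"', rest))
      if (!length(m)) vaekb_abort("query_parse",
                                  sprintf("unterminated string at position %d", i))
      val <- gsub('\\\\(.)', "\\1", substr(m, 2L, nchar(m) - 1L))
      push("string", val, i); i <- i + nchar(m); next
    }
    m <- regmatches(substr(q, i, n),
                    regexpr("^[A-Za-z][A-Za-z0-9_]*(:[A-Za-z0-9_]+)?",
                            substr(q, i, n)))
    if (length(m)) {
      if (grepl(":", m, fixed = TRUE)) push("pname", m, i)
      else if (grepl("^[0-9]+$", m)) push("num", m, i)
      else push("word", m, i)
      i <- i + nchar(m); next
    }
    m <- regmatches(substr(q, i, n), regexpr("^[0-9]+", substr(q, i, n)))
    if (length(m)) { push("num", m, i); i <- i + nchar(m); next }
    vaekb_abort("query_parse", sprintf("unexpected character '%s' at position %d",
                                       ch, i))
  }
  tokens
}

# normalize an IRI or prefixed name token to internal node form
sparql_node <- function(tok) {
  if (tok$type == "iri") {
    if (startsWith(tok$value, OBO_BASE))
      return(paste0("obo:", substring(tok$value, nchar(OBO_BASE) + 1L)))
    if (tok$value == "http://www.w3.org/2000/01/rdf-schema#subClassOf")
      return("rdfs:subClassOf")
    if (tok$value == "http://www.w3.org/2000/01/rdf-schema#label")
      return("rdfs:label")
    return(tok$value)
  }
  tok$value
}

#' Evaluate a query from the supported SPARQL subset
#'
#' @param kb A `vae_kb`.
#' @param query Query text; see the package vignette for the supported
#'   grammar (SELECT / COUNT-AS / WHERE basic graph patterns over
#'   `rdfs:subClassOf`, `rdfs:subClassOf*`, `rdfs:label` / FILTER regex /
#'   GROUP BY / ORDER BY / LIMIT). IRIs may be written as
#'   `<http://purl.obolibrary.org/obo/...>` or `obo:` CURIEs.
#' @return A data frame, one column per selected variable (names without the
#'   leading `?`).
#' @export
sparql_lite <- function(kb, query) {
  toks <- sparql_tokenize(query)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[[pos]] else NULL
  advance <- function() { t <- toks[[pos]]; pos <<- pos + 1L; t }
  expect <- function(type, value = NULL) {
    t <- peek()
    if (is.null(t) || t$type != type ||
        (!is.null(value) && toupper(t$value) != toupper(value)))
      vaekb_abort("query_parse",
                  sprintf("expected %s%s at position %s",
                          type, if (is.null(value)) "" else paste0(" '", value, "'"),
                          if (is.null(t)) "end of query" else t$pos))
    advance()
  }
  is_word <- function(t, w) !is.null(t) && t$type == "word" &&
    toupper(t$value) == w

  expect("word", "SELECT")
  select <- list()
  repeat {
    t <- peek()
    if (is.null(t)) vaekb_abort("query_parse", "unexpected end of query")
    if (t$type == "var") {
      advance(); select[[length(select) + 1L]] <- list(kind = "var", var = t$value)
    } else if (t$type == "punct" && t$value == "(") {
      advance(); expect("word", "COUNT"); expect("punct", "(")
      distinct <- FALSE
      if (is_word(peek(), "DISTINCT")) { advance(); distinct <- TRUE }
      v <- expect("var")$value
      expect("punct", ")"); expect("word", "AS")
      as_var <- expect("var")$value
      expect("punct", ")")
      select[[length(select) + 1L]] <-
        list(kind = "count", var = v, as = as_var, distinct = distinct)
    } else if (is_word(t, "WHERE")) break
    else vaekb_abort("query_parse",
                     sprintf("unsupported SELECT item at position %d", t$pos))
  }
  expect("word", "WHERE"); expect("punct", "{")

  patterns <- list(); filters <- list()
  repeat {
    t <- peek()
    if (is.null(t)) vaekb_abort("query_parse", "unclosed WHERE block")
    if (t$type == "punct" && t$value == "}") { advance(); break }
    if (is_word(t, "FILTER")) {
      advance()
      fn <- advance()
      if (!(fn$type %in% c("word") && tolower(fn$value) == "regex"))
        vaekb_abort("query_parse",
                    sprintf("only FILTER regex(...) supported (position %d)", fn$pos))
      expect("punct", "(")
      v <- expect("var")$value
      expect("punct", ",")
      re <- expect("string")$value
      expect("punct", ")")
      filters[[length(filters) + 1L]] <- list(var = v, regex = re)
      next
    }
    term <- function() {
      tt <- advance()
      if (tt$type == "var") return(list(kind = "var", value = tt$value))
      if (tt$type %in% c("iri", "pname")) {
        node <- sparql_node(tt)
        star <- FALSE
        nx <- peek()
        if (!is.null(nx) && nx$type == "punct" && nx$value == "*") {
          advance(); star <- TRUE
        }
        return(list(kind = "node", value = node, star = star))
      }
      if (tt$type == "string") return(list(kind = "lit", value = tt$value))
      vaekb_abort("query_parse",
                  sprintf("unsupported term at position %d", tt$pos))
    }
    s <- term(); p <- term(); o <- term()
    if (p$kind == "node" && isTRUE(p$star) && p$value != "rdfs:subClassOf")
      vaekb_abort("query_parse", "'*' only supported on rdfs:subClassOf")
    patterns[[length(patterns) + 1L]] <- list(s = s, p = p, o = o)
    t <- peek()
    if (!is.null(t) && t$type == "punct" && t$value == ".") advance()
  }

  group_by <- character(); order_by <- list(); limit <- NA_integer_
  while (!is.null(t <- peek())) {
    if (is_word(t, "GROUP")) {
      advance(); expect("word", "BY")
      while (!is.null(peek()) && peek()$type == "var")
        group_by <- c(group_by, advance()$value)
    } else if (is_word(t, "ORDER")) {
      advance(); expect("word", "BY")
      repeat {
        t2 <- peek()
        if (is_word(t2, "DESC") || is_word(t2, "ASC")) {
          dir <- toupper(advance()$value)
          expect("punct", "(")
          v <- expect("var")$value
          expect("punct", ")")
          order_by[[length(order_by) + 1L]] <- list(var = v, desc = dir == "DESC")
        } else if (!is.null(t2) && t2$type == "var") {
          order_by[[length(order_by) + 1L]] <-
            list(var = advance()$value, desc = FALSE)
        } else break
      }
    } else if (is_word(t, "LIMIT")) {
      advance(); limit <- as.integer(expect("num")$value)
    } else {
      vaekb_abort("query_parse",
                  sprintf("unsupported clause '%s' at position %d", t$value, t$pos))
    }
  }

  # --- evaluation ---------------------------------------------------------
  triples <- kb_named_triples(kb)
  closure <- NULL
  closure_table <- function() {
    if (!is.null(closure)) return(closure)
    ids <- names(kb$classes)
    rows <- lapply(ids, function(x) {
      anc <- c(x, kb_ancestors(kb, x))
      data.frame(s = paste0("obo:", x), p = "rdfs:subClassOf*",
                 o = paste0("obo:", anc), stringsAsFactors = FALSE)
    })
    closure <<- do.call(rbind, rows)
    closure
  }

  bindings <- NULL
  for (pat in patterns) {
    tab <- if (pat$p$kind == "node" && isTRUE(pat$p$star)) closure_table()
           else triples
    if (pat$p$kind == "node" && !isTRUE(pat$p$star))
      tab <- tab[tab$p == pat$p$value, , drop = FALSE]
    else if (pat$p$kind == "var")
      vaekb_abort("query_parse", "variable predicates are not supported")
    if (pat$s$kind != "var") tab <- tab[tab$s == pat$s$value, , drop = FALSE]
    if (pat$o$kind != "var") tab <- tab[tab$o == pat$o$value, , drop = FALSE]
    new <- data.frame(row.names = seq_len(nrow(tab)))
    if (pat$s$kind == "var") new[[pat$s$value]] <- tab$s
    if (pat$o$kind == "var") new[[pat$o$value]] <- tab$o
    if (!ncol(new)) new <- data.frame(.one = rep(1L, nrow(tab)))
    if (is.null(bindings)) bindings <- new
    else {
      common <- intersect(names(bindings), names(new))
      bindings <- if (length(common)) merge(bindings, new, by = common)
                  else merge(bindings, new, by = NULL)
    }
  }
  if (is.null(bindings)) bindings <- data.frame()
  bindings$.one <- NULL
  for (f in filters) {
    if (!f$var %in% names(bindings))
      vaekb_abort("query_parse", sprintf("FILTER on unbound variable %s", f$var))
    bindings <- bindings[grepl(f$regex, bindings[[f$var]]), , drop = FALSE]
  }

  has_count <- any(vapply(select, function(s) s$kind == "count", logical(1)))
  if (has_count) {
    plain <- vapply(Filter(function(s) s$kind == "var", select),
                    function(s) s$var, character(1))
    keys <- unique(c(group_by, plain))
    cnt <- Filter(function(s) s$kind == "count", select)[[1]]
    if (length(keys)) {
      grp <- interaction(bindings[keys], drop = TRUE, lex.order = TRUE)
      agg <- lapply(split(bindings, grp), function(d) {
        row <- d[1L, keys, drop = FALSE]
        v <- d[[cnt$var]]
        row[[cnt$as]] <- if (cnt$distinct) length(unique(v)) else length(v)
        row
      })
      out <- if (length(agg)) do.call(rbind, agg)
             else stats::setNames(
               data.frame(matrix(character(), ncol = length(keys)),
                          integer(0)), c(keys, cnt$as))
    } else {
      v <- bindings[[cnt$var]]
      out <- data.frame(x = if (cnt$distinct) length(unique(v)) else length(v))
      names(out) <- cnt$as
    }
  } else {
    vars <- vapply(select, function(s) s$var, character(1))
    missing <- setdiff(vars, names(bindings))
    for (v in missing) bindings[[v]] <- NA_character_
    out <- bindings[, vars, drop = FALSE]
  }

  sel_names <- vapply(select, function(s)
    if (s$kind == "count") s$as else s$var, character(1))
  out <- out[, sel_names, drop = FALSE]

  if (length(order_by) || nrow(out) > 1L) {
    keys <- list(); direction <- logical()
    for (ob in order_by) {
      if (ob$var %in% names(out)) {
        keys[[length(keys) + 1L]] <- out[[ob$var]]
        direction <- c(direction, ob$desc)
      }
    }
    for (v in setdiff(sel_names, vapply(order_by, function(o) o$var,
                                        character(1)))) {
      keys[[length(keys) + 1L]] <- out[[v]]
      direction <- c(direction, FALSE)
    }
    if (length(keys)) {
      ranks <- lapply(seq_along(keys), function(i) {
        k <- keys[[i]]
        k <- if (is.numeric(k)) k else xtfrm(k)
        if (direction[i]) -k else k
      })
      out <- out[do.call(order, c(ranks, list(method = "radix"))), ,
                 drop = FALSE]
    }
  }
  if (!is.na(limit)) out <- utils::head(out, limit)
  names(out) <- sub("^\\?", "", names(out))
  rownames(out) <- NULL
  out
}
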