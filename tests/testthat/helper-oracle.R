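# Independent oracles. These deliberately avoid the package's normalization /
# worklist machinery: plain fixpoint loops iterating every rule instance.

# brute-force EL saturation for KBs whose defining expressions are
# conjunctions of named classes and existential restrictions with NAMED
# fillers (what random_el_kb and the bundled figure hierarchy emit).
# Returns: named list id -> sorted strict named superclasses.
oracle_classify <- function(kb) {
  ids <- names(kb$classes)
  S <- stats::setNames(lapply(ids, function(x) x), ids) # S(X) starts as {X}
  edges <- list() # "r|X" -> targets
  # decompose expressions once
  decomp <- lapply(ids, function(c) {
    e <- kb$classes[[c]]$expression
    if (is.null(e)) return(NULL)
    args <- if (e$type == "and") e$args else list(e)
    named <- character(); ex <- list()
    for (a in args) {
      if (a$type == "named") named <- c(named, a$id)
      else if (a$type == "some" && a$filler$type == "named")
        ex[[length(ex) + 1L]] <- c(a$property, a$filler$id)
      else stop("oracle: unsupported expression shape")
    }
    list(named = named, ex = ex, equiv = identical(kb$classes[[c]]$style,
                                                   "equivalent"))
  })
  names(decomp) <- ids
  repeat {
    changed <- FALSE
    add <- function(X, B) {
      if (!B %in% S[[X]]) { S[[X]] <<- c(S[[X]], B); changed <<- TRUE }
    }
    add_edge <- function(r, X, Y) {
      k <- paste(r, X)
      if (!Y %in% edges[[k]]) { edges[[k]] <<- c(edges[[k]], Y); changed <<- TRUE }
    }
    for (X in ids) {
      for (A in S[[X]]) {
        for (P in kb$classes[[A]]$parents) add(X, P)
        d <- decomp[[A]]
        if (!is.null(d)) {
          for (N in d$named) add(X, N)
          for (e in d$ex) add_edge(e[1], X, e[2])
        }
      }
      # equivalence direction: expr ⊑ C
      for (C in ids) {
        d <- decomp[[C]]
        if (is.null(d) || !d$equiv) next
        ok <- all(d$named %in% S[[X]])
        if (ok) for (e in d$ex) {
          targets <- edges[[paste(e[1], X)]]
          if (!any(vapply(targets, function(Y) e[2] %in% S[[Y]], logical(1))))
            { ok <- FALSE; break }
        }
        if (ok) add(X, C)
      }
    }
    if (!changed) break
  }
  lapply(S, function(v) sort(setdiff(v, v[1])))
}

# plain recursive DFS over the asserted child map
oracle_descendants <- function(kb, id) {
  out <- character()
  visit <- function(x) {
    for (ch in kb$children[[x]]) {
      if (!ch %in% out) { out <<- c(out, ch); visit(ch) }
    }
  }
  visit(id)
  sort(out)
}

# per-construct triple tally mirroring the serialization schema
oracle_triple_count <- function(kb) {
  expr_count <- function(e) {
    switch(e$type,
      named = 0L,
      some = 3L + expr_count(e$filler),
      value = 3L,
      interval = {
        nf <- 1L + as.integer(is.finite(e$max))
        3L + 3L + nf + 2L * nf
      },
      and = ,
      or = 2L + 2L * length(e$args) +
        sum(vapply(e$args, expr_count, integer(1))))
  }
  n <- 2L * length(kb$properties)
  for (cls in kb$classes) {
    n <- n + 2L + length(cls$parents) +
      as.integer(!is.null(cls$definition)) +
      as.integer(!is.null(cls$definition_source))
    if (!is.null(cls$expression))
      n <- n + 1L + expr_count(cls$expression)
  }
  n
}
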