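# A small EL subsumption reasoner.
#
# The fragment covers exactly what the design pattern emits: named classes,
# conjunction, existential restriction over object properties, and
# definition-style equivalence (name == conjunctive expression). Datatype
# interval/value restrictions and the OR-clause over age groups are not
# reasoned over: they are encapsulated as opaque atoms during normalization,
# so two syntactically identical restrictions align but no interval
# subsumption is ever inferred.

# Normal forms (plain lists):
#   sub    : lhs ⊑ rhs                       (named atoms)
#   conj   : lhs1 ⊓ ... ⊓ lhsn ⊑ rhs
#   ex_rhs : lhs ⊑ ∃r.filler
#   ex_lhs : ∃r.filler ⊑ rhs

#' Normalize a knowledge base into EL normal forms
#'
#' Complex defining expressions are decomposed into the four EL normal forms
#' over named classes plus fresh auxiliary atoms; datatype restrictions and
#' disjunction fillers become opaque atoms keyed by their canonical rendering
#' (identical restrictions share an atom). Disjunction is only accepted inside
#' the filler of an `'occurs in population'` restriction.
#'
#' @param kb A `vae_kb`.
#' @return A list with `axioms` (list of normal-form axioms) and `aux_map`
#'   (named list mapping auxiliary/opaque atom names back to the rendered
#'   expression they stand for).
#' @export
el_normalize <- function(kb) {
  st <- new.env(parent = emptyenv())
  st$axioms <- list()
  st$aux_map <- list()
  st$aux_by_key <- character()  # ce_render key -> atom name
  st$n_aux <- 0L

  emit <- function(ax) st$axioms[[length(st$axioms) + 1L]] <- ax

  is_opaque_type <- function(e) e$type %in% c("interval", "value", "or")

  check_or <- function(e, in_pop_filler) {
    switch(e$type,
      named = , interval = , value = invisible(NULL),
      some = check_or(e$filler, identical(e$property, PROP_OCCURS_IN_POPULATION)),
      and = for (a in e$args) check_or(a, in_pop_filler),
      or = {
        if (!in_pop_filler)
          vaekb_abort("unsupported_axiom",
                      "disjunction only allowed inside an 'occurs in population' filler")
        for (a in e$args) check_or(a, in_pop_filler)
      }
    )
  }

  # named atom standing for an arbitrary expression; opaque for datatype/or
  # nodes, auxiliary (with both-direction definitional axioms) otherwise
  atom_for <- function(e) {
    if (e$type == "named") return(e$id)
    key <- ce_render(e)
    hit <- st$aux_by_key[key]
    if (!is.na(hit)) return(hit)
    if (is_opaque_type(e)) {
      st$n_aux <- st$n_aux + 1L
      name <- sprintf("opq:%d", st$n_aux)
      st$aux_by_key[key] <- name
      st$aux_map[[name]] <- key
      return(name)
    }
    st$n_aux <- st$n_aux + 1L
    name <- sprintf("aux:%d", st$n_aux)
    st$aux_by_key[key] <- name
    st$aux_map[[name]] <- key
    norm_sub(name, e)   # aux ⊑ e
    norm_sup(e, name)   # e ⊑ aux
    name
  }

  # C ⊑ expr
  norm_sub <- function(C, e) {
    switch(e$type,
      named = emit(list(type = "sub", lhs = C, rhs = e$id)),
      and = for (a in e$args) norm_sub(C, a),
      some = emit(list(type = "ex_rhs", lhs = C, r = e$property,
                       filler = atom_for(e$filler))),
      emit(list(type = "sub", lhs = C, rhs = atom_for(e)))
    )
  }

  # expr ⊑ C
  norm_sup <- function(e, C) {
    switch(e$type,
      named = emit(list(type = "sub", lhs = e$id, rhs = C)),
      and = {
        atoms <- vapply(e$args, atom_for, character(1))
        emit(list(type = "conj", lhs = unique(atoms), rhs = C))
      },
      some = emit(list(type = "ex_lhs", r = e$property,
                       filler = atom_for(e$filler), rhs = C)),
      emit(list(type = "sub", lhs = atom_for(e), rhs = C))
    )
  }

  for (id in names(kb$classes)) {
    cls <- kb$classes[[id]]
    for (p in cls$parents)
      emit(list(type = "sub", lhs = id, rhs = p))
    if (!is.null(cls$expression)) {
      check_or(cls$expression, FALSE)
      norm_sub(id, cls$expression)
      if (identical(cls$style, "equivalent"))
        norm_sup(cls$expression, id)
    }
  }
  list(axioms = st$axioms, aux_map = st$aux_map)
}

#' Classify a knowledge base
#'
#' Runs EL completion to the least fixpoint and fills `kb$inferred`, a map
#' from each named class to all its (strict) inferred named superclasses.
#' The result always contains the transitive closure of the asserted parents;
#' auxiliary normalization atoms never appear in the output. Idempotent.
#'
#' @param kb A `vae_kb` (mutated in place).
#' @return `kb`, invisibly.
#' @export
classify_kb <- function(kb) {
  norm <- el_normalize(kb)
  named <- names(kb$classes)
  atoms <- unique(c(named, unlist(lapply(norm$axioms, function(a)
    switch(a$type,
           sub = c(a$lhs, a$rhs),
           conj = c(a$lhs, a$rhs),
           ex_rhs = c(a$lhs, a$filler),
           ex_lhs = c(a$filler, a$rhs))))))

  # axiom indexes
  sub_by_lhs <- list(); conj_by_member <- list()
  ex_rhs_by_lhs <- list(); ex_lhs_by_key <- list()
  conj_axioms <- list()
  for (a in norm$axioms) {
    if (a$type == "sub") {
      sub_by_lhs[[a$lhs]] <- c(sub_by_lhs[[a$lhs]], a$rhs)
    } else if (a$type == "conj") {
      k <- length(conj_axioms) + 1L
      conj_axioms[[k]] <- a
      for (m in a$lhs)
        conj_by_member[[m]] <- c(conj_by_member[[m]], k)
    } else if (a$type == "ex_rhs") {
      ex_rhs_by_lhs[[a$lhs]] <-
        c(ex_rhs_by_lhs[[a$lhs]], list(list(r = a$r, filler = a$filler)))
    } else {
      key <- paste(a$r, a$filler, sep = "\r")
      ex_lhs_by_key[[key]] <- c(ex_lhs_by_key[[key]], a$rhs)
    }
  }
  ex_lhs_roles_by_filler <- list() # filler -> roles r having an ex_lhs axiom
  for (a in norm$axioms) if (a$type == "ex_lhs")
    ex_lhs_roles_by_filler[[a$filler]] <-
      unique(c(ex_lhs_roles_by_filler[[a$filler]], a$r))

  S <- new.env(parent = emptyenv())        # X -> superset atoms of X
  rev_edges <- new.env(parent = emptyenv())# "r\rY" -> predecessors X
  queue <- list(); qh <- 0L

  push <- function(ev) queue[[length(queue) + 1L]] <<- ev

  add_sub <- function(X, A) {
    cur <- S[[X]]
    if (!is.null(cur) && A %in% cur) return(invisible(NULL))
    S[[X]] <- c(cur, A)
    push(list(kind = "s", X = X, A = A))
  }
  add_edge <- function(r, X, Y) {
    key <- paste(r, Y, sep = "\r")
    cur <- rev_edges[[key]]
    if (!is.null(cur) && X %in% cur) return(invisible(NULL))
    rev_edges[[key]] <- c(cur, X)
    push(list(kind = "e", r = r, X = X, Y = Y))
  }

  for (X in atoms) add_sub(X, X)

  while (qh < length(queue)) {
    qh <- qh + 1L
    ev <- queue[[qh]]
    if (ev$kind == "s") {
      X <- ev$X; A <- ev$A
      for (B in sub_by_lhs[[A]]) add_sub(X, B)
      for (k in conj_by_member[[A]]) {
        ax <- conj_axioms[[k]]
        if (all(ax$lhs %in% S[[X]])) add_sub(X, ax$rhs)
      }
      for (e in ex_rhs_by_lhs[[A]]) add_edge(e$r, X, e$filler)
      # X (as some Y) gained member A: fire ex_lhs axioms ∃r.A ⊑ C for all
      # predecessors of X under r
      for (r in ex_lhs_roles_by_filler[[A]]) {
        rhs <- ex_lhs_by_key[[paste(r, A, sep = "\r")]]
        preds <- rev_edges[[paste(r, X, sep = "\r")]]
        for (Xp in preds) for (C in rhs) add_sub(Xp, C)
      }
    } else {
      # new edge r(X, Y): fire ∃r.B ⊑ C for every B already in S(Y)
      for (B in S[[ev$Y]]) {
        rhs <- ex_lhs_by_key[[paste(ev$r, B, sep = "\r")]]
        for (C in rhs) add_sub(ev$X, C)
      }
    }
  }

  inferred <- vector("list", length(named)); names(inferred) <- named
  for (X in named) {
    sup <- setdiff(S[[X]], X)
    inferred[[X]] <- sort(sup[sup %in% named])
  }
  kb$inferred <- inferred
  invisible(kb)
}

#' Inferred-only direct subsumption edges
#'
#' Direct edges of the inferred hierarchy that are not already derivable from
#' the transitive closure of the asserted parents — i.e. what classification
#' added. Pairs that are mutually subsumed (equivalent classes) are skipped.
#'
#' @param kb A classified `vae_kb`.
#' @return Data frame with columns `child`, `child_label`, `parent`,
#'   `parent_label`, sorted by (child label, parent label).
#' @export
inferred_only_edges <- function(kb) {
  if (is.null(kb$inferred))
    vaekb_abort("classification_not_run",
                "classify_kb() has not been run on this KB")
  rows <- list()
  for (c_id in names(kb$classes)) {
    inf <- kb$inferred[[c_id]]
    # strict subsumption only
    strict <- inf[!vapply(inf, function(p) c_id %in% kb$inferred[[p]], logical(1))]
    asserted <- kb_ancestors(kb, c_id)
    new_parents <- setdiff(strict, asserted)
    for (p in new_parents) {
      direct <- !any(vapply(strict, function(m)
        m != p && p %in% kb$inferred[[m] ] && !(m %in% kb$inferred[[p]]),
        logical(1)))
      if (direct)
        rows[[length(rows) + 1L]] <- data.frame(
          child = c_id, child_label = kb$classes[[c_id]]$label,
          parent = p, parent_label = kb$classes[[p]]$label,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(child = character(), child_label = character(),
                      parent = character(), parent_label = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$child_label, out$parent_label, method = "radix"), ]
  rownames(out) <- NULL
  out
}
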