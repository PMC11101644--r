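# Boolean rule inference from a regulatory map, following the CaSQ
# translation convention: activating reactions combine by OR across
# reactions, sources within one reaction by AND, and the inhibitor set gates
# the whole expression through AND NOT(i1 OR i2 OR ...). Species without
# regulators become model inputs with identity rules.

#' Logic expression constructors
#'
#' Expressions are nested lists with node kinds `lit`, `not`, `and`, `or`.
#' `NOT` appears only directly above a literal or an OR of literals, so the
#' inhibitor block stays in negation-normal position.
#'
#' @param id species id (for `lx_lit`).
#' @param x,... child expressions.
#' @name logic_expr
NULL

#' @rdname logic_expr
#' @export
lx_lit <- function(id) structure(list(op = "lit", id = id),
                                 class = "logic_expr")

#' @rdname logic_expr
#' @export
lx_not <- function(x) structure(list(op = "not", arg = x),
                                class = "logic_expr")

lx_nary <- function(op, args) {
  args <- args[!vapply(args, is.null, logical(1))]
  if (length(args) == 0) return(NULL)
  if (length(args) == 1) return(args[[1]])
  structure(list(op = op, args = args), class = "logic_expr")
}

#' @rdname logic_expr
#' @export
lx_and <- function(...) lx_nary("and", list(...))

#' @rdname logic_expr
#' @export
lx_or <- function(...) lx_nary("or", list(...))

#' Species ids referenced by an expression
#' @param expr a `logic_expr`.
#' @export
expr_literals <- function(expr) {
  if (is.null(expr)) return(character(0))
  switch(expr$op,
         lit = expr$id,
         not = expr_literals(expr$arg),
         unique(unlist(lapply(expr$args, expr_literals))))
}

#' Evaluate an expression on one or many states
#'
#' @param expr a `logic_expr`.
#' @param state either a named logical/integer vector (one state) or a
#'   logical matrix with one column per species id (many states).
#' @return a logical scalar (vector input) or logical vector with one entry
#'   per matrix row.
#' @export
eval_expr <- function(expr, state) {
  if (is.matrix(state)) {
    rec <- function(e) {
      switch(e$op,
             lit = state[, e$id],
             not = !rec(e$arg),
             and = Reduce(`&`, lapply(e$args, rec)),
             or = Reduce(`|`, lapply(e$args, rec)))
    }
  } else {
    rec <- function(e) {
      switch(e$op,
             lit = as.logical(state[[e$id]]),
             not = !rec(e$arg),
             and = all(vapply(e$args, rec, logical(1))),
             or = any(vapply(e$args, rec, logical(1))))
    }
  }
  rec(expr)
}

#' Canonical text form of a rule
#'
#' Deterministic, fully parenthesised rendering; operands of the commutative
#' operators are sorted lexicographically (C collation), so logically
#' identical rules print identically.
#'
#' @param rule a `logic_rule` or bare `logic_expr`.
#' @return a character scalar such as `"(A AND (NOT B))"`.
#' @export
rule_to_text <- function(rule) {
  expr <- if (inherits(rule, "logic_rule")) rule$expr else rule
  # sort key: a negated literal sorts by the literal's name, so
  # AND(A, NOT B) renders "(A AND (NOT B))", not "((NOT B) AND A)"
  key <- function(e) {
    switch(e$op,
           lit = e$id,
           not = paste0(key(e$arg), "~"),
           rec(e))
  }
  rec <- function(e) {
    switch(e$op,
           lit = e$id,
           not = sprintf("(NOT %s)", rec(e$arg)),
           and = ,
           or = {
             keys <- vapply(e$args, key, character(1))
             parts <- vapply(e$args, rec, character(1))[c_order(keys)]
             sprintf("(%s)", paste(parts,
                                   collapse = if (e$op == "and") " AND "
                                              else " OR "))
           })
  }
  rec(expr)
}

new_logic_rule <- function(target, expr, is_input = FALSE) {
  structure(list(target = target, expr = expr, is_input = is_input),
            class = "logic_rule")
}

#' Translate a regulatory map into a Boolean logical model
#'
#' For each species `t` with activating reactions `r1..rk` (sources within a
#' reaction combined by AND) and inhibiting regulators `i1..im`:
#' `f(t) = (r1 OR ... OR rk) AND NOT(i1 OR ... OR im)`. A species with only
#' inhibitors is constitutively ON unless inhibited (`NOT(...)`); a species
#' with no regulators becomes an input with the identity rule. Transport and
#' dissociation reactions (sign `neutral`) translate as activation of the
#' target by the source so that signal flow across compartments is kept;
#' degradation sink species are dropped from the model.
#'
#' @param map a validated `regulatory_map`.
#' @param drop_degradation drop species of kind `degradation` (and the
#'   interactions that touch them) before inference.
#' @return an object of class `logic_model` with one rule per species.
#' @export
infer_rules <- function(map, drop_degradation = TRUE) {
  issues <- validate_map(map)
  if (nrow(issues) > 0)
    stop_fmt("emtmap_validation_error",
             "map fails validation (%d issue(s); see validate_map()): e.g. %s [%s]",
             nrow(issues), issues$message[1], issues$id[1])
  sp <- map$species
  ints <- map$interactions
  if (drop_degradation) {
    deg <- sp$id[sp$kind == "degradation"]
    if (length(deg) > 0) {
      sp <- sp[!sp$id %in% deg, , drop = FALSE]
      touches <- vapply(seq_len(nrow(ints)), function(i)
        ints$target[[i]] %in% deg || any(ints$sources[[i]] %in% deg),
        logical(1))
      ints <- ints[!touches, , drop = FALSE]
    }
  }
  node_order <- sp$id
  rules <- vector("list", length(node_order))
  names(rules) <- node_order
  for (t in node_order) {
    rows <- which(vapply(ints$target, identical, logical(1), t))
    activators <- list()
    inhibitors <- character(0)
    for (i in rows) {
      if (identical(ints$sign[[i]], "inhibition")) {
        inhibitors <- c(inhibitors, ints$sources[[i]])
      } else {
        # activation and neutral (transport/dissociation) feed the OR block
        activators[[length(activators) + 1]] <-
          lx_nary("and", lapply(ints$sources[[i]], lx_lit))
      }
    }
    inhibitors <- unique(inhibitors)
    act_block <- lx_nary("or", activators)
    inh_block <- if (length(inhibitors) > 0)
      lx_not(lx_nary("or", lapply(inhibitors, lx_lit))) else NULL
    if (is.null(act_block) && is.null(inh_block)) {
      rules[[t]] <- new_logic_rule(t, lx_lit(t), is_input = TRUE)
    } else if (is.null(act_block)) {
      rules[[t]] <- new_logic_rule(t, inh_block)
    } else if (is.null(inh_block)) {
      rules[[t]] <- new_logic_rule(t, act_block)
    } else {
      rules[[t]] <- new_logic_rule(t, lx_nary("and",
                                              list(act_block, inh_block)))
    }
  }
  inputs <- node_order[vapply(rules, `[[`, logical(1), "is_input")]
  structure(list(rules = rules, node_order = node_order, inputs = inputs),
            class = "logic_model")
}

#' @export
print.logic_model <- function(x, ...) {
  cat(sprintf("logic_model: %d nodes (%d inputs)\n",
              length(x$node_order), length(x$inputs)))
  for (t in x$node_order) {
    tag <- if (x$rules[[t]]$is_input) " [input]" else ""
    cat(sprintf("  %s = %s%s\n", t, rule_to_text(x$rules[[t]]), tag))
  }
  invisible(x)
}

#' Export all rules as canonical text
#' @param model a `logic_model`.
#' @return named character vector of canonical rule strings.
#' @export
model_rules_text <- function(model) {
  vapply(model$rules, rule_to_text, character(1))
}

#' Truth table of a rule over its regulators
#'
#' Exhaustively evaluates the rule over all `2^k` assignments of its `k`
#' literals (regulators), in lexicographic literal order.
#'
#' @param expr a `logic_expr` or `logic_rule`.
#' @return data frame with one column per literal plus `value`.
#' @export
truth_table <- function(expr) {
  if (inherits(expr, "logic_rule")) expr <- expr$expr
  vars <- c_sort(expr_literals(expr))
  k <- length(vars)
  grid <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), k),
                                KEEP.OUT.ATTRS = FALSE))
  colnames(grid) <- vars
  out <- as.data.frame(grid)
  out$value <- if (k == 0) eval_expr(expr, logical(0)) else
    eval_expr(expr, grid)
  out
}

# Compile each rule into a fast closure over an unnamed logical state vector
# (positions follow model$node_order). Used by the simulation engine.
compile_rules <- function(model) {
  idx <- stats::setNames(seq_along(model$node_order), model$node_order)
  expr_to_call <- function(e) {
    switch(e$op,
           lit = call("[", as.name("s"), idx[[e$id]]),
           not = call("!", expr_to_call(e$arg)),
           and = Reduce(function(a, b) call("&&", a, b),
                        lapply(e$args, expr_to_call)),
           or = Reduce(function(a, b) call("||", a, b),
                       lapply(e$args, expr_to_call)))
  }
  lapply(model$rules, function(r) {
    f <- function(s) NULL
    body(f) <- expr_to_call(r$expr)
    environment(f) <- baseenv()
    f
  })
}

# Vectorised next-state of every node over a logical state matrix whose
# columns follow model$node_order.
eval_model_matrix <- function(model, M) {
  colnames(M) <- model$node_order
  out <- vapply(model$node_order, function(t) {
    v <- eval_expr(model$rules[[t]]$expr, M)
    if (length(v) == 1 && nrow(M) > 1) rep(v, nrow(M)) else v
  }, logical(nrow(M)))
  if (nrow(M) == 1) out <- matrix(out, nrow = 1,
                                  dimnames = list(NULL, model$node_order))
  out
}
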