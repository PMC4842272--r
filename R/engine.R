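# Inference: derive decision states from facts via scoring rules and
# workflows. Truth maintenance is by stateless full re-evaluation — every
# call recomputes all states from the current fact set, which makes results
# independent of fact insertion order and makes retraction exact by
# construction (no incremental bookkeeping to unwind).

#' Coerce facts to a question -> value list
#'
#' Accepts a named list (question id -> value) or a fact log tibble as built
#' by [fact_history()], in which case the latest value per question wins.
#'
#' @param facts facts in either form.
#' @return named list of values.
#' @export
as_fact_list <- function(facts) {
  if (is.data.frame(facts)) {
    if (nrow(facts) == 0) return(list())
    facts <- facts[order(facts$timestamp, facts$seq), , drop = FALSE]
    out <- list()
    for (i in seq_len(nrow(facts))) {
      out[[facts$question[[i]]]] <- facts$value[[i]]
    }
    out
  } else {
    facts
  }
}

fact_timestamps <- function(facts) {
  if (!is.data.frame(facts) || nrow(facts) == 0) return(NULL)
  facts <- facts[order(facts$timestamp, facts$seq), , drop = FALSE]
  ts <- list()
  for (i in seq_len(nrow(facts))) {
    ts[[facts$question[[i]]]] <- facts$timestamp[[i]]
  }
  ts
}

score_to_state <- function(score, thresholds) {
  if (score <= thresholds[["excluded"]]) "excluded"
  else if (score >= thresholds[["established"]]) "established"
  else if (score >= thresholds[["suggested"]]) "suggested"
  else "undefined"
}

#' Derive all decision states from a fact set
#'
#' Modules are evaluated in dependency order. Within a module every scoring
#' rule whose condition is true fires; fired category scores sum per target
#' decision and the sum maps to a state (default thresholds: established at
#' +42, suggested at +10, excluded at -42; exclusion is checked first).
#' Workflows then traverse from their start node along true-guard edges and
#' visited decide-nodes set their decision's state directly, overriding a
#' rule-derived state for the same decision. The dependency-ordered pass is
#' repeated until the state map is stable (a fixpoint), so modules may also
#' reference decisions evaluated later.
#'
#' @param registry a `ks_registry`.
#' @param facts facts for one substance (see [as_fact_list()]).
#' @return a `ks_decision_map`: tibble with columns `module`, `decision`,
#'   `label`, `state`, `score`, `support` (list-column of fired rule ids /
#'   active flow node ids). Attributes `fired` (fired-rule table) and
#'   `traces` (workflow traces) carry the explanation substrate.
#' @export
ks_evaluate <- function(registry, facts) {
  fl <- as_fact_list(facts)
  decs <- registry_decisions(registry)
  states <- stats::setNames(rep("undefined", nrow(decs)), decs$id)
  prev <- NULL
  pass <- NULL
  for (iter in seq_len(length(registry$modules) + 2L)) {
    pass <- evaluate_pass(registry, fl, states)
    if (identical(pass$states, prev)) break
    prev <- pass$states
    states <- pass$states
  }
  scores <- pass$scores
  support <- pass$support
  out <- tibble(
    module = decs$module,
    decision = decs$id,
    label = decs$label,
    state = unname(states[decs$id]),
    score = unname(scores[decs$id]),
    support = unname(support[decs$id])
  )
  attr(out, "fired") <- pass$fired
  attr(out, "traces") <- pass$traces
  class(out) <- c("ks_decision_map", class(out))
  out
}

evaluate_pass <- function(registry, fl, states_in) {
  decs <- registry_decisions(registry)
  states <- stats::setNames(rep("undefined", nrow(decs)), decs$id)
  scores <- stats::setNames(rep(0, nrow(decs)), decs$id)
  support <- stats::setNames(vector("list", nrow(decs)), decs$id)
  fired <- list()
  traces <- list()
  # states seen by condition evaluation: start from the previous pass so
  # forward references resolve at the fixpoint
  visible <- states_in
  for (mname in registry$order) {
    mod <- registry$modules[[mname]]
    # scoring rules
    for (i in seq_len(nrow(mod$rules))) {
      r <- mod$rules[i, ]
      res <- evaluate_condition(r$condition[[1]], fl, visible)
      if (isTRUE(res)) {
        scores[[r$target]] <- scores[[r$target]] + SCORE_CATEGORIES[[r$category]]
        support[[r$target]] <- c(support[[r$target]], r$id)
        fired[[length(fired) + 1]] <- tibble(
          rule = r$id, module = mname, target = r$target,
          category = r$category,
          questions = list(condition_questions(r$condition[[1]])),
          decisions = list(condition_decisions(r$condition[[1]])))
      }
    }
    for (d in mod$decisions$id) {
      if (length(support[[d]])) {
        states[[d]] <- score_to_state(scores[[d]], registry$thresholds)
      }
      visible[[d]] <- states[[d]]
    }
    # workflows: decide-nodes set states directly
    for (wf in mod$workflows) {
      tr <- trace_workflow(wf, fl, decisions = visible)
      traces[[wf$name]] <- tr
      for (nid in tr$visited) {
        node <- wf$nodes[wf$nodes$id == nid, ]
        if (node$kind == "decide") {
          states[[node$decision]] <- node$state
          support[[node$decision]] <-
            unique(c(support[[node$decision]], paste0(wf$name, ":", nid)))
          visible[[node$decision]] <- node$state
        }
      }
    }
  }
  list(states = states, scores = scores, support = support,
       fired = if (length(fired)) bind_rows(fired) else
         tibble(rule = character(), module = character(),
                target = character(), category = character(),
                questions = list(), decisions = list()),
       traces = traces)
}

#' @export
print.ks_decision_map <- function(x, ...) {
  cat("<ks_decision_map>\n")
  shown <- x[x$state != "undefined", , drop = FALSE]
  if (nrow(shown) == 0) {
    cat("  (no decisions derived)\n")
  } else {
    for (i in seq_len(nrow(shown))) {
      cat(sprintf("  [%s] %s: %s (score %s)\n", shown$module[[i]],
                  shown$decision[[i]], shown$state[[i]],
                  format(shown$score[[i]])))
    }
  }
  invisible(x)
}

#' Retract an answered question from a fact set
#'
#' The operational face of non-monotonicity: the fact disappears and a fresh
#' evaluation of the remaining facts is authoritative — identical to a
#' session that never saw the fact.
#'
#' @param facts named list or fact-log tibble.
#' @param question question id to retract.
#' @return the reduced fact set (same form as the input).
#' @export
retract <- function(facts, question) {
  if (is.data.frame(facts)) {
    if (!question %in% facts$question) {
      warn(sprintf("question '%s' was not answered; nothing retracted",
                   question))
      return(facts)
    }
    facts[facts$question != question, , drop = FALSE]
  } else {
    if (!question %in% names(facts)) {
      warn(sprintf("question '%s' was not answered; nothing retracted",
                   question))
      return(facts)
    }
    facts[names(facts) != question]
  }
}

#' Explain a derived decision
#'
#' Returns the responsible facts (question, value, timestamp) and the fired
#' rules / workflow steps behind one decision, following decision reuse
#' across modules transitively. Re-evaluating with only the responsible
#' facts reproduces the explained decision's state.
#'
#' @param registry a `ks_registry`.
#' @param facts facts for one substance.
#' @param decision_id decision to explain.
#' @return a `ks_explanation` list with elements `decision`, `state`,
#'   `responsible_facts` (tibble question/value/timestamp) and `fired`
#'   (character vector of rule ids and flow edge ids).
#' @export
ks_explain <- function(registry, facts, decision_id) {
  decs <- registry_decisions(registry)
  if (!decision_id %in% decs$id) {
    stop_knowsub(sprintf("unknown decision '%s'", decision_id),
                 "knowsub_not_found_error")
  }
  dm <- ks_evaluate(registry, facts)
  fired <- attr(dm, "fired")
  traces <- attr(dm, "traces")
  fl <- as_fact_list(facts)
  ts <- fact_timestamps(facts)

  seen <- character()
  questions <- character()
  sources <- character()
  collect <- function(d) {
    if (d %in% seen) return(invisible(NULL))
    seen <<- c(seen, d)
    # fired rules targeting d
    rr <- fired[fired$target == d, , drop = FALSE]
    for (i in seq_len(nrow(rr))) {
      questions <<- c(questions, rr$questions[[i]])
      sources <<- c(sources, rr$rule[[i]])
      for (dd in rr$decisions[[i]]) collect(dd)
    }
    # workflow path reaching a decide-node for d
    for (mod in registry$modules) {
      for (wf in mod$workflows) {
        tr <- traces[[wf$name]]
        if (is.null(tr)) next
        didx <- which(map_lgl(tr$visited, function(nid) {
          node <- wf$nodes[wf$nodes$id == nid, ]
          node$kind == "decide" && node$decision == d
        }))
        if (length(didx) == 0) next
        upto <- tr$taken[seq_len(min(didx) - 1)]
        for (eid in upto) {
          e <- wf$edges[paste0(wf$edges$from, "->", wf$edges$to) == eid, ]
          sources <<- c(sources, paste0(wf$name, ":", eid))
          g <- e$guard[[1]]
          if (!is.null(g)) {
            questions <<- c(questions, condition_questions(g))
            for (dd in condition_decisions(g)) collect(dd)
          }
        }
      }
    }
  }
  collect(decision_id)
  questions <- unique(questions)
  answered <- keep(questions, function(q) !is.null(fact_value(fl, q)))
  rf <- tibble(
    question = answered,
    value = map(answered, function(q) fl[[q]]),
    timestamp = map(answered, function(q) ts[[q]] %||% NA)
  )
  structure(list(decision = decision_id,
                 state = dm$state[dm$decision == decision_id],
                 responsible_facts = rf,
                 fired = unique(sources)),
            class = "ks_explanation")
}

#' @export
print.ks_explanation <- function(x, ...) {
  cat(sprintf("Decision %s: %s\n", x$decision, x$state))
  if (nrow(x$responsible_facts) == 0) {
    cat("  (no responsible facts)\n")
  } else {
    for (i in seq_len(nrow(x$responsible_facts))) {
      tsv <- x$responsible_facts$timestamp[[i]]
      tss <- if (length(tsv) == 1 && is.na(tsv[[1]])) "" else
        paste0("  [", format(tsv, tz = "UTC", usetz = TRUE), "]")
      cat(sprintf("  %s = %s%s\n", x$responsible_facts$question[[i]],
                  paste(format(x$responsible_facts$value[[i]]),
                        collapse = ", "), tss))
    }
  }
  invisible(x)
}

#' Restrict a fact set to an explanation's responsible facts
#'
#' @param facts the full fact set the explanation was computed from.
#' @param explanation a `ks_explanation`.
#' @return the restricted fact set (named list).
#' @export
restrict_facts <- function(facts, explanation) {
  fl <- as_fact_list(facts)
  fl[intersect(names(fl), explanation$responsible_facts$question)]
}

#' Trace a workflow for a fact set
#'
#' Deterministic traversal from the start node: at each node the outgoing
#' edges are tested in declaration order and the first edge with a true
#' guard (an absent guard counts as true) is taken; traversal stops at an
#' exit node, when no guard is true, or before an ask-node whose question
#' is still unanswered (the trace records reasoning that actually happened,
#' and an unanswered ask has not happened yet — with no facts at all the
#' trace is just the start node). If several guards are simultaneously
#' true the first declared wins and a warning is logged.
#'
#' @param workflow one workflow of a `ks_module`.
#' @param facts facts for one substance.
#' @param decisions named character vector of current decision states (for
#'   `state(...)` guards).
#' @return a `ks_trace` list: `workflow`, `visited` (node ids in order),
#'   `taken` (edge ids `"from->to"` in order).
#' @export
trace_workflow <- function(workflow, facts, decisions = character()) {
  fl <- as_fact_list(facts)
  nodes <- workflow$nodes
  current <- nodes$id[nodes$kind == "start"]
  visited <- current
  taken <- character()
  repeat {
    kind <- nodes$kind[nodes$id == current]
    if (kind == "exit") break
    out_edges <- which(workflow$edges$from == current)
    if (length(out_edges) == 0) break
    truth <- map_lgl(out_edges, function(i) {
      g <- workflow$edges$guard[[i]]
      if (is.null(g)) TRUE else
        isTRUE(evaluate_condition(g, fl, decisions))
    })
    if (!any(truth)) break
    if (sum(truth) > 1) {
      warn(sprintf(
        "flow '%s': %d guards simultaneously true at node '%s'; taking the first",
        workflow$name, sum(truth), current))
    }
    e <- out_edges[[which(truth)[[1]]]]
    target <- workflow$edges$to[[e]]
    tnode <- nodes[nodes$id == target, ]
    if (tnode$kind == "ask" && is.null(fact_value(fl, tnode$question))) {
      break
    }
    taken <- c(taken, paste0(workflow$edges$from[[e]], "->", target))
    current <- target
    visited <- c(visited, current)
  }
  structure(list(workflow = workflow$name, visited = visited, taken = taken),
            class = "ks_trace")
}

#' @export
print.ks_trace <- function(x, ...) {
  cat(sprintf("<ks_trace> %s: %s\n", x$workflow,
              paste(x$visited, collapse = " -> ")))
  invisible(x)
}

#' Mirror derived decision states into the RDF store
#'
#' For every non-undefined decision a triple
#' `(substance, ks:hasDecision, ks:dec_<id>_<state>)` is written, together
#' with a description of the state resource (`ks:decisionId`,
#' `ks:decisionState`, `ks:decisionModule`). Previously mirrored states for
#' the substance are replaced, never duplicated, so the dynamic views always
#' reflect the currently valid decisions.
#'
#' @param store a `ks_store`.
#' @param substance_uri substance resource.
#' @param decision_map a `ks_decision_map` from [ks_evaluate()].
#' @return the store, invisibly.
#' @export
mirror_decisions <- function(store, substance_uri, decision_map) {
  remove_triples(store, s = substance_uri,
                 p = ks_term(store, "hasDecision"))
  live <- decision_map[decision_map$state != "undefined", , drop = FALSE]
  for (i in seq_len(nrow(live))) {
    node <- ks_term(store, sprintf("dec_%s_%s", slugify(live$decision[[i]]),
                                   live$state[[i]]))
    add_triple(store, substance_uri, ks_term(store, "hasDecision"), node)
    add_triple(store, node, ks_term(store, "decisionId"),
               live$decision[[i]], "literal")
    add_triple(store, node, ks_term(store, "decisionState"),
               live$state[[i]], "literal")
    add_triple(store, node, ks_term(store, "decisionModule"),
               live$module[[i]], "literal")
  }
  invisible(store)
}

#' Plot the score profile of a decision map
#'
#' @param decision_map a `ks_decision_map`.
#' @return a ggplot: decisions on the y axis, summed rule score on the x
#'   axis, coloured by derived state.
#' @export
plot_decision_scores <- function(decision_map) {
  df <- tibble(decision = decision_map$decision,
               score = decision_map$score,
               state = decision_map$state)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = .data$decision,
                                   fill = .data$state)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "summed rule score", y = NULL,
                  title = "Decision score profile") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ks_decision_map <- function(object, ...) {
  plot_decision_scores(object)
}
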