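# Decision-module knowledge representation.
#
# A module bundles hierarchical questions, a decision hierarchy,
# non-monotonic scoring rules and acyclic workflows. Modules are written in
# a line-oriented plain-text dialect (UTF-8, `#` comments, two-space
# indentation expressing hierarchy):
#
#   MODULE Persistence
#   DEPENDS OtherModule, ...
#   QUESTIONS
#     ThCO2 "Degradation after 28 d [% ThCO2]" numeric unit=%
#     route "Uptake route" one_choice(water, sediment) explain="..."
#   DECISIONS
#     P "P criterion fulfilled"
#       vP "vP criterion fulfilled"
#   RULES
#     RULE r1: IF OR(ThCO2 < 60, ThOD < 60, DOC < 70) THEN nrb P7
#   FLOW name
#     START s
#     ASK a1 questionId
#     DECIDE d1 decisionId established
#     EXIT end
#     EDGE s -> a1
#     EDGE a1 -> d1 IF questionId >= 2000
#
# Conditions are three-valued (true / false / undefined, encoded as
# TRUE / FALSE / NA): AND, OR, NOT follow Kleene logic; a comparison on an
# unanswered question is undefined; known(q) is true when q is answered and
# undefined otherwise (this keeps evaluation monotone under fact extension);
# state(d) = s tests the current state of a decision.

SCORE_CATEGORIES <- c(N7 = -80, N6 = -40, N5 = -20, N4 = -10, N3 = -5,
                      N2 = -2, N1 = -1,
                      P1 = 1, P2 = 2, P3 = 5, P4 = 10, P5 = 20, P6 = 40,
                      P7 = 80)

QUESTION_TYPES <- c("one_choice", "multi_choice", "numeric", "date", "text")
DECISION_STATES <- c("established", "suggested", "undefined", "excluded")

# --- condition parsing ------------------------------------------------------

cond_tokenize <- function(text) {
  pats <- c(ws = "^\\s+",
            str = '^"(?:[^"\\\\]|\\\\.)*"',
            num = "^-?[0-9]+(\\.[0-9]+)?",
            op = "^(<=|>=|!=|=|<|>)",
            punct = "^[(),]",
            word = "^[A-Za-z_][A-Za-z0-9_.-]*")
  toks <- list()
  rest <- text
  off <- 0L
  while (nzchar(rest)) {
    matched <- FALSE
    for (ty in names(pats)) {
      m <- regexpr(pats[[ty]], rest, perl = TRUE)
      if (m == 1) {
        len <- attr(m, "match.length")
        val <- substr(rest, 1, len)
        if (ty != "ws") {
          toks[[length(toks) + 1]] <- list(type = ty, value = val,
                                           pos = off + 1L)
        }
        rest <- substr(rest, len + 1, nchar(rest))
        off <- off + len
        matched <- TRUE
        break
      }
    }
    if (!matched) {
      stop_knowsub(sprintf("condition syntax error near '%s'",
                           substr(rest, 1, 10)), "knowsub_parse_error")
    }
  }
  toks
}

#' Parse a condition expression
#'
#' @param text condition text, e.g. `"OR(ThCO2 < 60, DOC < 70)"`,
#'   `"known(BCF)"`, `"state(P) = established"`, `"route in (water, food)"`.
#' @return a condition AST (nested named lists), class `ks_condition`.
#' @export
parse_condition <- function(text) {
  toks <- cond_tokenize(text)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[[pos]] else NULL
  take <- function() { tk <- peek()
    if (is.null(tk)) stop_knowsub("condition ends unexpectedly",
                                  "knowsub_parse_error")
    pos <<- pos + 1L; tk }
  expect_punct <- function(v) {
    tk <- take()
    if (tk$type != "punct" || tk$value != v) {
      stop_knowsub(sprintf("expected '%s' in condition near position %d",
                           v, tk$pos), "knowsub_parse_error")
    }
  }
  literal <- function() {
    tk <- take()
    if (tk$type == "num") return(as.numeric(tk$value))
    if (tk$type == "str") return(ttl_unescape(gsub('^"|"$', "", tk$value)))
    if (tk$type == "word") return(tk$value)
    stop_knowsub(sprintf("expected literal near position %d", tk$pos),
                 "knowsub_parse_error")
  }
  expr <- function() {
    tk <- take()
    if (tk$type == "word" && tk$value %in% c("AND", "OR")) {
      expect_punct("(")
      args <- list(expr())
      while (!is.null(peek()) && peek()$value == ",") {
        take()
        args[[length(args) + 1]] <- expr()
      }
      expect_punct(")")
      return(list(kind = tolower(tk$value), args = args))
    }
    if (tk$type == "word" && tk$value == "NOT") {
      expect_punct("(")
      inner <- expr()
      expect_punct(")")
      return(list(kind = "not", arg = inner))
    }
    if (tk$type == "word" && tk$value == "known") {
      expect_punct("(")
      q <- take()
      expect_punct(")")
      return(list(kind = "known", question = q$value))
    }
    if (tk$type == "word" && tk$value == "state") {
      expect_punct("(")
      d <- take()
      expect_punct(")")
      op <- take()
      if (op$type != "op" || !op$value %in% c("=", "!=")) {
        stop_knowsub("state(...) must be compared with = or !=",
                     "knowsub_parse_error")
      }
      st <- take()
      if (!st$value %in% DECISION_STATES) {
        stop_knowsub(sprintf("unknown decision state '%s'", st$value),
                     "knowsub_parse_error")
      }
      return(list(kind = "dstate", decision = d$value, op = op$value,
                  state = st$value))
    }
    if (tk$type == "word") {
      nx <- take()
      if (nx$type == "word" && nx$value == "in") {
        expect_punct("(")
        lits <- list(literal())
        while (!is.null(peek()) && peek()$value == ",") {
          take()
          lits[[length(lits) + 1]] <- literal()
        }
        expect_punct(")")
        return(list(kind = "cmp", question = tk$value, op = "in",
                    rhs = lits))
      }
      if (nx$type == "op") {
        return(list(kind = "cmp", question = tk$value, op = nx$value,
                    rhs = literal()))
      }
      stop_knowsub(sprintf("expected operator after '%s'", tk$value),
                   "knowsub_parse_error")
    }
    stop_knowsub(sprintf("unexpected token '%s' in condition", tk$value),
                 "knowsub_parse_error")
  }
  out <- expr()
  if (pos <= length(toks)) {
    stop_knowsub("trailing tokens after condition", "knowsub_parse_error")
  }
  structure(out, class = "ks_condition")
}

format_condition <- function(cond) {
  fmt_lit <- function(x) {
    if (is.numeric(x)) format(x, scientific = FALSE) else {
      if (grepl("^[A-Za-z_][A-Za-z0-9_.-]*$", x)) x else
        paste0("\"", ttl_escape(x), "\"")
    }
  }
  switch(cond$kind,
    and = paste0("AND(", paste(map_chr(cond$args, format_condition),
                               collapse = ", "), ")"),
    or = paste0("OR(", paste(map_chr(cond$args, format_condition),
                             collapse = ", "), ")"),
    not = paste0("NOT(", format_condition(cond$arg), ")"),
    known = paste0("known(", cond$question, ")"),
    dstate = paste0("state(", cond$decision, ") ", cond$op, " ", cond$state),
    cmp = if (cond$op == "in") {
      paste0(cond$question, " in (",
             paste(map_chr(cond$rhs, fmt_lit), collapse = ", "), ")")
    } else {
      paste(cond$question, cond$op, fmt_lit(cond$rhs))
    })
}

condition_questions <- function(cond) {
  switch(cond$kind,
    and = unique(unlist(map(cond$args, condition_questions))),
    or = unique(unlist(map(cond$args, condition_questions))),
    not = condition_questions(cond$arg),
    known = cond$question,
    cmp = cond$question,
    dstate = character())
}

condition_decisions <- function(cond) {
  switch(cond$kind,
    and = unique(unlist(map(cond$args, condition_decisions))),
    or = unique(unlist(map(cond$args, condition_decisions))),
    not = condition_decisions(cond$arg),
    dstate = cond$decision,
    character())
}

# --- three-valued evaluation ------------------------------------------------

fact_value <- function(facts, q) {
  v <- facts[[q]]
  if (is.null(v)) return(NULL)
  if (length(v) == 1 && is.na(v)) return(NULL)  # explicit "unknown" answer
  v
}

#' Evaluate a condition under partial facts (three-valued)
#'
#' Kleene logic: `NA` stands for *undefined*. A comparison on an unanswered
#' question is undefined; `AND` is false as soon as one conjunct is false,
#' `OR` true as soon as one disjunct is true; `NOT(undefined)` is undefined.
#' `known(q)` is true when `q` is answered, undefined otherwise.
#' `state(d) = s` is evaluated against `decisions` (a named character vector
#' of current states; absent decisions count as `"undefined"`).
#'
#' @param condition a `ks_condition` (or text, parsed on the fly).
#' @param facts named list mapping question ids to answered values; missing
#'   entries and `NA` values mean unanswered.
#' @param decisions named character vector of decision states.
#' @return `TRUE`, `FALSE` or `NA`.
#' @export
evaluate_condition <- function(condition, facts, decisions = character()) {
  if (is.character(condition)) condition <- parse_condition(condition)
  ev <- function(c) {
    switch(c$kind,
      and = {
        vals <- map(c$args, ev)
        Reduce(function(a, b) a & b, vals)
      },
      or = {
        vals <- map(c$args, ev)
        Reduce(function(a, b) a | b, vals)
      },
      not = !ev(c$arg),
      known = if (is.null(fact_value(facts, c$question))) NA else TRUE,
      dstate = {
        st <- unname(decisions[c$decision] %theni% "undefined")
        if (c$op == "=") st == c$state else st != c$state
      },
      cmp = {
        v <- fact_value(facts, c$question)
        if (is.null(v)) return(NA)
        eval_compare(v, c$op, c$rhs, c$question)
      })
  }
  ev(condition)
}

eval_compare <- function(value, op, rhs, question) {
  if (op %in% c("<", "<=", ">", ">=")) {
    if (inherits(value, "Date")) value <- as.numeric(value)
    if (inherits(rhs, "Date")) rhs <- as.numeric(rhs)
    if (!is.numeric(value) || !is.numeric(rhs)) {
      stop_knowsub(sprintf(
        "numeric comparison on non-numeric answer for question '%s'",
        question), "knowsub_evaluation_error")
    }
    return(switch(op, "<" = any(value < rhs), "<=" = any(value <= rhs),
                  ">" = any(value > rhs), ">=" = any(value >= rhs)))
  }
  if (op == "in") {
    rhs_chr <- map_chr(rhs, as.character)
    return(any(as.character(value) %in% rhs_chr))
  }
  # = / != ; numeric compared numerically, everything else as text.
  # For multi-valued answers '=' means 'contains'.
  eq <- if (is.numeric(rhs)) {
    if (!is.numeric(value)) {
      stop_knowsub(sprintf(
        "numeric comparison on non-numeric answer for question '%s'",
        question), "knowsub_evaluation_error")
    }
    any(value == rhs)
  } else {
    any(as.character(value) == as.character(rhs))
  }
  if (op == "=") eq else !eq
}

# --- module parsing ---------------------------------------------------------

empty_questions <- function() {
  tibble(id = character(), prompt = character(), value_type = character(),
         choices = list(), unit = character(), parent = character(),
         explanation = character())
}

empty_decisions <- function() {
  tibble(id = character(), label = character(), parent = character(),
         module = character())
}

empty_rules <- function() {
  tibble(id = character(), condition = list(), condition_text = character(),
         target = character(), category = character())
}

parse_error <- function(line_no, msg) {
  stop_knowsub(sprintf("line %d: %s", line_no, msg), "knowsub_parse_error")
}

link_error <- function(line_no, msg) {
  stop_knowsub(sprintf("line %d: %s", line_no, msg), "knowsub_link_error")
}

# split a line into quoted strings and bare tokens
split_decl <- function(s) {
  m <- gregexpr('"(?:[^"\\\\]|\\\\.)*"|\\S+', s, perl = TRUE)[[1]]
  if (m[[1]] < 0) return(character())
  mapply(function(start, len) substr(s, start, start + len - 1),
         m, attr(m, "match.length"))
}

parse_question_decl <- function(rest, line_no) {
  # id "prompt" type[(choices)] [unit=u] [explain="..."]
  m <- regmatches(rest, regexec(
    '^([A-Za-z_][A-Za-z0-9_.-]*)\\s+"((?:[^"\\\\]|\\\\.)*)"\\s+([a-z_]+(?:\\(([^)]*)\\))?)(.*)$',
    rest))[[1]]
  if (length(m) == 0) parse_error(line_no, "malformed question declaration")
  id <- m[[2]]
  prompt <- ttl_unescape(m[[3]])
  opts <- trimws(m[[6]])
  vt <- sub("\\(.*$", "", m[[4]])
  if (!vt %in% QUESTION_TYPES) {
    parse_error(line_no, sprintf("unknown question type '%s'", vt))
  }
  choices <- character()
  if (nzchar(m[[5]])) {
    choices <- trimws(strsplit(m[[5]], ",")[[1]])
  }
  if (vt %in% c("one_choice", "multi_choice") && length(choices) == 0) {
    parse_error(line_no, sprintf("choice question '%s' needs choices", id))
  }
  if (!vt %in% c("one_choice", "multi_choice") && length(choices) > 0) {
    parse_error(line_no, sprintf("non-choice question '%s' has choices", id))
  }
  unit <- NA_character_
  explanation <- NA_character_
  um <- regmatches(opts, regexec("unit=(\\S+)", opts))[[1]]
  if (length(um)) unit <- um[[2]]
  em <- regmatches(opts, regexec('explain="((?:[^"\\\\]|\\\\.)*)"',
                                 opts))[[1]]
  if (length(em)) explanation <- ttl_unescape(em[[2]])
  tibble(id = id, prompt = prompt, value_type = vt, choices = list(choices),
         unit = unit, parent = NA_character_, explanation = explanation)
}

parse_decision_decl <- function(rest, line_no, module_name) {
  m <- regmatches(rest, regexec(
    '^([A-Za-z_][A-Za-z0-9_.-]*)\\s+"((?:[^"\\\\]|\\\\.)*)"\\s*$', rest))[[1]]
  if (length(m) == 0) parse_error(line_no, "malformed decision declaration")
  tibble(id = m[[2]], label = ttl_unescape(m[[3]]), parent = NA_character_,
         module = module_name)
}

#' Parse a decision module from its plain-text dialect
#'
#' @param text module text (see the package vignette for the dialect).
#' @param known_questions,known_decisions ids declared by modules this one
#'   depends on; references to them are legal.
#' @return a `ks_module` list with elements `name`, `depends_on`,
#'   `questions`, `decisions`, `rules`, `workflows`.
#' @export
parse_module <- function(text, known_questions = character(),
                         known_decisions = character()) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  mod <- list(name = "", depends_on = character(),
              questions = empty_questions(), decisions = empty_decisions(),
              rules = empty_rules(), workflows = list())
  section <- NULL
  flow <- NULL
  # indentation stack for hierarchies: list of (indent, id)
  hier <- list()
  flush_flow <- function() {
    if (!is.null(flow)) {
      mod$workflows[[flow$name]] <<- finalize_flow(flow)
      flow <<- NULL
    }
  }
  for (ln in seq_along(lines)) {
    raw <- lines[[ln]]
    line <- sub("(^|\\s)#.*$", "", raw)
    if (!nzchar(trimws(line))) next
    indent <- nchar(line) - nchar(sub("^ *", "", line))
    body <- trimws(line)
    first <- sub("\\s.*$", "", body)
    rest <- trimws(sub("^\\S+\\s*", "", body))
    if (first == "MODULE") {
      mod$name <- rest
      next
    }
    if (first == "DEPENDS") {
      mod$depends_on <- trimws(strsplit(rest, ",")[[1]])
      next
    }
    if (first %in% c("QUESTIONS", "DECISIONS", "RULES")) {
      flush_flow()
      section <- first
      hier <- list()
      next
    }
    if (first == "FLOW") {
      flush_flow()
      section <- "FLOW"
      if (!nzchar(rest)) parse_error(ln, "FLOW needs a name")
      flow <- list(name = rest, nodes = list(), edges = list(), line = ln)
      next
    }
    if (is.null(section)) parse_error(ln, "content before any section")
    if (section == "QUESTIONS") {
      q <- parse_question_decl(body, ln)
      q$parent <- hier_parent(hier, indent)
      hier <- hier_push(hier, indent, q$id)
      if (q$id %in% mod$questions$id) {
        parse_error(ln, sprintf("duplicate question id '%s'", q$id))
      }
      mod$questions <- bind_rows(mod$questions, q)
    } else if (section == "DECISIONS") {
      d <- parse_decision_decl(body, ln, mod$name)
      d$parent <- hier_parent(hier, indent)
      hier <- hier_push(hier, indent, d$id)
      if (d$id %in% mod$decisions$id) {
        parse_error(ln, sprintf("duplicate decision id '%s'", d$id))
      }
      mod$decisions <- bind_rows(mod$decisions, d)
    } else if (section == "RULES") {
      m <- regmatches(body, regexec(
        "^RULE\\s+([A-Za-z_][A-Za-z0-9_.-]*)\\s*:\\s*IF\\s+(.*)\\s+THEN\\s+(\\S+)\\s+(N[1-7]|P[1-7])\\s*$",
        body))[[1]]
      if (length(m) == 0) parse_error(ln, "malformed RULE line")
      cond <- tryCatch(parse_condition(m[[3]]),
                       knowsub_parse_error = function(e) {
                         parse_error(ln, conditionMessage(e))
                       })
      mod$rules <- bind_rows(mod$rules, tibble(
        id = m[[2]], condition = list(cond), condition_text = m[[3]],
        target = m[[4]], category = m[[5]]))
    } else if (section == "FLOW") {
      flow <- parse_flow_line(flow, first, rest, ln)
    }
  }
  flush_flow()
  link_check_module(mod, known_questions, known_decisions)
  structure(mod, class = "ks_module")
}

hier_parent <- function(hier, indent) {
  while (length(hier) && hier[[length(hier)]]$indent >= indent) {
    hier[[length(hier)]] <- NULL
  }
  if (length(hier)) hier[[length(hier)]]$id else NA_character_
}

hier_push <- function(hier, indent, id) {
  while (length(hier) && hier[[length(hier)]]$indent >= indent) {
    hier[[length(hier)]] <- NULL
  }
  hier[[length(hier) + 1]] <- list(indent = indent, id = id)
  hier
}

parse_flow_line <- function(flow, first, rest, ln) {
  toks <- split_decl(rest)
  if (first == "START") {
    if (length(toks) != 1) parse_error(ln, "START takes one node id")
    flow$nodes[[length(flow$nodes) + 1]] <-
      tibble(id = toks[[1]], kind = "start", question = NA_character_,
             decision = NA_character_, state = NA_character_)
  } else if (first == "ASK") {
    if (length(toks) != 2) parse_error(ln, "ASK takes node id + question id")
    flow$nodes[[length(flow$nodes) + 1]] <-
      tibble(id = toks[[1]], kind = "ask", question = toks[[2]],
             decision = NA_character_, state = NA_character_)
  } else if (first == "DECIDE") {
    if (length(toks) != 3 || !toks[[3]] %in% DECISION_STATES) {
      parse_error(ln, "DECIDE takes node id + decision id + state")
    }
    flow$nodes[[length(flow$nodes) + 1]] <-
      tibble(id = toks[[1]], kind = "decide", question = NA_character_,
             decision = toks[[2]], state = toks[[3]])
  } else if (first == "EXIT") {
    if (length(toks) != 1) parse_error(ln, "EXIT takes one node id")
    flow$nodes[[length(flow$nodes) + 1]] <-
      tibble(id = toks[[1]], kind = "exit", question = NA_character_,
             decision = NA_character_, state = NA_character_)
  } else if (first == "EDGE") {
    m <- regmatches(rest, regexec(
      "^(\\S+)\\s*->\\s*(\\S+?)(\\s+IF\\s+(.*))?$", rest))[[1]]
    if (length(m) == 0) parse_error(ln, "malformed EDGE line")
    guard_text <- if (nzchar(m[[5]] %||% "")) m[[5]] else NA_character_
    guard <- if (!is.na(guard_text)) {
      tryCatch(parse_condition(guard_text),
               knowsub_parse_error = function(e) {
                 parse_error(ln, conditionMessage(e))
               })
    } else NULL
    flow$edges[[length(flow$edges) + 1]] <-
      tibble(from = m[[2]], to = m[[3]], guard = list(guard),
             guard_text = guard_text)
  } else {
    parse_error(ln, sprintf("unknown flow statement '%s'", first))
  }
  flow
}

finalize_flow <- function(flow) {
  nodes <- if (length(flow$nodes)) bind_rows(flow$nodes) else
    tibble(id = character(), kind = character(), question = character(),
           decision = character(), state = character())
  edges <- if (length(flow$edges)) bind_rows(flow$edges) else
    tibble(from = character(), to = character(), guard = list(),
           guard_text = character())
  if (sum(nodes$kind == "start") != 1) {
    stop_knowsub(sprintf("flow '%s' must have exactly one start node",
                         flow$name), "knowsub_structure_error")
  }
  bad <- setdiff(c(edges$from, edges$to), nodes$id)
  if (length(bad)) {
    stop_knowsub(sprintf("flow '%s': edge references unknown node '%s'",
                         flow$name, bad[[1]]), "knowsub_link_error")
  }
  # acyclicity via Kahn's algorithm
  remaining <- nodes$id
  es <- edges[, c("from", "to")]
  repeat {
    sinks <- remaining[!remaining %in% es$from]
    if (length(sinks) == 0) break
    remaining <- setdiff(remaining, sinks)
    es <- es[!es$to %in% sinks, , drop = FALSE]
  }
  if (length(remaining)) {
    stop_knowsub(sprintf("flow '%s' contains a cycle through '%s'",
                         flow$name, remaining[[1]]),
                 "knowsub_structure_error")
  }
  no_out <- nodes$id[nodes$kind != "exit" & !nodes$id %in% edges$from]
  if (length(no_out)) {
    stop_knowsub(sprintf(
      "flow '%s': non-exit node '%s' has no outgoing edge",
      flow$name, no_out[[1]]), "knowsub_structure_error")
  }
  list(name = flow$name, nodes = nodes, edges = edges)
}

link_check_module <- function(mod, known_questions, known_decisions) {
  qids <- c(mod$questions$id, known_questions)
  dids <- c(mod$decisions$id, known_decisions)
  # question hierarchy forms a forest by construction (parents precede
  # children in the indentation stack), so only references need checking
  check_cond <- function(cond, what) {
    for (q in condition_questions(cond)) {
      if (!q %in% qids) {
        stop_knowsub(sprintf("%s references undeclared question '%s'",
                             what, q), "knowsub_link_error")
      }
    }
    for (d in condition_decisions(cond)) {
      if (!d %in% dids) {
        stop_knowsub(sprintf("%s references undeclared decision '%s'",
                             what, d), "knowsub_link_error")
      }
    }
  }
  for (i in seq_len(nrow(mod$rules))) {
    check_cond(mod$rules$condition[[i]],
               sprintf("rule '%s'", mod$rules$id[[i]]))
    if (!mod$rules$target[[i]] %in% mod$decisions$id) {
      stop_knowsub(sprintf("rule '%s' targets undeclared decision '%s'",
                           mod$rules$id[[i]], mod$rules$target[[i]]),
                   "knowsub_link_error")
    }
  }
  for (wf in mod$workflows) {
    asks <- wf$nodes$question[wf$nodes$kind == "ask"]
    for (q in asks) {
      if (!q %in% qids) {
        stop_knowsub(sprintf("flow '%s' asks undeclared question '%s'",
                             wf$name, q), "knowsub_link_error")
      }
    }
    decs <- wf$nodes$decision[wf$nodes$kind == "decide"]
    for (d in decs) {
      if (!d %in% dids) {
        stop_knowsub(sprintf("flow '%s' decides undeclared decision '%s'",
                             wf$name, d), "knowsub_link_error")
      }
    }
    for (i in seq_len(nrow(wf$edges))) {
      g <- wf$edges$guard[[i]]
      if (!is.null(g)) check_cond(g, sprintf("flow '%s' guard", wf$name))
    }
  }
  invisible(mod)
}

#' Serialize a module back to its plain-text dialect
#'
#' `parse_module(format_module(mod))` reproduces `mod`.
#'
#' @param mod a `ks_module`.
#' @return a single string of module text.
#' @export
format_module <- function(mod) {
  out <- c(paste("MODULE", mod$name))
  if (length(mod$depends_on)) {
    out <- c(out, paste("DEPENDS", paste(mod$depends_on, collapse = ", ")))
  }
  esc <- function(x) ttl_escape(x)
  depth_of <- function(df, id) {
    d <- 0L
    p <- df$parent[df$id == id]
    while (length(p) && !is.na(p)) {
      d <- d + 1L
      p <- df$parent[df$id == p]
    }
    d
  }
  if (nrow(mod$questions)) {
    out <- c(out, "QUESTIONS")
    for (i in seq_len(nrow(mod$questions))) {
      q <- mod$questions[i, ]
      ty <- q$value_type
      if (length(q$choices[[1]])) {
        ty <- sprintf("%s(%s)", ty, paste(q$choices[[1]], collapse = ", "))
      }
      line <- sprintf('%s%s "%s" %s',
                      strrep("  ", depth_of(mod$questions, q$id) + 1),
                      q$id, esc(q$prompt), ty)
      if (!is.na(q$unit)) line <- paste0(line, " unit=", q$unit)
      if (!is.na(q$explanation)) {
        line <- paste0(line, ' explain="', esc(q$explanation), '"')
      }
      out <- c(out, line)
    }
  }
  if (nrow(mod$decisions)) {
    out <- c(out, "DECISIONS")
    for (i in seq_len(nrow(mod$decisions))) {
      d <- mod$decisions[i, ]
      out <- c(out, sprintf('%s%s "%s"',
                            strrep("  ", depth_of(mod$decisions, d$id) + 1),
                            d$id, esc(d$label)))
    }
  }
  if (nrow(mod$rules)) {
    out <- c(out, "RULES")
    for (i in seq_len(nrow(mod$rules))) {
      r <- mod$rules[i, ]
      out <- c(out, sprintf("  RULE %s: IF %s THEN %s %s", r$id,
                            format_condition(r$condition[[1]]), r$target,
                            r$category))
    }
  }
  for (wf in mod$workflows) {
    out <- c(out, paste("FLOW", wf$name))
    for (i in seq_len(nrow(wf$nodes))) {
      n <- wf$nodes[i, ]
      out <- c(out, switch(n$kind,
        start = sprintf("  START %s", n$id),
        ask = sprintf("  ASK %s %s", n$id, n$question),
        decide = sprintf("  DECIDE %s %s %s", n$id, n$decision, n$state),
        exit = sprintf("  EXIT %s", n$id)))
    }
    for (i in seq_len(nrow(wf$edges))) {
      e <- wf$edges[i, ]
      line <- sprintf("  EDGE %s -> %s", e$from, e$to)
      if (!is.null(e$guard[[1]])) {
        line <- paste0(line, " IF ", format_condition(e$guard[[1]]))
      }
      out <- c(out, line)
    }
  }
  paste(out, collapse = "\n")
}

#' @export
print.ks_module <- function(x, ...) {
  cat(sprintf("<ks_module> %s: %d questions, %d decisions, %d rules, %d flows\n",
              x$name, nrow(x$questions), nrow(x$decisions), nrow(x$rules),
              length(x$workflows)))
  invisible(x)
}

# --- registry ---------------------------------------------------------------

#' Assemble modules into a registry
#'
#' The registry is the shared ontology of all modules: question and decision
#' ids are global, `depends_on` links must be acyclic, and evaluation
#' proceeds in dependency order.
#'
#' @param modules list of `ks_module` objects (any order).
#' @param thresholds score thresholds mapping summed rule scores to states.
#' @return a `ks_registry` list.
#' @export
ks_registry <- function(modules,
                        thresholds = c(established = 42, suggested = 10,
                                       excluded = -42)) {
  names(modules) <- map_chr(modules, "name")
  reg <- structure(list(modules = modules, thresholds = thresholds),
                   class = "ks_registry")
  reg$order <- module_order(reg)
  reg
}

module_order <- function(registry) {
  mods <- registry$modules
  remaining <- names(mods)
  order <- character()
  while (length(remaining)) {
    ready <- keep(remaining, function(m) {
      deps <- intersect(mods[[m]]$depends_on, names(mods))
      all(deps %in% order)
    })
    if (length(ready) == 0) {
      stop_knowsub(sprintf("dependency cycle among modules: %s",
                           paste(remaining, collapse = ", ")),
                   "knowsub_registry_error")
    }
    order <- c(order, sort(unlist(ready)))
    remaining <- setdiff(remaining, ready)
  }
  order
}

registry_questions <- function(registry) {
  bind_rows(map(registry$modules, "questions"))
}

registry_decisions <- function(registry) {
  bind_rows(map(registry$modules, "decisions"))
}

#' Load a registry from a YAML manifest
#'
#' The manifest names module files in dependency order:
#' ```yaml
#' modules:
#'   - persistence.kb
#'   - bioaccumulation.kb
#' ```
#' Paths are resolved relative to the manifest.
#'
#' @param manifest_path path to the YAML manifest.
#' @return a `ks_registry`.
#' @export
load_registry <- function(manifest_path) {
  spec <- yaml::read_yaml(manifest_path)
  base <- dirname(manifest_path)
  mods <- list()
  known_q <- character()
  known_d <- character()
  for (f in spec$modules) {
    path <- file.path(base, f)
    if (!file.exists(path)) {
      stop_knowsub(sprintf("module file not found: %s", path),
                   "knowsub_io_error")
    }
    text <- paste(readLines(path, encoding = "UTF-8", warn = FALSE),
                  collapse = "\n")
    mod <- parse_module(text, known_questions = known_q,
                        known_decisions = known_d)
    mods[[length(mods) + 1]] <- mod
    known_q <- c(known_q, mod$questions$id)
    known_d <- c(known_d, mod$decisions$id)
  }
  thresholds <- c(established = 42, suggested = 10, excluded = -42)
  if (!is.null(spec$thresholds)) {
    thresholds[names(spec$thresholds)] <- unlist(spec$thresholds)
  }
  ks_registry(mods, thresholds = thresholds)
}

#' Validate a module registry
#'
#' Reports duplicate ids across modules, dangling `depends_on` entries,
#' dangling cross-module references and unreachable workflow nodes. An empty
#' result means the registry is well-formed.
#'
#' @param registry a `ks_registry` (or bare list of modules).
#' @return a tibble of issues with columns `kind`, `module`, `detail`.
#' @export
validate_registry <- function(registry) {
  if (!inherits(registry, "ks_registry")) registry <- ks_registry(registry)
  issues <- list()
  add <- function(kind, module, detail) {
    issues[[length(issues) + 1]] <<- tibble(kind = kind, module = module,
                                            detail = detail)
  }
  mods <- registry$modules
  qs <- registry_questions(registry)
  ds <- registry_decisions(registry)
  for (dup in unique(qs$id[duplicated(qs$id)])) {
    add("duplicate_id", NA_character_,
        sprintf("question id '%s' declared in more than one module", dup))
  }
  for (dup in unique(ds$id[duplicated(ds$id)])) {
    add("duplicate_id", NA_character_,
        sprintf("decision id '%s' declared in more than one module", dup))
  }
  both <- intersect(qs$id, ds$id)
  for (b in both) {
    add("duplicate_id", NA_character_,
        sprintf("id '%s' used for both a question and a decision", b))
  }
  for (m in names(mods)) {
    for (dep in mods[[m]]$depends_on) {
      if (!dep %in% names(mods)) {
        add("dangling_dependency", m,
            sprintf("module '%s' depends on missing module '%s'", m, dep))
      }
    }
    for (i in seq_len(nrow(mods[[m]]$rules))) {
      cond <- mods[[m]]$rules$condition[[i]]
      for (d in condition_decisions(cond)) {
        if (!d %in% ds$id) {
          add("dangling_reference", m,
              sprintf("rule '%s' references unknown decision '%s'",
                      mods[[m]]$rules$id[[i]], d))
        }
      }
      for (q in condition_questions(cond)) {
        if (!q %in% qs$id) {
          add("dangling_reference", m,
              sprintf("rule '%s' references unknown question '%s'",
                      mods[[m]]$rules$id[[i]], q))
        }
      }
    }
    for (wf in mods[[m]]$workflows) {
      start <- wf$nodes$id[wf$nodes$kind == "start"]
      reach <- start
      repeat {
        nxt <- unique(wf$edges$to[wf$edges$from %in% reach])
        new <- setdiff(nxt, reach)
        if (length(new) == 0) break
        reach <- c(reach, new)
      }
      for (orphan in setdiff(wf$nodes$id, reach)) {
        add("unreachable_node", m,
            sprintf("flow '%s': node '%s' is unreachable from start",
                    wf$name, orphan))
      }
    }
  }
  if (length(issues)) bind_rows(issues) else
    tibble(kind = character(), module = character(), detail = character())
}
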