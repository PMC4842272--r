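# Interactive interview: ask only indicated, unanswered questions of a
# decision module; finish when the module's decisions are determined.
# Sessions are plain values — answering returns a new session — so
# transcripts are reproducible and interview answers feed the same stateless
# evaluation as bulk facts.

#' Compute a module's current question agenda
#'
#' Agenda policy: ask-nodes reachable from each workflow's start node along
#' edges whose guard is not false under the current facts (traversal order),
#' followed by the module's declared questions not asked by any workflow
#' (declaration order). Answered questions — including values reused from
#' other modules and explicit "unknown" answers — are skipped.
#'
#' @param registry a `ks_registry`.
#' @param module_name module whose agenda to compute.
#' @param facts current facts (named list or fact log).
#' @return character vector of question ids, possibly empty.
#' @export
compute_agenda <- function(registry, module_name, facts) {
  mod <- registry$modules[[module_name]]
  if (is.null(mod)) {
    stop_knowsub(sprintf("unknown module '%s'", module_name),
                 "knowsub_not_found_error")
  }
  fl <- as_fact_list(facts)
  dm <- ks_evaluate(registry, fl)
  states <- stats::setNames(dm$state, dm$decision)
  answered <- names(fl)
  agenda <- character()
  flow_questions <- character()
  for (wf in mod$workflows) {
    # nodes reachable while no guard on the way is definitely false
    frontier <- wf$nodes$id[wf$nodes$kind == "start"]
    reached <- frontier
    while (length(frontier)) {
      nxt <- character()
      for (nid in frontier) {
        out_edges <- which(wf$edges$from == nid)
        for (i in out_edges) {
          g <- wf$edges$guard[[i]]
          passable <- is.null(g) ||
            !isFALSE(evaluate_condition(g, fl, states))
          if (passable && !wf$edges$to[[i]] %in% reached) {
            nxt <- c(nxt, wf$edges$to[[i]])
          }
        }
      }
      reached <- c(reached, nxt)
      frontier <- nxt
    }
    for (nid in reached) {
      node <- wf$nodes[wf$nodes$id == nid, ]
      if (nrow(node) && node$kind == "ask") {
        flow_questions <- c(flow_questions, node$question)
        if (!node$question %in% answered) {
          agenda <- c(agenda, node$question)
        }
      }
    }
  }
  all_flow_qs <- unique(unlist(map(mod$workflows, function(wf) {
    wf$nodes$question[wf$nodes$kind == "ask"]
  })))
  init <- setdiff(mod$questions$id, all_flow_qs)
  agenda <- c(agenda, setdiff(init, answered))
  unique(agenda)
}

#' Start an interactive interview for a decision module
#'
#' @param registry a `ks_registry`.
#' @param module_name module to interview for.
#' @param facts existing facts (values entered in other modules are reused
#'   and their questions are not re-asked).
#' @param substance substance URI the session concerns (metadata only).
#' @return a `ks_session` list with fields `substance`, `module`, `agenda`,
#'   `log` (fact log of answers given in this session), `facts` (named
#'   list), `decisions` (current decision map) and `status`
#'   (`"running"`/`"finished"`).
#' @export
start_interview <- function(registry, module_name, facts = list(),
                            substance = NA_character_) {
  fl <- as_fact_list(facts)
  agenda <- compute_agenda(registry, module_name, fl)
  session <- list(
    substance = substance,
    module = module_name,
    registry = registry,
    facts = fl,
    log = empty_fact_log(),
    agenda = agenda,
    decisions = ks_evaluate(registry, fl),
    status = if (length(agenda)) "running" else "finished"
  )
  class(session) <- "ks_session"
  session
}

check_answer_type <- function(question_row, value) {
  if (length(value) == 1 && is.na(value)) return(invisible(TRUE)) # "unknown"
  vt <- question_row$value_type
  ok <- switch(vt,
    numeric = is.numeric(value) && length(value) == 1,
    text = is.character(value) && length(value) == 1,
    date = inherits(value, "Date") && length(value) == 1,
    one_choice = is.character(value) && length(value) == 1 &&
      value %in% question_row$choices[[1]],
    multi_choice = is.character(value) && length(value) >= 1 &&
      all(value %in% question_row$choices[[1]]))
  if (!isTRUE(ok)) {
    stop_knowsub(sprintf(
      "answer to question '%s' does not conform to type %s%s",
      question_row$id, vt,
      if (vt %in% c("one_choice", "multi_choice")) {
        sprintf(" (choices: %s)",
                paste(question_row$choices[[1]], collapse = ", "))
      } else ""), "knowsub_validation_error")
  }
  invisible(TRUE)
}

#' Answer a question in an interview session
#'
#' The fact is recorded with timestamp and author, inference is re-run and
#' the agenda recomputed: newly reachable ask-nodes join it, questions made
#' irrelevant by the answer leave it. `NA` is the admissible "unknown"
#' answer to any question — it is recorded but leaves conditions undefined.
#'
#' @param session a `ks_session`.
#' @param question_id question being answered.
#' @param value the typed answer (`NA` for unknown).
#' @param author who answers.
#' @param timestamp answer time (defaults to now, UTC).
#' @return the updated `ks_session`.
#' @export
answer <- function(session, question_id, value, author = "user",
                   timestamp = Sys.time()) {
  qs <- registry_questions(session$registry)
  qrow <- qs[qs$id == question_id, , drop = FALSE]
  if (nrow(qrow) == 0) {
    stop_knowsub(sprintf("unknown question '%s'", question_id),
                 "knowsub_not_found_error")
  }
  check_answer_type(qrow[1, ], value)
  if (!question_id %in% session$agenda) {
    warn(sprintf("question '%s' is not on the agenda; recording anyway",
                 question_id))
  }
  session$facts[[question_id]] <- value
  session$log <- append_fact(session$log, session$substance, question_id,
                             value, timestamp = timestamp, author = author,
                             source = "user")
  session$decisions <- ks_evaluate(session$registry, session$facts)
  session$agenda <- compute_agenda(session$registry, session$module,
                                   session$facts)
  session$status <- if (length(session$agenda)) "running" else "finished"
  session
}

#' The next question to ask, or NULL when the interview is finished
#'
#' @param session a `ks_session`.
#' @return question id (character scalar) or `NULL`.
#' @export
next_question <- function(session) {
  if (length(session$agenda) == 0) NULL else session$agenda[[1]]
}

#' @export
print.ks_session <- function(x, ...) {
  cat(sprintf("<ks_session> module %s (%s): %d question(s) on agenda\n",
              x$module, x$status, length(x$agenda)))
  if (length(x$agenda)) {
    qs <- registry_questions(x$registry)
    nq <- next_question(x)
    prompt <- qs$prompt[qs$id == nq]
    cat(sprintf("  next: %s — %s\n", nq, prompt))
  }
  invisible(x)
}

#' Run a scripted interview to completion
#'
#' Repeatedly asks [next_question()] and answers it from `script`; questions
#' the script has no entry for are answered "unknown". Used by the CLI's
#' scripted mode and by reproducibility checks.
#'
#' @param registry a `ks_registry`.
#' @param module_name module to interview for.
#' @param script named list question id -> value.
#' @param facts pre-existing facts.
#' @return the finished `ks_session`.
#' @export
run_scripted_interview <- function(registry, module_name, script,
                                   facts = list()) {
  session <- start_interview(registry, module_name, facts)
  base <- as.POSIXct("2016-01-01 00:00:00", tz = "UTC")
  step <- 0L
  while (session$status == "running") {
    q <- next_question(session)
    v <- if (q %in% names(script)) script[[q]] else NA
    step <- step + 1L
    session <- answer(session, q, v, author = "script",
                      timestamp = base + step)
  }
  session
}
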