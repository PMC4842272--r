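# Provenance: append-only timestamped fact history per substance, the
# time machine reconstructing previously valid decisions, and decision
# memos with optional attached formal decisions.

#' An empty fact log
#'
#' Columns: `substance`, `question`, `value` (list-column of typed values),
#' `timestamp` (POSIXct, UTC), `seq` (monotone tie-break), `author`,
#' `source` (`user`/`import`/`derived`), `reliability` (optional Klimisch
#' score 1-4 for measured data).
#'
#' @return a zero-row `ks_fact_history` tibble.
#' @export
fact_history <- function() {
  structure(
    tibble(substance = character(), question = character(), value = list(),
           timestamp = as.POSIXct(character(), tz = "UTC"), seq = integer(),
           author = character(), source = character(),
           reliability = integer()),
    class = c("ks_fact_history", class(tibble())))
}

empty_fact_log <- fact_history

append_fact <- function(history, substance, question, value,
                        timestamp = Sys.time(), author = "user",
                        source = "user", reliability = NA_integer_) {
  nseq <- if (nrow(history)) max(history$seq) + 1L else 1L
  row <- tibble(substance = substance, question = question,
                value = list(value),
                timestamp = as.POSIXct(timestamp, tz = "UTC"),
                seq = nseq, author = author, source = source,
                reliability = as.integer(reliability))
  out <- bind_rows(history, row)
  class(out) <- class(history)
  out
}

#' Record a fact in the history (append-only)
#'
#' Within one (substance, question) key timestamps must not decrease — a
#' correction is a *new* fact, never an edit. The current value of a
#' question is its latest entry.
#'
#' @param history a `ks_fact_history`.
#' @param substance substance URI.
#' @param question question id.
#' @param value typed value (`NA` for an explicit unknown).
#' @param timestamp fact time (POSIXct; coerced to UTC).
#' @param author acting team member.
#' @param source one of `user`, `import`, `derived`.
#' @param reliability optional Klimisch score (1-4).
#' @return the extended history.
#' @export
record_fact <- function(history, substance, question, value,
                        timestamp = Sys.time(), author = "user",
                        source = "user", reliability = NA_integer_) {
  if (!source %in% c("user", "import", "derived")) {
    stop_knowsub(sprintf("invalid fact source '%s'", source),
                 "knowsub_validation_error")
  }
  if (!is.na(reliability) && !reliability %in% 1:4) {
    stop_knowsub("reliability must be a Klimisch score 1-4",
                 "knowsub_validation_error")
  }
  timestamp <- as.POSIXct(timestamp, tz = "UTC")
  prior <- history[history$substance == substance &
                   history$question == question, , drop = FALSE]
  if (nrow(prior) && timestamp < max(prior$timestamp)) {
    stop_knowsub(sprintf(
      "out-of-order fact for (%s, %s): %s is earlier than latest %s",
      substance, question, format(timestamp, tz = "UTC"),
      format(max(prior$timestamp), tz = "UTC")),
      "knowsub_chronology_error")
  }
  append_fact(history, substance, question, value, timestamp, author,
              source, reliability)
}

#' Facts of one substance as a question -> value list (latest value wins)
#'
#' @param history a `ks_fact_history`.
#' @param substance substance URI.
#' @param at optional instant: use only facts with `timestamp <= at`.
#' @return named list of current values.
#' @export
current_facts <- function(history, substance, at = NULL) {
  h <- history[history$substance == substance, , drop = FALSE]
  if (!is.null(at)) {
    h <- h[h$timestamp <= as.POSIXct(at, tz = "UTC"), , drop = FALSE]
  }
  as_fact_list(h)
}

#' Reconstruct the decision map valid at an earlier instant (time machine)
#'
#' Equals a fresh evaluation of the fact set `{latest fact per question with
#' timestamp <= t}`; with `t = now` it equals the live evaluation.
#'
#' @param registry a `ks_registry`.
#' @param history a `ks_fact_history`.
#' @param substance substance URI.
#' @param t the instant to reconstruct.
#' @return a `ks_decision_map`.
#' @export
decisions_at <- function(registry, history, substance, t) {
  ks_evaluate(registry, current_facts(history, substance, at = t))
}

#' Persist / reload a fact log as CSV
#'
#' Values are serialized as text (multi-choice values joined with `|`);
#' numbers are restored as numerics on reload, everything else as text.
#'
#' @param history a `ks_fact_history`.
#' @param path CSV path.
#' @return `path` invisibly / the reloaded history.
#' @export
write_fact_log <- function(history, path) {
  flat <- tibble(
    substance = history$substance,
    question = history$question,
    value = map_chr(history$value, function(v) {
      if (length(v) == 1 && is.na(v)) "" else
        paste(format(v, scientific = FALSE, trim = TRUE), collapse = "|")
    }),
    timestamp = format(history$timestamp, "%Y-%m-%dT%H:%M:%OS3Z",
                       tz = "UTC"),
    seq = history$seq,
    author = history$author,
    source = history$source,
    reliability = history$reliability
  )
  readr::write_csv(flat, path, na = "")
  invisible(path)
}

#' @rdname write_fact_log
#' @export
read_fact_log <- function(path) {
  flat <- readr::read_csv(path, col_types = readr::cols(
    substance = "c", question = "c", value = "c", timestamp = "c",
    seq = "i", author = "c", source = "c", reliability = "i"))
  h <- fact_history()
  for (i in seq_len(nrow(flat))) {
    raw <- flat$value[[i]]
    v <- if (is.na(raw) || !nzchar(raw)) NA
    else if (grepl("\\|", raw)) strsplit(raw, "|", fixed = TRUE)[[1]]
    else if (grepl("^-?[0-9]+(\\.[0-9]+)?([eE][+-]?[0-9]+)?$", raw)) {
      as.numeric(raw)
    } else raw
    h <- append_fact(h, flat$substance[[i]], flat$question[[i]], v,
                     timestamp = as.POSIXct(flat$timestamp[[i]],
                                            format = "%Y-%m-%dT%H:%M:%OSZ",
                                            tz = "UTC"),
                     author = flat$author[[i]], source = flat$source[[i]],
                     reliability = flat$reliability[[i]])
  }
  h$seq <- flat$seq
  h
}

# --- decision memos ---------------------------------------------------------

#' Create a decision memo
#'
#' Free-text documentation attached to a substance; optionally carries a
#' formal decision (e.g. the memo "Toxic" attaching "T criterion
#' fulfilled").
#'
#' @param substance substance URI.
#' @param title,body memo text.
#' @param attached_decision optional decision id from the registry.
#' @param author author name.
#' @param created_at creation instant.
#' @return a `ks_memo` list.
#' @export
ks_memo <- function(substance, title, body = "", attached_decision = NULL,
                    author = "user", created_at = Sys.time()) {
  structure(list(substance = substance, title = title, body = body,
                 attached_decision = attached_decision, author = author,
                 created_at = as.POSIXct(created_at, tz = "UTC")),
            class = "ks_memo")
}

#' Add a memo to the store
#'
#' The memo is persisted as triples (`ks:Memo` node with title, body,
#' author, creation time and optional attached decision), so SPARQL views
#' reach it.
#'
#' @param store a `ks_store`.
#' @param memo a [ks_memo()].
#' @param registry optional `ks_registry`; when given, an attached decision
#'   must exist in it.
#' @return the memo id (URI).
#' @export
add_memo <- function(store, memo, registry = NULL) {
  if (!memo$substance %in% substance_uris(store)) {
    stop_knowsub(sprintf("unknown substance <%s>", memo$substance),
                 "knowsub_not_found_error")
  }
  if (!is.null(memo$attached_decision) && !is.null(registry)) {
    if (!memo$attached_decision %in% registry_decisions(registry)$id) {
      stop_knowsub(sprintf("attached decision '%s' not in registry",
                           memo$attached_decision), "knowsub_link_error")
    }
  }
  t <- store$triples
  n <- sum(t$p == RDF_TYPE & t$o == ks_term(store, "Memo"))
  id <- ks_term(store, sprintf("memo_%04d", n + 1L))
  add_triple(store, id, RDF_TYPE, ks_term(store, "Memo"))
  add_triple(store, id, ks_term(store, "aboutSubstance"), memo$substance)
  add_triple(store, id, ks_term(store, "memoTitle"), memo$title, "literal")
  if (nzchar(memo$body)) {
    add_triple(store, id, ks_term(store, "memoBody"), memo$body, "literal")
  }
  add_triple(store, id, ks_term(store, "memoAuthor"), memo$author, "literal")
  add_triple(store, id, ks_term(store, "memoCreated"),
             format(memo$created_at, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
             "literal")
  if (!is.null(memo$attached_decision)) {
    add_triple(store, id, ks_term(store, "attachedDecision"),
               memo$attached_decision, "literal")
  }
  id
}

#' List a substance's memos, ordered by creation time
#'
#' @param store a `ks_store`.
#' @param substance substance URI.
#' @return tibble with columns `id`, `title`, `body`, `author`,
#'   `created_at`, `attached_decision`, ascending by `created_at`.
#' @export
list_memos <- function(store, substance) {
  t <- store$triples
  ids <- t$s[t$p == ks_term(store, "aboutSubstance") & t$o == substance]
  get1 <- function(id, pred) {
    v <- t$o[t$s == id & t$p == ks_term(store, pred)]
    if (length(v)) v[[1]] else NA_character_
  }
  out <- tibble(
    id = ids,
    title = map_chr(ids, get1, "memoTitle"),
    body = map_chr(ids, get1, "memoBody"),
    author = map_chr(ids, get1, "memoAuthor"),
    created_at = as.POSIXct(map_chr(ids, get1, "memoCreated"),
                            format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    attached_decision = map_chr(ids, get1, "attachedDecision")
  )
  out[order(out$created_at, out$id), , drop = FALSE]
}
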