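# Dynamic views (named SPARQL queries rendered as tables), CSV export,
# bulk substance import and the substance info page.

#' Define a dynamic view
#'
#' A view is a named SPARQL SELECT query that is re-executed against the
#' current store state on every rendering (never cached).
#'
#' @param name view name (unique within a view registry).
#' @param sparql SELECT query text; parsed eagerly so broken views fail at
#'   definition time.
#' @param description one-line description.
#' @return a `ks_view` list.
#' @export
view_definition <- function(name, sparql, description = "") {
  q <- sparql_parse(sparql)
  if (q$form != "select") {
    stop_knowsub(sprintf("view '%s' must be a SELECT query", name),
                 "knowsub_view_error")
  }
  structure(list(name = name, sparql = sparql, description = description),
            class = "ks_view")
}

#' Load view definitions from a directory of .rq files
#'
#' The view name is the file name without extension; leading `#` comment
#' lines form the description.
#'
#' @param dir directory containing `*.rq` SPARQL files.
#' @return named list of `ks_view` objects.
#' @export
load_views <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.rq$", full.names = TRUE))
  views <- list()
  for (f in files) {
    lines <- readLines(f, encoding = "UTF-8", warn = FALSE)
    desc_lines <- character()
    for (l in lines) {
      if (grepl("^\\s*#", l)) {
        desc_lines <- c(desc_lines, sub("^\\s*#\\s?", "", l))
      } else if (nzchar(trimws(l))) break
    }
    name <- sub("\\.rq$", "", basename(f))
    views[[name]] <- view_definition(name, paste(lines, collapse = "\n"),
                                     paste(desc_lines, collapse = " "))
  }
  views
}

#' Render a dynamic view against the current store state
#'
#' @param store a `ks_store`.
#' @param view a `ks_view` (or raw SPARQL text).
#' @return a tibble (deterministic row order).
#' @export
render_view <- function(store, view) {
  sparql <- if (inherits(view, "ks_view")) view$sparql else view
  name <- if (inherits(view, "ks_view")) view$name else "<inline>"
  tryCatch(ks_query(store, sparql),
           knowsub_error = function(e) {
             stop_knowsub(sprintf("view '%s' failed: %s", name,
                                  conditionMessage(e)),
                          "knowsub_view_error")
           })
}

#' Export a result table as CSV or TSV
#'
#' RFC-4180-compliant output; a round-trip read reproduces the table.
#' Identical store states export byte-identical files.
#'
#' @param table a data frame / tibble.
#' @param path output path.
#' @param format `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
export_table <- function(table, path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  if (format == "csv") readr::write_csv(table, path, na = "")
  else readr::write_tsv(table, path, na = "")
  invisible(path)
}

#' Bulk-import substances (and facts) from a CSV table
#'
#' The header must contain `label`; `ec`, `cas`, `iupac`, `smiles` are
#' recognized identifier columns and any further column is treated as a
#' question id whose non-empty cells are recorded as import-sourced facts.
#' Rows whose CAS or EC fails its checksum are rejected with a reason.
#' Existing substances are merged, matching on CAS first, then EC, then
#' exact label; importing the same file twice therefore creates nothing new.
#'
#' @param store a `ks_store`.
#' @param history a `ks_fact_history` facts are appended to.
#' @param path CSV path.
#' @param timestamp timestamp for recorded facts.
#' @return a list: `summary` (tibble with `created`, `merged`,
#'   `facts_recorded`, `rejected`), `rejected` (tibble `row`, `label`,
#'   `reason`), `history` (the extended fact log).
#' @export
import_substances <- function(store, history, path,
                              timestamp = Sys.time()) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"))
  if (!"label" %in% names(df)) {
    stop_knowsub("import file lacks the required 'label' column",
                 "knowsub_format_error")
  }
  id_cols <- intersect(c("label", "ec", "cas", "iupac", "smiles"), names(df))
  question_cols <- setdiff(names(df), c(id_cols, "comment"))
  created <- 0L
  merged <- 0L
  facts_recorded <- 0L
  rejected <- list()
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    get <- function(col) {
      v <- if (col %in% names(row)) row[[col]] else NA_character_
      if (is.na(v) || !nzchar(v)) NULL else v
    }
    cas <- get("cas")
    ec <- get("ec")
    reason <- NULL
    if (!is.null(cas) && !validate_cas(cas)$checksum_ok) {
      reason <- sprintf("bad_checksum: CAS %s", cas)
    } else if (!is.null(ec) && !validate_ec(ec)$checksum_ok) {
      reason <- sprintf("bad_checksum: EC %s", ec)
    }
    if (!is.null(reason)) {
      rejected[[length(rejected) + 1]] <-
        tibble(row = i, label = get("label") %||% NA_character_,
               reason = reason)
      next
    }
    # merge key: CAS, then EC, then exact label
    t <- store$triples
    find_by <- function(pred, value) {
      if (is.null(value)) return(character())
      t$s[t$p == ks_term(store, pred) & t$o == value]
    }
    existing <- find_by("hasCAS", cas)
    if (length(existing) == 0) existing <- find_by("hasEC", ec)
    if (length(existing) == 0) existing <- find_by("hasLabel", get("label"))
    if (length(existing)) {
      uri <- existing[[1]]
      merged <- merged + 1L
      # add identifiers absent so far
      maybe_add <- function(pred, value) {
        if (!is.null(value) &&
            !any(t$s == uri & t$p == ks_term(store, pred) & t$o == value)) {
          add_triple(store, uri, ks_term(store, pred), value, "literal")
        }
      }
      maybe_add("hasCAS", cas)
      maybe_add("hasEC", ec)
      maybe_add("hasIUPAC", get("iupac"))
      maybe_add("hasSMILES", get("smiles"))
    } else {
      uri <- add_substance(store, substance_record(
        label = get("label"), cas_number = cas, ec_number = ec,
        iupac_name = get("iupac"), smiles = get("smiles")))
      created <- created + 1L
    }
    for (qc in question_cols) {
      v <- get(qc)
      if (is.null(v)) next
      tv <- if (grepl("^-?[0-9]+(\\.[0-9]+)?([eE][+-]?[0-9]+)?$", v)) {
        as.numeric(v)
      } else v
      history <- record_fact(history, uri, qc, tv, timestamp = timestamp,
                             author = "import", source = "import")
      facts_recorded <- facts_recorded + 1L
    }
  }
  rej <- if (length(rejected)) bind_rows(rejected) else
    tibble(row = integer(), label = character(), reason = character())
  list(
    summary = tibble(created = created, merged = merged,
                     facts_recorded = facts_recorded, rejected = nrow(rej)),
    rejected = rej,
    history = history
  )
}

#' Export the substance identifier table
#'
#' The inverse of [import_substances()]: identifier columns round-trip
#' losslessly.
#'
#' @param store a `ks_store`.
#' @return tibble with columns `label`, `ec`, `cas`, `iupac`, `smiles`,
#'   sorted by label.
#' @export
substance_table <- function(store) {
  subs <- substance_uris(store)
  rows <- map(subs, function(u) {
    ids <- substance_identifiers(store, u)
    one <- function(x) if (length(x[[1]])) x[[1]][[1]] else NA_character_
    tibble(label = one(ids$label), ec = one(ids$ec), cas = one(ids$cas),
           iupac = one(ids$iupac), smiles = one(ids$smiles))
  })
  out <- if (length(rows)) bind_rows(rows) else
    tibble(label = character(), ec = character(), cas = character(),
           iupac = character(), smiles = character())
  out[order(out$label), , drop = FALSE]
}

#' Render a substance's info page
#'
#' A plain-markdown summary in fixed section order: identifiers, current
#' decisions (grouped by module, final — i.e. top-of-hierarchy — decisions
#' first), memos (newest first), fact history summary.
#'
#' @param store a `ks_store`.
#' @param registry a `ks_registry`.
#' @param history a `ks_fact_history`.
#' @param substance substance URI.
#' @return a single markdown string (class `ks_info_page`).
#' @export
info_page <- function(store, registry, history, substance) {
  if (!substance %in% substance_uris(store)) {
    stop_knowsub(sprintf("unknown substance <%s>", substance),
                 "knowsub_not_found_error")
  }
  ids <- substance_identifiers(store, substance)
  label <- if (length(ids$label[[1]])) ids$label[[1]][[1]] else substance
  out <- c(sprintf("# %s", label), "", "## Identifiers", "")
  idline <- function(nm, vals) {
    if (length(vals)) sprintf("- %s: %s", nm, paste(vals, collapse = ", "))
  }
  out <- c(out,
           idline("EC", ids$ec[[1]]), idline("CAS", ids$cas[[1]]),
           idline("IUPAC", ids$iupac[[1]]), idline("SMILES", ids$smiles[[1]]),
           idline("Internal names", ids$internal_names[[1]]))
  out <- c(out, "", "## Current decisions", "")
  dm <- ks_evaluate(registry, current_facts(history, substance))
  live <- dm[dm$state != "undefined", , drop = FALSE]
  if (nrow(live) == 0) {
    out <- c(out, "none derived")
  } else {
    decs <- registry_decisions(registry)
    is_final <- is.na(decs$parent[match(live$decision, decs$id)])
    live <- live[order(!is_final, live$module, live$decision), , drop = FALSE]
    for (m in unique(live$module)) {
      out <- c(out, sprintf("### %s", m))
      sub <- live[live$module == m, , drop = FALSE]
      out <- c(out, sprintf("- %s: **%s** (%s)", sub$label, sub$state,
                            sub$decision), "")
    }
  }
  out <- c(out, "", "## Memos", "")
  memos <- list_memos(store, substance)
  if (nrow(memos) == 0) {
    out <- c(out, "none")
  } else {
    memos <- memos[order(memos$created_at, memos$id,
                         decreasing = TRUE), , drop = FALSE]
    for (i in seq_len(nrow(memos))) {
      att <- if (!is.na(memos$attached_decision[[i]])) {
        sprintf(" [decision: %s]", memos$attached_decision[[i]])
      } else ""
      out <- c(out, sprintf("- **%s**%s (%s, %s)", memos$title[[i]], att,
                            memos$author[[i]],
                            format(memos$created_at[[i]], "%Y-%m-%d",
                                   tz = "UTC")))
      if (!is.na(memos$body[[i]]) && nzchar(memos$body[[i]])) {
        out <- c(out, sprintf("  %s", memos$body[[i]]))
      }
    }
  }
  out <- c(out, "", "## Fact history", "")
  h <- history[history$substance == substance, , drop = FALSE]
  if (nrow(h) == 0) {
    out <- c(out, "no facts recorded")
  } else {
    fl <- as_fact_list(h)
    for (q in sort(names(fl))) {
      nrec <- sum(h$question == q)
      cur <- fl[[q]]
      curtxt <- if (length(cur) == 1 && is.na(cur)) "unknown" else
        paste(format(cur), collapse = ", ")
      out <- c(out, sprintf("- %s = %s (%d record%s)", q, curtxt, nrec,
                            if (nrec > 1) "s" else ""))
    }
  }
  page <- paste(out[!map_lgl(out, is.null)], collapse = "\n")
  class(page) <- c("ks_info_page", "character")
  page
}

#' @export
print.ks_info_page <- function(x, ...) {
  cat(unclass(x), "\n")
  invisible(x)
}
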