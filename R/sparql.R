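# SPARQL 1.1 SELECT/ASK engine over the in-memory triple table.
#
# Supported grammar (the subset the dynamic views and class queries use):
#   PREFIX pfx: <iri>            (any number, before the query form)
#   SELECT ?v1 ?v2 ... | SELECT * | ASK
#   WHERE { pattern }
# where pattern is a sequence of
#   triple blocks  s p o (; p o)* (, o)* .
#   OPTIONAL { pattern }
#   FILTER NOT EXISTS { pattern }
# Terms: <iri>, pfx:local, "literal", the keyword `a`, numbers (matched as
# plain literals) and ?variables. Solutions follow standard SPARQL BGP
# semantics; the engine additionally imposes a deterministic lexicographic
# row order (SPARQL itself leaves order unspecified) so that exports are
# reproducible.

sparql_tokenize <- function(text) {
  toks <- list()
  i <- 1L
  n <- nchar(text)
  push <- function(type, value, pos) {
    toks[[length(toks) + 1]] <<- list(type = type, value = value, pos = pos)
  }
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch == "#") {
      j <- regexpr("\n", substr(text, i, n), fixed = TRUE)
      i <- if (j < 0) n + 1L else i + j
      next
    }
    if (ch == "<") {
      j <- regexpr(">", substr(text, i, n), fixed = TRUE)
      if (j < 0) stop_knowsub(sprintf("query position %d: unterminated IRI", i),
                              "knowsub_query_syntax_error")
      push("iri", substr(text, i + 1, i + j - 2), i)
      i <- i + j
    } else if (ch == "\"") {
      j <- i + 1L
      while (j <= n && substr(text, j, j) != "\"") {
        if (substr(text, j, j) == "\\") j <- j + 1L
        j <- j + 1L
      }
      if (j > n) stop_knowsub(sprintf("query position %d: unterminated literal",
                                      i), "knowsub_query_syntax_error")
      push("literal", ttl_unescape(substr(text, i + 1, j - 1)), i)
      i <- j + 1L
    } else if (ch == "?" || ch == "$") {
      m <- regexpr("^[?$][A-Za-z_][A-Za-z0-9_]*", substr(text, i, n))
      if (m < 0) stop_knowsub(sprintf("query position %d: bad variable", i),
                              "knowsub_query_syntax_error")
      len <- attr(m, "match.length")
      push("var", substr(text, i + 1, i + len - 1), i)
      i <- i + len
    } else if (ch %in% c("{", "}", ".", ";", ",", "*", "(", ")")) {
      push(ch, ch, i)
      i <- i + 1L
    } else {
      m <- regexpr("^[A-Za-z0-9_:.-]+", substr(text, i, n))
      if (m < 0) stop_knowsub(sprintf("query position %d: unexpected '%s'",
                                      i, ch), "knowsub_query_syntax_error")
      len <- attr(m, "match.length")
      word <- substr(text, i, i + len - 1)
      while (grepl("\\.$", word) && !grepl(":", word)) {
        word <- substr(word, 1, nchar(word) - 1)
        len <- len - 1L
      }
      push("word", word, i)
      i <- i + len
    }
  }
  toks
}

sparql_parse <- function(text) {
  toks <- sparql_tokenize(text)
  pos <- 1L
  n <- length(toks)
  peek <- function() if (pos <= n) toks[[pos]] else NULL
  fail <- function(msg, tk = peek()) {
    where <- if (is.null(tk)) "end of query" else sprintf("position %d", tk$pos)
    stop_knowsub(sprintf("SPARQL syntax error at %s: %s", where, msg),
                 "knowsub_query_syntax_error")
  }
  take <- function() { tk <- peek(); if (is.null(tk)) fail("unexpected end")
    pos <<- pos + 1L; tk }
  expect <- function(type) {
    tk <- take()
    if (tk$type != type) fail(sprintf("expected '%s', got '%s'", type,
                                      tk$value), tk)
    tk
  }
  kw <- function(tk) toupper(tk$value %||% "")

  prefixes <- character()
  while (!is.null(peek()) && peek()$type == "word" &&
         kw(peek()) == "PREFIX") {
    take()
    pfx <- expect("word")
    iri <- expect("iri")
    prefixes[[sub(":$", "", pfx$value)]] <- iri$value
  }

  term <- function(tk) {
    switch(tk$type,
      iri = list(kind = "iri", value = tk$value),
      literal = list(kind = "literal", value = tk$value),
      var = list(kind = "var", value = tk$value),
      word = {
        if (tk$value == "a") {
          list(kind = "iri", value = RDF_TYPE)
        } else if (grepl("^[0-9.eE+-]+$", tk$value)) {
          list(kind = "literal", value = tk$value)
        } else {
          list(kind = "iri", value = resolve_pname(tk$value, prefixes,
                                                   tk$pos))
        }
      },
      fail("expected RDF term", tk))
  }

  parse_group <- function() {
    expect("{")
    elems <- list()
    repeat {
      tk <- peek()
      if (is.null(tk)) fail("unterminated group (missing '}')")
      if (tk$type == "}") { take(); break }
      if (tk$type == ".") { take(); next }
      if (tk$type == "word" && kw(tk) == "OPTIONAL") {
        take()
        elems[[length(elems) + 1]] <- list(kind = "optional",
                                           group = parse_group())
        next
      }
      if (tk$type == "word" && kw(tk) == "FILTER") {
        take()
        nx <- take()
        if (!(nx$type == "word" && kw(nx) == "NOT")) {
          fail("only FILTER NOT EXISTS is supported", nx)
        }
        ex <- take()
        if (!(ex$type == "word" && kw(ex) == "EXISTS")) {
          fail("expected EXISTS after NOT", ex)
        }
        elems[[length(elems) + 1]] <- list(kind = "not_exists",
                                           group = parse_group())
        next
      }
      # triples block
      s <- term(take())
      repeat {
        p <- term(take())
        repeat {
          o <- term(take())
          elems[[length(elems) + 1]] <- list(kind = "triple",
                                             s = s, p = p, o = o)
          if (!is.null(peek()) && peek()$type == ",") { take(); next }
          break
        }
        if (!is.null(peek()) && peek()$type == ";") {
          take()
          if (!is.null(peek()) && peek()$type %in% c(".", "}")) break
          next
        }
        break
      }
      if (!is.null(peek()) && peek()$type == ".") take()
    }
    elems
  }

  form <- take()
  if (form$type != "word") fail("expected SELECT or ASK", form)
  if (kw(form) == "SELECT") {
    vars <- character()
    star <- FALSE
    repeat {
      tk <- peek()
      if (is.null(tk)) fail("expected WHERE")
      if (tk$type == "var") { vars <- c(vars, take()$value); next }
      if (tk$type == "*") { take(); star <- TRUE; next }
      break
    }
    tk <- peek()
    if (!is.null(tk) && tk$type == "word" && kw(tk) == "WHERE") take()
    group <- parse_group()
    if (!is.null(peek())) fail("trailing tokens after query")
    list(form = "select", vars = vars, star = star, pattern = group)
  } else if (kw(form) == "ASK") {
    tk <- peek()
    if (!is.null(tk) && tk$type == "word" && kw(tk) == "WHERE") take()
    group <- parse_group()
    if (!is.null(peek())) fail("trailing tokens after query")
    list(form = "ask", pattern = group)
  } else {
    fail("only SELECT and ASK query forms are supported", form)
  }
}

# --- evaluation -------------------------------------------------------------

# A solution set is a tibble whose columns are variable names; zero columns
# with one row is the unit solution, zero rows is failure.
unit_solutions <- function() tibble(.rows = 1)

match_triple_pattern <- function(triples, pat) {
  keep <- rep(TRUE, nrow(triples))
  for (slot in c("s", "p", "o")) {
    tm <- pat[[slot]]
    if (tm$kind != "var") {
      kind_ok <- if (slot == "o") {
        triples$o_kind == tm$kind
      } else TRUE
      keep <- keep & triples[[slot]] == tm$value & kind_ok
    }
  }
  hit <- triples[keep, , drop = FALSE]
  bind <- list()
  consistent <- rep(TRUE, nrow(hit))
  for (slot in c("s", "p", "o")) {
    tm <- pat[[slot]]
    if (tm$kind == "var") {
      if (tm$value %in% names(bind)) {
        # repeated variable within one pattern: must bind consistently
        consistent <- consistent & bind[[tm$value]] == hit[[slot]]
      } else {
        bind[[tm$value]] <- hit[[slot]]
      }
    }
  }
  if (length(bind) == 0) return(tibble(.rows = as.integer(any(consistent))))
  distinct(as_tibble(bind)[consistent, , drop = FALSE])
}

join_solutions <- function(a, b) {
  if (ncol(a) == 0) return(if (nrow(a) > 0) b else b[0, , drop = FALSE])
  if (ncol(b) == 0) return(if (nrow(b) > 0) a else a[0, , drop = FALSE])
  common <- intersect(names(a), names(b))
  if (length(common) == 0) {
    if (nrow(a) == 0 || nrow(b) == 0) return(bind_cols(a[0, ], b[0, ]))
    return(tidyr::crossing(a, b))
  }
  inner_join(a, b, by = common, relationship = "many-to-many")
}

eval_pattern <- function(triples, elems, init = unit_solutions()) {
  sols <- init
  for (el in elems) {
    if (el$kind == "triple") {
      sols <- join_solutions(sols, match_triple_pattern(triples, el))
    } else if (el$kind == "optional") {
      opt <- eval_pattern(triples, el$group)
      common <- intersect(names(sols), names(opt))
      if (ncol(sols) == 0) {
        if (nrow(sols) > 0 && nrow(opt) > 0) sols <- opt
      } else if (length(common) == 0 && nrow(opt) > 0 && ncol(opt) > 0) {
        sols <- tidyr::crossing(sols, opt)
      } else if (length(common) > 0) {
        sols <- left_join(sols, opt, by = common,
                          relationship = "many-to-many")
      }
    } else if (el$kind == "not_exists") {
      if (nrow(sols) == 0) next
      keep <- map_lgl(seq_len(nrow(sols)), function(i) {
        seeded <- sols[i, , drop = FALSE]
        nrow(eval_pattern(triples, el$group, init = seeded)) == 0
      })
      sols <- sols[keep, , drop = FALSE]
    }
  }
  if (ncol(sols) == 0) sols else distinct(sols)
}

#' Run a SPARQL SELECT or ASK query against a store
#'
#' @param store a `ks_store`.
#' @param sparql_text query text (SELECT or ASK; see the package vignette for
#'   the supported subset).
#' @return for SELECT, a tibble with one column per projected variable and a
#'   deterministic lexicographic row order; for ASK, a logical scalar.
#' @examples
#' st <- ks_store()
#' add_substance(st, substance_record(label = "Kryptonite"))
#' ks_query(st, "PREFIX ks: <http://example.org/knowsub/ks#>
#'   SELECT ?label WHERE { ?s a ks:Substance . ?s ks:hasLabel ?label . }")
#' @export
ks_query <- function(store, sparql_text) {
  q <- sparql_parse(sparql_text)
  sols <- eval_pattern(store$triples, q$pattern)
  if (q$form == "ask") return(nrow(sols) > 0)
  vars <- if (q$star || length(q$vars) == 0) names(sols) else q$vars
  out <- tibble(.rows = nrow(sols))
  for (v in vars) {
    out[[v]] <- if (v %in% names(sols)) sols[[v]] else NA_character_
  }
  as_tibble(order_table(distinct(out)))
}
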