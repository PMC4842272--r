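# Turtle (RDF 1.1) reader/writer for the subset the substance graphs use:
# @prefix directives, IRIs, prefixed names, the `a` keyword, string literals
# with the usual escapes, and `;` / `,` predicate/object lists. Blank nodes
# and collections are rejected with a parse error (the substance vocabulary
# never produces them), which keeps graph isomorphism equal to triple-set
# equality and makes the save/load round trip exactly checkable.

TTL_ESCAPES <- c("\\" = "\\\\", "\"" = "\\\"", "\n" = "\\n",
                 "\r" = "\\r", "\t" = "\\t")

ttl_escape <- function(x) {
  for (i in seq_along(TTL_ESCAPES)) {
    x <- gsub(names(TTL_ESCAPES)[[i]], TTL_ESCAPES[[i]], x, fixed = TRUE)
  }
  x
}

ttl_unescape <- function(x) {
  out <- character(length(x))
  for (k in seq_along(x)) {
    s <- x[[k]]
    res <- ""
    i <- 1L
    n <- nchar(s)
    while (i <= n) {
      ch <- substr(s, i, i)
      if (ch == "\\" && i < n) {
        nxt <- substr(s, i + 1, i + 1)
        res <- paste0(res, switch(nxt, n = "\n", r = "\r", t = "\t",
                                  "\"" = "\"", "\\" = "\\", nxt))
        i <- i + 2L
      } else {
        res <- paste0(res, ch)
        i <- i + 1L
      }
    }
    out[[k]] <- res
  }
  out
}

ttl_tokenize <- function(lines) {
  toks <- list()
  for (ln in seq_along(lines)) {
    s <- lines[[ln]]
    i <- 1L
    n <- nchar(s)
    while (i <= n) {
      ch <- substr(s, i, i)
      if (grepl("^\\s$", ch)) { i <- i + 1L; next }
      if (ch == "#") break
      if (ch == "<") {
        j <- regexpr(">", substr(s, i, n), fixed = TRUE)
        if (j < 0) stop_knowsub(sprintf("line %d: unterminated IRI", ln),
                                "knowsub_parse_error")
        toks[[length(toks) + 1]] <- list(type = "iri",
          value = substr(s, i + 1, i + j - 2), line = ln)
        i <- i + j
      } else if (ch == "\"") {
        j <- i + 1L
        while (j <= n) {
          cj <- substr(s, j, j)
          if (cj == "\\") { j <- j + 2L; next }
          if (cj == "\"") break
          j <- j + 1L
        }
        if (j > n) stop_knowsub(sprintf("line %d: unterminated literal", ln),
                                "knowsub_parse_error")
        toks[[length(toks) + 1]] <- list(type = "literal",
          value = ttl_unescape(substr(s, i + 1, j - 1)), line = ln)
        i <- j + 1L
        # optional language tag or datatype — consumed, not retained
        rest <- substr(s, i, n)
        m <- regexpr("^(@[A-Za-z-]+|\\^\\^\\S+)", rest)
        if (m == 1) i <- i + attr(m, "match.length")
      } else if (ch %in% c(".", ";", ",")) {
        toks[[length(toks) + 1]] <- list(type = ch, value = ch, line = ln)
        i <- i + 1L
      } else if (ch %in% c("[", "]", "(", ")")) {
        stop_knowsub(sprintf("line %d: blank nodes/collections not supported",
                             ln), "knowsub_parse_error")
      } else {
        m <- regexpr("^[^\\s<>\".;,#]+[^\\s<>\";,#]*", substr(s, i, n),
                     perl = TRUE)
        len <- attr(m, "match.length")
        word <- substr(s, i, i + len - 1)
        # a trailing '.' belongs to the statement, not the name
        while (grepl("\\.$", word)) {
          word <- substr(word, 1, nchar(word) - 1)
          len <- len - 1L
        }
        if (len <= 0) stop_knowsub(sprintf("line %d: stray '%s'", ln, ch),
                                   "knowsub_parse_error")
        toks[[length(toks) + 1]] <- list(type = "word", value = word,
                                         line = ln)
        i <- i + len
      }
    }
  }
  toks
}

resolve_pname <- function(word, prefixes, line) {
  if (word == "a") return(RDF_TYPE)
  m <- regmatches(word, regexec("^([A-Za-z][A-Za-z0-9_-]*)?:(.*)$", word))[[1]]
  if (length(m) == 0) {
    stop_knowsub(sprintf("line %d: expected IRI or prefixed name, got '%s'",
                         line, word), "knowsub_parse_error")
  }
  pfx <- m[[2]]
  if (!pfx %in% names(prefixes)) {
    stop_knowsub(sprintf("line %d: undeclared prefix '%s:'", line, pfx),
                 "knowsub_parse_error")
  }
  paste0(prefixes[[pfx]], m[[3]])
}

#' Read a Turtle file into a store
#'
#' @param path path to a `.ttl` file.
#' @param ns namespace for terms the store itself mints afterwards; defaults
#'   to the file's `ks:` prefix when declared.
#' @return a `ks_store`.
#' @export
load_turtle <- function(path) {
  if (!file.exists(path)) {
    stop_knowsub(sprintf("no such file: %s", path), "knowsub_io_error")
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  toks <- ttl_tokenize(lines)
  prefixes <- character()
  triples <- list()
  i <- 1L
  n <- length(toks)
  term_at <- function(i) {
    tk <- toks[[i]]
    if (tk$type == "iri") list(v = tk$value, kind = "iri")
    else if (tk$type == "literal") list(v = tk$value, kind = "literal")
    else if (tk$type == "word") {
      list(v = resolve_pname(tk$value, prefixes, tk$line), kind = "iri")
    } else {
      stop_knowsub(sprintf("line %d: unexpected '%s'", tk$line, tk$value),
                   "knowsub_parse_error")
    }
  }
  while (i <= n) {
    tk <- toks[[i]]
    if (tk$type == "word" && tolower(tk$value) == "@prefix") {
      if (i + 2 > n || toks[[i + 1]]$type != "word" ||
          toks[[i + 2]]$type != "iri") {
        stop_knowsub(sprintf("line %d: malformed @prefix", tk$line),
                     "knowsub_parse_error")
      }
      pfx <- sub(":$", "", toks[[i + 1]]$value)
      prefixes[[pfx]] <- toks[[i + 2]]$value
      i <- i + 3L
      if (i <= n && toks[[i]]$type == ".") i <- i + 1L
      next
    }
    # subject predicate-object list
    subj <- term_at(i)
    if (subj$kind != "iri") {
      stop_knowsub(sprintf("line %d: literal subject", tk$line),
                   "knowsub_parse_error")
    }
    i <- i + 1L
    repeat {
      if (i > n) stop_knowsub("unexpected end of file (missing '.')",
                              "knowsub_parse_error")
      pred <- term_at(i)
      i <- i + 1L
      repeat {
        if (i > n) stop_knowsub("unexpected end of file (missing '.')",
                                "knowsub_parse_error")
        obj <- term_at(i)
        i <- i + 1L
        triples[[length(triples) + 1]] <-
          tibble(s = subj$v, p = pred$v, o = obj$v, o_kind = obj$kind)
        if (i <= n && toks[[i]]$type == ",") { i <- i + 1L; next }
        break
      }
      if (i <= n && toks[[i]]$type == ";") { i <- i + 1L
        # tolerate ';' directly before '.'
        if (i <= n && toks[[i]]$type == ".") { i <- i + 1L; break }
        next
      }
      if (i <= n && toks[[i]]$type == ".") { i <- i + 1L; break }
      stop_knowsub(sprintf("line %d: expected '.', ';' or ','",
                           toks[[min(i, n)]]$line), "knowsub_parse_error")
    }
  }
  ns <- prefixes[["ks"]] %||% KS_DEFAULT_NS
  store <- ks_store(ns = ns, bundled_terms = FALSE)
  tt <- bind_rows(triples)
  if (nrow(tt)) {
    tt <- distinct(tt)
    store$triples <- tt
  }
  store
}

#' Write a store to a Turtle file
#'
#' Output is canonical: prefixes first, subjects sorted, predicates and
#' objects grouped with `;`/`,` and sorted, so identical stores serialize to
#' byte-identical files.
#'
#' @param store a `ks_store`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_turtle <- function(store, path) {
  prefixes <- c(ks = store$ns, rdf = RDF_NS, rdfs = RDFS_NS)
  shorten <- function(iri) {
    for (pfx in names(prefixes)) {
      nsp <- prefixes[[pfx]]
      if (startsWith(iri, nsp)) {
        local <- substr(iri, nchar(nsp) + 1, nchar(iri))
        if (grepl("^[A-Za-z_][A-Za-z0-9_-]*$", local)) {
          if (pfx == "rdf" && local == "type") return("a")
          return(paste0(pfx, ":", local))
        }
      }
    }
    paste0("<", iri, ">")
  }
  render_obj <- function(o, kind) {
    if (kind == "iri") shorten(o) else paste0("\"", ttl_escape(o), "\"")
  }
  t <- order_table(store$triples)
  out <- sprintf("@prefix %s: <%s> .", names(prefixes), unname(prefixes))
  out <- c(out, "")
  for (subj in unique(t$s)) {
    rows <- t[t$s == subj, , drop = FALSE]
    plines <- character()
    for (pred in unique(rows$p)) {
      objs <- rows[rows$p == pred, , drop = FALSE]
      objtxt <- paste(mapply(render_obj, objs$o, objs$o_kind),
                      collapse = " , ")
      plines <- c(plines, paste0("    ", shorten(pred), " ", objtxt))
    }
    out <- c(out, paste0(shorten(subj), "\n",
                         paste(plines, collapse = " ;\n"), " ."))
  }
  writeLines(out, path, useBytes = FALSE)
  invisible(path)
}

#' Test whether two stores hold isomorphic graphs
#'
#' The graphs contain no blank nodes, so isomorphism reduces to equality of
#' the triple sets.
#'
#' @param a,b `ks_store` objects.
#' @return `TRUE`/`FALSE`.
#' @export
graphs_isomorphic <- function(a, b) {
  ta <- order_table(distinct(a$triples))
  tb <- order_table(distinct(b$triples))
  isTRUE(all.equal(as.data.frame(ta), as.data.frame(tb),
                   check.attributes = FALSE))
}
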