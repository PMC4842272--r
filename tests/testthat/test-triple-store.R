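KS <- "http://example.org/knowsub/ks#"

pbt_query <- function() {
  paste(readLines(knowsub_example_file("views", "pbt_substances.rq")),
        collapse = "\n")
}

non_pbt_query <- function() {
  paste(readLines(knowsub_example_file("views", "non_pbt_substances.rq")),
        collapse = "\n")
}

test_that("adding a substance writes one triple per identifier plus the type", {
  st <- ks_store()
  uri <- add_substance(st, substance_record(
    label = "Kryptonite", cas_number = "9999999-99-5",
    ec_number = "999-999-2"))
  t <- st$triples[st$triples$s == uri, ]
  expect_equal(nrow(t), 4)  # type + label + CAS + EC
  expect_true(any(t$p == paste0(KS, "hasLabel") & t$o == "Kryptonite"))

  st2 <- ks_store()
  u2 <- add_substance(st2, substance_record(label = "X"))
  expect_equal(nrow(st2$triples[st2$triples$s == u2, ]), 2)

  expect_error(add_substance(st, substance_record(label = "Kryptonite")),
               class = "knowsub_conflict_error")
  expect_error(add_substance(st, substance_record(label = "")),
               class = "knowsub_validation_error")
})

test_that("property assertion is idempotent and validated", {
  st <- ks_store()
  uri <- add_substance(st, substance_record(label = "Kryptonite"))
  for (p in c("persistent", "bioaccumulative", "toxic")) {
    assert_property(st, uri, p)
  }
  expect_setequal(members_of(st, pbt_class_definition()), uri)

  n <- nrow(st$triples)
  assert_property(st, uri, "persistent")
  expect_equal(nrow(st$triples), n)

  expect_error(assert_property(st, uri, "mutagenic"),
               class = "knowsub_not_found_error")
  expect_error(assert_property(st, paste0(KS, "nope"), "toxic"),
               class = "knowsub_not_found_error")
})

test_that("the PBT listing query and its NOT-EXISTS complement partition the store", {
  st <- ks_store()
  uri <- add_substance(st, substance_record(label = "Kryptonite"))
  for (p in c("persistent", "bioaccumulative", "toxic")) {
    assert_property(st, uri, p)
  }
  res <- ks_query(st, pbt_query())
  expect_equal(res$label, "Kryptonite")
  expect_equal(nrow(ks_query(st, non_pbt_query())), 0)

  other <- add_substance(st, substance_record(label = "Adamantium"))
  assert_property(st, other, "persistent")
  expect_equal(ks_query(st, pbt_query())$label, "Kryptonite")
  expect_equal(ks_query(st, non_pbt_query())$label, "Adamantium")

  empty <- ks_store()
  expect_equal(nrow(ks_query(empty, pbt_query())), 0)
})

test_that("ASK queries and syntax errors behave", {
  st <- ks_store()
  add_substance(st, substance_record(label = "Kryptonite"))
  expect_true(ks_query(st, sprintf(
    "PREFIX ks: <%s> ASK { ?s a ks:Substance . }", KS)))
  expect_false(ks_query(st, sprintf(
    "PREFIX ks: <%s> ASK { ?s ks:hasChemProperty ks:toxic . }", KS)))
  err <- tryCatch(ks_query(st, "SELECT ?x WHERE { ?x a "),
                  error = function(e) e)
  expect_s3_class(err, "knowsub_query_syntax_error")
  expect_match(conditionMessage(err), "position|end")
})

test_that("members_of equals the generated SPARQL query on random stores", {
  for (seed in 1:8) {
    n <- 3 + (seed * 7) %% 20
    st <- generate_random_store(n, seed = seed)
    cd <- pbt_class_definition()
    mem <- members_of(st, cd)
    via_sparql <- ks_query(st, classdef_sparql(st, cd))$s
    expect_equal(mem, sort(via_sparql %||% character()))
    expect_equal(mem, oracle_members(st, cd$chem_properties))
    comp <- ks_query(st, classdef_sparql(st, cd, complement = TRUE))$s
    all_subs <- ks_query(st, sprintf(
      "PREFIX ks: <%s> SELECT ?s WHERE { ?s a ks:Substance . }", KS))$s
    expect_setequal(c(mem, comp), all_subs)
    expect_length(intersect(mem, comp), 0)
  }
})

test_that("an empty requirement set admits every substance", {
  st <- generate_random_store(5, seed = 42)
  expect_setequal(members_of(st, class_definition("anything")),
                  substance_uris(st))
  expect_length(members_of(ks_store(), pbt_class_definition()), 0)
})

test_that("Turtle round-trip preserves the graph", {
  st <- load_turtle(knowsub_example_file("kryptonite.ttl"))
  expect_length(substance_uris(st), 1)
  expect_equal(sum(st$triples$p == paste0(KS, "hasChemProperty")), 3)

  path <- withr::local_tempfile(fileext = ".ttl")
  save_turtle(st, path)
  expect_true(graphs_isomorphic(st, load_turtle(path)))

  # arbitrary random store round-trips too
  st2 <- generate_random_store(12, seed = 3)
  save_turtle(st2, path)
  expect_true(graphs_isomorphic(st2, load_turtle(path)))

  # literal escaping survives
  st3 <- ks_store()
  add_substance(st3, substance_record(label = "A \"quoted\"\nlabel\t\\x"))
  save_turtle(st3, path)
  expect_true(graphs_isomorphic(st3, load_turtle(path)))
})

test_that("malformed Turtle is rejected with a line number", {
  path <- withr::local_tempfile(fileext = ".ttl")
  writeLines(c("@prefix ks: <http://x#> .", "ks:a ks:b"), path)
  err <- tryCatch(load_turtle(path), error = function(e) e)
  expect_s3_class(err, "knowsub_parse_error")

  writeLines(c("@prefix ks: <http://x#> .", "ks:a undeclared:b ks:c ."),
             path)
  err2 <- tryCatch(load_turtle(path), error = function(e) e)
  expect_s3_class(err2, "knowsub_parse_error")
  expect_match(conditionMessage(err2), "line 2")
})

test_that("query row order is invariant under triple insertion order", {
  recs <- generate_substances(10, seed = 5)
  st_fwd <- populate_store(recs)
  st_rev <- populate_store(recs[rev(seq_len(nrow(recs))), ])
  q <- sprintf(
    "PREFIX ks: <%s> SELECT ?label ?cas WHERE { ?s a ks:Substance . ?s ks:hasLabel ?label . ?s ks:hasCAS ?cas . }",
    KS)
  expect_identical(ks_query(st_fwd, q), ks_query(st_rev, q))
})

test_that("the rdflib Python toolchain agrees on the worked example", {
  # Independent cross-check of the Turtle writer and the SPARQL engine.
  st <- load_turtle(knowsub_example_file("kryptonite.ttl"))
  ttl <- withr::local_tempfile(fileext = ".ttl")
  save_turtle(st, ttl)
  py <- withr::local_tempfile(fileext = ".py")
  writeLines(c(
    "import sys, rdflib",
    "g = rdflib.Graph(); g.parse(sys.argv[1], format='turtle')",
    "print(len(g))",
    "q = open(sys.argv[2]).read()",
    "for row in g.query(q): print(row[0])"), py)
  out <- system2("python", c(py, ttl,
    knowsub_example_file("views", "pbt_substances.rq")),
    stdout = TRUE, stderr = FALSE)
  expect_equal(as.integer(out[[1]]), nrow(st$triples))
  expect_equal(out[-1], "Kryptonite")
})
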