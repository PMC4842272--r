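example_registry <- function() {
  load_registry(knowsub_example_file("modules", "registry.yaml"))
}

test_that("the bundled Persistence module parses with its biodegradation rule", {
  text <- paste(readLines(knowsub_example_file("modules", "persistence.kb")),
                collapse = "\n")
  mod <- parse_module(text)
  expect_equal(mod$name, "Persistence")
  expect_setequal(mod$questions$id, c("ThCO2", "ThOD", "DOC", "dt50_water"))
  expect_true("nrb" %in% mod$decisions$id)
  r <- mod$rules[mod$rules$id == "r_nrb", ]
  expect_equal(r$target, "nrb")
  expect_equal(r$category, "P7")
  # one failed threshold suffices
  expect_true(evaluate_condition(r$condition[[1]], list(ThCO2 = 45)))
  # vP is a child of P in the decision hierarchy
  expect_equal(mod$decisions$parent[mod$decisions$id == "vP"], "P")
})

test_that("empty text yields an empty module; bad references are link errors", {
  mod <- parse_module("")
  expect_equal(nrow(mod$questions), 0)
  expect_equal(nrow(mod$rules), 0)

  bad <- "MODULE M\nDECISIONS\n  d \"D\"\nRULES\n  RULE r1: IF nosuch < 5 THEN d P7"
  err <- tryCatch(parse_module(bad), error = function(e) e)
  expect_s3_class(err, "knowsub_link_error")
  expect_match(conditionMessage(err), "nosuch")

  cyc <- paste(
    "MODULE M", "QUESTIONS", '  q "Q" numeric', "FLOW f", "  START s",
    "  ASK a q", "  EDGE s -> a", "  EDGE a -> s", sep = "\n")
  expect_error(parse_module(cyc), class = "knowsub_structure_error")
})

test_that("three-valued condition semantics follow the Kleene lattice", {
  expect_true(evaluate_condition("ThCO2 < 60", list(ThCO2 = 45)))
  expect_false(evaluate_condition("ThCO2 < 60", list(ThCO2 = 80)))
  expect_true(is.na(evaluate_condition("ThCO2 < 60", list())))
  # explicit unknown answers leave conditions undefined
  expect_true(is.na(evaluate_condition("ThCO2 < 60", list(ThCO2 = NA))))

  expect_true(evaluate_condition("OR(a < 1, b < 1)", list(a = 0)))
  expect_true(is.na(evaluate_condition("AND(a < 1, b < 1)", list(a = 0))))
  expect_false(evaluate_condition("AND(a < 1, b < 1)", list(a = 5)))
  expect_true(is.na(evaluate_condition("NOT(a < 1)", list())))
  expect_true(evaluate_condition("known(a)", list(a = 3)))
  expect_true(is.na(evaluate_condition("known(a)", list())))

  expect_true(evaluate_condition("state(P) = established", list(),
                                 c(P = "established")))
  expect_false(evaluate_condition("state(P) = established", list(),
                                  c(P = "suggested")))
  expect_false(evaluate_condition("state(P) = established", list()))

  expect_true(evaluate_condition("route in (water, food)",
                                 list(route = "water")))
  expect_false(evaluate_condition("route in (water, food)",
                                  list(route = "air")))
  # multi-choice '=' means contains
  expect_true(evaluate_condition("route = water",
                                 list(route = c("air", "water"))))

  expect_error(evaluate_condition("a < 1", list(a = "text")),
               class = "knowsub_evaluation_error")
})

test_that("evaluation is monotone under fact extension", {
  set.seed(21)
  qids <- sprintf("q%d", 1:4)
  cids <- "c1"
  choices <- c("low", "mid", "high")
  for (i in 1:150) {
    cond <- parse_condition(random_condition_text(3, qids, cids, choices))
    base <- random_fact_assignment(qids, cids, choices, answer_prob = 0.4)
    ext <- random_fact_assignment(qids, cids, choices, answer_prob = 0.9)
    # extension: keep base answers, add new ones from ext
    extended <- ext
    for (q in names(base)) extended[[q]] <- base[[q]]
    v1 <- evaluate_condition(cond, base)
    v2 <- evaluate_condition(cond, extended)
    if (!is.na(v1)) expect_identical(v1, v2)
  }
})

test_that("the condition evaluator agrees with the independent interpreter", {
  set.seed(22)
  qids <- sprintf("q%d", 1:5)
  cids <- sprintf("c%d", 1:2)
  choices <- c("low", "mid", "high")
  for (i in 1:300) {
    cond <- parse_condition(random_condition_text(3, qids, cids, choices))
    facts <- random_fact_assignment(qids, cids, choices)
    expect_identical(tv_to_chr(evaluate_condition(cond, facts)),
                     oracle_eval_condition(cond, facts),
                     info = format_condition(cond))
  }
})

test_that("parse -> serialize -> parse is the identity on all bundled modules", {
  for (f in c("persistence.kb", "bioaccumulation.kb", "toxicity.kb",
              "pbt.kb")) {
    text <- paste(readLines(knowsub_example_file("modules", f)),
                  collapse = "\n")
    known_q <- c("ThCO2", "ThOD", "DOC", "dt50_water", "bcf_available",
                 "BCF", "log_kow", "chronic_noec", "carcinogenic")
    known_d <- c("nrb", "P", "vP", "B", "vB", "T", "PBT", "vPvB")
    m1 <- parse_module(text, known_q, known_d)
    m2 <- parse_module(format_module(m1), known_q, known_d)
    expect_equal(m2, m1)
  }
})

test_that("the registry validator flags duplicates, dangling deps and orphans", {
  reg <- example_registry()
  expect_equal(nrow(validate_registry(reg)), 0)

  m1 <- parse_module("MODULE A\nDECISIONS\n  B \"b\"")
  m2 <- parse_module("MODULE C\nDECISIONS\n  B \"b again\"")
  iss <- validate_registry(ks_registry(list(m1, m2)))
  expect_true(any(iss$kind == "duplicate_id" & grepl("'B'", iss$detail)))

  m3 <- parse_module("MODULE D\nDEPENDS Exposure\nDECISIONS\n  dx \"d\"")
  iss2 <- validate_registry(ks_registry(list(m3)))
  expect_true(any(iss2$kind == "dangling_dependency" &
                    grepl("Exposure", iss2$detail)))

  orphan <- paste(
    "MODULE E", "QUESTIONS", '  q "Q" numeric', "DECISIONS", '  d "D"',
    "FLOW f", "  START s", "  ASK a q", "  ASK lost q", "  EXIT x",
    "  EDGE s -> a", "  EDGE a -> x", "  EDGE lost -> x", sep = "\n")
  iss3 <- validate_registry(ks_registry(list(parse_module(orphan))))
  expect_true(any(iss3$kind == "unreachable_node" &
                    grepl("lost", iss3$detail)))
})

test_that("module dependency cycles are rejected", {
  ma <- parse_module("MODULE A\nDEPENDS B\nDECISIONS\n  da \"a\"")
  mb <- parse_module("MODULE B\nDEPENDS A\nDECISIONS\n  db \"b\"")
  expect_error(ks_registry(list(ma, mb)), class = "knowsub_registry_error")
})
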