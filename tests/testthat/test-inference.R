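kryptonite_facts <- function() {
  list(ThCO2 = 45, dt50_water = 75, bcf_available = "yes", BCF = 5300,
       chronic_noec = 0.004)
}

test_that("Kryptonite's P, B and T sub-decisions establish PBT", {
  ex <- kryptonite_example()
  dm <- ks_evaluate(ex$registry, kryptonite_facts())
  st <- setNames(dm$state, dm$decision)
  expect_equal(st[["P"]], "established")
  expect_equal(st[["B"]], "established")
  expect_equal(st[["T"]], "established")
  expect_equal(st[["PBT"]], "established")
  expect_equal(st[["vPvB"]], "established")
})

test_that("with no facts every decision is undefined", {
  ex <- kryptonite_example()
  dm <- ks_evaluate(ex$registry, list())
  expect_true(all(dm$state == "undefined"))
})

test_that("fired category scores sum and map through the state thresholds", {
  text <- paste(
    "MODULE M", "QUESTIONS", '  x "X" numeric', "DECISIONS", '  D "d"',
    "RULES",
    "  RULE rp: IF x > 0 THEN D P7",   # +80
    "  RULE rn: IF x > 1 THEN D N5",   # -20
    sep = "\n")
  reg <- ks_registry(list(parse_module(text)))
  dm <- ks_evaluate(reg, list(x = 5))
  expect_equal(dm$score[dm$decision == "D"], 60)
  expect_equal(dm$state[dm$decision == "D"], "established")
  expect_setequal(dm$support[[which(dm$decision == "D")]], c("rp", "rn"))

  # suggested band and exclusion band
  expect_equal(ks_evaluate(ks_registry(list(parse_module(paste(
    "MODULE M", "DECISIONS", '  D "d"', "QUESTIONS", '  x "X" numeric',
    "RULES", "  RULE r: IF x > 0 THEN D P4", sep = "\n")))),
    list(x = 1))$state, "suggested")
  expect_equal(ks_evaluate(ks_registry(list(parse_module(paste(
    "MODULE M", "DECISIONS", '  D "d"', "QUESTIONS", '  x "X" numeric',
    "RULES", "  RULE r: IF x > 0 THEN D N7", sep = "\n")))),
    list(x = 1))$state, "excluded")
})

test_that("evaluation is invariant under fact insertion order", {
  ex <- kryptonite_example()
  facts <- kryptonite_facts()
  ref <- ks_evaluate(ex$registry, facts)
  set.seed(31)
  for (i in 1:25) {
    perm <- facts[sample(names(facts))]
    expect_equal(as.data.frame(ks_evaluate(ex$registry, perm)),
                 as.data.frame(ref))
  }
})

test_that("retraction is exact: like a session that never saw the fact", {
  ex <- kryptonite_example()
  facts <- kryptonite_facts()
  dm <- ks_evaluate(ex$registry, facts)
  expect_equal(dm$state[dm$decision == "B"], "established")

  f2 <- retract(facts, "BCF")
  dm2 <- ks_evaluate(ex$registry, f2)
  expect_equal(dm2$state[dm2$decision == "B"], "undefined")
  expect_equal(dm2$state[dm2$decision == "PBT"], "undefined")
  # no support entry mentions the retracted question's consequences
  expect_length(dm2$support[[which(dm2$decision == "B")]], 0)
  # identical to a fresh fact set without BCF
  fresh <- facts[setdiff(names(facts), "BCF")]
  expect_equal(as.data.frame(dm2),
               as.data.frame(ks_evaluate(ex$registry, fresh)))

  # retracting an unreferenced fact changes nothing
  f3 <- c(facts, list(carcinogenic = "unknown"))
  expect_equal(as.data.frame(ks_evaluate(ex$registry,
                                         retract(f3, "carcinogenic"))),
               as.data.frame(dm))
  # retract + re-assert restores the original map
  expect_equal(as.data.frame(ks_evaluate(ex$registry,
                                         c(f2, list(BCF = 5300)))),
               as.data.frame(dm))
  expect_warning(retract(facts, "never_answered"), "not answered|nothing")
})

test_that("explanations carry the responsible facts transitively and are sound", {
  ex <- kryptonite_example()
  expl <- ks_explain(ex$registry, ex$answers, "PBT")
  expect_equal(expl$state, "established")
  # facts behind P, B and T are listed transitively
  expect_true(all(c("ThCO2", "dt50_water", "BCF", "chronic_noec",
                    "bcf_available") %in%
                    expl$responsible_facts$question))
  expect_false(any(is.na(unlist(expl$responsible_facts$timestamp))))
  # re-evaluating with only the responsible facts reproduces the state
  dm <- ks_evaluate(ex$registry, restrict_facts(ex$answers, expl))
  expect_equal(dm$state[dm$decision == "PBT"], "established")

  # undefined decision with nothing fired explains to an empty fact list
  e2 <- ks_explain(ex$registry, list(), "PBT")
  expect_equal(nrow(e2$responsible_facts), 0)
  expect_equal(e2$state, "undefined")

  expect_error(ks_explain(ex$registry, list(), "nope"),
               class = "knowsub_not_found_error")
})

test_that("explanation soundness holds on random registries", {
  for (seed in 1:40) {
    reg <- generate_random_registry(seed = seed, n_rules = 12)
    facts <- generate_random_facts(reg, seed = seed + 1000)
    dm <- ks_evaluate(reg, facts)
    for (d in dm$decision) {
      expl <- ks_explain(reg, facts, d)
      dm2 <- ks_evaluate(reg, restrict_facts(facts, expl))
      expect_equal(dm2$state[dm2$decision == d],
                   dm$state[dm$decision == d],
                   info = sprintf("seed %d decision %s", seed, d))
    }
  }
})

test_that("the rule engine agrees with the brute-force interpreter", {
  for (seed in 1:10) {
    reg <- generate_random_registry(seed = seed, n_rules = 15)
    for (j in 1:20) {
      facts <- generate_random_facts(reg, seed = seed * 1000 + j)
      dm <- ks_evaluate(reg, facts)
      bf <- oracle_rule_states(reg, facts)
      expect_equal(setNames(dm$state, dm$decision), bf$states)
      expect_equal(setNames(dm$score, dm$decision), bf$scores)
    }
  }
})

test_that("workflow traces follow the guards deterministically", {
  ex <- kryptonite_example()
  wf <- ex$registry$modules$Bioaccumulation$workflows[["bioaccumulation"]]

  tr <- trace_workflow(wf, list(bcf_available = "yes", BCF = 5300))
  expect_true("d_vb" %in% tr$visited)     # path through the vB decide-node
  expect_equal(tr$visited[[length(tr$visited)]], "x")

  tr2 <- trace_workflow(wf, list(bcf_available = "yes", BCF = 100))
  expect_equal(tr2$visited[[length(tr2$visited)]], "x")
  expect_true("d_notb" %in% tr2$visited)  # ends at the "not B" decision
  expect_false("d_vb" %in% tr2$visited)

  tr3 <- trace_workflow(wf, list())
  expect_equal(tr3$visited, "s")
  expect_length(tr3$taken, 0)

  # every taken edge's guard was true at traversal time
  facts <- list(bcf_available = "no", log_kow = 6)
  tr4 <- trace_workflow(wf, facts)
  for (eid in tr4$taken) {
    e <- wf$edges[paste0(wf$edges$from, "->", wf$edges$to) == eid, ]
    g <- e$guard[[1]]
    if (!is.null(g)) expect_true(evaluate_condition(g, facts))
  }
  # the log Kow screen only suggests B
  dm <- ks_evaluate(ex$registry, facts)
  expect_equal(dm$state[dm$decision == "B"], "suggested")
})

test_that("mirrored decisions replace cleanly and drive the screening view", {
  ex <- kryptonite_example()
  dm <- ks_evaluate(ex$registry, kryptonite_facts())
  mirror_decisions(ex$store, ex$substance, dm)
  view <- ex$views$pbt_screening
  expect_equal(render_view(ex$store, view)$label, "Kryptonite")

  n <- nrow(ex$store$triples)
  mirror_decisions(ex$store, ex$substance, dm)
  expect_equal(nrow(ex$store$triples), n)  # idempotent

  # all undefined -> zero hasDecision triples
  mirror_decisions(ex$store, ex$substance, ks_evaluate(ex$registry, list()))
  pred <- paste0(ex$store$ns, "hasDecision")
  expect_equal(sum(ex$store$triples$p == pred &
                     ex$store$triples$s == ex$substance), 0)
  expect_equal(nrow(render_view(ex$store, view)), 0)
})

test_that("dependency-ordered evaluation is already a fixpoint", {
  ex <- kryptonite_example()
  facts <- kryptonite_facts()
  dm1 <- ks_evaluate(ex$registry, facts)
  # seed a second full pass with the states of the first: nothing changes
  pass <- knowsub:::evaluate_pass(ex$registry, facts,
                                  setNames(dm1$state, dm1$decision))
  expect_equal(pass$states, setNames(dm1$state, dm1$decision))
})
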