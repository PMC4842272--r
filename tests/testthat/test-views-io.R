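test_that("views re-execute against current store state and export stably", {
  ex <- kryptonite_example()
  dm <- ks_evaluate(ex$registry, current_facts(ex$answers, ex$substance))
  mirror_decisions(ex$store, ex$substance, dm)
  view <- ex$views$pbt_screening
  tab <- render_view(ex$store, view)
  expect_equal(tab$label, "Kryptonite")

  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  export_table(tab, p1)
  export_table(render_view(ex$store, view), p2)  # unchanged store
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))

  # retraction flows through to the view on re-render (no caching)
  f2 <- retract(current_facts(ex$answers, ex$substance), "chronic_noec")
  mirror_decisions(ex$store, ex$substance, ks_evaluate(ex$registry, f2))
  expect_equal(nrow(render_view(ex$store, view)), 0)

  # empty store: header-only table and file
  empty_tab <- render_view(ks_store(), view)
  expect_equal(nrow(empty_tab), 0)
  export_table(empty_tab, p1)
  expect_equal(readLines(p1), "label,ec,cas")

  expect_error(view_definition("broken", "SELECT WHERE ("),
               class = "knowsub_query_syntax_error")
  expect_error(view_definition("ask", "ASK { ?s ?p ?o . }"),
               class = "knowsub_view_error")
})

test_that("CSV export quotes per RFC 4180 and round-trips", {
  tab <- tibble::tibble(label = c("plain", "has,comma", "has \"quote\""),
                        v = c("1", "2", "3"))
  path <- withr::local_tempfile(fileext = ".csv")
  export_table(tab, path)
  lines <- readLines(path)
  expect_equal(lines[[3]], "\"has,comma\",2")
  expect_equal(lines[[4]], "\"has \"\"quote\"\"\",3")
  back <- readr::read_csv(path, col_types = "cc")
  expect_equal(as.data.frame(back), as.data.frame(tab))
})

test_that("bulk import creates, merges idempotently and rejects bad checksums", {
  path <- withr::local_tempfile(fileext = ".csv")
  recs <- generate_substances(10, invalid_rate = 0, seed = 8)
  readr::write_csv(
    tibble::tibble(label = recs$label, cas = recs$cas, ec = recs$ec,
                   smiles = recs$smiles, ThCO2 = seq(5, 95, by = 10)),
    path)
  st <- ks_store()
  h <- fact_history()
  t0 <- as.POSIXct("2016-02-01", tz = "UTC")
  res <- import_substances(st, h, path, timestamp = t0)
  expect_equal(res$summary$created, 10)
  expect_equal(res$summary$merged, 0)
  expect_equal(res$summary$facts_recorded, 10)
  expect_true(all(res$history$source == "import"))

  res2 <- import_substances(st, res$history, path, timestamp = t0 + 60)
  expect_equal(res2$summary$created, 0)
  expect_equal(res2$summary$merged, 10)

  # a row with a broken CAS checksum is rejected with a reason
  readr::write_csv(tibble::tibble(label = "Broken", cas = "7732-18-4"),
                   path)
  res3 <- import_substances(st, res2$history, path)
  expect_equal(res3$summary$rejected, 1)
  expect_match(res3$rejected$reason, "bad_checksum")
  expect_false("Broken" %in% substance_table(st)$label)

  expect_error(import_substances(st, h, {
    readr::write_csv(tibble::tibble(cas = "7732-18-5"), path); path
  }), class = "knowsub_format_error")
})

test_that("import then export of the substance table is lossless", {
  path <- withr::local_tempfile(fileext = ".csv")
  recs <- generate_substances(12, invalid_rate = 0, seed = 13)
  readr::write_csv(tibble::tibble(label = recs$label, cas = recs$cas,
                                  ec = recs$ec, smiles = recs$smiles),
                   path)
  st <- ks_store()
  import_substances(st, fact_history(), path)
  tab <- substance_table(st)
  expect_equal(tab$label, sort(recs$label))
  m <- match(tab$label, recs$label)
  expect_equal(tab$cas, recs$cas[m])
  expect_equal(tab$ec, recs$ec[m])
  expect_equal(tab$smiles, recs$smiles[m])
})

test_that("the info page assembles its sections in fixed order", {
  ex <- kryptonite_example()
  h <- ex$answers
  add_memo(ex$store, ks_memo(ex$substance, "Toxic", "T assessment.",
                             attached_decision = "T", author = "carol",
                             created_at = as.POSIXct("2016-05-01",
                                                     tz = "UTC")),
           registry = ex$registry)
  page <- info_page(ex$store, ex$registry, h, ex$substance)
  txt <- unclass(page)
  expect_match(txt, "# Kryptonite")
  # three chem properties worth of identifiers + PBT decision + memo
  expect_match(txt, "CAS: 9999999-99-5")
  expect_match(txt, "PBT \\(persistent, bioaccumulative, toxic\\): \\*\\*established\\*\\*")
  expect_match(txt, "\\*\\*Toxic\\*\\* \\[decision: T\\]")
  # section order: identifiers < decisions < memos < fact history
  pos <- vapply(c("## Identifiers", "## Current decisions", "## Memos",
                  "## Fact history"),
                function(s) regexpr(s, txt, fixed = TRUE)[[1]], numeric(1))
  expect_true(all(diff(pos) > 0))
  # within a module group, final (hierarchy-root) decisions come first
  expect_lt(regexpr("- B criterion", txt, fixed = FALSE)[[1]],
            regexpr("- vB criterion", txt)[[1]])

  # a newer memo appears first on regeneration
  add_memo(ex$store, ks_memo(ex$substance, "Newer note",
                             created_at = as.POSIXct("2016-06-01",
                                                     tz = "UTC")))
  page2 <- unclass(info_page(ex$store, ex$registry, h, ex$substance))
  expect_lt(regexpr("Newer note", page2)[[1]],
            regexpr("\\*\\*Toxic\\*\\*", page2)[[1]])

  # substance without facts
  st <- ks_store()
  u <- add_substance(st, substance_record(label = "Bare"))
  bare <- unclass(info_page(st, ex$registry, fact_history(), u))
  expect_match(bare, "none derived")
  expect_error(info_page(st, ex$registry, fact_history(), "nope"),
               class = "knowsub_not_found_error")
})

test_that("every decision on the info page is reachable through a bundled view", {
  ex <- kryptonite_example()
  dm <- ks_evaluate(ex$registry, current_facts(ex$answers, ex$substance))
  mirror_decisions(ex$store, ex$substance, dm)
  overview <- render_view(ex$store, ex$views$substance_overview)
  live <- dm$decision[dm$state != "undefined"]
  shown <- overview$decision[overview$label == "Kryptonite"]
  expect_setequal(setdiff(live, shown), character())
})
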