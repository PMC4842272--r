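# Deterministic fixtures: synthetic substances with valid (or deliberately
# invalid) identifiers, random stores, random rule bases, and the bundled
# Kryptonite worked example. All generators are pure functions of their
# seed. Synthetic CAS/EC values are drawn from the reserved high-number
# 99xxxxx / 9xx ranges and never collide with real registry entries.

cas_check_digit <- function(body_digits) {
  sum(rev(body_digits) * seq_along(body_digits)) %% 10L
}

ec_check_remainder <- function(body_digits) {
  sum(body_digits * 1:6) %% 11L
}

make_cas <- function(body9) {
  # body9: 9 digits (7 + 2); returns a checksum-valid CAS string
  d <- as.integer(strsplit(body9, "")[[1]])
  sprintf("%s-%s-%d", substr(body9, 1, 7), substr(body9, 8, 9),
          cas_check_digit(d))
}

make_ec <- function(body6) {
  d <- as.integer(strsplit(body6, "")[[1]])
  rem <- ec_check_remainder(d)
  if (rem == 10L) return(NA_character_)  # body has no valid check digit
  sprintf("%s-%s-%d", substr(body6, 1, 3), substr(body6, 4, 6), rem)
}

#' Generate synthetic substance records
#'
#' Produces `n` records with unique labels and synthetic, checksum-valid CAS
#' and EC numbers; a fraction `invalid_rate` of the records (exactly
#' `round(n * invalid_rate)`) gets a CAS with a deliberately wrong check
#' digit, so identifier QC finds exactly that many failures.
#'
#' @param n number of substances.
#' @param invalid_rate fraction in \[0, 1\] of records with a broken CAS
#'   checksum.
#' @param seed RNG seed; identical specs yield identical output.
#' @param path optional CSV path to also write the table to (with a
#'   `comment` column marking every row SYNTHETIC).
#' @return tibble with columns `label`, `cas`, `ec`, `smiles`, `valid_cas`.
#' @export
generate_substances <- function(n, invalid_rate = 0, seed = 1, path = NULL) {
  if (invalid_rate < 0 || invalid_rate > 1) {
    stop_knowsub("invalid_rate must be within [0, 1]",
                 "knowsub_validation_error")
  }
  if (n == 0) {
    out <- tibble(label = character(), cas = character(), ec = character(),
                  smiles = character(), valid_cas = logical())
    if (!is.null(path)) readr::write_csv(out, path)
    return(out)
  }
  set.seed(seed)
  labels <- sprintf("Synthetic substance %04d", seq_len(n))
  cas_bodies <- sprintf("99%05d%02d", sample.int(99999, n, replace = FALSE),
                        sample(0:99, n, replace = TRUE))
  cas <- map_chr(cas_bodies, make_cas)
  ec <- character(n)
  for (i in seq_len(n)) {
    repeat {
      body <- sprintf("9%05d", sample.int(99999, 1))
      v <- make_ec(body)
      if (!is.na(v) && !v %in% ec) { ec[[i]] <- v; break }
    }
  }
  # unique linear alkane-style SMILES so a clean fixture has a clean
  # quality dashboard (no accidental duplicate identifiers)
  smiles <- map_chr(seq_len(n), function(i) strrep("C", i))
  n_bad <- round(n * invalid_rate)
  valid <- rep(TRUE, n)
  if (n_bad > 0) {
    bad_idx <- seq_len(n_bad)  # deterministic: the first round(n*rate) rows
    for (i in bad_idx) {
      check <- as.integer(substr(cas[[i]], nchar(cas[[i]]),
                                 nchar(cas[[i]])))
      cas[[i]] <- sub("[0-9]$", as.character((check + 1L) %% 10L), cas[[i]])
      valid[[i]] <- FALSE
    }
  }
  out <- tibble(label = labels, cas = cas, ec = ec, smiles = smiles,
                valid_cas = valid)
  if (!is.null(path)) {
    readr::write_csv(
      tibble(label = out$label, cas = out$cas, ec = out$ec,
             smiles = out$smiles, comment = "SYNTHETIC"), path)
  }
  out
}

#' Populate a store with generated substances
#'
#' @param records output of [generate_substances()].
#' @return a `ks_store` containing the records.
#' @export
populate_store <- function(records) {
  store <- ks_store()
  for (i in seq_len(nrow(records))) {
    add_substance(store, substance_record(
      label = records$label[[i]], cas_number = records$cas[[i]],
      ec_number = records$ec[[i]], smiles = records$smiles[[i]]))
  }
  store
}

#' Generate a random store with random chemical-property assertions
#'
#' Each substance gets an independent random subset of
#' persistent/bioaccumulative/toxic, so the PBT class and its complement
#' are non-trivial.
#'
#' @param n number of substances (<= a few hundred).
#' @param seed RNG seed.
#' @return a `ks_store`.
#' @export
generate_random_store <- function(n, seed = 1) {
  records <- generate_substances(n, invalid_rate = 0, seed = seed)
  store <- populate_store(records)
  set.seed(seed + 1L)
  props <- c("persistent", "bioaccumulative", "toxic")
  for (uri in substance_uris(store)) {
    for (p in props) {
      if (stats::runif(1) < 0.5) assert_property(store, uri, p)
    }
  }
  store
}

#' Path to a bundled fixture file
#' @param ... path components under the package's `extdata`.
#' @return absolute path.
#' @export
knowsub_example_file <- function(...) {
  system.file("extdata", ..., package = "knowsub", mustWork = TRUE)
}

#' The bundled Kryptonite worked example
#'
#' Loads the Kryptonite ontology, the four example decision modules
#' (Persistence, Bioaccumulation, Toxicity, PBT) and a scripted answer set
#' that drives the PBT decision to *established*: ready-biodegradability
#' failure (ThCO2 45% of the 60% pass level) plus a 75-day water half-life
#' for P/vP, a measured BCF of 5300 L/kg for B/vB, and a chronic NOEC of
#' 0.004 mg/L for T.
#'
#' @param companion if `TRUE`, a second, non-PBT substance (synthetic, only
#'   persistent) is added, so the NOT-EXISTS complement query is non-empty.
#' @return list with elements `store` (`ks_store`), `registry`
#'   (`ks_registry`), `substance` (Kryptonite's URI), `answers` (a
#'   `ks_fact_history` holding the scripted facts) and `views` (bundled
#'   dynamic views).
#' @export
kryptonite_example <- function(companion = FALSE) {
  store <- load_turtle(knowsub_example_file("kryptonite.ttl"))
  registry <- load_registry(knowsub_example_file("modules", "registry.yaml"))
  uri <- ks_term(store, "Kryptonite")
  if (companion) {
    comp <- add_substance(store, substance_record(
      label = "Adamantium", cas_number = make_cas("990000001"),
      ec_number = make_ec("900001")))
    assert_property(store, comp, "persistent")
  }
  base <- as.POSIXct("2016-04-23 10:00:00", tz = "UTC")
  answers <- fact_history()
  give <- function(h, q, v, mins, reliability = NA_integer_) {
    record_fact(h, uri, q, v, timestamp = base + mins * 60,
                author = "assessor", source = "user",
                reliability = reliability)
  }
  answers <- give(answers, "ThCO2", 45, 0, reliability = 1L)
  answers <- give(answers, "dt50_water", 75, 1, reliability = 2L)
  answers <- give(answers, "bcf_available", "yes", 2)
  answers <- give(answers, "BCF", 5300, 3, reliability = 1L)
  answers <- give(answers, "chronic_noec", 0.004, 4, reliability = 2L)
  views <- load_views(knowsub_example_file("views"))
  list(store = store, registry = registry, substance = uri,
       answers = answers, views = views)
}

#' Generate a random single-module registry for property-based testing
#'
#' Random numeric and one-choice questions, decisions, and `n_rules`
#' scoring rules with random conditions (depth <= 3). The result always
#' passes [validate_registry()].
#'
#' @param seed RNG seed.
#' @param n_rules number of rules (<= 50).
#' @return a `ks_registry` with one module named `"Random"`.
#' @export
generate_random_registry <- function(seed = 1, n_rules = 10) {
  if (n_rules > 50) {
    stop_knowsub("n_rules must be <= 50", "knowsub_validation_error")
  }
  set.seed(seed)
  n_q <- 5L
  n_c <- 2L
  n_d <- 4L
  qids <- sprintf("q%d", seq_len(n_q))
  cids <- sprintf("c%d", seq_len(n_c))
  dids <- sprintf("d%d", seq_len(n_d))
  choices <- c("low", "mid", "high")
  qlines <- c(
    sprintf('  %s "Numeric input %s" numeric', qids, qids),
    sprintf('  %s "Choice input %s" one_choice(%s)', cids, cids,
            paste(choices, collapse = ", ")))
  dlines <- sprintf('  %s "Random decision %s"', dids, dids)
  rand_cond <- function(depth) {
    pick <- stats::runif(1)
    if (depth <= 0 || pick < 0.45) {
      kind <- sample(c("num", "choice", "known"), 1,
                     prob = c(0.6, 0.25, 0.15))
      if (kind == "num") {
        sprintf("%s %s %d", sample(qids, 1),
                sample(c("<", "<=", ">", ">="), 1), sample(0:100, 1))
      } else if (kind == "choice") {
        sprintf("%s = %s", sample(cids, 1), sample(choices, 1))
      } else {
        sprintf("known(%s)", sample(qids, 1))
      }
    } else if (pick < 0.65) {
      sprintf("NOT(%s)", rand_cond(depth - 1))
    } else {
      op <- sample(c("AND", "OR"), 1)
      k <- sample(2:3, 1)
      sprintf("%s(%s)", op,
              paste(replicate(k, rand_cond(depth - 1)), collapse = ", "))
    }
  }
  rlines <- character()
  for (i in seq_len(n_rules)) {
    rlines <- c(rlines, sprintf(
      "  RULE r%d: IF %s THEN %s %s", i, rand_cond(2), sample(dids, 1),
      sample(names(SCORE_CATEGORIES), 1)))
  }
  text <- paste(c("MODULE Random", "QUESTIONS", qlines, "DECISIONS", dlines,
                  if (n_rules > 0) c("RULES", rlines)), collapse = "\n")
  ks_registry(list(parse_module(text)))
}

#' Generate a random fact set for a registry
#'
#' Each question is independently answered with probability
#' `answer_prob`; numeric questions get values in \[0, 100\], choice
#' questions a random choice.
#'
#' @param registry a `ks_registry`.
#' @param seed RNG seed.
#' @param answer_prob probability a question is answered.
#' @return named list question id -> value.
#' @export
generate_random_facts <- function(registry, seed = 1, answer_prob = 0.7) {
  set.seed(seed)
  qs <- registry_questions(registry)
  out <- list()
  for (i in seq_len(nrow(qs))) {
    if (stats::runif(1) > answer_prob) next
    q <- qs[i, ]
    out[[q$id]] <- switch(q$value_type,
      numeric = round(stats::runif(1, 0, 100), 1),
      one_choice = sample(q$choices[[1]], 1),
      multi_choice = sample(q$choices[[1]],
                            sample(seq_along(q$choices[[1]]), 1)),
      date = as.Date("2016-01-01") + sample(0:1000, 1),
      text = paste0("note-", sample(1000, 1)))
  }
  out
}
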