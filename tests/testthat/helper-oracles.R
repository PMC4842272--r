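# Independent oracles used across the suite. Each is written from the
# definition, deliberately in a different style from the package code, so
# agreement is evidence rather than tautology.

# -- check digits -------------------------------------------------------------

# CAS: digits d1..dk (left to right, hyphens removed, check digit excluded)
# carry weights k, k-1, ..., 1 read left to right; the check digit is the
# weighted sum mod 10.
oracle_cas_check_digit <- function(body) {
  ds <- as.integer(strsplit(body, "")[[1]])
  k <- length(ds)
  total <- 0L
  for (i in seq_len(k)) total <- total + ds[[i]] * (k - i + 1L)
  total %% 10L
}

# EC: digits d1..d6 left to right, weights 1..6, mod 11; remainder 10 means
# the body admits no valid check digit.
oracle_ec_check_digit <- function(body) {
  ds <- as.integer(strsplit(body, "")[[1]])
  total <- 0L
  for (i in 1:6) total <- total + ds[[i]] * i
  r <- total %% 11L
  if (r == 10L) NA_integer_ else r
}

# -- three-valued conditions --------------------------------------------------

# Recursive interpreter over {"T","F","U"}; written against the Kleene
# truth tables, not by reusing the package's NA logic.
oracle_eval_condition <- function(cond, facts, decisions = character()) {
  val_of <- function(q) {
    v <- facts[[q]]
    if (is.null(v) || (length(v) == 1 && is.na(v))) NULL else v
  }
  rec <- function(c) {
    if (c$kind == "and") {
      vs <- vapply(c$args, rec, character(1))
      if ("F" %in% vs) return("F")
      if ("U" %in% vs) return("U")
      return("T")
    }
    if (c$kind == "or") {
      vs <- vapply(c$args, rec, character(1))
      if ("T" %in% vs) return("T")
      if ("U" %in% vs) return("U")
      return("F")
    }
    if (c$kind == "not") {
      v <- rec(c$arg)
      return(switch(v, T = "F", F = "T", U = "U"))
    }
    if (c$kind == "known") {
      return(if (is.null(val_of(c$question))) "U" else "T")
    }
    if (c$kind == "dstate") {
      st <- if (c$decision %in% names(decisions)) {
        decisions[[c$decision]]
      } else "undefined"
      hit <- identical(st, c$state)
      return(if (c$op == "=") {
        if (hit) "T" else "F"
      } else {
        if (hit) "F" else "T"
      })
    }
    # cmp
    v <- val_of(c$question)
    if (is.null(v)) return("U")
    res <- switch(c$op,
      "<" = any(v < c$rhs), "<=" = any(v <= c$rhs),
      ">" = any(v > c$rhs), ">=" = any(v >= c$rhs),
      "=" = any(as.character(v) == as.character(c$rhs)),
      "!=" = !any(as.character(v) == as.character(c$rhs)),
      "in" = any(as.character(v) %in%
                   vapply(c$rhs, as.character, character(1))))
    if (res) "T" else "F"
  }
  rec(cond)
}

tv_to_chr <- function(x) if (is.na(x)) "U" else if (x) "T" else "F"

# -- rule engine --------------------------------------------------------------

# Brute force: enumerate every rule, test its condition with the oracle
# interpreter, sum the fired categories per target, map thresholds.
oracle_rule_states <- function(registry, facts) {
  cats <- c(N7 = -80, N6 = -40, N5 = -20, N4 = -10, N3 = -5, N2 = -2,
            N1 = -1, P1 = 1, P2 = 2, P3 = 5, P4 = 10, P5 = 20, P6 = 40,
            P7 = 80)
  decs <- unlist(lapply(registry$modules, function(m) m$decisions$id))
  scores <- setNames(numeric(length(decs)), decs)
  for (m in registry$modules) {
    for (i in seq_len(nrow(m$rules))) {
      r <- m$rules[i, ]
      if (oracle_eval_condition(r$condition[[1]], facts) == "T") {
        scores[[r$target]] <- scores[[r$target]] + cats[[r$category]]
      }
    }
  }
  th <- registry$thresholds
  states <- vapply(scores, function(s) {
    if (s <= th[["excluded"]]) "excluded"
    else if (s >= th[["established"]]) "established"
    else if (s >= th[["suggested"]]) "suggested"
    else "undefined"
  }, character(1))
  list(scores = scores, states = states)
}

# -- class membership ---------------------------------------------------------

# Brute force: scan all substances x all required pairs directly on the
# triple table.
oracle_members <- function(store, property_labels) {
  t <- store$triples
  ns <- store$ns
  type_p <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"
  subs <- unique(t$s[t$p == type_p & t$o == paste0(ns, "Substance")])
  terms <- vapply(property_labels, function(lab) {
    cand <- t$s[t$p == paste0(ns, "hasLabel") & t$o == lab]
    cand[cand %in% t$s[t$p == type_p & t$o == paste0(ns, "ChemProperty")]][1]
  }, character(1))
  ok <- vapply(subs, function(s) {
    all(vapply(terms, function(term) {
      any(t$s == s & t$p == paste0(ns, "hasChemProperty") & t$o == term)
    }, logical(1)))
  }, logical(1))
  sort(subs[ok])
}

# -- random condition generator (for oracle-equivalence properties) ----------

random_condition_text <- function(depth, qids, cids, choices) {
  leaf <- function() {
    r <- runif(1)
    if (r < 0.5) {
      sprintf("%s %s %d", sample(qids, 1),
              sample(c("<", "<=", ">", ">=", "=", "!="), 1),
              sample(0:100, 1))
    } else if (r < 0.8) {
      sprintf("%s = %s", sample(cids, 1), sample(choices, 1))
    } else {
      sprintf("known(%s)", sample(qids, 1))
    }
  }
  if (depth <= 0 || runif(1) < 0.4) return(leaf())
  r <- runif(1)
  if (r < 0.25) {
    sprintf("NOT(%s)", random_condition_text(depth - 1, qids, cids, choices))
  } else {
    sprintf("%s(%s)", sample(c("AND", "OR"), 1),
            paste(replicate(sample(2:3, 1),
                            random_condition_text(depth - 1, qids, cids,
                                                  choices)),
                  collapse = ", "))
  }
}

random_fact_assignment <- function(qids, cids, choices, answer_prob = 0.6) {
  out <- list()
  for (q in qids) {
    if (runif(1) < answer_prob) out[[q]] <- sample(0:100, 1) * 1.0
  }
  for (q in cids) {
    if (runif(1) < answer_prob) out[[q]] <- sample(choices, 1)
  }
  out
}
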