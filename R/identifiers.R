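# Identifier quality control: CAS / EC check digits, SMILES token sanity,
# duplicate and contraindicative identifier detection, quality dashboard.

validation_result <- function(identifier, scheme, well_formed, checksum_ok,
                              message) {
  structure(list(identifier = identifier, scheme = scheme,
                 well_formed = well_formed,
                 checksum_ok = well_formed && checksum_ok,
                 message = message),
            class = "ks_validation_result")
}

#' @export
print.ks_validation_result <- function(x, ...) {
  cat(sprintf("%s [%s]: %s\n", x$identifier, x$scheme, x$message))
  invisible(x)
}

#' Validate a CAS Registry Number
#'
#' A CAS number has the form `NNNNNNN-NN-R` (2-7 digits, 2 digits, check
#' digit). The check digit `R` is the weighted sum of the other digits,
#' weights 1, 2, 3, ... counted from the rightmost non-check digit leftward,
#' taken modulo 10. Water, 7732-18-5, checks as
#' (8*1 + 1*2 + 2*3 + 3*4 + 7*5 + 7*6) mod 10 = 105 mod 10 = 5.
#'
#' @param text candidate identifier.
#' @return a `ks_validation_result` with fields `well_formed`, `checksum_ok`
#'   and `message`. Failures are encoded in the result, never raised.
#' @export
validate_cas <- function(text) {
  if (!grepl("^[0-9]{2,7}-[0-9]{2}-[0-9]$", text)) {
    return(validation_result(text, "CAS", FALSE, FALSE,
                             "not of the form NNNNNNN-NN-R"))
  }
  digits <- as.integer(strsplit(gsub("-", "", text), "")[[1]])
  nd <- length(digits)
  body <- digits[-nd]
  check <- digits[[nd]]
  expected <- sum(rev(body) * seq_along(body)) %% 10L
  if (check == expected) {
    validation_result(text, "CAS", TRUE, TRUE, "valid CAS number")
  } else {
    validation_result(text, "CAS", TRUE, FALSE,
                      sprintf("checksum failed (expected check digit %d)",
                              expected))
  }
}

#' Validate an EC (EINECS/ELINCS) number
#'
#' An EC number has the form `NNN-NNN-R`. The check digit is
#' (1*d1 + 2*d2 + ... + 6*d6) mod 11, digits counted left to right. A
#' remainder of 10 has no valid check digit: no identifier with that body is
#' well-checksummed.
#'
#' @param text candidate identifier.
#' @return a `ks_validation_result`.
#' @export
validate_ec <- function(text) {
  if (!grepl("^[0-9]{3}-[0-9]{3}-[0-9]$", text)) {
    return(validation_result(text, "EC", FALSE, FALSE,
                             "not of the form NNN-NNN-R"))
  }
  digits <- as.integer(strsplit(gsub("-", "", text), "")[[1]])
  body <- digits[1:6]
  check <- digits[[7]]
  rem <- sum(body * 1:6) %% 11L
  if (rem == 10L) {
    validation_result(text, "EC", TRUE, FALSE,
                      "checksum failed (body has no valid check digit)")
  } else if (check == rem) {
    validation_result(text, "EC", TRUE, TRUE, "valid EC number")
  } else {
    validation_result(text, "EC", TRUE, FALSE,
                      sprintf("checksum failed (expected check digit %d)",
                              rem))
  }
}

#' Syntactic sanity check for a SMILES string
#'
#' Checks token legality and balanced brackets/ring closures only; no
#' chemistry is interpreted — SMILES serves purely as an identifier here.
#'
#' @param text candidate SMILES.
#' @return logical scalar.
#' @export
smiles_well_formed <- function(text) {
  if (!nzchar(text)) return(FALSE)
  if (grepl("[^A-Za-z0-9@+\\[\\]()=#$:/\\\\%.*-]", text, perl = TRUE)) {
    return(FALSE)
  }
  chars <- strsplit(text, "")[[1]]
  depth_par <- 0L
  depth_br <- 0L
  rings <- integer()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[[i]]
    if (ch == "(") depth_par <- depth_par + 1L
    if (ch == ")") { depth_par <- depth_par - 1L
      if (depth_par < 0) return(FALSE) }
    if (ch == "[") { depth_br <- depth_br + 1L
      if (depth_br > 1) return(FALSE) }
    if (ch == "]") { depth_br <- depth_br - 1L
      if (depth_br < 0) return(FALSE) }
    if (depth_br == 0 && grepl("[0-9]", ch)) {
      d <- as.integer(ch)
      if (d %in% rings) rings <- setdiff(rings, d) else rings <- c(rings, d)
    }
    i <- i + 1L
  }
  depth_par == 0L && depth_br == 0L && length(rings) == 0L
}

SINGLE_VALUED_SCHEMES <- c(CAS = "hasCAS", EC = "hasEC", IUPAC = "hasIUPAC",
                           SMILES = "hasSMILES")

identifier_table <- function(store) {
  t <- store$triples
  subs <- substance_uris(store)
  out <- list()
  for (scheme in names(SINGLE_VALUED_SCHEMES)) {
    pred <- ks_term(store, SINGLE_VALUED_SCHEMES[[scheme]])
    rows <- t[t$p == pred & t$s %in% subs, , drop = FALSE]
    if (nrow(rows)) {
      out[[scheme]] <- tibble(substance = rows$s, scheme = scheme,
                              value = rows$o)
    }
  }
  if (length(out)) bind_rows(out) else
    tibble(substance = character(), scheme = character(), value = character())
}

#' Run the identifier quality dashboard over a store
#'
#' Reports, per the continuous-quality-dashboard idea:
#' * `bad_checksum` — one finding per CAS/EC identifier failing its check
#'   digit (or malformed);
#' * `duplicate_identifier` — one finding per identifier value shared by two
#'   or more substances (possible duplicate registrations);
#' * `contraindicative_identifiers` — one finding per substance carrying two
#'   or more distinct values for a single-valued scheme (CAS, EC, IUPAC,
#'   SMILES). Internal names stay multi-valued and are never flagged.
#'
#' @param store a `ks_store`.
#' @return a `ks_quality_report`: a tibble of findings with columns `kind`,
#'   `substances` (list-column of URIs), `detail`, sorted by
#'   (kind, first substance), with the generation timestamp as attribute
#'   `generated_at`.
#' @export
run_quality_checks <- function(store) {
  ids <- identifier_table(store)
  findings <- list()
  add <- function(kind, substances, detail) {
    findings[[length(findings) + 1]] <<- tibble(
      kind = kind, substances = list(sort(unique(substances))),
      detail = detail)
  }
  # checksum findings
  if (nrow(ids)) {
    for (i in seq_len(nrow(ids))) {
      row <- ids[i, ]
      if (row$scheme == "CAS") {
        v <- validate_cas(row$value)
      } else if (row$scheme == "EC") {
        v <- validate_ec(row$value)
      } else next
      if (!v$checksum_ok) {
        add("bad_checksum", row$substance,
            sprintf("%s %s: %s", row$scheme, row$value, v$message))
      }
    }
    # duplicates: same (scheme, value) on >= 2 substances
    dup <- ids |>
      distinct(.data$substance, .data$scheme, .data$value) |>
      group_by(.data$scheme, .data$value) |>
      filter(n() >= 2) |>
      summarise(subs = list(sort(unique(.data$substance))), .groups = "drop")
    if (nrow(dup)) {
      for (i in seq_len(nrow(dup))) {
        add("duplicate_identifier", dup$subs[[i]],
            sprintf("%s %s shared by %d substances", dup$scheme[[i]],
                    dup$value[[i]], length(dup$subs[[i]])))
      }
    }
    # contraindicative: >= 2 distinct values for a single-valued scheme
    contra <- ids |>
      distinct(.data$substance, .data$scheme, .data$value) |>
      group_by(.data$substance, .data$scheme) |>
      filter(n() >= 2) |>
      summarise(vals = list(sort(unique(.data$value))), .groups = "drop")
    if (nrow(contra)) {
      for (i in seq_len(nrow(contra))) {
        add("contraindicative_identifiers", contra$substance[[i]],
            sprintf("%s has %d competing %s values: %s",
                    contra$substance[[i]], length(contra$vals[[i]]),
                    contra$scheme[[i]],
                    paste(contra$vals[[i]], collapse = ", ")))
      }
    }
  }
  rep <- if (length(findings)) bind_rows(findings) else
    tibble(kind = character(), substances = list(), detail = character())
  if (nrow(rep)) {
    first_sub <- map_chr(rep$substances, ~ .x[[1]] %||% "")
    rep <- rep[order(rep$kind, first_sub, rep$detail), , drop = FALSE]
  }
  attr(rep, "generated_at") <- Sys.time()
  class(rep) <- c("ks_quality_report", class(rep))
  rep
}

#' Export a quality report as CSV
#'
#' @param report a `ks_quality_report`.
#' @param path output path; columns `kind`, `substances`
#'   (semicolon-separated), `detail`.
#' @return `path`, invisibly.
#' @export
export_quality_report <- function(report, path) {
  flat <- tibble(
    kind = report$kind,
    substances = map_chr(report$substances, paste, collapse = ";"),
    detail = report$detail
  )
  readr::write_csv(flat, path)
  invisible(path)
}

#' @export
autoplot.ks_quality_report <- function(object, ...) {
  df <- tibble(kind = factor(object$kind,
                             levels = c("bad_checksum", "duplicate_identifier",
                                        "contraindicative_identifiers")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$kind)) +
    ggplot2::geom_bar(fill = "steelblue") +
    ggplot2::scale_x_discrete(drop = FALSE) +
    ggplot2::labs(x = NULL, y = "findings",
                  title = "Identifier quality dashboard") +
    ggplot2::theme_minimal()
}
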