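#' Create an in-memory RDF triple store for substance knowledge
#'
#' The store is the system's single source of truth: substances and their
#' identifiers, chemical-property assertions, mirrored decision states and
#' decision memos all live in one RDF graph. It is a reference object
#' (an environment), so the `add_*`/`assert_*` verbs mutate it in place and
#' return it invisibly, which lets calls chain naturally.
#'
#' The graph is held as a tibble of triples with columns `s`, `p`, `o` and
#' `o_kind` (`"iri"` or `"literal"`). The bundled vocabulary declares the
#' classes `ks:Substance` and `ks:ChemProperty`, the datatype properties
#' `ks:hasLabel`, `ks:hasCAS`, `ks:hasEC`, `ks:hasIUPAC`, `ks:hasSMILES`,
#' `ks:hasInternalName` and `ks:hasMemo`, and the class relation
#' `ks:hasChemProperty`. Three `ks:ChemProperty` instances are bundled:
#' persistent, bioaccumulative and toxic.
#'
#' @param ns namespace IRI under which all substance-vocabulary terms are
#'   minted (rendered with the prefix `ks:` on output).
#' @param bundled_terms if `TRUE` (default) declare the vocabulary and the
#'   three bundled chemical-property terms.
#' @return an object of class `ks_store`.
#' @examples
#' st <- ks_store()
#' add_substance(st, substance_record(label = "Kryptonite"))
#' @export
ks_store <- function(ns = KS_DEFAULT_NS, bundled_terms = TRUE) {
  store <- new.env(parent = emptyenv())
  store$ns <- ns
  store$triples <- tibble(
    s = character(), p = character(), o = character(), o_kind = character()
  )
  class(store) <- "ks_store"
  if (bundled_terms) {
    add_triple(store, ks_term(store, "Substance"), RDF_TYPE,
               paste0(RDFS_NS, "Class"))
    add_triple(store, ks_term(store, "ChemProperty"), RDF_TYPE,
               paste0(RDFS_NS, "Class"))
    for (prop in c("persistent", "bioaccumulative", "toxic")) {
      add_property_term(store, prop)
    }
  }
  store
}

#' @export
print.ks_store <- function(x, ...) {
  cat(sprintf("<ks_store> %d triples, %d substances (ns: %s)\n",
              nrow(x$triples), length(substance_uris(x)), x$ns))
  invisible(x)
}

#' Add one triple to a store (idempotent)
#' @param store a `ks_store`.
#' @param s,p,o subject IRI, predicate IRI, object (IRI or literal text).
#' @param o_kind `"iri"` or `"literal"`.
#' @return the store, invisibly.
#' @export
add_triple <- function(store, s, p, o, o_kind = "iri") {
  hit <- store$triples$s == s & store$triples$p == p &
    store$triples$o == o & store$triples$o_kind == o_kind
  if (!any(hit)) {
    store$triples <- vctrs_rbind(store$triples,
                                 tibble(s = s, p = p, o = o, o_kind = o_kind))
  }
  invisible(store)
}

vctrs_rbind <- function(a, b) dplyr::bind_rows(a, b)

# conjunctive delete: rows matching every non-NULL component go
remove_triples <- function(store, s = NULL, p = NULL, o = NULL) {
  del <- rep(TRUE, nrow(store$triples))
  if (!is.null(s)) del <- del & store$triples$s == s
  if (!is.null(p)) del <- del & store$triples$p == p
  if (!is.null(o)) del <- del & store$triples$o == o
  store$triples <- store$triples[!del, , drop = FALSE]
  invisible(store)
}

#' Construct a substance record
#'
#' A substance is the unifying concept of the system: one record carries its
#' identifier set. At least one identifier or the label must be non-empty.
#'
#' @param label display label (also used to mint the URI when none given).
#' @param uri optional resource identifier; defaults to `ks:<slug(label)>`.
#' @param cas_number,ec_number,iupac_name,smiles optional identifiers.
#' @param internal_names character vector of internal names.
#' @return a list of class `substance_record`.
#' @export
substance_record <- function(label = NULL, uri = NULL, cas_number = NULL,
                             ec_number = NULL, iupac_name = NULL,
                             smiles = NULL, internal_names = character()) {
  rec <- list(uri = uri, label = label, cas_number = cas_number,
              ec_number = ec_number, iupac_name = iupac_name,
              smiles = smiles, internal_names = internal_names)
  class(rec) <- "substance_record"
  rec
}

record_is_empty <- function(rec) {
  flds <- c(rec$label, rec$cas_number, rec$ec_number, rec$iupac_name,
            rec$smiles, rec$internal_names)
  all(!nzchar(flds %||% character()))
}

#' All substance URIs in a store
#' @param store a `ks_store`.
#' @return sorted character vector of substance resource identifiers.
#' @export
substance_uris <- function(store) {
  t <- store$triples
  sort(unique(t$s[t$p == RDF_TYPE & t$o == ks_term(store, "Substance")]))
}

#' Add a substance to the store
#'
#' Writes one triple per non-empty identifier field plus the
#' `rdf:type ks:Substance` assertion.
#'
#' @param store a `ks_store`.
#' @param record a [substance_record()].
#' @return the substance URI, invisibly returned attached to the store call;
#'   the function returns the URI (character scalar).
#' @export
add_substance <- function(store, record) {
  stopifnot(inherits(record, "substance_record"))
  if (record_is_empty(record)) {
    stop_knowsub("substance record has no identifier and no label",
                 "knowsub_validation_error")
  }
  uri <- record$uri %||% ks_term(store, slugify(record$label %||%
    record$cas_number %||% record$ec_number %||% record$iupac_name))
  if (uri %in% substance_uris(store)) {
    stop_knowsub(sprintf("substance <%s> already present", uri),
                 "knowsub_conflict_error")
  }
  add_triple(store, uri, RDF_TYPE, ks_term(store, "Substance"))
  lit <- function(pred, val) {
    for (v in val) {
      if (!is.null(v) && nzchar(v)) {
        add_triple(store, uri, ks_term(store, pred), v, "literal")
      }
    }
  }
  lit("hasLabel", record$label)
  lit("hasCAS", record$cas_number)
  lit("hasEC", record$ec_number)
  lit("hasIUPAC", record$iupac_name)
  lit("hasSMILES", record$smiles)
  lit("hasInternalName", record$internal_names)
  uri
}

#' Declare a chemical-property term
#'
#' @param store a `ks_store`.
#' @param label the property label, unique per store (e.g. "persistent").
#' @return the term URI.
#' @export
add_property_term <- function(store, label) {
  existing <- property_term_uri(store, label)
  if (!is.na(existing)) return(existing)
  uri <- ks_term(store, slugify(label))
  add_triple(store, uri, RDF_TYPE, ks_term(store, "ChemProperty"))
  add_triple(store, uri, ks_term(store, "hasLabel"), label, "literal")
  uri
}

property_term_uri <- function(store, label) {
  t <- store$triples
  terms <- t$s[t$p == RDF_TYPE & t$o == ks_term(store, "ChemProperty")]
  lab <- t$s[t$p == ks_term(store, "hasLabel") & t$o == label &
             t$s %in% terms]
  if (length(lab)) lab[[1]] else NA_character_
}

#' Assert a chemical property for a substance
#'
#' Connects a substance to a `ks:ChemProperty` instance via
#' `ks:hasChemProperty`. Idempotent.
#'
#' @param store a `ks_store`.
#' @param substance_uri substance resource identifier.
#' @param property_label label of an existing property term.
#' @return the store, invisibly.
#' @export
assert_property <- function(store, substance_uri, property_label) {
  if (!substance_uri %in% substance_uris(store)) {
    stop_knowsub(sprintf("unknown substance <%s>", substance_uri),
                 "knowsub_not_found_error")
  }
  term <- property_term_uri(store, property_label)
  if (is.na(term)) {
    stop_knowsub(sprintf("unknown chemical property '%s'", property_label),
                 "knowsub_not_found_error")
  }
  add_triple(store, substance_uri, ks_term(store, "hasChemProperty"), term)
}

#' Define a class of substances by required property values
#'
#' A class is an intersection of required (property, value) pairs — a
#' substance is a member iff every pair is asserted for it. An empty
#' requirement set makes every substance a member.
#'
#' @param name class name.
#' @param chem_properties labels of required chemical-property terms
#'   (shorthand for `(ks:hasChemProperty, term)` pairs).
#' @param requires optional tibble with columns `p` (predicate IRI or
#'   ks-local name) and `o` (object IRI/literal) for arbitrary pairs.
#' @return a `class_definition` object.
#' @export
class_definition <- function(name, chem_properties = character(),
                             requires = NULL) {
  structure(list(name = name, chem_properties = chem_properties,
                 requires = requires),
            class = "class_definition")
}

#' The PBT class: persistent, bioaccumulative and toxic
#' @return a [class_definition()].
#' @export
pbt_class_definition <- function() {
  class_definition("PBTSubstance",
                   chem_properties = c("persistent", "bioaccumulative", "toxic"))
}

classdef_pairs <- function(store, classdef) {
  pairs <- tibble(p = character(), o = character())
  for (lab in classdef$chem_properties) {
    term <- property_term_uri(store, lab)
    if (is.na(term)) {
      stop_knowsub(sprintf("class requires unknown property '%s'", lab),
                   "knowsub_not_found_error")
    }
    pairs <- bind_rows(pairs, tibble(p = ks_term(store, "hasChemProperty"),
                                     o = term))
  }
  if (!is.null(classdef$requires)) pairs <- bind_rows(pairs, classdef$requires)
  pairs
}

#' Compute the members of a substance class
#'
#' Scans the graph: exactly the substances for which every required
#' (property, value) pair is asserted. Equals the result of the equivalent
#' SPARQL query (see [classdef_sparql()]).
#'
#' @param store a `ks_store`.
#' @param classdef a [class_definition()].
#' @return sorted character vector of substance URIs.
#' @export
members_of <- function(store, classdef) {
  subs <- substance_uris(store)
  pairs <- classdef_pairs(store, classdef)
  if (nrow(pairs) == 0) return(subs)
  t <- store$triples
  ok <- map_lgl(subs, function(s) {
    all(map_lgl(seq_len(nrow(pairs)), function(i) {
      any(t$s == s & t$p == pairs$p[[i]] & t$o == pairs$o[[i]])
    }))
  })
  sort(subs[ok])
}

#' Mechanically generate the SPARQL query equivalent to a class definition
#'
#' @param store a `ks_store` (for namespace resolution).
#' @param classdef a [class_definition()].
#' @param complement if `TRUE` generate the NOT-EXISTS complement query
#'   (substances that are *not* members).
#' @return SPARQL SELECT text returning `?s`.
#' @export
classdef_sparql <- function(store, classdef, complement = FALSE) {
  pairs <- classdef_pairs(store, classdef)
  pat <- paste(sprintf("  ?s <%s> <%s> .", pairs$p, pairs$o), collapse = "\n")
  if (!complement) {
    sprintf("PREFIX ks: <%s>\nSELECT ?s WHERE {\n  ?s a ks:Substance .\n%s\n}",
            store$ns, pat)
  } else {
    sprintf(paste0("PREFIX ks: <%s>\nSELECT ?s WHERE {\n",
                   "  ?s a ks:Substance .\n  FILTER NOT EXISTS {\n%s\n  }\n}"),
            store$ns, pat)
  }
}

#' Fetch a substance's identifier set from the graph
#'
#' @param store a `ks_store`.
#' @param uri substance URI.
#' @return a one-row tibble with list-columns for multi-valued fields.
#' @export
substance_identifiers <- function(store, uri) {
  t <- store$triples
  get <- function(pred) sort(t$o[t$s == uri & t$p == ks_term(store, pred)])
  tibble(
    uri = uri,
    label = list(get("hasLabel")),
    cas = list(get("hasCAS")),
    ec = list(get("hasEC")),
    iupac = list(get("hasIUPAC")),
    smiles = list(get("hasSMILES")),
    internal_names = list(get("hasInternalName"))
  )
}

#' Tidy a store into its triple table
#'
#' @param x a `ks_store`.
#' @param ... unused.
#' @return a tibble of triples (`s`, `p`, `o`, `o_kind`), deterministically
#'   ordered.
#' @export
tidy.ks_store <- function(x, ...) {
  as_tibble(order_table(x$triples))
}

#' One-row summary of a store
#' @param x a `ks_store`.
#' @param ... unused.
#' @return a one-row tibble with triple, substance and memo counts.
#' @export
glance.ks_store <- function(x, ...) {
  t <- x$triples
  tibble(
    n_triples = nrow(t),
    n_substances = length(substance_uris(x)),
    n_property_assertions = sum(t$p == ks_term(x, "hasChemProperty")),
    n_memos = length(unique(t$s[t$p == RDF_TYPE &
                                t$o == ks_term(x, "Memo")]))
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
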