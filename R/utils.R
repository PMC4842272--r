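#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map_chr map_lgl map_int keep discard
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# Well-known vocabulary IRIs. The substance vocabulary lives under a single
# configurable prefix (default "ks:"); everything the engine mints goes there.
KS_DEFAULT_NS <- "http://example.org/knowsub/ks#"
RDF_TYPE <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"
RDF_NS <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
RDFS_NS <- "http://www.w3.org/2000/01/rdf-schema#"
OWL_NS <- "http://www.w3.org/2002/07/owl#"

ks_term <- function(store, local) paste0(store$ns, local)

#' Turn a label into a URI-safe slug
#'
#' Used to mint substance URIs from labels when no URI is given.
#'
#' @param x character vector of labels.
#' @return character vector of slugs.
#' @keywords internal
slugify <- function(x) {
  x <- gsub("[^A-Za-z0-9]+", "_", x)
  x <- gsub("^_+|_+$", "", x)
  ifelse(nzchar(x), x, "substance")
}

stop_knowsub <- function(msg, class) {
  abort(msg, class = c(class, "knowsub_error"))
}

# Deterministic row ordering: lexicographic over all columns, NA last.
order_table <- function(df) {
  if (nrow(df) == 0 || ncol(df) == 0) return(df)
  ord <- do.call(order, c(unname(as.list(df)), list(method = "radix")))
  df[ord, , drop = FALSE]
}

`%theni%` <- function(a, b) if (is.null(a) || length(a) == 0 || all(is.na(a))) b else a
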