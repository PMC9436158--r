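#' Ontology categories treated as non-disease
#'
#' Traits whose categories all fall in this set are flagged as not
#' disease-related (they stay in the network but are excluded from
#' disease-centric summaries).
#'
#' @return Character vector of EFO parent-category names.
#' @export
non_disease_categories <- function() {
  c("other measurement", "biological process", "body measurement",
    "lipid or lipoprotein measurement", "response to drug",
    "hematological measurement")
}

#' Map traits to ontology parent categories
#'
#' One entry per distinct trait label. A trait mapped to several EFO terms
#' carries the union of all their parent categories (a trait is assigned to
#' each possible term). URIs absent from the category map get the category
#' `"uncategorized"`. `disease_related` is FALSE only when every category of
#' the trait is in `non_disease` — categories drive the flag, never node
#' removal.
#'
#' @param records Association records data.frame
#'   (from [parse_association_table()]).
#' @param category_map data.frame with columns `uri` and `category`
#'   (multiple rows per URI allowed).
#' @param non_disease Character vector of categories counted as non-disease.
#' @return data.frame with columns `trait_label`, `efo_uris` (list),
#'   `categories` (list), `disease_related`, plus attribute
#'   `"uncovered_uris"` listing URIs missing from the map.
#' @export
map_trait_categories <- function(records, category_map,
                                 non_disease = non_disease_categories()) {
  stopifnot(all(c("uri", "category") %in% names(category_map)))
  labels <- unique(records$trait_label)
  uri_by_trait <- lapply(labels, function(tr) {
    sort(unique(unlist(records$efo_uris[records$trait_label == tr])))
  })
  cat_lookup <- split(category_map$category, category_map$uri)
  uncovered <- character(0)
  cats <- lapply(uri_by_trait, function(uris) {
    hit <- cat_lookup[uris]
    miss <- uris[vapply(hit, is.null, TRUE)]
    if (length(miss)) uncovered <<- union(uncovered, miss)
    found <- sort(unique(unlist(hit)))
    if (length(miss)) found <- sort(unique(c(found, "uncategorized")))
    if (!length(found)) found <- "uncategorized"
    found
  })
  if (length(uncovered)) {
    message(length(uncovered), " EFO URI(s) not covered by the category map")
  }
  out <- data.frame(trait_label = labels, stringsAsFactors = FALSE)
  out$efo_uris <- I(uri_by_trait)
  out$categories <- I(cats)
  out$disease_related <- vapply(cats, function(cc) !all(cc %in% non_disease), TRUE)
  attr(out, "uncovered_uris") <- uncovered
  out
}

#' Remove measurement-style and explicitly excluded traits
#'
#' Applies case-insensitive regular-expression patterns and an explicit
#' exclusion list to trait *labels* (never to categories). The defaults
#' remove traits whose label contains the word "measurement" or starts with
#' "response to", plus the explicit terms "age at onset" and
#' "age at diagnosis".
#'
#' @param traits Trait table from [map_trait_categories()] (any data.frame
#'   with a `trait_label` column works).
#' @param keyword_patterns Character vector of regular expressions.
#' @param explicit_exclusions Character vector of labels removed by exact
#'   (case-insensitive) match.
#' @return A list with `retained` (subset of `traits`) and `removed`
#'   (data.frame `trait_label`, `rule`).
#' @export
filter_traits <- function(traits,
                          keyword_patterns = c("\\bmeasurement\\b",
                                               "^response to\\b"),
                          explicit_exclusions = c("age at onset",
                                                  "age at diagnosis")) {
  for (pat in keyword_patterns) {
    ok <- tryCatch({ grepl(pat, "x"); TRUE }, error = function(e) FALSE,
                   warning = function(w) FALSE)
    if (!ok) stop("invalid keyword pattern: ", pat)
  }
  labels <- traits$trait_label
  rule <- rep(NA_character_, length(labels))
  for (pat in keyword_patterns) {
    hit <- is.na(rule) & grepl(pat, labels, ignore.case = TRUE, perl = TRUE)
    rule[hit] <- paste0("keyword:", pat)
  }
  excl <- tolower(labels) %in% tolower(explicit_exclusions)
  rule[is.na(rule) & excl] <- "explicit"
  removed_idx <- which(!is.na(rule))
  list(
    retained = traits[setdiff(seq_along(labels), removed_idx), , drop = FALSE],
    removed = data.frame(trait_label = labels[removed_idx],
                         rule = rule[removed_idx],
                         stringsAsFactors = FALSE)
  )
}
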