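#' Read a drug map TSV
#'
#' Dialect: `mesh_drug_id<TAB>ingredient_id<TAB>atc5_code`, `#` comment
#' lines allowed, no header. One ingredient may carry several ATC5 codes
#' (e.g. topical vs systemic formulations of the same moiety); the ATC4
#' class is the first five characters of the ATC5 code.
#'
#' @param path file path.
#' @return data.frame with columns `mesh_drug_id`, `ingredient_id`,
#'   `atc5_code`, `atc4_class`.
#' @export
read_drug_map <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  if (any(lengths(fields) < 3))
    stop("malformed drug map row: expected 3 tab-separated fields")
  drug_map(data.frame(mesh_drug_id = vapply(fields, `[`, "", 1L),
                      ingredient_id = vapply(fields, `[`, "", 2L),
                      atc5_code = vapply(fields, `[`, "", 3L),
                      stringsAsFactors = FALSE))
}

#' Construct a drug map
#'
#' @param rows data.frame with columns `mesh_drug_id`, `ingredient_id`,
#'   `atc5_code`.
#' @return the validated data.frame with derived `atc4_class` column.
#' @export
drug_map <- function(rows) {
  need <- c("mesh_drug_id", "ingredient_id", "atc5_code")
  stopifnot(is.data.frame(rows), all(need %in% names(rows)))
  rows <- unique(rows[need])
  rows$atc4_class <- substr(rows$atc5_code, 1L, 5L)
  rownames(rows) <- NULL
  rows
}

#' Write a drug map to its TSV dialect
#' @param map a drug map data.frame.
#' @param path output file path.
#' @export
write_drug_map <- function(map, path) {
  writeLines(c("# mesh_drug_id\tingredient_id\tatc5_code",
               paste(map$mesh_drug_id, map$ingredient_id, map$atc5_code, sep = "\t")),
             path, useBytes = TRUE)
  invisible(path)
}

#' ATC4 classes of an ingredient
#'
#' The distinct 5-character ATC4 prefixes of all the ingredient's ATC5
#' codes (e.g. ofloxacin J01MA01 + S01AE01 -> J01MA, S01AE).
#'
#' @param ingredient_id an ingredient present in the map.
#' @param map a drug map data.frame.
#' @return character vector of ATC4 class codes.
#' @export
drug_to_classes <- function(ingredient_id, map) {
  rows <- map[map$ingredient_id == ingredient_id, , drop = FALSE]
  if (!nrow(rows)) stop("unknown ingredient: ", ingredient_id)
  unique(rows$atc4_class)
}

#' Member ingredients of an ATC4 class
#'
#' @param atc4_class a 5-character ATC4 code.
#' @param map a drug map data.frame.
#' @return character vector of ingredient ids.
#' @export
class_members <- function(atc4_class, map) {
  unique(map$ingredient_id[map$atc4_class == atc4_class])
}

#' Extract candidate drug-adverse-event pairs
#'
#' Within each article, forms the cross product of the descriptors
#' qualified as a drug involved in an adverse event (e.g.
#' *ofloxacin/adverse effects*) and the descriptors qualified as an
#' adverse-event manifestation (e.g. *tendinopathy/chemically induced*).
#' Qualifier strings are matched case-insensitively against alias lists.
#' When a drug map is supplied, drugs are restricted to mapped MeSH drug
#' ids and reported as ingredients.
#'
#' @param corpus an [annotation_corpus] carrying qualifiers.
#' @param map optional drug map data.frame.
#' @param drug_qualifiers,event_qualifiers accepted qualifier aliases.
#' @return data.frame of unique (`drug`, `event`, `article_id`) triples.
#' @export
extract_candidate_pairs <- function(corpus, map = NULL,
                                    drug_qualifiers = c("adverse effects", "AE"),
                                    event_qualifiers = c("chemically induced", "CI")) {
  stopifnot(inherits(corpus, "annotation_corpus"))
  rec <- corpus$records
  ql <- tolower(trimws(rec$qualifier))
  drugs <- rec[ql %in% tolower(drug_qualifiers), c("article_id", "descriptor_id")]
  events <- rec[ql %in% tolower(event_qualifiers), c("article_id", "descriptor_id")]
  names(drugs)[2] <- "drug"
  names(events)[2] <- "event"
  if (!is.null(map)) {
    drugs <- merge(drugs, unique(map[c("mesh_drug_id", "ingredient_id")]),
                   by.x = "drug", by.y = "mesh_drug_id")
    drugs <- data.frame(article_id = drugs$article_id, drug = drugs$ingredient_id,
                        stringsAsFactors = FALSE)
  }
  if (!nrow(drugs) || !nrow(events))
    return(data.frame(drug = character(), event = character(),
                      article_id = character(), stringsAsFactors = FALSE))
  out <- merge(unique(drugs), unique(events), by = "article_id")
  out <- unique(out[c("drug", "event", "article_id")])
  out <- out[order(out$drug, out$event, out$article_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write candidate pairs to TSV
#' @param pairs a candidate-pair data.frame.
#' @param path output file path.
#' @export
write_candidate_pairs <- function(pairs, path) {
  writeLines(c("# drug\tevent\tarticle_id",
               paste(pairs$drug, pairs$event, pairs$article_id, sep = "\t")),
             path, useBytes = TRUE)
  invisible(path)
}

#' Build the set of interest for a drug or drug class
#'
#' The set of interest S holds every article linking the subject to a
#' qualified adverse event: for a single drug, the articles of its
#' candidate pairs; for an ATC4 class, the union over member ingredients.
#' Event counts m are the number of distinct articles in S annotated with
#' each representative term after rewriting the qualified event
#' annotations of those articles onto the abstraction level. All qualified
#' events on the subject's articles contribute to the profile, not only
#' the event of the extracted pair, since enrichment is computed over the
#' annotation profile of the article set.
#'
#' @param subject an ingredient id (or drug descriptor id when no map was
#'   used), or an ATC4 class code with `subject_type = "class"`.
#' @param pairs candidate pairs from [extract_candidate_pairs].
#' @param level an `abstraction_level`.
#' @param map drug map (required for `subject_type = "class"`).
#' @param subject_type `"drug"` or `"class"`.
#' @return An object of class `set_of_interest` with components `subject`,
#'   `subject_type`, `articles`, `s`, `event_counts` (named integer) and
#'   `event_articles` (named list representative -> article ids). A subject
#'   with zero supporting articles yields `s = 0` and empty counts,
#'   signalling "no signal" downstream.
#' @export
build_set_of_interest <- function(subject, pairs, level, map = NULL,
                                  subject_type = c("drug", "class")) {
  subject_type <- match.arg(subject_type)
  stopifnot(inherits(level, "abstraction_level"))
  members <- if (subject_type == "class") {
    if (is.null(map)) stop("a drug map is required for class-level subjects")
    class_members(subject, map)
  } else subject
  articles <- unique(pairs$article_id[pairs$drug %in% members])
  ev <- unique(pairs[pairs$article_id %in% articles, c("article_id", "event")])
  names(ev)[2] <- "descriptor_id"
  mapped <- apply_level(ev, level)
  event_articles <- lapply(split(mapped$article_id, mapped$term), unique)
  structure(list(subject = subject, subject_type = subject_type,
                 articles = articles, s = length(articles),
                 event_counts = vapply(event_articles, length, 0L),
                 event_articles = event_articles),
            class = "set_of_interest")
}

#' @export
print.set_of_interest <- function(x, ...) {
  cat(sprintf("<set_of_interest> %s '%s': s = %d articles, %d representative event terms\n",
              x$subject_type, x$subject, x$s, length(x$event_counts)))
  invisible(x)
}
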