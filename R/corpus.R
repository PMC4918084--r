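#' Construct an annotation corpus
#'
#' An annotation corpus is a deduplicated set of
#' (article, descriptor, qualifier) triples plus the universe of article
#' ids. The universe may be larger than the set of annotated articles
#' (articles with no annotations still count toward the reference size).
#'
#' @param records data.frame with columns `article_id`, `descriptor_id`,
#'   `qualifier` (qualifier may be empty; `NA` is treated as empty).
#' @param article_universe character vector of article ids; defaults to the
#'   articles appearing in `records`. Must contain every article in
#'   `records`.
#' @return An object of class `annotation_corpus`.
#' @export
annotation_corpus <- function(records, article_universe = NULL) {
  stopifnot(is.data.frame(records))
  need <- c("article_id", "descriptor_id")
  if (!all(need %in% names(records)))
    stop("records must have columns article_id, descriptor_id")
  if (is.null(records$qualifier)) records$qualifier <- ""
  records$article_id <- as.character(records$article_id)
  records$descriptor_id <- as.character(records$descriptor_id)
  records$qualifier <- as.character(records$qualifier)
  records$qualifier[is.na(records$qualifier)] <- ""
  records <- unique(records[c("article_id", "descriptor_id", "qualifier")])
  rownames(records) <- NULL
  if (is.null(article_universe)) {
    article_universe <- unique(records$article_id)
  } else {
    article_universe <- unique(as.character(article_universe))
    if (!all(records$article_id %in% article_universe))
      stop("article_universe must contain every article in records")
  }
  structure(list(records = records, article_universe = article_universe),
            class = "annotation_corpus")
}

#' @export
print.annotation_corpus <- function(x, ...) {
  cat(sprintf("<annotation_corpus> %d triples, %d annotated articles, universe %d\n",
              nrow(x$records), length(unique(x$records$article_id)),
              length(x$article_universe)))
  invisible(x)
}

#' Read an annotation corpus TSV
#'
#' Dialect: `article_id<TAB>descriptor_id<TAB>qualifier` (qualifier may be
#' empty), `#` comment lines allowed, no header row.
#'
#' @param path file path.
#' @param article_universe optional explicit universe (see
#'   [annotation_corpus]).
#' @return An `annotation_corpus`.
#' @export
read_annotations <- function(path, article_universe = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2))
    stop(sprintf("malformed annotation row at line %d", lineno[which(nf < 2)[1]]))
  records <- data.frame(
    article_id = vapply(fields, `[`, "", 1L),
    descriptor_id = vapply(fields, `[`, "", 2L),
    qualifier = vapply(fields, function(f) if (length(f) >= 3) f[3] else "", ""),
    stringsAsFactors = FALSE)
  annotation_corpus(records, article_universe)
}

#' Write an annotation corpus to its TSV dialect
#'
#' @param corpus an `annotation_corpus`.
#' @param path output file path.
#' @export
write_annotations <- function(corpus, path) {
  stopifnot(inherits(corpus, "annotation_corpus"))
  r <- corpus$records
  lines <- c("# article_id\tdescriptor_id\tqualifier",
             paste(r$article_id, r$descriptor_id, r$qualifier, sep = "\t"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
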