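STATS_FORMAT_VERSION <- 1L

#' Ancestor-propagated article sets
#'
#' For every term t, the aggregated article set a(t) is the union of the
#' articles directly annotated with t and the articles annotated with any
#' descendant of t along tree-number prefixes. Qualifiers are ignored:
#' reference frequencies are computed over all indexing, not qualified
#' subsets. Descriptors present in the corpus but absent from the
#' terminology are retained as leaf orphans (zero ancestors) with a
#' warning.
#'
#' @param corpus an [annotation_corpus].
#' @param term a [terminology].
#' @return named list term -> character vector of article ids.
#' @export
aggregate_article_sets <- function(corpus, term) {
  stopifnot(inherits(corpus, "annotation_corpus"), inherits(term, "terminology"))
  rec <- unique(corpus$records[c("article_id", "descriptor_id")])
  if (!nrow(rec)) return(stats::setNames(list(), character()))
  terms <- unique(rec$descriptor_id)
  orphan <- setdiff(terms, names(term$tree_numbers))
  if (length(orphan))
    warning(sprintf("%d annotated descriptor(s) absent from terminology retained as orphans (e.g. %s)",
                    length(orphan), orphan[1]))
  closure <- lapply(terms, function(d) {
    if (d %in% names(term$tree_numbers)) unique(c(d, ancestors(d, term))) else d
  })
  idx <- match(rec$descriptor_id, terms)
  expanded_term <- unlist(closure[idx], use.names = FALSE)
  expanded_art <- rep(rec$article_id, lengths(closure)[idx])
  pairs <- unique(data.frame(article_id = expanded_art, term = expanded_term,
                             stringsAsFactors = FALSE))
  lapply(split(pairs$article_id, pairs$term), unique)
}

#' Build reference statistics from an annotation corpus
#'
#' Computes, over the whole corpus: ancestor-propagated article sets a(t),
#' the reference size n = |article universe|, term probabilities
#' p(t) = |a(t)|/n, information content IC(t) = -log2 p(t) (in bits; terms
#' with empty a(t) carry no IC), and the sparse symmetric co-frequency
#' table of |a(x) intersect a(y)| for every unordered pair of terms that
#' co-occurs at least once.
#'
#' @param corpus an [annotation_corpus].
#' @param term a [terminology].
#' @return An object of class `reference_stats` with components `articles`
#'   (named list of aggregated article sets), `n`, `counts`, `p`, `ic`
#'   (named numeric vectors), and `cofreq` (data.frame `term1`, `term2`,
#'   `count` with `term1 < term2`).
#' @export
build_reference_stats <- function(corpus, term) {
  stopifnot(inherits(corpus, "annotation_corpus"))
  n <- length(corpus$article_universe)
  if (n == 0L) stop("empty article universe: reference size must be positive")
  articles <- aggregate_article_sets(corpus, term)
  counts <- vapply(articles, length, 0L)
  p <- counts / n
  ic <- -log2(p)
  cofreq <- cofrequency_table(articles)
  new_reference_stats(n, counts, ic, cofreq, articles)
}

new_reference_stats <- function(n, counts, ic, cofreq, articles = NULL) {
  key <- if (nrow(cofreq)) paste(cofreq$term1, cofreq$term2, sep = "\r") else character()
  structure(list(n = as.integer(n), counts = counts, p = counts / n, ic = ic,
                 cofreq = cofreq,
                 cofreq_index = stats::setNames(cofreq$count, key),
                 articles = articles),
            class = "reference_stats")
}

#' @export
print.reference_stats <- function(x, ...) {
  cat(sprintf("<reference_stats> n = %d articles, %d terms, %d stored co-frequency pairs\n",
              x$n, length(x$counts), nrow(x$cofreq)))
  invisible(x)
}

#' Pairwise term co-frequency table
#'
#' |a(x) intersect a(y)| for every unordered pair with a nonempty
#' intersection; pairs that never co-occur are not stored. Computed as the
#' cross-product of a sparse article-by-term incidence matrix.
#'
#' @param articles named list term -> article-id set (e.g. from
#'   [aggregate_article_sets]).
#' @return data.frame with columns `term1`, `term2`, `count`
#'   (`term1 < term2` lexicographically).
#' @export
cofrequency_table <- function(articles) {
  empty <- data.frame(term1 = character(), term2 = character(),
                      count = integer(), stringsAsFactors = FALSE)
  if (!length(articles)) return(empty)
  terms <- sort(names(articles))
  art <- unique(unlist(articles, use.names = FALSE))
  i <- match(unlist(articles[terms], use.names = FALSE), art)
  j <- rep(seq_along(terms), lengths(articles[terms]))
  m <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                            dims = c(length(art), length(terms)))
  cc <- methods::as(Matrix::triu(Matrix::crossprod(m), k = 1L), "TsparseMatrix")
  if (!length(cc@x)) return(empty)
  out <- data.frame(term1 = terms[cc@i + 1L], term2 = terms[cc@j + 1L],
                    count = as.integer(cc@x), stringsAsFactors = FALSE)
  out <- out[order(out$term1, out$term2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Look up a reference co-frequency
#'
#' Returns the stored co-count for an unordered pair, the aggregated count
#' for `x == y`, and 0 for pairs that never co-occur.
#'
#' @param stats a `reference_stats` object.
#' @param x,y term ids.
#' @return integer count.
#' @export
cofreq_count <- function(stats, x, y) {
  stopifnot(inherits(stats, "reference_stats"))
  if (x == y) {
    cnt <- stats$counts[x]
    return(if (is.na(cnt)) 0L else as.integer(cnt))
  }
  key <- paste(min(x, y), max(x, y), sep = "\r")
  out <- stats$cofreq_index[key]
  if (is.na(out)) 0L else as.integer(out)
}

#' Information content of terms
#'
#' IC(t) = -log2(|a(t)|/n) in bits, for terms with at least one aggregated
#' article.
#'
#' @param stats a `reference_stats` object.
#' @return named numeric vector of IC values.
#' @export
information_content <- function(stats) {
  stopifnot(inherits(stats, "reference_stats"))
  if (stats$n == 0L) stop("reference size is zero")
  stats$ic[stats$counts > 0L]
}

#' Persist reference statistics to a directory
#'
#' Writes `term_counts.tsv` (term, count, ic), `pair_counts.tsv`
#' (term1, term2, count) and `meta.json` (reference size n, format
#' version). Aggregated article sets are not persisted; the directory holds
#' exactly what signal detection needs, mirroring build-once /
#' analyze-many precomputation.
#'
#' @param stats a `reference_stats` object.
#' @param dir output directory (created if needed).
#' @export
write_reference_stats <- function(stats, dir) {
  stopifnot(inherits(stats, "reference_stats"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  terms <- sort(names(stats$counts))
  writeLines(c("# term\tcount\tic",
               sprintf("%s\t%d\t%.17g", terms, stats$counts[terms], stats$ic[terms])),
             file.path(dir, "term_counts.tsv"), useBytes = TRUE)
  cf <- stats$cofreq
  writeLines(c("# term1\tterm2\tcount",
               if (nrow(cf)) paste(cf$term1, cf$term2, cf$count, sep = "\t")),
             file.path(dir, "pair_counts.tsv"), useBytes = TRUE)
  jsonlite::write_json(
    list(format_version = STATS_FORMAT_VERSION, n = stats$n,
         n_terms = length(stats$counts), n_pairs = nrow(cf)),
    file.path(dir, "meta.json"), auto_unbox = TRUE)
  message(sprintf("reference stats: n = %d articles, %d terms, %d stored pairs -> %s",
                  stats$n, length(stats$counts), nrow(cf), dir))
  invisible(dir)
}

#' Load reference statistics from a directory
#'
#' @param dir a directory written by [write_reference_stats].
#' @return A `reference_stats` object (without aggregated article sets).
#' @export
read_reference_stats <- function(dir) {
  meta_path <- file.path(dir, "meta.json")
  if (!file.exists(meta_path)) stop("not a stats directory (no meta.json): ", dir)
  meta <- jsonlite::fromJSON(meta_path)
  if (is.null(meta$format_version) || meta$format_version != STATS_FORMAT_VERSION)
    stop("stale or incompatible stats cache (format_version mismatch); rebuild with build_reference_stats()")
  tc <- utils::read.delim(file.path(dir, "term_counts.tsv"), header = FALSE,
                          comment.char = "#", stringsAsFactors = FALSE,
                          col.names = c("term", "count", "ic"))
  pc_path <- file.path(dir, "pair_counts.tsv")
  pc_lines <- readLines(pc_path, warn = FALSE)
  pc_lines <- pc_lines[!grepl("^\\s*(#|$)", pc_lines)]
  if (length(pc_lines)) {
    f <- strsplit(pc_lines, "\t", fixed = TRUE)
    cofreq <- data.frame(term1 = vapply(f, `[`, "", 1L),
                         term2 = vapply(f, `[`, "", 2L),
                         count = as.integer(vapply(f, `[`, "", 3L)),
                         stringsAsFactors = FALSE)
  } else {
    cofreq <- data.frame(term1 = character(), term2 = character(),
                         count = integer(), stringsAsFactors = FALSE)
  }
  counts <- stats::setNames(as.integer(tc$count), tc$term)
  ic <- stats::setNames(as.numeric(tc$ic), tc$term)
  new_reference_stats(meta$n, counts, ic, cofreq)
}
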