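#' Construct a terminology from descriptor records
#'
#' A terminology is a multi-rooted DAG of descriptors in the style of MeSH:
#' every descriptor carries zero or more dot-delimited *tree numbers*
#' (e.g. `"C05.651.869"`), and the hierarchy is defined entirely by
#' tree-number prefixes, not by explicit parent links. A descriptor may hold
#' several tree numbers (multi-classification); supplementary-concept
#' records such as drugs may hold none, in which case they participate as
#' annotation subjects but never as aggregatable event terms.
#'
#' @param descriptor_id character vector of unique descriptor keys.
#' @param name display names, recycled/defaulted to `descriptor_id`.
#' @param tree_numbers list of character vectors (one per descriptor), or a
#'   character vector of `;`-separated tree numbers. Empty strings mean no
#'   tree number.
#' @return An object of class `terminology` with components `descriptors`
#'   (data.frame of `descriptor_id`, `name`), `tree_numbers` (named list),
#'   and `tree_index` (named character vector mapping each tree number to
#'   the single descriptor that owns it).
#' @export
terminology <- function(descriptor_id, name = descriptor_id, tree_numbers = NULL) {
  descriptor_id <- as.character(descriptor_id)
  if (anyDuplicated(descriptor_id))
    stop("duplicate descriptor_id; merge rows before constructing")
  if (is.null(tree_numbers))
    tree_numbers <- vector("list", length(descriptor_id))
  if (is.character(tree_numbers))
    tree_numbers <- strsplit(tree_numbers, ";", fixed = TRUE)
  stopifnot(length(tree_numbers) == length(descriptor_id))
  tree_numbers <- lapply(tree_numbers, function(x) {
    x <- trimws(as.character(x))
    unique(x[nzchar(x)])
  })
  names(tree_numbers) <- descriptor_id
  bad <- unlist(lapply(tree_numbers, function(x) x[grepl("(^\\.)|(\\.\\.)|(\\.$)", x)]))
  if (length(bad))
    stop("malformed tree number(s): ", paste(bad, collapse = ", "))
  tn_all <- unlist(tree_numbers, use.names = FALSE)
  owner <- rep(descriptor_id, lengths(tree_numbers))
  if (anyDuplicated(tn_all)) {
    dup <- unique(tn_all[duplicated(tn_all)])
    stop("tree number(s) assigned to more than one descriptor: ",
         paste(dup, collapse = ", "))
  }
  tree_index <- stats::setNames(owner, tn_all)
  structure(
    list(descriptors = data.frame(descriptor_id = descriptor_id,
                                  name = as.character(name),
                                  stringsAsFactors = FALSE),
         tree_numbers = tree_numbers,
         tree_index = tree_index),
    class = "terminology")
}

#' @export
print.terminology <- function(x, ...) {
  cat(sprintf("<terminology> %d descriptors, %d tree numbers\n",
              nrow(x$descriptors), length(x$tree_index)))
  invisible(x)
}

#' Read a terminology file
#'
#' TSV dialect: three tab-separated columns
#' `descriptor_id<TAB>name<TAB>tree_numbers`, tree numbers `;`-separated
#' (the third column may be empty for descriptors without tree numbers,
#' e.g. supplementary-concept drug records), UTF-8, `#` comment lines
#' allowed. JSON dialect: an array of objects with the same keys
#' (`tree_numbers` as an array of strings). Duplicate rows for the same
#' descriptor are merged by union of their tree numbers; extra columns are
#' ignored.
#'
#' @param path file path.
#' @param format `"tsv"` or `"json"`.
#' @return A [terminology] object.
#' @export
read_terminology <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "json") {
    recs <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
    id <- vapply(recs, function(r) as.character(r$descriptor_id), "")
    nm <- vapply(recs, function(r) as.character(r$name %||% r$descriptor_id), "")
    tns <- lapply(recs, function(r) as.character(r$tree_numbers))
  } else {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    keep <- !grepl("^\\s*(#|$)", lines)
    lineno <- which(keep)
    fields <- strsplit(lines[keep], "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 2))
      stop(sprintf("malformed terminology row at line %d: expected at least 2 tab-separated fields",
                   lineno[which(nf < 2)[1]]))
    id <- vapply(fields, `[`, "", 1L)
    nm <- vapply(fields, `[`, "", 2L)
    tns <- strsplit(vapply(fields, function(f) if (length(f) >= 3) f[3] else "", ""),
                    ";", fixed = TRUE)
  }
  # merge duplicate descriptor rows by union of tree numbers
  if (anyDuplicated(id)) {
    merged <- split(seq_along(id), id)[unique(id)]
    tns <- lapply(merged, function(i) unique(unlist(tns[i])))
    nm <- nm[vapply(merged, `[`, 1L, 1L)]
    id <- names(merged)
  }
  terminology(id, nm, tns)
}

#' Write a terminology to its TSV dialect
#'
#' @param x a [terminology] object.
#' @param path output file path.
#' @export
write_terminology <- function(x, path) {
  stopifnot(inherits(x, "terminology"))
  tn <- vapply(x$tree_numbers[x$descriptors$descriptor_id],
               paste, "", collapse = ";")
  lines <- c("# descriptor_id\tname\ttree_numbers",
             paste(x$descriptors$descriptor_id, x$descriptors$name, tn, sep = "\t"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Hierarchy level of a tree number
#'
#' The level is the 1-based count of dot-separated segments: `"C05"` is a
#' 1st-level tree number, `"C05.651"` 2nd level.
#'
#' @param tree_number character vector of path strings.
#' @return integer vector of levels.
#' @export
tree_level <- function(tree_number) {
  tree_number <- as.character(tree_number)
  if (any(!nzchar(tree_number) | is.na(tree_number)))
    stop("empty tree number")
  if (any(grepl("(^\\.)|(\\.\\.)|(\\.$)", tree_number)))
    stop("malformed tree number")
  lengths(strsplit(tree_number, ".", fixed = TRUE))
}

tn_prefixes <- function(tn) {
  segs <- strsplit(tn, ".", fixed = TRUE)[[1]]
  k <- length(segs)
  if (k < 2) return(character())
  vapply(seq_len(k - 1), function(i) paste(segs[seq_len(i)], collapse = "."), "")
}

#' Ancestors of a descriptor
#'
#' The union, over all tree numbers of the descriptor, of the descriptors
#' found at every proper prefix of the tree number. Prefixes not assigned
#' to any descriptor are skipped. The result contains the descriptor itself
#' only if it also owns one of its own ancestor tree numbers.
#'
#' @param term_id a descriptor id present in `term`.
#' @param term a [terminology] object.
#' @return character vector of ancestor descriptor ids (possibly empty).
#' @export
ancestors <- function(term_id, term) {
  stopifnot(inherits(term, "terminology"))
  if (!term_id %in% names(term$tree_numbers))
    stop("unknown descriptor: ", term_id)
  tns <- term$tree_numbers[[term_id]]
  if (!length(tns)) return(character())
  pref <- unique(unlist(lapply(tns, tn_prefixes)))
  hit <- term$tree_index[pref]
  unique(unname(hit[!is.na(hit)]))
}

#' Descendants of a descriptor
#'
#' All descriptors owning a tree number that extends one of the
#' descriptor's tree numbers by at least one segment.
#'
#' @inheritParams ancestors
#' @return character vector of descendant descriptor ids (possibly empty).
#' @export
descendants <- function(term_id, term) {
  stopifnot(inherits(term, "terminology"))
  if (!term_id %in% names(term$tree_numbers))
    stop("unknown descriptor: ", term_id)
  tns <- term$tree_numbers[[term_id]]
  if (!length(tns)) return(character())
  all_tn <- names(term$tree_index)
  hit <- logical(length(all_tn))
  for (tn in tns)
    hit <- hit | startsWith(all_tn, paste0(tn, "."))
  setdiff(unique(unname(term$tree_index[all_tn[hit]])), term_id)
}
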