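#' Build an information-content abstraction level
#'
#' An abstraction level is a subset of terminology terms (the
#' *representatives*) whose information content lies in the half-open range
#' `[ic_min, ic_max)`, together with a mapping of every term onto its
#' representative set:
#'
#' * a term with IC in range represents itself;
#' * a term with IC >= `ic_max` (too specific) is aggregated, independently
#'   along each of its tree-number paths, into the nearest (deepest)
#'   ancestor whose IC is in range, taking the union across paths;
#' * a term with IC < `ic_min` (too general), or a too-specific term with
#'   no in-range ancestor on any path, is excluded (maps to the empty set).
#'
#' Terms without a defined IC (never annotated in the reference set) are
#' excluded, as are terminology records without tree numbers
#' (supplementary-concept drug records participate as drugs, never as
#' aggregatable events). Annotated terms *absent* from the terminology
#' (orphans) are kept as their own representatives when their IC is in
#' range: they have no ancestors to aggregate into.
#'
#' @param term a [terminology].
#' @param ic named numeric vector of IC values in bits (e.g. from
#'   [information_content]).
#' @param ic_min,ic_max range bounds in bits, `ic_min < ic_max`; the lower
#'   bound is inclusive, the upper exclusive.
#' @return An object of class `abstraction_level` with components
#'   `mapping` (named list term -> character vector of representatives),
#'   `status` (named character: `"self"`, `"aggregated"`, `"excluded"`),
#'   `representatives`, `kind = "ic"`, `ic_min`, `ic_max`.
#' @export
build_abstraction_level <- function(term, ic, ic_min, ic_max) {
  stopifnot(inherits(term, "terminology"), is.numeric(ic))
  if (!is.numeric(ic_min) || !is.numeric(ic_max) || ic_min >= ic_max)
    stop("invalid IC range: ic_min must be < ic_max")
  ids <- union(names(term$tree_numbers), names(ic))
  in_range <- function(v) !is.na(v) & v >= ic_min & v < ic_max
  mapping <- vector("list", length(ids))
  names(mapping) <- ids
  status <- stats::setNames(rep("excluded", length(ids)), ids)
  for (id in ids) {
    v <- if (id %in% names(ic)) ic[[id]] else NA_real_
    in_term <- id %in% names(term$tree_numbers)
    if (is.na(v) || (in_term && !length(term$tree_numbers[[id]]))) {
      # no reference IC, or a tree-number-less (supplementary) record
      mapping[[id]] <- character()
    } else if (in_range(v)) {
      mapping[[id]] <- id
      status[[id]] <- "self"
    } else if (v < ic_min) {
      mapping[[id]] <- character()
    } else {
      # too specific: nearest in-range ancestor per tree-number path
      reps <- character()
      tns <- if (id %in% names(term$tree_numbers)) term$tree_numbers[[id]] else character()
      for (tn in tns) {
        pref <- rev(tn_prefixes(tn))  # deepest first
        anc_ids <- term$tree_index[pref]
        anc_ids <- anc_ids[!is.na(anc_ids)]
        for (aid in anc_ids) {
          av <- if (aid %in% names(ic)) ic[[aid]] else NA_real_
          if (in_range(av)) { reps <- c(reps, aid); break }
        }
      }
      reps <- unique(unname(reps))
      mapping[[id]] <- reps
      if (length(reps)) status[[id]] <- "aggregated"
    }
  }
  new_abstraction_level(mapping, status, kind = "ic",
                        ic_min = ic_min, ic_max = ic_max)
}

new_abstraction_level <- function(mapping, status, kind,
                                  ic_min = NA_real_, ic_max = NA_real_,
                                  tree_level = NA_integer_) {
  reps <- names(status)[status == "self"]
  structure(list(mapping = mapping, status = status,
                 representatives = reps, kind = kind,
                 ic_min = ic_min, ic_max = ic_max, tree_level = tree_level),
            class = "abstraction_level")
}

#' @export
print.abstraction_level <- function(x, ...) {
  cov <- level_coverage(x)
  rng <- if (x$kind == "ic")
    sprintf("IC [%g, %g)", x$ic_min, x$ic_max)
  else
    sprintf("tree level %d", x$tree_level)
  cat(sprintf("<abstraction_level> %s: %d representatives; %d self, %d aggregated, %d excluded\n",
              rng, length(x$representatives), cov$self, cov$aggregated, cov$excluded))
  invisible(x)
}

#' Build a fixed-tree-level mapping
#'
#' The fixed hierarchical-level alternative to IC-based abstraction: each
#' term maps to the descriptors found at the level-`level` prefixes of its
#' tree numbers (itself when a tree number is already at that level). Terms
#' whose tree numbers are all shallower than `level` are excluded.
#'
#' @param term a [terminology].
#' @param level positive integer hierarchy level (1 = top).
#' @return An `abstraction_level` object with `kind = "tree"`.
#' @export
build_tree_level <- function(term, level) {
  stopifnot(inherits(term, "terminology"))
  level <- as.integer(level)
  if (is.na(level) || level < 1L) stop("level must be a positive integer")
  ids <- names(term$tree_numbers)
  mapping <- vector("list", length(ids))
  names(mapping) <- ids
  status <- stats::setNames(rep("excluded", length(ids)), ids)
  for (id in ids) {
    reps <- character()
    for (tn in term$tree_numbers[[id]]) {
      segs <- strsplit(tn, ".", fixed = TRUE)[[1]]
      if (length(segs) < level) next
      pref <- paste(segs[seq_len(level)], collapse = ".")
      rid <- term$tree_index[pref]
      if (!is.na(rid)) reps <- c(reps, unname(rid))
    }
    reps <- unique(reps)
    mapping[[id]] <- reps
    if (length(reps))
      status[[id]] <- if (identical(reps, id)) "self" else "aggregated"
  }
  # a multi-classified term can be both itself and aggregated elsewhere;
  # count it as self when it represents itself on some path
  self_ids <- ids[vapply(ids, function(i) i %in% mapping[[i]], TRUE)]
  status[self_ids] <- "self"
  new_abstraction_level(mapping, status, kind = "tree", tree_level = level)
}

#' Coverage accounting for an abstraction level
#'
#' @param level an `abstraction_level`.
#' @return list with counts `self`, `aggregated`, `excluded`, `total` and
#'   the character vector `excluded_terms`.
#' @export
level_coverage <- function(level) {
  stopifnot(inherits(level, "abstraction_level"))
  s <- level$status
  list(self = sum(s == "self"), aggregated = sum(s == "aggregated"),
       excluded = sum(s == "excluded"), total = length(s),
       excluded_terms = names(s)[s == "excluded"])
}

#' Rewrite annotations onto an abstraction level
#'
#' Replaces each annotated term by its representative set and deduplicates
#' at article level: an article contributes at most once per
#' representative. Terms excluded from the level (or unknown to it) are
#' dropped and counted in the coverage report attached as attribute
#' `"coverage"`.
#'
#' @param annotations data.frame with columns `article_id` and
#'   `descriptor_id` (extra columns ignored).
#' @param level an `abstraction_level` built over the same terminology.
#' @return data.frame with columns `article_id`, `term` (representative),
#'   unique rows; attribute `coverage` lists original term counts by fate.
#' @export
apply_level <- function(annotations, level) {
  stopifnot(is.data.frame(annotations), inherits(level, "abstraction_level"))
  ann <- unique(annotations[c("article_id", "descriptor_id")])
  orig_terms <- unique(ann$descriptor_id)
  reps <- level$mapping[ann$descriptor_id]
  reps[vapply(reps, is.null, TRUE)] <- list(character())
  out <- data.frame(
    article_id = rep(ann$article_id, lengths(reps)),
    term = unlist(reps, use.names = FALSE),
    stringsAsFactors = FALSE)
  out <- unique(out)
  rownames(out) <- NULL
  covered <- orig_terms[vapply(orig_terms, function(t)
    length(level$mapping[[t]] %||% character()) > 0, TRUE)]
  excluded <- setdiff(orig_terms, covered)
  attr(out, "coverage") <- list(n_original = length(orig_terms),
                                n_covered = length(covered),
                                n_excluded = length(excluded),
                                excluded_terms = excluded)
  out
}

#' Map a gold-standard outcome term onto an abstraction level
#'
#' @param outcome a descriptor id.
#' @param level an `abstraction_level`.
#' @return character vector of representative term(s); an outcome whose
#'   tree paths carry several in-range ancestors yields all of them and the
#'   caller must choose.
#' @export
map_outcome_to_level <- function(outcome, level) {
  stopifnot(inherits(level, "abstraction_level"))
  reps <- level$mapping[[outcome]]
  if (is.null(reps) || !length(reps)) {
    rng <- if (level$kind == "ic")
      sprintf("IC range [%g, %g)", level$ic_min, level$ic_max)
    else sprintf("tree level %d", level$tree_level)
    stop(sprintf("outcome term '%s' is excluded at %s; choose another abstraction level",
                 outcome, rng))
  }
  reps
}

#' Export an abstraction level to TSV
#'
#' Dialect: `original_id<TAB>representative_ids(;)<TAB>status`, status one
#' of `self`, `aggregated`, `excluded`.
#'
#' @param level an `abstraction_level`.
#' @param path output file path.
#' @export
write_level <- function(level, path) {
  stopifnot(inherits(level, "abstraction_level"))
  ids <- names(level$status)
  reps <- vapply(level$mapping[ids], paste, "", collapse = ";")
  writeLines(c("# original_id\trepresentative_ids\tstatus",
               paste(ids, reps, level$status[ids], sep = "\t")),
             path, useBytes = TRUE)
  invisible(path)
}
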