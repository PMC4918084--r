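#' Upper-tail hypergeometric enrichment p-value
#'
#' The probability of observing `m` or more articles annotated with a term
#' in a set of interest of size `s`, when `a` of the `n` reference articles
#' carry the term: P(X >= m) for X ~ Hypergeometric(population `n`,
#' successes `a`, draws `s`). The bound is inclusive; `m = 0` yields 1.
#' Computed via the survival function of [stats::phyper] (never by
#' subtracting a CDF from 1, which loses precision at extreme tails).
#'
#' @param m observed count in the set of interest, `0 <= m <= min(a, s)`.
#' @param s set-of-interest size.
#' @param a reference count of the term.
#' @param n reference set size.
#' @return p-value in (0, 1].
#' @export
hypergeom_upper_tail <- function(m, s, a, n) {
  check_count <- function(x, nm) {
    if (length(x) != 1L || is.na(x) || x < 0 || x != floor(x))
      stop(nm, " must be a single non-negative integer")
  }
  check_count(m, "m"); check_count(s, "s"); check_count(a, "a"); check_count(n, "n")
  if (a > n || s > n) stop("a and s must not exceed n")
  if (m > min(a, s)) stop("m must not exceed min(a, s)")
  if (m == 0) return(1)
  stats::phyper(m - 1, a, n - a, s, lower.tail = FALSE)
}

#' Conditional enrichment p-value for a term pair
#'
#' Re-tests term x given another enriched term y: the probability of
#' observing `m_xy` or more set-of-interest articles annotated with both x
#' and y, given that `o` set-of-interest articles carry y, where the
#' reference set supplies the population (`a_y` articles with y, of which
#' `a_xy` also carry x). Structurally the same hypergeometric survival
#' test: X ~ Hypergeometric(population `a_y`, successes `a_xy`, draws
#' `o`). When x rides along with y as often as their reference
#' co-frequency predicts, the joint count is unsurprising and the p-value
#' is large.
#'
#' @param m_xy set-of-interest articles annotated with both x and y.
#' @param o set-of-interest articles annotated with y.
#' @param a_xy reference co-count of (x, y), at least 1.
#' @param a_y reference count of y, positive.
#' @return p-value in (0, 1]; `m_xy = 0` yields 1.
#' @export
conditional_p <- function(m_xy, o, a_xy, a_y) {
  if (length(a_y) != 1L || is.na(a_y) || a_y <= 0) stop("a_y must be positive")
  if (a_xy < 1) stop("a_xy must be at least 1")
  if (m_xy > min(o, a_xy)) stop("m_xy must not exceed min(o, a_xy)")
  hypergeom_upper_tail(m_xy, o, a_xy, a_y)
}

#' Pairwise conditional adjustment of enrichment p-values
#'
#' For each first-stage enriched term x, the adjusted p-value is the
#' maximum of its raw p-value and the conditional p-values against every
#' other enriched term y whose reference co-count with x is at least 1
#' (pairs that never co-occur in the reference are not conditioned on).
#' Including the raw p-value in the maximum guarantees
#' `adjusted_p >= raw_p`. A term with no eligible partner keeps its raw
#' p-value.
#'
#' @param raw_p named numeric vector of raw p-values for the enriched
#'   terms (names are term ids).
#' @param soi the [build_set_of_interest] result the raw p-values were
#'   computed on.
#' @param stats a `reference_stats` object.
#' @return named numeric vector of adjusted p-values.
#' @export
adjusted_pvalues <- function(raw_p, soi, stats) {
  stopifnot(inherits(soi, "set_of_interest"), inherits(stats, "reference_stats"))
  terms <- names(raw_p)
  out <- raw_p
  for (x in terms) {
    ax <- soi$event_articles[[x]]
    for (y in setdiff(terms, x)) {
      a_xy <- cofreq_count(stats, x, y)
      if (a_xy < 1L) next
      o <- soi$event_counts[[y]]
      m_xy <- length(intersect(ax, soi$event_articles[[y]]))
      out[[x]] <- max(out[[x]], conditional_p(m_xy, o, a_xy, stats$counts[[y]]))
    }
  }
  out
}

#' Proportional reporting ratio with 95% confidence interval
#'
#' PRR = (a/(a+b)) / (c/(c+d)) over the 2x2 contingency table where `a`
#' counts articles mentioning the drug with the adverse event, `b` the
#' drug without the event, `c` the event without the drug and `d` neither.
#' If any cell is zero, the usual continuity correction adds 0.5 to all
#' four cells before computing. The 95% CI is the log-scale Wald interval
#' exp(ln PRR +/- 1.96 sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d))) on the
#' (possibly corrected) cells.
#'
#' @param a,b,c,d non-negative cell counts.
#' @return list with `prr`, `ci_low`, `ci_high` and the (possibly
#'   corrected) `cells`.
#' @export
prr <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0)) stop("cell counts must be non-negative")
  if (any(cells == 0)) cells <- cells + 0.5
  a <- cells[["a"]]; b <- cells[["b"]]; c <- cells[["c"]]; d <- cells[["d"]]
  est <- (a / (a + b)) / (c / (c + d))
  se <- sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d))
  list(prr = est,
       ci_low = exp(log(est) - 1.96 * se),
       ci_high = exp(log(est) + 1.96 * se),
       cells = cells)
}

#' Detect drug-adverse-event signals
#'
#' Runs enrichment (`method = "gea"`) or the proportional-reporting-ratio
#' baseline (`method = "prr"`) for one or more subjects over a candidate
#' pair set, at a given abstraction level.
#'
#' GEA: for every representative event term observed in the subject's set
#' of interest, the raw p-value comes from [hypergeom_upper_tail] against
#' the reference counts; terms with raw p below the first-stage
#' eligibility threshold `alpha1` then receive the pairwise conditional
#' adjustment of [adjusted_pvalues]. Results are sorted by adjusted
#' p-value, then term id, and flagged at the thresholds p < 0.1 / 0.05 /
#' 0.005 (strict).
#'
#' PRR: the contingency universe is the full candidate article set;
#' for a drug class, `a`/`b` count articles mentioning any member drug and
#' `c`/`d` articles mentioning any other drug. Results are sorted by
#' descending PRR and flagged at PRR > 1 / 1.5 / 5 (strict).
#'
#' @param pairs candidate pairs from [extract_candidate_pairs].
#' @param stats a `reference_stats` object.
#' @param level an `abstraction_level`.
#' @param subjects character vector of subjects; default all drugs (or all
#'   ATC4 classes of the map for `subject_type = "class"`).
#' @param method `"gea"` or `"prr"`.
#' @param map drug map (required for class subjects).
#' @param subject_type `"drug"` or `"class"`.
#' @param alpha1 first-stage eligibility threshold for the conditional
#'   adjustment (default 0.1, the loosest reporting threshold).
#' @param p_adjust optional multiple-testing correction applied to the
#'   adjusted p-values per subject: `"none"` (default) or `"BH"`.
#' @return data.frame of signal results; for GEA columns `subject`,
#'   `term`, `m`, `s`, `a`, `n`, `raw_p`, `adjusted_p`,
#'   `signal_0.1`, `signal_0.05`, `signal_0.005`; for PRR columns
#'   `subject`, `term`, `a`, `b`, `c`, `d`, `prr`, `ci_low`, `ci_high`,
#'   `signal_1`, `signal_1.5`, `signal_5`. Subjects with an empty set of
#'   interest contribute no rows ("no signal").
#' @export
detect_signals <- function(pairs, stats, level, subjects = NULL,
                           method = c("gea", "prr"), map = NULL,
                           subject_type = c("drug", "class"),
                           alpha1 = 0.1, p_adjust = c("none", "BH")) {
  method <- match.arg(method)
  subject_type <- match.arg(subject_type)
  p_adjust <- match.arg(p_adjust)
  stopifnot(inherits(stats, "reference_stats"), inherits(level, "abstraction_level"))
  if (is.null(subjects)) {
    subjects <- if (subject_type == "class") {
      if (is.null(map)) stop("a drug map is required for class-level subjects")
      sort(unique(map$atc4_class[map$ingredient_id %in% unique(pairs$drug)]))
    } else sort(unique(pairs$drug))
  }
  if (method == "prr") {
    universe_events <- {
      ev <- unique(pairs[c("article_id", "event")])
      names(ev)[2] <- "descriptor_id"
      mapped <- apply_level(ev, level)
      lapply(split(mapped$article_id, mapped$term), unique)
    }
    universe <- unique(pairs$article_id)
    drug_articles <- lapply(split(pairs$article_id, pairs$drug), unique)
  }
  res <- lapply(subjects, function(subject) {
    if (method == "gea") {
      gea_one_subject(subject, pairs, stats, level, map, subject_type, alpha1)
    } else {
      prr_one_subject(subject, universe, universe_events, drug_articles,
                      map, subject_type)
    }
  })
  out <- do.call(rbind, res)
  if (is.null(out) || !nrow(out)) return(empty_signal_frame(method))
  if (method == "gea") {
    if (p_adjust == "BH") {
      for (sub in unique(out$subject)) {
        i <- out$subject == sub
        out$adjusted_p[i] <- stats::p.adjust(out$adjusted_p[i], method = "BH")
      }
    }
    out <- out[order(out$subject, out$adjusted_p, out$term), , drop = FALSE]
    out$signal_0.1 <- out$adjusted_p < 0.1
    out$signal_0.05 <- out$adjusted_p < 0.05
    out$signal_0.005 <- out$adjusted_p < 0.005
  } else {
    out <- out[order(out$subject, -out$prr, out$term), , drop = FALSE]
    out$signal_1 <- out$prr > 1
    out$signal_1.5 <- out$prr > 1.5
    out$signal_5 <- out$prr > 5
  }
  rownames(out) <- NULL
  out
}

empty_signal_frame <- function(method) {
  if (method == "gea")
    data.frame(subject = character(), term = character(), m = integer(),
               s = integer(), a = integer(), n = integer(),
               raw_p = numeric(), adjusted_p = numeric(),
               signal_0.1 = logical(), signal_0.05 = logical(),
               signal_0.005 = logical(), stringsAsFactors = FALSE)
  else
    data.frame(subject = character(), term = character(), a = numeric(),
               b = numeric(), c = numeric(), d = numeric(), prr = numeric(),
               ci_low = numeric(), ci_high = numeric(),
               signal_1 = logical(), signal_1.5 = logical(),
               signal_5 = logical(), stringsAsFactors = FALSE)
}

gea_one_subject <- function(subject, pairs, stats, level, map, subject_type, alpha1) {
  soi <- build_set_of_interest(subject, pairs, level, map, subject_type)
  if (soi$s == 0L || !length(soi$event_counts)) return(NULL)
  terms <- names(soi$event_counts)
  known <- terms %in% names(stats$counts)
  if (any(!known))
    warning(sprintf("%d representative term(s) absent from reference stats skipped for subject %s",
                    sum(!known), subject))
  terms <- terms[known]
  if (!length(terms)) return(NULL)
  raw <- vapply(terms, function(x)
    hypergeom_upper_tail(soi$event_counts[[x]], soi$s,
                         stats$counts[[x]], stats$n), 0)
  enriched <- raw[raw < alpha1]
  adj <- raw
  if (length(enriched))
    adj[names(enriched)] <- adjusted_pvalues(enriched, soi, stats)
  data.frame(subject = subject, term = terms,
             m = unname(soi$event_counts[terms]), s = soi$s,
             a = unname(stats$counts[terms]), n = stats$n,
             raw_p = unname(raw), adjusted_p = unname(adj),
             stringsAsFactors = FALSE)
}

prr_one_subject <- function(subject, universe, universe_events, drug_articles,
                            map, subject_type) {
  members <- if (subject_type == "class") {
    if (is.null(map)) stop("a drug map is required for class-level subjects")
    class_members(subject, map)
  } else subject
  s_art <- unique(unlist(drug_articles[intersect(members, names(drug_articles))],
                         use.names = FALSE))
  if (!length(s_art)) return(NULL)
  other <- if (subject_type == "class") {
    setdiff(unique(unlist(drug_articles[setdiff(names(drug_articles), members)],
                          use.names = FALSE)), s_art)
  } else setdiff(universe, s_art)
  rows <- lapply(names(universe_events), function(term) {
    ev_art <- universe_events[[term]]
    a <- length(intersect(s_art, ev_art))
    if (a == 0L) return(NULL)
    b <- length(s_art) - a
    c <- length(intersect(other, ev_art))
    d <- length(other) - c
    est <- prr(a, b, c, d)
    data.frame(subject = subject, term = term, a = a, b = b, c = c, d = d,
               prr = est$prr, ci_low = est$ci_low, ci_high = est$ci_high,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a signal result table to TSV
#' @param results a data.frame from [detect_signals].
#' @param path output file path.
#' @export
write_signals <- function(results, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# ", paste(names(results), collapse = "\t")), con)
  if (nrow(results))
    utils::write.table(results, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(path)
}
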