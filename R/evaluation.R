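#' Read a gold standard TSV
#'
#' Dialect: `subject<TAB>outcome_term<TAB>label`, label `positive` or
#' `negative`, `#` comment lines allowed, no header.
#'
#' @param path file path.
#' @return data.frame with columns `subject`, `outcome`, `label`.
#' @export
read_gold <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  if (any(lengths(fields) < 3))
    stop("malformed gold standard row: expected 3 tab-separated fields")
  gold_standard(data.frame(subject = vapply(fields, `[`, "", 1L),
                           outcome = vapply(fields, `[`, "", 2L),
                           label = vapply(fields, `[`, "", 3L),
                           stringsAsFactors = FALSE))
}

#' Construct/validate a gold standard table
#'
#' @param rows data.frame with columns `subject`, `outcome`, `label`
#'   (`positive`/`negative`).
#' @return the validated, deduplicated data.frame.
#' @export
gold_standard <- function(rows) {
  need <- c("subject", "outcome", "label")
  stopifnot(is.data.frame(rows), all(need %in% names(rows)))
  rows <- unique(rows[need])
  if (!all(rows$label %in% c("positive", "negative")))
    stop("labels must be 'positive' or 'negative'")
  key <- paste(rows$subject, rows$outcome, sep = "\r")
  if (anyDuplicated(key))
    stop("subject-outcome pair with conflicting labels: ",
         key[duplicated(key)][1])
  rownames(rows) <- NULL
  rows
}

#' Write a gold standard to its TSV dialect
#' @param gold a gold standard data.frame.
#' @param path output file path.
#' @export
write_gold <- function(gold, path) {
  writeLines(c("# subject\toutcome\tlabel",
               paste(gold$subject, gold$outcome, gold$label, sep = "\t")),
             path, useBytes = TRUE)
  invisible(path)
}

#' Lift a drug-level gold standard to ATC4 drug classes
#'
#' Each drug's label propagates to all its ATC4 classes. When positive and
#' negative control drugs for the same outcome land in the same class, the
#' class becomes a positive control and is removed from the negatives
#' (e.g. one negative fluoroquinolone among six positives still makes
#' J01MA positive for that outcome). Subjects absent from the drug map
#' are dropped with a warning.
#'
#' @param gold drug-level gold standard (subjects are ingredient ids).
#' @param map a drug map data.frame.
#' @return a class-level gold standard data.frame.
#' @export
lift_gold_to_classes <- function(gold, map) {
  known <- gold$subject %in% map$ingredient_id
  if (any(!known))
    warning(sprintf("%d gold subject(s) absent from drug map dropped", sum(!known)))
  gold <- gold[known, , drop = FALSE]
  if (!nrow(gold))
    return(gold_standard(data.frame(subject = character(), outcome = character(),
                                    label = character(), stringsAsFactors = FALSE)))
  lifted <- do.call(rbind, lapply(seq_len(nrow(gold)), function(i) {
    data.frame(subject = drug_to_classes(gold$subject[i], map),
               outcome = gold$outcome[i], label = gold$label[i],
               stringsAsFactors = FALSE)
  }))
  lifted <- unique(lifted)
  key <- paste(lifted$subject, lifted$outcome, sep = "\r")
  pos_key <- unique(key[lifted$label == "positive"])
  lifted <- lifted[!(lifted$label == "negative" & key %in% pos_key), , drop = FALSE]
  gold_standard(lifted)
}

#' Score gold-standard pairs against a signal table
#'
#' For each gold (subject, outcome) row, the outcome is mapped to its
#' representative term(s) under the abstraction level and the best signal
#' among them is taken: the minimum adjusted p-value for GEA, the maximum
#' PRR for the PRR baseline. The comparable score orientation is
#' -log10(adjusted p) for GEA and the PRR value itself, so that larger is
#' always stronger. Pairs without any supporting signal row (e.g. drugs
#' with zero literature support) have `NA` score: the absence of any
#' article results in no signal, and such pairs rank below all scored
#' pairs.
#'
#' @param results a signal table from [detect_signals].
#' @param gold a gold standard data.frame.
#' @param level the `abstraction_level` used for detection.
#' @param method `"gea"` or `"prr"`.
#' @return the gold data.frame with added columns `best_p` or `best_prr`
#'   (NA when scoreless) and `score`.
#' @export
score_gold <- function(results, gold, level, method = c("gea", "prr")) {
  method <- match.arg(method)
  out <- gold
  out$score <- NA_real_
  stat <- rep(NA_real_, nrow(gold))
  for (i in seq_len(nrow(gold))) {
    reps <- map_outcome_to_level(gold$outcome[i], level)
    rows <- results[results$subject == gold$subject[i] & results$term %in% reps, , drop = FALSE]
    if (!nrow(rows)) next
    if (method == "gea") {
      stat[i] <- min(rows$adjusted_p)
      out$score[i] <- -log10(stat[i])
    } else {
      stat[i] <- max(rows$prr)
      out$score[i] <- stat[i]
    }
  }
  if (method == "gea") out$best_p <- stat else out$best_prr <- stat
  out
}

#' Confusion matrix at a decision threshold
#'
#' A scored gold pair passing the threshold (adjusted p strictly below it
#' for GEA, PRR strictly above it for PRR) counts as TP if positive else
#' FP; a failing or scoreless pair counts as FN if positive else TN.
#'
#' @param scored output of [score_gold].
#' @param threshold decision threshold.
#' @param method `"gea"` or `"prr"`.
#' @return list with counts `tp`, `fp`, `tn`, `fn`, class
#'   `confusion_matrix`.
#' @export
confusion_at_threshold <- function(scored, threshold, method = c("gea", "prr")) {
  method <- match.arg(method)
  flag <- if (method == "gea") {
    !is.na(scored$best_p) & scored$best_p < threshold
  } else {
    !is.na(scored$best_prr) & scored$best_prr > threshold
  }
  pos <- scored$label == "positive"
  confusion_matrix(tp = sum(flag & pos), fp = sum(flag & !pos),
                   tn = sum(!flag & !pos), fn = sum(!flag & pos))
}

#' Construct a confusion matrix
#' @param tp,fp,tn,fn non-negative counts.
#' @return list of the four counts, class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, fp, tn, fn) {
  cm <- list(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(unlist(cm) < 0)) stop("confusion counts must be non-negative")
  structure(cm, class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> TP %d  FP %d  TN %d  FN %d\n",
              x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Precision, recall and F1 from a confusion matrix
#'
#' Precision = TP/(TP+FP), recall = TP/(TP+FN), F1 their harmonic mean.
#' Undefined quantities (zero denominators) are reported as `NA`.
#'
#' @param cm a `confusion_matrix`.
#' @return list with `precision`, `recall`, `f1` (unrounded).
#' @export
metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  precision <- if (cm$tp + cm$fp > 0) cm$tp / (cm$tp + cm$fp) else NA_real_
  recall <- if (cm$tp + cm$fn > 0) cm$tp / (cm$tp + cm$fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  list(precision = precision, recall = recall, f1 = f1)
}

#' Round half-up to a number of decimal places
#'
#' Reported metrics are conventionally printed half-up at two decimals
#' (0.915 -> 0.92), unlike [round]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 2).
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Rank-based ROC AUC
#'
#' The concordance probability that a random positive scores above a
#' random negative, with ties counted 1/2. `NA` scores (subjects with no
#' supporting article, hence no signal) rank below all present scores and
#' are tied among themselves. Invariant under strictly monotone transforms
#' of the scores.
#'
#' @param score numeric vector (larger = stronger signal; `NA` allowed).
#' @param label character or logical vector: `"positive"`/`"negative"` or
#'   TRUE/FALSE.
#' @return AUC between 0 and 1.
#' @export
roc_auc <- function(score, label) {
  if (is.character(label) || is.factor(label)) label <- as.character(label) == "positive"
  stopifnot(length(score) == length(label))
  if (!any(label) || all(label))
    stop("AUC needs at least one positive and one negative")
  score[is.na(score)] <- -Inf
  r <- rank(score, ties.method = "average")
  np <- sum(label); nn <- sum(!label)
  (sum(r[label]) - np * (np + 1) / 2) / (np * nn)
}

#' Evaluate a signal table against a gold standard
#'
#' Scores every gold pair ([score_gold]), sweeps the decision thresholds,
#' and computes the ROC AUC, pooled over outcomes and per outcome.
#'
#' @param results a signal table from [detect_signals].
#' @param gold a gold standard data.frame.
#' @param level the `abstraction_level` used for detection.
#' @param method `"gea"` or `"prr"`.
#' @param thresholds decision thresholds to sweep; defaults to
#'   0.1/0.05/0.005 for GEA and 1/1.5/5 for PRR.
#' @return list with `scored` (per-pair scores), `by_threshold`
#'   (data.frame of confusion counts and 2-dp metrics per threshold),
#'   `auc` (pooled) and `auc_by_outcome`.
#' @export
evaluate_signals <- function(results, gold, level, method = c("gea", "prr"),
                             thresholds = NULL) {
  method <- match.arg(method)
  if (!nrow(gold)) stop("empty gold standard")
  if (is.null(thresholds))
    thresholds <- if (method == "gea") c(0.1, 0.05, 0.005) else c(1, 1.5, 5)
  scored <- score_gold(results, gold, level, method)
  by_threshold <- do.call(rbind, lapply(thresholds, function(t) {
    cm <- confusion_at_threshold(scored, t, method)
    mt <- metrics(cm)
    data.frame(threshold = t, tp = cm$tp, fp = cm$fp, tn = cm$tn, fn = cm$fn,
               precision = round_half_up(mt$precision),
               recall = round_half_up(mt$recall),
               f1 = round_half_up(mt$f1))
  }))
  auc_by_outcome <- vapply(unique(scored$outcome), function(o) {
    sub <- scored[scored$outcome == o, , drop = FALSE]
    if (length(unique(sub$label)) < 2) return(NA_real_)
    roc_auc(sub$score, sub$label)
  }, 0)
  list(scored = scored, by_threshold = by_threshold,
       auc = roc_auc(scored$score, scored$label),
       auc_by_outcome = auc_by_outcome)
}
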