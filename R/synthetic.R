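#' Configuration for the synthetic study generator
#'
#' Defines the shape of a synthetic terminology, annotation corpus, drug
#' map and gold standard with planted drug-adverse-event associations, so
#' the full pipeline can be exercised and calibrated without any external
#' corpus. One seeded generator stream is used per artifact section
#' (terminology / corpus / gold) so components regenerate independently.
#'
#' @param seed integer; fully determines all output.
#' @param n_articles number of background articles.
#' @param depth,branching disease tree shape: `branching` roots, each node
#'   with `branching` children down to `depth` levels (depth 3, branching
#'   3 gives 3 + 9 + 27 = 39 disease terms).
#' @param n_drug_terms number of drug descriptors (supplementary-concept
#'   style: zero tree numbers).
#' @param multi_parent_fraction fraction of non-root disease terms given a
#'   second tree number under another branch (multi-classification).
#' @param background_rate per-leaf-term probability that an article is
#'   annotated with the term.
#' @param drug_rate probability that an article mentions one (uniformly
#'   chosen) drug.
#' @param drug_qualifier_rate probability that a background drug mention
#'   carries the "adverse effects" qualifier; the rest are plain mentions
#'   (therapeutic-use context) that never enter candidate pairs, as with
#'   most drug indexing in real literature.
#' @param event_qualifier_rate probability that a disease annotation
#'   carries the event qualifier ("chemically induced") rather than none.
#' @param planted data.frame with columns `drug` (mesh drug id), `event`
#'   (leaf descriptor id), `multiplier` (relative risk of qualified event
#'   emission in the pair's supporting articles, >= 1), `n_supporting`
#'   (number of supporting articles emitted, each mentioning the drug).
#'   With multiplier 1 the supporting articles behave like background
#'   drug-mention articles (a null corpus); the emission probability
#'   min(1, multiplier x background_rate x event_qualifier_rate)
#'   saturates at 1 for large multipliers, so every supporting article
#'   then carries the event.
#' @return a validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, n_articles = 2000L, depth = 3L,
                              branching = 3L, n_drug_terms = 20L,
                              multi_parent_fraction = 0.15,
                              background_rate = 0.04, drug_rate = 0.05,
                              drug_qualifier_rate = 0.25,
                              event_qualifier_rate = 0.5,
                              planted = NULL) {
  rates <- c(multi_parent_fraction, background_rate, drug_rate,
             drug_qualifier_rate, event_qualifier_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must be in [0, 1]")
  stopifnot(n_articles >= 0, depth >= 1, branching >= 1, n_drug_terms >= 0)
  if (is.null(planted))
    planted <- data.frame(drug = character(), event = character(),
                          multiplier = numeric(), n_supporting = integer(),
                          stringsAsFactors = FALSE)
  stopifnot(all(c("drug", "event", "multiplier", "n_supporting") %in% names(planted)))
  if (nrow(planted) && any(planted$multiplier < 1))
    stop("planted multipliers must be >= 1")
  structure(list(seed = as.integer(seed), n_articles = as.integer(n_articles),
                 depth = as.integer(depth), branching = as.integer(branching),
                 n_drug_terms = as.integer(n_drug_terms),
                 multi_parent_fraction = multi_parent_fraction,
                 background_rate = background_rate, drug_rate = drug_rate,
                 drug_qualifier_rate = drug_qualifier_rate,
                 event_qualifier_rate = event_qualifier_rate,
                 planted = planted),
            class = "simulation_config")
}

#' Generate a synthetic terminology
#'
#' A multi-level disease tree ("C" branch) with deterministic descriptor
#' ids, plus tree-number-less drug descriptors. A configurable fraction of
#' non-root disease terms receives a second tree number grafted under a
#' shallower node in another branch, emulating MeSH multi-classification.
#'
#' @param cfg a [simulation_config].
#' @return a [terminology].
#' @export
generate_terminology <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  tns <- sprintf("C%02d", seq_len(cfg$branching))
  levels_list <- list(tns)
  for (lvl in seq_len(cfg$depth - 1L)) {
    prev <- levels_list[[lvl]]
    kids <- as.vector(vapply(prev, function(p)
      sprintf("%s.%02d", p, seq_len(cfg$branching)), character(cfg$branching)))
    levels_list[[lvl + 1L]] <- kids
  }
  all_tn <- unlist(levels_list)
  ids <- sprintf("D%04d", seq_along(all_tn))
  tn_list <- as.list(all_tn)
  # multi-parenting: graft a second tree number under a shallower node.
  # Only leaves are grafted so every placement carries a complete path and
  # ancestor closures stay consistent across a descriptor's tree numbers
  # (in MeSH each placement has its own full tree number).
  depth_of <- rep(seq_along(levels_list), lengths(levels_list))
  eligible <- if (cfg$depth > 1L) which(depth_of == cfg$depth) else integer()
  n_multi <- round(cfg$multi_parent_fraction * length(eligible))
  if (n_multi > 0) {
    chosen <- sort(sample(eligible, n_multi))
    for (k in chosen) {
      hosts <- which(depth_of < depth_of[k])
      host <- if (length(hosts) == 1L) hosts else sample(hosts, 1L)
      tn_list[[k]] <- c(tn_list[[k]], sprintf("%s.x%02d", all_tn[host], k))
    }
  }
  names <- sprintf("Disease term %s", ids)
  if (cfg$n_drug_terms > 0) {
    drug_ids <- sprintf("DRUG%03d", seq_len(cfg$n_drug_terms))
    ids <- c(ids, drug_ids)
    names <- c(names, sprintf("Drug %03d", seq_len(cfg$n_drug_terms)))
    tn_list <- c(tn_list, rep(list(character()), cfg$n_drug_terms))
  }
  terminology(ids, names, tn_list)
}

#' Generate a synthetic drug map
#'
#' Ingredients `ING001`... mapped 1:1 to the terminology's drug
#' descriptors, grouped into ATC4 classes of up to four members; one in
#' five drugs additionally receives a second (topical-style) ATC5 code in
#' a separate "S" class.
#'
#' @param cfg a [simulation_config].
#' @return a drug map data.frame.
#' @export
generate_drug_map <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  n <- cfg$n_drug_terms
  if (n == 0)
    return(drug_map(data.frame(mesh_drug_id = character(),
                               ingredient_id = character(),
                               atc5_code = character(), stringsAsFactors = FALSE)))
  i <- seq_len(n)
  cls <- (i - 1L) %/% 4L + 1L
  class_code <- sprintf("%s%02dAA", LETTERS[(cls - 1L) %% 26L + 1L],
                        (cls - 1L) %/% 26L + 1L)
  member <- (i - 1L) %% 4L + 1L
  rows <- data.frame(mesh_drug_id = sprintf("DRUG%03d", i),
                     ingredient_id = sprintf("ING%03d", i),
                     atc5_code = sprintf("%s%02d", class_code, member),
                     stringsAsFactors = FALSE)
  dual <- i[i %% 5L == 0L]
  if (length(dual))
    rows <- rbind(rows, data.frame(
      mesh_drug_id = sprintf("DRUG%03d", dual),
      ingredient_id = sprintf("ING%03d", dual),
      atc5_code = sprintf("S%02dAA%02d", (dual - 1L) %/% 4L + 1L, (dual - 1L) %% 4L + 1L),
      stringsAsFactors = FALSE))
  drug_map(rows)
}

#' Leaf disease terms of a generated terminology
#' @param term a [terminology].
#' @return character vector of descriptor ids with no descendants and at
#'   least one tree number.
#' @export
leaf_terms <- function(term) {
  ids <- names(term$tree_numbers)[lengths(term$tree_numbers) > 0]
  all_tn <- names(term$tree_index)
  has_child <- vapply(ids, function(id)
    any(vapply(term$tree_numbers[[id]], function(tn)
      any(startsWith(all_tn, paste0(tn, "."))), TRUE)), TRUE)
  ids[!has_child]
}

#' Generate a synthetic annotation corpus with planted associations
#'
#' Background articles draw annotations independently per leaf disease
#' term at `background_rate` (internal-node counts arise purely through
#' ancestor propagation, as with real MeSH indexing); each annotation
#' carries the event qualifier with probability `event_qualifier_rate`.
#' An article mentions a uniformly chosen drug with probability
#' `drug_rate`, carrying the "adverse effects" qualifier with probability
#' `drug_qualifier_rate` (a plain mention otherwise). Every planted
#' (drug, event) pair appends `n_supporting` extra articles mentioning the
#' drug, in which the event is emitted with the event qualifier at
#' probability min(1, multiplier x background_rate x
#' event_qualifier_rate); supporting articles also draw ordinary
#' background annotations.
#'
#' @param cfg a [simulation_config].
#' @param term the terminology from [generate_terminology].
#' @return list with `corpus` (an [annotation_corpus]) and `truth`
#'   (data.frame of planted pairs with the realized co-annotated article
#'   count `n_emitted`).
#' @export
generate_corpus <- function(cfg, term) {
  stopifnot(inherits(cfg, "simulation_config"), inherits(term, "terminology"))
  set.seed(cfg$seed + 1L)
  leaves <- leaf_terms(term)
  drugs <- names(term$tree_numbers)[lengths(term$tree_numbers) == 0]
  art_ids <- sprintf("A%06d", seq_len(cfg$n_articles))
  recs <- list()
  if (cfg$n_articles > 0 && length(leaves)) {
    hit <- matrix(stats::runif(cfg$n_articles * length(leaves)) < cfg$background_rate,
                  nrow = cfg$n_articles)
    idx <- which(hit, arr.ind = TRUE)
    qual <- ifelse(stats::runif(nrow(idx)) < cfg$event_qualifier_rate,
                   "chemically induced", "")
    recs[[length(recs) + 1L]] <- data.frame(
      article_id = art_ids[idx[, 1L]], descriptor_id = leaves[idx[, 2L]],
      qualifier = qual, stringsAsFactors = FALSE)
  }
  if (cfg$n_articles > 0 && length(drugs)) {
    has_drug <- stats::runif(cfg$n_articles) < cfg$drug_rate
    if (any(has_drug))
      recs[[length(recs) + 1L]] <- data.frame(
        article_id = art_ids[has_drug],
        descriptor_id = sample(drugs, sum(has_drug), replace = TRUE),
        qualifier = ifelse(stats::runif(sum(has_drug)) < cfg$drug_qualifier_rate,
                           "adverse effects", ""),
        stringsAsFactors = FALSE)
  }
  truth <- cfg$planted
  truth$n_emitted <- integer(nrow(truth) + 0L)
  next_id <- cfg$n_articles
  for (i in seq_len(nrow(cfg$planted))) {
    p <- cfg$planted[i, ]
    sup_ids <- sprintf("A%06d", next_id + seq_len(p$n_supporting))
    next_id <- next_id + p$n_supporting
    art_ids <- c(art_ids, sup_ids)
    recs[[length(recs) + 1L]] <- data.frame(
      article_id = sup_ids, descriptor_id = p$drug,
      qualifier = "adverse effects", stringsAsFactors = FALSE)
    p_emit <- min(1, p$multiplier * cfg$background_rate * cfg$event_qualifier_rate)
    emit <- stats::runif(p$n_supporting) < p_emit
    truth$n_emitted[i] <- sum(emit)
    if (any(emit))
      recs[[length(recs) + 1L]] <- data.frame(
        article_id = sup_ids[emit], descriptor_id = p$event,
        qualifier = "chemically induced", stringsAsFactors = FALSE)
    if (length(leaves)) {
      hit <- matrix(stats::runif(p$n_supporting * length(leaves)) < cfg$background_rate,
                    nrow = p$n_supporting)
      idx <- which(hit, arr.ind = TRUE)
      if (nrow(idx))
        recs[[length(recs) + 1L]] <- data.frame(
          article_id = sup_ids[idx[, 1L]], descriptor_id = leaves[idx[, 2L]],
          qualifier = ifelse(stats::runif(nrow(idx)) < cfg$event_qualifier_rate,
                             "chemically induced", ""),
          stringsAsFactors = FALSE)
    }
  }
  records <- if (length(recs)) do.call(rbind, recs) else
    data.frame(article_id = character(), descriptor_id = character(),
               qualifier = character(), stringsAsFactors = FALSE)
  list(corpus = annotation_corpus(records, article_universe = art_ids),
       truth = truth)
}

#' Generate a gold standard from planted ground truth
#'
#' Positives are the planted pairs (subjects as ingredient ids via the
#' drug map, outcomes as the planted event terms). Negatives are
#' `n_decoy_negatives` drug-event combinations sampled uniformly from the
#' unplanted cross product of mapped drugs and candidate outcome terms, so
#' they are never co-emitted above background. Decoys never overlap
#' positives.
#'
#' @param truth the `truth` table from [generate_corpus].
#' @param term the generated terminology.
#' @param map the generated drug map.
#' @param n_decoy_negatives number of negative controls to sample.
#' @param cfg the [simulation_config] (for the seeded gold stream).
#' @return a gold standard data.frame.
#' @export
generate_gold <- function(truth, term, map, n_decoy_negatives, cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed + 2L)
  mesh_to_ing <- stats::setNames(map$ingredient_id, map$mesh_drug_id)
  pos <- data.frame(subject = unname(mesh_to_ing[truth$drug]),
                    outcome = truth$event, label = "positive",
                    stringsAsFactors = FALSE)
  if (anyNA(pos$subject)) stop("planted drug missing from drug map")
  pos <- unique(pos)
  outcomes <- if (nrow(truth)) unique(truth$event) else leaf_terms(term)
  all_comb <- expand.grid(subject = unique(map$ingredient_id), outcome = outcomes,
                          stringsAsFactors = FALSE)
  key <- paste(all_comb$subject, all_comb$outcome, sep = "\r")
  pos_key <- paste(pos$subject, pos$outcome, sep = "\r")
  candidates <- all_comb[!key %in% pos_key, , drop = FALSE]
  n_neg <- min(n_decoy_negatives, nrow(candidates))
  neg <- candidates[sample(nrow(candidates), n_neg), , drop = FALSE]
  neg$label <- rep("negative", nrow(neg))
  gold_standard(rbind(pos, neg))
}
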