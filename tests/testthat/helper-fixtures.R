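# Shared fixtures and independent oracles for the test suite.

# Small disease terminology with a multi-classified term (D08 sits under
# both C01.01 and C02) and an orphan-free 3-level chain under C01.
tiny_terminology <- function() {
  terminology(
    descriptor_id = c("D01", "D02", "D03", "D04", "D05", "D06", "D07", "D08",
                      "D09", "DRUG1", "DRUG2"),
    name = c("Root one", "Root two", "Mid 1.1", "Mid 1.2", "Leaf 1.1.1",
             "Leaf 1.1.2", "Leaf 1.2.1", "Multi leaf", "Leaf 2.1",
             "Drug one", "Drug two"),
    tree_numbers = list("C01", "C02", "C01.01", "C01.02",
                        "C01.01.01", "C01.01.02", "C01.02.01",
                        c("C01.01.03", "C02.08"), "C02.01",
                        character(), character()))
}

# Mood-disorders chain used for the ancestor example.
mood_terminology <- function() {
  terminology(
    descriptor_id = c("D019964", "D008107x", "D001523"),
    name = c("Depressive Disorder", "Mood Disorders", "Mental Disorders"),
    tree_numbers = list("F03.600.300", "F03.600", "F03"))
}

# Cardiovascular fixture with reference IC values used to pin the
# abstraction-level semantics (range [4.0, 7.5)).
cardio_fixture <- function() {
  term <- terminology(
    descriptor_id = c("CVD", "VASC", "ANEU", "ANEUR", "CONG", "CVAB",
                      "NERV", "DEMY"),
    name = c("Cardiovascular Diseases", "Vascular Diseases", "Aneurysm",
             "Aneurysm, Ruptured", "Congenital Abnormalities",
             "Cardiovascular Abnormalities", "Nervous System Diseases",
             "Demyelinating Diseases"),
    tree_numbers = list("C14", "C14.907", "C14.907.055", "C14.907.055.090",
                        "C16.131", c("C14.240", "C16.131.240"),
                        "C10", "C10.314"))
  ic <- c(CVD = 3.53, VASC = 4.03, ANEU = 7.79, ANEUR = 10.65,
          CONG = 5.55, CVAB = 7.14, NERV = 3.40, DEMY = 8.13)
  list(term = term, ic = ic)
}

# Brute-force hypergeometric upper tail by direct pmf enumeration with
# choose(); independent of stats::phyper.
hyper_tail_enum <- function(m, s, a, n) {
  if (m == 0) return(1)
  k <- seq(m, min(a, s))
  sum(choose(a, k) * choose(n - a, s - k)) / choose(n, s)
}

# Ancestors by explicit graph traversal: build parent edges from one-step
# prefix relations, then walk the graph (oracle for prefix arithmetic).
ancestors_by_traversal <- function(id, term) {
  parents_of <- function(x) {
    out <- character()
    for (tn in term$tree_numbers[[x]]) {
      segs <- strsplit(tn, ".", fixed = TRUE)[[1]]
      if (length(segs) < 2) next
      p <- paste(segs[-length(segs)], collapse = ".")
      # climb past prefixes not assigned to any descriptor
      while (nzchar(p)) {
        hit <- term$tree_index[p]
        if (!is.na(hit)) { out <- c(out, unname(hit)); break }
        segs2 <- strsplit(p, ".", fixed = TRUE)[[1]]
        if (length(segs2) < 2) break
        p <- paste(segs2[-length(segs2)], collapse = ".")
      }
    }
    unique(out)
  }
  seen <- character()
  frontier <- parents_of(id)
  while (length(frontier)) {
    seen <- union(seen, frontier)
    frontier <- setdiff(unique(unlist(lapply(frontier, parents_of))), seen)
  }
  seen
}

# Corpus over tiny_terminology with hand-checkable aggregation.
tiny_corpus <- function() {
  annotation_corpus(data.frame(
    article_id = c("X1", "X1", "X2", "X3", "X4", "X5", "X5", "X6", "X7",
                   "X8", "X9", "X10"),
    descriptor_id = c("D05", "DRUG1", "D05", "D06", "D07", "D08", "DRUG2",
                      "D09", "D03", "D01", "D05", "D08"),
    qualifier = c("chemically induced", "adverse effects", "", "",
                  "chemically induced", "chemically induced",
                  "adverse effects", "", "", "", "", ""),
    stringsAsFactors = FALSE))
}

# Parent/child dependency fixture: X (child, 50 articles, always
# co-indexed with its parent P) drives the signal; P has 150 further
# articles of its own. The drug's 20 articles all carry both terms.
dependency_fixture <- function() {
  n_art <- 1000L
  art <- sprintf("R%04d", seq_len(n_art))
  recs <- rbind(
    data.frame(article_id = art[1:50], descriptor_id = "X",
               qualifier = "chemically induced", stringsAsFactors = FALSE),
    data.frame(article_id = art[1:50], descriptor_id = "P",
               qualifier = "chemically induced", stringsAsFactors = FALSE),
    data.frame(article_id = art[51:200], descriptor_id = "P",
               qualifier = "", stringsAsFactors = FALSE),
    data.frame(article_id = art[1:20], descriptor_id = "DRUGX",
               qualifier = "adverse effects", stringsAsFactors = FALSE))
  term <- terminology(c("P", "X", "DRUGX"),
                      c("Parent disease", "Child disease", "Drug X"),
                      list("C01", "C01.01", character()))
  corpus <- annotation_corpus(recs, article_universe = art)
  stats <- build_reference_stats(corpus, term)
  level <- build_abstraction_level(term, information_content(stats),
                                   ic_min = 2, ic_max = 5)
  pairs <- extract_candidate_pairs(corpus)
  list(term = term, corpus = corpus, stats = stats, level = level,
       pairs = pairs)
}

# Default synthetic study conditions with planted associations; the
# multiplier saturates qualified-event emission so every supporting
# article carries the event.
planted_config <- function(seed, n_planted = 6L, multiplier = 100,
                           n_supporting = 28L) {
  planted <- data.frame(
    drug = sprintf("DRUG%03d", seq_len(n_planted)),
    event = character(n_planted),
    multiplier = multiplier, n_supporting = n_supporting,
    stringsAsFactors = FALSE)
  cfg0 <- simulation_config(seed = seed)
  term <- generate_terminology(cfg0)
  leaves <- leaf_terms(term)
  planted$event <- leaves[seq_len(n_planted)]
  simulation_config(seed = seed, planted = planted)
}

# One full synthetic pipeline run: stats, level over the leaf IC band,
# GEA + PRR detection for all ingredients, gold with decoy negatives.
run_synthetic_pipeline <- function(seed, n_decoys = 30L, cfg = planted_config(seed)) {
  term <- generate_terminology(cfg)
  map <- generate_drug_map(cfg)
  gen <- generate_corpus(cfg, term)
  stats <- build_reference_stats(gen$corpus, term)
  level <- build_abstraction_level(term, information_content(stats),
                                   ic_min = 3, ic_max = 12)
  pairs <- extract_candidate_pairs(gen$corpus, map)
  gea <- detect_signals(pairs, stats, level, method = "gea", map = map)
  prr_res <- detect_signals(pairs, stats, level, method = "prr", map = map)
  gold <- generate_gold(gen$truth, term, map, n_decoy_negatives = n_decoys, cfg)
  list(cfg = cfg, term = term, map = map, corpus = gen$corpus,
       truth = gen$truth, stats = stats, level = level, pairs = pairs,
       gea = gea, prr = prr_res, gold = gold)
}
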