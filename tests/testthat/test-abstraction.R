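test_that("IC range mapping reproduces the cardiovascular fixture", {
  fx <- cardio_fixture()
  lvl <- build_abstraction_level(fx$term, fx$ic, ic_min = 4.0, ic_max = 7.5)
  # too-specific aneurysm terms aggregate into Vascular Diseases
  expect_identical(lvl$mapping[["ANEU"]], "VASC")
  expect_identical(lvl$mapping[["ANEUR"]], "VASC")
  expect_identical(lvl$status[["ANEU"]], "aggregated")
  # in-range terms represent themselves
  expect_identical(lvl$mapping[["CVAB"]], "CVAB")
  expect_identical(lvl$mapping[["CONG"]], "CONG")
  expect_identical(lvl$mapping[["VASC"]], "VASC")
  # too-general terms and unsalvageable specific terms are excluded
  expect_identical(lvl$mapping[["CVD"]], character())
  expect_identical(lvl$mapping[["NERV"]], character())
  expect_identical(lvl$mapping[["DEMY"]], character())
  expect_setequal(lvl$representatives, c("VASC", "CONG", "CVAB"))
})

test_that("range semantics are half-open and validated", {
  fx <- cardio_fixture()
  # a term exactly at ic_max is aggregated (upper bound exclusive), a term
  # exactly at ic_min keeps itself (lower bound inclusive)
  lvl <- build_abstraction_level(fx$term, fx$ic, ic_min = 5.55, ic_max = 7.14)
  expect_identical(lvl$status[["CONG"]], "self")
  expect_identical(lvl$mapping[["CVAB"]], "CONG")
  expect_identical(lvl$status[["CVAB"]], "aggregated")
  expect_error(build_abstraction_level(fx$term, fx$ic, 5, 5), "ic_min")
})

test_that("aggregation picks the nearest in-range ancestor on each path", {
  term <- tiny_terminology()
  ic <- c(D01 = 1.5, D02 = 2.0, D03 = 4.5, D04 = 5.0, D05 = 9.0,
          D06 = 8.0, D07 = 8.5, D08 = 9.5, D09 = 6.0)
  lvl <- build_abstraction_level(term, ic, ic_min = 4.0, ic_max = 7.0)
  # D05 skips nothing: D03 (4.5) is the nearest ancestor in range
  expect_identical(lvl$mapping[["D05"]], "D03")
  # multi-classified D08: C01.01 path gives D03; C02 path has only D02
  # (too general) so contributes nothing
  expect_identical(lvl$mapping[["D08"]], "D03")
  # nearest-ancestor property: nothing in range strictly between
  for (id in names(lvl$status)[lvl$status == "aggregated"]) {
    for (r in lvl$mapping[[id]]) {
      between <- setdiff(intersect(ancestors(id, term),
                                   descendants(r, term)), c(id, r))
      for (b in between)
        expect_false(!is.na(ic[b]) && ic[b] >= 4.0 && ic[b] < 7.0)
    }
  }
  # every representative IC lies in range
  for (r in lvl$representatives)
    expect_true(ic[[r]] >= 4.0 && ic[[r]] < 7.0)
  # drugs carry no IC and are excluded
  expect_identical(lvl$mapping[["DRUG1"]], character())
})

test_that("multi-branch terms keep representatives from every path", {
  term <- tiny_terminology()
  ic <- c(D01 = 1.5, D02 = 4.2, D03 = 4.5, D04 = 5.0, D05 = 9.0,
          D06 = 8.0, D07 = 8.5, D08 = 9.5, D09 = 6.0)
  lvl <- build_abstraction_level(term, ic, ic_min = 4.0, ic_max = 7.0)
  expect_setequal(lvl$mapping[["D08"]], c("D03", "D02"))
})

test_that("fixed tree-level mapping follows tree-number prefixes", {
  term <- terminology(
    c("MUSC", "TEND", "RHAB", "C05ROOT"),
    c("Muscular Diseases", "Tendinopathy", "Rhabdomyolysis",
      "Musculoskeletal Diseases"),
    list("C05.651", "C05.651.869", "C05.651.807", "C05"))
  lvl <- build_tree_level(term, 2L)
  expect_identical(lvl$mapping[["TEND"]], "MUSC")
  expect_identical(lvl$mapping[["RHAB"]], "MUSC")
  expect_identical(lvl$mapping[["MUSC"]], "MUSC")
  expect_identical(lvl$status[["MUSC"]], "self")
  # 1st-level term has no 2nd-level prefix: excluded
  expect_identical(lvl$mapping[["C05ROOT"]], character())
  expect_error(build_tree_level(term, 0), "positive")
})

test_that("apply_level deduplicates per article and reports coverage", {
  fx <- cardio_fixture()
  lvl <- build_abstraction_level(fx$term, fx$ic, ic_min = 4.0, ic_max = 7.5)
  ann <- data.frame(
    article_id = c("A1", "A1", "A2", "A2", "A3"),
    descriptor_id = c("ANEU", "ANEUR", "CVAB", "DEMY", "CVD"),
    stringsAsFactors = FALSE)
  out <- apply_level(ann, lvl)
  # A1 carries both aneurysm terms -> one Vascular Diseases count
  expect_identical(out$term[out$article_id == "A1"], "VASC")
  expect_identical(nrow(out[out$article_id == "A1", ]), 1L)
  # DEMY and CVD dropped
  expect_false("A3" %in% out$article_id)
  cov <- attr(out, "coverage")
  expect_identical(cov$n_original, 5L)
  expect_identical(cov$n_covered + cov$n_excluded, cov$n_original)
  expect_setequal(cov$excluded_terms, c("DEMY", "CVD"))
})

test_that("a multi-classified term is counted under several representatives", {
  term <- tiny_terminology()
  ic <- c(D01 = 1.5, D02 = 4.2, D03 = 4.5, D04 = 5.0, D05 = 9.0,
          D06 = 8.0, D07 = 8.5, D08 = 9.5, D09 = 6.0)
  lvl <- build_abstraction_level(term, ic, ic_min = 4.0, ic_max = 7.0)
  out <- apply_level(data.frame(article_id = "A1", descriptor_id = "D08"), lvl)
  expect_setequal(out$term, c("D03", "D02"))
})

test_that("supplementary records are never representatives; orphans self-map", {
  term <- tiny_terminology()
  ic <- c(D03 = 4.5, D05 = 5.0, DRUG1 = 5.0, GHOST = 5.0)
  lvl <- build_abstraction_level(term, ic, ic_min = 4.0, ic_max = 7.0)
  # DRUG1 is in the terminology with zero tree numbers: a drug record,
  # excluded from event aggregation despite an in-range IC
  expect_identical(lvl$mapping[["DRUG1"]], character())
  expect_false("DRUG1" %in% lvl$representatives)
  # GHOST is annotated but absent from the terminology: an orphan leaf
  # that represents itself
  expect_identical(lvl$mapping[["GHOST"]], "GHOST")
})

test_that("map_outcome_to_level errors for excluded outcomes", {
  fx <- cardio_fixture()
  lvl <- build_abstraction_level(fx$term, fx$ic, ic_min = 4.0, ic_max = 7.5)
  expect_identical(map_outcome_to_level("ANEUR", lvl), "VASC")
  expect_identical(map_outcome_to_level("CONG", lvl), "CONG")
  expect_error(map_outcome_to_level("DEMY", lvl), "DEMY.*excluded")
})

test_that("level export TSV lists every original with status", {
  fx <- cardio_fixture()
  lvl <- build_abstraction_level(fx$term, fx$ic, ic_min = 4.0, ic_max = 7.5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_level(lvl, path)
  tab <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           col.names = c("original", "reps", "status"))
  expect_identical(nrow(tab), length(lvl$status))
  expect_setequal(tab$status, c("self", "aggregated", "excluded"))
  expect_identical(tab$reps[tab$original == "ANEU"], "VASC")
})
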