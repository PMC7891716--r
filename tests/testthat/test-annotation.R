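test_that("pairwise agreement pools unordered same-document pairs", {
  # two annotators sharing 4 docs, 2 matching
  recs <- annotations_from(list(
    d1 = list(a1 = list("A", 7), a2 = list("A", 6)),
    d2 = list(a1 = list("B", 7), a2 = list("B", 6)),
    d3 = list(a1 = list("A", 7), a2 = list("B", 6)),
    d4 = list(a1 = list("B", 7), a2 = list("A", 6))))
  expect_equal(pairwise_agreement(recs), 0.5)

  all_same <- annotations_from(list(
    d1 = list(a1 = list("A", 5), a2 = list("A", 5), a3 = list("A", 5))))
  expect_equal(pairwise_agreement(all_same), 1)

  triple <- annotations_from(list(
    d1 = list(a1 = list("A", 5), a2 = list("A", 5), a3 = list("B", 5))))
  expect_equal(pairwise_agreement(triple), 1 / 3)

  singles <- annotations_from(list(d1 = list(a1 = list("A", 5))))
  expect_error(pairwise_agreement(singles), "two or more")
})

test_that("Cohen's kappa matches its closed form on worked cases", {
  expect_equal(cohens_kappa(cbind(c("A", "B", "C"), c("A", "B", "C"))), 1)
  # p_o = 0.5 and p_e = 0.5 forces kappa = 0
  expect_equal(cohens_kappa(cbind(c(1, 1, 0, 0), c(1, 0, 0, 1))), 0)
  expect_lt(cohens_kappa(cbind(c("A", "B"), c("B", "A"))), 0)
  expect_message(k <- cohens_kappa(cbind(c("A", "A"), c("A", "A"))),
                 "degenerate")
  expect_equal(k, 1)
})

test_that("kappa and agreement match brute-force oracles on random tables", {
  set.seed(101)
  for (i in 1:200) {
    tab <- random_annotation_table()
    pairs <- cantm:::.annotation_pairs(tab)
    if (nrow(pairs) < 2L) next
    expect_equal(pairwise_agreement(tab), agreement_bruteforce(tab))
    expect_equal(suppressMessages(cohens_kappa(pairs)),
                 kappa_bruteforce(pairs[, 1], pairs[, 2]))
  }
})

test_that("annotator scores equal leave-one-out agreement changes", {
  # a3 disagrees with a consensus pair on every document
  recs <- annotations_from(list(
    d1 = list(a1 = list("A", 7), a2 = list("A", 7), a3 = list("B", 7)),
    d2 = list(a1 = list("B", 7), a2 = list("B", 7), a3 = list("A", 7)),
    d3 = list(a1 = list("A", 7), a2 = list("A", 7), a3 = list("C", 7))))
  sc <- score_annotators(recs)
  expect_identical(sc$annotator_id[1], "a3")
  expect_gt(sc$score[1], 0)
  # consensus members: removal leaves agreement at 1 among the remaining pair
  base <- pairwise_agreement(recs)
  for (a in c("a1", "a2", "a3")) {
    rest <- recs[recs$annotator_id != a, ]
    expect_equal(sc$score[sc$annotator_id == a],
                 pairwise_agreement(rest) - base)
  }

  consensus <- annotations_from(list(
    d1 = list(a1 = list("A", 7), a2 = list("A", 7), a3 = list("A", 7))))
  expect_true(all(score_annotators(consensus)$score == 0))
})

test_that("removing the most harmful annotator never decreases agreement", {
  set.seed(77)
  for (i in 1:25) {
    tab <- random_annotation_table(n_docs = 10L, n_annotators = 4L)
    pairs_per_ann <- table(tab$annotator_id)
    sc <- tryCatch(score_annotators(tab), error = function(e) NULL)
    if (is.null(sc) || !any(sc$defined)) next
    worst <- sc$annotator_id[sc$defined][1]
    if (sc$score[sc$defined][1] <= 0) next
    before <- pairwise_agreement(tab)
    rest <- tab[tab$annotator_id != worst, ]
    after <- tryCatch(pairwise_agreement(rest), error = function(e) NA_real_)
    if (!is.na(after)) expect_gte(after, before)
  }
})

test_that("confidence filtering respects per-annotator thresholds and is idempotent", {
  recs <- annotations_from(list(
    d1 = list(a1 = list("A", 5)), d2 = list(a1 = list("A", 6)),
    d3 = list(a1 = list("A", 7))))
  kept <- filter_by_confidence(recs)
  expect_identical(nrow(kept), 2L)
  expect_identical(filter_by_confidence(kept), kept)

  expect_identical(filter_by_confidence(recs, default_threshold = 0L), recs)

  two <- annotations_from(list(
    d1 = list(a1 = list("A", 9), a2 = list("B", 8)),
    d2 = list(a1 = list("A", 8), a2 = list("B", 9))))
  strict <- filter_by_confidence(two, thresholds = c(a1 = 9L),
                                 default_threshold = 0L)
  expect_identical(strict$confidence[strict$annotator_id == "a1"], 9L)
  expect_identical(nrow(strict[strict$annotator_id == "a2", ]), 2L)
  expect_error(filter_by_confidence(recs, thresholds = c(a1 = 12L)), "0..9")
})

test_that("label merging applies majority, confidence and tie-break rules", {
  recs <- annotations_from(list(
    maj = list(a1 = list("A", 7), a2 = list("B", 9), a3 = list("A", 5)),
    conf = list(a1 = list("A", 7), a2 = list("B", 9)),
    tie = list(a1 = list("B", 7), a2 = list("A", 7)),
    solo = list(a1 = list("C", 4))))
  m <- merge_labels(recs)
  m <- m[match(c("maj", "conf", "tie", "solo"), m$doc_id), ]
  expect_identical(m$category, c("A", "B", "A", "C"))
  expect_identical(m$rule_used, c("majority", "confidence", "tie_broken", "single"))
  expect_identical(nrow(m), length(unique(recs$doc_id)))
})

test_that("merged output covers exactly the documents with retained records", {
  set.seed(11)
  for (i in 1:20) {
    tab <- random_annotation_table(n_docs = 12L)
    kept <- filter_by_confidence(tab, default_threshold = 6L)
    if (nrow(kept) == 0L) next
    m <- merge_labels(kept)
    expect_setequal(m$doc_id, unique(kept$doc_id))
  }
})

test_that("category counts report totals and majority share", {
  cc <- category_counts(rep(c("A", "B"), c(3, 1)))
  expect_identical(cc$total, 4L)
  expect_equal(cc$majority_share_pct, 75.0)
  expect_equal(category_counts(rep("A", 5))$majority_share_pct, 100.0)
})

test_that("annotation tables round-trip through CSV", {
  tab <- random_annotation_table()
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tab, path, row.names = FALSE)
  back <- read_annotations(path)
  expect_identical(back$category, tab$category)
  expect_identical(back$confidence, tab$confidence)
  expect_error(read_annotations(path, label_set = "A"), "unknown category")
})
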