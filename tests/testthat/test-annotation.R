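ann_fixture <- function() {
  data.frame(
    contig_id = paste0("contig", 1:8),
    description = c("sperm autoantigenic protein 17",
                    "",
                    "sexual dimorphism gene",
                    "testis-specific serine kinase",
                    "vitellogenin a precursor, eggs",
                    "heat shock protein 70",
                    "Ovary-Specific Transcript",
                    "malexpressin pseudogene"),
    length_bp = c(800, 120, 640, 900, 1500, 700, 450, 300),
    stringsAsFactors = FALSE)
}

test_that("keyword selection honours word boundaries, plurals and case", {
  sel <- keyword_select(ann_fixture())
  expect_setequal(sel$contig_id, c("contig1", "contig4", "contig5", "contig7"))
  expect_equal(sel$matched_keywords[sel$contig_id == "contig1"], "sperm")
  expect_equal(sel$matched_keywords[sel$contig_id == "contig4"], "testis")
  expect_equal(sel$matched_keywords[sel$contig_id == "contig5"], "egg")
  expect_equal(sel$matched_keywords[sel$contig_id == "contig7"], "ovary")

  # substring mode also catches embedded keywords ("sexual", "malexpressin")
  sub <- keyword_select(ann_fixture(), mode = "substring")
  expect_true(all(c("contig3", "contig8") %in% sub$contig_id))
  expect_false("contig3" %in% sel$contig_id)
  expect_false("contig2" %in% sub$contig_id)   # empty description never matches
})

test_that("keyword selection is a subset, idempotent and order-invariant", {
  recs <- ann_fixture()
  sel <- keyword_select(recs)
  expect_true(all(sel$contig_id %in% recs$contig_id))
  again <- keyword_select(sel[, c("contig_id", "description", "length_bp")])
  expect_equal(again$contig_id, sel$contig_id)
  shuffled <- recs[rev(seq_len(nrow(recs))), ]
  expect_setequal(keyword_select(shuffled)$contig_id, sel$contig_id)
  expect_error(keyword_select(recs, character(0)), "empty")
  expect_error(keyword_select(recs, c("sex", "Sex")), "duplicate")
})

test_that("length-annotation profile bins conserve records", {
  recs <- data.frame(contig_id = paste0("c", 1:100),
                     length_bp = seq(100, 1090, by = 10))
  all_on <- length_annotation_profile(recs, rep(TRUE, 100), 100)
  expect_true(all(all_on$frac_annotated == 1))
  expect_equal(sum(all_on$n_contigs), 100)

  step <- length_annotation_profile(recs, recs$length_bp >= 500, 100)
  expect_true(all(step$frac_annotated[step$bin_start < 500] == 0))
  expect_true(all(step$frac_annotated[step$bin_start >= 500] == 1))

  # logistic annotation probability -> broadly increasing binned fractions
  set.seed(8)
  n <- 4000
  len <- sample(100:2000, n, replace = TRUE)
  pr <- plogis((len - 800) / 200)
  prof <- length_annotation_profile(
    data.frame(contig_id = paste0("s", 1:n), length_bp = len),
    runif(n) < pr, 200)
  expect_equal(sum(prof$n_contigs), n)
  expect_true(all(diff(prof$frac_annotated) > -0.15))
  expect_error(length_annotation_profile(recs, rep(TRUE, 100), 10), ">= 50")
})

test_that("category counts enumerate distinct contigs per category", {
  recs <- ann_fixture()
  map <- list(gametes = c("sperm", "egg"),
              gonad = c("testis", "ovary"),
              chaperone = "heat shock")
  got <- category_counts(recs, map)
  # hand enumeration over the 8 fixture rows:
  #  gametes: contig1 (sperm), contig5 (eggs) -> 2
  #  gonad:   contig4 (testis), contig7 (ovary) -> 2
  #  chaperone: "heat shock" is two tokens, word mode finds neither -> 0
  expect_equal(got$n_contigs, c(2L, 2L, 0L))
  sub <- category_counts(recs, list(hs = "heat shock"), mode = "substring")
  expect_equal(sub$n_contigs, 1L)

  both <- category_counts(recs, list(a = "sperm", b = c("sperm", "protein")))
  expect_equal(both$n_contigs, c(1L, 2L))      # a contig may hit both lists
  empty <- category_counts(recs[0, ], map)
  expect_equal(empty$n_contigs, c(0L, 0L, 0L))
  expect_error(category_counts(recs, setNames(list("x", "y"), c("a", "a"))),
               "unique")
})
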