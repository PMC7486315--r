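test_that("the packaged key parses with the printed structure", {
  expect_equal(length(key$couplets), 11L)
  expect_equal(sort(as.integer(names(key$couplets))), 1:11)
  expect_equal(length(key$taxa), 12L)
  expect_setequal(key$taxa, names(terminals))
  for (cp in key$couplets) expect_length(cp$leads, 2L)
})

test_that("structurally broken keys are rejected", {
  mk <- function(...) list(name = "k", couplets = list(...))
  lead <- function(out, v = 1) {
    o <- list(text = "x", predicates = list(list(
      structure = "calyx", property = "length", comparator = ">",
      value = v, unit = "mm")))
    c(o, out)
  }
  # missing goto target
  p <- write_key_doc(mk(list(id = 1, leads = list(lead(list(goto = 99)),
                                                  lead(list(taxon = "A"))))))
  expect_error(read_key(p), "missing couplet", class = "arenosae_bad_key")
  # cycle back to the entry couplet
  p2 <- write_key_doc(mk(
    list(id = 1, leads = list(lead(list(goto = 2)), lead(list(taxon = "A")))),
    list(id = 2, leads = list(lead(list(goto = 1)), lead(list(taxon = "B"))))))
  expect_error(read_key(p2), "cycle", class = "arenosae_bad_key")
  # a couplet must have exactly two leads
  p3 <- write_key_doc(mk(list(id = 1, leads = list(lead(list(taxon = "A"))))))
  expect_error(read_key(p3), "exactly 2", class = "arenosae_bad_key")
  # unreachable couplet
  p4 <- write_key_doc(mk(
    list(id = 1, leads = list(lead(list(taxon = "A")),
                              lead(list(taxon = "B")))),
    list(id = 2, leads = list(lead(list(taxon = "C")),
                              lead(list(taxon = "D"))))))
  expect_error(read_key(p4), "unreachable", class = "arenosae_bad_key")
})

test_that("predicate evaluation is three-valued with policy semantics", {
  g <- descs[["Silene georgievskyi"]]
  pcal <- list(structure = "calyx", property = "length", comparator = ">",
               value = 20, unit = "mm")
  for (mode in c("strict-range", "midpoint", "overlap"))
    expect_equal(eval_predicate(g, pcal, ont, satisfaction_policy(mode)),
                 "true")
  plow <- list(structure = "calyx", property = "length", comparator = "<",
               value = 10, unit = "mm")
  expect_equal(eval_predicate(descs[["Silene striata"]], plow, ont), "false")
  # anthophore 5.0-6.0 mm against "< 6 mm" separates the three modes
  cyp <- descs[["Silene microsperma subsp. cypria"]]
  p6 <- list(structure = "anthophore", property = "length", comparator = "<",
             value = 6, unit = "mm")
  expect_equal(eval_predicate(cyp, p6, ont,
                              satisfaction_policy("strict-range")), "false")
  expect_equal(eval_predicate(cyp, p6, ont, satisfaction_policy("midpoint")),
               "true")
  expect_equal(eval_predicate(cyp, p6, ont, satisfaction_policy("overlap")),
               "true")
  # unrecorded slot is unknown, not false
  punk <- list(structure = "seed", property = "width", comparator = ">",
               value = 1, unit = "mm")
  expect_equal(eval_predicate(descs[["Silene striata"]], punk, ont),
               "unknown")
  # units convert before comparison
  pcm <- list(structure = "calyx", property = "length", comparator = ">",
              value = 2, unit = "cm")
  expect_equal(eval_predicate(g, pcm, ont), "true")
  # incompatible comparator and property kind is an error
  pbad <- list(structure = "calyx", property = "length",
               comparator = "state-in", states = "pink")
  expect_error(eval_predicate(g, pbad, ont),
               class = "arenosae_bad_predicate")
  # relative predicates: obviously-longer-than entails longer-than
  prel <- list(structure = "internode[position=uppermost]",
               property = "relative-length", comparator = "relative-is",
               relation = "longer-than")
  expect_equal(eval_predicate(g, prel, ont), "true")
  expect_equal(eval_predicate(cyp, prel, ont), "false")
})

test_that("policy truth sets are nested: strict within midpoint within overlap", {
  set.seed(7)
  rank3 <- c("strict-range" = 1, "midpoint" = 2, "overlap" = 3)
  for (i in seq_len(300)) {
    r <- rand_range()
    d <- mini_desc("x", list(descriptive_element("calyx", "length", r)))
    p <- list(structure = "calyx", property = "length",
              comparator = sample(c("<", ">"), 1),
              value = round(stats::runif(1, 0, 50), 1), unit = "mm")
    res <- vapply(names(rank3), function(m)
      eval_predicate(d, p, ont, satisfaction_policy(m)), character(1))
    if (res[["strict-range"]] == "true") expect_equal(res[["midpoint"]],
                                                      "true")
    if (res[["midpoint"]] == "true") expect_equal(res[["overlap"]], "true")
  }
})

test_that("evaluation terminates at the printed couplets for the worked examples", {
  tr <- evaluate_key(descs[["Silene georgievskyi"]], key, ont)
  expect_identical(tr$outcomes, "Silene georgievskyi")
  expect_equal(tr$terminal_couplets[["Silene georgievskyi"]], 3L)
  expect_equal(tr$visited$couplet, c(1L, 2L, 3L))
  tr2 <- evaluate_key(descs[["Silene exsudans"]], key, ont)
  expect_identical(tr2$outcomes, "Silene exsudans")
  expect_equal(tr2$terminal_couplets[["Silene exsudans"]], 1L)
})

test_that("an all-unknown description reaches every terminal taxon", {
  empty <- mini_desc("mystery", list())
  tr <- evaluate_key(empty, key, ont)
  expect_setequal(tr$outcomes, key$taxa)
  expect_equal(nrow(tr$visited), 11L)
  # under fail handling the walk stops without outcomes instead
  trf <- evaluate_key(empty, key, ont,
                      satisfaction_policy(unknown_handling = "fail"))
  expect_length(trf$outcomes, 0L)
})

test_that("every terminal taxon's description contains it in the outcome set", {
  audit <- check_key_consistency(key, terminals, ont)
  expect_true(all(audit$membership))
  expect_equal(nrow(audit), 12L)
  expect_error(check_key_consistency(key, terminals[-1], ont),
               class = "arenosae_bad_key")
})

test_that("trace outcomes are invariant under couplet renumbering", {
  lead <- function(cmp, v, out) c(list(text = "x", predicates = list(list(
    structure = "anthophore", property = "length", comparator = cmp,
    value = v, unit = "mm"))), out)
  doc1 <- list(name = "k", couplets = list(
    list(id = 1, leads = list(lead(">", 6, list(goto = 2)),
                              lead("<", 6, list(taxon = "shortling")))),
    list(id = 2, leads = list(lead(">", 12, list(taxon = "longling")),
                              lead("<", 12, list(taxon = "midling"))))))
  doc2 <- list(name = "k", couplets = list(
    list(id = 40, leads = list(lead(">", 12, list(taxon = "longling")),
                               lead("<", 12, list(taxon = "midling")))),
    list(id = 7, leads = list(lead(">", 6, list(goto = 40)),
                              lead("<", 6, list(taxon = "shortling"))))))
  k1 <- read_key(write_key_doc(doc1))
  k2 <- read_key(write_key_doc(doc2))
  for (len in list(c(2, 4), c(8, 10), c(14, 15))) {
    d <- mini_desc("x", list(descriptive_element("anthophore", "length",
                                                 quant_range(len[1],
                                                             len[2]))))
    expect_identical(evaluate_key(d, k1, ont)$outcomes,
                     evaluate_key(d, k2, ont)$outcomes)
  }
})

test_that("the audit flags couplets whose two leads both admit a taxon", {
  lead <- function(v, out) c(list(text = "x", predicates = list(list(
    structure = "calyx", property = "length", comparator = ">",
    value = v, unit = "mm"))), out)
  doc <- list(name = "k", couplets = list(
    list(id = 1, leads = list(lead(5, list(taxon = "A")),
                              lead(5, list(taxon = "B"))))))
  k <- read_key(write_key_doc(doc))
  ds <- list(A = mini_desc("A", list(descriptive_element(
    "calyx", "length", quant_range(8, 10)))),
    B = mini_desc("B", list(descriptive_element(
      "calyx", "length", quant_range(9, 12)))))
  audit <- check_key_consistency(k, ds, ont)
  expect_true(all(audit$ambiguous_couplets == "1"))
  expect_true(all(audit$membership))
  # and membership failure is reported when a lead contradicts its taxon
  ds$A <- mini_desc("A", list(descriptive_element(
    "calyx", "length", quant_range(1, 2))))
  audit2 <- check_key_consistency(
    k, ds, ont, satisfaction_policy(unknown_handling = "fail"))
  expect_false(audit2$membership[audit2$taxon == "A"])
})
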