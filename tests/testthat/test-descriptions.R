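test_that("every packaged description validates with zero findings", {
  for (d in descs) {
    rep <- validate_description(d, tpl, ont)
    expect_equal(nrow(rep), 0L, info = d$taxon)
  }
})

test_that("validation reports malformed scores and units as findings", {
  bad <- mini_desc("broken", list(
    descriptive_element("calyx", "length",
                        structure(list(extreme_low = NULL, main_low = 14,
                                       main_high = 10, extreme_high = NULL,
                                       unit = "mm"), class = "quant_range")),
    descriptive_element("anthophore", "length", quant_range(1, 2, unit = "kg")),
    descriptive_element("calyx", "shape", qual_score("rhomboid"),
                        modifiers = list(list(kind = "temporal",
                                              value = "at-anthesis")))))
  rep <- validate_description(bad, tpl, ont)
  expect_true(any(grepl("malformed range", rep$message)))
  expect_true(any(grepl("unit not permitted", rep$message)))
  expect_true(any(grepl("unknown state", rep$message)))
  # duplicate slot in the same modifier context
  dup <- mini_desc("dup", list(
    descriptive_element("calyx", "length", quant_range(1, 2)),
    descriptive_element("calyx", "length", quant_range(2, 3))))
  expect_true(any(grepl("duplicate", validate_description(dup, tpl,
                                                          ont)$message)))
})

test_that("fixture serialisation is canonical and byte-stable", {
  files <- list.files(arenosae_file("descriptions"), full.names = TRUE)
  for (f in files) {
    d <- read_description(f)
    txt <- write_description(d, tpl)
    expect_identical(txt, paste(readLines(f, encoding = "UTF-8"),
                                collapse = "\n"), info = basename(f))
    # read(write(read(x))) is a fixed point
    p <- tempfile(fileext = ".json")
    write_description(d, tpl, path = p)
    expect_identical(write_description(read_description(p), tpl), txt)
  }
})

test_that("constant-feature intersection follows the policy semantics", {
  a <- mini_desc("a", list(
    descriptive_element("style", "number", quant_range(3, 3, unit = "count")),
    descriptive_element("calyx", "length", quant_range(10, 14))))
  b <- mini_desc("b", list(
    descriptive_element("style", "number", quant_range(3, 3, unit = "count")),
    descriptive_element("calyx", "length", quant_range(9, 13))))
  strict <- intersect_constant(list(a, b), ont, policy = "strict")
  expect_equal(length(strict$elements), 1L)
  expect_equal(strict$elements[[1]]$property, "number")
  encl <- intersect_constant(list(a, b), ont, policy = "enclosing")
  calyx <- Filter(function(e) e$structure == "calyx", encl$elements)[[1]]
  expect_equal(calyx$provenance, "hull")
  expect_equal(c(calyx$score$main_low, calyx$score$main_high), c(9, 14))
  # slots unknown in any input are excluded
  c3 <- mini_desc("c", list(
    descriptive_element("calyx", "length", quant_range(10, 14))))
  expect_equal(length(intersect_constant(list(a, b, c3), ont)$elements), 0L)
  expect_error(intersect_constant(list(a, taxon_description(
    "x", "species", list(), template = "other")), ont),
    class = "arenosae_mixed_templates")
})

test_that("strict intersection is commutative and associative", {
  g <- gen_descriptions(n_taxa = 4, n_chars = 12, constant_fraction = 0.5,
                        seed = 11)
  ds <- g$taxa
  i1 <- intersect_constant(ds, g$ontology)
  i2 <- intersect_constant(rev(ds), g$ontology)
  sig <- function(x) write_description(x, g$template)
  expect_identical(sort(vapply(i1$elements, arenosae:::de_key, character(1))),
                   sort(vapply(i2$elements, arenosae:::de_key, character(1))))
  # associativity: pairwise fold equals joint intersection
  fold <- intersect_constant(list(intersect_constant(ds[1:2], g$ontology),
                                  intersect_constant(ds[3:4], g$ontology)),
                             g$ontology)
  expect_identical(sort(vapply(fold$elements, arenosae:::de_key,
                               character(1))),
                   sort(vapply(i1$elements, arenosae:::de_key, character(1))))
})

test_that("factor and expand are inverse on synthetic parent/child sets", {
  for (seed in c(2, 9, 23)) {
    g <- gen_descriptions(n_taxa = 3, n_chars = 10, constant_fraction = 0.4,
                          seed = seed)
    for (child in g$taxa) {
      f <- factor_descriptions(g$parent, list(child), g$ontology)[[1]]
      # factoring strips exactly the constant slots
      expect_equal(length(f$elements),
                   length(child$elements) - length(g$parent$elements))
      back <- expand_description(f, g$parent, g$template)
      expect_identical(write_description(back, g$template),
                       write_description(child, g$template))
      # and factoring the expanded child restores the factored form
      f2 <- factor_descriptions(g$parent, list(back), g$ontology)[[1]]
      expect_identical(write_description(f2, g$template),
                       write_description(f, g$template))
    }
  }
})

test_that("conflicting child elements survive factoring", {
  parent <- mini_desc("p", list(
    descriptive_element("style", "number", quant_range(3, 3, unit = "count")),
    descriptive_element("calyx", "length", quant_range(10, 16))))
  child <- mini_desc("c", list(
    descriptive_element("style", "number", quant_range(3, 3, unit = "count")),
    descriptive_element("calyx", "length", quant_range(25, 30))))
  f <- factor_descriptions(parent, list(child), ont)[[1]]
  expect_equal(length(f$elements), 1L)
  expect_equal(f$elements[[1]]$structure, "calyx")
  # on expansion the child's conflicting score wins
  back <- expand_description(f, parent, tpl)
  calyx <- Filter(function(e) e$structure == "calyx", back$elements)[[1]]
  expect_equal(calyx$score$main_low, 25)
})

test_that("diff classifies slots into only/conflict sets", {
  a <- descs[["Silene arenosa"]]
  expect_equal(nrow(diff_descriptions(a, a, ont)), 0L)
  d <- diff_descriptions(a, descs[["Silene leyseroides"]], ont)
  conflicts <- d$slot[d$status == "conflict"]
  expect_true(any(grepl("anthophore :: indumentum", conflicts)))
  expect_true(any(grepl("anthophore :: length", conflicts)))
  a2 <- a
  a2$elements <- a2$elements[-1]
  d2 <- diff_descriptions(a, a2, ont)
  expect_equal(sum(d2$status == "only-A"), 1L)
  expect_equal(sum(d2$status == "only-B"), 0L)
})

test_that("query returns printed scores, unknowns, and converted units", {
  g <- descs[["Silene georgievskyi"]]
  sc <- query_description(g, "anthophore", "length", ont, unit = "mm")
  expect_equal(c(sc$main_low, sc$main_high), c(13, 16))
  expect_null(query_description(descs[["Silene striata"]], "seed", "width",
                                ont))
  up <- query_description(descs[["Silene arenosa"]],
                          "internode[position=uppermost]", "length", ont,
                          unit = "mm")
  expect_equal(c(up$main_low, up$main_high), c(15, 40))
  expect_error(query_description(g, "anthophore", "length", ont,
                                 unit = "furlong"),
               class = "arenosae_unknown_unit")
})

test_that("query is unit-covariant across the registry", {
  for (d in descs) for (e in d$elements) {
    if (!inherits(e$score, "quant_range") ||
        identical(e$score$unit, "count")) next
    mm <- query_description(d, e$structure, e$property, ont, unit = "mm",
                            modifiers = e$modifiers)
    cm <- query_description(d, e$structure, e$property, ont, unit = "cm",
                            modifiers = e$modifiers)
    expect_equal(cm$main_low * 10, mm$main_low)
    expect_equal(cm$main_high * 10, mm$main_high)
  }
})
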