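# Descriptive elements and taxon descriptions.
#
# A descriptive element (DE) is structure + property + one score
# (+ modifiers).  Scores are quantitative ranges with optional parenthetical
# extremes, sets of alternative qualitative states, relative comparisons
# against another structure, or integer count ranges.  Absence of a slot
# means "not recorded", never "absent organ"; downstream logic is
# three-valued.

#' Quantitative range score
#'
#' Ranges follow the printed convention `(extreme_low–)main_low–main_high
#' (–extreme_high)`, e.g. a calyx of "(8.0–)9.0–13.0(–14.0) mm".  Extremes
#' are optional; `extreme_low <= main_low <= main_high <= extreme_high` must
#' hold where present.  Counts use the reserved unit `"count"` with integer
#' bounds.
#'
#' @param main_low,main_high main range bounds.
#' @param unit unit token (`"mm"`, `"cm"`, or `"count"`).
#' @param extreme_low,extreme_high optional extreme bounds.
#' @return a `quant_range`.
#' @export
quant_range <- function(main_low, main_high, unit = "mm",
                        extreme_low = NULL, extreme_high = NULL) {
  r <- structure(list(extreme_low = extreme_low, main_low = main_low,
                      main_high = main_high, extreme_high = extreme_high,
                      unit = unit), class = "quant_range")
  check_quant_range(r)
  r
}

check_quant_range <- function(r) {
  b <- c(r$extreme_low, r$main_low, r$main_high, r$extreme_high)
  if (anyNA(b) || is.unsorted(b))
    abort("malformed range: bounds must be ordered", "arenosae_bad_range")
  invisible(r)
}

#' Qualitative score: a set of alternative states
#' @param states non-empty character vector; alternatives ("A or B").
#' @return a `qual_score`.
#' @export
qual_score <- function(states) {
  stopifnot(is.character(states), length(states) >= 1L)
  structure(list(states = states), class = "qual_score")
}

#' Relative score: comparison against another structure
#' @param relation one of `"longer-than"`, `"obviously-longer-than"`,
#'   `"equal-to"`, `"shorter-than"`.
#' @param reference structure path of the reference structure.
#' @return a `relative_score`.
#' @export
relative_score <- function(relation, reference) {
  relation <- match.arg(relation, RELATIVE_RELATIONS)
  structure(list(relation = relation, reference = reference),
            class = "relative_score")
}

score_type <- function(s) {
  if (inherits(s, "quant_range"))
    return(if (identical(s$unit, "count")) "count" else "range")
  if (inherits(s, "qual_score")) return("states")
  if (inherits(s, "relative_score")) return("relative")
  abort("unknown score object", "arenosae_bad_score")
}

#' Descriptive element
#'
#' @param structure structure path string (canonicalised against the
#'   ontology during validation).
#' @param property property name.
#' @param score a [quant_range()], [qual_score()] or [relative_score()].
#' @param modifiers list of `list(kind=, value=)` modifiers.
#' @param provenance optional flag, e.g. `"supplemented"` for characters
#'   taken from key leads or remarks rather than the formal account.
#' @return a `descriptive_element`.
#' @export
descriptive_element <- function(structure, property, score,
                                modifiers = list(), provenance = NULL) {
  structure(list(structure = structure, property = property, score = score,
                 modifiers = modifiers, provenance = provenance),
            class = "descriptive_element")
}

# modifier context: temporal + spatial modifiers identify distinct DEs on the
# same slot ("cylindrical at anthesis" vs "clavate in fruit")
modifier_context <- function(modifiers) {
  if (length(modifiers) == 0L) return("")
  ctx <- vapply(modifiers, function(m)
    if (m$kind %in% c("temporal", "spatial"))
      paste0(m$kind, "=", m$value) else "", character(1))
  paste(sort(ctx[nzchar(ctx)]), collapse = ";")
}

de_key <- function(de) paste0(slot_key(de$structure, de$property), " @ ",
                              modifier_context(de$modifiers))

#' Taxon description
#'
#' @param taxon taxon name.
#' @param rank `"section"`, `"species"` or `"subspecies"`.
#' @param elements ordered list of [descriptive_element()]s.
#' @param parent parent taxon name, if any.
#' @param template name of the template the description conforms to.
#' @return a `taxon_description`.
#' @export
taxon_description <- function(taxon, rank, elements, parent = NULL,
                              template = NULL) {
  rank <- match.arg(rank, c("section", "species", "subspecies"))
  structure(list(taxon = taxon, rank = rank, parent = parent,
                 template = template, elements = elements),
            class = "taxon_description")
}

#' @export
print.taxon_description <- function(x, ...) {
  cat("<taxon_description> ", x$taxon, " (", x$rank, "), ",
      length(x$elements), " elements\n", sep = "")
  invisible(x)
}

score_from_json <- function(sc) {
  switch(sc$type %||% "range",
    range = ,
    count = quant_range(sc$main_low, sc$main_high,
                        unit = sc$unit %||% if (identical(sc$type, "count"))
                          "count" else "mm",
                        extreme_low = sc$extreme_low,
                        extreme_high = sc$extreme_high),
    states = qual_score(unlist(sc$states)),
    relative = relative_score(sc$relation, sc$reference),
    abort(paste0("unknown score type '", sc$type, "'"), "arenosae_bad_score"))
}

score_to_json <- function(s) {
  switch(score_type(s),
    range = Filter(Negate(is.null),
                   list(type = "range", extreme_low = s$extreme_low,
                        main_low = s$main_low, main_high = s$main_high,
                        extreme_high = s$extreme_high, unit = s$unit)),
    count = Filter(Negate(is.null),
                   list(type = "count", extreme_low = s$extreme_low,
                        main_low = s$main_low, main_high = s$main_high,
                        extreme_high = s$extreme_high)),
    states = list(type = "states", states = as.list(sort(s$states))),
    relative = list(type = "relative", relation = s$relation,
                    reference = s$reference))
}

#' Read a taxon description document
#'
#' @param path JSON description document.
#' @return a `taxon_description`.
#' @export
read_description <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  els <- lapply(doc$elements, function(e)
    descriptive_element(nfc(e$structure), nfc(e$property),
                        score_from_json(e$score),
                        modifiers = lapply(e$modifiers %||% list(), function(m)
                          list(kind = m$kind, value = m$value)),
                        provenance = e$provenance))
  taxon_description(nfc(doc$taxon), doc$rank, els, parent = nfc(doc$parent),
                    template = doc$template)
}

#' Write a taxon description in canonical serialisation
#'
#' Canonical form: elements sorted by template slot order (then modifier
#' context), JSON keys in fixed order, state sets sorted.  Canonical output
#' is byte-stable: writing what was read back yields identical bytes, which
#' is what the factoring round-trip tests compare.
#'
#' @param desc a `taxon_description`.
#' @param template optional `description_template` giving slot order.
#' @param path file to write; omit to return the JSON text.
#' @return path invisibly, or JSON string.
#' @export
write_description <- function(desc, template = NULL, path = NULL) {
  els <- desc$elements
  if (!is.null(template)) els <- order_elements(els, template)
  doc <- Filter(Negate(is.null), list(
    taxon = desc$taxon, rank = desc$rank, parent = desc$parent,
    template = desc$template,
    elements = lapply(els, function(e) Filter(Negate(is.null), list(
      structure = e$structure, property = e$property,
      score = score_to_json(e$score),
      modifiers = if (length(e$modifiers))
        lapply(e$modifiers[order(vapply(e$modifiers, function(m)
          paste(m$kind, m$value), character(1)))],
          function(m) list(kind = m$kind, value = m$value)),
      provenance = e$provenance)))))
  txt <- as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = 2L,
                                       digits = NA, null = "null"))
  if (is.null(path)) return(txt)
  writeLines(txt, path, useBytes = TRUE)
  invisible(path)
}

order_elements <- function(elements, template) {
  idx <- template_slot_index(template)
  pos <- vapply(elements, function(e) {
    i <- idx[slot_key(e$structure, e$property)]
    if (is.na(i)) Inf else as.numeric(i)
  }, numeric(1))
  ctx <- vapply(elements, function(e) modifier_context(e$modifiers),
                character(1))
  elements[order(pos, ctx)]
}

convert_unit <- function(value, from, to, ontology) {
  if (identical(from, to)) return(value)
  uf <- ontology$units[[from]]; ut <- ontology$units[[to]]
  if (is.null(uf) || is.null(ut))
    abort(paste0("unknown unit '", if (is.null(uf)) from else to, "'"),
          "arenosae_unknown_unit")
  if (!identical(uf$dim, ut$dim))
    abort(paste0("cannot convert ", from, " to ", to), "arenosae_unknown_unit")
  value * uf$factor / ut$factor
}

convert_range <- function(r, to, ontology) {
  cv <- function(x) if (is.null(x)) NULL else convert_unit(x, r$unit, to,
                                                           ontology)
  quant_range(cv(r$main_low), cv(r$main_high), unit = to,
              extreme_low = cv(r$extreme_low), extreme_high = cv(r$extreme_high))
}

#' Validate a description against a template
#'
#' Findings are data, not errors: the report lists unknown slots, structure
#' paths that do not resolve, score kinds that do not match the property
#' kind, states outside the property's vocabulary, units outside the
#' registry, malformed ranges, disallowed modifier values, duplicate
#' (slot, modifier-context) pairs, and element order inconsistent with the
#' template.  An empty report means the description is valid.
#'
#' @param desc a `taxon_description`.
#' @param template a `description_template`.
#' @param ontology the `ontology` behind the template.
#' @return a `validation_report` (data frame of severity, slot, message).
#' @export
validate_description <- function(desc, template, ontology) {
  findings <- list()
  add <- function(severity, slot, message)
    findings[[length(findings) + 1L]] <<-
      data.frame(severity = severity, slot = slot, message = message)
  idx <- template_slot_index(template)
  seen <- character()
  last_pos <- 0
  for (e in desc$elements) {
    slot <- slot_key(e$structure, e$property)
    ref <- tryCatch(resolve_structure_ref(ontology, e$structure),
                    arenosae_error = function(c) c)
    if (inherits(ref, "condition")) {
      add("error", slot, conditionMessage(ref)); next
    }
    prop <- ontology$properties[[e$property]]
    if (is.null(prop)) {
      add("error", slot, paste0("unknown property '", e$property, "'")); next
    }
    i <- idx[slot]
    if (is.na(i)) add("error", slot, "slot not in template")
    else {
      if (i < last_pos) add("warning", slot, "element out of template order")
      last_pos <- max(last_pos, i)
    }
    st <- score_type(e$score)
    kind_ok <- switch(prop$kind, qualitative = st == "states",
                      quantitative = st %in% c("range", "relative"),
                      count = st == "count",
                      relative = st == "relative")
    if (!kind_ok)
      add("error", slot, paste0("score kind '", st,
                                "' does not match ", prop$kind,
                                " property"))
    if (st == "range") {
      u <- ontology$units[[e$score$unit]]
      if (is.null(u) || !identical(u$dim, "length"))
        add("error", slot, paste0("unit not permitted: '", e$score$unit, "'"))
      bad <- tryCatch({check_quant_range(e$score); NULL},
                      arenosae_error = function(c) conditionMessage(c))
      if (!is.null(bad)) add("error", slot, "malformed range")
    }
    if (st == "count") {
      b <- c(e$score$main_low, e$score$main_high)
      if (any(b < 0) || any(b != floor(b)))
        add("error", slot, "count must use non-negative integer bounds")
    }
    if (st == "states" && kind_ok) {
      bad <- setdiff(e$score$states, prop$states)
      if (length(bad))
        add("error", slot, paste0("unknown state(s): ",
                                  paste(bad, collapse = ", ")))
    }
    if (st == "relative") {
      r <- tryCatch(resolve_structure_ref(ontology, e$score$reference),
                    arenosae_error = function(c) c)
      if (inherits(r, "condition")) add("error", slot, conditionMessage(r))
    }
    for (m in e$modifiers) {
      vocab <- ontology$modifiers[[m$kind]]
      if (is.null(vocab))
        add("error", slot, paste0("unknown modifier kind '", m$kind, "'"))
      else if (!m$value %in% vocab)
        add("error", slot, paste0("modifier value '", m$value,
                                  "' not permitted for kind '", m$kind, "'"))
    }
    k <- de_key(e)
    if (k %in% seen)
      add("error", slot, "duplicate element for slot and modifier context")
    seen <- c(seen, k)
  }
  rep <- if (length(findings)) do.call(rbind, findings)
         else data.frame(severity = character(), slot = character(),
                         message = character())
  structure(rep, class = c("validation_report", "data.frame"))
}

#' @export
print.validation_report <- function(x, ...) {
  if (nrow(x) == 0L) cat("<validation_report> valid (no findings)\n")
  else {
    cat("<validation_report> ", nrow(x), " finding(s)\n", sep = "")
    print.data.frame(x)
  }
  invisible(x)
}

scores_equal <- function(a, b, ontology) {
  ta <- score_type(a); tb <- score_type(b)
  if (!identical(ta, tb)) return(FALSE)
  if (ta %in% c("range", "count")) {
    to <- if (ta == "count") "count" else "mm"
    a <- convert_range(a, to, ontology); b <- convert_range(b, to, ontology)
    same <- function(x, y) (is.null(x) && is.null(y)) ||
      (!is.null(x) && !is.null(y) && isTRUE(all.equal(x, y)))
    return(same(a$extreme_low, b$extreme_low) && same(a$main_low, b$main_low) &&
           same(a$main_high, b$main_high) &&
           same(a$extreme_high, b$extreme_high))
  }
  if (ta == "states") return(setequal(a$states, b$states))
  identical(a$relation, b$relation) && identical(a$reference, b$reference)
}

modifiers_equal <- function(a, b) {
  key <- function(ms) sort(vapply(ms, function(m) paste0(m$kind, "=", m$value),
                                  character(1)))
  identical(key(a), key(b))
}

elements_equal <- function(a, b, ontology) {
  identical(a$structure, b$structure) && identical(a$property, b$property) &&
    modifiers_equal(a$modifiers, b$modifiers) &&
    scores_equal(a$score, b$score, ontology)
}

element_map <- function(desc) {
  m <- list()
  for (e in desc$elements) m[[de_key(e)]] <- e
  m
}

#' Intersection of constant features across descriptions
#'
#' Returns a description containing, for every slot recorded in *all*
#' inputs, the shared score: identical state sets for qualitative slots,
#' identical ranges (policy `"strict"`) or their enclosing hull flagged
#' `"hull"` (policy `"enclosing"`) for quantitative slots, identical values
#' for counts and relative scores.  Slots unknown in any input are excluded.
#' Under the strict policy the operation is commutative and associative.
#'
#' @param descs list of `taxon_description`s sharing one template.
#' @param ontology the shared `ontology`.
#' @param policy `"strict"` or `"enclosing"`.
#' @param taxon name for the resulting description.
#' @return a `taxon_description` of rank `"section"`.
#' @export
intersect_constant <- function(descs, ontology, policy = c("strict",
                                                           "enclosing"),
                               taxon = "constant features") {
  policy <- match.arg(policy)
  stopifnot(length(descs) >= 2L)
  tmpl <- unique(vapply(descs, function(d) d$template %||% "", character(1)))
  if (length(tmpl) != 1L)
    abort("descriptions use mixed templates", "arenosae_mixed_templates")
  maps <- lapply(descs, element_map)
  keys <- names(maps[[1]])
  out <- list()
  for (k in keys) {
    es <- lapply(maps, `[[`, k)
    if (any(vapply(es, is.null, logical(1)))) next
    first <- es[[1]]
    if (!all(vapply(es[-1], function(e)
      modifiers_equal(e$modifiers, first$modifiers), logical(1)))) next
    st <- score_type(first$score)
    if (all(vapply(es[-1], function(e)
      scores_equal(e$score, first$score, ontology), logical(1)))) {
      out[[length(out) + 1L]] <- first
    } else if (policy == "enclosing" && st %in% c("range", "count") &&
               all(vapply(es[-1], function(e)
                 score_type(e$score) == st, logical(1)))) {
      to <- if (st == "count") "count" else first$score$unit
      rs <- lapply(es, function(e) convert_range(e$score, to, ontology))
      lo <- vapply(rs, function(r) r$extreme_low %||% r$main_low, numeric(1))
      hi <- vapply(rs, function(r) r$extreme_high %||% r$main_high, numeric(1))
      hull <- quant_range(min(vapply(rs, `[[`, numeric(1), "main_low")),
                          max(vapply(rs, `[[`, numeric(1), "main_high")),
                          unit = to,
                          extreme_low = if (min(lo) < min(vapply(rs, `[[`,
                            numeric(1), "main_low"))) min(lo),
                          extreme_high = if (max(hi) > max(vapply(rs, `[[`,
                            numeric(1), "main_high"))) max(hi))
      de <- descriptive_element(first$structure, first$property, hull,
                                modifiers = first$modifiers,
                                provenance = "hull")
      out[[length(out) + 1L]] <- de
    }
  }
  taxon_description(taxon, "section", out, template = descs[[1]]$template)
}

#' Factor constant parent features out of child descriptions
#'
#' Removes from each child every element identical (same slot, modifier
#' context, score and modifiers) to a parent element.  Inverse of
#' [expand_description()]: expanding a factored child against the same
#' parent restores it, and factoring an expanded child restores the factored
#' form — this is how the packaged accounts avoid repeating the section's
#' constant features.
#'
#' @param parent the parent (e.g. section-level) `taxon_description`.
#' @param children list of child `taxon_description`s.
#' @param ontology the shared `ontology`.
#' @return list of factored `taxon_description`s.
#' @export
factor_descriptions <- function(parent, children, ontology) {
  pm <- element_map(parent)
  lapply(children, function(ch) {
    keep <- vapply(ch$elements, function(e) {
      pe <- pm[[de_key(e)]]
      is.null(pe) || !elements_equal(e, pe, ontology)
    }, logical(1))
    ch$elements <- ch$elements[keep]
    ch
  })
}

#' Expand a factored child with its parent's features
#'
#' Merges parent elements into the child at every (slot, modifier-context)
#' the child does not record; on conflict the child's element wins.
#'
#' @param child a `taxon_description`.
#' @param parent the parent `taxon_description`.
#' @param template optional template used to re-order merged elements.
#' @return the expanded `taxon_description`.
#' @export
expand_description <- function(child, parent, template = NULL) {
  cm <- element_map(child)
  extra <- Filter(function(e) is.null(cm[[de_key(e)]]), parent$elements)
  child$elements <- c(child$elements, extra)
  if (!is.null(template))
    child$elements <- order_elements(child$elements, template)
  child
}

#' Slot-wise difference of two descriptions
#'
#' Classifies every slot (with modifier context) into `equal`, `only-A`,
#' `only-B` or `conflict`.  An empty report means the descriptions are
#' identical slot-wise.
#'
#' @param a,b `taxon_description`s sharing a template.
#' @param ontology the shared `ontology`.
#' @return a `diff_report` data frame (slot, status).
#' @export
diff_descriptions <- function(a, b, ontology) {
  ma <- element_map(a); mb <- element_map(b)
  keys <- union(names(ma), names(mb))
  status <- vapply(keys, function(k) {
    ea <- ma[[k]]; eb <- mb[[k]]
    if (is.null(eb)) "only-A"
    else if (is.null(ea)) "only-B"
    else if (elements_equal(ea, eb, ontology)) "equal"
    else "conflict"
  }, character(1))
  rep <- data.frame(slot = keys, status = unname(status))
  rep <- rep[rep$status != "equal", , drop = FALSE]
  rownames(rep) <- NULL
  structure(rep, class = c("diff_report", "data.frame"))
}

#' Query a description for one score
#'
#' Looks up the element at (structure path, property), optionally filtered
#' by modifiers; quantitative scores are converted to the requested unit.
#' Returns `NULL` (printed as unknown) when the taxon does not record the
#' slot — e.g. seed measurements of a taxon whose account says
#' "Seeds unknown.".
#'
#' @param desc a `taxon_description`.
#' @param structure structure path string.
#' @param property property name.
#' @param ontology an `ontology` (needed for unit conversion).
#' @param unit optional unit to convert quantitative scores to.
#' @param modifiers optional list of modifiers selecting a context.
#' @return the score, or `NULL` if the slot is not recorded.
#' @export
query_description <- function(desc, structure, property, ontology,
                              unit = NULL, modifiers = NULL) {
  ctx <- if (is.null(modifiers)) NULL else modifier_context(modifiers)
  hits <- Filter(function(e)
    identical(e$structure, structure) && identical(e$property, property) &&
      (is.null(ctx) || identical(modifier_context(e$modifiers), ctx)),
    desc$elements)
  if (length(hits) == 0L) return(NULL)
  sc <- hits[[1]]$score
  if (!is.null(unit) && inherits(sc, "quant_range"))
    sc <- convert_range(sc, unit, ontology)
  sc
}
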