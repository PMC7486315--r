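# Dichotomous identification key: parsing, three-valued evaluation, audits.
#
# A key is a set of numbered couplets with exactly two leads; each lead is a
# conjunction of predicates over structured descriptions and routes to
# another couplet or ends at a taxon.  Characters a description does not
# record evaluate to "unknown", and range-versus-threshold semantics are a
# policy choice, since a printed key never states them.

KEY_COMPARATORS <- c("<", ">", "<=", ">=", "state-in", "range-within",
                     "relative-is", "count-cmp")

#' Satisfaction policy for key evaluation
#'
#' Quantitative predicate semantics: `"strict-range"` requires the whole
#' main range to satisfy the comparison, `"midpoint"` tests the midpoint of
#' the main range, `"overlap"` requires some point of the main range to
#' satisfy it.  `include_extremes` widens the tested range to the
#' parenthetical extremes.  `unknown_handling` controls what happens when no
#' lead of a couplet is true: `"both-branches"` explores both and unions the
#' outcomes; `"fail"` stops with no outcome.
#'
#' @param mode `"midpoint"` (default), `"strict-range"` or `"overlap"`.
#' @param include_extremes logical.
#' @param unknown_handling `"both-branches"` or `"fail"`.
#' @return a `satisfaction_policy`.
#' @export
satisfaction_policy <- function(mode = c("midpoint", "strict-range",
                                         "overlap"),
                                include_extremes = FALSE,
                                unknown_handling = c("both-branches",
                                                     "fail")) {
  structure(list(mode = match.arg(mode),
                 include_extremes = isTRUE(include_extremes),
                 unknown_handling = match.arg(unknown_handling)),
            class = "satisfaction_policy")
}

#' Read and validate a dichotomous key document
#'
#' Structural invariants: couplet ids unique, exactly two leads per couplet,
#' every goto target exists, the couplet graph from the entry couplet is
#' acyclic and every couplet is reachable.
#'
#' @param path JSON key document.
#' @return an `identification_key`.
#' @export
read_key <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  couplets <- list()
  for (cp in doc$couplets) {
    id <- as.integer(cp$id)
    if (!is.null(couplets[[as.character(id)]]))
      abort(paste0("duplicate couplet id ", id), "arenosae_bad_key")
    if (length(cp$leads) != 2L)
      abort(paste0("couplet ", id, " must have exactly 2 leads"),
            "arenosae_bad_key")
    leads <- lapply(cp$leads, function(ld) {
      preds <- lapply(ld$predicates %||% list(), function(p) {
        cmp <- match.arg(p$comparator, KEY_COMPARATORS)
        list(structure = nfc(p$structure), property = nfc(p$property),
             comparator = cmp, value = p$value,
             unit = nfc(p$unit), states = nfc(unlist(p$states)),
             relation = nfc(p$relation),
             modifiers = lapply(p$modifiers %||% list(), function(m)
               list(kind = m$kind, value = m$value)))
      })
      if (length(preds) == 0L)
        abort(paste0("couplet ", id, " has a lead with no predicates"),
              "arenosae_bad_key")
      out <- if (!is.null(ld$taxon)) list(taxon = nfc(ld$taxon))
             else if (!is.null(ld$goto)) list(goto = as.integer(ld$goto))
             else abort(paste0("couplet ", id, " lead lacks an outcome"),
                        "arenosae_bad_key")
      list(predicates = preds, outcome = out, note = ld$note %||% NULL,
           text = ld$text %||% NULL)
    })
    couplets[[as.character(id)]] <- list(id = id, leads = leads)
  }
  ids <- as.integer(names(couplets))
  for (cp in couplets) for (ld in cp$leads)
    if (!is.null(ld$outcome$goto) && !(ld$outcome$goto %in% ids))
      abort(paste0("couplet ", cp$id, " points to missing couplet ",
                   ld$outcome$goto), "arenosae_bad_key")
  entry <- min(ids)
  # reachability + acyclicity (DFS with colouring)
  colour <- stats::setNames(rep(0L, length(ids)), as.character(ids))
  visit <- function(id) {
    key <- as.character(id)
    if (colour[[key]] == 1L)
      abort(paste0("cycle through couplet ", id), "arenosae_bad_key")
    if (colour[[key]] == 2L) return(invisible())
    colour[[key]] <<- 1L
    for (ld in couplets[[key]]$leads)
      if (!is.null(ld$outcome$goto)) visit(ld$outcome$goto)
    colour[[key]] <<- 2L
  }
  visit(entry)
  if (any(colour == 0L))
    abort(paste0("unreachable couplet(s): ",
                 paste(names(colour)[colour == 0L], collapse = ", ")),
          "arenosae_bad_key")
  taxa <- unlist(lapply(couplets, function(cp)
    lapply(cp$leads, function(ld) ld$outcome$taxon)))
  structure(list(name = doc$name %||% "key", preamble = doc$preamble %||% "",
                 entry = entry, couplets = couplets,
                 taxa = unname(taxa)), class = "identification_key")
}

#' @export
print.identification_key <- function(x, ...) {
  cat("<identification_key> '", x$name, "': ", length(x$couplets),
      " couplets, ", length(x$taxa), " terminal taxa\n", sep = "")
  invisible(x)
}

range_bounds <- function(r, policy) {
  lo <- r$main_low; hi <- r$main_high
  if (policy$include_extremes) {
    lo <- r$extreme_low %||% lo
    hi <- r$extreme_high %||% hi
  }
  c(lo, hi)
}

eval_numeric <- function(r, cmp, v, policy) {
  b <- range_bounds(r, policy); lo <- b[1]; hi <- b[2]
  mid <- (r$main_low + r$main_high) / 2
  test <- function(x) switch(cmp, "<" = x < v, ">" = x > v,
                             "<=" = x <= v, ">=" = x >= v)
  switch(policy$mode,
    "strict-range" = if (cmp %in% c("<", "<=")) test(hi) else test(lo),
    "midpoint" = test(mid),
    "overlap" = if (cmp %in% c("<", "<=")) test(lo) else test(hi))
}

eval_within <- function(r, lohi, policy) {
  b <- range_bounds(r, policy); lo <- b[1]; hi <- b[2]
  mid <- (r$main_low + r$main_high) / 2
  switch(policy$mode,
    "strict-range" = lohi[1] <= lo && hi <= lohi[2],
    "midpoint" = lohi[1] <= mid && mid <= lohi[2],
    "overlap" = hi >= lohi[1] && lo <= lohi[2])
}

tv <- function(x) {
  if (isTRUE(x)) "true" else if (isFALSE(x)) "false" else "unknown"
}

#' Evaluate one key predicate against a description
#'
#' Three-valued: `"unknown"` when the description does not record the
#' predicate's slot.  Quantitative comparisons convert both sides to the
#' property's canonical unit first.  `state-in` is true when the recorded
#' state set intersects the predicate's set.  `relative-is` matches the
#' relation, with `obviously-longer-than` entailing `longer-than`.  When
#' several modifier contexts record the slot, the predicate is true if any
#' context satisfies it.
#'
#' @param desc a `taxon_description`.
#' @param predicate a predicate list (see [read_key()]).
#' @param ontology an `ontology` for unit conversion.
#' @param policy a [satisfaction_policy()].
#' @return `"true"`, `"false"` or `"unknown"`.
#' @export
eval_predicate <- function(desc, predicate, ontology,
                           policy = satisfaction_policy()) {
  ctxwant <- predicate$modifiers %||% list()
  hits <- Filter(function(e)
    identical(e$structure, predicate$structure) &&
      identical(e$property, predicate$property) &&
      (length(ctxwant) == 0L ||
         identical(modifier_context(e$modifiers), modifier_context(ctxwant))),
    desc$elements)
  if (length(hits) == 0L) return("unknown")
  res <- vapply(hits, function(e) {
    sc <- e$score
    cmp <- predicate$comparator
    if (cmp %in% c("<", ">", "<=", ">=", "count-cmp", "range-within")) {
      if (!inherits(sc, "quant_range"))
        abort(paste0("comparator '", cmp, "' needs a quantitative score at ",
                     predicate$structure), "arenosae_bad_predicate")
      to <- if (identical(sc$unit, "count")) "count"
            else predicate$unit %||% "mm"
      r <- convert_range(sc, to, ontology)
      if (cmp == "range-within") {
        v <- unlist(predicate$value)
        return(eval_within(r, c(v[1], v[2]), policy))
      }
      if (cmp == "count-cmp") cmp <- predicate$relation %||% ">"
      return(eval_numeric(r, cmp, as.numeric(predicate$value), policy))
    }
    if (cmp == "state-in") {
      if (!inherits(sc, "qual_score"))
        abort(paste0("comparator 'state-in' needs a qualitative score at ",
                     predicate$structure), "arenosae_bad_predicate")
      return(length(intersect(sc$states, predicate$states)) > 0L)
    }
    if (cmp == "relative-is") {
      if (!inherits(sc, "relative_score"))
        abort(paste0("comparator 'relative-is' needs a relative score at ",
                     predicate$structure), "arenosae_bad_predicate")
      if (identical(predicate$relation, "longer-than"))
        return(sc$relation %in% c("longer-than", "obviously-longer-than"))
      return(identical(sc$relation, predicate$relation))
    }
    abort(paste0("unsupported comparator '", cmp, "'"),
          "arenosae_bad_predicate")
  }, logical(1))
  tv(any(res))
}

eval_lead <- function(desc, lead, ontology, policy) {
  vals <- vapply(lead$predicates, function(p)
    eval_predicate(desc, p, ontology, policy), character(1))
  if (any(vals == "false")) "false"
  else if (any(vals == "unknown")) "unknown"
  else "true"
}

#' Evaluate a description through a key
#'
#' Deterministic: at each couplet the leads whose conjunction is true are
#' followed; when no lead is true (a false/unknown mix), both leads are
#' explored under `"both-branches"` handling and the outcomes unioned, or
#' the walk stops under `"fail"`.  The trace records every couplet visit,
#' the lead(s) chosen, and for each taxon outcome the couplet it was emitted
#' at.
#'
#' @param desc a `taxon_description`.
#' @param key an `identification_key`.
#' @param ontology an `ontology`.
#' @param policy a [satisfaction_policy()].
#' @return an `evaluation_trace` with `visited`, `outcomes` and
#'   `terminal_couplets`.
#' @export
evaluate_key <- function(desc, key, ontology,
                         policy = satisfaction_policy()) {
  visited <- list()
  outcomes <- character()
  terminal <- integer()
  seen <- integer()
  walk <- function(id) {
    if (id %in% seen) return(invisible())
    seen <<- c(seen, id)
    cp <- key$couplets[[as.character(id)]]
    vals <- vapply(cp$leads, function(ld)
      eval_lead(desc, ld, ontology, policy), character(1))
    take <- if (any(vals == "true")) which(vals == "true")
            else if (policy$unknown_handling == "both-branches")
              seq_along(cp$leads)
            else integer()
    chosen <- if (length(take) == 0L) "none"
              else if (length(take) == 2L) "both"
              else as.character(take)
    visited[[length(visited) + 1L]] <<-
      data.frame(couplet = id, lead = chosen)
    for (i in take) {
      out <- cp$leads[[i]]$outcome
      if (!is.null(out$taxon)) {
        if (!out$taxon %in% outcomes) {
          outcomes <<- c(outcomes, out$taxon)
          terminal[[out$taxon]] <<- id
        }
      } else walk(out$goto)
    }
  }
  walk(key$entry)
  structure(list(visited = do.call(rbind, visited), outcomes = outcomes,
                 terminal_couplets = terminal),
            class = "evaluation_trace")
}

#' @export
print.evaluation_trace <- function(x, ...) {
  cat("<evaluation_trace> outcome(s): ",
      if (length(x$outcomes)) paste(x$outcomes, collapse = ", ") else "none",
      "\n  couplets visited: ",
      paste(x$visited$couplet, collapse = " -> "), "\n", sep = "")
  invisible(x)
}

#' Audit a key against the descriptions of its terminal taxa
#'
#' For every terminal taxon: (a) membership — whether evaluating the taxon's
#' own description contains the taxon in the outcome set; (b) discrimination
#' — the couplets on the taxon's accepting path where the sibling lead is
#' also true or unknown for it (i.e. where the key fails to separate
#' cleanly).
#'
#' @param key an `identification_key`.
#' @param descs named list of `taxon_description`s, one per terminal taxon.
#' @param ontology an `ontology`.
#' @param policy a [satisfaction_policy()].
#' @return a `key_audit` data frame with columns `taxon`, `membership`,
#'   `terminal_couplet`, `ambiguous_couplets`.
#' @export
check_key_consistency <- function(key, descs, ontology,
                                  policy = satisfaction_policy()) {
  missing <- setdiff(key$taxa, names(descs))
  if (length(missing))
    abort(paste0("terminal taxa without description: ",
                 paste(missing, collapse = ", ")), "arenosae_bad_key")
  rows <- lapply(key$taxa, function(tx) {
    d <- descs[[tx]]
    tr <- evaluate_key(d, key, ontology, policy)
    amb <- character()
    for (i in seq_len(nrow(tr$visited))) {
      id <- tr$visited$couplet[i]
      cp <- key$couplets[[as.character(id)]]
      vals <- vapply(cp$leads, function(ld)
        eval_lead(d, ld, ontology, policy), character(1))
      if (sum(vals != "false") > 1L) amb <- c(amb, as.character(id))
    }
    data.frame(taxon = tx, membership = tx %in% tr$outcomes,
               terminal_couplet = if (tx %in% names(tr$terminal_couplets))
                 tr$terminal_couplets[[tx]] else NA_integer_,
               ambiguous_couplets = paste(amb, collapse = ","))
  })
  structure(do.call(rbind, rows), class = c("key_audit", "data.frame"))
}
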