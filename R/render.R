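# Telegraphic rendering and parsing of the printed description syntax.
#
# Quantitative ranges use parenthetical extremes, "(8.0–)9.0–13.0(–14.0) mm";
# adjacent length x width slots render as dimension pairs,
# "10.0–40.0 × 2.0–4.0 mm".  The contract is slot-wise phrase equality, not
# full-sentence byte equality with the printed accounts.

#' Rendering style
#'
#' @param dash range glyph; en dash by default.
#' @param times dimension-pair glyph; multiplication sign by default.
#' @param ascii use ASCII fallbacks (`-`, `x`) for terminals without the
#'   typographic glyphs.
#' @param decimals decimal places for length values.
#' @return a `render_style`.
#' @export
render_style <- function(dash = "–", times = "×", ascii = FALSE,
                         decimals = 1L) {
  if (ascii) { dash <- "-"; times <- "x" }
  stopifnot(nchar(dash) == 1L, nchar(times) == 1L)
  structure(list(dash = dash, times = times, decimals = decimals),
            class = "render_style")
}

fmt_num <- function(x, unit, style) {
  if (identical(unit, "count")) format(x, trim = TRUE)
  else formatC(x, format = "f", digits = style$decimals)
}

#' Format a quantitative range
#'
#' Produces the printed pattern `(EL–)ML–MH(–EH) unit`, with parentheses
#' omitted when extremes are absent and one decimal for length values.
#'
#' @param r a [quant_range()].
#' @param style a [render_style()].
#' @param with_unit append the unit token?
#' @return a character scalar, e.g. `"(8.0–)9.0–13.0(–14.0) mm"`.
#' @export
format_quant <- function(r, style = render_style(), with_unit = TRUE) {
  d <- style$dash
  n <- function(x) fmt_num(x, r$unit, style)
  out <- paste0(
    if (!is.null(r$extreme_low)) paste0("(", n(r$extreme_low), d, ")"),
    n(r$main_low), d, n(r$main_high),
    if (!is.null(r$extreme_high)) paste0("(", d, n(r$extreme_high), ")"))
  if (with_unit && !identical(r$unit, "count"))
    out <- paste0(out, " ", r$unit)
  out
}

NUM_RE <- "[0-9]+(?:\\.[0-9]+)?"

range_re <- function() {
  d <- "(?:–|-)"
  paste0("^\\s*(?:\\((", NUM_RE, ")", d, "\\))?\\s*(", NUM_RE, ")\\s*", d,
         "\\s*(", NUM_RE, ")\\s*(?:\\(", d, "(", NUM_RE, ")\\))?",
         "\\s*(mm|cm)?\\s*$")
}

parse_one_range <- function(text, unit_default = NULL) {
  m <- regmatches(text, regexec(range_re(), text, perl = TRUE))[[1]]
  if (length(m) == 0L) {
    # locate first offending character for the error message
    ok <- regexpr(paste0("^\\s*(?:\\(", NUM_RE, "(?:–|-)\\))?\\s*",
                         NUM_RE, "(?:(?:–|-)", NUM_RE, ")?"),
                  text, perl = TRUE)
    pos <- if (ok > 0) attr(ok, "match.length") + 1L else 1L
    abort(paste0("malformed range '", text, "' (at position ", pos, ")"),
          "arenosae_parse_error")
  }
  num <- function(s) if (nzchar(s)) as.numeric(s) else NULL
  unit <- if (nzchar(m[6])) m[6] else unit_default
  if (is.null(unit))
    abort(paste0("range '", text, "' has no unit"), "arenosae_parse_error")
  quant_range(num(m[3]), num(m[4]), unit = unit,
              extreme_low = num(m[2]), extreme_high = num(m[5]))
}

#' Parse the printed range notation
#'
#' Inverse of [format_quant()]; accepts en dashes or ASCII hyphens, and
#' dimension pairs such as `"10.0–30.0 × 2.0–4.0 mm"` (the unit after the
#' second range applies to both).
#'
#' @param text range text.
#' @return a [quant_range()], or a list of two for a dimension pair.
#' @export
parse_quant <- function(text) {
  stopifnot(is_string(text))
  parts <- strsplit(text, "\\s*(?:×|(?<=[0-9 ])x(?=[ 0-9]))\\s*",
                    perl = TRUE)[[1]]
  if (length(parts) == 1L) return(parse_one_range(parts))
  if (length(parts) != 2L)
    abort(paste0("malformed dimension pair '", text, "'"),
          "arenosae_parse_error")
  second <- parse_one_range(parts[2])
  first <- parse_one_range(parts[1], unit_default = second$unit)
  list(first, second)
}

relative_phrase <- function(score, template) {
  rel <- c("longer-than" = "longer than",
           "obviously-longer-than" = "obviously longer than",
           "equal-to" = "equal to",
           "shorter-than" = "shorter than")[[score$relation]]
  ref_label <- score$reference
  for (sl in template$slots)
    if (identical(sl$structure, score$reference)) { ref_label <- sl$label; break }
  if (identical(ref_label, score$reference) &&
      grepl("next-upper", score$reference, fixed = TRUE))
    ref_label <- "the next upper internode"
  paste(rel, ref_label)
}

modifier_phrase <- function(modifiers) {
  tm <- Filter(function(m) m$kind == "temporal", modifiers)
  if (length(tm) == 0L) return("")
  paste0(" ", c("at-anthesis" = "at anthesis", "in-fruit" = "in fruit",
                "in-flower" = "in flower")[vapply(tm, `[[`, character(1),
                                                  "value")])
}

render_score_text <- function(e, slot, style, template) {
  sc <- e$score
  switch(score_type(sc),
    range = ,
    count = {
      txt <- format_quant(sc, style)
      if (!is.null(slot$suffix)) txt <- paste(txt, slot$suffix)
      paste0(txt, modifier_phrase(e$modifiers))
    },
    states = paste0(paste(gsub("-", " ", sc$states), collapse = " or "),
                    modifier_phrase(e$modifiers)),
    relative = relative_phrase(sc, template))
}

#' Render a description as telegraphic text
#'
#' Emits one phrase group per template structure, in slot order: the group
#' label, then each recorded score in slot order.  Adjacent length and width
#' ranges in the same unit merge into a dimension pair; relative scores are
#' connected with "and"; temporal contexts of the same slot are joined with
#' "and" ("cylindrical at anthesis and clavate in fruit").  Groups whose
#' slots are flagged `sentence` end with a period.
#'
#' @param desc a `taxon_description`.
#' @param template the `description_template` giving order and phrasing.
#' @param style a [render_style()].
#' @return character vector of rendered phrase groups.
#' @export
render_description <- function(desc, template, style = render_style()) {
  els <- order_elements(desc$elements, template)
  if (length(els) == 0L) return(character())
  idx <- template_slot_index(template)
  groups <- list()
  for (e in els) {
    i <- idx[slot_key(e$structure, e$property)]
    if (is.na(i)) next
    g <- paste0("#", template$slots[[i]]$label)
    groups[[g]] <- c(groups[[g]], list(list(e = e, slot = template$slots[[i]])))
  }
  out <- character()
  for (g in names(groups)) {
    items <- groups[[g]]
    label <- sub("^#", "", g)
    parts <- character(); sentence <- FALSE
    k <- 1L
    while (k <= length(items)) {
      it <- items[[k]]
      sentence <- sentence || isTRUE(it$slot$sentence)
      # merge adjacent length x width ranges into a dimension pair
      if (k < length(items) && identical(it$e$property, "length") &&
          inherits(it$e$score, "quant_range") &&
          identical(items[[k + 1L]]$e$property, "width") &&
          inherits(items[[k + 1L]]$e$score, "quant_range") &&
          identical(it$e$score$unit, items[[k + 1L]]$e$score$unit)) {
        txt <- paste0(format_quant(it$e$score, style, with_unit = FALSE),
                      " ", style$times, " ",
                      format_quant(items[[k + 1L]]$e$score, style))
        if (!is.null(it$slot$suffix)) txt <- paste(txt, it$slot$suffix)
        parts <- c(parts, txt)
        k <- k + 2L
        next
      }
      txt <- render_score_text(it$e, it$slot, style, template)
      if (score_type(it$e$score) == "relative" && length(parts))
        parts[length(parts)] <- paste(parts[length(parts)], "and", txt)
      else if (score_type(it$e$score) == "states" && k > 1L &&
               length(parts) &&
               identical(it$e$property, items[[k - 1L]]$e$property)) {
        parts[length(parts)] <- paste(parts[length(parts)], "and", txt)
      } else parts <- c(parts, txt)
      k <- k + 1L
    }
    body <- paste(parts, collapse = ", ")
    txt <- if (nzchar(label)) paste(label, body) else body
    if (sentence) txt <- paste0(txt, ".")
    out <- c(out, txt)
  }
  out
}
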