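# Controlled vocabulary (base ontology) and pro-forma description templates.
#
# An ontology holds structure terms (a part-of tree), property terms
# (qualitative / quantitative / count / relative) with their states or units,
# specifier definitions that single out one instance from a collection of
# structures ("the uppermost internode", "the first flower"), and the
# permitted modifier vocabulary.  Documents are JSON, UTF-8, NFC-normalised.

ORDINAL_KEYWORDS <- c("first", "uppermost", "next-upper", "lower-part",
                      "upper-part")
RELATIVE_RELATIONS <- c("longer-than", "obviously-longer-than", "equal-to",
                        "shorter-than")
PROPERTY_KINDS <- c("qualitative", "quantitative", "count", "relative")
MODIFIER_KINDS <- c("frequency", "relative", "spatial", "temporal")

nfc <- function(x) {
  if (is.null(x)) return(x)
  enc2utf8(iconv(x, to = "UTF-8"))
}

#' Load a base ontology from a JSON document
#'
#' Reads and validates an ontology document: structure terms with a single
#' part-of parent, property terms (qualitative properties need at least one
#' state, quantitative ones exactly one canonical unit from the unit
#' registry), specifier definitions, and the modifier vocabulary.  The loaded
#' ontology is closed under reference: any dangling name is an error.
#'
#' @param path path to a JSON ontology document.
#' @return an object of class `ontology`.
#' @examples
#' ont <- load_ontology(arenosae_file("ontology.json"))
#' ont
#' @export
load_ontology <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  build_ontology(doc, source = path)
}

build_ontology <- function(doc, source = "<document>") {
  units <- list()
  for (u in doc$units %||% list()) {
    units[[nfc(u$name)]] <- list(dim = u$dim %||% "length",
                                 factor = as.numeric(u$factor %||% 1))
  }
  structures <- list()
  for (s in doc$structures %||% list()) {
    nm <- nfc(s$name)
    if (!is.null(structures[[nm]]))
      abort(paste0("duplicate structure term: ", nm), "arenosae_dup_term")
    structures[[nm]] <- list(name = nm, parent = nfc(s$parent),
                             synonyms = nfc(unlist(s$synonyms)) %||% character(),
                             note = s$note %||% "")
  }
  # synonym table resolves to canonical names at load time
  syn <- character()
  for (s in structures) for (a in s$synonyms) {
    if (!is.null(structures[[a]]) || a %in% names(syn))
      abort(paste0("duplicate structure term: ", a), "arenosae_dup_term")
    syn[[a]] <- s$name
  }
  # parents resolve; part-of graph is a tree (acyclic, single parent)
  for (s in structures) {
    if (!is.null(s$parent) && is.null(structures[[s$parent]]))
      abort(paste0("dangling reference: structure '", s$name,
                   "' has unknown parent '", s$parent, "'"),
            "arenosae_dangling_ref")
  }
  for (s in structures) {
    seen <- character(); p <- s$name
    while (!is.null(p)) {
      if (p %in% seen)
        abort(paste0("part-of cycle involving '", p, "'"), "arenosae_cycle")
      seen <- c(seen, p)
      p <- structures[[p]]$parent
    }
  }
  properties <- list()
  for (p in doc$properties %||% list()) {
    nm <- nfc(p$name)
    if (!is.null(properties[[nm]]))
      abort(paste0("duplicate property term: ", nm), "arenosae_dup_term")
    kind <- match.arg(p$kind, PROPERTY_KINDS)
    states <- nfc(unlist(p$states)) %||% character()
    if (kind == "qualitative" && length(states) < 1L)
      abort(paste0("qualitative property '", nm, "' has no states"),
            "arenosae_invalid_ontology")
    if (anyDuplicated(states))
      abort(paste0("duplicate state in property '", nm, "'"),
            "arenosae_dup_term")
    cu <- nfc(p$canonical_unit)
    if (kind == "quantitative") {
      if (is.null(cu) || is.null(units[[cu]]))
        abort(paste0("quantitative property '", nm,
                     "' needs a canonical unit from the registry"),
              "arenosae_invalid_ontology")
    }
    if (kind == "count") cu <- "count"
    app <- nfc(unlist(p$applicable_structures)) %||% character()
    for (a in app) if (is.null(structures[[a]]) && !(a %in% names(syn)))
      abort(paste0("dangling reference: property '", nm,
                   "' applies to unknown structure '", a, "'"),
            "arenosae_dangling_ref")
    properties[[nm]] <- list(name = nm, kind = kind, states = states,
                             canonical_unit = cu, applicable = app)
  }
  specifiers <- list()
  for (sd in doc$specifiers %||% list()) {
    bs <- nfc(sd$base_structure)
    if (is.null(structures[[bs]]) && !(bs %in% names(syn)))
      abort(paste0("dangling reference: specifier on unknown structure '",
                   bs, "'"), "arenosae_dangling_ref")
    disc <- nfc(sd$discriminator)
    if (is.null(properties[[disc]]) && !all(unlist(sd$allowed_values) %in%
                                            ORDINAL_KEYWORDS) &&
        !isTRUE(sd$declared))
      abort(paste0("specifier discriminator '", disc,
                   "' is neither a property nor a declared ordinal keyword"),
            "arenosae_dangling_ref")
    specifiers[[length(specifiers) + 1L]] <-
      list(base_structure = bs, discriminator = disc,
           allowed_values = nfc(unlist(sd$allowed_values)))
  }
  modifiers <- list()
  for (k in names(doc$modifiers %||% list()))
    modifiers[[k]] <- nfc(unlist(doc$modifiers[[k]]))
  for (k in names(modifiers))
    if (!k %in% MODIFIER_KINDS)
      abort(paste0("unknown modifier kind '", k, "'"),
            "arenosae_invalid_ontology")
  structure(list(version = doc$version %||% "0",
                 provenance = doc$provenance %||% "reconstructed",
                 units = units, structures = structures, synonyms = syn,
                 properties = properties, specifiers = specifiers,
                 modifiers = modifiers, source = source),
            class = "ontology")
}

#' @export
print.ontology <- function(x, ...) {
  cat("<ontology> version ", x$version, " (", x$provenance, ")\n",
      "  structures: ", length(x$structures),
      "  properties: ", length(x$properties),
      "  specifiers: ", length(x$specifiers), "\n", sep = "")
  invisible(x)
}

#' Serialise an ontology back to its JSON document form
#'
#' `serialize_ontology()` is the inverse of [load_ontology()]: loading the
#' written file yields an identical ontology.
#'
#' @param ontology an `ontology`.
#' @param path file to write; omit to return the JSON text.
#' @return the path, invisibly, or the JSON string when `path` is `NULL`.
#' @export
serialize_ontology <- function(ontology, path = NULL) {
  doc <- list(
    version = ontology$version,
    provenance = ontology$provenance,
    units = unname(lapply(names(ontology$units), function(n)
      list(name = n, dim = ontology$units[[n]]$dim,
           factor = ontology$units[[n]]$factor))),
    structures = unname(lapply(ontology$structures, function(s)
      list(name = s$name, parent = s$parent, synonyms = as.list(s$synonyms),
           note = s$note))),
    properties = unname(lapply(ontology$properties, function(p)
      list(name = p$name, kind = p$kind, states = as.list(p$states),
           canonical_unit = p$canonical_unit,
           applicable_structures = as.list(p$applicable)))),
    specifiers = unname(lapply(ontology$specifiers, function(sd)
      list(base_structure = sd$base_structure,
           discriminator = sd$discriminator, declared = TRUE,
           allowed_values = as.list(sd$allowed_values)))),
    modifiers = ontology$modifiers)
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = 2L, digits = NA,
                          null = "null")
  if (is.null(path)) return(as.character(txt))
  writeLines(as.character(txt), path, useBytes = TRUE)
  invisible(path)
}

canonical_structure <- function(ontology, name) {
  if (!is.null(ontology$structures[[name]])) return(name)
  if (name %in% names(ontology$synonyms)) return(ontology$synonyms[[name]])
  abort(paste0("unknown structure '", name, "'"), "arenosae_unknown_term")
}

is_part_of <- function(ontology, child, ancestor) {
  p <- ontology$structures[[child]]$parent
  while (!is.null(p)) {
    if (identical(p, ancestor)) return(TRUE)
    p <- ontology$structures[[p]]$parent
  }
  FALSE
}

#' Resolve a structure path with specifiers
#'
#' Paths use the syntax `structure[specifier=value]/substructure...`, e.g.
#' `"internode[position=uppermost]"` or `"flower[order=first]/pedicel"`.
#' Each segment must resolve in the ontology (synonyms map to the canonical
#' name), each non-initial segment must be part-of the previous one, and each
#' specifier must match a specifier definition (or a built-in ordinal
#' keyword).
#'
#' @param ontology an `ontology`.
#' @param path a structure path string.
#' @return a `structure_ref` with `segments` and a canonical string form.
#' @examples
#' ont <- load_ontology(arenosae_file("ontology.json"))
#' resolve_structure_ref(ont, "internode[position=uppermost]")
#' resolve_structure_ref(ont, "flower[order=first]/pedicel")
#' @export
resolve_structure_ref <- function(ontology, path) {
  stopifnot(is_string(path))
  segs <- strsplit(nfc(path), "/", fixed = TRUE)[[1]]
  if (length(segs) == 0L)
    abort("empty structure path", "arenosae_bad_path")
  out <- vector("list", length(segs))
  prev <- NULL
  for (i in seq_along(segs)) {
    seg <- segs[[i]]
    m <- regmatches(seg, regexec("^([^\\[\\]=]+)(\\[([^\\[\\]=]+)=([^\\[\\]=]+)\\])?$",
                                 seg, perl = TRUE))[[1]]
    if (length(m) == 0L)
      abort(paste0("malformed path segment '", seg, "'"), "arenosae_bad_path")
    nm <- canonical_structure(ontology, m[2])
    spec <- NULL
    if (nzchar(m[3])) {
      disc <- m[4]; val <- m[5]
      ok <- FALSE
      for (sd in ontology$specifiers) {
        if (identical(sd$base_structure, nm) &&
            identical(sd$discriminator, disc)) {
          if (!val %in% sd$allowed_values)
            abort(paste0("specifier value '", val, "' not allowed for ",
                         nm, "[", disc, "]"), "arenosae_unknown_specifier")
          ok <- TRUE
        }
      }
      if (!ok && val %in% ORDINAL_KEYWORDS) ok <- TRUE
      if (!ok)
        abort(paste0("unknown specifier ", disc, "=", val, " on '", nm, "'"),
              "arenosae_unknown_specifier")
      spec <- stats::setNames(val, disc)
    }
    if (!is.null(prev) && !is_part_of(ontology, nm, prev))
      abort(paste0("'", nm, "' is not part of '", prev, "'"),
            "arenosae_bad_path")
    out[[i]] <- list(structure = nm, specifiers = spec)
    prev <- nm
  }
  structure(list(segments = out), class = "structure_ref")
}

#' @export
format.structure_ref <- function(x, ...) {
  paste(vapply(x$segments, function(s) {
    if (is.null(s$specifiers)) s$structure
    else paste0(s$structure, "[", names(s$specifiers), "=", s$specifiers, "]")
  }, character(1)), collapse = "/")
}

#' @export
print.structure_ref <- function(x, ...) {
  cat("<structure_ref> ", format(x), "\n", sep = "")
  invisible(x)
}

ref_string <- function(ontology, path) format(resolve_structure_ref(ontology, path))

terminal_structure <- function(path) {
  seg <- utils::tail(strsplit(path, "/", fixed = TRUE)[[1]], 1L)
  sub("\\[.*$", "", seg)
}

#' Derive a pro-forma description template from an ontology
#'
#' A template is an ordered list of slots, each naming a structure path and a
#' property plus rendering hints (label, suffix, whether the slot group forms
#' a full sentence).  Slot order is total and drives both validation and
#' rendering order.  Deriving a template from its own slot selection is
#' idempotent.
#'
#' @param ontology an `ontology`.
#' @param slots list of slot lists with elements `structure`, `property` and
#'   optional `label`, `suffix`, `sentence`, `unit`.
#' @param name template name.
#' @return an object of class `description_template`.
#' @export
derive_template <- function(ontology, slots, name = "template") {
  out <- vector("list", length(slots))
  for (i in seq_along(slots)) {
    sl <- slots[[i]]
    ref <- resolve_structure_ref(ontology, sl$structure)
    prop <- ontology$properties[[nfc(sl$property)]]
    if (is.null(prop))
      abort(paste0("unknown property '", sl$property, "'"),
            "arenosae_unknown_term")
    term <- terminal_structure(format(ref))
    if (length(prop$applicable) && !term %in% prop$applicable)
      abort(paste0("property '", prop$name, "' not applicable to '",
                   term, "'"), "arenosae_unknown_term")
    out[[i]] <- list(structure = format(ref), property = prop$name,
                     label = sl$label %||% term,
                     suffix = sl$suffix %||% NULL,
                     sentence = sl$sentence %||% TRUE,
                     unit = sl$unit %||% NULL)
  }
  keys <- vapply(out, function(s) paste(s$structure, s$property), character(1))
  if (anyDuplicated(keys))
    abort("duplicate template slot", "arenosae_dup_term")
  structure(list(name = name, ontology_version = ontology$version,
                 slots = out), class = "description_template")
}

#' Load a description template document
#'
#' @param path JSON template document.
#' @param ontology the `ontology` the template draws its terms from.
#' @return a `description_template`.
#' @export
load_template <- function(path, ontology) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  derive_template(ontology, doc$slots, name = doc$name %||% "template")
}

#' @export
print.description_template <- function(x, ...) {
  cat("<description_template> '", x$name, "', ", length(x$slots),
      " slots\n", sep = "")
  invisible(x)
}

slot_key <- function(structure, property) paste0(structure, " :: ", property)

template_slot_index <- function(template) {
  stats::setNames(seq_along(template$slots),
                  vapply(template$slots,
                         function(s) slot_key(s$structure, s$property),
                         character(1)))
}
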