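# Synthetic generators: descriptions with a controlled constant fraction,
# and posterior tree samples with a known true partition and a tip
# reassignment ("flip") probability, so every other module is testable
# without any external data.

#' Generate a synthetic ontology, template, and descriptions
#'
#' Builds `n_chars` character slots on `n_chars` synthetic organs
#' (alternating quantitative and qualitative properties) and draws one
#' description per taxon.  Exactly `round(constant_fraction * n_chars)`
#' slots carry an identical score in every taxon; each remaining slot is
#' guaranteed to differ in at least one taxon.  The truth record (the
#' constant-slot description) is returned alongside, so constant-feature
#' intersection and parent/child factoring can be checked against
#' construction.
#'
#' @param n_taxa number of taxa (at least 2).
#' @param n_chars number of character slots.
#' @param constant_fraction fraction of slots constant across all taxa.
#' @param seed integer seed; same seed, same output.
#' @return list with `ontology`, `template`, `parent` (constant truth),
#'   `taxa` (list of `taxon_description`), `constant_slots` (indices).
#' @export
gen_descriptions <- function(n_taxa, n_chars, constant_fraction, seed = 1L) {
  stopifnot(n_taxa >= 2L, n_chars >= 1L,
            constant_fraction >= 0, constant_fraction <= 1)
  n_const <- round(constant_fraction * n_chars)
  with_seed(seed, {
    organs <- paste0("organ", seq_len(n_chars))
    states <- paste0("state", 1:6)
    doc <- list(
      version = "synthetic", provenance = "synthetic",
      units = list(list(name = "mm", dim = "length", factor = 1),
                   list(name = "cm", dim = "length", factor = 10),
                   list(name = "count", dim = "count", factor = 1)),
      structures = c(list(list(name = "body", parent = NULL)),
                     lapply(organs, function(o)
                       list(name = o, parent = "body"))),
      properties = list(
        list(name = "length", kind = "quantitative", canonical_unit = "mm"),
        list(name = "form", kind = "qualitative",
             states = as.list(states))),
      modifiers = list(frequency = list("usually", "rarely")))
    ont <- build_ontology(doc, source = "<synthetic>")
    slots <- lapply(seq_len(n_chars), function(i)
      list(structure = organs[i],
           property = if (i %% 2L == 0L) "form" else "length"))
    tmpl <- derive_template(ont, slots, name = "synthetic")
    draw_score <- function(i) {
      if (i %% 2L == 0L) qual_score(sample(states, sample(1:2, 1)))
      else {
        lo <- round(stats::runif(1, 1, 20), 1)
        quant_range(lo, lo + round(stats::runif(1, 0.5, 10), 1), unit = "mm")
      }
    }
    const_idx <- sort(sample(n_chars, n_const))
    const_scores <- lapply(const_idx, draw_score)
    taxa_scores <- lapply(seq_len(n_taxa), function(t)
      lapply(seq_len(n_chars), draw_score))
    for (j in seq_along(const_idx))
      for (t in seq_len(n_taxa))
        taxa_scores[[t]][[const_idx[j]]] <- const_scores[[j]]
    ontology_equal <- function(a, b) scores_equal(a, b, ont)
    for (i in setdiff(seq_len(n_chars), const_idx)) {
      # force at least one taxon to differ at a variable slot
      base <- taxa_scores[[1]][[i]]
      if (all(vapply(taxa_scores, function(s) ontology_equal(s[[i]], base),
                     logical(1)))) {
        t <- sample(2:n_taxa, 1)
        repeat {
          alt <- draw_score(i)
          if (!ontology_equal(alt, base)) break
        }
        taxa_scores[[t]][[i]] <- alt
      }
    }
    mk_desc <- function(name, scores, idx) {
      els <- lapply(idx, function(i)
        descriptive_element(organs[i],
                            if (i %% 2L == 0L) "form" else "length",
                            scores[[match(i, idx)]]))
      taxon_description(name, "species", els, template = "synthetic")
    }
    parent <- taxon_description(
      "synthetic parent", "section",
      lapply(seq_along(const_idx), function(j)
        descriptive_element(organs[const_idx[j]],
                            if (const_idx[j] %% 2L == 0L) "form" else
                              "length", const_scores[[j]])),
      template = "synthetic")
    taxa <- lapply(seq_len(n_taxa), function(t)
      mk_desc(paste0("taxon", t), taxa_scores[[t]], seq_len(n_chars)))
    list(ontology = ont, template = tmpl, parent = parent, taxa = taxa,
         constant_slots = const_idx)
  })
}

# newick string for one ultrametric sample given a class assignment
assignment_newick <- function(assign, within_height, between_height) {
  classes <- split(names(assign), assign)
  classes <- classes[order(vapply(classes, `[[`, character(1), 1L))]
  sub_nwk <- lapply(classes, function(tips) {
    if (length(tips) == 1L) return(list(nwk = tips, h = 0))
    hs <- sort(stats::runif(length(tips) - 1L, 0, within_height))
    nwk <- tips[1]; h <- 0
    for (k in seq_along(hs)) {
      nwk <- paste0("(", nwk, ":", format(hs[k] - h, digits = 17),
                    ",", tips[k + 1L], ":", format(hs[k], digits = 17), ")")
      h <- hs[k]
    }
    list(nwk = nwk, h = h)
  })
  nwks <- lapply(sub_nwk, `[[`, "nwk")
  hs <- vapply(sub_nwk, `[[`, numeric(1), "h")
  if (length(nwks) == 1L)
    return(paste0(nwks[[1]], ";"))
  # join class roots at heights at or above the between-class scale
  joins <- between_height * (1 + 0.25 * seq_len(length(nwks) - 1L)) +
    stats::runif(length(nwks) - 1L, 0, between_height / 10)
  joins <- sort(joins)
  nwk <- nwks[[1]]; h <- hs[[1]]
  for (k in seq_along(joins)) {
    nwk <- paste0("(", nwk, ":", format(joins[k] - h, digits = 17),
                  ",", nwks[[k + 1L]], ":",
                  format(joins[k] - hs[[k + 1L]], digits = 17), ")")
    h <- joins[k]
  }
  paste0(nwk, ";")
}

#' Generate a synthetic posterior of ultrametric species trees
#'
#' Emulates the structure of a posterior species-tree sample with respect to
#' a known partition: in each sample, every tip is independently reassigned
#' to a uniformly drawn *other* class with probability `flip_prob`; tips of
#' one realised class coalesce at heights uniform on `(0, within_height)`,
#' and class roots join at heights at or above `between_height`.  With
#' `within_height < epsilon < between_height`, collapse partitioning at
#' `epsilon` recovers exactly the realised class assignment of each sample,
#' so co-clustering probabilities follow from the reassignment rule in
#' closed form (see [flip_cocluster_prob()]).
#'
#' @param true_partition named character vector mapping tip label to class.
#' @param n_samples number of samples.
#' @param flip_prob per-tip reassignment probability `q`.
#' @param within_height within-class coalescent scale (default `2e-5`).
#' @param between_height between-class scale (default `1e-2`).
#' @param seed integer seed.
#' @return a `tree_samples` object.
#' @export
gen_posterior <- function(true_partition, n_samples, flip_prob = 0,
                          within_height = 2e-5, between_height = 1e-2,
                          seed = 1L) {
  stopifnot(flip_prob >= 0, flip_prob <= 1, within_height < between_height)
  classes <- unique(true_partition)
  if (length(classes) < 2L && flip_prob > 0)
    abort("single-class partition with flip_prob > 0 has no target class",
          "arenosae_bad_config")
  tips <- names(true_partition)
  stopifnot(!is.null(tips), !anyDuplicated(tips))
  with_seed(seed, {
    trees <- vector("list", n_samples)
    for (s in seq_len(n_samples)) {
      assign <- true_partition
      flip <- stats::runif(length(tips)) < flip_prob
      for (i in which(flip))
        assign[i] <- sample(setdiff(classes, true_partition[i]), 1L)
      trees[[s]] <- ape::read.tree(
        text = assignment_newick(assign, within_height, between_height))
    }
    tree_samples(trees, source = "<synthetic>")
  })
}

#' Analytic co-clustering probability under the flip model
#'
#' For tips of the same true class the probability of landing in the same
#' realised class is `(1-q)^2 + q^2/(C-1)`; for tips of different classes it
#' is `2 q (1-q)/(C-1) + q^2 (C-2)/(C-1)^2`, where `C` is the number of
#' classes.
#'
#' @param q flip probability.
#' @param n_classes number of classes `C`.
#' @param same are the two tips in the same true class?
#' @return a probability.
#' @export
flip_cocluster_prob <- function(q, n_classes, same) {
  C <- n_classes
  if (same) (1 - q)^2 + q^2 / (C - 1)
  else 2 * q * (1 - q) / (C - 1) + q^2 * (C - 2) / (C - 1)^2
}
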