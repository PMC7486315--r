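# shared fixture dataset, loaded once per test run
arx <- load_arenosae()
ont <- arx$ontology
tpl <- arx$template
key <- arx$key
descs <- arx$descriptions
terminals <- descs[names(descs) != "Silene sect. Arenosae"]

# brute-force O(n^2) oracle: all-pairs MRCA-height thresholding via the
# cophenetic distance (= 2 * MRCA height on an ultrametric tree), closed
# transitively by repeated merging -- independent of the package's
# tree-walk implementation
oracle_partition <- function(tree, epsilon) {
  h <- stats::cophenetic(tree) / 2
  labs <- rownames(h)
  classes <- as.list(labs)
  repeat {
    merged <- FALSE
    for (i in seq_along(classes)) {
      if (i > length(classes) - 1L) break
      for (j in seq(i + 1L, length(classes))) {
        if (any(h[classes[[i]], classes[[j]], drop = FALSE] < epsilon)) {
          classes[[i]] <- c(classes[[i]], classes[[j]])
          classes[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  classes <- lapply(classes, sort)
  classes[order(vapply(classes, `[[`, character(1), 1L))]
}

# a collapse height strictly between two realised MRCA heights, so boundary
# ties cannot blur the strict-inequality contract with float noise
rand_eps <- function(tree) {
  hs <- sort(unique(as.vector(stats::cophenetic(tree) / 2)))
  # drop float near-duplicates of one node height (cophenetic sums distinct
  # edge paths) so the midpoint sits well clear of every realised height
  hs <- hs[c(TRUE, diff(hs) > 1e-6 * max(hs))]
  i <- sample(length(hs) - 1L, 1L)
  (hs[i] + hs[i + 1L]) / 2
}

partition_sig <- function(p)
  paste(vapply(p, paste, character(1), collapse = ","), collapse = "|")

# random 1-decimal quantitative range, optionally with extremes
rand_range <- function(unit = "mm") {
  v <- sort(round(stats::runif(4, 0, 50), 1))
  has_el <- stats::runif(1) < 0.5 && v[1] < v[2]
  has_eh <- stats::runif(1) < 0.5 && v[3] < v[4]
  quant_range(v[2], v[3], unit = unit,
              extreme_low = if (has_el) v[1],
              extreme_high = if (has_eh) v[4])
}

mini_desc <- function(taxon, elements)
  taxon_description(taxon, "species", elements, template = "silene-arenosae")

write_key_doc <- function(doc) {
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  path
}
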