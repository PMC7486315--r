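# Posterior cluster similarity matrix from species-tree samples.
#
# Pipeline: read a posterior sample of ultrametric species trees (NEXUS with
# translate table and bracketed metadata, or plain Newick), discard a
# burn-in fraction, partition the tips of each tree at a collapse height
# (tips whose MRCA sits below the threshold belong to the same "ideal
# population"), accumulate pairwise co-clustering frequencies, and sort the
# matrix by the summary-tree topology for display.

ULTRAMETRIC_TOL <- 1e-8  # relative to root height; failing trees are rejected

strip_tree_comments <- function(lines) {
  txt <- paste(lines, collapse = "\n")
  # bracketed (possibly nested) comments / BEAST annotations
  repeat {
    new <- gsub("\\[[^][]*\\]", "", txt)
    if (identical(new, txt)) break
    txt <- new
  }
  txt
}

#' Read a posterior sample of trees
#'
#' Accepts NEXUS TREES blocks (translate tables honoured, bracketed
#' annotations stripped) or plain Newick, one tree per line.  All samples
#' must share one tip set.
#'
#' @param path tree file.
#' @param format `"auto"` (detect `#NEXUS`), `"nexus"` or `"newick"`.
#' @return a `tree_samples` object wrapping an `ape::multiPhylo`.
#' @export
read_tree_samples <- function(path, format = c("auto", "nexus", "newick")) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  if (format == "auto")
    format <- if (any(grepl("#NEXUS", lines, ignore.case = TRUE))) "nexus"
              else "newick"
  txt <- strip_tree_comments(lines)
  tmp <- tempfile(fileext = if (format == "nexus") ".nex" else ".nwk")
  on.exit(unlink(tmp))
  writeLines(txt, tmp)
  trees <- tryCatch(
    if (format == "nexus") ape::read.nexus(tmp) else ape::read.tree(tmp),
    error = function(e) abort(paste0("unparseable tree file: ",
                                     conditionMessage(e)),
                              "arenosae_io_error"))
  if (inherits(trees, "phylo")) trees <- c(trees)
  if (length(trees) == 0L)
    abort("no trees in file", "arenosae_io_error")
  tips <- sort(trees[[1]]$tip.label)
  for (i in seq_along(trees))
    if (!identical(sort(trees[[i]]$tip.label), tips))
      abort(paste0("inconsistent tip set in sample ", i),
            "arenosae_inconsistent_tips")
  tree_samples(trees, source = path)
}

#' Construct a tree sample set from a list of `phylo` trees
#'
#' @param trees a `multiPhylo` or list of `phylo` objects over one tip set.
#' @param source optional source metadata.
#' @return a `tree_samples` object.
#' @export
tree_samples <- function(trees, source = NULL) {
  if (inherits(trees, "phylo")) trees <- c(trees)
  class(trees) <- "multiPhylo"
  structure(list(trees = trees, labels = sort(trees[[1]]$tip.label),
                 source = source), class = "tree_samples")
}

#' @export
print.tree_samples <- function(x, ...) {
  cat("<tree_samples> ", length(x$trees), " trees over ",
      length(x$labels), " tips\n", sep = "")
  invisible(x)
}

#' @export
length.tree_samples <- function(x) length(x$trees)

#' Discard a burn-in fraction of samples
#'
#' Removes the first `floor(fraction * N)` samples, so results are
#' reproducible bit-for-bit for any N.
#'
#' @param samples a `tree_samples`.
#' @param fraction burn-in fraction in `[0, 1)`.
#' @return a `tree_samples`.
#' @export
apply_burnin <- function(samples, fraction) {
  stopifnot(fraction >= 0, fraction < 1)
  n <- length(samples$trees)
  drop <- floor(fraction * n)
  samples$trees <- samples$trees[(drop + 1L):n]
  class(samples$trees) <- "multiPhylo"
  samples
}

# node heights (time above the tips) for an ultrametric tree; errors, naming
# the most offending tip, if the tree is not ultrametric within tolerance
node_heights <- function(tree, tol = ULTRAMETRIC_TOL) {
  depths <- ape::node.depth.edgelength(tree)
  ntip <- length(tree$tip.label)
  H <- max(depths[seq_len(ntip)])
  dev <- abs(depths[seq_len(ntip)] - H)
  if (H > 0 && max(dev) > tol * H)
    abort(paste0("tree is not ultrametric: tip '",
                 tree$tip.label[which.max(dev)], "' deviates by ",
                 format(max(dev))), "arenosae_not_ultrametric")
  H - depths
}

#' Partition tips at a collapse height
#'
#' Tips `i`, `j` share a class iff the height of their most recent common
#' ancestor is strictly below `epsilon` (the collapse height approximates
#' zero node height, so equality at the threshold does not cluster).
#' Ultrametricity guarantees the relation is an equivalence, so the result
#' is a valid partition.
#'
#' @param tree an ultrametric `phylo`.
#' @param epsilon collapse height.
#' @return a `tip_partition`: list of character vectors (classes).
#' @export
collapse_partition <- function(tree, epsilon) {
  h <- node_heights(tree)
  ntip <- length(tree$tip.label)
  parent <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  cls <- integer(ntip)
  for (i in seq_len(ntip)) {
    node <- i
    p <- parent[node]
    while (p != 0L && h[p] < epsilon) {
      node <- p
      p <- parent[node]
    }
    cls[i] <- node
  }
  split_classes <- split(tree$tip.label, cls)
  canonical_partition(unname(split_classes))
}

canonical_partition <- function(classes) {
  classes <- lapply(classes, sort)
  classes <- classes[order(vapply(classes, `[[`, character(1), 1L))]
  structure(classes, class = "tip_partition")
}

#' @export
print.tip_partition <- function(x, ...) {
  cat("<tip_partition> ", length(x), " class(es): ",
      paste(vapply(x, function(cl) paste0("{", paste(cl, collapse = ","),
                                          "}"), character(1)),
            collapse = " "), "\n", sep = "")
  invisible(x)
}

partition_signature <- function(p)
  paste(vapply(p, paste, character(1), collapse = ","), collapse = "|")

partition_membership <- function(p, labels) {
  z <- integer(length(labels)); names(z) <- labels
  for (i in seq_along(p)) z[p[[i]]] <- i
  z
}

#' Posterior co-clustering similarity matrix
#'
#' Entry (i, j) is the fraction of posterior samples in which tips i and j
#' fall in the same collapse-height class.  The matrix is symmetric with a
#' unit diagonal, entries in `[0, 1]`, and is invariant to sample order.
#'
#' @param samples a `tree_samples` (apply burn-in first).
#' @param epsilon collapse height.
#' @return a `similarity_matrix`.
#' @export
similarity_matrix <- function(samples, epsilon) {
  if (length(samples$trees) == 0L)
    abort("empty sample set", "arenosae_empty_samples")
  labels <- samples$labels
  n <- length(labels)
  M <- matrix(0, n, n, dimnames = list(labels, labels))
  for (tr in samples$trees) {
    z <- partition_membership(collapse_partition(tr, epsilon), labels)
    M <- M + outer(z, z, "==")
  }
  M <- M / length(samples$trees)
  structure(list(labels = labels, matrix = M,
                 n_samples = length(samples$trees), epsilon = epsilon),
            class = "similarity_matrix")
}

#' @export
as.matrix.similarity_matrix <- function(x, ...) x$matrix

#' @export
print.similarity_matrix <- function(x, ...) {
  cat("<similarity_matrix> ", length(x$labels), " tips, ",
      x$n_samples, " samples, collapse height ", format(x$epsilon),
      "\n", sep = "")
  invisible(x)
}

#' Posterior frequencies of distinct partitions
#'
#' @param samples a `tree_samples`.
#' @param epsilon collapse height.
#' @return list of `list(partition=, frequency=)`, frequencies summing to 1,
#'   sorted by decreasing frequency (ties by signature).
#' @export
cluster_frequency_table <- function(samples, epsilon) {
  if (length(samples$trees) == 0L)
    abort("empty sample set", "arenosae_empty_samples")
  parts <- lapply(samples$trees, collapse_partition, epsilon = epsilon)
  sigs <- vapply(parts, partition_signature, character(1))
  tab <- table(sigs)
  ord <- order(-as.integer(tab), names(tab))
  lapply(ord, function(i) {
    sig <- names(tab)[i]
    list(partition = parts[[match(sig, sigs)]],
         frequency = as.integer(tab[i]) / length(parts))
  })
}

# left-to-right tip order of a ladderized tree: at every node smaller clades
# first, larger clades last, ties broken by smallest tip label
ladder_order <- function(tree) {
  ntip <- length(tree$tip.label)
  children <- split(tree$edge[, 2], tree$edge[, 1])
  rec <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    subs <- lapply(children[[as.character(node)]], rec)
    sizes <- lengths(subs)
    mins <- vapply(subs, min, character(1))
    unlist(subs[order(sizes, mins)])
  }
  rec(ntip + 1L)
}

#' Sort a similarity matrix by a summary-tree topology
#'
#' Rows and columns are permuted to the left-to-right tip order of the
#' ladderized summary tree (smaller clades first, larger clades last, ties
#' by label); this is how heatmaps of the matrix are conventionally
#' displayed.  Sorting is idempotent and invariant to the incoming label
#' order.
#'
#' @param m a `similarity_matrix`.
#' @param summary an ultrametric `phylo` whose tips equal the matrix labels.
#' @return the permuted `similarity_matrix`.
#' @export
sort_by_tree <- function(m, summary) {
  if (!setequal(summary$tip.label, m$labels))
    abort("summary tree tips do not match matrix labels",
          "arenosae_label_mismatch")
  ord <- ladder_order(summary)
  m$matrix <- m$matrix[ord, ord]
  m$labels <- ord
  m
}

#' Write / read a similarity matrix as labelled CSV
#'
#' @param m a `similarity_matrix`.
#' @param path CSV file.
#' @return the path invisibly (`write_similarity`), or the
#'   `similarity_matrix` (`read_similarity`).
#' @export
write_similarity <- function(m, path) {
  df <- data.frame(label = m$labels, m$matrix, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_similarity
#' @param n_samples,epsilon metadata to attach on read (CSV stores only the
#'   matrix).
#' @export
read_similarity <- function(path, n_samples = NA_integer_,
                            epsilon = NA_real_) {
  df <- utils::read.csv(path, check.names = FALSE)
  labels <- as.character(df$label)
  M <- as.matrix(df[, -1, drop = FALSE])
  rownames(M) <- labels
  structure(list(labels = labels, matrix = M, n_samples = n_samples,
                 epsilon = epsilon), class = "similarity_matrix")
}

#' Plot a similarity-matrix heatmap
#'
#' @param m a `similarity_matrix` (sorted with [sort_by_tree()] if desired).
#' @param path output image; `.png` or `.svg` by extension.
#' @return the path invisibly.
#' @export
plot_heatmap <- function(m, path) {
  n <- length(m$labels)
  ext <- tolower(tools::file_ext(path))
  if (ext == "svg") grDevices::svg(path, width = 7, height = 7)
  else grDevices::png(path, width = 700, height = 700)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(6, 6, 2, 1))  # device-local; dies with dev.off()
  graphics::image(seq_len(n), seq_len(n), t(m$matrix[n:1, , drop = FALSE]),
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  zlim = c(0, 1), axes = FALSE, xlab = "", ylab = "")
  graphics::axis(1, at = seq_len(n), labels = m$labels, las = 2,
                 cex.axis = 0.7)
  graphics::axis(2, at = seq_len(n), labels = rev(m$labels), las = 2,
                 cex.axis = 0.7)
  graphics::box()
  invisible(path)
}

#' Recover a partition by thresholding a similarity matrix
#'
#' Tips are joined whenever their similarity exceeds the threshold, and the
#' connected components of the resulting graph form the classes (posterior
#' co-clustering above 0.5 cannot be transitive-free for well-separated
#' clusters, so components are the natural reading).
#'
#' @param m a `similarity_matrix`.
#' @param threshold similarity threshold; 0.5 by default.
#' @return a `tip_partition`.
#' @export
threshold_partition <- function(m, threshold = 0.5) {
  n <- length(m$labels)
  cls <- seq_len(n)
  find <- function(i) { while (cls[i] != i) i <- cls[i]; i }
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n))
    if (m$matrix[i, j] > threshold) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) cls[ri] <- rj
    }
  roots <- vapply(seq_len(n), find, integer(1))
  canonical_partition(unname(split(m$labels, roots)))
}
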