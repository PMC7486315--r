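# Packaged Silene sect. Arenosae dataset: base ontology, description
# template, the section + species + subspecies descriptions, and the
# dichotomous key.  Characters that the formal accounts do not record but
# the key or the morphological remarks require (flowering time, tooth margin
# width, fleshy leaves) carry provenance "supplemented".

#' Path to a packaged data file
#'
#' @param ... path components below `extdata/`.
#' @return the file path.
#' @export
arenosae_file <- function(...) fixture_path(...)

#' Load the packaged Silene sect. Arenosae dataset
#'
#' @return a list with `ontology`, `template`, `descriptions` (named list of
#'   `taxon_description`s, the section first) and `key`.
#' @examples
#' arx <- load_arenosae()
#' arx$key
#' @export
load_arenosae <- function() {
  ontology <- load_ontology(arenosae_file("ontology.json"))
  template <- load_template(arenosae_file("template_silene.json"), ontology)
  files <- sort(list.files(arenosae_file("descriptions"),
                           pattern = "\\.json$", full.names = TRUE))
  descs <- lapply(files, read_description)
  names(descs) <- vapply(descs, `[[`, character(1), "taxon")
  section <- which(vapply(descs, `[[`, character(1), "rank") == "section")
  descs <- c(descs[section], descs[-section])
  key <- read_key(arenosae_file("arenosae_key.json"))
  list(ontology = ontology, template = template, descriptions = descs,
       key = key)
}

#' Census of the packaged dataset
#'
#' Counts the species of the section (species-rank descriptions plus any
#' species that is represented only through its subspecies) and the
#' subspecies, and reports the number of key couplets.
#'
#' @param dataset the list returned by [load_arenosae()]; loaded if omitted.
#' @return a list with `n_species`, `n_subspecies`, `n_couplets`,
#'   `n_terminal_taxa`.
#' @export
arenosae_census <- function(dataset = load_arenosae()) {
  descs <- dataset$descriptions
  ranks <- vapply(descs, `[[`, character(1), "rank")
  species <- names(descs)[ranks == "species"]
  subsp <- descs[ranks == "subspecies"]
  parents <- unique(vapply(subsp, function(d) d$parent %||% NA_character_,
                           character(1)))
  species_all <- union(species, parents[!is.na(parents)])
  list(n_species = length(species_all),
       n_subspecies = length(subsp),
       n_couplets = length(dataset$key$couplets),
       n_terminal_taxa = length(dataset$key$taxa))
}
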