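# Species catalogue and vegetation-based expected class.

#' Load the species-to-class catalogue
#'
#' Each catalogue row maps a species (exact binomial) or a genus to the set
#' of hydrological classes whose regime it tolerates. Exact species entries
#' take precedence over genus entries. The packaged default covers the
#' common southeast Asian mangrove groups: *Avicennia alba* and
#' *Sonneratia* in class 2; *Avicennia*, *Rhizophora* and *Bruguiera*
#' around 2*; *Rhizophora*, *Ceriops* and *Bruguiera* in 3; *Lumnitzera*,
#' *Bruguiera* and *Acrostichum aureum* in 4; *Ceriops* and *Phoenix
#' paludosa* in 5. For other biogeographic regions, supply a locally
#' calibrated CSV with columns `pattern,match,classes` (classes separated
#' by `|`).
#'
#' @param path optional path to a catalogue CSV; default is the packaged
#'   catalogue.
#' @return A data frame with columns `pattern`, `match`
#'   (`"species"`/`"genus"`) and `classes` (list column of label vectors).
#' @export
species_catalogue <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "species_catalogue.csv",
                        package = "mangrovehydro", mustWork = TRUE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("pattern", "match", "classes") %in% names(df)))
  df$classes <- lapply(strsplit(df$classes, "|", fixed = TRUE), trimws)
  df
}

# "Avicennia sp." / "A. marina" style cleanup: returns c(full_name, genus).
split_species_name <- function(name) {
  name <- trimws(gsub("\\s+", " ", name))
  name <- sub("\\s+sp\\.?$", "", name)
  genus <- strsplit(name, " ")[[1]][1]
  list(full = name, genus = genus)
}

#' Class set for one species
#'
#' Looks the species up in the catalogue: an exact binomial entry wins;
#' otherwise the genus entry applies (so *Avicennia alba* maps to class 2
#' while any other *Avicennia* maps to 2*). Unknown taxa return an empty
#' set with a warning.
#'
#' @param name species name (binomial, or `"Genus sp."`).
#' @param catalogue a [species_catalogue()] data frame.
#' @return Character vector of class labels (possibly empty).
#' @export
species_classes <- function(name, catalogue = species_catalogue()) {
  nm <- split_species_name(name)
  hit <- catalogue$match == "species" & tolower(catalogue$pattern) == tolower(nm$full)
  if (!any(hit)) {
    hit <- catalogue$match == "genus" & tolower(catalogue$pattern) == tolower(nm$genus)
  }
  if (!any(hit)) {
    warning("species not in catalogue: ", name)
    return(character(0))
  }
  sort_classes(unique(unlist(catalogue$classes[hit])))
}

sort_classes <- function(x) x[order(class_rank(x))]

#' Expected hydrological class from a vegetation inventory
#'
#' Converts an inventory (species in dominance order) into the class the
#' vegetation indicates. Planted species are dropped first: planting choice
#' reflects management, not hydrology. Starting from the dominant species'
#' class set, the candidate set is intersected with each subsequent
#' species' set down the dominance order as long as the intersection stays
#' non-empty (stopping before it would empty). If a unique class remains it
#' is returned; if the dominant and second species carry disjoint singleton
#' sets, the alternative label "X/Y" (wet-to-dry) is returned; otherwise
#' the remaining set is returned as an alternative label. Sapling species,
#' when given, act only as a tie-breaker among the remaining candidates
#' (young recruits reflect the present regime better than mature trees).
#' All per-species candidate sets are exposed so an expert can override.
#'
#' @param species character vector, dominance order.
#' @param planted logical vector (same length) flagging planted species.
#' @param saplings optional character vector of species present as young
#'   saplings.
#' @param catalogue a [species_catalogue()] data frame.
#' @return A list with `label` (a [class_label()] or `NA` when
#'   undetermined), `undetermined` flag, and `candidates` (named list of
#'   class sets per retained species).
#' @export
expected_class <- function(species, planted = rep(FALSE, length(species)),
                           saplings = NULL, catalogue = species_catalogue()) {
  stopifnot(length(planted) == length(species))
  keep <- !planted
  species <- species[keep]
  if (!length(species)) {
    return(list(label = NA, undetermined = TRUE, candidates = list()))
  }
  sets <- lapply(species, species_classes, catalogue = catalogue)
  names(sets) <- species
  nonempty <- lengths(sets) > 0
  if (!any(nonempty)) {
    return(list(label = NA, undetermined = TRUE, candidates = sets))
  }
  sets_use <- sets[nonempty]
  cur <- sets_use[[1]]
  if (length(sets_use) >= 2) {
    s2 <- sets_use[[2]]
    if (length(cur) == 1 && length(s2) == 1 && !s2 %in% cur) {
      # disjoint singletons: genuine alternative between the two
      return(list(label = class_label(c(cur, s2), "alternative"),
                  undetermined = FALSE, candidates = sets))
    }
    for (s in sets_use[-1]) {
      nxt <- intersect(cur, s)
      if (!length(nxt)) break
      cur <- nxt
    }
  }
  if (length(cur) > 1 && !is.null(saplings)) {
    sap <- unique(unlist(lapply(saplings, species_classes, catalogue = catalogue)))
    tie <- intersect(cur, sap)
    if (length(tie)) cur <- tie
  }
  cur <- sort_classes(cur)
  label <- if (length(cur) == 1) class_label(cur, "single")
           else class_label(cur, "alternative")
  list(label = label, undetermined = FALSE, candidates = sets)
}
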