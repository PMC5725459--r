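#' Read an ortholog-group table
#'
#' TSV with columns `species`, `protein_id`, `group_id` (orthoDB-like). A
#' protein may belong to at most one group per species entry.
#'
#' @param path TSV path with a header row.
#' @return Data frame of class `ortholog_map`.
#' @export
read_ortholog_map <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  as_ortholog_map(df)
}

#' @rdname read_ortholog_map
#' @param df Data frame with `species`, `protein_id`, `group_id`.
#' @export
as_ortholog_map <- function(df) {
  needed <- c("species", "protein_id", "group_id")
  if (!all(needed %in% names(df))) {
    stop("ortholog map must have columns: ", paste(needed, collapse = ", "))
  }
  key <- paste(df$species, df$protein_id)
  if (anyDuplicated(key)) {
    stop("protein mapped to more than one group: ",
         key[duplicated(key)][1])
  }
  class(df) <- c("ortholog_map", "data.frame")
  df
}

#' @rdname read_ortholog_map
#' @param map An `ortholog_map`.
#' @export
write_ortholog_map <- function(map, path) {
  write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

# Group id of a protein in a species (NA if unmapped).
ortholog_group <- function(map, species, protein) {
  hit <- map$group_id[map$species == species & map$protein_id == protein]
  if (length(hit)) hit[1] else NA_character_
}

# Member proteins of a group in a species.
group_members <- function(map, species, group) {
  map$protein_id[map$species == species & map$group_id == group]
}

#' Transfer a focal protein interaction to another species
#'
#' Maps the two focal proteins to their ortholog groups and declares the
#' interaction `present` in the target species exactly when strictly more
#' than half of all possible cross-group protein pairs interact there
#' (species edges with score at or above `min_score`). A pair of a protein
#' with itself (overlapping groups) is excluded from the count. When either
#' group has no member in the species -- or a focal protein is not mapped
#' to any group -- the state is `unknown`.
#'
#' @param protein_a,protein_b Focal (dog) protein ids.
#' @param species Target species name.
#' @param ortholog_map An `ortholog_map`.
#' @param species_network The target species' `scored_network`.
#' @param min_score Score threshold for counting an interaction
#'   (default 0.7, inclusive).
#' @param focal_species Name of the focal species in the map (default
#'   `"dog"`).
#' @return `"present"`, `"absent"` or `"unknown"`. Symmetric in the two
#'   proteins.
#' @export
transfer_interaction <- function(protein_a, protein_b, species, ortholog_map,
                                 species_network, min_score = 0.7,
                                 focal_species = "dog") {
  ga <- ortholog_group(ortholog_map, focal_species, protein_a)
  gb <- ortholog_group(ortholog_map, focal_species, protein_b)
  if (is.na(ga) || is.na(gb)) {
    message("focal protein without ortholog group: ",
            if (is.na(ga)) protein_a else protein_b)
    return("unknown")
  }
  ma <- group_members(ortholog_map, species, ga)
  mb <- group_members(ortholog_map, species, gb)
  if (!length(ma) || !length(mb)) return("unknown")
  pairs <- expand.grid(a = ma, b = mb, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$a != pairs$b, , drop = FALSE]
  keys <- unique(pair_key(pairs$a, pairs$b))
  if (!length(keys)) return("unknown")
  ed <- species_network$edges
  edge_keys <- pair_key(ed$protein_a[ed$score >= min_score],
                        ed$protein_b[ed$score >= min_score])
  n_int <- sum(keys %in% edge_keys)
  if (n_int / length(keys) > 0.5) "present" else "absent"
}

#' Build cross-species interaction profiles for focal protein pairs
#'
#' For each focal pair, records the interaction state per species: the
#' focal species' state is read directly from its own network (`present`
#' iff the edge exists with score at or above `min_score`; never
#' `unknown`), other species get the majority-rule state from
#' [transfer_interaction()].
#'
#' @param pairs Data frame with columns `protein_a`, `protein_b` (focal
#'   pairs).
#' @param ortholog_map An `ortholog_map`.
#' @param networks Named list of `scored_network`s, one per species,
#'   including the focal species.
#' @param species Character vector of species to profile (default: names
#'   of `networks`).
#' @param focal_species Focal species name (default `"dog"`).
#' @param min_score Score threshold (default 0.7).
#' @return Character matrix (pairs x species) with values
#'   `"present"`/`"absent"`/`"unknown"`; rows named by [pair_key()].
#' @export
build_interaction_profiles <- function(pairs, ortholog_map, networks,
                                       species = names(networks),
                                       focal_species = "dog",
                                       min_score = 0.7) {
  stopifnot(focal_species %in% names(networks))
  n <- nrow(pairs)
  prof <- matrix("unknown", nrow = n, ncol = length(species),
                 dimnames = list(pair_key(pairs$protein_a, pairs$protein_b),
                                 species))
  focal_ed <- networks[[focal_species]]$edges
  focal_keys <- pair_key(focal_ed$protein_a[focal_ed$score >= min_score],
                         focal_ed$protein_b[focal_ed$score >= min_score])
  # precomputed lookups (same rule as transfer_interaction, vectorized)
  focal_rows <- ortholog_map$species == focal_species
  focal_groups <- setNames(ortholog_map$group_id[focal_rows],
                           ortholog_map$protein_id[focal_rows])
  ga <- unname(focal_groups[pairs$protein_a])
  gb <- unname(focal_groups[pairs$protein_b])
  if (anyNA(ga) || anyNA(gb)) {
    message(sum(is.na(ga) | is.na(gb)),
            " pair(s) with an unmapped focal protein set to unknown")
  }
  for (sp in species) {
    if (sp == focal_species) {
      prof[, sp] <- ifelse(rownames(prof) %in% focal_keys, "present", "absent")
      next
    }
    sp_rows <- ortholog_map$species == sp
    members <- split(ortholog_map$protein_id[sp_rows],
                     ortholog_map$group_id[sp_rows])
    ed <- networks[[sp]]$edges
    edge_keys <- pair_key(ed$protein_a[ed$score >= min_score],
                          ed$protein_b[ed$score >= min_score])
    for (i in seq_len(n)) {
      if (is.na(ga[i]) || is.na(gb[i])) next
      ma <- members[[ga[i]]]
      mb <- members[[gb[i]]]
      if (is.null(ma) || is.null(mb)) next
      keys <- unique(pair_key(rep(ma, times = length(mb)),
                              rep(mb, each = length(ma))))
      keys <- keys[sub("\\|.*", "", keys) != sub(".*\\|", "", keys)]
      if (!length(keys)) next
      n_int <- sum(keys %in% edge_keys)
      prof[i, sp] <- if (n_int / length(keys) > 0.5) "present" else "absent"
    }
  }
  prof
}

# present/absent/unknown matrix -> 1/0/NA numeric matrix.
profiles_to_states <- function(profiles) {
  states <- matrix(NA_real_, nrow = nrow(profiles), ncol = ncol(profiles),
                   dimnames = dimnames(profiles))
  states[profiles == "present"] <- 1
  states[profiles == "absent"] <- 0
  states
}
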