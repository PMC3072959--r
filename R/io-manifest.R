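# Species manifest: the comparison panel. Each entry names a species, its
# proteome (and optionally genome) file, and the nested clade tags that
# drive classification: social_insect < hymenoptera < insect < metazoan,
# with outgroup_non_metazoan for non-metazoan outgroups such as yeast.

#' Construct and validate a species manifest
#'
#' @param species data.frame with columns `id`, `proteome` (path or NA),
#'   `genome` (path or NA), `clades` (comma-separated tags from
#'   `social_insect, hymenoptera, insect, metazoan, outgroup_non_metazoan`),
#'   and `focal` (logical).
#' @return Object of class `species_manifest` (the validated data.frame
#'   with a `clade_list` list-column).
#' @details Invariants enforced: unique identifiers; exactly one focal
#'   species; every non-focal entry has a proteome; clade tags nested
#'   (social_insect implies hymenoptera implies insect implies metazoan);
#'   `outgroup_non_metazoan` excludes all other tags.
#' @export
species_manifest <- function(species) {
  req <- c("id", "proteome", "genome", "clades", "focal")
  if (!all(req %in% names(species)))
    stop("manifest needs columns: ", paste(req, collapse = ", "))
  species$id <- as.character(species$id)
  if (anyDuplicated(species$id))
    stop("duplicate species identifiers: ",
         paste(unique(species$id[duplicated(species$id)]), collapse = ", "))
  if (sum(species$focal) != 1L)
    stop("exactly one focal species required, found ", sum(species$focal))
  clade_list <- lapply(strsplit(as.character(species$clades), ","),
                       function(x) {
                         x <- trimws(x[nzchar(trimws(x))])
                         bad <- setdiff(x, CLADE_TAGS)
                         if (length(bad) > 0)
                           stop("unknown clade tag(s): ", paste(bad, collapse = ", "))
                         x
                       })
  nested <- c("social_insect", "hymenoptera", "insect", "metazoan")
  for (i in seq_along(clade_list)) {
    tags <- clade_list[[i]]
    if ("outgroup_non_metazoan" %in% tags && length(tags) > 1)
      stop("species ", species$id[i],
           ": outgroup_non_metazoan excludes other clade tags")
    pos <- match(intersect(nested, tags), nested)
    if (length(pos) > 0) {
      needed <- nested[seq(min(pos), length(nested))]
      missing <- setdiff(needed, tags)
      if (length(missing) > 0)
        stop("species ", species$id[i], ": clade tags must be nested; ",
             paste(tags, collapse = "+"), " lacks ",
             paste(missing, collapse = ", "))
    }
    if (length(tags) == 0)
      stop("species ", species$id[i], ": at least one clade tag required")
  }
  no_prot <- !species$focal & (is.na(species$proteome) | !nzchar(species$proteome))
  if (any(no_prot))
    stop("non-focal species without proteome: ",
         paste(species$id[no_prot], collapse = ", "))
  species$clade_list <- clade_list
  structure(species, class = c("species_manifest", "data.frame"))
}

#' Read a species manifest from TSV or YAML
#'
#' TSV form: columns `id`, `proteome`, `genome`, `clades` (comma-separated),
#' `focal` (TRUE/FALSE); empty or `.` path fields mean absent. YAML form: a
#' list of entries with keys `id`, `proteome`, `genome`, `clades` (list),
#' `focal`. Relative file paths are resolved against the manifest's
#' directory.
#'
#' @param path Manifest path (`.tsv`/`.txt` or `.yml`/`.yaml`).
#' @return A validated [species_manifest()].
#' @export
read_species_manifest <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  base <- dirname(path)
  resolve <- function(p) {
    p <- as.character(p)
    p[!nzchar(p) | p == "." | is.na(p)] <- NA_character_
    ifelse(is.na(p) | grepl("^/", p), p, file.path(base, p))
  }
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    entries <- yaml::read_yaml(path)
    df <- data.frame(
      id = vapply(entries, function(e) as.character(e$id), character(1)),
      proteome = vapply(entries, function(e)
        as.character(e$proteome %||% NA_character_), character(1)),
      genome = vapply(entries, function(e)
        as.character(e$genome %||% NA_character_), character(1)),
      clades = vapply(entries, function(e)
        paste(unlist(e$clades), collapse = ","), character(1)),
      focal = vapply(entries, function(e) isTRUE(e$focal), logical(1)),
      stringsAsFactors = FALSE)
  } else {
    df <- read.delim(path, stringsAsFactors = FALSE,
                     colClasses = c(focal = "logical"))
  }
  df$proteome <- resolve(df$proteome)
  df$genome <- resolve(df$genome)
  species_manifest(df)
}

#' Write a species manifest as TSV
#' @param manifest A [species_manifest()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_species_manifest <- function(manifest, path) {
  df <- as.data.frame(manifest)[, c("id", "proteome", "genome", "clades", "focal")]
  df$proteome[is.na(df$proteome)] <- ""
  df$genome[is.na(df$genome)] <- ""
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

focal_id <- function(manifest) manifest$id[manifest$focal]

comparison_ids <- function(manifest) manifest$id[!manifest$focal]

# Non-focal species carrying (or lacking) a clade tag.
species_with_tag <- function(manifest, tag, negate = FALSE) {
  has <- vapply(manifest$clade_list, function(x) tag %in% x, logical(1))
  if (negate) has <- !has
  manifest$id[has & !manifest$focal]
}
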