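#' Species groups
#'
#' Three kinds of species group drive Cocktail conditions:
#' * `TC` (total cover, `#TC`): the condition compares the combined cover of
#'   all member species present, pooled by the independence rule.
#' * `SC` (single cover, `#SC`): the highest cover attained by any single
#'   member.
#' * `SOC` (sociological, `###`): the group counts as present when at least
#'   `min_members` members occur (default: half the members, rounded up).
#'
#' @param name group name.
#' @param kind one of `"TC"`, `"SC"`, `"SOC"`.
#' @param members character vector of member taxa (non-empty, unique).
#' @param min_members presence threshold for `SOC` groups; `NULL` means
#'   `ceiling(length(members) / 2)`.
#' @return an object of class `species_group`.
#' @export
species_group <- function(name, kind = c("TC", "SC", "SOC"), members,
                          min_members = NULL) {
  kind <- match.arg(kind)
  members <- as.character(members)
  if (!length(members)) stop("species group '", name, "' has no members")
  norm <- normalize_name(members)
  if (anyDuplicated(norm)) {
    stop("species group '", name, "' has duplicated members")
  }
  if (!is.null(min_members)) {
    stopifnot(min_members >= 1, min_members <= length(members))
  }
  structure(list(name = name, kind = kind, members = members,
                 norm_members = norm, min_members = min_members),
            class = "species_group")
}

#' @export
print.species_group <- function(x, ...) {
  cat(sprintf("species_group '%s' [%s], %d members\n", x$name, x$kind,
              length(x$members)))
  invisible(x)
}

#' Read a species-group registry from YAML
#'
#' The file holds a `groups:` list of entries with `name`, `kind`
#' (`TC`/`SC`/`SOC`), `members`, and optional `min_members`. The packaged
#' registry (`vc_extdata("species_groups.yaml")`) carries the
#' Isoeto-Nanojuncetea class group, the three alliance total-cover groups
#' and the eight sociological groups used by the packaged definitions.
#'
#' @param path YAML file path.
#' @return named list of [species_group()] objects.
#' @export
read_species_groups <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$groups)) stop("no 'groups' entry in ", path)
  gs <- lapply(y$groups, function(g) {
    species_group(g$name, g$kind, unlist(g$members),
                  min_members = g$min_members)
  })
  names(gs) <- vapply(gs, `[[`, character(1), "name")
  if (anyDuplicated(normalize_name(names(gs)))) {
    stop("duplicated group names in ", path)
  }
  gs
}

find_group <- function(registry, name) {
  idx <- match(normalize_name(name), normalize_name(names(registry)))
  if (is.na(idx)) stop("unknown species group: '", name, "'")
  registry[[idx]]
}

#' Total cover of a #TC species group in a releve
#'
#' Combined percentage cover of all member species present, pooled by the
#' independence rule `100 * (1 - prod(1 - c_i))`. Absent members contribute
#' nothing; an empty intersection gives 0.
#'
#' @param cover named cover-fraction vector of one plot, as produced by
#'   [releve_cover()] / [plot_covers()].
#' @param group a `TC` [species_group()].
#' @return percentage in `[0, 100]`.
#' @export
total_cover <- function(cover, group) {
  stopifnot(inherits(group, "species_group"))
  if (group$kind != "TC") stop("total_cover needs a TC group")
  hit <- cover[names(cover) %in% group$norm_members]
  100 * combine_covers(unname(hit))
}

#' Highest single cover of a #SC species group in a releve
#'
#' @inheritParams total_cover
#' @param group an `SC` [species_group()].
#' @return percentage in `[0, 100]`; 0 when no member is present.
#' @export
max_single_cover <- function(cover, group) {
  stopifnot(inherits(group, "species_group"))
  if (group$kind != "SC") stop("max_single_cover needs an SC group")
  hit <- cover[names(cover) %in% group$norm_members]
  if (!length(hit)) return(0)
  100 * max(unname(hit))
}

#' Presence of a sociological (###) species group in a releve
#'
#' @inheritParams total_cover
#' @param group a `SOC` [species_group()].
#' @param min_members override of the presence threshold; default is the
#'   group's own `min_members`, itself defaulting to half the members
#'   rounded up.
#' @return logical.
#' @export
sociological_presence <- function(cover, group, min_members = NULL) {
  stopifnot(inherits(group, "species_group"))
  if (group$kind != "SOC") stop("sociological_presence needs a SOC group")
  thr <- min_members %||% group$min_members %||%
    ceiling(length(group$members) / 2)
  sum(group$norm_members %in% names(cover)[cover > 0]) >= thr
}
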