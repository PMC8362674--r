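#' Syntaxon hierarchies
#'
#' A rooted class -> alliance -> association tree; every node carries a
#' formal definition. Exactly one node has rank `"class"` (the root); each
#' alliance's parent is the class; each association's parent is an alliance.
#' "Community"-rank informal units are treated as associations (their
#' `type` field distinguishes them).
#'
#' @param nodes list of node lists with fields `name`, `rank`
#'   (`class`/`alliance`/`association`), `parent` (`NULL` for the root),
#'   `formula` (string), and optional `type`, `cluster`, `unit_id`.
#' @param groups species-group registry used to parse the formulas.
#' @return an object of class `syntaxon_hierarchy`.
#' @seealso [read_hierarchy()], [classify()], [classify_table()]
#' @export
syntaxon_hierarchy <- function(nodes, groups) {
  nm <- vapply(nodes, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicated syntaxon names")
  rk <- vapply(nodes, `[[`, character(1), "rank")
  if (!all(rk %in% c("class", "alliance", "association"))) {
    stop("ranks must be class, alliance or association")
  }
  if (sum(rk == "class") != 1L) stop("hierarchy needs exactly one class root")
  parent <- vapply(nodes, function(n) n$parent %||% NA_character_,
                   character(1))
  for (i in seq_along(nodes)) {
    if (rk[i] == "class") {
      if (!is.na(parent[i])) stop("the class root cannot have a parent")
      next
    }
    if (is.na(parent[i])) stop("non-root node '", nm[i], "' needs a parent")
    pi <- match(parent[i], nm)
    if (is.na(pi)) stop("unknown parent '", parent[i], "' of '", nm[i], "'")
    want <- if (rk[i] == "alliance") "class" else "alliance"
    if (rk[pi] != want) {
      stop("node '", nm[i], "' (", rk[i], ") must have a ", want, " parent")
    }
  }
  nodes <- lapply(nodes, function(n) {
    n$defn <- parse_definition(n$formula, groups)
    n
  })
  names(nodes) <- nm
  structure(list(nodes = nodes, groups = groups),
            class = "syntaxon_hierarchy")
}

#' @export
print.syntaxon_hierarchy <- function(x, ...) {
  rk <- vapply(x$nodes, `[[`, character(1), "rank")
  cat("syntaxon_hierarchy:", sum(rk == "class"), "class,",
      sum(rk == "alliance"), "alliances,", sum(rk == "association"),
      "associations/communities\n")
  invisible(x)
}

#' Read a syntaxon hierarchy (formal-definition file) from YAML
#'
#' The file holds a `syntaxa:` list of nodes (`name`, `rank`, `parent`,
#' `formula`, optional `type`, `cluster`, `unit_id`). The packaged
#' definition set (`vc_extdata("syntaxa_reconstructed.yaml")`) is a
#' reconstruction: its structure follows the published multilevel expert
#' system for Isoeto-Nanojuncetea vegetation, with every threshold kept in
#' that one editable file.
#'
#' @param path YAML definition file.
#' @param groups species-group registry; default: the packaged registry.
#' @return a [syntaxon_hierarchy()].
#' @export
read_hierarchy <- function(path, groups = load_packaged_groups()) {
  y <- yaml::read_yaml(path)
  if (is.null(y$syntaxa)) stop("no 'syntaxa' entry in ", path)
  syntaxon_hierarchy(y$syntaxa, groups)
}

hierarchy_nodes_of_rank <- function(hierarchy, rank) {
  keep <- vapply(hierarchy$nodes, function(n) n$rank == rank, logical(1))
  hierarchy$nodes[keep][order(names(hierarchy$nodes)[keep])]
}

hierarchy_ancestors <- function(hierarchy, name) {
  out <- character(0)
  cur <- hierarchy$nodes[[name]]
  while (!is.null(cur$parent)) {
    out <- c(out, cur$parent)
    cur <- hierarchy$nodes[[cur$parent]]
  }
  out
}

#' Unequivocal hierarchical classification of one releve
#'
#' Association-rank definitions are evaluated first (in name order, for
#' deterministic conflict reporting). Exactly one match assigns that
#' association together with its alliance and the class. Several matches
#' set the conflict flag, leave the association rank unassigned and fall
#' back to the alliance rank, where the same unique-match rule applies;
#' the class definition is evaluated last as a fallback. A releve is thus
#' assigned to at most one unit per rank.
#'
#' @param cover named cover-fraction vector of one plot ([releve_cover()]).
#' @param hierarchy a [syntaxon_hierarchy()].
#' @return list with elements `class`, `alliance`, `association` (each a
#'   name or `NA`), `conflict` (logical) and `conflict_nodes` (character).
#' @export
classify <- function(cover, hierarchy) {
  stopifnot(inherits(hierarchy, "syntaxon_hierarchy"))
  res <- list(class = NA_character_, alliance = NA_character_,
              association = NA_character_, conflict = FALSE,
              conflict_nodes = character(0))
  for (rank in c("association", "alliance", "class")) {
    nodes <- hierarchy_nodes_of_rank(hierarchy, rank)
    hits <- names(nodes)[vapply(nodes, function(n) evaluate(n$defn, cover),
                                logical(1))]
    if (length(hits) == 1L) {
      res[[rank]] <- hits
      for (anc in hierarchy_ancestors(hierarchy, hits)) {
        res[[hierarchy$nodes[[anc]]$rank]] <- anc
      }
      return(res)
    }
    if (length(hits) > 1L) {
      res$conflict <- TRUE
      res$conflict_nodes <- c(res$conflict_nodes, hits)
    }
  }
  res
}

#' Classify every plot of a releve table
#'
#' @param table a `releve_table`.
#' @param hierarchy a [syntaxon_hierarchy()].
#' @return data frame with one row per plot (`plot_id`, `class`, `alliance`,
#'   `association`, `conflict`, `conflict_nodes`), of class
#'   `cocktail_classification`, with a [classification_summary()] attached
#'   as attribute `"summary"`.
#' @export
classify_table <- function(table, hierarchy) {
  stopifnot(inherits(table, "releve_table"))
  covs <- plot_covers(table)
  rows <- lapply(names(covs), function(p) {
    r <- classify(covs[[p]], hierarchy)
    data.frame(plot_id = p, class = r$class, alliance = r$alliance,
               association = r$association, conflict = r$conflict,
               conflict_nodes = paste(r$conflict_nodes, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(plot_id = character(), class = character(),
               alliance = character(), association = character(),
               conflict = logical(), conflict_nodes = character(),
               stringsAsFactors = FALSE)
  class(out) <- c("cocktail_classification", "data.frame")
  attr(out, "summary") <- classification_summary(out, hierarchy)
  out
}

#' Per-node and per-level classification counts
#'
#' Summarises a classification the way formalized vegetation surveys report
#' it: counts per association, relevés classified at the alliance level
#' only, at the class level only, and unassigned.
#'
#' @param result a [classify_table()] result.
#' @param hierarchy the hierarchy used.
#' @return list with `per_node` (data frame `name`, `rank`, `n`) and
#'   `levels` (named counts: `association_level`, `alliance_only`,
#'   `class_only`, `unassigned`, `total`).
#' @export
classification_summary <- function(result, hierarchy) {
  nodes <- hierarchy$nodes
  per_node <- data.frame(
    name = names(nodes),
    rank = vapply(nodes, `[[`, character(1), "rank"),
    n = vapply(names(nodes), function(nm) {
      rk <- nodes[[nm]]$rank
      sum(!is.na(result[[rk]]) & result[[rk]] == nm)
    }, integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  levels <- c(
    association_level = sum(!is.na(result$association)),
    alliance_only = sum(is.na(result$association) & !is.na(result$alliance)),
    class_only = sum(is.na(result$alliance) & !is.na(result$class)),
    unassigned = sum(is.na(result$class)),
    total = nrow(result))
  list(per_node = per_node, levels = levels)
}

#' @export
print.cocktail_classification <- function(x, ...) {
  s <- attr(x, "summary")
  cat("cocktail_classification:", nrow(x), "releves —",
      s$levels[["association_level"]], "at association level,",
      s$levels[["alliance_only"]], "alliance only,",
      s$levels[["class_only"]], "class only,",
      s$levels[["unassigned"]], "unassigned\n")
  invisible(x)
}

# --- packaged fixtures -------------------------------------------------------

#' Packaged species-group registry
#' @return named list of [species_group()]s.
#' @export
load_packaged_groups <- function() {
  read_species_groups(vc_extdata("species_groups.yaml"))
}

#' Packaged (reconstructed) syntaxon hierarchy
#' @return a [syntaxon_hierarchy()].
#' @export
load_packaged_hierarchy <- function() {
  read_hierarchy(vc_extdata("syntaxa_reconstructed.yaml"),
                 load_packaged_groups())
}

#' The 63 preselected class diagnostic species
#'
#' Species eligible for the "diagnostic" role in [species_roles()]; all
#' other species passing the fidelity test are "differential".
#'
#' @return character vector of 63 taxon names.
#' @export
load_class_species <- function() {
  readLines(vc_extdata("class_species.txt"), encoding = "UTF-8")
}

#' Reported relevé counts of the reference survey
#'
#' The published per-unit relevé counts (three alliances, 14 units) and the
#' survey totals, packaged for internal-consistency checks and as
#' plot-count targets for [default_profiles()].
#'
#' @return list with `totals` (named numeric) and `units` (data frame
#'   `unit_id`, `name`, `alliance`, `cluster`, `type`, `releves`).
#' @export
load_reported_counts <- function() {
  y <- yaml::read_yaml(vc_extdata("reported_counts.yaml"))
  units <- do.call(rbind, lapply(y$units, function(u) {
    data.frame(unit_id = u$unit_id, name = u$name, alliance = u$alliance,
               cluster = u$cluster, type = u$type, releves = u$releves,
               stringsAsFactors = FALSE)
  }))
  alliances <- do.call(rbind, lapply(y$alliances, function(a) {
    data.frame(name = a$name, cluster = a$cluster, releves = a$releves,
               stringsAsFactors = FALSE)
  }))
  list(totals = unlist(y$totals), alliances = alliances, units = units)
}
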