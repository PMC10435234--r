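#' Region ontologies
#'
#' The region ontology is the hierarchy from fine atlas segments through
#' developmental regions to major brain divisions (in the Astyanax atlas:
#' 180 fine segments, 13 developmental regions, 4 major divisions). It is
#' supplied as a tab-separated file with header columns `region_id`, `name`,
#' `parent_id`, `level`; `level` is one of `fine`, `developmental`, `major`;
#' `parent_id` is empty (or `NA`) for roots; lines starting with `#` are
#' comments.
#'
#' @name region_ontology
NULL

.ontology_levels <- c("fine", "developmental", "major")

#' Load and validate a region ontology
#'
#' Validates uniqueness of ids, existence of parents, absence of cycles, and
#' that each parent sits at a strictly coarser level than its children, so
#' that every fine region maps to exactly one developmental region and one
#' major division.
#'
#' @param path path to a TSV file (columns `region_id`, `name`, `parent_id`,
#'   `level`; `#` comments allowed).
#' @return An object of class `region_ontology`: a data frame of the rows
#'   plus lookup support for [fine_to()].
#' @export
load_ontology <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  region_ontology(df)
}

#' @param df data frame with the ontology columns (alternative entry point
#'   for programmatic construction).
#' @rdname load_ontology
#' @export
region_ontology <- function(df) {
  need <- c("region_id", "name", "parent_id", "level")
  if (!all(need %in% names(df)))
    stop("ontology must have columns: ", paste(need, collapse = ", "))
  df <- df[need]
  df$region_id <- as.integer(df$region_id)
  df$parent_id <- suppressWarnings(as.integer(df$parent_id))
  df$level <- as.character(df$level)
  if (anyNA(df$region_id)) stop("missing region_id")
  if (anyDuplicated(df$region_id))
    stop("duplicate region_id: ",
         paste(unique(df$region_id[duplicated(df$region_id)]), collapse = ", "))
  bad <- setdiff(df$level, .ontology_levels)
  if (length(bad)) stop("unknown ontology level(s): ", paste(bad, collapse = ", "))
  has_parent <- !is.na(df$parent_id)
  orphan <- setdiff(df$parent_id[has_parent], df$region_id)
  if (length(orphan))
    stop("parent_id not present in ontology: ", paste(orphan, collapse = ", "))
  lev <- match(df$level, .ontology_levels)   # 1 fine .. 3 major
  plev <- lev[match(df$parent_id, df$region_id)]
  wrong <- has_parent & !(plev > lev)
  if (any(wrong))
    stop("parent must be at a coarser level than child; offending region_id: ",
         paste(df$region_id[wrong], collapse = ", "))
  # cycle check by walking each chain (levels strictly increase so any cycle
  # would already have failed above, but guard against pathological input)
  parent_of <- df$parent_id[match(df$region_id, df$region_id)]
  for (i in seq_len(nrow(df))) {
    seen <- integer(0); cur <- df$region_id[i]
    repeat {
      p <- df$parent_id[match(cur, df$region_id)]
      if (is.na(p)) break
      if (p %in% seen) stop("cycle in ontology at region_id ", p)
      seen <- c(seen, p); cur <- p
      if (length(seen) > nrow(df)) stop("cycle in ontology")
    }
  }
  class(df) <- c("region_ontology", "data.frame")
  df
}

#' Map fine region ids to ancestors at a coarser level
#'
#' @param onto a `region_ontology`.
#' @param level target level: `"fine"`, `"developmental"` or `"major"`.
#' @return Named integer vector: names are fine region ids, values the
#'   ancestor id at `level`. A total function over fine ids (validation
#'   guarantees each chain reaches every coarser level).
#' @export
fine_to <- function(onto, level = c("developmental", "major", "fine")) {
  level <- match.arg(level)
  stopifnot(inherits(onto, "region_ontology"))
  fine_ids <- onto$region_id[onto$level == "fine"]
  out <- vapply(fine_ids, function(id) {
    cur <- id
    repeat {
      row <- match(cur, onto$region_id)
      if (onto$level[row] == level) return(cur)
      p <- onto$parent_id[row]
      if (is.na(p))
        stop("fine region ", id, " has no ancestor at level '", level, "'")
      cur <- p
    }
  }, integer(1))
  names(out) <- fine_ids
  out
}

#' Aggregate a fine-level label volume to a coarser ontology level
#'
#' Relabels every nonzero voxel to its ancestor region at the requested
#' level; background voxels are untouched, and the total nonzero voxel
#' count is conserved exactly.
#'
#' @param vol a [label_volume()] whose nonzero labels are fine-level ids.
#' @param onto a `region_ontology`.
#' @param level target level.
#' @return A [label_volume()] at the coarser level.
#' @export
aggregate_labels <- function(vol, onto,
                             level = c("developmental", "major", "fine")) {
  level <- match.arg(level)
  stopifnot(inherits(vol, "label_volume"))
  if (level == "fine") return(vol)
  map <- fine_to(onto, level)
  labs <- sort(unique(as.vector(vol$grid)))
  labs <- labs[labs != 0L]
  unknown <- setdiff(labs, as.integer(names(map)))
  if (length(unknown))
    stop("label(s) absent from ontology fine level: ",
         paste(unknown, collapse = ", "))
  # translate via a dense lookup table for speed
  lut <- integer(max(labs) + 1L)          # index = label + 1; 0 stays 0
  lut[as.integer(names(map)) + 1L] <- as.integer(map)
  g <- vol$grid
  nz <- g != 0L
  g[nz] <- lut[g[nz] + 1L]
  label_volume(g, voxel_size = vol$voxel_size, dv_axis = vol$dv_axis,
               dv_increasing_ventral = vol$dv_increasing_ventral)
}

#' Write an ontology table to TSV
#' @param onto a `region_ontology`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ontology <- function(onto, path) {
  utils::write.table(as.data.frame(onto), path, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}
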