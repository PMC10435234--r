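#' Landmark tables
#'
#' Landmark data are long-format tables with one row per landmark per
#' specimen per region: columns `specimen_id`, `population`, `region`,
#' `landmark_id` (integer), `role` (one of `fixed`, `curve_semi`,
#' `surface_semi`), and world coordinates `x`, `y`, `z` in micrometres.
#' Within a region every specimen must carry the identical ordered set of
#' landmark ids with identical roles, so that configurations are directly
#' comparable across specimens.
#'
#' @name landmark_table
NULL

.landmark_roles <- c("fixed", "curve_semi", "surface_semi")
.landmark_cols <- c("specimen_id", "population", "region", "landmark_id",
                    "role", "x", "y", "z")

#' Validate a landmark table
#'
#' @param df data frame with the landmark columns.
#' @return The validated table with class `landmark_table`.
#' @export
landmark_table <- function(df) {
  if (!all(.landmark_cols %in% names(df)))
    stop("landmark table must have columns: ",
         paste(.landmark_cols, collapse = ", "))
  df <- as.data.frame(df)[.landmark_cols]
  df$specimen_id <- as.character(df$specimen_id)
  df$population <- as.character(df$population)
  df$region <- as.character(df$region)
  df$landmark_id <- as.integer(df$landmark_id)
  df$role <- as.character(df$role)
  bad <- setdiff(unique(df$role), .landmark_roles)
  if (length(bad)) stop("unknown landmark role(s): ", paste(bad, collapse = ", "))
  if (!all(is.finite(df$x) & is.finite(df$y) & is.finite(df$z)))
    stop("non-finite landmark coordinates")
  key <- paste(df$specimen_id, df$region, df$landmark_id)
  if (anyDuplicated(key))
    stop("duplicate (specimen_id, region, landmark_id): ",
         paste(utils::head(key[duplicated(key)], 3), collapse = "; "))
  # identical ordered landmark set and roles per region
  for (reg in unique(df$region)) {
    sub <- df[df$region == reg, ]
    specs <- unique(sub$specimen_id)
    ref <- sub[sub$specimen_id == specs[1L], ]
    ref <- ref[order(ref$landmark_id), c("landmark_id", "role")]
    offenders <- character(0)
    for (s in specs[-1L]) {
      cur <- sub[sub$specimen_id == s, ]
      cur <- cur[order(cur$landmark_id), c("landmark_id", "role")]
      if (!identical(cur$landmark_id, ref$landmark_id) ||
          !identical(cur$role, ref$role))
        offenders <- c(offenders, s)
    }
    if (length(offenders))
      stop("inconsistent landmark sets in region '", reg, "' for specimen(s): ",
           paste(offenders, collapse = ", "),
           " (reference specimen: ", specs[1L], ")")
  }
  class(df) <- c("landmark_table", "data.frame")
  df
}

#' Read a landmark table from CSV
#'
#' @param path path to a CSV file with the [landmark_table] columns.
#' @return A validated `landmark_table`.
#' @export
read_landmark_table <- function(path) {
  landmark_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a landmark table to CSV
#' @param lm a `landmark_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_landmark_table <- function(lm, path) {
  utils::write.csv(as.data.frame(lm), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Extract per-region configurations as an n x K x 3 array
#'
#' @param lm a `landmark_table`.
#' @param region region name to extract.
#' @return List with `coords` (n x K x 3 array, specimens in dimnames),
#'   `roles` (length-K character, ordered by landmark id), `landmark_id`,
#'   `specimens`, and `population` (per specimen).
#' @export
landmark_array <- function(lm, region) {
  stopifnot(inherits(lm, "landmark_table"))
  sub <- lm[lm$region == region, ]
  if (nrow(sub) == 0L) stop("no landmarks for region '", region, "'")
  ids <- sort(unique(sub$landmark_id))
  specs <- unique(sub$specimen_id)
  K <- length(ids)
  arr <- array(NA_real_, c(length(specs), K, 3L),
               dimnames = list(specs, ids, c("x", "y", "z")))
  sub <- sub[order(match(sub$specimen_id, specs), sub$landmark_id), ]
  arr[cbind(rep(seq_along(specs), each = K), rep(seq_len(K), length(specs)), 1L)] <- sub$x
  arr[cbind(rep(seq_along(specs), each = K), rep(seq_len(K), length(specs)), 2L)] <- sub$y
  arr[cbind(rep(seq_along(specs), each = K), rep(seq_len(K), length(specs)), 3L)] <- sub$z
  ref <- sub[sub$specimen_id == specs[1L], ]
  ref <- ref[order(ref$landmark_id), ]
  pop <- sub$population[match(specs, sub$specimen_id)]
  list(coords = arr, roles = ref$role, landmark_id = ids,
       specimens = specs, population = pop)
}
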