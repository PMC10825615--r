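#' Tile-feature bag for one slide
#'
#' A bag holds every tile kept from one whole-slide image: its grid
#' coordinates (pixels, top-left corner of each tile) and one feature row per
#' tile, extracted upstream by whatever feature extractor the study uses.
#' Bags are the instance containers of the weakly supervised survival model:
#' supervision exists only at the patient level, never per tile.
#'
#' @param slide_id single string identifying the slide.
#' @param patient_id single string identifying the patient the slide belongs to.
#' @param coords integer matrix with `n_tiles` rows and 2 columns (x, y), the
#'   top-left pixel of each tile; rows must be unique within the slide.
#' @param features numeric matrix, `n_tiles` x d, of finite tile features,
#'   aligned row-for-row with `coords`.
#' @param tile_labels optional integer/logical vector of per-tile ground-truth
#'   labels (synthetic cohorts only); `NULL` for real data.
#' @return An object of class `tile_bag`.
#' @export
tile_bag <- function(slide_id, patient_id, coords, features, tile_labels = NULL) {
  coords <- as.matrix(coords)
  features <- as.matrix(features)
  if (!is.character(slide_id) || length(slide_id) != 1L)
    stop("slide_id must be a single string")
  if (!is.character(patient_id) || length(patient_id) != 1L)
    stop("patient_id must be a single string")
  if (nrow(features) < 1L) stop("a tile bag needs at least one tile")
  if (nrow(coords) != nrow(features))
    stop("coords and features must have one row per tile")
  if (ncol(coords) != 2L) stop("coords must have two columns (x, y)")
  if (anyDuplicated(coords) > 0L)
    stop("tile coordinates must be unique within a slide")
  if (!all(is.finite(features))) stop("features must be finite")
  if (!is.null(tile_labels) && length(tile_labels) != nrow(features))
    stop("tile_labels must align with tiles")
  structure(
    list(slide_id = slide_id, patient_id = patient_id,
         coords = coords, features = features, tile_labels = tile_labels),
    class = "tile_bag")
}

#' @export
print.tile_bag <- function(x, ...) {
  cat(sprintf("<tile_bag> slide %s (patient %s): %d tiles x %d features\n",
              x$slide_id, x$patient_id, nrow(x$features), ncol(x$features)))
  invisible(x)
}

n_tiles <- function(bag) nrow(bag$features)

#' Regular tile grid over an image
#'
#' Enumerates the non-overlapping square tiles of side `tile_px` that fit
#' entirely inside a `width_px` x `height_px` image. Coordinates are 0-based
#' pixel positions of each tile's top-left corner; a tile occupies the
#' half-open square `[x, x + tile_px) x [y, y + tile_px)`. Partial tiles at
#' the right/bottom margins are dropped, not padded. Tiles are returned in
#' row-major order (x fastest).
#'
#' @param width_px,height_px image dimensions in pixels (positive integers).
#' @param tile_px tile side in pixels; the default 224 corresponds to
#'   112 micrometers at 0.5 micrometers per pixel.
#' @return Integer matrix with columns `x`, `y`, one row per tile; zero rows
#'   when the tile does not fit.
#' @export
tile_grid <- function(width_px, height_px, tile_px = 224L) {
  stopifnot(width_px >= 1, height_px >= 1, tile_px >= 1)
  nx <- width_px %/% tile_px
  ny <- height_px %/% tile_px
  if (nx < 1L || ny < 1L)
    return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("x", "y"))))
  xs <- (seq_len(nx) - 1L) * tile_px
  ys <- (seq_len(ny) - 1L) * tile_px
  cbind(x = rep(xs, times = ny), y = rep(ys, each = nx))
}

#' Random tile subsampling
#'
#' Caps a bag at `max_tiles` tiles by uniform sampling without replacement,
#' keeping coordinate/feature alignment. Bags at or under the cap pass
#' through untouched, so the operation is idempotent at a fixed cap.
#'
#' @param bag a [tile_bag()].
#' @param max_tiles maximum tiles retained (default 20000).
#' @param seed integer seed making the selection reproducible.
#' @return A `tile_bag` with at most `max_tiles` tiles.
#' @export
subsample_tiles <- function(bag, max_tiles = 20000L, seed = 1L) {
  stopifnot(inherits(bag, "tile_bag"), max_tiles >= 1)
  n <- n_tiles(bag)
  if (n <= max_tiles) return(bag)
  keep <- local_seed(seed, sort(sample.int(n, max_tiles)))
  tile_bag(bag$slide_id, bag$patient_id,
           bag$coords[keep, , drop = FALSE],
           bag$features[keep, , drop = FALSE],
           if (!is.null(bag$tile_labels)) bag$tile_labels[keep])
}

#' Score-threshold tile filter
#'
#' Retains tiles whose external score is at least `threshold`. This is the
#' insertion point for an upstream tile classifier (e.g. a tumor/non-tumor
#' detector): the classifier itself lives outside this package, only its
#' scores enter here.
#'
#' @param bag a [tile_bag()].
#' @param tile_scores numeric vector, one score per tile.
#' @param threshold retain tiles with `score >= threshold`.
#' @return A filtered `tile_bag`; removing every tile is an error.
#' @export
filter_tiles <- function(bag, tile_scores, threshold) {
  stopifnot(inherits(bag, "tile_bag"))
  if (length(tile_scores) != n_tiles(bag))
    stop("tile_scores must align with tiles")
  keep <- which(tile_scores >= threshold)
  if (length(keep) == 0L)
    stop("filter removed every tile of slide ", bag$slide_id)
  tile_bag(bag$slide_id, bag$patient_id,
           bag$coords[keep, , drop = FALSE],
           bag$features[keep, , drop = FALSE],
           if (!is.null(bag$tile_labels)) bag$tile_labels[keep])
}

#' Validate a clinical covariate table
#'
#' @param clinical data.frame with a `patient_id` column and one row per
#'   patient; covariates numeric or binary, missing values as `NA`.
#' @return The table, invisibly, after validation.
#' @export
validate_clinical <- function(clinical) {
  if (!"patient_id" %in% names(clinical)) stop("clinical table needs patient_id")
  if (anyDuplicated(clinical$patient_id) > 0L)
    stop("duplicated patient_id in clinical table")
  invisible(clinical)
}

#' Validate an outcome table
#'
#' One row per (patient, endpoint): observed time in months, event indicator,
#' endpoint label (RFS or DSS).
#'
#' @param outcomes data.frame with columns `patient_id`, `time_months`,
#'   `event`, `endpoint`.
#' @return The table, invisibly, after validation.
#' @export
validate_outcomes <- function(outcomes) {
  need <- c("patient_id", "time_months", "event", "endpoint")
  miss <- setdiff(need, names(outcomes))
  if (length(miss)) stop("outcome table missing columns: ", paste(miss, collapse = ", "))
  if (!all(is.finite(outcomes$time_months)) || any(outcomes$time_months <= 0))
    stop("time_months must be finite and positive")
  if (!all(outcomes$event %in% c(0, 1))) stop("event must be 0 or 1")
  if (!all(outcomes$endpoint %in% c("RFS", "DSS", "OS")))
    stop("endpoint must be RFS, DSS or OS")
  if (anyDuplicated(outcomes[c("patient_id", "endpoint")]) > 0L)
    stop("one row per (patient, endpoint) required")
  invisible(outcomes)
}

validate_cohort_tables <- function(bags, clinical, outcomes) {
  validate_clinical(clinical)
  validate_outcomes(outcomes)
  bag_pat <- unique(vapply(bags, `[[`, character(1), "patient_id"))
  extra <- setdiff(clinical$patient_id, outcomes$patient_id)
  if (length(extra))
    stop("clinical patients absent from outcomes: ", paste(extra, collapse = ", "))
  extra <- setdiff(bag_pat, clinical$patient_id)
  if (length(extra))
    stop("bag patients absent from clinical table: ", paste(extra, collapse = ", "))
  d <- unique(vapply(bags, function(b) ncol(b$features), integer(1)))
  if (length(d) > 1L) stop("feature dimension differs across bags")
  invisible(TRUE)
}

#' Write a cohort to disk
#'
#' Layout: one Parquet file per slide (`features_<slide_id>.parquet`, columns
#' `x`, `y`, optional `tile_label`, then `f1..fd`), plus `clinical.csv` and
#' `outcomes.csv`. Parquet keeps feature doubles bit-exact; the delimited
#' tables stay language-neutral.
#'
#' @param cohort a cohort list with elements `bags`, `clinical`, `outcomes`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  validate_cohort_tables(cohort$bags, cohort$clinical, cohort$outcomes)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (bag in cohort$bags) {
    df <- data.frame(patient_id = bag$patient_id,
                     x = bag$coords[, 1], y = bag$coords[, 2])
    if (!is.null(bag$tile_labels)) df$tile_label <- as.integer(bag$tile_labels)
    feat <- as.data.frame(bag$features)
    names(feat) <- paste0("f", seq_len(ncol(feat)))
    arrow::write_parquet(cbind(df, feat),
                         file.path(dir, paste0("features_", bag$slide_id, ".parquet")))
  }
  data.table::fwrite(cohort$clinical, file.path(dir, "clinical.csv"))
  data.table::fwrite(cohort$outcomes, file.path(dir, "outcomes.csv"))
  invisible(dir)
}

#' Read a cohort from disk
#'
#' Inverse of [write_cohort()]: loads every `features_*.parquet` slide file
#' plus `clinical.csv` and `outcomes.csv`, validates cross-table consistency
#' and returns the same structure [generate_cohort()] produces (without the
#' `truth` element unless tile labels were stored).
#'
#' @param dir directory written by [write_cohort()].
#' @return List with `bags`, `clinical`, `outcomes`.
#' @export
read_cohort <- function(dir) {
  files <- sort(list.files(dir, pattern = "^features_.*\\.parquet$", full.names = TRUE))
  if (!length(files)) stop("no slide feature files under ", dir)
  bags <- lapply(files, function(f) {
    df <- as.data.frame(arrow::read_parquet(f))
    slide_id <- sub("^features_(.*)\\.parquet$", "\\1", basename(f))
    fcols <- grep("^f[0-9]+$", names(df), value = TRUE)
    fcols <- fcols[order(as.integer(sub("^f", "", fcols)))]
    tile_bag(slide_id, df$patient_id[1],
             cbind(x = df$x, y = df$y),
             as.matrix(df[fcols]),
             if ("tile_label" %in% names(df)) df$tile_label else NULL)
  })
  clinical <- as.data.frame(data.table::fread(file.path(dir, "clinical.csv")))
  outcomes <- as.data.frame(data.table::fread(file.path(dir, "outcomes.csv")))
  validate_cohort_tables(bags, clinical, outcomes)
  list(bags = bags, clinical = clinical, outcomes = outcomes)
}

# Run expr under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards.
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}
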