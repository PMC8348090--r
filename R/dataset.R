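# Published inventory of the dairy-cow jaw-movement segment collection:
# file counts and total durations (s) per behavior x forage cell.
INVENTORY_TABLE <- data.frame(
  forage_species = rep(c("alfalfa", "tall_fescue"), each = 6),
  forage_height = rep(rep(c("short", "tall"), each = 3), 2),
  behavior = rep(c("bite", "chew", "chew_bite"), 4),
  n_files = c(179, 260, 123, 148, 416, 322,
              94, 454, 217, 100, 487, 238),
  duration_s = c(72.78, 74.24, 71.99, 175.20, 184.56, 182.90,
                 143.87, 144.79, 141.59, 155.19, 149.78, 150.48),
  stringsAsFactors = FALSE
)

#' Manifest matching the reference segment inventory
#'
#' Expands the published per-cell file counts and total durations of the
#' dairy-cow jaw-movement segment collection into a manifest: each cell
#' contributes its file count, with the cell's total duration divided
#' equally among its files. Useful for exercising the inventory,
#' balancing, and splitting protocol without the recordings themselves.
#'
#' @return A manifest `data.frame` with 3038 rows.
#' @export
reference_manifest <- function() {
  rows <- lapply(seq_len(nrow(INVENTORY_TABLE)), function(i) {
    cell <- INVENTORY_TABLE[i, ]
    data.frame(
      file = sprintf("%s_%s_%s_%04d.wav", cell$behavior, cell$forage_species,
                     cell$forage_height, seq_len(cell$n_files)),
      behavior = cell$behavior,
      forage_species = cell$forage_species,
      forage_height = cell$forage_height,
      duration_s = cell$duration_s / cell$n_files,
      stringsAsFactors = FALSE)
  })
  validate_manifest(do.call(rbind, rows))
}

#' Inventory summary of a manifest
#'
#' Tabulates file counts and total durations per
#' behavior x forage species x forage height cell, per-behavior totals,
#' and grand totals.
#'
#' @param manifest A manifest `data.frame`.
#' @return An object of class `inventory_summary` with `cells` (a
#'   `data.frame`), `behavior_totals`, and `grand` totals.
#' @export
inventory <- function(manifest) {
  if (nrow(manifest) == 0L) {
    return(structure(list(
      cells = data.frame(),
      behavior_totals = data.frame(
        behavior = BEHAVIORS, n_files = 0L, duration_s = 0,
        stringsAsFactors = FALSE),
      grand = list(n_files = 0L, duration_s = 0)),
      class = "inventory_summary"))
  }
  validate_manifest(manifest)
  key <- interaction(manifest$behavior, manifest$forage_species,
                     manifest$forage_height, drop = TRUE)
  cells <- do.call(rbind, lapply(split(manifest, key), function(g) {
    data.frame(behavior = g$behavior[1], forage_species = g$forage_species[1],
               forage_height = g$forage_height[1], n_files = nrow(g),
               duration_s = sum(g$duration_s), stringsAsFactors = FALSE)
  }))
  rownames(cells) <- NULL
  behavior_totals <- do.call(rbind, lapply(BEHAVIORS, function(b) {
    sel <- manifest$behavior == b
    data.frame(behavior = b, n_files = sum(sel),
               duration_s = sum(manifest$duration_s[sel]),
               stringsAsFactors = FALSE)
  }))
  structure(list(cells = cells, behavior_totals = behavior_totals,
                 grand = list(n_files = nrow(manifest),
                              duration_s = sum(manifest$duration_s))),
            class = "inventory_summary")
}

#' @export
print.inventory_summary <- function(x, ...) {
  cat("<inventory_summary>\n")
  if (nrow(x$behavior_totals)) {
    print(x$behavior_totals, row.names = FALSE)
  }
  cat(sprintf("grand total: %d files, %.2f s\n",
              x$grand$n_files, x$grand$duration_s))
  invisible(x)
}

#' Balance a manifest by file count
#'
#' Subsamples each behavior without replacement, uniformly at random, down
#' to the smallest per-behavior file count. The minority behavior is
#' retained in full, so its total duration is unchanged; the durations of
#' the subsampled behaviors depend on the draw.
#'
#' @param manifest A manifest `data.frame` with at least one file per
#'   behavior.
#' @param seed Integer seed for the subsampling draw.
#' @return The balanced manifest (row order: behavior blocks in the input
#'   order of first appearance of the retained rows).
#' @export
balance_by_count <- function(manifest, seed = 1L) {
  validate_manifest(manifest)
  counts <- table(factor(manifest$behavior, levels = BEHAVIORS))
  if (any(counts == 0L)) {
    stop("cannot balance: behavior(s) with zero files: ",
         paste(names(counts)[counts == 0L], collapse = ", "), call. = FALSE)
  }
  target <- min(counts)
  with_seed(seed, {
    keep <- unlist(lapply(BEHAVIORS, function(b) {
      rows <- which(manifest$behavior == b)
      if (length(rows) > target) sort(sample(rows, target)) else rows
    }))
  })
  manifest[sort(keep), , drop = FALSE]
}

#' Split specification
#'
#' @param ratios Length-3 positive fractions `(train, val, test)` summing
#'   to 1 (default `c(0.7, 0.1, 0.2)`).
#' @param seed Integer seed for the randomized assignment.
#' @param stratify_by `"behavior"` (default) to split within each behavior
#'   class, or `"none"`.
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(ratios = c(0.7, 0.1, 0.2), seed = 1L,
                       stratify_by = c("behavior", "none")) {
  stratify_by <- match.arg(stratify_by)
  if (length(ratios) != 3L || any(ratios <= 0) ||
      abs(sum(ratios) - 1) > 1e-8) {
    stop("ratios must be three positive fractions summing to 1", call. = FALSE)
  }
  structure(list(ratios = ratios, seed = as.integer(seed),
                 stratify_by = stratify_by),
            class = "split_spec")
}

# floor/floor/remainder partition of n rows after a seeded shuffle
split_indices <- function(n, ratios) {
  n_train <- floor(ratios[1] * n)
  n_val <- floor(ratios[2] * n)
  list(train = seq_len(n_train),
       val = seq_len(n_val) + n_train,
       test = seq_len(n - n_train - n_val) + n_train + n_val)
}

#' Randomized train/validation/test split
#'
#' Partitions a manifest into disjoint, exhaustive train/validation/test
#' subsets with sizes `floor(r1 n)`, `floor(r2 n)`, and the remainder.
#' With `stratify_by = "behavior"` the floor policy is applied within each
#' behavior class, guaranteeing per-class representation.
#'
#' @param manifest A manifest `data.frame`.
#' @param spec A [split_spec].
#' @return A named list of three manifests `train`, `val`, `test`.
#' @export
split_manifest <- function(manifest, spec = split_spec()) {
  stopifnot(inherits(spec, "split_spec"))
  validate_manifest(manifest)
  assign_one <- function(rows, seed) {
    perm <- with_seed(seed, sample(rows))
    idx <- split_indices(length(rows), spec$ratios)
    lapply(idx, function(i) sort(perm[i]))
  }
  if (spec$stratify_by == "behavior") {
    small <- table(factor(manifest$behavior, levels = BEHAVIORS))
    if (any(small < 3L)) {
      stop("stratified split needs >= 3 files per behavior; got ",
           paste(sprintf("%s=%d", names(small), small), collapse = ", "),
           call. = FALSE)
    }
    parts <- lapply(seq_along(BEHAVIORS), function(k) {
      assign_one(which(manifest$behavior == BEHAVIORS[k]),
                 derive_seed(spec$seed, k))
    })
    out <- lapply(c(train = 1L, val = 2L, test = 3L), function(j) {
      manifest[sort(unlist(lapply(parts, `[[`, j))), , drop = FALSE]
    })
  } else {
    idx <- assign_one(seq_len(nrow(manifest)), spec$seed)
    out <- lapply(idx, function(i) manifest[i, , drop = FALSE])
  }
  out
}

#' Filter a manifest by forage condition
#'
#' @param manifest A manifest `data.frame`.
#' @param species Optional forage species to keep (`NULL` = all).
#' @param height Optional forage height to keep (`NULL` = all).
#' @return The filtered manifest.
#' @export
filter_by_forage <- function(manifest, species = NULL, height = NULL) {
  keep <- rep(TRUE, nrow(manifest))
  if (!is.null(species)) {
    species <- match_enum(species, FORAGE_SPECIES, "species")
    keep <- keep & manifest$forage_species == species
  }
  if (!is.null(height)) {
    height <- match_enum(height, FORAGE_HEIGHTS, "height")
    keep <- keep & manifest$forage_height == height
  }
  manifest[keep, , drop = FALSE]
}
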