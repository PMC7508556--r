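# Data model and file I/O: specimen/trait tables, 3D landmark tables,
# phylogenies. Delimited text throughout (comma default, tab accepted);
# Newick for trees.

#' Construct a landmark configuration
#'
#' A single skeletal structure of a single specimen: 18 named 3D landmarks
#' in mm, with a structure (`pectoral`/`pelvic`) and side (`left`/`right`)
#' label. Downstream superimposition requires all configurations to be on
#' the left side; right-side configurations are reflected first with
#' [mirror_configuration()].
#'
#' @param coords numeric 18 x 3 matrix of landmark coordinates (mm).
#' @param structure `"pectoral"` or `"pelvic"`.
#' @param side `"left"` or `"right"`.
#' @return An object of class `landmark_config`.
#' @export
landmark_configuration <- function(coords, structure, side = "left") {
  coords <- as.matrix(coords)
  structure <- match.arg(structure, c("pectoral", "pelvic"))
  side <- match.arg(side, c("left", "right"))
  if (!is.numeric(coords) || nrow(coords) != 18L || ncol(coords) != 3L)
    .stopf("expected 18 landmarks x 3 coordinates, got %d x %d",
           nrow(coords), ncol(coords))
  if (any(!is.finite(coords)))
    .stopf("landmark coordinates must be finite (structure %s)", structure)
  dimnames(coords) <- list(sprintf("L%02d", 1:18), c("x", "y", "z"))
  structure(list(coords = coords, structure = structure, side = side),
            class = "landmark_config")
}

#' @export
print.landmark_config <- function(x, ...) {
  cat(sprintf("landmark_config: %s girdle, %s side, 18 x 3 (mm), CS = %.4f\n",
              x$structure, x$side, centroid_size(x)))
  invisible(x)
}

.trait_class_from_name <- function(nm) {
  cls <- rep(NA_character_, length(nm))
  cls[startsWith(nm, "shape_")] <- "shape"
  cls[startsWith(nm, "len_")]   <- "length"
  cls[startsWith(nm, "thick_")] <- "thickness"
  cls[startsWith(nm, "size_")]  <- "size"
  cls
}

#' Construct a morphometric dataset
#'
#' Bundles specimen metadata records with an (optional) trait matrix,
#' per-specimen landmark configurations and a raw linear-measurement table.
#' Invariants (unique specimen ids, valid factor levels, treatment only for
#' experimental animals, positive raw linear measurements) are enforced;
#' [validate_dataset()] re-checks them and tallies the design.
#'
#' @param records data.frame with columns `specimen_id`, `species`, `island`,
#'   `ecomorph`, `sex`, `source`, `treatment`.
#' @param traits optional numeric matrix (rows = specimens, in `records`
#'   order) whose column names carry provenance prefixes `shape_pec_`,
#'   `shape_pel_`, `len_`, `thick_`, `size_`.
#' @param landmarks optional named list `specimen_id -> list(pectoral=,
#'   pelvic=)` of [landmark_configuration()] objects.
#' @param linear optional data.frame of raw lengths/thicknesses in mm with a
#'   `specimen_id` column.
#' @return An object of class `morph_dataset`.
#' @export
morph_dataset <- function(records, traits = NULL, landmarks = NULL,
                          linear = NULL) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  missing_cols <- setdiff(META_COLS, names(records))
  if (length(missing_cols))
    .stopf("records lack metadata column(s): %s",
           paste(missing_cols, collapse = ", "))
  dup <- records$specimen_id[duplicated(records$specimen_id)]
  if (length(dup))
    .stopf("duplicate specimen id(s): %s", paste(unique(dup), collapse = ", "))
  .check_levels <- function(x, levels, col, allow_na = TRUE) {
    bad <- !(x %in% levels) & !(allow_na & is.na(x))
    if (any(bad))
      .stopf("unknown %s value(s): %s (rows %s)", col,
             paste(unique(x[bad]), collapse = ", "),
             paste(which(bad), collapse = ", "))
  }
  .check_levels(records$island, ISLANDS, "island")
  .check_levels(records$ecomorph, ECOMORPHS, "ecomorph")
  .check_levels(records$sex, SEXES, "sex", allow_na = FALSE)
  .check_levels(records$source, SOURCES, "source", allow_na = FALSE)
  .check_levels(records$treatment, TREATMENTS, "treatment")
  bad_exp <- records$source == "experiment" & is.na(records$treatment)
  if (any(bad_exp))
    .stopf("experimental specimen(s) without treatment: %s",
           paste(records$specimen_id[bad_exp], collapse = ", "))
  bad_mus <- records$source == "museum" & !is.na(records$treatment)
  if (any(bad_mus))
    .stopf("museum specimen(s) with a treatment: %s",
           paste(records$specimen_id[bad_mus], collapse = ", "))
  if (!is.null(traits)) {
    traits <- as.matrix(traits)
    storage.mode(traits) <- "double"
    if (nrow(traits) != nrow(records))
      .stopf("trait matrix has %d rows but records has %d",
             nrow(traits), nrow(records))
    rownames(traits) <- records$specimen_id
  }
  if (!is.null(linear)) {
    lin_num <- linear[setdiff(names(linear), "specimen_id")]
    neg <- vapply(lin_num, function(v) any(!is.na(v) & v <= 0), logical(1L))
    if (any(neg))
      .stopf("non-positive raw linear measurement in column(s): %s",
             paste(names(lin_num)[neg], collapse = ", "))
  }
  structure(list(records = records, traits = traits,
                 landmarks = landmarks, linear = linear),
            class = "morph_dataset")
}

#' @export
print.morph_dataset <- function(x, ...) {
  cat(sprintf("morph_dataset: %d specimens, %d species",
              nrow(x$records), length(unique(x$records$species))))
  if (!is.null(x$traits)) cat(sprintf(", %d traits", ncol(x$traits)))
  if (!is.null(x$landmarks)) cat(sprintf(", landmarks for %d specimens",
                                         length(x$landmarks)))
  cat("\n")
  invisible(x)
}

.read_delim_auto <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    na.strings = c("", "NA"), stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "")
}

#' Read a specimen/trait table
#'
#' One header row; the fixed-named metadata columns (`specimen_id`,
#' `species`, `island`, `ecomorph`, `sex`, `source`, `treatment`) followed
#' by trait columns whose provenance is encoded by name prefix
#' (`shape_pec_`, `shape_pel_`, `len_`, `thick_`, `size_`). Comma- or
#' tab-delimited; empty cells and `NA` both read as missing.
#'
#' @param path path to a delimited text file.
#' @return A [morph_dataset()] with typed records and a numeric trait matrix
#'   (possibly 0-column when the file holds metadata only).
#' @export
read_specimen_table <- function(path) {
  df <- .read_delim_auto(path)
  missing_cols <- setdiff(META_COLS, names(df))
  if (length(missing_cols))
    .stopf("file %s lacks metadata column(s): %s", path,
           paste(missing_cols, collapse = ", "))
  trait_cols <- setdiff(names(df), META_COLS)
  traits <- NULL
  if (length(trait_cols)) {
    traits <- matrix(NA_real_, nrow(df), length(trait_cols),
                     dimnames = list(NULL, trait_cols))
    for (j in seq_along(trait_cols)) {
      v <- df[[trait_cols[j]]]
      num <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & is.na(num))
      if (length(bad))
        .stopf("non-numeric trait cell in column '%s', row %d ('%s')",
               trait_cols[j], bad[1L], v[bad[1L]])
      traits[, j] <- num
    }
    unknown <- trait_cols[is.na(.trait_class_from_name(trait_cols))]
    if (length(unknown))
      .warnf("trait column(s) without provenance prefix: %s",
             paste(unknown, collapse = ", "))
  }
  for (cc in META_COLS) df[[cc]] <- as.character(df[[cc]])
  morph_dataset(df[META_COLS], traits = traits)
}

#' Write a specimen/trait table
#'
#' Inverse of [read_specimen_table()]; numeric values are written at full
#' precision so that a write/read round trip reproduces them to 1e-12.
#'
#' @param dataset a [morph_dataset()].
#' @param path output path.
#' @param sep field separator, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_specimen_table <- function(dataset, path, sep = ",") {
  stopifnot(inherits(dataset, "morph_dataset"))
  out <- dataset$records
  if (!is.null(dataset$traits) && ncol(dataset$traits)) {
    tr <- as.data.frame(dataset$traits)
    # full precision for lossless round trips
    tr[] <- lapply(tr, function(v) sprintf("%.17g", v))
    tr[is.na(dataset$traits)] <- NA
    out <- cbind(out, tr)
  }
  utils::write.table(out, path, sep = sep, quote = FALSE, na = "NA",
                     row.names = FALSE)
  invisible(path)
}

#' Read a long-format 3D landmark table
#'
#' Expects columns `specimen_id`, `structure` (pectoral/pelvic), `side`
#' (left/right), `landmark` (index 1-18), `x`, `y`, `z` in mm. Each
#' specimen x structure block must contain exactly the 18 indices.
#'
#' @param path path to a delimited text file.
#' @return Named list `specimen_id -> list(pectoral = , pelvic = )` of
#'   [landmark_configuration()] objects (a structure absent from the file is
#'   absent from the inner list).
#' @export
read_landmarks <- function(path) {
  df <- .read_delim_auto(path)
  need <- c("specimen_id", "structure", "side", "landmark", "x", "y", "z")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    .stopf("landmark file lacks column(s): %s",
           paste(missing_cols, collapse = ", "))
  out <- list()
  for (key in split(seq_len(nrow(df)),
                    paste(df$specimen_id, df$structure, sep = "\r"))) {
    block <- df[key, ]
    id <- block$specimen_id[1L]
    struct <- block$structure[1L]
    idx <- sort(block$landmark)
    if (!identical(as.integer(idx), 1:18))
      .stopf("specimen %s, %s girdle: expected 18 landmarks indexed 1-18, got %d",
             id, struct, nrow(block))
    side <- unique(block$side)
    if (length(side) != 1L)
      .stopf("specimen %s, %s girdle: inconsistent side labels", id, struct)
    block <- block[order(block$landmark), ]
    cfg <- landmark_configuration(as.matrix(block[, c("x", "y", "z")]),
                                  structure = struct, side = side)
    out[[id]][[struct]] <- cfg
  }
  out
}

#' Write landmark configurations as a long-format table
#'
#' @param landmarks named list as returned by [read_landmarks()].
#' @param path output path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(landmarks, path, sep = ",") {
  rows <- list()
  for (id in names(landmarks)) {
    for (struct in names(landmarks[[id]])) {
      cfg <- landmarks[[id]][[struct]]
      rows[[length(rows) + 1L]] <- data.frame(
        specimen_id = id, structure = cfg$structure, side = cfg$side,
        landmark = 1:18, x = cfg$coords[, 1L], y = cfg$coords[, 2L],
        z = cfg$coords[, 3L], stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  df$x <- sprintf("%.17g", df$x)
  df$y <- sprintf("%.17g", df$y)
  df$z <- sprintf("%.17g", df$z)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phylogeny from a Newick file
#'
#' @param path path to a Newick file.
#' @return An [ape::read.tree()] `phylo` object; branch lengths are
#'   required, zero-length branches tolerated with a warning.
#' @export
read_tree <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) .stopf("could not parse Newick file %s", path)
  .check_tree(tree)
  tree
}

.check_tree <- function(tree) {
  if (is.null(tree$edge.length))
    .stopf("tree has no branch lengths; they are required")
  if (any(tree$edge.length < 0)) .stopf("negative branch length in tree")
  if (any(tree$edge.length == 0)) .warnf("tree contains zero-length branches")
  if (anyDuplicated(tree$tip.label))
    .stopf("duplicate tip labels: %s",
           paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
                 collapse = ", "))
  invisible(tree)
}

#' Prune a phylogeny to a set of tips
#'
#' Retains only the requested tips and collapses redundant internal nodes;
#' patristic distances among retained tips are preserved exactly.
#'
#' @param tree a `phylo` object.
#' @param tips character vector of tip labels to keep.
#' @return The pruned `phylo` object.
#' @export
prune_tree <- function(tree, tips) {
  missing_tips <- setdiff(tips, tree$tip.label)
  if (length(missing_tips))
    .stopf("tip %s not found in tree", paste(missing_tips, collapse = ", "))
  ape::keep.tip(tree, tips)
}

#' Graft a new tip onto a sister tip's terminal branch
#'
#' Attaches `new_tip` along the terminal branch of `sister_tip`, at
#' `fraction` of the branch measured from the sister's parent node (the
#' attachment point the source phylogeny does not determine; default
#' halfway). The new tip's branch length equals the remaining distance to
#' the sister, so an ultrametric input stays ultrametric and the graft is
#' contemporaneous with its sister.
#'
#' @param tree a `phylo` object.
#' @param new_tip label of the tip to add (must be absent).
#' @param sister_tip label of the existing sister (must be present).
#' @param fraction attachment point in (0, 1) along the sister's terminal
#'   branch, from the parent node.
#' @return The augmented `phylo` object.
#' @export
graft_tip <- function(tree, new_tip, sister_tip, fraction = 0.5) {
  if (new_tip %in% tree$tip.label)
    .stopf("tip '%s' already present in tree", new_tip)
  if (!(sister_tip %in% tree$tip.label))
    .stopf("sister tip '%s' not found in tree", sister_tip)
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1)
    .stopf("fraction must lie strictly between 0 and 1")
  where <- match(sister_tip, tree$tip.label)
  b <- tree$edge.length[tree$edge[, 2L] == where]
  # position is measured rootward from the sister tip
  pos <- b * (1 - fraction)
  phytools::bind.tip(tree, new_tip, edge.length = pos, where = where,
                     position = pos)
}

#' Patristic distance between two tips
#'
#' Sum of branch lengths along the path connecting the tips.
#'
#' @param tree a `phylo` object.
#' @param a,b tip labels.
#' @return A single non-negative number.
#' @export
patristic_distance <- function(tree, a, b) {
  d <- ape::cophenetic.phylo(tree)
  for (tip in c(a, b)) if (!(tip %in% rownames(d)))
    .stopf("tip %s not found in tree", tip)
  d[a, b]
}

#' Validate a morphometric dataset and tally its design
#'
#' Re-checks the `morph_dataset` invariants without aborting and counts
#' specimens per island x ecomorph cell.
#'
#' @param dataset a [morph_dataset()] (or a bare records data.frame).
#' @return A list of class `validation_report` with `errors`, `warnings`
#'   and `counts` (island x ecomorph table); `errors` is empty iff the
#'   dataset passes all invariants.
#' @export
validate_dataset <- function(dataset) {
  records <- if (inherits(dataset, "morph_dataset")) dataset$records
             else as.data.frame(dataset)
  errors <- character(0)
  warnings <- character(0)
  dup <- unique(records$specimen_id[duplicated(records$specimen_id)])
  if (length(dup))
    errors <- c(errors, sprintf("duplicate specimen id(s): %s",
                                paste(dup, collapse = ", ")))
  chk <- function(x, lv, nm) {
    bad <- unique(x[!(x %in% lv) & !is.na(x)])
    if (length(bad)) sprintf("unknown %s value(s): %s", nm,
                             paste(bad, collapse = ", "))
  }
  errors <- c(errors,
              chk(records$island, ISLANDS, "island"),
              chk(records$ecomorph, ECOMORPHS, "ecomorph"),
              chk(records$sex, SEXES, "sex"),
              chk(records$source, SOURCES, "source"),
              chk(records$treatment, TREATMENTS, "treatment"))
  bad_exp <- records$source == "experiment" & is.na(records$treatment)
  if (any(bad_exp, na.rm = TRUE))
    errors <- c(errors, sprintf("experimental specimen(s) without treatment: %s",
                                paste(records$specimen_id[which(bad_exp)],
                                      collapse = ", ")))
  bad_mus <- records$source == "museum" & !is.na(records$treatment)
  if (any(bad_mus, na.rm = TRUE))
    errors <- c(errors, sprintf("museum specimen(s) with treatment: %s",
                                paste(records$specimen_id[which(bad_mus)],
                                      collapse = ", ")))
  if (inherits(dataset, "morph_dataset") && !is.null(dataset$linear)) {
    lin <- dataset$linear[setdiff(names(dataset$linear), "specimen_id")]
    neg <- vapply(lin, function(v) any(!is.na(v) & v <= 0), logical(1L))
    if (any(neg))
      errors <- c(errors, sprintf("non-positive linear measurement column(s): %s",
                                  paste(names(lin)[neg], collapse = ", ")))
    mfrac <- mean(is.na(as.matrix(lin)))
    if (mfrac > 0.1)
      warnings <- c(warnings,
                    sprintf("%.1f%% of linear measurements missing", 100 * mfrac))
  }
  counts <- table(island = factor(records$island, ISLANDS),
                  ecomorph = factor(records$ecomorph, ECOMORPHS))
  structure(list(errors = errors, warnings = warnings, counts = counts),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("validation_report: %d error(s), %d warning(s)\n",
              length(x$errors), length(x$warnings)))
  for (e in x$errors) cat("  error: ", e, "\n", sep = "")
  for (w in x$warnings) cat("  warning: ", w, "\n", sep = "")
  print(x$counts)
  invisible(x)
}
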