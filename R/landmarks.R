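# Landmark bookkeeping and morphometrics file formats. Landmark definition
# files are plain UTF-8 text, one definition per non-comment line:
#
#   <number> [type=1|2|3] <free-text description>
#
# with running numbers contiguous from 1 and optional '#' comment lines.
# Symmetry maps use lines 'midline <numbers...>' and 'pair <left> <right>'.
# Exports are TPS (LM3= dialect, 3D) and an NTSYS rectangular coordinate
# matrix; both ship with readers so round trips are testable bit-exactly.

#' Construct landmark definitions
#'
#' @param numbers running integers, unique and contiguous from 1.
#' @param descriptions free-text descriptions.
#' @param lm_type optional Bookstein landmark types (1, 2 or 3; NA allowed).
#' @param role optional roles (`"regular"`, `"plane_point"`, `"axis_point"`).
#' @return data.frame of class `landmark_defs`.
#' @export
landmark_defs <- function(numbers, descriptions, lm_type = NA_integer_,
                          role = "regular") {
  numbers <- as.integer(numbers)
  n <- length(numbers)
  if (n == 0) stop("no landmark definitions", call. = FALSE)
  if (anyDuplicated(numbers)) {
    stop("duplicate landmark number: ", numbers[duplicated(numbers)][1],
         call. = FALSE)
  }
  if (!identical(sort(numbers), seq_len(n))) {
    missing <- setdiff(seq_len(n), numbers)[1]
    stop("landmark numbers must be contiguous from 1; missing ", missing,
         call. = FALSE)
  }
  lm_type <- rep_len(as.integer(lm_type), n)
  if (any(!is.na(lm_type) & !(lm_type %in% 1:3))) {
    stop("lm_type must be 1, 2 or 3", call. = FALSE)
  }
  d <- data.frame(number = numbers, description = as.character(descriptions),
                  lm_type = lm_type, role = rep_len(role, n),
                  stringsAsFactors = FALSE)
  d <- d[order(d$number), ]
  rownames(d) <- NULL
  class(d) <- c("landmark_defs", "data.frame")
  d
}

#' Load a landmark definition file
#'
#' @param path text file: `<number> [type=N] <description>` per line,
#'   `#` comments and blank lines ignored.
#' @return a [landmark_defs()] data.frame.
#' @export
load_landmark_list <- function(path) {
  if (!file.exists(path)) stop("landmark file not found: ", path, call. = FALSE)
  raw <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- which(nzchar(trimws(raw)) & !startsWith(trimws(raw), "#"))
  if (length(keep) == 0) stop("empty landmark file: ", path, call. = FALSE)
  nums <- integer(0); descs <- character(0); types <- integer(0)
  for (li in keep) {
    toks <- strsplit(trimws(raw[li]), "\\s+")[[1]]
    num <- suppressWarnings(as.integer(toks[1]))
    if (is.na(num)) {
      stop("line ", li, ": expected a landmark number, got '", toks[1], "'",
           call. = FALSE)
    }
    toks <- toks[-1]
    ty <- NA_integer_
    if (length(toks) && grepl("^type=[123]$", toks[1])) {
      ty <- as.integer(sub("type=", "", toks[1]))
      toks <- toks[-1]
    }
    nums <- c(nums, num)
    types <- c(types, ty)
    descs <- c(descs, paste(toks, collapse = " "))
  }
  expected <- seq_along(nums)
  bad <- which(nums != expected)
  if (length(bad)) {
    stop("line ", keep[bad[1]], ": landmark numbered ", nums[bad[1]],
         " where ", expected[bad[1]], " was expected (numbers must run 1, 2, ...)",
         call. = FALSE)
  }
  landmark_defs(nums, descs, types)
}

#' Create an empty landmark set for one specimen
#'
#' @param defs a [landmark_defs()] data.frame.
#' @param specimen_id specimen label written to exports.
#' @return a `landmark_set`: `defs`, `coords` (n x 3 matrix, NA until
#'   marked), `specimen_id`.
#' @export
new_landmark_set <- function(defs, specimen_id = "specimen") {
  stopifnot(inherits(defs, "landmark_defs"))
  coords <- matrix(NA_real_, nrow(defs), 3,
                   dimnames = list(defs$number, c("x", "y", "z")))
  structure(list(defs = defs, coords = coords,
                 specimen_id = as.character(specimen_id)),
            class = "landmark_set")
}

#' Store the cursor position as a landmark's coordinates
#'
#' Re-marking an already-marked landmark overwrites it with a notice.
#'
#' @param set a `landmark_set`.
#' @param number landmark number.
#' @param cursor a `cursor3d` (or a length-3 world point).
#' @return the updated `landmark_set`.
#' @export
mark_point <- function(set, number, cursor) {
  stopifnot(inherits(set, "landmark_set"))
  i <- match(as.integer(number), set$defs$number)
  if (is.na(i)) stop("unknown landmark number ", number, call. = FALSE)
  pos <- if (inherits(cursor, "cursor3d")) cursor$position else as.numeric(cursor)
  if (!anyNA(set$coords[i, ])) {
    message("re-marking landmark ", number, " (previous coordinates overwritten)")
  }
  set$coords[i, ] <- pos
  set
}

#' Stored coordinates of a marked landmark
#'
#' The session-level jump moves the synchronized cursor here and regenerates
#' the slices; this accessor returns the coordinates.
#'
#' @param set a `landmark_set`.
#' @param number landmark number, already marked.
#' @return world point (length 3).
#' @export
jump_stored <- function(set, number) {
  stopifnot(inherits(set, "landmark_set"))
  i <- match(as.integer(number), set$defs$number)
  if (is.na(i)) stop("unknown landmark number ", number, call. = FALSE)
  if (anyNA(set$coords[i, ])) {
    stop("landmark ", number, " has not been marked yet", call. = FALSE)
  }
  as.numeric(set$coords[i, ])
}

#' Construct a bilateral symmetry map
#'
#' @param midline landmark numbers lying on the sagittal plane.
#' @param pairs 2-column matrix (or data.frame) of (left, right) landmark
#'   numbers; linking lines for display run between pair members.
#' @param defs the [landmark_defs()] the numbers refer to.
#' @return a `symmetry_map` with `midline` and `pairs`.
#' @export
symmetry_map <- function(midline, pairs, defs) {
  stopifnot(inherits(defs, "landmark_defs"))
  midline <- as.integer(midline)
  if (is.data.frame(pairs)) pairs <- as.matrix(pairs)
  if (length(pairs) == 0) {
    pairs <- matrix(integer(0), 0, 2)
  } else if (!is.matrix(pairs)) {
    pairs <- matrix(as.integer(pairs), ncol = 2, byrow = TRUE)
  }
  storage.mode(pairs) <- "integer"
  all_nums <- c(midline, as.vector(pairs))
  unknown <- setdiff(all_nums, defs$number)
  if (length(unknown)) {
    stop("symmetry map references unknown landmark number ", unknown[1],
         call. = FALSE)
  }
  if (any(pairs[, 1] == pairs[, 2])) {
    stop("a landmark cannot be paired with itself", call. = FALSE)
  }
  paired <- as.vector(pairs)
  if (anyDuplicated(paired)) {
    stop("landmark ", paired[duplicated(paired)][1],
         " appears in more than one pair", call. = FALSE)
  }
  both <- intersect(midline, paired)
  if (length(both)) {
    stop("landmark ", both[1], " cannot be both midline and paired", call. = FALSE)
  }
  colnames(pairs) <- c("left", "right")
  structure(list(midline = sort(unique(midline)), pairs = pairs),
            class = "symmetry_map")
}

#' Load a symmetry map file
#'
#' @param path text file with lines `midline <numbers...>` and
#'   `pair <left> <right>`; `#` comments allowed.
#' @param defs the [landmark_defs()] the numbers refer to.
#' @return a [symmetry_map()].
#' @export
load_symmetry_map <- function(path, defs) {
  if (!file.exists(path)) stop("symmetry file not found: ", path, call. = FALSE)
  raw <- trimws(readLines(path, warn = FALSE, encoding = "UTF-8"))
  raw <- raw[nzchar(raw) & !startsWith(raw, "#")]
  midline <- integer(0)
  pairs <- matrix(integer(0), 0, 2)
  for (line in raw) {
    toks <- strsplit(line, "\\s+")[[1]]
    if (toks[1] == "midline") {
      midline <- c(midline, as.integer(toks[-1]))
    } else if (toks[1] == "pair") {
      if (length(toks) != 3) stop("bad pair line: ", line, call. = FALSE)
      pairs <- rbind(pairs, as.integer(toks[2:3]))
    } else {
      stop("unrecognized symmetry line: ", line, call. = FALSE)
    }
  }
  symmetry_map(midline, pairs, defs)
}

#' Endpoints of the left-right linking lines
#'
#' The computational version of the "linking lines" visual ordering check:
#' each row gives the two marked coordinates a display would connect.
#'
#' @param set a fully (or partially) marked `landmark_set`.
#' @param map a [symmetry_map()].
#' @return data.frame with pair numbers and both endpoints' coordinates
#'   (NA where unmarked).
#' @export
linking_lines <- function(set, map) {
  stopifnot(inherits(set, "landmark_set"), inherits(map, "symmetry_map"))
  li <- match(map$pairs[, 1], set$defs$number)
  ri <- match(map$pairs[, 2], set$defs$number)
  data.frame(left = map$pairs[, 1], right = map$pairs[, 2],
             lx = set$coords[li, 1], ly = set$coords[li, 2], lz = set$coords[li, 3],
             rx = set$coords[ri, 1], ry = set$coords[ri, 2], rz = set$coords[ri, 3])
}

# --- TPS ---------------------------------------------------------------------

#' Export a landmark set as a 3D TPS file
#'
#' Dialect: `LM3=<n>` header, n lines of space-separated `x y z` in fixed
#' decimal, `ID=<specimen_id>` trailer. Coordinates are written in world
#' (physical) units by default; `units = "voxel"` divides by the volume
#' spacing for grid-unit output.
#'
#' @param set a `landmark_set`.
#' @param path output file.
#' @param strict error when any landmark is unmarked (default). With
#'   `strict = FALSE` unmarked landmarks are silently omitted from the
#'   count and rows.
#' @param digits decimal places written.
#' @param units `"world"` or `"voxel"`.
#' @param spacing voxel spacing, required for `units = "voxel"`.
#' @return `path`, invisibly.
#' @export
export_tps <- function(set, path, strict = TRUE, digits = 6,
                       units = c("world", "voxel"), spacing = NULL) {
  stopifnot(inherits(set, "landmark_set"))
  units <- match.arg(units)
  unmarked <- set$defs$number[apply(set$coords, 1, anyNA)]
  if (length(unmarked) && strict) {
    stop("unmarked landmarks: ", paste(unmarked, collapse = ", "),
         " (use strict = FALSE to export only marked landmarks)", call. = FALSE)
  }
  keep <- !apply(set$coords, 1, anyNA)
  m <- set$coords[keep, , drop = FALSE]
  if (units == "voxel") {
    if (is.null(spacing)) stop("voxel units need the volume spacing", call. = FALSE)
    m <- sweep(m, 2, as.numeric(spacing), "/")
  }
  fmt <- paste0("%.", digits, "f")
  lines <- c(sprintf("LM3=%d", nrow(m)),
             sprintf(paste(fmt, fmt, fmt), m[, 1], m[, 2], m[, 3]),
             sprintf("ID=%s", set$specimen_id))
  writeLines(lines, path)
  invisible(path)
}

#' Read a TPS file written by [export_tps()]
#'
#' @param path TPS file.
#' @return list with `coords` (n x 3 matrix) and `specimen_id`.
#' @export
read_tps <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (!grepl("^LM3?=\\d+$", lines[1])) {
    stop("not a TPS file (expected LM3=<n> header): ", path, call. = FALSE)
  }
  n <- as.integer(sub("^LM3?=", "", lines[1]))
  if (length(lines) < n + 1) stop("truncated TPS file: ", path, call. = FALSE)
  coords <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("x", "y", "z")))
  for (i in seq_len(n)) {
    coords[i, ] <- as.numeric(strsplit(lines[1 + i], "\\s+")[[1]])[1:3]
  }
  idline <- grep("^ID=", lines, value = TRUE)
  list(coords = coords,
       specimen_id = if (length(idline)) sub("^ID=", "", idline[1]) else NA_character_)
}

# --- NTSYS -------------------------------------------------------------------

#' Export landmark sets as an NTSYS rectangular coordinate matrix
#'
#' Dialect: header `1 <n_specimens> <3*n_landmarks> 0`, then per specimen a
#' row-label line (the specimen id) followed by the flattened coordinates
#' `x1 y1 z1 x2 y2 z2 ...` on one line.
#'
#' @param sets list of fully marked `landmark_set`s sharing the same defs.
#' @param path output file.
#' @param digits decimal places written.
#' @return `path`, invisibly.
#' @export
export_ntsys <- function(sets, path, digits = 6) {
  if (inherits(sets, "landmark_set")) sets <- list(sets)
  stopifnot(length(sets) >= 1)
  d0 <- sets[[1]]$defs
  for (s in sets) {
    if (!inherits(s, "landmark_set")) stop("sets must be landmark_sets", call. = FALSE)
    if (nrow(s$defs) != nrow(d0) || !identical(s$defs$number, d0$number)) {
      stop("all specimens must share the same landmark definitions", call. = FALSE)
    }
    if (anyNA(s$coords)) {
      stop("specimen '", s$specimen_id, "' has unmarked landmarks", call. = FALSE)
    }
  }
  ncols <- 3L * nrow(d0)
  fmt <- paste0("%.", digits, "f")
  lines <- sprintf("1 %d %d 0", length(sets), ncols)
  for (s in sets) {
    flat <- as.vector(t(s$coords))  # x1 y1 z1 x2 ...
    lines <- c(lines, s$specimen_id, paste(sprintf(fmt, flat), collapse = " "))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read an NTSYS file written by [export_ntsys()]
#'
#' @param path NTSYS file.
#' @return list with `coords` (list of n x 3 matrices, one per specimen),
#'   `specimen_ids`, `header` (the four header integers).
#' @export
read_ntsys <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  header <- as.numeric(strsplit(lines[1], "\\s+")[[1]])
  if (length(header) != 4 || header[1] != 1) {
    stop("not an NTSYS rectangular matrix file: ", path, call. = FALSE)
  }
  nspec <- header[2]; ncols <- header[3]
  if (ncols %% 3 != 0) stop("NTSYS column count not divisible by 3", call. = FALSE)
  if (length(lines) < 1 + 2 * nspec) stop("truncated NTSYS file: ", path, call. = FALSE)
  ids <- character(nspec)
  coords <- vector("list", nspec)
  for (s in seq_len(nspec)) {
    ids[s] <- lines[2 * s]
    flat <- as.numeric(strsplit(lines[2 * s + 1], "\\s+")[[1]])
    if (length(flat) != ncols) {
      stop("specimen '", ids[s], "' row has ", length(flat), " values, expected ",
           ncols, call. = FALSE)
    }
    coords[[s]] <- matrix(flat, ncol = 3, byrow = TRUE,
                          dimnames = list(NULL, c("x", "y", "z")))
  }
  list(coords = coords, specimen_ids = ids, header = header)
}

# --- precision statistic -----------------------------------------------------

#' Repeat-to-median distance statistic, grouped by landmark type
#'
#' For each landmark, the coordinate-wise (marginal) median across repeated
#' digitizations of the same specimen is taken as the reference position;
#' each repeat's Euclidean distance to it, expressed in voxel units, is the
#' precision measure. Distances are pooled by Bookstein landmark type.
#'
#' @param repeats list (length >= 2) of fully marked `landmark_set`s of the
#'   same specimen, sharing defs.
#' @param defs [landmark_defs()] carrying `lm_type` (defaults to the first
#'   repeat's defs).
#' @param spacing voxel spacing used to convert world distances to voxels.
#' @return list with `distances` (data.frame: landmark number, type, repeat,
#'   distance in voxels), `by_type` (named list of pooled distance vectors)
#'   and `summary` (per-type n, median, q1, q3).
#' @export
precision_stats <- function(repeats, defs = NULL, spacing = c(1, 1, 1)) {
  if (length(repeats) < 2) stop("need at least two repeats", call. = FALSE)
  defs <- defs %||% repeats[[1]]$defs
  spacing <- as.numeric(spacing)
  nlm <- nrow(defs)
  for (s in repeats) {
    if (nrow(s$coords) != nlm) stop("repeats disagree on landmark count", call. = FALSE)
    if (anyNA(s$coords)) {
      stop("repeat '", s$specimen_id, "' has unmarked landmarks", call. = FALSE)
    }
  }
  nrep <- length(repeats)
  rows <- vector("list", nlm)
  for (i in seq_len(nlm)) {
    pts <- t(vapply(repeats, function(s) s$coords[i, ], numeric(3)))
    med <- apply(pts, 2, stats::median)
    dv <- sweep(sweep(pts, 2, med, "-"), 2, spacing, "/")
    dist <- sqrt(rowSums(dv^2))
    rows[[i]] <- data.frame(number = defs$number[i], lm_type = defs$lm_type[i],
                            rep = seq_len(nrep), distance = dist)
  }
  distances <- do.call(rbind, rows)
  types <- sort(unique(distances$lm_type[!is.na(distances$lm_type)]))
  by_type <- lapply(types, function(t) distances$distance[distances$lm_type %in% t])
  names(by_type) <- paste0("type", types)
  summ <- do.call(rbind, lapply(types, function(t) {
    d <- distances$distance[distances$lm_type %in% t]
    data.frame(lm_type = t, n = length(d),
               median = stats::median(d),
               q1 = unname(stats::quantile(d, 0.25)),
               q3 = unname(stats::quantile(d, 0.75)))
  }))
  list(distances = distances, by_type = by_type, summary = summ)
}
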