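# Scripted session: the headless replacement for the interactive GUI.
# A session is an environment (reference semantics) holding the volume, the
# single synchronized cursor, the view, render settings, the landmark set,
# symmetry map, plane/axis anchors, the picking threshold and a command log.
# Every state change goes through the command handlers, so a session script
# is a complete, replayable record of a digitization.

#' Create an empty landmarking session
#'
#' @return a `landmark_session` environment with a plain-command `log`.
#'   There is exactly one cursor per session: every slice, pick and mark
#'   operation reads and writes the same instance.
#' @export
new_session <- function() {
  s <- new.env(parent = emptyenv())
  s$volume <- NULL
  s$cursor <- NULL
  s$view <- NULL
  s$tf <- NULL
  s$lights <- light_set(ambient = 1)
  s$threshold <- NULL
  s$landmarks <- NULL
  s$symmetry <- NULL
  s$plane <- NULL
  s$axis <- NULL
  s$plane_points <- matrix(NA_real_, 3, 3,
                           dimnames = list(c("PL1", "PL2", "PL3"), c("x", "y", "z")))
  s$axis_points <- matrix(NA_real_, 2, 3,
                          dimnames = list(c("A1", "A2"), c("x", "y", "z")))
  s$log <- character(0)
  s$outputs <- character(0)
  class(s) <- "landmark_session"
  s
}

session_log <- function(s, line) {
  s$log <- c(s$log, line)
  invisible(s)
}

#' Attach a volume to a session
#'
#' Initializes the cursor at the volume center and regenerates the slices
#' (the load-time behaviour of the interactive tool).
#'
#' @param s a `landmark_session`.
#' @param v a volume.
#' @return the session, invisibly.
#' @export
session_set_volume <- function(s, v) {
  stopifnot(inherits(s, "landmark_session"), is_volume(v))
  s$volume <- v
  s$cursor <- init_cursor(v)
  s$slices <- extract_slices(v, s$cursor)
  if (is.null(s$view)) s$view <- view_for_volume(v)
  session_log(s, sprintf("volume %d %d %d", v$dims[1], v$dims[2], v$dims[3]))
  invisible(s)
}

#' Save the session state as a plain-text (JSON) file
#'
#' Records the cursor, threshold, plane/axis anchors and all marked
#' landmark coordinates (not the voxel grid itself).
#'
#' @param s a `landmark_session`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
session_save <- function(s, path) {
  state <- list(
    cursor = if (!is.null(s$cursor)) s$cursor$position,
    threshold = s$threshold,
    plane_points = s$plane_points,
    axis_points = s$axis_points,
    specimen_id = if (!is.null(s$landmarks)) s$landmarks$specimen_id,
    landmarks = if (!is.null(s$landmarks)) {
      data.frame(number = s$landmarks$defs$number,
                 description = s$landmarks$defs$description,
                 s$landmarks$coords)
    }
  )
  jsonlite::write_json(state, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}

#' Write the session log with timestamps
#'
#' @param s a `landmark_session`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
session_save_log <- function(s, path) {
  stamp <- format(Sys.time(), "%Y-%m-%d %H:%M:%S")
  writeLines(paste0("[", stamp, "] ", s$log), path)
  invisible(path)
}

parse_num_vec <- function(s) as.numeric(strsplit(s, ",", fixed = TRUE)[[1]])

# one command handler; returns nothing, mutates the session
session_command <- function(s, tokens, base_dir = ".") {
  cmd <- tokens[1]
  args <- tokens[-1]
  rel <- function(p) if (grepl("^/", p)) p else file.path(base_dir, p)
  need_vol <- function() if (is.null(s$volume)) stop("no volume loaded", call. = FALSE)
  need_lm <- function() if (is.null(s$landmarks)) stop("no landmark list loaded", call. = FALSE)
  need_plane <- function() if (is.null(s$plane)) stop("no plane defined", call. = FALSE)
  kv <- function(key, default = NULL) {
    hit <- grep(paste0("^", key, "="), args, value = TRUE)
    if (length(hit)) sub(paste0("^", key, "="), "", hit[1]) else default
  }
  rebuild_plane <- function() {
    if (!anyNA(s$plane_points)) {
      s$plane <- plane_from_points(s$plane_points[1, ], s$plane_points[2, ],
                                   s$plane_points[3, ])
      session_log(s, "plane recomputed from anchors")
    }
    if (!anyNA(s$axis_points)) {
      s$axis <- axis_from_points(s$axis_points[1, ], s$axis_points[2, ])
    }
  }
  switch(cmd,
    "load" = {
      session_set_volume(s, read_volume(rel(args[1])))
    },
    "load-dicom" = {
      files <- args
      if (length(files) == 1 && dir.exists(rel(files[1]))) {
        files <- list.files(rel(files[1]), pattern = "\\.dcm$", full.names = TRUE)
      } else {
        files <- vapply(files, rel, "")
      }
      session_set_volume(s, read_dicom_stack(files))
    },
    "phantom" = {
      spec <- phantom_spec(
        kind = kv("kind", "two_shell"),
        dims = as.integer(parse_num_vec(kv("dims", "32,32,32"))),
        spacing = parse_num_vec(kv("spacing", "1,1,1")),
        noise_sigma = as.numeric(kv("noise", "0")),
        seed = as.integer(kv("seed", "1")))
      ph <- phantom_generate(spec)
      s$phantom_truth <- ph
      session_set_volume(s, ph$volume)
    },
    "downsample" = {
      need_vol()
      s$volume <- downsample(s$volume, as.integer(args[1:3]))
      s$cursor <- init_cursor(s$volume)
      s$slices <- extract_slices(s$volume, s$cursor)
      s$view <- view_for_volume(s$volume, forward = s$view$forward, up = s$view$up)
    },
    "threshold" = {
      s$threshold <- as.numeric(args[1])
    },
    "view" = {
      need_vol()
      fw <- parse_num_vec(kv("forward", "0,0,1"))
      up <- parse_num_vec(kv("up", "0,1,0"))
      px <- as.integer(kv("size", "65"))
      s$view <- view_for_volume(s$volume, forward = fw, up = up, image_px = px)
    },
    "landmarks" = {
      s$landmarks <- new_landmark_set(load_landmark_list(rel(args[1])),
                                      specimen_id = kv("id", "specimen"))
    },
    "specimen" = {
      need_lm()
      s$landmarks$specimen_id <- args[1]
    },
    "symmetry" = {
      need_lm()
      s$symmetry <- load_symmetry_map(rel(args[1]), s$landmarks$defs)
    },
    "plane-points" = {
      pts <- lapply(args[1:3], parse_num_vec)
      s$plane_points[] <- do.call(rbind, pts)
      rebuild_plane()
    },
    "plane" = {
      need_lm()
      for (i in 1:3) {
        s$plane_points[i, ] <- jump_stored(s$landmarks, as.integer(args[i]))
      }
      rebuild_plane()
    },
    "plane-point" = {
      # store the cursor as plane anchor PL<slot>; the plane (and dependent
      # axis) are recomputed eagerly whenever an anchor changes
      need_vol()
      slot <- as.integer(args[1])
      stopifnot(slot %in% 1:3)
      s$plane_points[slot, ] <- s$cursor$position
      rebuild_plane()
    },
    "axis-points" = {
      pts <- lapply(args[1:2], parse_num_vec)
      s$axis_points[] <- do.call(rbind, pts)
      s$axis <- axis_from_points(s$axis_points[1, ], s$axis_points[2, ])
    },
    "axis" = {
      need_lm()
      for (i in 1:2) {
        s$axis_points[i, ] <- jump_stored(s$landmarks, as.integer(args[i]))
      }
      s$axis <- axis_from_points(s$axis_points[1, ], s$axis_points[2, ])
    },
    "rotate-plane" = {
      need_vol(); need_plane()
      s$view <- rotate_to_plane(s$view, s$plane,
                                flip_normal = "flip-normal" %in% args)
    },
    "rotate-axis" = {
      need_vol(); need_plane()
      if (is.null(s$axis)) stop("no axis defined", call. = FALSE)
      s$view <- rotate_to_axis(s$view, s$plane, s$axis,
                               flip_normal = "flip-normal" %in% args)
    },
    "reflect" = {
      need_vol(); need_plane()
      s$cursor <- set_cursor(s$volume, s$cursor,
                             reflect_point(s$plane, s$cursor$position))
      s$slices <- extract_slices(s$volume, s$cursor)
    },
    "pick" = {
      pick(s, as.numeric(args[1:2]))
    },
    "move" = {
      need_vol()
      s$cursor <- move_cursor(s$volume, s$cursor, args[1], as.numeric(args[2]))
      s$slices <- extract_slices(s$volume, s$cursor)
    },
    "cursor" = {
      need_vol()
      s$cursor <- set_cursor(s$volume, s$cursor, parse_num_vec(args[1]))
      s$slices <- extract_slices(s$volume, s$cursor)
    },
    "mark" = {
      need_lm()
      s$landmarks <- mark_point(s$landmarks, as.integer(args[1]), s$cursor)
    },
    "jump" = {
      need_vol(); need_lm()
      s$cursor <- set_cursor(s$volume, s$cursor,
                             jump_stored(s$landmarks, as.integer(args[1])))
      s$slices <- extract_slices(s$volume, s$cursor)
    },
    "preset" = {
      p <- read_render_preset(rel(args[1]))
      s$tf <- p$tf
      s$lights <- p$lights
    },
    "transfer" = {
      s$tf <- transfer_function(as.numeric(kv("low", "0")),
                                as.numeric(kv("high", "1")),
                                max_opacity = as.numeric(kv("max_opacity", "1")),
                                reflectivity_gain = as.numeric(kv("gain", "1")),
                                mode = kv("mode", "surface"))
    },
    "render" = {
      need_vol()
      if (is.null(s$tf)) stop("no transfer function configured", call. = FALSE)
      img <- render_raycast(s$volume, s$view, s$tf, s$lights)
      out <- rel(args[1])
      save_png(img, out)
      s$outputs <- c(s$outputs, out)
    },
    "slices" = {
      need_vol()
      paths <- save_slices_png(s$volume, s$cursor, rel(args[1]))
      s$outputs <- c(s$outputs, paths)
    },
    "export-tps" = {
      need_lm()
      out <- rel(args[1])
      export_tps(s$landmarks, out, strict = !("partial" %in% args))
      s$outputs <- c(s$outputs, out)
    },
    "export-ntsys" = {
      need_lm()
      out <- rel(args[1])
      export_ntsys(list(s$landmarks), out)
      s$outputs <- c(s$outputs, out)
    },
    "save-session" = {
      out <- rel(args[1])
      session_save(s, out)
      s$outputs <- c(s$outputs, out)
    },
    stop("unknown command '", cmd, "'", call. = FALSE)
  )
  invisible(NULL)
}

#' Run a session script
#'
#' Executes plain-text commands in order against one session. Commands are
#' whitespace-delimited; `#` lines and blank lines are skipped. The first
#' invalid command aborts with its line number, and any files the aborted
#' script already wrote are removed. Given identical inputs, replaying a
#' script yields byte-identical exports.
#'
#' Supported commands: `load`, `load-dicom`, `phantom`, `downsample`,
#' `threshold`, `view`, `landmarks`, `specimen`, `symmetry`, `plane`,
#' `plane-points`, `plane-point`, `axis`, `axis-points`, `rotate-plane`,
#' `rotate-axis`, `reflect`, `pick`, `move`, `cursor`, `mark`, `jump`,
#' `preset`, `transfer`, `render`, `slices`, `export-tps`, `export-ntsys`,
#' `save-session`.
#'
#' @param commands character vector of commands (one per element), or a
#'   length-1 path to a script file when `is_file = TRUE`.
#' @param session an existing session to continue, or `NULL` for a fresh one.
#' @param base_dir directory relative paths resolve against.
#' @param is_file treat `commands` as a script file path?
#' @return the final `landmark_session`, invisibly.
#' @export
run_script <- function(commands, session = NULL, base_dir = ".", is_file = FALSE) {
  if (is_file) commands <- readLines(commands, warn = FALSE)
  s <- session %||% new_session()
  for (li in seq_along(commands)) {
    line <- trimws(commands[li])
    if (!nzchar(line) || startsWith(line, "#")) next
    tokens <- strsplit(line, "\\s+")[[1]]
    ok <- tryCatch({
      session_command(s, tokens, base_dir = base_dir)
      session_log(s, line)
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok)) {
      file.remove(s$outputs[file.exists(s$outputs)])
      stop("script error at line ", li, " ('", line, "'): ",
           conditionMessage(ok), call. = FALSE)
    }
  }
  invisible(s)
}
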