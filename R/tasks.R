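# Registry of the six training tasks and the error-rule table. Scene
# dimensions are package defaults (the devices this engine emulates publish
# no scene geometry): workspace cuboid 200 x 200 x 200 mm centred 150 mm
# above the sensor-pad origin, trocar pivots at (+-60, 40, 60) mm, target
# spheres radius 8 mm, containers radius 15 mm. Everything is overridable
# through a scene JSON file.

ERROR_CLASSES <- c(
  "OFF_TIP_CONTACT", "WORKSPACE_BOUNDARY", "TARGET_CONTACT_EXCESS",
  "CONTAINER_CONTACT", "INSTRUMENT_CLASH", "OVAL_CONTACT_EXCESS",
  "OFF_PATH_TIME", "DIATHERMY_OFF_TARGET", "EXCESS_BURN_TIME"
)

ERROR_APPLICABILITY <- list(
  OFF_TIP_CONTACT       = 1:6,           # off-tip contact with the target
  WORKSPACE_BOUNDARY    = 1:6,           # contact with workspace limits
  TARGET_CONTACT_EXCESS = c(1L, 2L),     # undue contacts with the target sphere
  CONTAINER_CONTACT     = c(1L, 2L),     # contact with container margins
  INSTRUMENT_CLASH      = c(3L, 4L),     # undue instrument-instrument contact
  OVAL_CONTACT_EXCESS   = 4L,            # contacts with the oval beyond the permitted number
  OFF_PATH_TIME         = c(1L, 2L, 4L, 6L),  # time with tip outside the ideal path
  DIATHERMY_OFF_TARGET  = c(5L, 6L),     # diathermy away from the stated targets
  EXCESS_BURN_TIME      = c(5L, 6L)      # on-target burn beyond the 2 s threshold
)

DEFAULT_WEIGHTS <- c(
  OFF_TIP_CONTACT       = 3L,
  WORKSPACE_BOUNDARY    = 2L,
  TARGET_CONTACT_EXCESS = 2L,
  CONTAINER_CONTACT     = 2L,
  INSTRUMENT_CLASH      = 2L,
  OVAL_CONTACT_EXCESS   = 3L,
  OFF_PATH_TIME         = 1L,
  DIATHERMY_OFF_TARGET  = 5L,   # the one weight the scoring scheme fixes
  EXCESS_BURN_TIME      = 4L
)

TASK_NAMES <- c(
  "Grip and placement",
  "Transfer and placement of an object",
  "Cross (bimanual traversal)",
  "Removal and reinsertion of instruments",
  "Diathermy",
  "Target manipulation and diathermy"
)

TASK_EQUIVALENTS <- c(
  "Tissue gripping and retraction; clip placement; hemostasis",
  "Needle transfer between a grasper and a needle holder",
  "Running the small intestine",
  "One instrument stabilises an organ while the other is withdrawn and reintroduced",
  "Cauterising a bleeding vessel",
  "Presenting and steadying a target for cautery"
)

#' Error classes and their per-task applicability
#'
#' The engine recognises nine error classes: off-tip contact with a target
#' (all tasks), contact with the workspace limits (all tasks), undue contacts
#' with the target sphere (tasks 1-2), contact with container margins (tasks
#' 1-2), instrument-instrument clash (tasks 3-4), contacts with the oval
#' beyond the permitted number (task 4), time spent outside the ideal path
#' (tasks 1, 2, 4, 6), diathermy off the stated targets (tasks 5-6), and
#' excess burn time (tasks 5-6).
#'
#' @return A data.frame with columns `class`, `description`, and
#'   `applicable_tasks` (list column of integer vectors).
#' @export
error_classes <- function() {
  data.frame(
    class = ERROR_CLASSES,
    description = c(
      "contact of the target with a part of the forceps other than the tip",
      "contact of the instrument with the limits of the virtual working space",
      "undue contacts of the instrument with the target sphere",
      "contact of the instrument or the sphere with the container margins",
      "undue contact between the two instruments",
      "contacts with the oval exceeding the permitted number",
      "time during which the tip remained outside the ideal path",
      "diathermy of the sphere outside the stated targets",
      "on-target burn time beyond the threshold (excess burn)"
    ),
    applicable_tasks = I(unname(ERROR_APPLICABILITY[ERROR_CLASSES])),
    stringsAsFactors = FALSE
  )
}

#' Default error-weight table
#'
#' Each error class carries an integer weight between 1 (least important)
#' and 5 (most important); diathermy off target is the most serious error
#' and is fixed at 5. The remaining defaults are package choices and are
#' fully user-configurable.
#'
#' @param override Optional named numeric vector or list of per-class
#'   overrides, e.g. `c(WORKSPACE_BOUNDARY = 3)`.
#' @return Named integer vector over all nine classes.
#' @export
default_weights <- function(override = NULL) {
  w <- DEFAULT_WEIGHTS
  if (!is.null(override)) {
    override <- unlist(override)
    bad <- setdiff(names(override), ERROR_CLASSES)
    if (length(bad)) stop("unknown error class in weights: ", paste(bad, collapse = ", "),
                          call. = FALSE)
    w[names(override)] <- as.integer(override)
  }
  w
}

#' Validate an error-weight table
#'
#' @param weights Named numeric vector of weights.
#' @return Character vector of violations; empty when the table is valid.
#' @export
validate_weights <- function(weights) {
  v <- character()
  missing <- setdiff(ERROR_CLASSES, names(weights))
  if (length(missing)) v <- c(v, paste0("missing class: ", missing))
  known <- intersect(names(weights), ERROR_CLASSES)
  w <- weights[known]
  off <- known[!is.finite(w) | w < 1 | w > 5]
  if (length(off)) v <- c(v, paste0("weight out of [1,5] for class: ", off))
  extra <- setdiff(names(weights), ERROR_CLASSES)
  if (length(extra)) v <- c(v, paste0("unknown class: ", extra))
  v
}

# Diathermy targets sit in a line across the front-top of the cautery field,
# spread perpendicular to the shaft direction so the shaft aimed at one
# target clears its neighbours.
diathermy_target_line <- function(base_c, radius = 30) {
  xs <- c(-24, -12, 0, 12, 24)
  t(vapply(xs, function(x) {
    rem <- sqrt(radius^2 - x^2)
    base_c + c(x, 0.6 * rem, 0.8 * rem)
  }, numeric(3)))
}

# Named waypoints of the flawless route for one task, derived from the scene
# geometry. One source of truth: the ideal path is the polyline through these
# waypoints, and the trajectory simulator schedules its motion through the
# very same points. Containers are entered from high above along their axis;
# sphere grasps and diathermy touches approach collinearly with the shaft
# through a standoff point so the shaft clears the sphere.
scene_waypoints <- function(task_id, shapes, pivots, homes, workspace, dh) {
  nh <- if (dh == "left") "right" else "left"
  wp <- list(dh = dh, nh = nh)
  so <- function(shape, hand) shape$center + 30 * unit_to(shape$center, pivots[[hand]])
  if (task_id %in% c(1L, 2L, 6L)) {
    wp$grasp_standoff <- so(shapes$target, dh)
    wp$grasp <- touch_point(shapes$target, pivots[[dh]], pen = 3)
  }
  if (task_id == 1L) {
    wp$entry <- c(45, 225, -25)       # above the goal dish, on its axis
    wp$place <- c(45, 165, -25)       # release point inside the dish
    wp$via <- c(sign(homes[[dh]][1]) * 75, 195, 40)
  } else if (task_id == 2L) {
    wp$xfer <- c(0, 170, 30)
    wp$recv <- wp$xfer + c(0, 0, -6)  # receiving jaw next to the held object
    wp$entry <- c(50, 210, -20)
    wp$place <- c(50, 157, -20)
    wp$via <- c(sign(homes[[nh]][1]) * 75, 195, 30)
  } else if (task_id == 4L) {
    ctr <- (workspace$min_corner + workspace$max_corner) / 2
    u <- unit_to(pivots[[dh]], ctr)
    wp$work <- c(30, 150, 20)
    wp$out <- pivots[[dh]] - 30 * u   # withdrawn past the entry portal
    wp$oval_touch <- touch_point(shapes$oval, pivots[[nh]], pen = 7)
    wp$oval_away <- shapes$oval$center +
      30 * unit_to(shapes$oval$center, pivots[[nh]])
  } else if (task_id %in% c(5L, 6L)) {
    burn_hand <- if (task_id == 5L) dh else nh
    tn <- grep("^target[0-9]+$", names(shapes), value = TRUE)
    wp$burn_hand <- burn_hand
    wp$burn_standoffs <- t(vapply(tn, function(nm) so(shapes[[nm]], burn_hand),
                                  numeric(3)))
    wp$burn_touches <- t(vapply(tn, function(nm)
      touch_point(shapes[[nm]], pivots[[burn_hand]], pen = 1), numeric(3)))
    if (task_id == 6L) {
      wp$place <- c(50, 150, 10)      # inside the cube
      wp$burn_via <- c(-55, 165, 25)  # keeps the cautery shaft off the sphere
    }
  }
  wp
}

# drop consecutive duplicate vertices, then build the polyline
route_polyline <- function(...) {
  v <- rbind(...)
  keep <- c(TRUE, rowSums((v[-1L, , drop = FALSE] -
                             v[-nrow(v), , drop = FALSE])^2) > 1e-12)
  polyline3(v[keep, , drop = FALSE])
}

# interleave standoff_i, touch_i, standoff_i for the cautery sequence
burn_route <- function(wp) {
  do.call(rbind, lapply(seq_len(nrow(wp$burn_touches)), function(i)
    rbind(wp$burn_standoffs[i, ], wp$burn_touches[i, ], wp$burn_standoffs[i, ])))
}

# Default scene geometry for one task, with task roles resolved for the
# given dominant hand. Returns the pieces load_task() assembles.
default_scene <- function(task_id, dominant_hand = "right") {
  ws <- cuboid(c(-100, 50, -100), c(100, 250, 100))
  pivots <- list(left = pt3(-60, 40, 60), right = pt3(60, 40, 60))
  homes <- list(left = pt3(-40, 130, 30), right = pt3(40, 130, 30))
  dh <- dominant_hand; nh <- if (dh == "left") "right" else "left"

  shapes <- list(); roles <- list(); ideal <- list(left = NULL, right = NULL)
  completion <- NULL; path_hands <- character()

  if (task_id == 1L) {
    shapes$target <- sphere(c(-30, 150, 0), 8)
    shapes$goal <- cylinder(c(45, 150, -25), c(45, 180, -25), 15, hollow = TRUE)
    roles <- list(graspable = "target", goal = "goal", containers = "goal")
    wp <- scene_waypoints(1L, shapes, pivots, homes, ws, dh)
    ideal[[dh]] <- route_polyline(homes[[dh]], wp$grasp_standoff, wp$grasp,
                                  wp$entry, wp$place, wp$entry, wp$via, homes[[dh]])
    path_hands <- dh
    completion <- list(kind = "PLACED_IN_SHAPE", object = "target", shape = "goal")
  } else if (task_id == 2L) {
    shapes$target <- sphere(c(-35, 150, 0), 8)
    shapes$container <- cylinder(c(50, 140, -20), c(50, 175, -20), 15, hollow = TRUE)
    roles <- list(graspable = "target", goal = "container", containers = "container")
    wp <- scene_waypoints(2L, shapes, pivots, homes, ws, dh)
    ideal[[dh]] <- route_polyline(homes[[dh]], wp$grasp_standoff, wp$grasp,
                                  wp$xfer, homes[[dh]])
    ideal[[nh]] <- route_polyline(homes[[nh]], wp$recv, wp$entry, wp$place,
                                  wp$entry, wp$via, homes[[nh]])
    path_hands <- c(dh, nh)
    completion <- list(kind = "TRANSFER_THEN_PLACED", object = "target", shape = "container")
  } else if (task_id == 3L) {
    shapes$conduit <- cylinder(c(-70, 150, -20), c(70, 150, -20), 30, hollow = TRUE)
    roles <- list()
    ideal$left <- polyline3(rbind(c(-60, 165, -38), c(60, 165, -38)))
    ideal$right <- polyline3(rbind(c(-60, 165, -2), c(60, 165, -2)))
    path_hands <- c("left", "right")
    completion <- list(kind = "TRAVERSAL_COMPLETE", fraction = 0.95, hands = c("left", "right"))
  } else if (task_id == 4L) {
    shapes$oval <- sphere(c(-30, 150, -10), 12)
    roles <- list(oval = "oval")
    wp <- scene_waypoints(4L, shapes, pivots, homes, ws, dh)
    # the withdrawal leg through the entry portal is part of the ideal route
    ideal[[dh]] <- route_polyline(homes[[dh]], wp$work, wp$out, wp$work, homes[[dh]])
    path_hands <- dh
    completion <- list(kind = "REMOVE_REINSERT_COUNT", hand = dh, cycles = 1L)
  } else if (task_id == 5L) {
    base_c <- c(0, 170, -30)
    shapes$base <- sphere(base_c, 30)
    ctrs <- diathermy_target_line(base_c)
    tnames <- paste0("target", 1:5)
    for (i in 1:5) shapes[[tnames[i]]] <- sphere(ctrs[i, ], 5)
    roles <- list(diathermy_targets = tnames)
    wp <- scene_waypoints(5L, shapes, pivots, homes, ws, dh)
    ideal[[dh]] <- route_polyline(homes[[dh]], burn_route(wp), homes[[dh]])
    path_hands <- dh
    completion <- list(kind = "ALL_TARGETS_CAUTERIZED", targets = tnames)
  } else if (task_id == 6L) {
    shapes$target <- sphere(c(-30, 150, 20), 8)
    shapes$cube <- cuboid(c(30, 130, -10), c(70, 170, 30))
    ctrs <- diathermy_target_line(c(0, 170, -30))
    tnames <- paste0("target", 1:5)
    for (i in 1:5) shapes[[tnames[i]]] <- sphere(ctrs[i, ], 5)
    roles <- list(graspable = "target", goal = "cube", diathermy_targets = tnames)
    wp <- scene_waypoints(6L, shapes, pivots, homes, ws, dh)
    ideal[[dh]] <- route_polyline(homes[[dh]], wp$grasp_standoff, wp$grasp,
                                  wp$place, homes[[dh]])
    ideal[[nh]] <- route_polyline(homes[[nh]], wp$burn_via, burn_route(wp),
                                  homes[[nh]])
    path_hands <- c(dh, nh)
    completion <- list(kind = "PLACED_AND_CAUTERIZED", object = "target",
                       shape = "cube", targets = tnames)
  } else {
    stop("unknown task_id: ", task_id, call. = FALSE)
  }

  list(workspace = ws, pivots = pivots, homes = homes, shapes = shapes,
       roles = roles, ideal_path = ideal, path_hands = path_hands,
       completion = completion)
}

#' Load a task definition
#'
#' Builds the full definition of one of the six registered tasks: scene
#' shapes, trocar pivots, per-hand ideal paths, applicable error classes and
#' the completion criterion. Task 3 is bimanual (both hands dominant, the
#' dominant-hand option is unavailable); all other tasks take a configurable
#' dominant hand.
#'
#' @param task_id Integer in 1..6.
#' @param scene_file Optional path to a scene JSON overriding the packaged
#'   default layout (see [write_task_json()] for the format).
#' @param dominant_hand `"right"` (default) or `"left"`; ignored for task 3.
#' @return A `lapskill_task` object.
#' @export
load_task <- function(task_id, scene_file = NULL, dominant_hand = c("right", "left")) {
  dominant_hand <- match.arg(dominant_hand)
  if (!is.numeric(task_id) || length(task_id) != 1L || !(task_id %in% 1:6))
    stop("task_id must be a single integer in 1..6", call. = FALSE)
  task_id <- as.integer(task_id)
  if (task_id == 3L) dominant_hand <- "right"  # bimanual; both hands dominant

  sc <- default_scene(task_id, dominant_hand)
  task <- structure(list(
    task_id = task_id,
    name = TASK_NAMES[task_id],
    surgical_equivalent = TASK_EQUIVALENTS[task_id],
    bimanual = task_id == 3L,
    dominant_hand_configurable = task_id != 3L,
    dominant_hand = dominant_hand,
    workspace = sc$workspace,
    pivots = sc$pivots,
    homes = sc$homes,
    shapes = sc$shapes,
    roles = sc$roles,
    ideal_path = sc$ideal_path,
    path_hands = sc$path_hands,
    completion = sc$completion,
    permitted_oval_contacts = if (task_id == 4L) 2L else NA_integer_,
    error_classes = ERROR_CLASSES[vapply(ERROR_APPLICABILITY, function(a) task_id %in% a, logical(1))]
  ), class = "lapskill_task")

  if (!is.null(scene_file)) task <- apply_scene_json(task, scene_file)
  task
}

shape_to_list <- function(name, s) {
  switch(s$kind,
    sphere = list(name = name, kind = "sphere", center = s$center, radius = s$radius),
    cylinder = list(name = name, kind = "cylinder", axis_a = s$axis_a,
                    axis_b = s$axis_b, radius = s$radius, hollow = s$hollow),
    cuboid = list(name = name, kind = "cuboid", min_corner = s$min_corner,
                  max_corner = s$max_corner))
}

shape_from_list <- function(x, where = "shape") {
  need <- function(f) {
    if (is.null(x[[f]])) stop("scene JSON: missing field '", f, "' in ", where, call. = FALSE)
    x[[f]]
  }
  kind <- need("kind")
  switch(kind,
    sphere = sphere(unlist(need("center")), need("radius")),
    cylinder = cylinder(unlist(need("axis_a")), unlist(need("axis_b")),
                        need("radius"), isTRUE(x$hollow)),
    cuboid = cuboid(unlist(need("min_corner")), unlist(need("max_corner"))),
    stop("scene JSON: unknown shape kind '", kind, "' in ", where, call. = FALSE))
}

#' Serialise a task definition to JSON
#'
#' The file written here is accepted back by [load_task()] via its
#' `scene_file` argument and round-trips the scene exactly.
#'
#' @param task A `lapskill_task`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_task_json <- function(task, path) {
  x <- list(
    task_id = task$task_id,
    dominant_hand = task$dominant_hand,
    workspace = shape_to_list("workspace", task$workspace)[-1],
    pivots = task$pivots,
    homes = task$homes,
    shapes = unname(Map(shape_to_list, names(task$shapes), task$shapes)),
    roles = task$roles,
    ideal_path = lapply(task$ideal_path, function(p) if (is.null(p)) NULL else unclass(p)),
    path_hands = task$path_hands,
    completion = task$completion
  )
  if (!is.na(task$permitted_oval_contacts))
    x$permitted_oval_contacts <- task$permitted_oval_contacts
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

# Merge a scene JSON (possibly partial) over the default task definition.
apply_scene_json <- function(task, scene_file) {
  if (!file.exists(scene_file)) stop("scene file not found: ", scene_file, call. = FALSE)
  x <- tryCatch(jsonlite::read_json(scene_file, simplifyVector = FALSE),
                error = function(e) stop("malformed scene JSON (", scene_file, "): ",
                                         conditionMessage(e), call. = FALSE))
  if (!is.null(x$task_id) && as.integer(x$task_id) != task$task_id)
    stop("scene JSON: task_id ", x$task_id, " does not match requested task ",
         task$task_id, call. = FALSE)
  if (!is.null(x$workspace)) {
    x$workspace$kind <- x$workspace$kind %||% "cuboid"
    task$workspace <- shape_from_list(x$workspace, "workspace")
  }
  if (!is.null(x$pivots)) {
    for (h in c("left", "right")) if (!is.null(x$pivots[[h]]))
      task$pivots[[h]] <- pt3(x$pivots[[h]][[1]], x$pivots[[h]][[2]], x$pivots[[h]][[3]])
  }
  if (!is.null(x$homes)) {
    for (h in c("left", "right")) if (!is.null(x$homes[[h]]))
      task$homes[[h]] <- pt3(x$homes[[h]][[1]], x$homes[[h]][[2]], x$homes[[h]][[3]])
  }
  if (!is.null(x$shapes)) {
    for (i in seq_along(x$shapes)) {
      s <- x$shapes[[i]]
      if (is.null(s$name)) stop("scene JSON: shapes[", i, "] has no name", call. = FALSE)
      task$shapes[[s$name]] <- shape_from_list(s, paste0("shapes[", i, "]"))
    }
  }
  if (!is.null(x$roles)) for (nm in names(x$roles)) task$roles[[nm]] <- unlist(x$roles[[nm]])
  if (!is.null(x$ideal_path)) {
    for (h in c("left", "right")) if (!is.null(x$ideal_path[[h]])) {
      v <- do.call(rbind, lapply(x$ideal_path[[h]], unlist))
      task$ideal_path[[h]] <- polyline3(v)
    }
  }
  if (!is.null(x$path_hands)) task$path_hands <- unlist(x$path_hands)
  if (!is.null(x$completion)) {
    cmp <- x$completion
    cmp[vapply(cmp, is.list, logical(1))] <-
      lapply(cmp[vapply(cmp, is.list, logical(1))], unlist)
    task$completion <- cmp
  }
  poc <- suppressWarnings(as.integer(x$permitted_oval_contacts))
  if (length(poc) == 1L && !is.na(poc)) task$permitted_oval_contacts <- poc
  task
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.lapskill_task <- function(x, ...) {
  cat(sprintf("Task %d: %s\n", x$task_id, x$name))
  cat(sprintf("  surgical equivalent: %s\n", x$surgical_equivalent))
  cat(sprintf("  bimanual: %s; dominant hand: %s%s\n", x$bimanual, x$dominant_hand,
              if (x$dominant_hand_configurable) " (configurable)" else ""))
  cat(sprintf("  shapes: %s\n", paste(names(x$shapes), collapse = ", ")))
  cat(sprintf("  completion: %s\n", x$completion$kind))
  cat(sprintf("  error classes: %s\n", paste(x$error_classes, collapse = ", ")))
  invisible(x)
}
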