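#' Fruit kinds used by the reaching task
#' @export
FRUIT_KINDS <- c("orange", "apple", "pear")

#' Depth-usage classes
#' @export
DEPTH_CLASSES <- c("no_depth", "only_depth", "combined_depth")

#' Visualization-technology conditions
#' @export
CONDITIONS <- c("IVR", "AR", "Screen")

#' Build the experimental protocol for one experiment
#'
#' Encodes the task structure and geometry of the fruit-reaching experiments:
#' the reaching workspace (0.3588 x 0.2847 x 0.3726 m), the block structure
#' (experiment 1: eight blocks of 6, 12, 12, 12, 18, 18, 18, 6 fruits, 102 in
#' total; experiment 2: six blocks of 6, 6, 6, 12, 12, 6 fruits, 48 in total),
#' the 22 canonical target locations, the fruit collider shapes, the home /
#' cursor sphere diameters and the 0.4--0.6 s dwell interval at the home
#' sphere.
#'
#' Coordinates use a right-handed frame centred on the workspace centre:
#' x = horizontal (positive right), y = vertical (positive up), z = depth
#' (positive away from the participant).
#'
#' @param experiment_id `"exp1"` (healthy elderly protocol) or `"exp2"`
#'   (patient protocol: fewer fruits, 5 cm home sphere, shifted workspace).
#' @param location_seed integer seed fixing the canonical 22-location set.
#' @return An object of class `reach_protocol`: a list with elements
#'   `experiment_id`, `workspace`, `blocks` (tibble), `locations` (tibble of
#'   22 target offsets with depth classes), `dwell_interval`,
#'   `home_sphere_diameter`, `cursor_sphere_diameter` and `colliders`.
#' @examples
#' p <- build_protocol("exp1")
#' sum(p$blocks$n_fruits)  # 102
#' @export
build_protocol <- function(experiment_id = c("exp1", "exp2"), location_seed = 1L) {
  experiment_id <- match.arg(experiment_id)

  workspace <- if (experiment_id == "exp1") {
    workspace_spec(center_offset = c(right = 0.198, down = 0.1998, forward = 0.444))
  } else {
    workspace_spec(center_offset = c(right = 0, down = 0.31, forward = 0.40))
  }

  blocks <- if (experiment_id == "exp1") {
    tibble::tibble(
      block_index = 1:8,
      n_fruits    = c(6L, 12L, 12L, 12L, 18L, 18L, 18L, 6L),
      allowed     = c(list("pear"), rep(list(FRUIT_KINDS), 6), list("pear")),
      require_all = c(FALSE, rep(TRUE, 6), FALSE)
    )
  } else {
    tibble::tibble(
      block_index = 1:6,
      n_fruits    = c(6L, 6L, 6L, 12L, 12L, 6L),
      allowed     = list("pear", c("pear", "orange"), FRUIT_KINDS,
                         c("pear", "orange"), FRUIT_KINDS, "pear"),
      require_all = c(FALSE, TRUE, TRUE, TRUE, TRUE, FALSE)
    )
  }

  proto <- structure(list(
    experiment_id         = experiment_id,
    workspace             = workspace,
    blocks                = blocks,
    locations             = generate_location_set(workspace, seed = location_seed),
    dwell_interval        = c(0.4, 0.6),
    home_sphere_diameter  = if (experiment_id == "exp1") 0.04 else 0.05,
    cursor_sphere_diameter = 0.04,
    colliders             = list(
      orange = collider_spec("sphere", sphere_diameter = 0.10),
      apple  = collider_spec("sphere", sphere_diameter = 0.0752),
      pear   = collider_spec("sphere_plus_capsule", sphere_diameter = 0.0578,
                             capsule_height = 0.0731, capsule_diameter = 0.0238)
    )
  ), class = "reach_protocol")
  validate_protocol(proto)
  proto
}

#' Workspace geometry
#'
#' @param width,height,depth workspace extents in metres.
#' @param center_offset named 3-vector (right, down, forward) locating the
#'   workspace centre relative to the participant's eyes, metres.
#' @return A list of class `workspace_spec`.
#' @export
workspace_spec <- function(width = 0.3588, height = 0.2847, depth = 0.3726,
                           center_offset = c(right = 0, down = 0, forward = 0)) {
  for (nm in c("width", "height", "depth")) {
    .assert_scalar_num(get(nm), nm, positive = TRUE)
  }
  .assert(length(center_offset) == 3L && is.numeric(center_offset),
          "`center_offset` must be a numeric 3-vector")
  structure(list(width = width, height = height, depth = depth,
                 center_offset = center_offset),
            class = "workspace_spec")
}

#' Fruit collider geometry
#'
#' @param shape `"sphere"` or `"sphere_plus_capsule"` (the pear: a lower
#'   sphere plus an upper capsule).
#' @param sphere_diameter sphere diameter, m.
#' @param capsule_height,capsule_diameter capsule axis length and diameter, m
#'   (only for `"sphere_plus_capsule"`).
#' @return A list of class `collider_spec`.
#' @export
collider_spec <- function(shape = c("sphere", "sphere_plus_capsule"),
                          sphere_diameter,
                          capsule_height = NULL, capsule_diameter = NULL) {
  shape <- match.arg(shape)
  .assert_scalar_num(sphere_diameter, "sphere_diameter", positive = TRUE)
  if (shape == "sphere_plus_capsule") {
    .assert_scalar_num(capsule_height, "capsule_height", positive = TRUE)
    .assert_scalar_num(capsule_diameter, "capsule_diameter", positive = TRUE)
  }
  structure(list(shape = shape, sphere_diameter = sphere_diameter,
                 capsule_height = capsule_height,
                 capsule_diameter = capsule_diameter),
            class = "collider_spec")
}

validate_protocol <- function(p) {
  .assert(inherits(p, "reach_protocol"), "not a reach_protocol")
  total <- sum(p$blocks$n_fruits)
  expected <- if (p$experiment_id == "exp1") 102L else 48L
  .assert(total == expected, "block sizes sum to %d, expected %d", total, expected)
  .assert(all(p$blocks$n_fruits > 0), "all blocks must contain fruits")
  .assert(all(lengths(p$blocks$allowed) > 0), "allowed categories must be non-empty")
  .assert(nrow(p$locations) == 22L, "protocol must carry 22 target locations")
  .assert(identical(p$dwell_interval, c(0.4, 0.6)), "dwell interval must be [0.4, 0.6] s")
  invisible(p)
}

#' Classify a target location by depth usage
#'
#' Reaching movements are grouped into three categories depending on whether
#' the target offset from the workspace centre requires motion along the
#' depth axis: `no_depth` (horizontal and/or vertical only), `only_depth`
#' (depth axis alone), `combined_depth` (depth combined with at least one
#' other axis).
#'
#' @param offset numeric 3-vector (horizontal, vertical, depth) in metres.
#' @param tol axis-use tolerance in metres; a component with absolute value
#'   at most `tol` counts as unused. Default 1 mm.
#' @return One of `"no_depth"`, `"only_depth"`, `"combined_depth"`.
#' @examples
#' classify_depth_usage(c(0.10, 0.05, 0))    # "no_depth"
#' classify_depth_usage(c(0, 0, 0.12))       # "only_depth"
#' classify_depth_usage(c(0.10, 0, 0.10))    # "combined_depth"
#' @export
classify_depth_usage <- function(offset, tol = 0.001) {
  offset <- .vec3(offset, "offset")
  .assert_scalar_num(tol, "tol")
  used <- abs(offset) > tol
  .assert(any(used), "degenerate target at the workspace centre (all axes within tol)")
  if (!used[3]) return("no_depth")
  if (!used[1] && !used[2]) return("only_depth")
  "combined_depth"
}

#' Generate the canonical set of 22 target locations
#'
#' Places 22 targets inside the workspace with the documented depth-usage
#' structure: 8 `no_depth` (2 horizontal-only, 2 vertical-only, 4 combining
#' horizontal and vertical), 2 `only_depth` (one nearer, one farther than
#' the centre), and 12 `combined_depth` (8 using all three axes, 4 combining
#' depth with the horizontal axis). Exact coordinates are not part of the
#' published protocol, so targets sit at grid-aligned fractions (1/3, 2/3 of
#' the half-extent) with a small seeded within-class jitter on the axes each
#' class actually uses; unused axes are exact zeros.
#'
#' @param workspace a [workspace_spec()].
#' @param seed integer seed; the same seed always yields the same set.
#' @return A tibble with columns `location_id`, `x`, `y`, `z` (metres,
#'   offsets from the workspace centre), `subtype` and `depth_class`.
#' @export
generate_location_set <- function(workspace, seed = 1L) {
  .assert(inherits(workspace, "workspace_spec"), "`workspace` must be a workspace_spec")
  h <- c(workspace$width, workspace$height, workspace$depth) / 2

  base <- rbind(
    # no_depth: 2 horizontal-only, 2 vertical-only, 4 horizontal+vertical
    cbind(x = c(-2, 2) / 3, y = 0, z = 0, subtype = 1),
    cbind(x = 0, y = c(-2, 2) / 3, z = 0, subtype = 2),
    cbind(x = rep(c(-2, 2) / 3, each = 2), y = rep(c(-2, 2) / 3, 2), z = 0, subtype = 3),
    # only_depth: one nearer, one farther than the centre
    cbind(x = 0, y = 0, z = c(-2, 2) / 3, subtype = 4),
    # combined_depth: 8 three-axis corners + 4 depth+horizontal
    cbind(x = rep(c(-2, 2) / 3, each = 4),
          y = rep(rep(c(-1, 1) / 3, each = 2), 2),
          z = rep(c(-2, 2) / 3, 4), subtype = 5),
    cbind(x = rep(c(-2, 2) / 3, each = 2), y = 0, z = rep(c(-1, 1) * 0.5, 2), subtype = 6)
  )
  subtype_names <- c("horizontal", "vertical", "horizontal_vertical",
                     "depth_only", "three_axis", "depth_horizontal")

  coords <- .with_seed(seed, {
    out <- base[, c("x", "y", "z"), drop = FALSE]
    for (i in seq_len(nrow(out))) {
      for (j in 1:3) {
        if (out[i, j] != 0) {
          out[i, j] <- out[i, j] + runif(1, -1 / 12, 1 / 12)
        }
      }
    }
    out
  })
  coords <- sweep(coords, 2, h, `*`)

  tibble::tibble(
    location_id = seq_len(nrow(coords)),
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    subtype = subtype_names[base[, "subtype"]],
    depth_class = vapply(seq_len(nrow(coords)),
                         function(i) classify_depth_usage(coords[i, ]),
                         character(1))
  )
}

#' Plan the ordered fruit sequence of one session
#'
#' Draws, for a given protocol and seed, the ordered list of fruits to be
#' presented: block by block, assigning each fruit a category satisfying the
#' block constraints (pear-only blocks; blocks that must contain at least one
#' fruit of every allowed category) and a target location sampled from the
#' canonical 22-location set, avoiding immediate repeats of the same location.
#'
#' @param protocol a [build_protocol()] result.
#' @param seed integer seed; fixed seed gives an identical sequence.
#' @return A tibble with one row per fruit: `trial_index`, `block_index`,
#'   `fruit_kind`, `location_id`, `x`, `y`, `z`, `depth_class`.
#' @export
plan_trial_sequence <- function(protocol, seed = 1L) {
  validate_protocol(protocol)
  .with_seed(seed, {
    plan <- lapply(seq_len(nrow(protocol$blocks)), function(b) {
      n <- protocol$blocks$n_fruits[b]
      allowed <- protocol$blocks$allowed[[b]]
      if (isTRUE(protocol$blocks$require_all[b])) {
        .assert(n >= length(allowed),
                "block %d cannot contain every required category (%d fruits, %d categories)",
                b, n, length(allowed))
        kinds <- c(allowed, sample(allowed, n - length(allowed), replace = TRUE))
        kinds <- sample(kinds)
      } else {
        kinds <- sample(allowed, n, replace = TRUE)
      }
      tibble::tibble(block_index = protocol$blocks$block_index[b], fruit_kind = kinds)
    })
    plan <- dplyr::bind_rows(plan)

    n_total <- nrow(plan)
    loc_ids <- integer(n_total)
    prev <- 0L
    for (i in seq_len(n_total)) {
      pool <- setdiff(protocol$locations$location_id, prev)
      loc_ids[i] <- sample(pool, 1L)
      prev <- loc_ids[i]
    }
    plan$trial_index <- seq_len(n_total)
    plan$location_id <- loc_ids
    dplyr::select(
      dplyr::left_join(plan, protocol$locations[, c("location_id", "x", "y", "z", "depth_class")],
                       by = "location_id"),
      "trial_index", "block_index", "fruit_kind", "location_id",
      "x", "y", "z", "depth_class"
    )
  })
}

#' Serialize a protocol to YAML
#'
#' Writes the full protocol (units: metres, seconds) to a YAML file. Numeric
#' values are stored as 17-significant-digit decimal strings so the file
#' round-trips bit-exactly through [read_protocol_yaml()].
#'
#' @param protocol a `reach_protocol`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_protocol_yaml <- function(protocol, path) {
  validate_protocol(protocol)
  num <- function(x) format(x, digits = 17, scientific = FALSE, trim = TRUE)
  obj <- list(
    experiment_id = protocol$experiment_id,
    units = list(length = "m", time = "s"),
    workspace = list(
      width = num(protocol$workspace$width),
      height = num(protocol$workspace$height),
      depth = num(protocol$workspace$depth),
      center_offset = as.list(setNames(num(protocol$workspace$center_offset),
                                       c("right", "down", "forward")))
    ),
    blocks = lapply(seq_len(nrow(protocol$blocks)), function(i) list(
      block_index = protocol$blocks$block_index[i],
      n_fruits = protocol$blocks$n_fruits[i],
      allowed = as.list(protocol$blocks$allowed[[i]]),
      require_all = protocol$blocks$require_all[i]
    )),
    locations = lapply(seq_len(nrow(protocol$locations)), function(i) list(
      location_id = protocol$locations$location_id[i],
      x = num(protocol$locations$x[i]),
      y = num(protocol$locations$y[i]),
      z = num(protocol$locations$z[i]),
      subtype = protocol$locations$subtype[i],
      depth_class = protocol$locations$depth_class[i]
    )),
    dwell_interval = as.list(num(protocol$dwell_interval)),
    home_sphere_diameter = num(protocol$home_sphere_diameter),
    cursor_sphere_diameter = num(protocol$cursor_sphere_diameter),
    colliders = lapply(protocol$colliders, function(cl) {
      out <- list(shape = cl$shape, sphere_diameter = num(cl$sphere_diameter))
      if (!is.null(cl$capsule_height)) {
        out$capsule_height <- num(cl$capsule_height)
        out$capsule_diameter <- num(cl$capsule_diameter)
      }
      out
    })
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read a protocol back from YAML
#'
#' @param path file written by [write_protocol_yaml()].
#' @return A `reach_protocol` object.
#' @export
read_protocol_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  num <- function(x) as.numeric(x)
  locations <- dplyr::bind_rows(lapply(obj$locations, function(l) tibble::tibble(
    location_id = as.integer(l$location_id),
    x = num(l$x), y = num(l$y), z = num(l$z),
    subtype = l$subtype, depth_class = l$depth_class
  )))
  blocks <- tibble::tibble(
    block_index = vapply(obj$blocks, function(b) as.integer(b$block_index), integer(1)),
    n_fruits = vapply(obj$blocks, function(b) as.integer(b$n_fruits), integer(1)),
    allowed = lapply(obj$blocks, function(b) unlist(b$allowed)),
    require_all = vapply(obj$blocks, function(b) isTRUE(b$require_all), logical(1))
  )
  proto <- structure(list(
    experiment_id = obj$experiment_id,
    workspace = workspace_spec(
      width = num(obj$workspace$width), height = num(obj$workspace$height),
      depth = num(obj$workspace$depth),
      center_offset = setNames(num(unlist(obj$workspace$center_offset)),
                               c("right", "down", "forward"))
    ),
    blocks = blocks,
    locations = locations,
    dwell_interval = num(unlist(obj$dwell_interval)),
    home_sphere_diameter = num(obj$home_sphere_diameter),
    cursor_sphere_diameter = num(obj$cursor_sphere_diameter),
    colliders = lapply(obj$colliders, function(cl) collider_spec(
      shape = cl$shape, sphere_diameter = num(cl$sphere_diameter),
      capsule_height = if (is.null(cl$capsule_height)) NULL else num(cl$capsule_height),
      capsule_diameter = if (is.null(cl$capsule_diameter)) NULL else num(cl$capsule_diameter)
    ))
  ), class = "reach_protocol")
  validate_protocol(proto)
  proto
}
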